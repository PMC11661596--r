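## End-to-end orchestration: simulate -> (detect) -> bursts -> metrics ->
## stats from a single config, with a reproducibility manifest.

#' Run configuration
#'
#' @param profiles character vector of condition names ([mea_conditions()]).
#' @param n_wells wells per condition.
#' @param seed integer seed (recorded in the manifest).
#' @param out_dir output directory (created if missing).
#' @param duration_s recording length, seconds.
#' @param base a [baseline_params()].
#' @param dp,bp,np analysis parameter objects.
#' @return an object of class `run_config`.
#' @export
run_config <- function(profiles, n_wells = 8, seed = 1,
                       out_dir = tempfile("meaoxia_run_"), duration_s = 600,
                       base = baseline_params(), dp = detection_params(),
                       bp = burst_params(), np = network_burst_params()) {
    bad <- setdiff(profiles, mea_conditions())
    if (length(bad)) stop("unknown profile(s): ", paste(bad, collapse = ", "))
    structure(list(profiles = profiles, n_wells = n_wells,
                   seed = as.integer(seed), out_dir = out_dir,
                   duration_s = duration_s, base = base, dp = dp, bp = bp,
                   np = np), class = "run_config")
}

# Simulate and analyse one condition arm; returns the normalised tidy table.
.run_condition <- function(cfg, profile_name, seed) {
    profile <- condition_profile(profile_name)
    wells <- simulate_condition(profile, cfg$base, n_wells = cfg$n_wells,
                                seed = seed, duration_s = cfg$duration_s)
    tc <- do.call(rbind, lapply(wells, well_timecourse, dp = cfg$dp,
                                bp = cfg$bp, np = cfg$np))
    rownames(tc) <- NULL
    normalize_to_baseline(tc)
}

#' Run a full in silico experiment
#'
#' Simulates every configured condition over the complete recording
#' schedule, writes per-condition spike tables (baseline + recovery as a
#' compact sample), the tidy normalised time-course CSV, the group
#' mean +/- SEM summary CSV, a raster plot of the first well's baseline,
#' and a JSON manifest (config, seed, package version, output checksums).
#' Identical config + seed reproduce identical outputs.
#'
#' @param cfg a [run_config()].
#' @return list with `timecourse`, `summary`, `files`, `manifest`
#'   (invisibly writes everything under `cfg$out_dir`).
#' @export
run_experiment <- function(cfg) {
    stopifnot(inherits(cfg, "run_config"))
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    tcs <- list(); files <- character(0)
    for (i in seq_along(cfg$profiles)) {
        pn <- cfg$profiles[i]
        seed_i <- cfg$seed + 7919L * (i - 1L)
        profile <- condition_profile(pn)
        first_well <- simulate_experiment(profile, cfg$base, seed = seed_i,
                                          well_id = "W01",
                                          duration_s = cfg$duration_s)
        spike_file <- file.path(cfg$out_dir, paste0(pn, "_W01_baseline.tsv"))
        write_spike_table(first_well[[1]], spike_file)
        raster_file <- file.path(cfg$out_dir, paste0(pn, "_W01_raster.png"))
        export_raster(first_well[[1]],
                      window = c(0, min(60, cfg$duration_s)),
                      path = raster_file)
        files <- c(files, spike_file, raster_file)
        tcs[[pn]] <- .run_condition(cfg, pn, seed_i)
    }
    tc <- do.call(rbind, tcs); rownames(tc) <- NULL
    summ <- aggregate_timecourse(tc)
    tc_file <- file.path(cfg$out_dir, "timecourse.csv")
    summ_file <- file.path(cfg$out_dir, "summary.csv")
    utils::write.csv(tc, tc_file, row.names = FALSE)
    utils::write.csv(summ, summ_file, row.names = FALSE)
    files <- c(files, tc_file, summ_file)
    manifest <- list(
        package_version = as.character(utils::packageVersion("meaoxia")),
        seed = cfg$seed, profiles = cfg$profiles, n_wells = cfg$n_wells,
        duration_s = cfg$duration_s,
        checksums = as.list(setNames(tools::md5sum(files), basename(files))))
    man_file <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, man_file, auto_unbox = TRUE, pretty = TRUE)
    invisible(list(timecourse = tc, summary = summ,
                   files = c(files, man_file), manifest = manifest))
}

#' Compare two or more conditions statistically
#'
#' Runs (or accepts) normalised time courses for at least two conditions
#' and applies the statistical protocol to the recovery-phase normalised
#' NBR (and MFR): two-way ANOVA (condition x timepoint, Type III) on the
#' full treatment + recovery series, ROUT outlier report per condition at
#' recovery, and Tukey comparisons within timepoints.
#'
#' @param cfg a [run_config()] listing >= 2 profiles.
#' @param metric normalised metric column to analyse.
#' @return list with `anova`, `tukey`, `outliers`, `timecourse`.
#' @export
compare_conditions <- function(cfg, metric = "nbr_pct") {
    stopifnot(inherits(cfg, "run_config"))
    if (length(cfg$profiles) < 2)
        stop("compare_conditions needs at least 2 profiles")
    tcs <- lapply(seq_along(cfg$profiles), function(i)
        .run_condition(cfg, cfg$profiles[i], cfg$seed + 7919L * (i - 1L)))
    tc <- do.call(rbind, tcs); rownames(tc) <- NULL
    sub <- tc[tc$phase != "baseline" & !is.na(tc[[metric]]), , drop = FALSE]
    sub$timepoint_h <- factor(sub$timepoint_h)
    an <- two_way_anova(sub, metric, "condition", "timepoint_h")
    tk <- posthoc(an, "tukey")
    outl <- lapply(split(tc[tc$phase == "recovery", ],
                         tc$condition[tc$phase == "recovery"]),
                   function(g) rout_outliers(g[[metric]][!is.na(g[[metric]])]))
    list(anova = an, tukey = tk, outliers = outl, timecourse = tc)
}

#' Command-line entry point
#'
#' Thin dispatcher for `Rscript -e 'meaoxia::meaoxia_cli()' <cmd> ...` or
#' the installed `inst/cli/meaoxia` script. Subcommands: `simulate` (write
#' spike tables for one profile), `metrics` (spike table in, time-course
#' CSV out), `run` and `compare` (full pipeline from flags).
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
meaoxia_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
    usage <- paste(
        "usage: meaoxia <simulate|metrics|run|compare> [options]",
        "  simulate --profile <name> --wells <n> --seed <s> --out <dir>",
        "  metrics  --in <spike_table.tsv> --out <csv>",
        "  run      --profiles <a,b> --wells <n> --seed <s> --out <dir>",
        "  compare  --profiles <a,b> --wells <n> --seed <s>", sep = "\n")
    if (!length(args)) { message(usage); return(invisible(1L)) }
    cmd <- args[1]
    opt <- function(name, default = NULL) {
        i <- which(args == paste0("--", name))
        if (length(i) && i < length(args)) args[i + 1] else default
    }
    if (cmd == "simulate") {
        prof <- condition_profile(opt("profile", "normothermia_hypoxia"))
        out <- opt("out", "."); dir.create(out, showWarnings = FALSE,
                                           recursive = TRUE)
        wells <- simulate_condition(prof,
                                    n_wells = as.integer(opt("wells", "8")),
                                    seed = as.integer(opt("seed", "1")))
        sched <- mea_schedule()
        for (i in seq_len(nrow(sched))) {
            recs <- lapply(wells, `[[`, i)
            write_spike_table(recs, file.path(out,
                sprintf("%s_t%02g_%s.tsv", prof$name, sched$timepoint_h[i],
                        sched$phase[i])))
        }
        message("wrote ", nrow(sched), " spike tables to ", out)
    } else if (cmd == "metrics") {
        recs <- read_spike_table(opt("in"))
        rows <- do.call(rbind, lapply(recs, function(r) {
            m <- compute_metrics(r)
            data.frame(well_id = r$well_id, mfr = m$mfr, nbr = m$nbr,
                       nbd_ms = m$nbd_ms, n_active = m$n_active,
                       included = apply_inclusion(m))
        }))
        utils::write.csv(rows, opt("out", "metrics.csv"), row.names = FALSE)
    } else if (cmd %in% c("run", "compare")) {
        cfg <- run_config(strsplit(opt("profiles",
                                       "normothermia_hypoxia"), ",")[[1]],
                          n_wells = as.integer(opt("wells", "8")),
                          seed = as.integer(opt("seed", "1")),
                          out_dir = opt("out", tempfile("meaoxia_run_")))
        if (cmd == "run") run_experiment(cfg) else {
            cc <- compare_conditions(cfg)
            print(cc$anova)
            print(utils::head(cc$tukey[order(cc$tukey$p_adj), ], 20))
        }
    } else { message(usage); return(invisible(1L)) }
    invisible(0L)
}
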