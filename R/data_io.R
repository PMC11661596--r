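## Canonical data model for multiwell MEA recordings plus plain-text I/O.
## All times are seconds (64-bit doubles); all windows are half-open [t0, t1).

#' Experimental conditions, phases and the recording schedule
#'
#' A recording session covers one 10-minute baseline recording under
#' normoxia/normothermia, 24 treatment recordings every 2 h during the 48-h
#' exposure, and one recovery recording 6 h after physiological conditions
#' are restored (timepoint 54 h).
#'
#' @return `mea_conditions()` returns the condition names understood by
#'   [condition_profile()]; `mea_schedule()` returns a data.frame with
#'   columns `phase` and `timepoint_h`.
#' @export
mea_conditions <- function() {
    c("normothermia_hypoxia", "hypothermia_hypoxia", "hyperthermia_hypoxia",
      "hypothermia_normoxia", "hyperthermia_normoxia", "control_normoxia")
}

#' @rdname mea_conditions
#' @export
mea_schedule <- function() {
    data.frame(
        phase = c("baseline", rep("treatment", 24L), "recovery"),
        timepoint_h = c(0, seq(2, 48, by = 2), 54),
        stringsAsFactors = FALSE
    )
}

#' Recording metadata
#'
#' @param condition one of [mea_conditions()].
#' @param phase `"baseline"`, `"treatment"` or `"recovery"`.
#' @param timepoint_h hours since treatment onset (0 for baseline, 2--48 for
#'   treatment, 54 for the +6 h recovery recording).
#' @param duration_s recording length in seconds (default 600).
#' @return an object of class `recording_meta`.
#' @export
recording_meta <- function(condition, phase = "baseline", timepoint_h = 0,
                           duration_s = 600) {
    condition <- match.arg(condition, mea_conditions())
    phase <- match.arg(phase, c("baseline", "treatment", "recovery"))
    stopifnot(duration_s > 0)
    sched <- mea_schedule()
    ok <- any(sched$phase == phase & sched$timepoint_h == timepoint_h)
    if (!ok)
        stop("timepoint_h ", timepoint_h, " not in the ", phase, " schedule")
    structure(list(condition = condition, phase = phase,
                   timepoint_h = timepoint_h, duration_s = duration_s),
              class = "recording_meta")
}

#' Spike train for one electrode
#'
#' @param well_id well identifier.
#' @param electrode_id integer 0--11.
#' @param times spike times in seconds, strictly ascending, in
#'   `[0, duration)`.
#' @param duration recording length in seconds.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(well_id, electrode_id, times, duration) {
    electrode_id <- as.integer(electrode_id)
    stopifnot(electrode_id >= 0L, electrode_id <= 11L, duration > 0)
    times <- as.numeric(times)
    if (length(times)) {
        if (is.unsorted(times, strictly = TRUE))
            stop("spike times must be strictly ascending")
        if (times[1] < 0 || times[length(times)] >= duration)
            stop("spike times must lie in [0, duration)")
    }
    structure(list(well_id = as.character(well_id),
                   electrode_id = electrode_id,
                   times = times, duration = as.numeric(duration)),
              class = "spike_train")
}

#' Raw voltage trace for one electrode
#'
#' @param well_id,electrode_id identifiers as in [spike_train()].
#' @param samples voltages in microvolts.
#' @param sampling_rate Hz (default 10000).
#' @return an object of class `electrode_trace`.
#' @export
electrode_trace <- function(well_id, electrode_id, samples,
                            sampling_rate = 10000) {
    stopifnot(sampling_rate > 0)
    structure(list(well_id = as.character(well_id),
                   electrode_id = as.integer(electrode_id),
                   samples = as.numeric(samples),
                   sampling_rate = sampling_rate),
              class = "electrode_trace")
}

#' One well of a multiwell MEA recording
#'
#' A well always carries exactly 12 electrodes; electrodes without spikes are
#' represented as empty trains (never dropped), and are excluded downstream
#' by the activity criterion rather than at I/O time.
#'
#' @param well_id well identifier.
#' @param meta a [recording_meta()].
#' @param trains list of up to 12 [spike_train()]s (missing electrodes are
#'   filled with empty trains).
#' @param traces optional list of 12 [electrode_trace()]s.
#' @param truth optional generator ground truth (see [simulate_recording()]).
#' @return an object of class `well_recording`.
#' @export
well_recording <- function(well_id, meta, trains = NULL, traces = NULL,
                           truth = NULL) {
    stopifnot(inherits(meta, "recording_meta"))
    full <- vector("list", 12L)
    for (tr in trains %||% list()) {
        stopifnot(inherits(tr, "spike_train"))
        if (!is.null(full[[tr$electrode_id + 1L]]))
            stop("duplicate electrode_id ", tr$electrode_id,
                 " in well ", well_id)
        full[[tr$electrode_id + 1L]] <- tr
    }
    for (e in which(vapply(full, is.null, logical(1))))
        full[[e]] <- spike_train(well_id, e - 1L, numeric(0), meta$duration_s)
    structure(list(well_id = as.character(well_id), meta = meta,
                   trains = full, traces = traces, truth = truth),
              class = "well_recording")
}

#' @export
print.well_recording <- function(x, ...) {
    n <- sum(vapply(x$trains, function(t) length(t$times), integer(1)))
    cat(sprintf("<well_recording> well %s | %s / %s / %g h | %g s | %d spikes\n",
                x$well_id, x$meta$condition, x$meta$phase,
                x$meta$timepoint_h, x$meta$duration_s, n))
    invisible(x)
}

.meta_line <- function(rec) {
    m <- rec$meta
    sprintf("# well=%s condition=%s phase=%s timepoint_h=%g duration_s=%g",
            rec$well_id, m$condition, m$phase, m$timepoint_h, m$duration_s)
}

#' Write spike tables
#'
#' The native on-disk format is a TSV with a `#`-prefixed metadata header:
#' one `# well=...` line per well (condition, phase, timepoint, duration)
#' followed by the columns `well_id`, `electrode_id`, `spike_time_s`. The
#' format round-trips losslessly with [read_spike_table()] to 1e-6 s.
#'
#' @param recordings a `well_recording` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(recordings, path) {
    if (inherits(recordings, "well_recording"))
        recordings <- list(recordings)
    con <- try(file(path, "w"), silent = TRUE)
    if (inherits(con, "try-error")) stop("cannot write to ", path)
    on.exit(close(con))
    writeLines("# mea_spike_table v1", con)
    for (rec in recordings) writeLines(.meta_line(rec), con)
    writeLines("well_id\telectrode_id\tspike_time_s", con)
    for (rec in recordings) {
        for (tr in rec$trains) {
            if (!length(tr$times)) next
            writeLines(sprintf("%s\t%d\t%.6f", tr$well_id, tr$electrode_id,
                               tr$times), con)
        }
    }
    invisible(path)
}

#' Read spike tables
#'
#' @param path a file written by [write_spike_table()] (or hand-built in the
#'   same format).
#' @return a named list of [well_recording()]s, in header order.
#' @export
read_spike_table <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    hdr <- grepl("^#", lines)
    if (!length(lines) || lines[1] != "# mea_spike_table v1")
        stop("not a mea_spike_table file: ", path)
    metas <- list()
    for (ln in lines[hdr][-1]) {
        toks <- strsplit(sub("^#\\s*", "", ln), "\\s+")[[1]]
        kv <- strsplit(toks, "=", fixed = TRUE)
        vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
        if (is.na(vals["well"])) stop("malformed header line: ", ln)
        metas[[vals[["well"]]]] <- recording_meta(
            condition = vals[["condition"]], phase = vals[["phase"]],
            timepoint_h = as.numeric(vals[["timepoint_h"]]),
            duration_s = as.numeric(vals[["duration_s"]]))
    }
    if (!length(metas)) stop("no '# well=' header lines in ", path)
    body_idx <- which(!hdr)
    if (!length(body_idx) || lines[body_idx[1]] !=
            "well_id\telectrode_id\tspike_time_s")
        stop("missing column header line in ", path)
    data_idx <- body_idx[-1]
    data_idx <- data_idx[nzchar(lines[data_idx])]
    df <- data.frame(well_id = character(0), electrode_id = integer(0),
                     spike_time_s = numeric(0))
    if (length(data_idx)) {
        parts <- strsplit(lines[data_idx], "\t", fixed = TRUE)
        bad <- which(lengths(parts) != 3L)
        if (length(bad))
            stop("malformed row at line ", data_idx[bad[1]], " of ", path)
        df <- data.frame(
            well_id = vapply(parts, `[`, "", 1L),
            electrode_id = suppressWarnings(
                as.integer(vapply(parts, `[`, "", 2L))),
            spike_time_s = suppressWarnings(
                as.numeric(vapply(parts, `[`, "", 3L))),
            stringsAsFactors = FALSE)
        bad <- which(is.na(df$electrode_id) | is.na(df$spike_time_s))
        if (length(bad))
            stop("malformed row at line ", data_idx[bad[1]], " of ", path)
    }
    out <- list()
    for (w in names(metas)) {
        meta <- metas[[w]]
        sub <- df[df$well_id == w, , drop = FALSE]
        if (any(sub$spike_time_s >= meta$duration_s))
            stop("spike_time_s >= duration_s in well ", w)
        trains <- list()
        for (e in sort(unique(sub$electrode_id))) {
            tt <- sort(sub$spike_time_s[sub$electrode_id == e])
            dup <- duplicated(tt)
            if (any(dup)) {
                warning(sum(dup), " duplicate spike time(s) collapsed on well ",
                        w, " electrode ", e)
                tt <- tt[!dup]
            }
            trains[[length(trains) + 1L]] <- spike_train(w, e, tt,
                                                         meta$duration_s)
        }
        out[[w]] <- well_recording(w, meta, trains)
    }
    unknown <- setdiff(unique(df$well_id), names(metas))
    if (length(unknown))
        stop("data rows for undeclared well(s): ",
             paste(unknown, collapse = ", "))
    out
}

#' Export a raster plot of one well
#'
#' One row per electrode, one tick per spike falling in the half-open window
#' `[t0, t1)`. Output is deterministic for a fixed recording and style.
#'
#' @param recording a [well_recording()].
#' @param window numeric `c(t0, t1)`, seconds; defaults to the full recording.
#' @param path output file; extension selects the device (`.png` or `.svg`).
#' @param width,height device size in pixels (png) or inches (svg).
#' @return `path`, invisibly; the number of ticks drawn as attribute
#'   `"n_ticks"`.
#' @export
export_raster <- function(recording, window = NULL, path = "raster.png",
                          width = 900, height = 400) {
    dur <- recording$meta$duration_s
    if (is.null(window)) window <- c(0, dur)
    t0 <- window[1]; t1 <- window[2]
    if (!(t0 < t1) || t0 < 0 || t1 > dur)
        stop("window must satisfy 0 <= t0 < t1 <= duration")
    ext <- tolower(sub(".*\\.", "", path))
    if (ext == "svg") svg(path, width = width / 100, height = height / 100)
    else png(path, width = width, height = height)
    on.exit(dev.off())
    plot.new()
    plot.window(xlim = c(t0, t1), ylim = c(0.5, 12.5))
    n_ticks <- 0L
    for (tr in recording$trains) {
        tt <- tr$times[tr$times >= t0 & tr$times < t1]
        n_ticks <- n_ticks + length(tt)
        if (length(tt))
            segments(tt, tr$electrode_id + 0.7, tt, tr$electrode_id + 1.3)
    }
    axis(1); axis(2, at = 1:12, labels = 0:11, las = 1)
    title(xlab = "time (s)", ylab = "electrode",
          main = sprintf("%s  %s %g h", recording$well_id,
                         recording$meta$phase, recording$meta$timepoint_h))
    box()
    out <- path
    attr(out, "n_ticks") <- n_ticks
    invisible(out)
}
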