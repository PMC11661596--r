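## Per-recording network metrics (MFR / NBR / NBD), inclusion criteria,
## per-well baseline normalisation and condition-level aggregation.

#' Compute MFR, NBR and NBD for one recording
#'
#' MFR is the mean firing rate over active electrodes (spikes/s); NBR the
#' network burst count per minute; NBD the mean network burst duration in
#' ms, undefined (NA) when no network bursts were detected. A recording
#' with no active electrodes has MFR 0 and `mfr_defined = FALSE`.
#'
#' @param recording a [well_recording()] with spike trains.
#' @param dp a [detection_params()] (activity criterion).
#' @param bp a [burst_params()].
#' @param np a [network_burst_params()].
#' @return an object of class `network_metrics`: a list with `mfr`, `nbr`,
#'   `nbd_ms`, `n_active`, `n_bursting`, `n_network_bursts`, `mfr_defined`.
#' @export
compute_metrics <- function(recording, dp = detection_params(),
                            bp = burst_params(),
                            np = network_burst_params()) {
    stopifnot(inherits(recording, "well_recording"))
    dur <- recording$meta$duration_s
    rates <- vapply(recording$trains, function(t)
        length(t$times) / t$duration, numeric(1))
    act <- rates >= dp$active_rate_min
    mfr <- if (any(act)) mean(rates[act]) else 0
    b <- well_bursts(recording, bp)
    nb <- detect_network_bursts(recording, bp, np, bursts = b)
    nbd <- if (nrow(nb)) mean(nb$end_s - nb$start_s) * 1000 else NA_real_
    structure(list(mfr = mfr, nbr = nrow(nb) / (dur / 60), nbd_ms = nbd,
                   n_active = sum(act),
                   n_bursting = length(bursting_channels(recording, bp,
                                                         bursts = b)),
                   n_network_bursts = nrow(nb), mfr_defined = any(act)),
              class = "network_metrics")
}

#' Network inclusion criterion
#'
#' A network is included in analysis iff MFR > `mfr_min` AND NBR >
#' `nbr_min`; both inequalities strict.
#'
#' @param metrics a `network_metrics` object (or anything with `mfr`/`nbr`).
#' @param mfr_min spikes/s (default 0.1).
#' @param nbr_min network bursts/min (default 1).
#' @return logical.
#' @export
apply_inclusion <- function(metrics, mfr_min = 0.1, nbr_min = 1) {
    isTRUE(metrics$mfr > mfr_min && metrics$nbr > nbr_min)
}

#' Tidy metrics time course for one well
#'
#' @param recordings the schedule list for one well (see
#'   [simulate_experiment()]), spike trains present.
#' @param dp,bp,np parameter objects as in [compute_metrics()].
#' @return data.frame, one row per recording: identifiers, raw metrics and
#'   the baseline inclusion flag.
#' @export
well_timecourse <- function(recordings, dp = detection_params(),
                            bp = burst_params(),
                            np = network_burst_params()) {
    rows <- lapply(recordings, function(rec) {
        m <- compute_metrics(rec, dp, bp, np)
        data.frame(well_id = rec$well_id, condition = rec$meta$condition,
                   phase = rec$meta$phase,
                   timepoint_h = rec$meta$timepoint_h,
                   mfr = m$mfr, nbr = m$nbr, nbd_ms = m$nbd_ms,
                   n_active = m$n_active, n_bursting = m$n_bursting,
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    base <- df[df$phase == "baseline", , drop = FALSE]
    if (nrow(base) != 1L) stop("well must have exactly one baseline recording")
    df$included <- apply_inclusion(list(mfr = base$mfr, nbr = base$nbr))
    df
}

#' Normalise a well time course to its own baseline
#'
#' Adds `mfr_pct`, `nbr_pct`, `nbd_pct`: each metric as 100 x value /
#' baseline value of the same well. A metric whose baseline is zero (or,
#' for NBD, undefined) gives a missing normalised series; timepoints with
#' no network bursts have missing `nbd_pct` (not zero). Wells whose
#' baseline fails the inclusion criterion are dropped with a message.
#'
#' @param df output of [well_timecourse()] (one or several wells row-bound).
#' @return the data.frame with normalised columns, excluded wells removed.
#' @export
normalize_to_baseline <- function(df) {
    keep <- unique(df$well_id[df$included])
    dropped <- setdiff(unique(df$well_id), keep)
    if (length(dropped))
        message("dropping ", length(dropped),
                " well(s) failing baseline inclusion: ",
                paste(dropped, collapse = ", "))
    df <- df[df$well_id %in% keep, , drop = FALSE]
    norm_one <- function(sub) {
        base <- sub[sub$phase == "baseline", ]
        pct <- function(x, b) if (is.na(b) || b <= 0) rep(NA_real_,
                                                          length(x))
                              else 100 * x / b
        sub$mfr_pct <- pct(sub$mfr, base$mfr)
        sub$nbr_pct <- pct(sub$nbr, base$nbr)
        sub$nbd_pct <- pct(sub$nbd_ms, base$nbd_ms)
        sub
    }
    if (!nrow(df)) {
        df$mfr_pct <- df$nbr_pct <- df$nbd_pct <- numeric(0)
        return(df)
    }
    out <- do.call(rbind, lapply(split(df, df$well_id), norm_one))
    rownames(out) <- NULL
    out
}

#' Group mean and SEM per timepoint
#'
#' Aggregates a normalised time course over the included wells of one or
#' several conditions. SEM = SD / sqrt(n); NA values (e.g. NBD at no-burst
#' timepoints) are excluded from that metric's n.
#'
#' @param df output of [normalize_to_baseline()].
#' @param metrics which columns to summarise.
#' @return data.frame with columns `condition`, `phase`, `timepoint_h`,
#'   `metric`, `mean`, `sem`, `n`.
#' @export
aggregate_timecourse <- function(df, metrics = c("mfr_pct", "nbr_pct",
                                                 "nbd_pct")) {
    groups <- split(df, list(df$condition, df$timepoint_h), drop = TRUE)
    rows <- lapply(groups, function(g) {
        do.call(rbind, lapply(metrics, function(m) {
            v <- g[[m]]; v <- v[!is.na(v)]
            n <- length(v)
            data.frame(condition = g$condition[1], phase = g$phase[1],
                       timepoint_h = g$timepoint_h[1], metric = m,
                       mean = if (n) mean(v) else NA_real_,
                       sem = if (n > 1) sd(v) / sqrt(n) else
                             if (n == 1) 0 else NA_real_,
                       n = n, stringsAsFactors = FALSE)
        }))
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$condition, out$timepoint_h, out$metric), ]
    rownames(out) <- NULL
    out
}

#' Earliest timepoint of complete activity loss
#'
#' Scans the treatment timepoints of a (raw, unnormalised) time course and
#' returns the first at which every well's MFR and NBR are both zero, or NA
#' if activity never fully ceases.
#'
#' @param df output of [well_timecourse()] rows for one condition.
#' @return hours (numeric scalar) or NA.
#' @export
loss_of_activity_time <- function(df) {
    tr <- df[df$phase == "treatment", , drop = FALSE]
    for (t in sort(unique(tr$timepoint_h))) {
        sub <- tr[tr$timepoint_h == t, ]
        if (all(sub$mfr == 0) && all(sub$nbr == 0)) return(t)
    }
    NA_real_
}
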