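## Synthetic MEA experiments: tonic Poisson firing per electrode plus shared
## network-burst events whose rate and duration follow a condition profile.
## The generator records its own ground truth so every detection stage can
## be scored without external labels.

#' Baseline activity parameters for the generator
#'
#' Defaults describe a healthy hiPSC-derived network at baseline that
#' comfortably passes the inclusion criteria (MFR > 0.1 spikes/s,
#' NBR > 1/min): tonic firing 1 spike/s per electrode, 2 network bursts/min
#' of 500 ms involving 10 of 12 electrodes. Spikes inside a burst are laid
#' out at `isi_in_burst_ms` spacing, so the spike count per burst follows
#' the burst duration (a fixed count per burst cannot respect the 50 ms
#' intra-burst ISI rule across the duration range the profiles span).
#'
#' @param tonic_rate tonic firing rate per electrode, spikes/s.
#' @param nbr_per_min baseline network burst rate, events/min.
#' @param nbd_ms baseline network burst duration, ms.
#' @param isi_in_burst_ms spacing of spikes within a burst, ms (< 50).
#' @param n_participating electrodes recruited per network burst (>= 6).
#' @param jitter_ms per-channel onset jitter within an event, +/- ms.
#' @param event_dur_cv lognormal CV of per-event duration.
#' @param well_cv lognormal well-to-well CV applied to the recovery-phase
#'   multipliers (across-well dispersion; within-recording dispersion comes
#'   from the Poisson draws).
#' @return an object of class `baseline_params`.
#' @export
baseline_params <- function(tonic_rate = 1, nbr_per_min = 2, nbd_ms = 500,
                            isi_in_burst_ms = 40, n_participating = 10,
                            jitter_ms = 10, event_dur_cv = 0.1,
                            well_cv = 0.2) {
    stopifnot(tonic_rate > 0, nbr_per_min > 0, nbd_ms > 0,
              isi_in_burst_ms > 0, isi_in_burst_ms <= 50,
              n_participating >= 6, n_participating <= 12,
              jitter_ms >= 0, event_dur_cv >= 0, well_cv >= 0)
    structure(as.list(environment()), class = "baseline_params")
}

# Spikes per burst of duration dur_s at the configured intra-burst spacing;
# never below the 4-spike detection minimum.
.spikes_per_burst <- function(dur_s, isi_s) {
    pmax(4L, as.integer(ceiling(dur_s / isi_s)) + 1L)
}

# Expected per-electrode spike rate (spikes/s) contributed by network-burst
# events at the given multipliers.
.burst_rate_contrib <- function(base, nbr_mult, nbd_mult) {
    dur <- base$nbd_ms / 1000 * nbd_mult
    nspk <- .spikes_per_burst(dur, base$isi_in_burst_ms / 1000)
    (base$nbr_per_min * nbr_mult / 60) * (base$n_participating / 12) * nspk
}

# Multipliers for one scheduled recording. The profile's mfr multiplier
# targets the *total* per-electrode rate (the observable MFR); the tonic
# component is back-solved from it, so pipeline-normalised MFR tracks the
# profile directly.
.recording_mult <- function(profile, meta) {
    if (meta$phase == "recovery") {
        rf <- profile$recovery_frac
        list(mfr = rf[["mfr"]], nbr = rf[["nbr"]], nbd = rf[["nbd"]])
    } else if (meta$phase == "baseline") {
        list(mfr = 1, nbr = 1, nbd = 1)
    } else {
        fr <- profile_frac(profile, meta$timepoint_h)
        list(mfr = fr$mfr, nbr = fr$nbr, nbd = fr$nbd)
    }
}

#' Simulate one 10-minute well recording
#'
#' Network-burst events are drawn as a Poisson process at rate
#' `nbr_per_min * nbr_mult` (events closer than 200 ms to the previous
#' event's end are thinned so that distinct events remain distinct to the
#' detector; realised events are the recorded ground truth). Each event
#' recruits `n_participating` electrodes; every recruited electrode receives
#' one burst of duration `nbd_ms * nbd_mult` (lognormal per-event
#' variability), offset by a per-channel jitter, with spikes evenly spaced
#' at `isi_in_burst_ms`. Independent tonic Poisson spikes top the electrode
#' up to the profile's target total rate. A fixed seed gives identical
#' output.
#'
#' @param profile a [condition_profile()].
#' @param base a [baseline_params()].
#' @param meta a [recording_meta()].
#' @param seed optional integer seed (restores the caller's RNG state).
#' @param well_id well identifier.
#' @param mult optional list(mfr, nbr, nbd) overriding the profile at this
#'   recording (used for per-well recovery variability).
#' @return a [well_recording()] whose `truth` field holds the realised
#'   events (`data.frame(start, end, n_channels)`), the multipliers and the
#'   expected rates.
#' @export
simulate_recording <- function(profile, base, meta, seed = NULL,
                               well_id = "W01", mult = NULL) {
    stopifnot(inherits(profile, "condition_profile"),
              inherits(base, "baseline_params"),
              inherits(meta, "recording_meta"))
    mult <- mult %||% .recording_mult(profile, meta)
    if (any(unlist(mult) < 0)) stop("negative rate multiplier")
    with_seed(seed, {
        dur_rec <- meta$duration_s
        isi <- base$isi_in_burst_ms / 1000
        jit <- base$jitter_ms / 1000
        nbd_s <- base$nbd_ms / 1000 * mult$nbd

        ## --- network-burst events ---------------------------------------
        lam_ev <- base$nbr_per_min / 60 * mult$nbr
        n_ev <- if (lam_ev > 0 && nbd_s > 0) rpois(1, lam_ev * dur_rec) else 0L
        spikes <- vector("list", 12L)
        events <- data.frame(start = numeric(0), end = numeric(0),
                             n_channels = integer(0))
        if (n_ev > 0) {
            margin <- nbd_s * 1.5 + 0.1
            starts <- sort(runif(n_ev, margin, max(margin + 1e-6,
                                                   dur_rec - margin)))
            if (base$event_dur_cv > 0) {
                s <- sqrt(log(1 + base$event_dur_cv^2))
                durs <- nbd_s * rlnorm(n_ev, -s^2 / 2, s)
            } else durs <- rep(nbd_s, n_ev)
            keep <- rep(TRUE, n_ev)
            last_end <- -Inf
            for (i in seq_len(n_ev)) {
                if (starts[i] < last_end + 0.2) keep[i] <- FALSE
                else last_end <- starts[i] + durs[i]
            }
            starts <- starts[keep]; durs <- durs[keep]
            ev_nch <- integer(length(starts))
            for (i in seq_along(starts)) {
                chans <- sample.int(12L, base$n_participating) - 1L
                ev_nch[i] <- length(chans)
                nspk <- .spikes_per_burst(durs[i], isi)
                for (ch in chans) {
                    t0 <- starts[i] + runif(1, -jit, jit)
                    tt <- t0 + seq(0, durs[i], length.out = nspk)
                    spikes[[ch + 1L]] <- c(spikes[[ch + 1L]], tt)
                }
            }
            events <- data.frame(start = starts, end = starts + durs,
                                 n_channels = ev_nch)
        }

        ## --- tonic top-up to the target total rate ----------------------
        base_total <- base$tonic_rate + .burst_rate_contrib(base, 1, 1)
        target_total <- base_total * mult$mfr
        contrib <- .burst_rate_contrib(base, mult$nbr, mult$nbd)
        lam_tonic <- max(0, target_total - contrib)
        for (e in 1:12) {
            n <- rpois(1, lam_tonic * dur_rec)
            if (n > 0)
                spikes[[e]] <- c(spikes[[e]], runif(n, 0, dur_rec))
        }

        trains <- vector("list", 12L)
        for (e in 1:12) {
            tt <- sort(spikes[[e]] %||% numeric(0))
            tt <- tt[tt >= 0 & tt < dur_rec]
            if (length(tt) > 1) tt <- tt[c(TRUE, diff(tt) > 1e-9)]
            trains[[e]] <- spike_train(well_id, e - 1L, tt, dur_rec)
        }
        truth <- list(events = events, mult = mult,
                      tonic_rate = lam_tonic, target_total_rate = target_total)
        well_recording(well_id, meta, trains, truth = truth)
    })
}

#' Simulate the full recording schedule for one well
#'
#' Emits 26 recordings: baseline, 24 treatment recordings (2--48 h every
#' 2 h) and the +6 h recovery recording, each `duration_s` long. Recovery
#' multipliers are drawn around the profile's `recovery_frac` with
#' well-to-well lognormal variability (`well_cv`).
#'
#' @inheritParams simulate_recording
#' @param duration_s recording length, seconds.
#' @return a list of 26 [well_recording()]s in schedule order.
#' @export
simulate_experiment <- function(profile, base = baseline_params(),
                                seed = NULL, well_id = "W01",
                                duration_s = 600) {
    with_seed(seed, {
        sched <- mea_schedule()
        rf <- profile$recovery_frac
        if (base$well_cv > 0) {
            s <- sqrt(log(1 + base$well_cv^2))
            wmult <- rlnorm(3, -s^2 / 2, s)
        } else wmult <- rep(1, 3)
        rec_mult <- list(mfr = rf[["mfr"]] * wmult[1],
                         nbr = rf[["nbr"]] * wmult[2],
                         nbd = rf[["nbd"]] * wmult[3])
        lapply(seq_len(nrow(sched)), function(i) {
            meta <- recording_meta(profile$name, sched$phase[i],
                                   sched$timepoint_h[i], duration_s)
            mult <- if (sched$phase[i] == "recovery") rec_mult else NULL
            simulate_recording(profile, base, meta, seed = NULL,
                               well_id = well_id, mult = mult)
        })
    })
}

#' Simulate a multi-well condition arm
#'
#' @inheritParams simulate_experiment
#' @param n_wells number of wells.
#' @return a named list (one entry per well) of schedule lists as returned
#'   by [simulate_experiment()].
#' @export
simulate_condition <- function(profile, base = baseline_params(),
                               n_wells = 20, seed = NULL,
                               duration_s = 600) {
    with_seed(seed, {
        wells <- sprintf("W%02d", seq_len(n_wells))
        setNames(lapply(wells, function(w)
            simulate_experiment(profile, base, seed = NULL, well_id = w,
                                duration_s = duration_s)), wells)
    })
}

#' Spike waveform parameters for trace rendering
#'
#' @param amplitude_uv peak (negative-phase) amplitude, microvolts.
#' @param noise_sd_uv Gaussian background noise SD, microvolts.
#' @param sampling_rate Hz.
#' @return an object of class `waveform_params`.
#' @export
waveform_params <- function(amplitude_uv = 50, noise_sd_uv = 3,
                            sampling_rate = 10000) {
    stopifnot(amplitude_uv >= 0, noise_sd_uv > 0, sampling_rate > 0)
    structure(list(amplitude_uv = amplitude_uv, noise_sd_uv = noise_sd_uv,
                   sampling_rate = sampling_rate),
              class = "waveform_params")
}

# Biphasic extracellular spike template (sharp negative trough followed by a
# slower positive rebound), ~1.6 ms long, trough normalised to -1 at a known
# offset.
.spike_template <- function(sampling_rate) {
    t <- seq(0, 1.6e-3, by = 1 / sampling_rate)
    w <- -exp(-((t - 4e-4) / 1.2e-4)^2) + 0.35 * exp(-((t - 8e-4) / 3e-4)^2)
    w <- w / abs(min(w))
    list(w = w, trough_offset = which.min(w) - 1L)
}

#' Render spike trains into noisy voltage traces
#'
#' Each spike places the biphasic template so its trough lands at the spike
#' time; Gaussian noise of SD `noise_sd_uv` is added. Ground-truth spike
#' times are retained in the returned recording, so detector sensitivity can
#' be scored exactly. Memory scales with `duration_s * sampling_rate * 12`;
#' use short recordings for trace-level work.
#'
#' @param recording a [well_recording()] with spike trains.
#' @param wf a [waveform_params()].
#' @param seed optional integer seed.
#' @return the recording with `traces` filled in and `truth$spike_times`
#'   set; spikes closer than the template width are summed (overlapped) and
#'   their count reported as attribute `"n_overlapped"` of the traces list.
#' @export
render_traces <- function(recording, wf = waveform_params(), seed = NULL) {
    stopifnot(inherits(recording, "well_recording"),
              inherits(wf, "waveform_params"))
    with_seed(seed, {
        fs <- wf$sampling_rate
        n <- round(recording$meta$duration_s * fs)
        tmpl <- .spike_template(fs)
        w <- tmpl$w * wf$amplitude_uv
        lw <- length(w)
        n_overlap <- 0L
        traces <- vector("list", 12L)
        for (e in 1:12) {
            x <- rnorm(n, 0, wf$noise_sd_uv)
            tt <- recording$trains[[e]]$times
            if (length(tt)) {
                idx <- round(tt * fs) - tmpl$trough_offset
                d <- diff(sort(round(tt * fs)))
                n_overlap <- n_overlap + sum(d < lw)
                for (i0 in idx) {
                    a <- max(1L, i0 + 1L); b <- min(n, i0 + lw)
                    if (b >= a)
                        x[a:b] <- x[a:b] + w[(a - i0):(b - i0)]
                }
            }
            traces[[e]] <- electrode_trace(recording$well_id, e - 1L, x, fs)
        }
        if (n_overlap > 0)
            message(n_overlap, " spike pair(s) closer than the template width",
                    " were overlapped")
        attr(traces, "n_overlapped") <- n_overlap
        recording$traces <- traces
        recording$truth$spike_times <- lapply(recording$trains,
                                              function(t) t$times)
        recording
    })
}
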