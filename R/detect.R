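## Spike detection: Butterworth band filtering (zero-phase), robust noise
## estimation, 5-sigma bipolar threshold crossing, activity classification.

#' Band filter specification
#'
#' Defaults are the acquisition chain of the assay: 2nd-order Butterworth
#' high-pass at 100 Hz and 4th-order Butterworth low-pass at 3.5 kHz,
#' applied zero-phase (forward-backward) so channel latencies are not
#' shifted.
#'
#' @param highpass_hz,highpass_order high-pass cutoff (Hz) and order.
#' @param lowpass_hz,lowpass_order low-pass cutoff (Hz) and order.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_hz = 100, highpass_order = 2,
                        lowpass_hz = 3500, lowpass_order = 4) {
    stopifnot(highpass_hz > 0, lowpass_hz > highpass_hz,
              highpass_order >= 1, lowpass_order >= 1)
    structure(list(highpass_hz = highpass_hz, highpass_order = highpass_order,
                   lowpass_hz = lowpass_hz, lowpass_order = lowpass_order),
              class = "filter_spec")
}

# Digital Butterworth design via the bilinear transform (matches the usual
# scipy/Matlab butter() coefficients). cutoff in Hz, fs in Hz.
butter_coefficients <- function(order, cutoff_hz, fs, type = c("low", "high")) {
    type <- match.arg(type)
    if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
        stop("cutoff must lie strictly below the Nyquist frequency")
    Wn <- cutoff_hz / (fs / 2)
    fs2 <- 2
    warped <- 2 * fs2 * tan(pi * Wn / fs2)
    k <- seq_len(order)
    p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP prototype
    if (type == "low") {
        p <- warped * p
        z <- complex(0)
        gain <- warped^order
    } else {
        z <- rep(0 + 0i, order)
        p <- warped / p
        gain <- 1
    }
    ## bilinear transform
    fs2x2 <- 2 * fs2
    pz <- (fs2x2 + p) / (fs2x2 - p)
    zz <- if (length(z)) (fs2x2 + z) / (fs2x2 - z) else complex(0)
    gain <- gain * Re(prod(fs2x2 - z) / prod(fs2x2 - p))
    zz <- c(zz, rep(-1 + 0i, order - length(zz)))  # zeros at infinity -> -1
    b <- Re(.poly_from_roots(zz)) * gain
    a <- Re(.poly_from_roots(pz))
    list(b = b, a = a)
}

.poly_from_roots <- function(r) {
    p <- 1 + 0i
    for (ri in r) p <- c(p, 0) - c(0, p * ri)
    p
}

# Zero-phase IIR filtering: odd-reflection padding, forward pass, reverse,
# forward pass again, un-pad (filtfilt).
filtfilt_iir <- function(b, a, x) {
    n <- length(x)
    pad <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L), 250L))
    if (pad < 1L) return(iir_filter_cpp(b, a, rev(iir_filter_cpp(b, a, x))))
    pre <- 2 * x[1] - x[(pad + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - pad)]
    ext <- c(pre, x, post)
    y <- iir_filter_cpp(b, a, ext)
    y <- rev(iir_filter_cpp(b, a, rev(y)))
    y[(pad + 1L):(pad + n)]
}

#' Band-filter an electrode trace
#'
#' Applies the high-pass then the low-pass Butterworth filter, each
#' zero-phase (forward-backward), so the DC component is rejected and
#' in-band amplitudes/latencies are preserved.
#'
#' @param trace an [electrode_trace()].
#' @param spec a [filter_spec()].
#' @return the filtered [electrode_trace()].
#' @export
bandpass <- function(trace, spec = filter_spec()) {
    stopifnot(inherits(trace, "electrode_trace"),
              inherits(spec, "filter_spec"))
    fs <- trace$sampling_rate
    if (spec$lowpass_hz >= fs / 2)
        stop("low-pass cutoff at or above Nyquist (", fs / 2, " Hz)")
    hp <- butter_coefficients(spec$highpass_order, spec$highpass_hz, fs, "high")
    lp <- butter_coefficients(spec$lowpass_order, spec$lowpass_hz, fs, "low")
    x <- filtfilt_iir(hp$b, hp$a, trace$samples)
    x <- filtfilt_iir(lp$b, lp$a, x)
    trace$samples <- x
    trace
}

#' Robust noise SD of a filtered trace
#'
#' `median(|x|) / 0.6745`, the MAD-about-zero estimator: sparse large spikes
#' barely move it, so spikes do not inflate their own detection threshold.
#'
#' @param trace an [electrode_trace()] (already filtered, zero-mean).
#' @return noise SD in the trace's units (microvolts).
#' @export
estimate_noise_sd <- function(trace) {
    stopifnot(inherits(trace, "electrode_trace"))
    if (!length(trace$samples)) stop("empty trace")
    median(abs(trace$samples)) / 0.6745
}

#' Spike detection parameters
#'
#' @param threshold_multiplier detection threshold in units of noise SD
#'   (default 5).
#' @param active_rate_min minimum firing rate (spikes/s) for an electrode to
#'   count as active (default 0.1, inclusive).
#' @param dead_time_ms refractory period after an accepted spike, ms.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(threshold_multiplier = 5, active_rate_min = 0.1,
                             dead_time_ms = 2) {
    stopifnot(threshold_multiplier > 0, active_rate_min >= 0,
              dead_time_ms >= 0)
    structure(list(threshold_multiplier = threshold_multiplier,
                   active_rate_min = active_rate_min,
                   dead_time_ms = dead_time_ms),
              class = "detection_params")
}

#' Detect spikes on a filtered trace
#'
#' Bipolar thresholding: samples with `|x| >` `threshold_multiplier` times
#' the robust noise SD are grouped into contiguous crossing events; each
#' event yields one spike timed at its absolute extremum; events starting
#' within `dead_time_ms` of the last accepted spike are suppressed.
#'
#' @param trace a filtered [electrode_trace()].
#' @param params a [detection_params()].
#' @param noise_sd optional externally supplied noise SD (defaults to
#'   [estimate_noise_sd()]).
#' @return a [spike_train()] (possibly empty).
#' @export
detect_spikes <- function(trace, params = detection_params(),
                          noise_sd = NULL) {
    stopifnot(inherits(trace, "electrode_trace"))
    fs <- trace$sampling_rate
    x <- trace$samples
    dur <- length(x) / fs
    sd0 <- noise_sd %||% estimate_noise_sd(trace)
    thr <- params$threshold_multiplier * sd0
    above <- abs(x) > thr
    if (!any(above))
        return(spike_train(trace$well_id, trace$electrode_id, numeric(0), dur))
    d <- diff(c(FALSE, above))
    starts <- which(d == 1L)
    ends <- which(d == -1L) - 1L
    if (length(ends) < length(starts)) ends <- c(ends, length(x))
    peak_idx <- vapply(seq_along(starts), function(i) {
        seg <- starts[i]:ends[i]
        seg[which.max(abs(x[seg]))]
    }, integer(1))
    dead <- params$dead_time_ms / 1000 * fs
    keep <- logical(length(peak_idx))
    last <- -Inf
    for (i in seq_along(starts)) {
        if (starts[i] - last > dead) {
            keep[i] <- TRUE
            last <- peak_idx[i]
        }
    }
    times <- (peak_idx[keep] - 1L) / fs
    spike_train(trace$well_id, trace$electrode_id, times, dur)
}

#' Detect spikes on all electrodes of a well
#'
#' Filters each trace with `spec` and runs [detect_spikes()].
#'
#' @param recording a [well_recording()] with traces.
#' @param spec a [filter_spec()].
#' @param params a [detection_params()].
#' @return the recording with `trains` replaced by the detected trains.
#' @export
detect_well <- function(recording, spec = filter_spec(),
                        params = detection_params()) {
    stopifnot(inherits(recording, "well_recording"))
    if (is.null(recording$traces)) stop("recording carries no traces")
    recording$trains <- lapply(recording$traces, function(tr)
        detect_spikes(bandpass(tr, spec), params))
    recording
}

#' Active electrodes of a recording
#'
#' Electrodes firing at `active_rate_min` spikes/s or more ("minimum of 0.1
#' spikes per second" read as inclusive).
#'
#' @param recording a [well_recording()] with spike trains.
#' @param params a [detection_params()].
#' @return integer vector of electrode ids (0-based).
#' @export
active_electrodes <- function(recording, params = detection_params()) {
    stopifnot(inherits(recording, "well_recording"))
    rates <- vapply(recording$trains, function(t)
        length(t$times) / t$duration, numeric(1))
    which(rates >= params$active_rate_min) - 1L
}
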