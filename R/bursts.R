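## Single-channel burst detection (ISI rule) and network-burst detection
## (overlap chains with a channel-concurrency requirement).

#' Burst detection parameters
#'
#' A burst is a run of at least `min_spikes` spikes with inter-spike
#' intervals of at most `max_isi_ms` (inclusive); candidate bursts on one
#' electrode separated by less than `min_inter_burst_ms` are merged into one
#' event. A channel is a bursting channel at `bursting_rate_min` bursts/min
#' or more (inclusive).
#'
#' @param min_spikes minimum spikes per burst (default 4).
#' @param max_isi_ms maximum intra-burst inter-spike interval, ms (50).
#' @param min_inter_burst_ms minimum separation of distinct bursts, ms (100).
#' @param bursting_rate_min bursting-channel threshold, bursts/min (0.4).
#' @return an object of class `burst_params`.
#' @export
burst_params <- function(min_spikes = 4, max_isi_ms = 50,
                         min_inter_burst_ms = 100, bursting_rate_min = 0.4) {
    stopifnot(min_spikes >= 2, max_isi_ms > 0,
              min_inter_burst_ms >= max_isi_ms, bursting_rate_min >= 0)
    structure(list(min_spikes = as.integer(min_spikes),
                   max_isi_ms = max_isi_ms,
                   min_inter_burst_ms = min_inter_burst_ms,
                   bursting_rate_min = bursting_rate_min),
              class = "burst_params")
}

#' Network burst detection parameters
#'
#' @param min_channels minimum distinct channels contributing bursts to the
#'   overlap chain (default 6).
#' @param min_concurrent minimum channels bursting simultaneously at some
#'   instant during the chain (default 4).
#' @return an object of class `network_burst_params`.
#' @export
network_burst_params <- function(min_channels = 6, min_concurrent = 4) {
    stopifnot(min_concurrent <= min_channels, min_channels <= 12)
    structure(list(min_channels = as.integer(min_channels),
                   min_concurrent = as.integer(min_concurrent)),
              class = "network_burst_params")
}

#' Detect bursts on one spike train
#'
#' Maximal runs of consecutive spikes with ISI <= `max_isi_ms` and length
#' >= `min_spikes` become candidate bursts; candidates whose gap to the
#' previous candidate is below `min_inter_burst_ms` are merged. Burst start
#' and end are the first and last member spike times.
#'
#' @param train a [spike_train()].
#' @param p a [burst_params()].
#' @return data.frame with columns `electrode_id`, `start_s`, `end_s`,
#'   `n_spikes` (zero rows when no bursts).
#' @export
detect_bursts <- function(train, p = burst_params()) {
    stopifnot(inherits(train, "spike_train"))
    empty <- data.frame(electrode_id = integer(0), start_s = numeric(0),
                        end_s = numeric(0), n_spikes = integer(0))
    tt <- train$times
    if (length(tt) < p$min_spikes) return(empty)
    ok <- diff(tt) <= p$max_isi_ms / 1000
    r <- rle(ok)
    ends_run <- cumsum(r$lengths)
    starts_run <- ends_run - r$lengths + 1L
    sel <- r$values & r$lengths >= p$min_spikes - 1L
    if (!any(sel)) return(empty)
    s_idx <- starts_run[sel]            # first ISI index -> first spike
    e_idx <- ends_run[sel] + 1L         # last spike index
    start <- tt[s_idx]; end <- tt[e_idx]
    n <- e_idx - s_idx + 1L
    ## merge candidates separated by < min_inter_burst
    if (length(start) > 1L) {
        gap <- start[-1] - end[-length(end)]
        grp <- cumsum(c(1L, as.integer(gap >= p$min_inter_burst_ms / 1000)))
        start <- tapply(start, grp, min)
        end <- tapply(end, grp, max)
        n <- as.integer(tapply(n, grp, sum))
    }
    data.frame(electrode_id = train$electrode_id,
               start_s = as.numeric(start), end_s = as.numeric(end),
               n_spikes = as.integer(n), row.names = NULL)
}

#' All bursts of a well
#'
#' @param recording a [well_recording()] with spike trains.
#' @param p a [burst_params()].
#' @return row-bound [detect_bursts()] output for the 12 electrodes.
#' @export
well_bursts <- function(recording, p = burst_params()) {
    stopifnot(inherits(recording, "well_recording"))
    do.call(rbind, lapply(recording$trains, detect_bursts, p = p))
}

#' Bursting channels of a recording
#'
#' @param recording a [well_recording()] with spike trains.
#' @param p a [burst_params()].
#' @param bursts optional precomputed [well_bursts()] table.
#' @return integer vector of electrode ids (0-based) with
#'   bursts/min >= `bursting_rate_min`.
#' @export
bursting_channels <- function(recording, p = burst_params(), bursts = NULL) {
    b <- bursts %||% well_bursts(recording, p)
    dur_min <- recording$meta$duration_s / 60
    cnt <- table(factor(b$electrode_id, levels = 0:11))
    which(as.numeric(cnt) / dur_min >= p$bursting_rate_min) - 1L
}

# Maximum number of distinct channels simultaneously in burst, for a table
# of bursts (closed intervals: a burst ending exactly when another starts
# counts as concurrent). Sweep-line: starts sort before ends at equal time.
.max_concurrency <- function(b) {
    if (!nrow(b)) return(0L)
    ev_t <- c(b$start_s, b$end_s)
    ev_d <- c(rep(1L, nrow(b)), rep(-1L, nrow(b)))
    o <- order(ev_t, -ev_d)
    max(cumsum(ev_d[o]))
}

#' Detect network bursts
#'
#' Bursts from all channels are chained by temporal overlap (closed
#' intervals; touching endpoints count). Each maximal chain qualifying on
#' (a) at least `min_channels` distinct contributing channels and (b) some
#' instant covered by bursts from at least `min_concurrent` distinct
#' channels becomes a network burst spanning `[min start, max end]` of its
#' members.
#'
#' @param recording a [well_recording()] with spike trains.
#' @param bp a [burst_params()].
#' @param np a [network_burst_params()].
#' @param bursts optional precomputed [well_bursts()] table.
#' @return data.frame with columns `start_s`, `end_s`, `n_channels`,
#'   `n_bursts`; member bursts are attached as the list attribute
#'   `"members"` (one burst table per network burst).
#' @export
detect_network_bursts <- function(recording, bp = burst_params(),
                                  np = network_burst_params(),
                                  bursts = NULL) {
    b <- bursts %||% well_bursts(recording, bp)
    empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                        n_channels = integer(0), n_bursts = integer(0))
    attr(empty, "members") <- list()
    if (!nrow(b)) return(empty)
    b <- b[order(b$start_s, b$end_s), , drop = FALSE]
    ## overlap-connected components via running max end (closed intervals)
    run_end <- cummax(b$end_s)
    new_comp <- c(TRUE, b$start_s[-1] > run_end[-nrow(b)])
    comp <- cumsum(new_comp)
    out <- empty; members <- list()
    for (k in unique(comp)) {
        m <- b[comp == k, , drop = FALSE]
        nch <- length(unique(m$electrode_id))
        if (nch < np$min_channels) next
        if (.max_concurrency(m) < np$min_concurrent) next
        out <- rbind(out, data.frame(start_s = min(m$start_s),
                                     end_s = max(m$end_s),
                                     n_channels = nch,
                                     n_bursts = nrow(m)))
        members[[length(members) + 1L]] <- m
    }
    rownames(out) <- NULL
    attr(out, "members") <- members
    out
}
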