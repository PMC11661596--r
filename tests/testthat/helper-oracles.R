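# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# Maximal runs of ISI <= max_isi, minimum length, then gap-based merging --
# written as a plain loop over spikes.
oracle_bursts <- function(times, min_spikes = 4, max_isi = 0.05,
                          min_gap = 0.1) {
    cand <- list()
    i <- 1
    n <- length(times)
    while (i <= n) {
        j <- i
        while (j < n && times[j + 1] - times[j] <= max_isi) j <- j + 1
        if (j - i + 1 >= min_spikes)
            cand[[length(cand) + 1]] <- c(start = times[i], end = times[j],
                                          n = j - i + 1)
        i <- j + 1
    }
    if (!length(cand)) return(data.frame(start = numeric(0),
                                         end = numeric(0), n = integer(0)))
    m <- as.data.frame(do.call(rbind, cand))
    out <- m[1, , drop = FALSE]
    for (k in seq_len(nrow(m))[-1]) {
        if (m$start[k] - out$end[nrow(out)] < min_gap) {
            out$end[nrow(out)] <- m$end[k]
            out$n[nrow(out)] <- out$n[nrow(out)] + m$n[k]
        } else out <- rbind(out, m[k, ])
    }
    rownames(out) <- NULL
    out
}

# Exhaustive concurrency: evaluate channel coverage at every burst start
# and end (closed intervals -- candidate extrema are at the endpoints).
oracle_max_concurrency <- function(b) {
    if (!nrow(b)) return(0L)
    pts <- sort(unique(c(b$start_s, b$end_s)))
    best <- 0L
    for (t in pts) {
        cover <- unique(b$electrode_id[b$start_s <= t & b$end_s >= t])
        best <- max(best, length(cover))
    }
    best
}

# Overlap-connected components by transitive closure of the adjacency
# matrix (closed-interval overlap).
oracle_components <- function(b) {
    n <- nrow(b)
    if (!n) return(integer(0))
    adj <- outer(seq_len(n), seq_len(n), function(i, j)
        b$start_s[i] <= b$end_s[j] & b$start_s[j] <= b$end_s[i])
    reach <- adj
    repeat {
        nxt <- (reach %*% reach) > 0
        if (identical(nxt, reach)) break
        reach <- nxt
    }
    comp <- integer(n)
    cur <- 0
    for (i in seq_len(n)) {
        if (comp[i] == 0) {
            cur <- cur + 1
            comp[reach[i, ]] <- cur
        }
    }
    comp
}

# Full network-burst oracle on a burst table.
oracle_network_bursts <- function(b, min_channels = 6, min_concurrent = 4) {
    comp <- oracle_components(b)
    out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_channels = integer(0), n_bursts = integer(0))
    for (k in sort(unique(comp))) {
        m <- b[comp == k, , drop = FALSE]
        if (length(unique(m$electrode_id)) < min_channels) next
        if (oracle_max_concurrency(m) < min_concurrent) next
        out <- rbind(out, data.frame(start_s = min(m$start_s),
                                     end_s = max(m$end_s),
                                     n_channels = length(unique(m$electrode_id)),
                                     n_bursts = nrow(m)))
    }
    out[order(out$start_s), , drop = FALSE]
}

# Sample-by-sample spike detector: every |x|>thr sample opens an event;
# contiguous supra-threshold samples are one event; events starting within
# dead samples of the last accepted peak are suppressed.
oracle_detect <- function(x, thr, dead_samples) {
    peaks <- integer(0)
    i <- 1; n <- length(x); last <- -Inf
    while (i <= n) {
        if (abs(x[i]) > thr) {
            j <- i
            while (j < n && abs(x[j + 1]) > thr) j <- j + 1
            if (i - last > dead_samples) {
                seg <- i:j
                pk <- seg[which.max(abs(x[seg]))]
                peaks <- c(peaks, pk)
                last <- pk
            }
            i <- j + 1
        } else i <- i + 1
    }
    peaks
}

# Random multi-channel burst instance for oracle cross-checks.
random_burst_table <- function(n_channels = sample(2:12, 1),
                               max_bursts = 5, t_max = 10) {
    rows <- list()
    for (ch in sample(0:11, n_channels)) {
        k <- sample.int(max_bursts, 1)
        s <- sort(runif(k, 0, t_max))
        d <- runif(k, 0.05, 0.8)
        e <- s + d
        # enforce per-channel disjointness with >=100 ms gaps
        keep <- rep(TRUE, k)
        last_end <- -Inf
        for (i in seq_len(k)) {
            if (s[i] < last_end + 0.1) keep[i] <- FALSE
            else last_end <- e[i]
        }
        if (any(keep))
            rows[[length(rows) + 1]] <- data.frame(
                electrode_id = ch, start_s = s[keep], end_s = e[keep],
                n_spikes = 4L)
    }
    do.call(rbind, rows)
}

# Build a well_recording directly from a burst table by laying spikes
# inside each burst (>= 4 spikes at ISIs <= 50 ms spanning the extent).
recording_from_bursts <- function(b, duration = 20) {
    trains <- list()
    for (ch in unique(b$electrode_id)) {
        sub <- b[b$electrode_id == ch, , drop = FALSE]
        tt <- unlist(lapply(seq_len(nrow(sub)), function(i) {
            n <- max(4L, ceiling((sub$end_s[i] - sub$start_s[i]) / 0.04) + 1L)
            seq(sub$start_s[i], sub$end_s[i], length.out = n)
        }))
        trains[[length(trains) + 1]] <-
            spike_train("T", ch, sort(tt), duration)
    }
    well_recording("T", recording_meta("control_normoxia", "baseline", 0,
                                       duration), trains)
}
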