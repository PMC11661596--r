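mk_train <- function(times, ch = 0, dur = 600)
    spike_train("T", ch, times, dur)

test_that("burst definition worked examples are exact", {
    p <- burst_params()
    ## 4 spikes at 40 ms ISI -> one burst spanning [0, 0.12]
    b <- detect_bursts(mk_train(c(0, 0.04, 0.08, 0.12)), p)
    expect_equal(nrow(b), 1)
    expect_equal(b$n_spikes, 4L)
    expect_equal(c(b$start_s, b$end_s), c(0, 0.12))
    ## 3 spikes -> no burst
    expect_equal(nrow(detect_bursts(mk_train(c(0, 0.04, 0.08)), p)), 0)
    ## ISI boundary is inclusive: 50 ms ISIs count
    b50 <- detect_bursts(mk_train(c(0, 0.05, 0.10, 0.15)), p)
    expect_equal(nrow(b50), 1)
    ## two 4-spike runs separated by 70 ms (< 100 ms) merge into 8 spikes
    run1 <- c(0, 0.04, 0.08, 0.12)
    run2 <- 0.19 + c(0, 0.04, 0.08, 0.12)
    bm <- detect_bursts(mk_train(c(run1, run2)), p)
    expect_equal(nrow(bm), 1)
    expect_equal(bm$n_spikes, 8L)
    expect_equal(bm$end_s, 0.31)
    ## gap of exactly 100 ms stays two bursts
    run3 <- 0.22 + c(0, 0.04, 0.08, 0.12)
    b2 <- detect_bursts(mk_train(c(run1, run3)), p)
    expect_equal(nrow(b2), 2)
})

test_that("detect_bursts agrees with the brute-force oracle", {
    p <- burst_params()
    with_seed(101, {
        for (rep in 1:200) {
            n <- sample(0:60, 1)
            tt <- sort(runif(n, 0, 5))
            tt <- tt[c(TRUE, diff(tt) > 1e-6)]
            got <- detect_bursts(mk_train(tt, dur = 6), p)
            want <- oracle_bursts(tt)
            expect_equal(nrow(got), nrow(want))
            if (nrow(got)) {
                expect_equal(got$start_s, want$start)
                expect_equal(got$end_s, want$end)
                expect_equal(got$n_spikes, as.integer(want$n))
            }
        }
    })
})

test_that("per-channel bursts are disjoint, >= 100 ms apart, >= 4 spikes", {
    p <- burst_params()
    with_seed(55, {
        for (rep in 1:50) {
            tt <- sort(runif(sample(20:80, 1), 0, 10))
            tt <- tt[c(TRUE, diff(tt) > 1e-6)]
            b <- detect_bursts(mk_train(tt, dur = 11), p)
            if (nrow(b) > 1) {
                gaps <- b$start_s[-1] - b$end_s[-nrow(b)]
                expect_true(all(gaps >= p$min_inter_burst_ms / 1000))
            }
            expect_true(all(b$n_spikes >= p$min_spikes))
            ## every spike lies in at most one burst
            if (nrow(b)) {
                inb <- vapply(tt, function(t)
                    sum(t >= b$start_s & t <= b$end_s), numeric(1))
                expect_true(all(inb <= 1))
            }
        }
    })
})

test_that("relaxing max_isi never decreases spikes inside bursts", {
    with_seed(77, {
        tt <- sort(runif(200, 0, 20))
        n_in <- vapply(c(20, 50, 80, 120), function(isi) {
            b <- detect_bursts(mk_train(tt, dur = 21),
                               burst_params(max_isi_ms = isi,
                                            min_inter_burst_ms = 120))
            sum(b$n_spikes)
        }, numeric(1))
        expect_true(all(diff(n_in) >= 0))
    })
})

test_that("bursting channel rule is >= 0.4 bursts/min", {
    burst_at <- function(t0) t0 + c(0, 0.04, 0.08, 0.12)
    mk_ch <- function(ch, n) mk_train(unlist(lapply(seq_len(n) * 60,
                                                    burst_at)), ch)
    meta <- recording_meta("control_normoxia", "baseline", 0, 600)
    rec <- well_recording("T", meta, list(mk_ch(0, 4), mk_ch(1, 3)))
    expect_equal(bursting_channels(rec), 0L)  # 4/10 min = 0.4 in; 0.3 out
    empty <- well_recording("T", meta, list())
    expect_length(bursting_channels(empty), 0)
})

test_that("network burst worked examples are exact", {
    np <- network_burst_params()
    burst6 <- function(chs) do.call(rbind, lapply(chs, function(ch)
        data.frame(electrode_id = ch, start_s = 0, end_s = 0.2,
                   n_spikes = 4L)))
    ## 6 channels, one simultaneous burst each -> one NB of duration 0.2
    nb <- detect_network_bursts(NULL, bursts = burst6(0:5), np = np)
    expect_equal(nrow(nb), 1)
    expect_equal(nb$n_channels, 6L)
    expect_equal(nb$end_s - nb$start_s, 0.2)
    ## 5 channels -> fails the 6-distinct-channel rule
    expect_equal(nrow(detect_network_bursts(NULL, bursts = burst6(0:4),
                                            np = np)), 0)
    ## 6 channels chained pairwise with max concurrency below 4 -> rejected
    chain <- do.call(rbind, lapply(0:5, function(i)
        data.frame(electrode_id = i, start_s = i * 0.15,
                   end_s = i * 0.15 + 0.2, n_spikes = 4L)))
    expect_equal(oracle_max_concurrency(chain), 2L)
    expect_equal(nrow(detect_network_bursts(NULL, bursts = chain, np = np)), 0)
    ## same chain with wider bursts reaching 4-concurrency -> accepted
    chain$end_s <- chain$start_s + 0.5
    expect_gte(oracle_max_concurrency(chain), 4L)
    expect_equal(nrow(detect_network_bursts(NULL, bursts = chain, np = np)), 1)
})

test_that("network bursts match the exhaustive oracle on random instances", {
    np <- network_burst_params()
    with_seed(202, {
        for (rep in 1:150) {
            b <- random_burst_table()
            got <- detect_network_bursts(NULL, bursts = b, np = np)
            want <- oracle_network_bursts(b)
            expect_equal(nrow(got), nrow(want))
            if (nrow(got)) {
                expect_equal(got$start_s, want$start_s)
                expect_equal(got$end_s, want$end_s)
                expect_equal(got$n_channels, want$n_channels)
            }
            expect_lte(sum(got$n_bursts), nrow(b))
        }
    })
})

test_that("spike-level and burst-table network burst paths agree", {
    with_seed(303, {
        for (rep in 1:20) {
            b <- random_burst_table(n_channels = sample(6:12, 1))
            rec <- recording_from_bursts(b)
            got <- detect_network_bursts(rec)
            want <- oracle_network_bursts(well_bursts(rec))
            expect_equal(nrow(got), nrow(want))
        }
    })
})
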