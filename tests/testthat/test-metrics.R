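meta600 <- recording_meta("control_normoxia", "baseline", 0, 600)

regular_train <- function(ch, n, dur = 600)
    spike_train("T", ch, seq(0.5, dur - 0.5, length.out = n), dur)

test_that("MFR averages over active electrodes only", {
    ## rates 0.2, 0.3 active; 0.05 inactive -> MFR 0.25
    rec <- well_recording("T", meta600,
                          list(regular_train(0, 120), regular_train(1, 180),
                               regular_train(2, 30)))
    m <- compute_metrics(rec)
    expect_equal(m$mfr, 0.25)
    expect_equal(m$n_active, 2L)
    expect_true(m$mfr_defined)
    ## no active electrodes -> MFR 0, flagged
    silent <- well_recording("T", meta600, list(regular_train(0, 10)))
    ms <- compute_metrics(silent)
    expect_equal(ms$mfr, 0)
    expect_false(ms$mfr_defined)
    expect_true(is.na(ms$nbd_ms))
})

test_that("NBR and NBD come from detected network bursts", {
    ## 12 synchronous events in 600 s across 8 channels -> NBR 1.2/min
    events <- seq(20, 580, length.out = 12)
    trains <- lapply(0:7, function(ch) {
        tt <- unlist(lapply(events, function(t0)
            t0 + seq(0, 0.4, length.out = 11)))
        spike_train("T", ch, tt, 600)
    })
    rec <- well_recording("T", meta600, trains)
    m <- compute_metrics(rec)
    expect_equal(m$nbr, 1.2)
    expect_equal(m$n_network_bursts, 12L)
    expect_equal(m$nbd_ms, 400, tolerance = 0.01)
})

test_that("estimated NBD tracks the generator's ground truth", {
    p <- condition_profile("control_normoxia")
    nbd <- with_seed(21, vapply(1:15, function(i) {
        r <- simulate_recording(p, baseline_params(),
                                recording_meta("control_normoxia",
                                               "baseline", 0, 600))
        compute_metrics(r)$nbd_ms
    }, numeric(1)))
    expect_lt(abs(mean(nbd) / 500 - 1), 0.10)
})

test_that("inclusion criterion is strict on both thresholds", {
    expect_true(apply_inclusion(list(mfr = 0.5, nbr = 2)))
    expect_false(apply_inclusion(list(mfr = 0.5, nbr = 1.0)))
    expect_false(apply_inclusion(list(mfr = 0.1, nbr = 2)))
    expect_false(apply_inclusion(list(mfr = 0, nbr = 0)))
})

test_that("baseline normalisation identities hold", {
    p <- condition_profile("control_normoxia")
    wells <- simulate_condition(p, n_wells = 2, seed = 31, duration_s = 600)
    tc <- do.call(rbind, lapply(wells, well_timecourse))
    ntc <- normalize_to_baseline(tc)
    base <- ntc[ntc$phase == "baseline", ]
    expect_equal(base$mfr_pct, rep(100, nrow(base)))
    expect_equal(base$nbr_pct, rep(100, nrow(base)))
    expect_equal(base$nbd_pct, rep(100, nrow(base)))
})

test_that("normalisation arithmetic and missing rules", {
    mk_row <- function(phase, t, mfr, nbr, nbd, included = TRUE)
        data.frame(well_id = "W", condition = "normothermia_hypoxia",
                   phase = phase, timepoint_h = t, mfr = mfr, nbr = nbr,
                   nbd_ms = nbd, n_active = 12, n_bursting = 10,
                   included = included)
    df <- rbind(mk_row("baseline", 0, 1.0, 2.0, 500),
                mk_row("treatment", 24, 0.54, 3.4, NA),
                mk_row("treatment", 48, 0, 0, NA))
    n <- normalize_to_baseline(df)
    expect_equal(n$mfr_pct, c(100, 54, 0))
    expect_equal(n$nbr_pct, c(100, 170, 0))
    expect_equal(n$nbd_pct, c(100, NA, NA))
    ## baseline failing inclusion drops the well with a message
    df2 <- rbind(mk_row("baseline", 0, 0.05, 0.5, 500, included = FALSE),
                 mk_row("treatment", 24, 0.5, 2, 400, included = FALSE))
    expect_message(out <- normalize_to_baseline(df2), "inclusion")
    expect_equal(nrow(out), 0)
})

test_that("aggregation gives the closed-form mean and SEM", {
    df <- data.frame(well_id = paste0("W", 1:4),
                     condition = "normothermia_hypoxia", phase = "recovery",
                     timepoint_h = 54, mfr_pct = c(10, 20, 30, 40),
                     nbr_pct = 50, nbd_pct = NA_real_)
    agg <- aggregate_timecourse(df)
    mfr <- agg[agg$metric == "mfr_pct", ]
    expect_equal(mfr$mean, 25)
    expect_equal(mfr$sem, sd(c(10, 20, 30, 40)) / 2)
    expect_equal(mfr$sem, 6.455, tolerance = 1e-4)
    expect_equal(agg[agg$metric == "nbr_pct", ]$sem, 0)
    expect_equal(agg[agg$metric == "nbd_pct", ]$n, 0)
})

test_that("loss-of-activity time is the first all-zero treatment timepoint", {
    mk <- function(w, t, mfr, nbr)
        data.frame(well_id = w, condition = "x", phase = "treatment",
                   timepoint_h = t, mfr = mfr, nbr = nbr)
    df <- rbind(mk("a", 40, 0.2, 1), mk("b", 40, 0, 0),
                mk("a", 42, 0, 0), mk("b", 42, 0, 0),
                mk("a", 44, 0, 0), mk("b", 44, 0, 0))
    expect_equal(loss_of_activity_time(df), 42)
    expect_true(is.na(loss_of_activity_time(mk("a", 42, 1, 1))))
})
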