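test_that("viability generator marks only the configured classes", {
    f <- synth_viability_field(60, c(1, 0, 0), seed = 1)
    expect_equal(unique(f$truth$centers$label), "live")
    ## marker channels are background only (well below blob amplitudes)
    expect_lt(quantile(f$channels$cellevent, 0.999), 0.2)
    expect_lt(quantile(f$channels$pi, 0.999), 0.2)
    ## reproducible under seed
    f2 <- synth_viability_field(60, c(1, 0, 0), seed = 1)
    expect_identical(f$channels$dapi, f2$channels$dapi)
})

test_that("classifier handles blank and pure-live fields", {
    blank <- field_image(list(dapi = matrix(0, 64, 64),
                              cellevent = matrix(0, 64, 64),
                              pi = matrix(0, 64, 64)), 0.32)
    cc <- classify_viability(blank)
    expect_equal(cc$n_total, 0L)
    expect_true(cc$flagged)
    f <- synth_viability_field(50, c(1, 0, 0), seed = 3)
    cc <- classify_viability(f)
    expect_equal(cc$n_live, 50L)
    expect_equal(cc$n_apoptotic + cc$n_dead + cc$n_unclassified, 0L)
})

test_that("per-cell classification accuracy is >= 95% against ground truth", {
    frac <- c(live = 0.4, apoptotic = 0.2, dead = 0.35, unclassified = 0.05)
    correct <- 0L; total <- 0L
    cons_ok <- TRUE
    with_seed(17, {
        for (i in 1:5) {
            f <- synth_viability_field(100, frac)
            cc <- classify_viability(f)
            cons_ok <- cons_ok &&
                (cc$n_live + cc$n_apoptotic + cc$n_dead +
                 cc$n_unclassified == cc$n_total)
            truth <- f$truth$centers
            ## match each segmented nucleus to the nearest true centre
            for (j in seq_len(nrow(cc$centroids))) {
                d2 <- (truth$r - cc$centroids$r[j])^2 +
                      (truth$c - cc$centroids$c[j])^2
                k <- which.min(d2)
                total <- total + 1L
                if (d2[k] < 8^2 &&
                    truth$label[k] == cc$centroids$label[j])
                    correct <- correct + 1L
            }
        }
    })
    expect_true(cons_ok)
    expect_gte(correct / total, 0.95)
})

test_that("classification is invariant to global intensity scaling", {
    f <- synth_viability_field(80, c(0.5, 0.2, 0.3), seed = 9)
    f_scaled <- f
    f_scaled$channels <- lapply(f$channels, function(m) m * 12.5)
    a <- classify_viability(f)
    b <- classify_viability(f_scaled)
    expect_equal(a$labels, b$labels)
})

test_that("puncta generator bookkeeping matches the curve arc length", {
    f <- synth_puncta_field(density_per_10um = 1.0, seed = 5)
    recomputed <- sum(vapply(f$truth$paths, function(p)
        sum(sqrt(rowSums(diff(p)^2))), numeric(1))) * f$pixel_size_um
    expect_lt(abs(recomputed / f$truth$total_length_um - 1), 0.02)
    ## density 0 -> no on-neurite puncta
    f0 <- synth_puncta_field(density_per_10um = 0, seed = 6)
    expect_equal(sum(f0$truth$puncta$on_neurite), 0)
    ## reproducibility
    expect_identical(synth_puncta_field(density_per_10um = 1, seed = 7)$channels$synapsin,
                     synth_puncta_field(density_per_10um = 1, seed = 7)$channels$synapsin)
})

test_that("a straight neurite with 10 puncta gives ~1 per 10 um", {
    ## 100 um horizontal neurite (625 px at 0.16 um/px) with 10 puncta
    nr <- 128; nc <- 700
    map2 <- matrix(0, nr, nc); syn <- matrix(0, nr, nc)
    for (x in seq(30, 30 + 625, by = 1))
        map2 <- meaoxia:::.stamp_blob(map2, 64, x, 1.2, 0.6)
    for (x in seq(60, 600, length.out = 10))
        syn <- meaoxia:::.stamp_blob(syn, 64, x, 1.9, 1)
    set.seed(4)
    f <- field_image(list(map2 = map2 + matrix(rnorm(nr * nc, 0, 0.02), nr, nc),
                          synapsin = syn + matrix(rnorm(nr * nc, 0, 0.02), nr, nc)),
                     0.16)
    q <- quantify_puncta(f)
    expect_equal(q$n_puncta, 10L)
    expect_equal(q$neurite_length_um, 100, tolerance = 0.05)
    expect_equal(q$density_per_10um, 1.0, tolerance = 0.08)
})

test_that("distractor puncta beyond the association radius are not counted", {
    nr <- 128; nc <- 400
    map2 <- matrix(0, nr, nc); syn <- matrix(0, nr, nc)
    for (x in 20:380) map2 <- meaoxia:::.stamp_blob(map2, 30, x, 1.2, 0.6)
    ## puncta 60 px (~10 um) away from the neurite
    for (x in c(100, 200, 300))
        syn <- meaoxia:::.stamp_blob(syn, 110, x, 1.9, 1)
    set.seed(8)
    f <- field_image(list(map2 = map2 + matrix(rnorm(nr * nc, 0, 0.02), nr, nc),
                          synapsin = syn + matrix(rnorm(nr * nc, 0, 0.02), nr, nc)),
                     0.16)
    q <- quantify_puncta(f)
    expect_equal(q$n_puncta, 0L)
})

test_that("too little neurite flags the density as undefined", {
    nr <- 64; nc <- 64
    set.seed(2)
    f <- field_image(list(map2 = matrix(rnorm(nr * nc, 0, 0.02), nr, nc),
                          synapsin = matrix(rnorm(nr * nc, 0, 0.02), nr, nc)),
                     0.16)
    q <- quantify_puncta(f)
    expect_true(q$flagged)
    expect_true(is.na(q$density_per_10um))
})

test_that("density recovery is approximately unbiased across the range", {
    ## slope of recovered vs true across the tested densities ~ 1
    dens <- c(0.5, 1.0, 1.6)
    est <- with_seed(23, vapply(dens, function(d) {
        mean(vapply(1:4, function(i)
            quantify_puncta(synth_puncta_field(density_per_10um = d))$density_per_10um,
            numeric(1)))
    }, numeric(1)))
    expect_true(all(abs(est / dens - 1) < 0.2))
    slope <- coef(lm(est ~ dens))[2]
    expect_gt(slope, 0.75)
    expect_lt(slope, 1.15)
})
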