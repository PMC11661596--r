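test_that("KS normality behaves on normal and skewed samples", {
    with_seed(1, {
        res <- ks_normality(rnorm(200))
        expect_gt(res$p_value, 0.05)
        res_exp <- ks_normality(rexp(100))
        expect_lt(res_exp$p_value, 0.05)
    })
    expect_error(ks_normality(rnorm(4)), "at least 5")
    expect_error(ks_normality(rep(1, 10)), "constant")
})

test_that("KS p-values are ~uniform under the null", {
    pv <- with_seed(5, vapply(1:40, function(i)
        ks_normality(rnorm(30), B = 499)$p_value, numeric(1)))
    expect_gt(mean(pv > 0.05), 0.80)
    expect_gt(mean(pv), 0.3)
})

test_that("ROUT flags gross outliers and spares clean data", {
    x <- with_seed(2, rnorm(20))
    rep_clean <- rout_outliers(x)
    xo <- c(x, rep_clean$center + 10 * rep_clean$robust_sd)
    rep_out <- rout_outliers(xo)
    expect_true(length(xo) %in% rep_out$flagged)
    expect_true(all(rep_out$flagged %in% seq_along(xo)))
    expect_warning(rout_outliers(rnorm(3)), "fewer than 5")
    ## average false-flag fraction on clean normal data stays ~<= Q
    frac <- with_seed(3, vapply(1:500, function(i)
        length(rout_outliers(rnorm(20))$flagged) / 20, numeric(1)))
    expect_lte(mean(frac), 0.015)
})

test_that("Type-III two-way ANOVA matches the reduced-model definition", {
    set.seed(2)
    df <- data.frame(A = rep(c("a", "b", "c"), times = c(8, 10, 12)))
    df$B <- unlist(lapply(c(8, 10, 12), function(n)
        rep(c("x", "y"), length.out = n)))
    df$y <- rnorm(30) + (df$A == "b") * 0.8 + (df$B == "y") * 0.5
    an <- two_way_anova(df, "y", "A", "B")
    expect_equal(an$term, c("A", "B", "A:B", "Residuals"))
    expect_equal(an$df, c(2, 1, 2, 24))
    ## frozen from the independent statsmodels Type-III oracle on this
    ## exact (seeded) data set
    expect_equal(an$sumsq[1:3], c(4.65897518, 2.56278636, 0.84740588),
                 tolerance = 1e-6)
    expect_equal(an$p_value[1:3], c(0.16613709, 0.15740306, 0.70674239),
                 tolerance = 1e-6)
    expect_error(two_way_anova(df[df$A == "a", ], "y", "A", "B"),
                 "at least 2 levels")
    df_bad <- df[!(df$A == "c" & df$B == "y"), ]
    expect_error(two_way_anova(df_bad, "y", "A", "B"), "empty design cell: c x y")
})

test_that("the ANOVA detects a large injected effect", {
    det <- with_seed(7, vapply(1:30, function(i) {
        d <- expand.grid(A = c("ctl", "trt"), B = factor(1:3),
                         rep = 1:10)
        d$y <- rnorm(nrow(d)) + (d$A == "trt") * 3
        an <- two_way_anova(d, "y", "A", "B")
        an$p_value[an$term == "A"] < 0.05
    }, logical(1)))
    expect_gte(mean(det), 0.99)
})

test_that("Tukey adjusted p matches the studentized-range oracle", {
    set.seed(11)
    d <- expand.grid(A = c("a", "b", "c"), B = c("t1", "t2"), rep = 1:8)
    d$y <- rnorm(nrow(d)) + (d$A == "c") * 1.5
    an <- two_way_anova(d, "y", "A", "B")
    tk <- posthoc(an, "tukey")
    info <- attr(an, "fit")
    ## recompute one comparison from first principles
    g1 <- d$y[d$A == "a" & d$B == "t1"]; g2 <- d$y[d$A == "c" & d$B == "t1"]
    q <- abs(mean(g2) - mean(g1)) /
        sqrt(info$mse * (1 / 8 + 1 / 8) / 2)
    p_oracle <- ptukey(q, 3, info$df_res, lower.tail = FALSE)
    row <- tk[tk$family == "t1" & tk$comparison == "c - a", ]
    expect_equal(row$p_adj, p_oracle, tolerance = 1e-3)
    expect_true(all(tk$p_adj >= tk$p_raw - 1e-12))
    expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
})

test_that("Sidak adjustment follows the closed formula", {
    set.seed(12)
    d <- expand.grid(A = c("a", "b"), B = factor(1:5), rep = 1:6)
    d$y <- rnorm(nrow(d))
    an <- two_way_anova(d, "y", "A", "B")
    sk <- posthoc(an, "sidak")
    expect_equal(nrow(sk), 5)
    expect_equal(sk$p_adj, 1 - (1 - sk$p_raw)^5, tolerance = 1e-12)
})

test_that("Dunnett adjustment matches an independent reference value", {
    ## k = 1 comparison reduces to the plain two-sided t p-value
    expect_equal(meaoxia:::dunnett_p_adjust(2.1, 1, 30),
                 2 * pt(-2.1, 30), tolerance = 1e-6)
    ## k = 3, df = 40, |t| = 2.3: frozen from the mvtnorm equicorrelated
    ## multivariate-t oracle (0.5 correlation)
    expect_equal(meaoxia:::dunnett_p_adjust(2.3, 3, 40), 0.06875,
                 tolerance = 1e-3)
    ## monotone in |t|
    ps <- vapply(c(1, 2, 3, 4), function(t)
        meaoxia:::dunnett_p_adjust(t, 3, 40), numeric(1))
    expect_true(all(diff(ps) < 0))
})

test_that("Dunnett family runs against the baseline reference", {
    set.seed(13)
    d <- expand.grid(A = c("ctl", "trt"), B = c("base", "t6", "t24"),
                     rep = 1:6)
    d$y <- rnorm(nrow(d)) + (d$B == "t24") * 2
    an <- two_way_anova(d, "y", "A", "B")
    dn <- posthoc(an, "dunnett", reference = "base")
    expect_equal(nrow(dn), 4)  # 2 conditions x 2 non-reference timepoints
    expect_true(all(dn$p_adj >= dn$p_raw - 1e-12))
    expect_error(posthoc(an, "dunnett"), "reference")
    expect_error(posthoc(an, "dunnett", reference = "nope"), "not found")
})

test_that("identical groups give adjusted p near 1", {
    set.seed(14)
    base <- rnorm(12)
    d <- data.frame(A = rep(c("a", "b"), each = 12),
                    B = rep(rep(c("t1", "t2"), each = 6), 2),
                    y = c(base, base + rnorm(12, 0, 1e-8)))
    d$y <- d$y + rnorm(24, 0, 1)  # shared noise floor, no group effect
    an <- two_way_anova(d, "y", "A", "B")
    tk <- posthoc(an, "tukey")
    expect_true(all(tk$p_adj > 0.01))
})

test_that("star annotation uses the reporting cutpoints", {
    expect_equal(p_stars(c(0.2, 0.04, 0.004, 4e-4, 5e-5)),
                 c("", "*", "**", "***", "****"))
    expect_equal(format_p(c(0.2345, 2e-5)), c("0.2345", "<0.0001"))
})
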