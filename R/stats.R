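## Statistical protocol: KS (Lilliefors) normality, ROUT-style robust
## outlier flagging at Q = 1%, two-way ANOVA with Type-III sums of squares,
## and the Tukey / Sidak / Dunnett post-hoc families.

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' One-sample KS statistic against a normal with the sample's mean and SD.
#' Because the parameters are estimated, the classical KS null distribution
#' does not apply (Lilliefors' situation); the p-value is obtained by a
#' parametric bootstrap (`B` simulated normal samples of the same size, D
#' recomputed with re-estimated parameters each time), which is exact up to
#' Monte-Carlo error. Consumes the RNG stream.
#'
#' @param x numeric sample, n >= 5, non-constant.
#' @param B bootstrap replicates.
#' @return list with `statistic` (D), `p_value`, `n`, and `method`.
#' @export
ks_normality <- function(x, B = 1999) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 5) stop("need at least 5 observations")
    if (sd(x) == 0) stop("constant sample")
    D_of <- function(v) {
        v <- sort(v)
        F0 <- pnorm(v, mean(v), sd(v))
        i <- seq_len(length(v))
        max(i / length(v) - F0, F0 - (i - 1) / length(v))
    }
    D <- D_of(x)
    Dstar <- vapply(seq_len(B), function(i) D_of(rnorm(n)), numeric(1))
    list(statistic = D, p_value = (1 + sum(Dstar >= D)) / (B + 1), n = n,
         method = "KS normality (estimated parameters, parametric bootstrap)")
}

#' ROUT-style robust outlier flagging (one-sample location case)
#'
#' Robust centre = median; robust scale = the 68.27th percentile of the
#' absolute residuals (the RSDR of a robust fit reduced to the location
#' case), with a small-sample df correction. Each point's residual is
#' converted to a t-statistic and the set of outliers is selected by
#' Benjamini-Hochberg FDR control at level `Q`. Points are flagged, never
#' silently dropped.
#'
#' @param x numeric sample.
#' @param Q FDR level (default 0.01, i.e. "Q = 1%").
#' @return an object of class `outlier_report`: `flagged` (indices into
#'   `x`), `center`, `robust_sd`, `Q`, `p_values`.
#' @export
rout_outliers <- function(x, Q = 0.01) {
    n <- length(x)
    if (n < 5) {
        warning("fewer than 5 observations; no outlier test performed")
        return(structure(list(flagged = integer(0), center = NA_real_,
                              robust_sd = NA_real_, Q = Q,
                              p_values = rep(NA_real_, n)),
                         class = "outlier_report"))
    }
    center <- median(x)
    resid <- x - center
    rsd <- quantile(abs(resid), 0.6827, names = FALSE) * sqrt(n / (n - 1))
    if (rsd <= 0) rsd <- .Machine$double.eps
    tval <- resid / rsd
    p <- 2 * pt(-abs(tval), df = n - 1)
    flagged <- which(p.adjust(p, method = "BH") < Q)
    structure(list(flagged = flagged, center = center, robust_sd = rsd,
                   Q = Q, p_values = p), class = "outlier_report")
}

# Model matrices for a two-factor design with sum-to-zero contrasts.
.two_way_mm <- function(df, value, factor_a, factor_b) {
    df[[factor_a]] <- factor(df[[factor_a]])
    df[[factor_b]] <- factor(df[[factor_b]])
    if (nlevels(df[[factor_a]]) < 2 || nlevels(df[[factor_b]]) < 2)
        stop("each factor needs at least 2 levels")
    cells <- table(df[[factor_a]], df[[factor_b]])
    if (any(cells == 0)) {
        idx <- which(cells == 0, arr.ind = TRUE)[1, ]
        stop("empty design cell: ", rownames(cells)[idx[1]], " x ",
             colnames(cells)[idx[2]])
    }
    form <- stats::as.formula(paste0("`", value, "` ~ `", factor_a, "` * `",
                                     factor_b, "`"))
    mm <- model.matrix(form, df, contrasts.arg =
        setNames(list("contr.sum", "contr.sum"), c(factor_a, factor_b)))
    list(df = df, mm = mm, y = df[[value]],
         assign = attr(mm, "assign"),
         terms = attr(stats::terms(form), "term.labels"))
}

#' Two-way ANOVA with Type-III sums of squares
#'
#' Main effects and interaction, each tested by comparing the full
#' sum-to-zero-coded model against the model with that term's columns
#' removed (Type III, appropriate for the unbalanced well counts of
#' multi-condition MEA experiments).
#'
#' @param df data.frame.
#' @param value name of the response column.
#' @param factor_a,factor_b names of the two factor columns (condition and
#'   timepoint).
#' @return data.frame with one row per term: `term`, `df`, `sumsq`,
#'   `meansq`, `statistic` (F), `p_value`, plus a `Residuals` row. The
#'   fitted pieces are attached as attribute `"fit"`.
#' @export
two_way_anova <- function(df, value, factor_a, factor_b) {
    d <- .two_way_mm(df, value, factor_a, factor_b)
    full <- lm.fit(d$mm, d$y)
    rss_full <- sum(full$residuals^2)
    df_res <- length(d$y) - full$rank
    if (df_res < 1) stop("no residual degrees of freedom")
    rows <- lapply(seq_along(d$terms), function(k) {
        keep <- d$assign != k
        red <- lm.fit(d$mm[, keep, drop = FALSE], d$y)
        ss <- sum(red$residuals^2) - rss_full
        dfk <- sum(d$assign == k)
        Fk <- (ss / dfk) / (rss_full / df_res)
        data.frame(term = gsub("`", "", d$terms[k]), df = dfk, sumsq = ss,
                   meansq = ss / dfk, statistic = Fk,
                   p_value = pf(Fk, dfk, df_res, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    })
    out <- rbind(do.call(rbind, rows),
                 data.frame(term = "Residuals", df = df_res, sumsq = rss_full,
                            meansq = rss_full / df_res, statistic = NA,
                            p_value = NA))
    rownames(out) <- NULL
    attr(out, "fit") <- list(mse = rss_full / df_res, df_res = df_res,
                             data = d$df, value = value,
                             factor_a = factor_a, factor_b = factor_b)
    out
}

# Two-sided Dunnett adjusted p for the maximum of k |t| statistics sharing
# a control group (equicorrelation 1/2, residual df `df`): numerical
# integration over the studentising scale and the control's normal score.
dunnett_p_adjust <- function(tval, k, df) {
    tval <- abs(tval)
    if (k <= 1) return(2 * pt(-tval, df))
    inner <- function(u) {
        c0 <- sqrt(2) * tval * u
        f <- function(z) dnorm(z) * (pnorm(z + c0) - pnorm(z - c0))^k
        integrate(f, -8, 8, rel.tol = 1e-8)$value
    }
    # outer integral over the studentising scale u = s/sigma ~ sqrt(chi2_df/df)
    gv <- function(u) vapply(u, function(ui)
        exp((df / 2) * log(df / 2) - lgamma(df / 2) +
            (df - 1) * log(ui) - df * ui^2 / 2 + log(2)) * inner(ui),
        numeric(1))
    pcov <- integrate(gv, 1e-6, 10, rel.tol = 1e-7)$value
    min(1, max(0, 1 - pcov))
}

#' Post-hoc multiple comparisons after a two-way ANOVA
#'
#' All families use the pooled residual mean square of the fitted model.
#' `tukey`: all pairs of `factor_a` levels within each `factor_b` level,
#' studentized-range adjusted. `sidak`: the two-group `factor_a` contrast
#' within each `factor_b` level, Sidak-adjusted across the `factor_b`
#' family. `dunnett`: each `factor_b` level against the designated
#' `reference` level within each `factor_a` level.
#'
#' @param fit output of [two_way_anova()].
#' @param method `"tukey"`, `"sidak"` or `"dunnett"`.
#' @param reference reference level of `factor_b` (required for Dunnett;
#'   typically the baseline timepoint).
#' @return data.frame of class `comparison_result` with columns `family`,
#'   `comparison`, `estimate`, `statistic`, `p_raw`, `p_adj`, `method`,
#'   `stars`.
#' @export
posthoc <- function(fit, method = c("tukey", "sidak", "dunnett"),
                    reference = NULL) {
    method <- match.arg(method)
    info <- attr(fit, "fit")
    if (is.null(info)) stop("fit must come from two_way_anova()")
    d <- info$data
    A <- factor(d[[info$factor_a]]); B <- factor(d[[info$factor_b]])
    y <- d[[info$value]]
    mse <- info$mse; df_res <- info$df_res
    res <- list()
    add <- function(family, comparison, est, stat, p_raw, p_adj) {
        res[[length(res) + 1L]] <<- data.frame(
            family = family, comparison = comparison, estimate = est,
            statistic = stat, p_raw = p_raw,
            p_adj = min(1, max(p_adj, p_raw)), method = method,
            stringsAsFactors = FALSE)
    }
    if (method == "tukey") {
        k <- nlevels(A)
        for (b in levels(B)) {
            sel <- B == b
            for (i in seq_len(k - 1)) for (j in (i + 1):k) {
                g1 <- y[sel & A == levels(A)[i]]
                g2 <- y[sel & A == levels(A)[j]]
                if (!length(g1) || !length(g2)) next
                est <- mean(g2) - mean(g1)
                se <- sqrt(mse * (1 / length(g1) + 1 / length(g2)))
                q <- abs(est) / (se / sqrt(2))
                praw <- 2 * pt(-abs(est) / se, df_res)
                padj <- ptukey(q, k, df_res, lower.tail = FALSE)
                add(b, paste(levels(A)[j], "-", levels(A)[i]), est,
                    est / se, praw, padj)
            }
        }
    } else if (method == "sidak") {
        if (nlevels(A) != 2)
            stop("sidak family expects exactly 2 levels of factor_a")
        m <- nlevels(B)
        for (b in levels(B)) {
            sel <- B == b
            g1 <- y[sel & A == levels(A)[1]]
            g2 <- y[sel & A == levels(A)[2]]
            est <- mean(g2) - mean(g1)
            se <- sqrt(mse * (1 / length(g1) + 1 / length(g2)))
            praw <- 2 * pt(-abs(est) / se, df_res)
            add(b, paste0(levels(A)[2], " - ", levels(A)[1], " @ ", b),
                est, est / se, praw, 1 - (1 - praw)^m)
        }
    } else {
        if (is.null(reference)) stop("dunnett requires a reference level")
        if (!reference %in% levels(B))
            stop("reference level not found in factor_b")
        k <- nlevels(B) - 1L
        for (a in levels(A)) {
            ref <- y[A == a & B == reference]
            for (b in setdiff(levels(B), reference)) {
                g <- y[A == a & B == b]
                if (!length(g) || !length(ref)) next
                est <- mean(g) - mean(ref)
                se <- sqrt(mse * (1 / length(g) + 1 / length(ref)))
                tv <- est / se
                praw <- 2 * pt(-abs(tv), df_res)
                add(a, paste0(b, " - ", reference, " @ ", a), est, tv,
                    praw, dunnett_p_adjust(tv, k, df_res))
            }
        }
    }
    out <- do.call(rbind, res)
    out$stars <- p_stars(out$p_adj)
    class(out) <- c("comparison_result", class(out))
    out
}

#' Significance stars and p-value formatting
#'
#' Star cutpoints 0.05 / 0.005 / 0.0005 / 0.0001; p-values below 0.0001 are
#' reported as `"<0.0001"`.
#'
#' @param p numeric p-values.
#' @return character vector.
#' @export
p_stars <- function(p) {
    cut_pts <- analysis_defaults()$star_cutpoints
    vapply(p, function(pi) {
        if (is.na(pi)) return("")
        if (pi < cut_pts[4]) "****"
        else if (pi < cut_pts[3]) "***"
        else if (pi < cut_pts[2]) "**"
        else if (pi < cut_pts[1]) "*"
        else ""
    }, character(1))
}

#' @rdname p_stars
#' @export
format_p <- function(p) {
    vapply(p, function(pi) {
        if (is.na(pi)) return("NA")
        if (pi < 1e-4) "<0.0001" else sprintf("%.4g", pi)
    }, character(1))
}
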