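## Immunocytochemistry arm: synthetic 3-channel fluorescence fields with
## ground truth, nucleus segmentation + marker-colocalization viability
## classification, and synapsin puncta density along MAP2-positive neurite
## skeletons.

#' A multi-channel fluorescence field
#'
#' @param channels named list of equal-dimension intensity matrices
#'   (viability fields: `dapi`, `cellevent`, `pi`; puncta fields: `dapi`,
#'   `map2`, `synapsin`).
#' @param pixel_size_um micrometres per pixel.
#' @param truth optional generator ground truth.
#' @return an object of class `field_image`.
#' @export
field_image <- function(channels, pixel_size_um, truth = NULL) {
    stopifnot(is.list(channels), length(channels) >= 1, pixel_size_um > 0)
    dims <- vapply(channels, dim, numeric(2))
    if (any(dims != dims[, 1])) stop("channel dimensions differ")
    structure(list(channels = channels, pixel_size_um = pixel_size_um,
                   truth = truth), class = "field_image")
}

# Stamp a Gaussian blob of peak `amp` and width `sigma` (px) centred at
# (r, c) into matrix `img` (in place semantics via return).
.stamp_blob <- function(img, r, c, sigma, amp) {
    half <- ceiling(4 * sigma)
    rr <- max(1, round(r) - half):min(nrow(img), round(r) + half)
    cc <- max(1, round(c) - half):min(ncol(img), round(c) + half)
    g <- outer(rr - r, cc - c, function(dr, dc)
        exp(-(dr^2 + dc^2) / (2 * sigma^2)))
    img[rr, cc] <- img[rr, cc] + amp * g
    img
}

#' Synthesize a viability field (DAPI / CellEvent / PI)
#'
#' Nuclei are Gaussian blobs in the DAPI channel placed with a minimum
#' separation; each cell is drawn a class from `fractions`. Apoptotic and
#' dead cells are additionally marked in the CellEvent channel, dead cells
#' also in the PI channel; "unclassified" cells (a PI-without-CellEvent
#' pattern outside the assay's rubric) are marked in PI only. Ground truth
#' labels are stored in `truth`.
#'
#' @param n_cells nuclei per field (~100 for a 40x field).
#' @param fractions class probabilities, named or ordered
#'   `(live, apoptotic, dead[, unclassified])`; renormalised to sum to 1.
#' @param noise_sd Gaussian background noise SD (intensity units ~ [0,1]).
#' @param dim image size in pixels.
#' @param pixel_size_um micrometres per pixel (0.32 ~ 40x objective).
#' @param seed optional integer seed.
#' @return a [field_image()]; if placement fails for some cells a warning
#'   reports the overcrowding and fewer nuclei are placed.
#' @export
synth_viability_field <- function(n_cells = 100,
                                  fractions = c(live = 0.9, apoptotic = 0.06,
                                                dead = 0.03,
                                                unclassified = 0.01),
                                  noise_sd = 0.02, dim = c(384, 384),
                                  pixel_size_um = 0.32, seed = NULL) {
    if (length(fractions) == 3) fractions <- c(fractions, 0)
    stopifnot(length(fractions) == 4, all(fractions >= 0), sum(fractions) > 0)
    fractions <- fractions / sum(fractions)
    with_seed(seed, {
        nr <- dim[1]; nc <- dim[2]
        # min_sep is chosen so that two adjacent nuclei's Gaussian tails
        # cannot sum above a global threshold and bridge into one component
        sigma <- 3.5; min_sep <- 16; margin <- 10
        xs <- numeric(0); ys <- numeric(0)
        tries <- 0L
        while (length(xs) < n_cells && tries < n_cells * 200L) {
            tries <- tries + 1L
            x <- runif(1, margin, nr - margin)
            y <- runif(1, margin, nc - margin)
            if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
                xs <- c(xs, x); ys <- c(ys, y)
            }
        }
        if (length(xs) < n_cells)
            warning("field overcrowded: placed ", length(xs), " of ",
                    n_cells, " nuclei")
        n <- length(xs)
        labels <- sample(c("live", "apoptotic", "dead", "unclassified"),
                         n, replace = TRUE, prob = fractions)
        ch <- list(dapi = matrix(0, nr, nc), cellevent = matrix(0, nr, nc),
                   pi = matrix(0, nr, nc))
        for (i in seq_len(n)) {
            amp <- runif(1, 0.7, 1)
            ch$dapi <- .stamp_blob(ch$dapi, xs[i], ys[i], sigma, amp)
            if (labels[i] %in% c("apoptotic", "dead"))
                ch$cellevent <- .stamp_blob(ch$cellevent, xs[i], ys[i],
                                            sigma, 0.8 * amp)
            if (labels[i] %in% c("dead", "unclassified"))
                ch$pi <- .stamp_blob(ch$pi, xs[i], ys[i], sigma, 0.8 * amp)
        }
        ch <- lapply(ch, function(m) m + matrix(rnorm(nr * nc, 0, noise_sd),
                                                nr, nc))
        field_image(ch, pixel_size_um,
                    truth = list(centers = data.frame(r = xs, c = ys,
                                                      label = labels)))
    })
}

#' Otsu threshold of an intensity vector
#'
#' @param v numeric vector (or matrix) of intensities.
#' @param n_breaks histogram resolution.
#' @return threshold value maximising between-class variance.
#' @export
otsu_threshold <- function(v, n_breaks = 256) {
    v <- as.numeric(v)
    rng <- range(v, finite = TRUE)
    if (diff(rng) <= 0) return(rng[1])
    h <- hist(v, breaks = seq(rng[1], rng[2], length.out = n_breaks + 1),
              plot = FALSE)
    w <- h$counts / sum(h$counts)
    mids <- h$mids
    w1 <- cumsum(w); w2 <- 1 - w1
    mu1 <- cumsum(w * mids) / pmax(w1, 1e-12)
    mu_t <- sum(w * mids)
    mu2 <- (mu_t - cumsum(w * mids)) / pmax(w2, 1e-12)
    bcv <- w1 * w2 * (mu1 - mu2)^2
    mids[which.max(bcv)]
}

#' Segment nuclei in a DAPI channel
#'
#' Otsu threshold, 8-connected component labelling, minimum-size filter.
#'
#' @param dapi intensity matrix.
#' @param min_size_px minimum nucleus area in pixels.
#' @return list with the label matrix `labels` (0 background) and the kept
#'   component ids `ids`.
#' @export
segment_nuclei <- function(dapi, min_size_px = 30) {
    thr <- otsu_threshold(dapi)
    mask <- dapi > thr
    if (!any(mask)) return(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                                ids = integer(0)))
    lab <- label_components_cpp(mask)
    sizes <- tabulate(lab[lab > 0L])
    list(labels = lab, ids = which(sizes >= min_size_px))
}

# Marker positivity of segmented nuclei for one channel, invariant to
# global intensity scaling: a channel with no real signal (reference
# amplitude below 5 robust noise widths) yields all-negative.
.marker_positive <- function(channel, labels, ids) {
    if (!length(ids)) return(logical(0))
    bg <- median(channel)
    means <- vapply(ids, function(i) mean(channel[labels == i]), numeric(1))
    amp_ref <- max(means - bg)
    if (amp_ref < 5 * mad(channel)) return(rep(FALSE, length(ids)))
    (means - bg) > 0.3 * amp_ref
}

#' Classify cell viability by marker colocalization
#'
#' Nuclei are segmented on DAPI; each nucleus is scored positive/negative
#' for CellEvent and PI by its mean in-mask intensity against an adaptive,
#' scale-invariant threshold. Labels follow the colocalization rubric:
#' live = DAPI only, apoptotic = DAPI + CellEvent, dead = DAPI + CellEvent
#' + PI; the DAPI + PI-only pattern is reported separately as
#' `unclassified` rather than silently folded into a class.
#'
#' @param field a [field_image()] with channels `dapi`, `cellevent`, `pi`.
#' @param min_size_px minimum nucleus area.
#' @return an object of class `cell_counts`: counts `n_live`,
#'   `n_apoptotic`, `n_dead`, `n_unclassified`, `n_total`, `fractions`
#'   (over classified cells, i.e. excluding unclassified), and per-nucleus
#'   `centroids` (row/column/label). Zero segmented nuclei gives zero
#'   counts with `flagged = TRUE`.
#' @export
classify_viability <- function(field, min_size_px = 30) {
    stopifnot(inherits(field, "field_image"),
              all(c("dapi", "cellevent", "pi") %in% names(field$channels)))
    seg <- segment_nuclei(field$channels$dapi, min_size_px)
    ids <- seg$ids
    ce <- .marker_positive(field$channels$cellevent, seg$labels, ids)
    pi_ <- .marker_positive(field$channels$pi, seg$labels, ids)
    lab <- rep("live", length(ids))
    lab[ce & !pi_] <- "apoptotic"
    lab[ce & pi_] <- "dead"
    lab[!ce & pi_] <- "unclassified"
    cent <- if (length(ids)) {
        idx <- which(seg$labels > 0 & matrix(seg$labels %in% ids,
                                             nrow(seg$labels)), arr.ind = TRUE)
        l <- seg$labels[seg$labels > 0 & seg$labels %in% ids]
        data.frame(r = tapply(idx[, 1], l, mean)[as.character(ids)],
                   c = tapply(idx[, 2], l, mean)[as.character(ids)],
                   label = lab, row.names = NULL)
    } else data.frame(r = numeric(0), c = numeric(0), label = character(0))
    n <- c(n_live = sum(lab == "live"), n_apoptotic = sum(lab == "apoptotic"),
           n_dead = sum(lab == "dead"),
           n_unclassified = sum(lab == "unclassified"))
    ncl <- sum(n[1:3])
    structure(list(n_live = n[["n_live"]], n_apoptotic = n[["n_apoptotic"]],
                   n_dead = n[["n_dead"]],
                   n_unclassified = n[["n_unclassified"]],
                   n_total = length(ids),
                   fractions = if (ncl > 0) n[1:3] / ncl else
                       setNames(rep(NA_real_, 3), names(n)[1:3]),
                   labels = lab, centroids = cent,
                   flagged = length(ids) == 0L),
              class = "cell_counts")
}

#' Synthesize a puncta field (DAPI / MAP2 / synapsin)
#'
#' Neurites are random-walk curves of known arc length drawn into the MAP2
#' channel; synapsin puncta are placed along each curve as a Poisson
#' process at linear density `density_per_10um` (per 10 um), plus
#' off-neurite distractor puncta at least 3 um from any neurite. Ground
#' truth (paths, total length, puncta positions) is stored.
#'
#' @param n_neurites curves per field.
#' @param density_per_10um on-neurite puncta per 10 um of neurite.
#' @param dim image size in pixels.
#' @param pixel_size_um micrometres per pixel (0.16 ~ 60x objective).
#' @param noise_sd background noise SD.
#' @param n_distractors off-neurite puncta.
#' @param seed optional integer seed.
#' @return a [field_image()].
#' @export
synth_puncta_field <- function(n_neurites = 6, density_per_10um = 1.2,
                               dim = c(512, 512), pixel_size_um = 0.16,
                               noise_sd = 0.02, n_distractors = 5,
                               seed = NULL) {
    stopifnot(density_per_10um >= 0)
    with_seed(seed, {
        nr <- dim[1]; nc <- dim[2]
        margin <- 12
        map2 <- matrix(0, nr, nc)
        syn <- matrix(0, nr, nc)
        dapi <- matrix(0, nr, nc)
        paths <- list()
        puncta <- data.frame(r = numeric(0), c = numeric(0),
                             on_neurite = logical(0))
        for (k in seq_len(n_neurites)) {
            n_steps <- sample(380:480, 1)
            r <- runif(1, margin, nr - margin)
            c <- runif(1, margin, nc - margin)
            ang <- runif(1, 0, 2 * pi)
            pts <- matrix(NA_real_, n_steps + 1, 2)
            pts[1, ] <- c(r, c)
            for (i in seq_len(n_steps)) {
                ang <- ang + rnorm(1, 0, 0.08)
                r2 <- r + cos(ang); c2 <- c + sin(ang)
                # reflect off the field margin
                if (r2 < margin || r2 > nr - margin) {
                    ang <- pi - ang; r2 <- r + cos(ang); c2 <- c + sin(ang)
                }
                if (c2 < margin || c2 > nc - margin) {
                    ang <- -ang; r2 <- r + cos(ang); c2 <- c + sin(ang)
                }
                r <- min(max(r2, margin), nr - margin)
                c <- min(max(c2, margin), nc - margin)
                pts[i + 1, ] <- c(r, c)
            }
            paths[[k]] <- pts
            for (i in seq_len(nrow(pts)))
                map2 <- .stamp_blob(map2, pts[i, 1], pts[i, 2], 1.2, 0.6)
            len_um <- sum(sqrt(rowSums(diff(pts)^2))) * pixel_size_um
            n_p <- rpois(1, density_per_10um * len_um / 10)
            if (n_p > 0) {
                s <- runif(n_p, 0, nrow(pts) - 1)
                i0 <- floor(s) + 1; fr <- s - floor(s)
                pr <- pts[i0, 1] * (1 - fr) + pts[pmin(i0 + 1, nrow(pts)), 1] * fr
                pc <- pts[i0, 2] * (1 - fr) + pts[pmin(i0 + 1, nrow(pts)), 2] * fr
                for (i in seq_len(n_p))
                    syn <- .stamp_blob(syn, pr[i], pc[i], 1.9,
                                       runif(1, 0.8, 1.2))
                puncta <- rbind(puncta, data.frame(r = pr, c = pc,
                                                   on_neurite = TRUE))
            }
        }
        all_pts <- do.call(rbind, paths)
        excl_px <- 3 / pixel_size_um
        placed <- 0L; tries <- 0L
        while (placed < n_distractors && tries < 100L * n_distractors) {
            tries <- tries + 1L
            r <- runif(1, margin, nr - margin)
            c <- runif(1, margin, nc - margin)
            if (min((all_pts[, 1] - r)^2 + (all_pts[, 2] - c)^2) >
                    excl_px^2) {
                syn <- .stamp_blob(syn, r, c, 1.9, runif(1, 0.8, 1.2))
                puncta <- rbind(puncta, data.frame(r = r, c = c,
                                                   on_neurite = FALSE))
                placed <- placed + 1L
            }
        }
        for (i in seq_len(3))
            dapi <- .stamp_blob(dapi, runif(1, margin, nr - margin),
                                runif(1, margin, nc - margin), 5, 0.9)
        noise <- function(m) m + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
        total_len <- sum(vapply(paths, function(p)
            sum(sqrt(rowSums(diff(p)^2))), numeric(1))) * pixel_size_um
        field_image(list(dapi = noise(dapi), map2 = noise(map2),
                         synapsin = noise(syn)), pixel_size_um,
                    truth = list(paths = paths, total_length_um = total_len,
                                 puncta = puncta,
                                 density_per_10um = density_per_10um))
    })
}

# Morphological thinning (Guo-Hall) of a logical mask, vectorised over
# shifted neighbour matrices. Guo-Hall is preferred over Zhang-Suen here
# because it does not leave the 2-px staircases that inflate path-length
# estimates on oblique curves.
skeletonize <- function(mask) {
    sh <- function(m, dr, dc) {
        nr <- nrow(m); nc <- ncol(m)
        out <- matrix(FALSE, nr, nc)
        rs <- max(1, 1 + dr):min(nr, nr + dr)
        cs <- max(1, 1 + dc):min(nc, nc + dc)
        out[rs, cs] <- m[rs - dr, cs - dc]
        out
    }
    m <- mask
    repeat {
        changed <- FALSE
        for (pass in 0:1) {
            p2 <- sh(m, -1, 0); p3 <- sh(m, -1, 1); p4 <- sh(m, 0, 1)
            p5 <- sh(m, 1, 1); p6 <- sh(m, 1, 0); p7 <- sh(m, 1, -1)
            p8 <- sh(m, 0, -1); p9 <- sh(m, -1, -1)
            C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
                 (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
            N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
            N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
            N <- pmin(N1, N2)
            m2 <- if (pass == 0) ((p6 | p7 | !p9) & p8) else
                                 ((p2 | p3 | !p5) & p4)
            cond <- m & C == 1 & N >= 2 & N <= 3 & !m2
            if (any(cond)) {
                m[cond] <- FALSE
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    m
}

# Skeleton path length in pixels: orthogonal and diagonal pixel
# adjacencies weighted by the Vossepoel-Smeulders step lengths (0.980 /
# 1.406). A diagonal adjacency that merely shortcuts two orthogonal steps
# through a corner pixel is not an extra path segment and is skipped.
.skeleton_length_px <- function(s) {
    nr <- nrow(s); nc <- ncol(s)
    orth <- sum(s[, -1] & s[, -nc]) + sum(s[-1, ] & s[-nr, ])
    ri <- 1:(nr - 1); ci <- 1:(nc - 1)
    # pairs (r,c)-(r+1,c+1), bridged by (r+1,c) or (r,c+1)
    d1 <- s[ri, ci] & s[ri + 1, ci + 1] &
        !(s[ri + 1, ci] | s[ri, ci + 1])
    # pairs (r+1,c)-(r,c+1), bridged by (r,c) or (r+1,c+1)
    d2 <- s[ri + 1, ci] & s[ri, ci + 1] &
        !(s[ri, ci] | s[ri + 1, ci + 1])
    0.980 * orth + 1.406 * (sum(d1) + sum(d2))
}

.gauss_blur <- function(img, sigma) {
    half <- ceiling(3 * sigma)
    k <- dnorm(-half:half, sd = sigma)
    k <- k / sum(k)
    pad <- function(m, n) rbind(m[rep(1, n), , drop = FALSE], m,
                                m[rep(nrow(m), n), , drop = FALSE])
    conv1 <- function(m) {
        mp <- pad(m, half)
        out <- matrix(0, nrow(m), ncol(m))
        for (i in seq_along(k))
            out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
        out
    }
    t(conv1(t(conv1(img))))
}

#' Quantify synapsin puncta per 10 um of MAP2-positive neurite
#'
#' The MAP2 channel is thresholded (adaptive, scale-invariant) and
#' skeletonized; neurite length is the diagonal-corrected skeleton path
#' length times the pixel size. Puncta are local maxima of the
#' difference-of-Gaussians-filtered synapsin channel above a robust noise
#' threshold, counted when within `assoc_radius_um` of the skeleton.
#'
#' @param field a [field_image()] with channels `map2` and `synapsin`.
#' @param assoc_radius_um maximum punctum-to-skeleton distance (default
#'   1 um).
#' @param min_length_um below this total neurite length the density is
#'   undefined (NA, flagged).
#' @param dog_sigma_px inner scale of the DoG detector (outer = 1.6x).
#' @return an object of class `puncta_result`: `n_puncta`,
#'   `neurite_length_um`, `density_per_10um`, `flagged`.
#' @export
quantify_puncta <- function(field, assoc_radius_um = 1, min_length_um = 10,
                            dog_sigma_px = 1.6) {
    stopifnot(inherits(field, "field_image"),
              all(c("map2", "synapsin") %in% names(field$channels)))
    px <- field$pixel_size_um
    map2 <- field$channels$map2
    bg <- median(map2)
    ref <- quantile(map2, 0.999)
    # contrast guard: a channel with no structure above the noise floor
    # yields an empty mask rather than thresholding pure noise
    mask <- if ((ref - bg) < 5 * mad(as.numeric(map2)))
        matrix(FALSE, nrow(map2), ncol(map2))
    else map2 > bg + 0.25 * (ref - bg)
    skel <- skeletonize(mask)
    len_um <- .skeleton_length_px(skel) * px
    syn <- field$channels$synapsin
    dog <- .gauss_blur(syn, dog_sigma_px) - .gauss_blur(syn,
                                                        1.6 * dog_sigma_px)
    thr <- max(6 * mad(as.numeric(dog)), 1e-9)
    nr <- nrow(dog); nc <- ncol(dog)
    inner <- 2:(nr - 1)
    innc <- 2:(nc - 1)
    ctr <- dog[inner, innc]
    is_max <- ctr > thr &
        ctr >= dog[inner - 1, innc] & ctr >= dog[inner + 1, innc] &
        ctr >= dog[inner, innc - 1] & ctr >= dog[inner, innc + 1] &
        ctr >= dog[inner - 1, innc - 1] & ctr >= dog[inner - 1, innc + 1] &
        ctr >= dog[inner + 1, innc - 1] & ctr > dog[inner + 1, innc + 1]
    pk <- which(is_max, arr.ind = TRUE) + 1L
    n_assoc <- 0L
    if (nrow(pk) && any(skel)) {
        sk <- which(skel, arr.ind = TRUE)
        rad_px <- assoc_radius_um / px
        for (i in seq_len(nrow(pk))) {
            d2 <- (sk[, 1] - pk[i, 1])^2 + (sk[, 2] - pk[i, 2])^2
            if (min(d2) <= rad_px^2) n_assoc <- n_assoc + 1L
        }
    }
    flagged <- len_um < min_length_um
    structure(list(n_puncta = n_assoc, neurite_length_um = len_um,
                   density_per_10um = if (flagged) NA_real_ else
                       10 * n_assoc / len_um,
                   flagged = flagged),
              class = "puncta_result")
}
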