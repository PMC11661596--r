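## Packaged condition profiles: ground-truth multipliers of baseline activity
## as piecewise-linear functions of hours since treatment onset, one profile
## per oxygen x temperature regimen, plus the packaged imaging calibration
## tables. Knots live in inst/extdata/*.json, not in code.

.meaoxia_cache <- new.env(parent = emptyenv())

.read_extdata <- function(name) {
    key <- paste0("json_", name)
    if (!is.null(.meaoxia_cache[[key]])) return(.meaoxia_cache[[key]])
    path <- system.file("extdata", name, package = "meaoxia")
    if (path == "") stop("packaged file not found: ", name)
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    x[["_comment"]] <- NULL
    .meaoxia_cache[[key]] <- x
    x
}

#' Analysis constants
#'
#' The detection/burst/network-burst/inclusion constants of the assay as a
#' named list, read from the packaged `paper_defaults.json`.
#' @return a named list.
#' @export
analysis_defaults <- function() .read_extdata("paper_defaults.json")

#' Condition profiles
#'
#' A condition profile encodes, for one oxygen x temperature regimen, the
#' ground-truth time course of network activity as unitless multipliers of
#' baseline per-electrode firing rate (`mfr`), network burst rate (`nbr`) and
#' network burst duration (`nbd`), piecewise linear in hours since treatment
#' onset, plus the multipliers at the +6 h recovery recording
#' (`recovery_frac`).
#'
#' @param name one of [mea_conditions()].
#' @return `condition_profile()` returns an object of class
#'   `condition_profile`; `condition_profiles()` returns all packaged
#'   profiles as a named list.
#' @export
condition_profile <- function(name) {
    all <- .read_extdata("condition_profiles.json")
    name <- match.arg(name, names(all))
    p <- all[[name]]
    k <- p$knots
    stopifnot(!is.unsorted(k$t_h), all(k$mfr >= 0), all(k$nbr >= 0),
              all(k$nbd >= 0), k$mfr[1] == 1, k$nbr[1] == 1, k$nbd[1] == 1)
    structure(list(name = name, knots = k,
                   recovery_frac = unlist(p$recovery_frac),
                   description = p$description),
              class = "condition_profile")
}

#' @rdname condition_profile
#' @export
condition_profiles <- function() {
    nm <- names(.read_extdata("condition_profiles.json"))
    setNames(lapply(nm, condition_profile), nm)
}

#' Evaluate a profile's multipliers at treatment time t
#'
#' Linear interpolation between knots; constant extrapolation beyond the
#' last knot.
#'
#' @param profile a [condition_profile()].
#' @param t_h hours since treatment onset (vectorised).
#' @return a data.frame with columns `t_h`, `mfr`, `nbr`, `nbd`.
#' @export
profile_frac <- function(profile, t_h) {
    stopifnot(inherits(profile, "condition_profile"))
    k <- profile$knots
    f <- function(y) approx(k$t_h, y, xout = t_h, rule = 2)$y
    data.frame(t_h = t_h, mfr = f(k$mfr), nbr = f(k$nbr), nbd = f(k$nbd))
}

#' @export
print.condition_profile <- function(x, ...) {
    cat(sprintf("<condition_profile> %s\n  %s\n  recovery_frac: mfr %.2f nbr %.2f nbd %.2f\n",
                x$name, x$description, x$recovery_frac[["mfr"]],
                x$recovery_frac[["nbr"]], x$recovery_frac[["nbd"]]))
    invisible(x)
}

#' Packaged immunocytochemistry calibration tables
#'
#' `viability_compositions()` returns the per-condition live/apoptotic/dead/
#' unclassified percentages used by the viability field generator;
#' `puncta_density_table()` returns the per-condition synapsin puncta
#' densities (per 10 um of neurite) used by the puncta field generator.
#'
#' @return a named list (compositions) or named numeric vector (densities).
#' @export
viability_compositions <- function() .read_extdata("viability_compositions.json")

#' @rdname viability_compositions
#' @export
puncta_density_table <- function() unlist(.read_extdata("puncta_densities.json"))
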