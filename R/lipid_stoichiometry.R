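#' Fit a linear intensity standard curve
#'
#' Ordinary least-squares line of signal intensity (e.g. a 31P NMR peak) on
#' standard concentration. The intercept is fitted by default because a
#' baseline signal is plausible; `through_origin = TRUE` forces it to zero.
#'
#' @param points Data frame with columns `concentration` (mM) and
#'   `intensity`, or two numeric vectors via `concentration`/`intensity`.
#' @param concentration,intensity Alternative vector interface.
#' @param through_origin Force the intercept to zero.
#' @return An object of class `standard_curve`: `slope` (units/mM),
#'   `intercept`, `r_squared`, `points`.
#' @export
fit_standard_curve <- function(points = NULL, concentration = NULL,
                               intensity = NULL, through_origin = FALSE) {
  if (is.null(points)) {
    points <- tibble::tibble(concentration = concentration,
                             intensity = intensity)
  }
  points <- tibble::as_tibble(points)
  if (!all(c("concentration", "intensity") %in% names(points))) {
    stop("standard curve needs columns concentration, intensity",
         call. = FALSE)
  }
  if (nrow(points) < 3L) stop("need at least 3 standard points", call. = FALSE)
  if (length(unique(points$concentration)) < 2L) {
    stop("standards must span at least 2 distinct concentrations",
         call. = FALSE)
  }
  fit <- if (through_origin) {
    stats::lm(intensity ~ 0 + concentration, data = points)
  } else {
    stats::lm(intensity ~ concentration, data = points)
  }
  cf <- stats::coef(fit)
  slope <- unname(cf["concentration"])
  intercept <- if (through_origin) 0 else unname(cf["(Intercept)"])
  if (!(slope > 0)) {
    stop("fitted standard-curve slope must be positive", call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = summary(fit)$r.squared, points = points,
         through_origin = through_origin),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> intensity = %.4g * mM %+.4g (r^2 = %.4f, %d points)\n",
    x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Lipid:protein binding stoichiometry from a standard curve
#'
#' Each replicate sample intensity is inverted through the standard curve to
#' a lipid concentration, `(intensity - intercept) / slope`, and divided by
#' the protein concentration to give moles of lipid per mole of protein.
#' Replicates are aggregated at the ratio level (mean and n-1 standard
#' deviation). Intensities below the fitted intercept would imply negative
#' lipid concentrations and are excluded with a warning.
#'
#' @param sample_intensities Numeric vector of replicate intensities.
#' @param curve A [fit_standard_curve()] result.
#' @param protein_concentration Protein concentration in the same units as
#'   the standard concentrations (mM); must be > 0.
#' @return An object of class `stoichiometry_estimate`: `replicate_values`,
#'   `mean`, `sd`, `n_excluded`.
#' @export
estimate_stoichiometry <- function(sample_intensities, curve,
                                   protein_concentration) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!(protein_concentration > 0)) {
    stop("protein_concentration must be > 0", call. = FALSE)
  }
  lipid <- (sample_intensities - curve$intercept) / curve$slope
  neg <- lipid < 0
  if (any(neg)) {
    warning(sum(neg), " replicate(s) below the curve intercept imply ",
            "negative lipid concentration; excluded", call. = FALSE)
  }
  ratios <- lipid[!neg] / protein_concentration
  if (length(ratios) == 0L) {
    stop("no usable replicates after excluding negative concentrations",
         call. = FALSE)
  }
  structure(
    list(replicate_values = ratios,
         mean = mean(ratios),
         sd = if (length(ratios) > 1L) stats::sd(ratios) else NA_real_,
         n_excluded = sum(neg)),
    class = "stoichiometry_estimate"
  )
}

#' @export
print.stoichiometry_estimate <- function(x, ...) {
  cat(sprintf(
    "<stoichiometry_estimate> %.2f +/- %.2f lipids per protein (n = %d%s)\n",
    x$mean, x$sd, length(x$replicate_values),
    if (x$n_excluded) sprintf(", %d excluded", x$n_excluded) else ""))
  invisible(x)
}
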