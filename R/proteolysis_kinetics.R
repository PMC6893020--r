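#' Read an SDS-PAGE densitometry table
#'
#' Expected columns: `condition`, `concentration_uM`, `time_min`,
#' `band_fraction` (substrate band intensity relative to t = 0, in [0, 1]).
#' Gel-image quantification is upstream of this package; the input contract
#' is the quantified table.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_densitometry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_densitometry(tibble::as_tibble(df))
}

#' Validate a densitometry table
#'
#' Checks the column contract, that band fractions lie in [0, 1], and that
#' every (condition, concentration) series includes a t = 0 row with
#' band_fraction 1 (the normalization anchor).
#'
#' @param table A data frame with columns `condition`, `concentration_uM`,
#'   `time_min`, `band_fraction`.
#' @return The table, invisibly usable downstream.
#' @export
validate_densitometry <- function(table) {
  need <- c("condition", "concentration_uM", "time_min", "band_fraction")
  if (!all(need %in% names(table))) {
    stop("densitometry table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(table$band_fraction < 0 | table$band_fraction > 1)) {
    stop("band_fraction must lie in [0, 1]", call. = FALSE)
  }
  anchors <- dplyr::summarise(
    dplyr::group_by(table, .data$condition, .data$concentration_uM),
    has_t0 = any(.data$time_min == 0 & .data$band_fraction == 1),
    .groups = "drop"
  )
  if (!all(anchors$has_t0)) {
    stop("every (condition, concentration) series needs a t = 0 row with band_fraction = 1",
         call. = FALSE)
  }
  tibble::as_tibble(table)
}

#' Concentration-normalized proteolysis rate from densitometry
#'
#' For each substrate concentration the initial rate is the average substrate
#' loss per minute, `(1 - band_fraction) / time`, over the sampled timepoints
#' (an initial-rate approximation appropriate for short, linear-range
#' sampling). The per-concentration rates are then regressed on concentration
#' through the origin — a true proteolysis rate is zero at zero substrate —
#' giving a slope in units of substrate loss per minute per uM. The
#' (uncentered) r-squared of that zero-intercept fit diagnoses whether the
#' measurements lie in the linear range: saturating rates fit a line through
#' the origin poorly.
#'
#' @param table Densitometry table (see [read_densitometry()]).
#' @param condition Condition name to fit.
#' @param r2_threshold Linearity threshold on r-squared (default 0.9).
#' @return An object of class `rate_estimate`: `condition`, `slope`,
#'   `r_squared`, `linear_range_ok` (NA when only one concentration was
#'   measured), `rates` (per-concentration tibble), `relative_rate`
#'   (NA until normalized with [relative_rate()]).
#' @export
fit_rate <- function(table, condition, r2_threshold = 0.9) {
  table <- validate_densitometry(table)
  sub <- table[table$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for condition '", condition, "'",
                            call. = FALSE)
  obs <- sub[sub$time_min > 0, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no post-zero timepoints for '", condition, "'",
                            call. = FALSE)
  rates <- dplyr::summarise(
    dplyr::group_by(obs, .data$concentration_uM),
    rate = mean((1 - .data$band_fraction) / .data$time_min),
    n_timepoints = dplyr::n(),
    .groups = "drop"
  )
  x <- rates$concentration_uM
  y <- rates$rate
  slope <- sum(x * y) / sum(x^2)
  rss <- sum((y - slope * x)^2)
  tss <- sum(y^2)  # uncentered: the model has no intercept
  r_squared <- if (tss > 0) max(0, 1 - rss / tss) else 1
  if (length(unique(x)) < 2L) {
    warning("single concentration for '", condition,
            "': linear range cannot be assessed", call. = FALSE)
    linear_ok <- NA
  } else {
    linear_ok <- r_squared >= r2_threshold
  }
  structure(
    list(condition = condition, slope = slope, r_squared = r_squared,
         linear_range_ok = linear_ok, rates = rates,
         relative_rate = NA_real_),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> %s: slope = %.4g min^-1 uM^-1 (r^2 = %.3f, linear range %s)\n",
    x$condition, x$slope, x$r_squared,
    if (is.na(x$linear_range_ok)) "not assessed" else
      if (x$linear_range_ok) "ok" else "violated"))
  if (!is.na(x$relative_rate)) {
    cat(sprintf("  relative rate vs apo: %.3f\n", x$relative_rate))
  }
  invisible(x)
}

#' Apo-normalized relative proteolysis rate
#'
#' Divides a sample's concentration-normalized rate by the apo (ligand-free)
#' reference, yielding the dimensionless relative rate of proteolysis; apo vs
#' itself is 1 by construction and a slope of zero (no detectable cleavage)
#' yields 0.
#'
#' @param sample,apo [fit_rate()] results.
#' @return The relative rate (dimensionless).
#' @export
relative_rate <- function(sample, apo) {
  stopifnot(inherits(sample, "rate_estimate"), inherits(apo, "rate_estimate"))
  if (!(apo$slope > 0)) {
    stop("apo reference slope must be > 0 to normalize", call. = FALSE)
  }
  sample$slope / apo$slope
}
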