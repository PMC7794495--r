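#' Conspecific aggregation index
#'
#' For every nest `i`, the aggregation index is the summed exponential decay
#' of distances to all other nests active in the same season:
#' `S_i = sum_{j != i} exp(-d_ij)`. It is a standard proxy for conspecific
#' density: nests embedded in tight clusters score high, isolated nests score
#' near zero. Distances are taken in kilometres by default; at metre scale
#' `exp(-d)` underflows for any realistic nest spacing, so the kilometre is
#' the scale at which the index actually varies (switchable for completeness).
#'
#' @param nests Data frame with columns `nest_id`, `x_km`, `y_km` and
#'   optionally `year`. When a `year` column is present the index is computed
#'   within year, over the nests active that year.
#' @param distance_unit `"km"` (default) or `"m"`.
#' @return `nests` with an added numeric column `S` (and the original
#'   `year` column when supplied).
#' @examples
#' nests <- data.frame(nest_id = c("a", "b"), x_km = c(0, 0), y_km = c(0, 1))
#' aggregation_index(nests)$S  # both exp(-1)
#' @export
aggregation_index <- function(nests, distance_unit = c("km", "m")) {
  distance_unit <- match.arg(distance_unit)
  check_nest_frame(nests)
  out <- nests
  out$S <- NA_real_
  for (idx in year_groups(nests)) {
    d <- pair_distances(nests[idx, , drop = FALSE], distance_unit)
    ek <- exp(-d)
    diag(ek) <- 0
    out$S[idx] <- rowSums(ek)
  }
  out
}

#' Productivity-weighted aggregation index
#'
#' Variant of [aggregation_index()] in which each neighbour's contribution is
#' weighted by its productivity (fledglings that season):
#' `P_i = sum_{j != i} prod_j * exp(-d_ij)`. With all productivities equal to
#' 1 it reduces exactly to the plain aggregation index.
#'
#' @inheritParams aggregation_index
#' @param productivities Non-negative numeric vector, one entry per row of
#'   `nests` (the productivity of that nest-year).
#' @return `nests` with an added numeric column `P`.
#' @export
productivity_weighted_index <- function(nests, productivities,
                                        distance_unit = c("km", "m")) {
  distance_unit <- match.arg(distance_unit)
  check_nest_frame(nests)
  if (length(productivities) != nrow(nests))
    stop("'productivities' must have one value per nest row")
  if (any(is.na(productivities)) || any(productivities < 0))
    stop("productivities must be non-negative and non-missing")
  out <- nests
  out$P <- NA_real_
  for (idx in year_groups(nests)) {
    d <- pair_distances(nests[idx, , drop = FALSE], distance_unit)
    ek <- exp(-d)
    diag(ek) <- 0
    # same summation path as the plain index, so unit productivities
    # reproduce S bit-for-bit
    w <- matrix(productivities[idx], nrow(ek), ncol(ek), byrow = TRUE)
    out$P[idx] <- rowSums(ek * w)
  }
  out
}

#' Residual conspecific productivity
#'
#' The neighbourhood-productivity covariate used downstream is not `P` itself
#' but the residual of an ordinary least-squares regression of `P` on `S`
#' (with intercept), so that it captures whether neighbours are more or less
#' productive than their density alone predicts. Residuals are computed over
#' the whole table supplied (per-year tables should be residualised per year
#' by the caller if desired; the joint fit is the default because the two
#' indices share a common scale across seasons).
#'
#' @param table Data frame carrying numeric columns `S` and `P` for at least
#'   3 nests.
#' @return `table` with an added column `P_resid`; residuals sum to zero.
#' @export
residual_conspecific_productivity <- function(table) {
  if (!all(c("S", "P") %in% names(table)))
    stop("'table' must contain columns 'S' and 'P'")
  if (nrow(table) < 3) stop("need at least 3 nests to residualise P on S")
  if (stats::var(table$S) == 0)
    stop("degenerate design: all aggregation-index values identical")
  fit <- stats::lm(P ~ S, data = table)
  table$P_resid <- stats::residuals(fit)
  table
}

#' Centre covariates before modelling
#'
#' Subtracts the mean so that main effects in models with interactions are
#' interpretable at the average covariate value. The removed mean is kept as
#' an attribute for back-transformation.
#'
#' @param values Numeric vector (non-empty).
#' @return Centred numeric vector with attribute `"center"` holding the mean.
#' @examples
#' center_covariates(c(1, 2, 3))
#' @export
center_covariates <- function(values) {
  if (length(values) == 0) stop("cannot centre an empty vector")
  if (!is.numeric(values)) stop("'values' must be numeric")
  m <- mean(values)
  structure(values - m, center = m)
}

#' Body condition of a chick
#'
#' Condition is the residual of a log-log allometry of body mass on wing
#' length: `log10(mass) - (intercept + slope * log10(wing))`. The default
#' coefficients (1.45, 0.37) are the published allometric line for the study
#' system; base-10 logarithms are used because with natural logs those
#' coefficients would imply implausibly light birds (~28 g instead of ~180 g).
#'
#' @param mass_g Body mass in grams (positive).
#' @param wing_mm Wing length in millimetres (positive).
#' @param coefficients A list or [condition_coefficients()] object with
#'   entries `intercept`, `slope`, `log_base`.
#' @return Numeric vector of condition residuals (dimensionless, log10 g).
#' @examples
#' body_condition(200, 160)  # ~0.0355 above the allometric line
#' @export
body_condition <- function(mass_g, wing_mm,
                           coefficients = condition_coefficients()) {
  if (any(mass_g <= 0) || any(wing_mm <= 0))
    stop("mass and wing length must be positive")
  lg <- function(x) log(x, base = coefficients$log_base)
  lg(mass_g) - (coefficients$intercept + coefficients$slope * lg(wing_mm))
}

#' @rdname body_condition
#' @param intercept,slope,log_base Allometric coefficients and log base.
#' @export
condition_coefficients <- function(intercept = 1.45, slope = 0.37,
                                   log_base = 10) {
  if (!is.finite(slope) || !is.finite(intercept))
    stop("allometric coefficients must be finite")
  structure(list(intercept = intercept, slope = slope, log_base = log_base),
            class = "owl_condition_coefficients")
}

#' Refit the mass-wing allometry on a chick cohort
#'
#' OLS of `log10(mass)` on `log10(wing)`, returning coefficients in the same
#' form consumed by [body_condition()]. Used to recalibrate condition on
#' synthetic cohorts.
#'
#' @param chicks Data frame with positive columns `mass_g` and `wing_mm`
#'   (at least 3 rows).
#' @inheritParams body_condition
#' @return A [condition_coefficients()] object.
#' @export
fit_condition_regression <- function(chicks, log_base = 10) {
  if (nrow(chicks) < 3) stop("need at least 3 chicks")
  if (any(chicks$mass_g <= 0) || any(chicks$wing_mm <= 0))
    stop("mass and wing length must be positive")
  lw <- log(chicks$wing_mm, base = log_base)
  lm_ <- log(chicks$mass_g, base = log_base)
  if (stats::var(lw) == 0)
    stop("degenerate design: all wing lengths identical")
  fit <- stats::lm(lm_ ~ lw)
  condition_coefficients(intercept = unname(stats::coef(fit)[1]),
                         slope = unname(stats::coef(fit)[2]),
                         log_base = log_base)
}

#' Spatial index table for a set of breeding events
#'
#' Convenience wrapper chaining [aggregation_index()],
#' [productivity_weighted_index()] and [residual_conspecific_productivity()]
#' on nest-year records.
#'
#' @param nests Data frame of nests (`nest_id`, `x_km`, `y_km`, optional
#'   `year`).
#' @param productivities Productivity per row of `nests`.
#' @inheritParams aggregation_index
#' @return Data frame with columns `S`, `P`, `P_resid` appended.
#' @export
spatial_indices <- function(nests, productivities,
                            distance_unit = c("km", "m")) {
  distance_unit <- match.arg(distance_unit)
  tab <- aggregation_index(nests, distance_unit)
  tab$P <- productivity_weighted_index(nests, productivities, distance_unit)$P
  residual_conspecific_productivity(tab)
}

# ---- internal helpers -------------------------------------------------------

check_nest_frame <- function(nests) {
  if (!is.data.frame(nests) || nrow(nests) == 0)
    stop("'nests' must be a non-empty data frame")
  if (!all(c("x_km", "y_km") %in% names(nests)))
    stop("'nests' must contain coordinate columns 'x_km' and 'y_km'")
  invisible(nests)
}

year_groups <- function(nests) {
  if ("year" %in% names(nests)) {
    split(seq_len(nrow(nests)), nests$year)
  } else {
    list(seq_len(nrow(nests)))
  }
}

pair_distances <- function(nests, distance_unit) {
  xy <- cbind(nests$x_km, nests$y_km)
  if (distance_unit == "m") xy <- xy * 1000
  as.matrix(stats::dist(xy))
}
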