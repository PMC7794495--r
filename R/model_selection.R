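#' Fit a GLM or GLMM from the study's model families
#'
#' Single fitting surface for every regression model the pipeline uses:
#' binomial (logit), Poisson (log), negative binomial (log) and Gaussian
#' (identity) responses, optionally with an intercept-only zero-inflation
#' component and/or Gaussian random intercepts. Plain fixed-effect models
#' without zero-inflation go through [stats::glm()] (or [MASS::glm.nb()]);
#' anything with random intercepts or zero-inflation is fitted by Laplace-
#' approximated maximum likelihood via \pkg{glmmTMB}. The returned object
#' carries the log-likelihood, the parameter count `k` (including
#' dispersion, zero-inflation and random-effect variance parameters), the
#' sample size `n`, and the fixed-effect estimates with their covariance —
#' everything the AICc machinery needs.
#'
#' @param formula Model formula for the fixed effects (response on the left).
#' @param data Data frame.
#' @param family `"binomial"`, `"poisson"`, `"negative_binomial"` or
#'   `"gaussian"` (canonical links: logit, log, log, identity).
#' @param zero_inflated Add an intercept-only zero-inflation component
#'   (count families only).
#' @param random Optional character vector of grouping-factor column names;
#'   each contributes a Gaussian random intercept.
#' @param name Model label used in model-set tables (default: deparsed
#'   formula).
#' @return Object of class `owl_fit`.
#' @examples
#' d <- data.frame(y = c(rep(1, 7), rep(0, 3)))
#' coef(fit_glm(y ~ 1, d, family = "binomial"))  # qlogis(0.7)
#' @export
fit_glm <- function(formula, data,
                    family = c("binomial", "poisson", "negative_binomial",
                               "gaussian"),
                    zero_inflated = FALSE, random = NULL, name = NULL) {
  family <- match.arg(family)
  if (is.null(name)) name <- deparse(formula)
  if (zero_inflated && family %in% c("binomial", "gaussian"))
    stop("zero-inflation is only supported for count families")
  if (!is.null(random)) {
    if (!all(random %in% names(data)))
      stop("random-effect grouping columns missing from 'data'")
    for (g in random)
      if (length(unique(data[[g]])) < 2)
        stop(sprintf("random term '%s' needs at least 2 groups", g))
  }
  use_tmb <- zero_inflated || !is.null(random)
  if (zero_inflated) {
    resp <- stats::model.response(stats::model.frame(formula, data))
    if (all(resp == 0)) {
      # degenerate: the zero-inflation mass absorbs everything and the ML
      # likelihood of the data is exactly 1 (count coefficients are not
      # identifiable and are reported as 0 with infinite variance)
      warning(sprintf(
        "model '%s': all-zero response; zero-inflation absorbs all mass",
        name))
      X <- stats::model.matrix(formula, data)
      est <- stats::setNames(rep(0, ncol(X)), colnames(X))
      k <- ncol(X) + 1 + (family == "negative_binomial") +
        length(random)
      out <- list(name = name, fit = NULL, engine = "degenerate",
                  family = family, zero_inflated = TRUE, random = random,
                  loglik = 0, k = k, n = nrow(X), estimates = est,
                  vcov = diag(Inf, ncol(X)) |>
                    `dimnames<-`(list(colnames(X), colnames(X))))
      class(out) <- "owl_fit"
      return(out)
    }
  }
  if (use_tmb) {
    fam <- switch(family,
                  binomial = stats::binomial(),
                  poisson = stats::poisson(),
                  negative_binomial = glmmTMB::nbinom2(),
                  gaussian = stats::gaussian())
    # Laplace ML; random-intercept variances sitting on the 0 boundary break
    # the observed information, in which case the offending terms are dropped
    # and the model collapses toward the plain fixed-effect fit.
    repeat {
      f <- formula
      if (length(random) > 0) {
        re <- paste(sprintf("(1 | %s)", random), collapse = " + ")
        f <- stats::as.formula(paste(deparse(formula), "+", re),
                               env = environment(formula))
      }
      fit <- suppressWarnings(
        glmmTMB::glmmTMB(f, data = data, family = fam,
                         ziformula = if (zero_inflated) ~1 else ~0))
      vc <- tryCatch(as.matrix(stats::vcov(fit)$cond), error = function(e) NA)
      vc_ok <- is.matrix(vc) && all(is.finite(vc)) &&
        is.finite(as.numeric(stats::logLik(fit)))
      if (vc_ok || length(random) == 0) break
      vars <- vapply(glmmTMB::VarCorr(fit)$cond, function(m) m[1], numeric(1))
      drop <- names(vars)[vars < 1e-6]
      if (length(drop) == 0) break
      random <- setdiff(random, drop)
      if (length(random) == 0 && !zero_inflated) {
        return(fit_glm(formula, data, family = family, zero_inflated = FALSE,
                       random = NULL, name = name))
      }
    }
    if (!vc_ok)
      warning(sprintf("model '%s' did not converge cleanly", name))
    ll <- stats::logLik(fit)
    est <- glmmTMB::fixef(fit)$cond
    if (!is.matrix(vc)) vc <- matrix(NA_real_, length(est), length(est))
    dimnames(vc) <- list(names(est), names(est))
    out <- list(name = name, fit = fit, engine = "glmmTMB", family = family,
                zero_inflated = zero_inflated,
                random = if (length(random) > 0) random else NULL,
                loglik = as.numeric(ll), k = attr(ll, "df"),
                n = stats::nobs(fit), estimates = est, vcov = vc)
  } else {
    fit <- switch(family,
                  binomial = stats::glm(formula, data = data,
                                        family = stats::binomial()),
                  poisson = stats::glm(formula, data = data,
                                       family = stats::poisson()),
                  gaussian = stats::glm(formula, data = data,
                                        family = stats::gaussian()),
                  negative_binomial = MASS::glm.nb(formula, data = data))
    if (family == "binomial" &&
        any(abs(stats::coef(fit)) > 15, na.rm = TRUE))
      warning(sprintf("model '%s': possible complete separation", name))
    if (anyNA(stats::coef(fit)))
      stop(sprintf("model '%s': rank-deficient design", name))
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")  # counts sigma (gaussian) / theta (neg-bin)
    out <- list(name = name, fit = fit, engine = "glm", family = family,
                zero_inflated = FALSE, random = NULL,
                loglik = as.numeric(ll), k = k, n = stats::nobs(fit),
                estimates = stats::coef(fit), vcov = stats::vcov(fit))
  }
  class(out) <- "owl_fit"
  out
}

#' @rdname fit_glm
#' @param grouping Character vector of grouping factors (random intercepts).
#' @details `fit_random_intercept()` is a thin alias of `fit_glm()` with a
#'   mandatory grouping term, mirroring the "year (and nest) as random
#'   terms" structure used throughout the analyses. When the estimated
#'   random-effect variance collapses to 0 the fixed effects coincide with
#'   the plain GLM fit.
#' @export
fit_random_intercept <- function(formula, data, family = "poisson",
                                 grouping, zero_inflated = FALSE,
                                 name = NULL) {
  if (missing(grouping) || length(grouping) < 1)
    stop("'grouping' is required")
  fit_glm(formula, data, family = family, zero_inflated = zero_inflated,
          random = grouping, name = name)
}

#' @export
print.owl_fit <- function(x, ...) {
  cat(sprintf("<owl_fit> %s [%s%s%s] logLik = %.3f, k = %d, n = %d\n",
              x$name, x$family,
              if (x$zero_inflated) ", zero-inflated" else "",
              if (!is.null(x$random))
                paste0(", (1|", paste(x$random, collapse = ") + (1|"), ")")
              else "",
              x$loglik, x$k, x$n))
  invisible(x)
}

#' @export
coef.owl_fit <- function(object, ...) object$estimates

#' @export
logLik.owl_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
vcov.owl_fit <- function(object, ...) object$vcov

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`; converges to AIC as
#' `n` grows.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size (must exceed `k + 1`).
#' @return Numeric AICc.
#' @examples
#' aicc(-100, 3, 10)  # 210
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1))
    stop("AICc undefined: need n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Assemble a model set with AICc, delta and Akaike weights
#'
#' Orders candidate models by AICc, computes the gap to the best model
#' (`delta`) and the normalised evidence weights
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`. Ties are broken by
#' model name so ordering is reproducible. All models must be fitted to the
#' same response data (checked through `n`).
#'
#' @param models List of `owl_fit` (or [fit_cjs()]) objects.
#' @return Object of class `owl_model_set`: list with a `table` data frame
#'   (`model`, `k`, `loglik`, `AICc`, `delta`, `weight`) and the fitted
#'   `models` in table order.
#' @export
build_model_set <- function(models) {
  if (length(models) < 1) stop("need at least one model")
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- vapply(models, function(m) m$name, character(1))
  ns <- vapply(models, function(m) m$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("models were fitted to different data (sample sizes differ)")
  ic <- vapply(models, function(m)
    if (!is.null(m$aicc)) m$aicc else aicc(m$loglik, m$k, m$n), numeric(1))
  ord <- order(ic, names(models))
  ic <- ic[ord]
  models <- models[ord]
  delta <- ic - ic[1]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tab <- data.frame(
    model = names(models),
    k = vapply(models, function(m) m$k, numeric(1)),
    loglik = vapply(models, function(m) m$loglik, numeric(1)),
    AICc = ic, delta = delta, weight = w,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, models = models), class = "owl_model_set")
}

#' @export
print.owl_model_set <- function(x, digits = 3, ...) {
  tab <- x$table
  tab$loglik <- round(tab$loglik, digits)
  tab$AICc <- round(tab$AICc, digits)
  tab$delta <- round(tab$delta, digits)
  tab$weight <- round(tab$weight, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Full-model (multimodel) averaging of coefficients
#'
#' Averages each requested coefficient over the candidate set with Akaike
#' weights, substituting 0 (with zero variance) in models where the term is
#' absent — the convention under which confidence intervals are reported for
#' weakly supported terms. The unconditional variance combines the
#' within-model variance with the between-model spread:
#' `var = sum_i w_i (var_i + (b_i - bbar)^2)`; 95% CIs are normal-based.
#' By default the whole candidate set is averaged; `delta_max` restricts the
#' set (weights renormalised), e.g. `delta_max = 2` for top-model averaging.
#'
#' @param model_set An [build_model_set()] object.
#' @param terms Character vector of coefficient names (each must appear in
#'   at least one model).
#' @param delta_max Optional delta-AICc cutoff restricting the averaged set.
#' @return Data frame: `term`, `estimate`, `ci_low`, `ci_high`.
#' @export
model_average <- function(model_set, terms, delta_max = Inf) {
  stopifnot(inherits(model_set, "owl_model_set"))
  if (length(terms) == 0) stop("'terms' must be non-empty")
  keep <- model_set$table$delta <= delta_max
  models <- model_set$models[keep]
  w <- model_set$table$weight[keep]
  w <- w / sum(w)
  out <- lapply(terms, function(term) {
    b <- v <- numeric(length(models))
    seen <- FALSE
    for (i in seq_along(models)) {
      est <- models[[i]]$estimates
      j <- match(term, names(est))
      if (!is.na(j)) {
        seen <- TRUE
        b[i] <- est[j]
        v[i] <- models[[i]]$vcov[j, j]
      }
    }
    if (!seen)
      stop(sprintf("term '%s' appears in no model of the set", term))
    bbar <- sum(w * b)
    se <- sqrt(sum(w * (v + (b - bbar)^2)))
    data.frame(term = term, estimate = bbar,
               ci_low = bbar - 1.96 * se, ci_high = bbar + 1.96 * se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a model-set table to CSV
#'
#' Mirrors the published table layout (model, k, AICc, delta-AICc, weight).
#'
#' @param model_set An [build_model_set()] object.
#' @param path Output file path.
#' @export
write_model_set_csv <- function(model_set, path) {
  stopifnot(inherits(model_set, "owl_model_set"))
  utils::write.csv(model_set$table[, c("model", "k", "AICc", "delta",
                                       "weight")],
                   path, row.names = FALSE)
  invisible(path)
}
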