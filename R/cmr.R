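#' Encounter-history utilities
#'
#' `parse_histories()` turns the character `history` column of an
#' encounter-history data frame into a 0/1 matrix and locates the marking
#' (first-capture) occasion of every individual.
#'
#' @param histories Data frame with a character column `history`
#'   (e.g. `"0110100"`); all histories must share one length and contain at
#'   least one detection.
#' @return List: `ch` (integer matrix individuals x occasions), `first`,
#'   `last` (first/last detection occasion per individual).
#' @export
parse_histories <- function(histories) {
  if (!is.data.frame(histories) || nrow(histories) == 0 ||
      !"history" %in% names(histories))
    stop("'histories' must be a non-empty data frame with a 'history' column")
  hs <- histories$history
  len <- unique(nchar(hs))
  if (length(len) != 1) stop("all encounter histories must have equal length")
  ch <- matrix(as.integer(unlist(strsplit(hs, ""), use.names = FALSE)),
               nrow = length(hs), ncol = len, byrow = TRUE)
  if (!all(ch %in% 0:1)) stop("histories must be strings of 0s and 1s")
  if (any(rowSums(ch) == 0)) stop("every history needs at least one detection")
  first <- apply(ch == 1, 1, which.max)
  last <- len + 1 - apply(ch[, len:1, drop = FALSE] == 1, 1, which.max)
  list(ch = ch, first = first, last = last)
}

# Interval- and occasion-level design grids for the CJS likelihood.
#
# phi grid: one row per (individual, interval t = occasion t -> t+1) with
# t >= first capture. Variables: ageclass (JuvU/JuvR/Ad: juvenile parameters
# apply to the first interval after marking only), time (factor), habitat,
# family_unit (0/1), condition (centred), and the indicator shorthands
# juvU/juvR/adult for interactive structures.
#
# p grid: one row per (individual, occasion o > first) with time (factor),
# effort (low/high) and habitat.
cjs_grids <- function(histories, parsed, effort) {
  n <- nrow(parsed$ch)
  T_ <- ncol(parsed$ch)
  first <- parsed$first
  hab <- if ("habitat" %in% names(histories)) histories$habitat
  else rep("urban", n)
  fu <- if ("born_in_family_unit" %in% names(histories))
    as.numeric(histories$born_in_family_unit) else rep(0, n)
  cond <- if ("body_condition" %in% names(histories))
    histories$body_condition else rep(0, n)
  cond <- cond - mean(cond)

  ip <- tp <- integer(0)
  for (t in seq_len(T_ - 1)) {
    at_risk <- which(first <= t)
    ip <- c(ip, at_risk)
    tp <- c(tp, rep.int(t, length(at_risk)))
  }
  juv <- first[ip] == tp
  agecl <- ifelse(juv, ifelse(hab[ip] == "urban", "JuvU", "JuvR"), "Ad")
  phi_df <- data.frame(
    ageclass = factor(agecl, levels = intersect(c("JuvU", "JuvR", "Ad"),
                                                unique(agecl))),
    time = factor(tp),
    habitat = hab[ip],
    family_unit = fu[ip],
    condition = cond[ip],
    juvU = as.numeric(agecl == "JuvU"),
    juvR = as.numeric(agecl == "JuvR"),
    adult = as.numeric(agecl == "Ad"))

  io <- to <- integer(0)
  for (o in 2:T_) {
    seen <- which(first < o)
    io <- c(io, seen)
    to <- c(to, rep.int(o, length(seen)))
  }
  p_df <- data.frame(
    time = factor(to),
    effort = factor(effort[to], levels = c("low", "high")),
    habitat = hab[io])
  p_df$effort <- droplevels(p_df$effort)

  list(n = n, T = T_, ip = ip, tp = tp, io = io, to = to,
       phi_df = phi_df, p_df = p_df)
}

# Negative log-likelihood of the individual-level CJS model, vectorised via
# the backward "never seen again" recursion
# chi_t = 1 - phi_t (1 - (1 - p_{t+1}) chi_{t+1}).
cjs_nll_factory <- function(parsed, grids, Xphi, Xp) {
  n <- grids$n; T_ <- grids$T
  ch <- parsed$ch; first <- parsed$first; last <- parsed$last
  idx_phi <- cbind(grids$ip, grids$tp)
  idx_p <- cbind(grids$io, grids$to)
  # cells contributing direct survival/detection terms: intervals from first
  # capture up to the last detection
  live <- grids$tp < last[grids$ip]
  det_at <- cbind(grids$ip, grids$tp + 1)[live, , drop = FALSE]
  h_det <- ch[det_at]
  idx_chi <- cbind(seq_len(n), last)
  kphi <- ncol(Xphi)

  function(par) {
    phi_v <- stats::plogis(drop(Xphi %*% par[seq_len(kphi)]))
    p_v <- stats::plogis(drop(Xp %*% par[-seq_len(kphi)]))
    phi <- matrix(NA_real_, n, T_ - 1)
    p <- matrix(NA_real_, n, T_)
    phi[idx_phi] <- phi_v
    p[idx_p] <- p_v
    chi <- matrix(1, n, T_)
    for (t in (T_ - 1):1)
      chi[, t] <- 1 - phi[, t] * (1 - (1 - p[, t + 1]) * chi[, t + 1])
    pd <- p[det_at]
    ll <- sum(log(pmax(phi[idx_phi][live], 1e-300))) +
      sum(h_det * log(pmax(pd, 1e-300)) +
            (1 - h_det) * log(pmax(1 - pd, 1e-300))) +
      sum(log(pmax(chi[idx_chi], 1e-300)))
    -ll
  }
}

#' Cormack-Jolly-Seber log-likelihood
#'
#' Log-probability of a set of encounter histories, conditional on first
#' capture, under supplied survival and recapture probabilities. Survival
#' `phi` and recapture `p` may be scalars (constant model), or full matrices
#' (`individuals x (T-1)` intervals and `individuals x T` occasions) for
#' arbitrary structures. Each individual's contribution multiplies survival
#' terms over intervals and detection/non-detection terms over occasions up
#' to its last sighting, then the absorbing "never seen again" probability
#' computed by backward recursion.
#'
#' @param histories Encounter-history data frame (see [parse_histories()]).
#' @param phi Survival probability: scalar or matrix `n x (T-1)`.
#' @param p Recapture probability: scalar or matrix `n x T` (column 1 unused).
#' @return Total log-likelihood (natural log).
#' @examples
#' h <- data.frame(history = "10")
#' cjs_loglik(h, phi = 0.8, p = 0.5)  # log(1 - 0.8 * 0.5)
#' @export
cjs_loglik <- function(histories, phi, p) {
  parsed <- parse_histories(histories)
  n <- nrow(parsed$ch); T_ <- ncol(parsed$ch)
  if (length(phi) == 1) phi <- matrix(phi, n, T_ - 1)
  if (length(p) == 1) p <- matrix(p, n, T_)
  stopifnot(all(dim(phi) == c(n, T_ - 1)), all(dim(p) == c(n, T_)))
  ll <- 0
  for (i in seq_len(n)) {
    f <- parsed$first[i]; l <- parsed$last[i]
    chi <- 1
    if (l < T_)
      for (t in (T_ - 1):l)
        chi <- 1 - phi[i, t] * (1 - (1 - p[i, t + 1]) * chi)
    li <- log(pmax(chi, 1e-300))
    if (l > f) {
      for (t in f:(l - 1)) {
        li <- li + log(pmax(phi[i, t], 1e-300)) +
          ifelse(parsed$ch[i, t + 1] == 1,
                 log(pmax(p[i, t + 1], 1e-300)),
                 log(pmax(1 - p[i, t + 1], 1e-300)))
      }
    }
    ll <- ll + li
  }
  ll
}

#' Fit a Cormack-Jolly-Seber model by maximum likelihood
#'
#' Individual-level CJS likelihood (so individual covariates are supported)
#' maximised on the logit scale by quasi-Newton (BFGS). Survival structures
#' are specified as formulas over `ageclass` (JuvU/JuvR/Ad; juvenile
#' parameters apply to the first interval after marking only), `time`
#' (interval factor), `habitat`, `family_unit`, `condition` (centred
#' body-condition covariate) and the indicators `juvU`, `juvR`, `adult` for
#' age-class-specific covariate slopes. Recapture structures use `time`
#' (occasion factor), `effort` (low/high per occasion) and `habitat`.
#' Confidence intervals come from the observed information via the delta
#' method, back-transformed to the probability scale.
#'
#' @param histories Encounter-history data frame: columns `history`, and
#'   optionally `habitat`, `born_in_family_unit`, `body_condition`.
#' @param phi Right-hand-side formula for survival (default `~ ageclass`).
#' @param p Right-hand-side formula for recapture (default `~ effort`).
#' @param effort Character vector `"low"`/`"high"` per occasion (default:
#'   first two occasions low, remainder high).
#' @param name Model label.
#' @return Object of class `owl_cjs`: logit-scale `estimates` and `vcov`,
#'   `loglik`, `k`, `n` (individuals), `aicc`, fitted `phi_mat`/`p_mat`, and
#'   a `confounded_terminal` flag (set when both survival and recapture are
#'   fully time-dependent, leaving the last phi*p product unidentifiable).
#' @export
fit_cjs <- function(histories, phi = ~ ageclass, p = ~ effort,
                    effort = NULL, name = NULL) {
  parsed <- parse_histories(histories)
  T_ <- ncol(parsed$ch)
  if (T_ < 2) stop("need at least 2 occasions")
  if (is.null(effort))
    effort <- c(rep("low", min(2, T_)), rep("high", max(0, T_ - 2)))
  if (length(effort) != T_)
    stop("'effort' must have one entry per occasion")
  grids <- cjs_grids(histories, parsed, effort)
  phi_tm <- stats::terms(phi)
  p_tm <- stats::terms(p)
  mf_phi <- stats::model.frame(phi_tm, grids$phi_df)
  mf_p <- stats::model.frame(p_tm, grids$p_df)
  Xphi <- stats::model.matrix(phi_tm, mf_phi)
  Xp <- stats::model.matrix(p_tm, mf_p)
  for (nm in c("Xphi", "Xp")) {
    X <- get(nm)
    if (qr(X)$rank < ncol(X))
      warning(sprintf(
        "%s design matrix is rank deficient; affected parameters are not identifiable",
        if (nm == "Xphi") "survival" else "recapture"))
  }
  colnames(Xphi) <- paste0("phi:", colnames(Xphi))
  colnames(Xp) <- paste0("p:", colnames(Xp))
  nll <- cjs_nll_factory(parsed, grids, Xphi, Xp)
  k <- ncol(Xphi) + ncol(Xp)
  start <- rep(0, k)
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 1000, reltol = 1e-10))
  if (opt$convergence != 0)
    warning(sprintf("CJS fit '%s' did not converge (code %d)",
                    name %||% "unnamed", opt$convergence))
  est <- stats::setNames(opt$par, c(colnames(Xphi), colnames(Xp)))
  vc <- tryCatch(solve(opt$hessian), error = function(e) MASS::ginv(opt$hessian))
  dimnames(vc) <- list(names(est), names(est))
  boundary <- any(abs(est) > 10)
  n <- nrow(parsed$ch)
  ll <- -opt$value
  kphi <- ncol(Xphi)
  phi_v <- stats::plogis(drop(Xphi %*% est[seq_len(kphi)]))
  p_v <- stats::plogis(drop(Xp %*% est[-seq_len(kphi)]))
  phi_mat <- matrix(NA_real_, n, T_ - 1)
  p_mat <- matrix(NA_real_, n, T_)
  phi_mat[cbind(grids$ip, grids$tp)] <- phi_v
  p_mat[cbind(grids$io, grids$to)] <- p_v
  confounded <- "time" %in% all.vars(phi) && "time" %in% all.vars(p)
  out <- list(name = name %||% sprintf("phi(%s) p(%s)",
                                       deparse(phi[[2]]), deparse(p[[2]])),
              estimates = est, vcov = vc, loglik = ll, k = k, n = n,
              aicc = aicc(ll, k, n),
              phi_formula = phi, p_formula = p, effort = effort,
              phi_terms = phi_tm, p_terms = p_tm,
              phi_xlev = stats::.getXlevels(phi_tm, mf_phi),
              p_xlev = stats::.getXlevels(p_tm, mf_p),
              kphi = kphi,
              phi_mat = phi_mat, p_mat = p_mat,
              histories = histories, parsed = parsed,
              boundary = boundary, confounded_terminal = confounded,
              convergence = opt$convergence)
  class(out) <- "owl_cjs"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.owl_cjs <- function(x, ...) {
  cat(sprintf("<owl_cjs> %s\n  logLik = %.3f, k = %d, n = %d, AICc = %.2f\n",
              x$name, x$loglik, x$k, x$n, x$aicc))
  if (x$boundary) cat("  note: boundary estimate(s) on the logit scale\n")
  if (x$confounded_terminal)
    cat("  note: terminal phi*p product confounded (fully time-varying)\n")
  invisible(x)
}

#' @export
coef.owl_cjs <- function(object, ...) object$estimates

#' @export
logLik.owl_cjs <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Derived survival or recapture probabilities from a CJS fit
#'
#' Evaluates the fitted linear predictor at user-supplied covariate rows and
#' back-transforms with delta-method confidence intervals.
#'
#' @param fit An [fit_cjs()] object.
#' @param newdata Data frame of covariate rows (same variables as the
#'   corresponding formula; factor levels must match the fit).
#' @param type `"phi"` or `"p"`.
#' @return Data frame: `estimate`, `se`, `ci_low`, `ci_high` (probability
#'   scale), one row per row of `newdata`.
#' @export
predict_cjs <- function(fit, newdata, type = c("phi", "p")) {
  type <- match.arg(type)
  tm <- if (type == "phi") fit$phi_terms else fit$p_terms
  xlev <- if (type == "phi") fit$phi_xlev else fit$p_xlev
  X <- stats::model.matrix(tm, newdata, xlev = xlev)
  sel <- if (type == "phi") seq_len(fit$kphi)
  else (fit$kphi + 1):length(fit$estimates)
  beta <- fit$estimates[sel]
  V <- fit$vcov[sel, sel, drop = FALSE]
  eta <- drop(X %*% beta)
  se_eta <- sqrt(pmax(rowSums((X %*% V) * X), 0))
  est <- stats::plogis(eta)
  data.frame(estimate = est,
             se = se_eta * est * (1 - est),
             ci_low = stats::plogis(eta - 1.96 * se_eta),
             ci_high = stats::plogis(eta + 1.96 * se_eta))
}

#' Akaike-weight model averaging of CJS survival estimates
#'
#' Averages derived real-scale survival (or recapture) estimates over a set
#' of CJS fits to the same data, with unconditional standard errors
#' combining within-fit variance and between-fit spread.
#'
#' @param fits List of [fit_cjs()] objects fitted to identical data.
#' @param newdata Covariate rows at which to evaluate the parameter (passed
#'   to [predict_cjs()]); every fit must be able to evaluate them.
#' @param type `"phi"` or `"p"`.
#' @return Data frame with one row per row of `newdata`: `estimate`,
#'   `se`, `ci_low`, `ci_high` (probability scale, CI clipped to `[0, 1]`),
#'   plus the model-set table as attribute `"model_set"`.
#' @export
cjs_model_average <- function(fits, newdata, type = c("phi", "p")) {
  type <- match.arg(type)
  ms <- build_model_set(fits)
  w <- ms$table$weight
  preds <- lapply(ms$models, predict_cjs, newdata = newdata, type = type)
  est <- sapply(preds, `[[`, "estimate")
  se <- sapply(preds, `[[`, "se")
  if (is.null(dim(est))) { est <- matrix(est, nrow = 1); se <- matrix(se, nrow = 1) }
  bbar <- drop(est %*% w)
  vunc <- drop((se^2 + (est - bbar)^2) %*% w)
  out <- data.frame(estimate = bbar, se = sqrt(vunc),
                    ci_low = pmax(bbar - 1.96 * sqrt(vunc), 0),
                    ci_high = pmin(bbar + 1.96 * sqrt(vunc), 1))
  attr(out, "model_set") <- ms$table
  out
}

#' Release/recapture m-array
#'
#' Classic CMR summary: for each release occasion, the number of individuals
#' released (detected there) and the occasion of their first subsequent
#' recapture. Row sums satisfy `released = sum(recaptures) + never_seen`.
#'
#' @param histories Encounter-history data frame.
#' @return Data frame with columns `occasion`, `released`, `next_2`, ...,
#'   `next_T`, `never_seen`.
#' @export
m_array <- function(histories) {
  parsed <- parse_histories(histories)
  ch <- parsed$ch
  T_ <- ncol(ch)
  rel <- integer(T_ - 1)
  m <- matrix(0L, T_ - 1, T_ - 1,
              dimnames = list(NULL, paste0("next_", 2:T_)))
  for (i in seq_len(nrow(ch))) {
    dets <- which(ch[i, ] == 1)
    for (j in seq_along(dets)) {
      t <- dets[j]
      if (t < T_) {
        rel[t] <- rel[t] + 1L
        if (j < length(dets)) m[t, dets[j + 1] - 1] <- m[t, dets[j + 1] - 1] + 1L
      }
    }
  }
  data.frame(occasion = 1:(T_ - 1), released = rel, m,
             never_seen = rel - rowSums(m))
}

#' Upper-tail chi-square probability
#'
#' Survival function of the chi-square distribution, as used for the overall
#' goodness-of-fit statistic of a CJS model.
#'
#' @param chi2 Observed statistic (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @return Upper-tail probability.
#' @examples
#' chisq_gof_p(34.34, 43)  # 0.824
#' @export
chisq_gof_p <- function(chi2, df) {
  if (any(chi2 < 0)) stop("'chi2' must be non-negative")
  if (any(df < 1)) stop("'df' must be at least 1")
  stats::pchisq(chi2, df, lower.tail = FALSE)
}

#' Parametric-bootstrap goodness of fit for a CJS model
#'
#' Simulates encounter histories from the fitted model (same individuals,
#' marking occasions and covariates), refits the same structure, and
#' compares the deviance (-2 log-likelihood) of the data against the
#' simulated distribution. Also reports the dispersion ratio
#' `c_hat = observed deviance / mean simulated deviance`.
#'
#' @param fit An [fit_cjs()] object.
#' @param n_rep Number of bootstrap replicates (a warning is issued below
#'   50).
#' @param seed Optional integer seed.
#' @return List: `p` (proportion of simulated deviances >= observed),
#'   `c_hat`, `observed_deviance`, `simulated_deviances`.
#' @export
bootstrap_gof <- function(fit, n_rep = 100, seed = NULL) {
  stopifnot(inherits(fit, "owl_cjs"))
  if (n_rep < 50) warning("fewer than 50 bootstrap replicates")
  if (!is.null(seed)) set.seed(seed)
  obs_dev <- -2 * fit$loglik
  devs <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- simulate_from_cjs(fit)
    refit <- fit_cjs(sim, phi = fit$phi_formula, p = fit$p_formula,
                     effort = fit$effort, name = "gof_rep")
    devs[r] <- -2 * refit$loglik
  }
  list(p = mean(devs >= obs_dev), c_hat = obs_dev / mean(devs),
       observed_deviance = obs_dev, simulated_deviances = devs)
}

# Draw new encounter histories from a fitted CJS model, conditioning on the
# observed marking occasions and covariates.
simulate_from_cjs <- function(fit) {
  parsed <- fit$parsed
  n <- nrow(parsed$ch); T_ <- ncol(parsed$ch)
  ch <- matrix(0L, n, T_)
  ch[cbind(seq_len(n), parsed$first)] <- 1L
  alive <- rep(TRUE, n)
  for (t in seq_len(T_ - 1)) {
    started <- parsed$first <= t
    phi_t <- fit$phi_mat[, t]
    surv <- stats::runif(n) < ifelse(is.na(phi_t), 0, phi_t)
    alive <- alive & (!started | surv)
    p_t1 <- fit$p_mat[, t + 1]
    det <- started & alive & (stats::runif(n) < ifelse(is.na(p_t1), 0, p_t1))
    ch[det, t + 1] <- 1L
  }
  out <- fit$histories
  out$history <- apply(ch, 1, paste0, collapse = "")
  out
}
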