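#' Analysis reports
#'
#' Every `run_*_analysis()` function returns an `owl_report`: the analysis
#' name, one or more AICc model-set tables, model-averaged estimates with
#' 95% confidence intervals, and any analysis-specific extras (attendance
#' proportions, averaged survival by group, ...). Reports are plain lists of
#' data frames — deterministic for a given input — and print compactly.
#'
#' @param x An `owl_report`.
#' @param ... Unused.
#' @export
print.owl_report <- function(x, ...) {
  cat(sprintf("== %s ==\n", x$analysis))
  for (nm in names(x$model_sets)) {
    cat(sprintf("\nModel set: %s\n", nm))
    print(x$model_sets[[nm]])
  }
  if (!is.null(x$averaged)) {
    cat("\nModel-averaged estimates (95% CI):\n")
    print(x$averaged, row.names = FALSE)
  }
  invisible(x)
}

report <- function(analysis, model_sets, averaged = NULL, extras = list()) {
  structure(c(list(analysis = analysis, model_sets = model_sets,
                   averaged = averaged), extras),
            class = "owl_report")
}

#' Monthly natal-nest attendance analysis
#'
#' Binomial GLM of monthly presence on time, habitat and their interaction
#' (rural as the reference habitat), the model used to show that fledglings
#' remain at urban natal nests longer than at rural ones.
#'
#' @param attendance Data frame from [simulate_attendance()] (or user data
#'   with columns `present`, `month`, `habitat`).
#' @return An `owl_report` with the single-model set, coefficient table with
#'   Wald 95% CIs, and the observed monthly attendance proportions by
#'   habitat.
#' @export
run_attendance_analysis <- function(attendance) {
  if (!is.data.frame(attendance) || nrow(attendance) == 0)
    stop("'attendance' must be a non-empty data frame")
  stopifnot(all(c("present", "month", "habitat") %in% names(attendance)))
  d <- attendance
  if (length(unique(d$habitat)) < 2)
    stop("attendance data must include both urban and rural birds")
  d$habitat <- factor(d$habitat, levels = c("rural", "urban"))
  fit <- fit_glm(present ~ month * habitat, d, family = "binomial",
                 name = "time * habitat")
  ci <- sqrt(diag(fit$vcov))
  est <- data.frame(term = names(fit$estimates),
                    estimate = unname(fit$estimates),
                    ci_low = unname(fit$estimates - 1.96 * ci),
                    ci_high = unname(fit$estimates + 1.96 * ci),
                    stringsAsFactors = FALSE)
  props <- stats::aggregate(present ~ month + habitat, data = d, FUN = mean)
  report("monthly natal-nest attendance",
         model_sets = list(attendance = build_model_set(list(fit))),
         averaged = est,
         extras = list(monthly_proportions = props))
}

#' Family-unit occurrence analysis
#'
#' Fits the 11-model binomial candidate set relating the probability that a
#' breeding event is a family unit to habitat, conspecific density
#' (aggregation index) and residual conspecific productivity, with year as a
#' random intercept, then model-averages over the full set. Covariates are
#' centred before fitting.
#'
#' @param events Breeding events carrying `unit_type`, `habitat`, `year`
#'   and the spatial covariates `S` and `P_resid` (as produced by
#'   [simulate_breeding_seasons()], or joined from [spatial_indices()] via
#'   `indices`).
#' @param indices Optional spatial-index table (`nest_id`, `year`, `S`,
#'   `P_resid`) to join onto `events`.
#' @return An `owl_report` with the model-set table and averaged estimates
#'   for habitat, density, productivity and their interactions.
#' @export
run_family_unit_analysis <- function(events, indices = NULL) {
  d <- events
  if (!is.null(indices))
    d <- merge(d[setdiff(names(d), c("S", "P", "P_resid"))], indices,
               by = intersect(c("nest_id", "year"), names(indices)))
  stopifnot(all(c("unit_type", "habitat", "year", "S", "P_resid") %in%
                  names(d)))
  d$family <- as.numeric(d$unit_type == "family")
  if (all(d$family == 0) || all(d$family == 1))
    stop("degenerate response: the sample contains a single unit type, ",
         "the occurrence model cannot be fitted (complete separation)")
  d$habitat <- factor(d$habitat, levels = c("rural", "urban"))
  d$density <- as.numeric(center_covariates(d$S))
  d$productivity <- as.numeric(center_covariates(d$P_resid))
  d$year <- factor(d$year)
  forms <- list(
    "habitat + productivity + density" = family ~ habitat + productivity + density,
    "habitat * productivity + density" = family ~ habitat * productivity + density,
    "habitat * density + productivity" = family ~ habitat * density + productivity,
    "habitat + density"                = family ~ habitat + density,
    "habitat * density"                = family ~ habitat * density,
    "habitat * productivity"           = family ~ habitat * productivity,
    "habitat + productivity"           = family ~ habitat + productivity,
    "habitat"                          = family ~ habitat,
    "density"                          = family ~ density,
    "productivity"                     = family ~ productivity,
    "null"                             = family ~ 1)
  fits <- mapply(function(f, nm)
    fit_glm(f, d, family = "binomial", random = "year", name = nm),
    forms, names(forms), SIMPLIFY = FALSE)
  ms <- build_model_set(fits)
  avg <- model_average(ms, c("habitaturban", "density", "productivity",
                             "habitaturban:productivity",
                             "habitaturban:density"))
  report("family-unit occurrence", model_sets = list(occurrence = ms),
         averaged = avg)
}

#' Productivity analyses
#'
#' Zero-inflated Poisson mixed models of annual productivity: (a) over all
#' monitored nests, on habitat, family unit and their interaction with year
#' as a random term; (b) restricted to nests occupied at least once by a
#' family unit, with nest and year random terms. Both candidate sets are
#' model-averaged over the full set.
#'
#' @param events Breeding events (`productivity`, `unit_type`, `habitat`,
#'   `year`, `nest_id`).
#' @return An `owl_report` with both model sets and averaged estimates.
#' @export
run_productivity_analyses <- function(events) {
  stopifnot(all(c("productivity", "unit_type", "habitat", "year",
                  "nest_id") %in% names(events)))
  d <- events
  d$family_unit <- as.numeric(d$unit_type == "family")
  d$habitat <- factor(d$habitat, levels = c("rural", "urban"))
  d$year <- factor(d$year)
  forms_all <- list(
    "habitat * family unit" = productivity ~ habitat * family_unit,
    "habitat + family unit" = productivity ~ habitat + family_unit,
    "habitat"               = productivity ~ habitat,
    "family unit"           = productivity ~ family_unit,
    "null"                  = productivity ~ 1)
  fits_all <- mapply(function(f, nm)
    fit_glm(f, d, family = "poisson", zero_inflated = TRUE,
            random = "year", name = nm),
    forms_all, names(forms_all), SIMPLIFY = FALSE)
  ms_all <- build_model_set(fits_all)
  avg_all <- model_average(ms_all, c("habitaturban", "family_unit",
                                     "habitaturban:family_unit"))

  fam_nests <- unique(d$nest_id[d$family_unit == 1])
  model_sets <- list(all_nests = ms_all)
  averaged <- cbind(set = "all_nests", avg_all)
  if (length(fam_nests) >= 2) {
    df <- d[d$nest_id %in% fam_nests, , drop = FALSE]
    forms_fam <- list(
      "null"                  = productivity ~ 1,
      "habitat"               = productivity ~ habitat,
      "family unit"           = productivity ~ family_unit,
      "habitat + family unit" = productivity ~ habitat + family_unit,
      "habitat * family unit" = productivity ~ habitat * family_unit)
    fits_fam <- mapply(function(f, nm)
      fit_glm(f, df, family = "poisson", zero_inflated = TRUE,
              random = c("year", "nest_id"), name = nm),
      forms_fam, names(forms_fam), SIMPLIFY = FALSE)
    ms_fam <- build_model_set(fits_fam)
    avg_fam <- model_average(ms_fam, c("habitaturban", "family_unit"))
    model_sets$family_nests <- ms_fam
    averaged <- rbind(averaged, cbind(set = "family_nests", avg_fam))
  }
  report("annual productivity", model_sets = model_sets, averaged = averaged)
}

#' Body-condition analyses
#'
#' Gaussian mixed models of chick body condition (the log-log mass/wing
#' residual) on family unit and habitat, with nest and year random
#' intercepts; fitted over all nests and over nests occupied at least once
#' by a family unit.
#'
#' @param chicks Chick records (`mass_g`, `wing_mm`, `born_in_family_unit`,
#'   `habitat`, `year`, `natal_nest`).
#' @param coefficients Allometric line for the condition residual
#'   (default [condition_coefficients()]).
#' @return An `owl_report` with both model sets and averaged estimates.
#' @export
run_condition_analyses <- function(chicks,
                                   coefficients = condition_coefficients()) {
  stopifnot(all(c("mass_g", "wing_mm", "born_in_family_unit", "habitat",
                  "year", "natal_nest") %in% names(chicks)))
  d <- chicks
  d$condition <- body_condition(d$mass_g, d$wing_mm, coefficients)
  d$family_unit <- as.numeric(d$born_in_family_unit)
  d$habitat <- factor(d$habitat, levels = c("rural", "urban"))
  d$year <- factor(d$year)
  forms <- list(
    "family unit"           = condition ~ family_unit,
    "habitat + family unit" = condition ~ habitat + family_unit,
    "habitat * family unit" = condition ~ habitat * family_unit,
    "null"                  = condition ~ 1,
    "habitat"               = condition ~ habitat)
  fit_set <- function(df) {
    fits <- mapply(function(f, nm)
      fit_glm(f, df, family = "gaussian", random = c("year", "natal_nest"),
              name = nm),
      forms, names(forms), SIMPLIFY = FALSE)
    ms <- build_model_set(fits)
    list(ms = ms,
         avg = model_average(ms, c("family_unit", "habitaturban",
                                   "habitaturban:family_unit")))
  }
  all_set <- fit_set(d)
  model_sets <- list(all_nests = all_set$ms)
  averaged <- cbind(set = "all_nests", all_set$avg)
  fam_nests <- unique(d$natal_nest[d$family_unit == 1])
  df <- d[d$natal_nest %in% fam_nests, , drop = FALSE]
  if (length(fam_nests) >= 2 && nrow(df) > 10 &&
      length(unique(df$family_unit)) > 1) {
    fam_set <- fit_set(df)
    model_sets$family_nests <- fam_set$ms
    averaged <- rbind(averaged, cbind(set = "family_nests", fam_set$avg))
  }
  report("chick body condition", model_sets = model_sets,
         averaged = averaged)
}

#' Lifetime reproductive success analysis
#'
#' Zero-inflated negative-binomial GLM of lifetime reproductive success on
#' dispersal strategy (delayed vs first-year dispersal), compared against
#' the null model. For delayers the LRS is expected to already include the
#' natal-year brood (first-degree-relatedness equivalence); this function
#' takes the `lrs` column as given.
#'
#' @param individuals Data frame with columns `strategy` (`"delayed"` /
#'   `"dispersed"`) and `lrs` (non-negative integer).
#' @param zero_inflated Correct for zero inflation (default `TRUE`).
#' @return An `owl_report` with the 2-model set and the averaged strategy
#'   effect.
#' @export
run_lrs_analysis <- function(individuals, zero_inflated = TRUE) {
  stopifnot(all(c("strategy", "lrs") %in% names(individuals)))
  d <- individuals
  d$delayed <- as.numeric(d$strategy == "delayed")
  fits <- list(
    "null" = fit_glm(lrs ~ 1, d, family = "negative_binomial",
                     zero_inflated = zero_inflated, name = "null"),
    "delayed dispersal" = fit_glm(lrs ~ delayed, d,
                                  family = "negative_binomial",
                                  zero_inflated = zero_inflated,
                                  name = "delayed dispersal"))
  ms <- build_model_set(fits)
  avg <- model_average(ms, "delayed")
  report("lifetime reproductive success", model_sets = list(lrs = ms),
         averaged = avg)
}

#' Survival analyses (CJS model sets)
#'
#' Fits the two published CJS candidate sets on encounter histories of birds
#' marked as chicks — the family-structure set (does being born in a family
#' unit change juvenile/adult survival?) and the body-condition set (does
#' chick condition carry into survival?) — with age classes JuvU/JuvR/Ad,
#' additive time variation on survival and a fieldwork-effort effect on
#' recapture. Survival is model-averaged by age class over each set.
#'
#' @param histories Encounter histories (`history`, `habitat`,
#'   `born_in_family_unit`, `body_condition`).
#' @param models Which sets to fit: subset of `c("family", "condition")`.
#' @param effort `"low"`/`"high"` per occasion (default: first two low).
#' @param time_in_phi Include additive time variation in survival (default
#'   `TRUE`; automatically dropped, with a message, when only two occasions
#'   are available and time effects collapse).
#' @return An `owl_report`: one model-set table per requested set, averaged
#'   survival by age class (from the first requested set), and the averaged
#'   condition slope when the condition set is fitted.
#' @export
run_survival_analyses <- function(histories,
                                  models = c("family", "condition"),
                                  effort = NULL, time_in_phi = TRUE) {
  models <- match.arg(models, several.ok = TRUE)
  parsed <- parse_histories(histories)
  T_ <- ncol(parsed$ch)
  if (T_ <= 2 && time_in_phi) {
    message("only two occasions: time effects collapse and are dropped")
    time_in_phi <- FALSE
  }
  tt <- if (time_in_phi) " + time" else ""
  f <- function(rhs) stats::as.formula(paste("~", rhs, tt))
  if (is.null(effort))
    effort <- c(rep("low", min(2, T_)), rep("high", max(0, T_ - 2)))
  # recapture needs both effort levels among occasions 2..T to be estimable
  p_form <- if (length(unique(effort[-1])) >= 2) ~ effort else ~ 1
  family_forms <- list(
    "(JuvU/JuvR/Ad)" = f("ageclass"),
    "(JuvU/JuvR/Ad) + family unit" = f("ageclass + family_unit"),
    "(JuvU/(JuvR*family unit)/Ad)" = f("ageclass + I(juvR*family_unit)"),
    "(JuvU/JuvR/(Ad*family unit))" = f("ageclass + I(adult*family_unit)"),
    "((JuvU*family unit)/JuvR/Ad)" = f("ageclass + I(juvU*family_unit)"),
    "(((JuvU/JuvR)*family unit)/Ad)" =
      f("ageclass + I(juvU*family_unit) + I(juvR*family_unit)"),
    "((JuvU/JuvR/Ad)*family unit)" =
      f("ageclass + I(juvU*family_unit) + I(juvR*family_unit) + I(adult*family_unit)"))
  condition_forms <- list(
    "(JuvU/JuvR/Ad) + body condition" = f("ageclass + condition"),
    "((JuvU/JuvR) + body condition)/Ad" =
      f("ageclass + I((juvU + juvR)*condition)"),
    "(JuvU*body condition)/JuvR/Ad" = f("ageclass + I(juvU*condition)"),
    "JuvU/(JuvR*body condition)/Ad" = f("ageclass + I(juvR*condition)"),
    "JuvU/JuvR/(Ad*body condition)" = f("ageclass + I(adult*condition)"),
    "(JuvU/JuvR/Ad)" = f("ageclass"))
  sets <- list(family = family_forms, condition = condition_forms)[models]
  model_sets <- list()
  fits_by_set <- list()
  for (nm in names(sets)) {
    fits <- mapply(function(fm, label)
      fit_cjs(histories, phi = fm, p = p_form, effort = effort,
              name = label),
      sets[[nm]], names(sets[[nm]]), SIMPLIFY = FALSE)
    fits_by_set[[nm]] <- fits
    model_sets[[nm]] <- build_model_set(fits)
  }
  habs <- if ("habitat" %in% names(histories)) unique(histories$habitat)
  else "urban"
  classes <- c(if ("urban" %in% habs) "JuvU",
               if ("rural" %in% habs) "JuvR",
               if (T_ > 2) "Ad")
  nd <- data.frame(ageclass = factor(classes,
                                     levels = c("JuvU", "JuvR", "Ad")),
                   time = factor(1), family_unit = 0, condition = 0,
                   juvU = as.numeric(classes == "JuvU"),
                   juvR = as.numeric(classes == "JuvR"),
                   adult = as.numeric(classes == "Ad"))
  first_set <- fits_by_set[[1]]
  avg_phi <- cjs_model_average(first_set, nd, type = "phi")
  avg_phi <- cbind(class = classes, avg_phi)
  extras <- list(averaged_survival = avg_phi)
  averaged <- NULL
  if ("condition" %in% names(fits_by_set)) {
    cms <- build_model_set(fits_by_set$condition)
    averaged <- model_average(cms, "phi:condition")
  }
  report("apparent survival (CJS)", model_sets = model_sets,
         averaged = averaged, extras = extras)
}

#' One-shot simulation of a full study dataset
#'
#' Convenience wrapper chaining the landscape, breeding, chick, attendance,
#' encounter-history and dispersal generators under one config.
#'
#' @param config An [sim_config()] object.
#' @param n_occasions Occasions for the encounter histories.
#' @return List: `nests`, `events`, `chicks`, `attendance`, `histories`,
#'   `dispersal`.
#' @export
simulate_study <- function(config = sim_config(), n_occasions = 10) {
  nests <- simulate_landscape(config)
  events <- simulate_breeding_seasons(nests, config)
  chicks <- simulate_chicks(events, config)
  attendance <- simulate_attendance(chicks, config)
  histories <- simulate_encounter_histories(chicks, config,
                                            n_occasions = n_occasions)
  dispersal <- simulate_dispersal(config)
  list(nests = nests, events = events, chicks = chicks,
       attendance = attendance, histories = histories,
       dispersal = dispersal)
}
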