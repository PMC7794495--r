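#' Simulate the nesting landscape
#'
#' Places nests in two square habitats. Urban nests follow a parent-child
#' (Thomas-type) cluster process with a small within-cluster scale, so each
#' nest has several close neighbours; rural nests spread loose clusters over
#' a habitat twice the linear extent, emulating the large rural expanses
#' around a city. The conspecific aggregation index is therefore
#' systematically higher around urban nests — the density gradient the
#' family-unit model feeds on. The rural square is offset from the urban one
#' so cross-habitat distances are large and the two habitats do not inflate
#' each other's indices.
#'
#' @param config An [sim_config()] object.
#' @return Data frame of nest records: `nest_id`, `habitat`
#'   (`"urban"`/`"rural"`), `x_km`, `y_km`.
#' @export
simulate_landscape <- function(config) {
  validate_config(config)
  with_config_seed(config, 101)
  ext <- config$extent_km
  urban <- cluster_points(config$n_nests_urban, ext,
                          n_parents = max(1L, round(config$n_nests_urban / 8)),
                          sd_km = ext / 20)
  rural <- cluster_points(config$n_nests_rural, 2 * ext,
                          n_parents = max(1L, round(config$n_nests_rural / 4)),
                          sd_km = ext / 8)
  rural$x <- rural$x + 3 * ext  # spatially disjoint habitats
  n_u <- config$n_nests_urban
  n_r <- config$n_nests_rural
  data.frame(
    nest_id = c(sprintf("U%04d", seq_len_safe(n_u)),
                sprintf("R%04d", seq_len_safe(n_r))),
    habitat = rep(c("urban", "rural"), c(n_u, n_r)),
    x_km = c(urban$x, rural$x),
    y_km = c(urban$y, rural$y),
    stringsAsFactors = FALSE
  )
}

seq_len_safe <- function(n) if (n > 0) seq_len(n) else integer(0)

cluster_points <- function(n, extent, n_parents, sd_km) {
  if (n == 0) return(list(x = numeric(0), y = numeric(0)))
  px <- stats::runif(n_parents, 0, extent)
  py <- stats::runif(n_parents, 0, extent)
  parent <- sample.int(n_parents, n, replace = TRUE)
  x <- pmin(pmax(px[parent] + stats::rnorm(n, 0, sd_km), 0), extent)
  y <- pmin(pmax(py[parent] + stats::rnorm(n, 0, sd_km), 0), extent)
  list(x = x, y = y)
}

#' Simulate annual breeding events
#'
#' For every nest and season, draws whether the breeding unit is a plain pair
#' or a family unit (pair plus 1-2 extra adults) from a logistic model whose
#' linear predictor combines a habitat baseline with the nest's conspecific
#' aggregation index and residual neighbourhood productivity (centred within
#' habitat; the config slopes act per raw covariate unit, matching the scale
#' on which the analysis reports them). The habitat baseline is calibrated
#' numerically each season so that the marginal family-unit fraction equals
#' the configured habitat probability despite the covariate spread.
#' Productivity is then drawn from a zero-inflated Poisson with a
#' habitat-specific mean and a log-scale family-unit effect. The
#' neighbourhood-productivity index is computed from provisional productivity
#' draws (the previous season's information, conceptually) to avoid
#' circularity between family status and neighbour productivity.
#'
#' @param nests Output of [simulate_landscape()].
#' @param config An [sim_config()] object.
#' @return Data frame of breeding events: `nest_id`, `habitat`, `year`,
#'   `unit_type` (`"pair"`/`"family"`), `n_extra_adults`, `productivity`,
#'   `male_id`, `female_id`, `extra_ids`, plus the generator-side covariates
#'   `S` and `P_resid`.
#' @export
simulate_breeding_seasons <- function(nests, config) {
  validate_config(config)
  if (!is.data.frame(nests) || nrow(nests) == 0)
    stop("'nests' must be a non-empty data frame of nest records")
  with_config_seed(config, 202)
  S <- aggregation_index(nests)$S
  out <- vector("list", config$n_years)
  for (yr in seq_len(config$n_years)) {
    n <- nrow(nests)
    base_prod <- rzipois(n,
                         lambda = ifelse(nests$habitat == "urban",
                                         config$productivity_mean_urban,
                                         config$productivity_mean_rural),
                         pi0 = config$zero_inflation_prob)
    P <- productivity_weighted_index(nests, base_prod)$P
    P_resid <- if (n >= 3 && stats::var(S) > 0)
      stats::residuals(stats::lm(P ~ S)) else rep(0, n)
    slope_part <- config$density_effect * center_within(S, nests$habitat) +
      config$productivity_effect * center_within(P_resid, nests$habitat)
    eta <- rep(-Inf, n)
    for (hb in unique(nests$habitat)) {
      sel <- nests$habitat == hb
      target <- if (hb == "urban") config$p_family_urban
      else config$p_family_rural
      eta[sel] <- calibrate_logit_intercept(slope_part[sel], target) +
        slope_part[sel]
    }
    family <- stats::runif(n) < stats::plogis(eta)
    n_extra <- ifelse(family, ifelse(stats::runif(n) < 0.97, 1L, 2L), 0L)
    lambda <- ifelse(nests$habitat == "urban",
                     config$productivity_mean_urban,
                     config$productivity_mean_rural) *
      exp(config$family_productivity_effect * family)
    prod <- rzipois(n, lambda, config$zero_inflation_prob)
    out[[yr]] <- data.frame(
      nest_id = nests$nest_id,
      habitat = nests$habitat,
      year = yr,
      unit_type = ifelse(family, "family", "pair"),
      n_extra_adults = n_extra,
      productivity = prod,
      male_id = sprintf("M_%s_y%02d", nests$nest_id, yr),
      female_id = sprintf("F_%s_y%02d", nests$nest_id, yr),
      extra_ids = ifelse(family, sprintf("X_%s_y%02d", nests$nest_id, yr), ""),
      S = S,
      P_resid = P_resid,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

center_within <- function(x, group) {
  out <- numeric(length(x))
  for (g in unique(group)) {
    sel <- group == g
    out[sel] <- x[sel] - mean(x[sel])
  }
  out
}

# Solve for the intercept b0 with mean(plogis(b0 + offsets)) = target, so
# the habitat's marginal family-unit frequency matches the configured value
# regardless of the covariate spread.
calibrate_logit_intercept <- function(offsets, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  stats::uniroot(function(b) mean(stats::plogis(b + offsets)) - target,
                 interval = c(-25, 25))$root
}

rzipois <- function(n, lambda, pi0) {
  ifelse(stats::runif(n) < pi0, 0L, stats::rpois(n, lambda))
}

#' Simulate fledgling morphometrics
#'
#' One chick record per simulated fledgling. Wing length is drawn from a
#' normal distribution (an assumption — the source system reports none), and
#' log10 body mass follows the allometric line `1.45 + 0.37*log10(wing)` plus
#' the family-unit condition shift and Gaussian noise.
#'
#' @param events Output of [simulate_breeding_seasons()].
#' @param config An [sim_config()] object.
#' @return Data frame of chick records: `chick_id`, `natal_nest`, `habitat`,
#'   `year`, `sex`, `wing_mm`, `mass_g`, `born_in_family_unit`, `condition`.
#' @export
simulate_chicks <- function(events, config) {
  validate_config(config)
  if (!is.data.frame(events) || nrow(events) == 0)
    stop("'events' must be a non-empty data frame of breeding events")
  with_config_seed(config, 303)
  idx <- rep(seq_len(nrow(events)), events$productivity)
  n <- length(idx)
  if (n == 0) {
    return(data.frame(chick_id = character(0), natal_nest = character(0),
                      habitat = character(0), year = integer(0),
                      sex = character(0), wing_mm = numeric(0),
                      mass_g = numeric(0),
                      born_in_family_unit = logical(0),
                      condition = numeric(0)))
  }
  wing <- pmax(stats::rnorm(n, config$wing_mean_mm, config$wing_sd_mm), 60)
  fu <- events$unit_type[idx] == "family"
  cc <- condition_coefficients()
  resid <- config$condition_family_effect * fu +
    stats::rnorm(n, 0, config$condition_sd)
  mass <- 10^(cc$intercept + cc$slope * log10(wing) + resid)
  data.frame(
    chick_id = sprintf("C%06d", seq_len(n)),
    natal_nest = events$nest_id[idx],
    habitat = events$habitat[idx],
    year = events$year[idx],
    sex = sample(c("M", "F"), n, replace = TRUE),
    wing_mm = wing,
    mass_g = mass,
    born_in_family_unit = fu,
    condition = resid,
    stringsAsFactors = FALSE
  )
}

#' Simulate monthly natal-nest attendance
#'
#' Monthly presence of fledglings at their natal nests from January (month 1)
#' to July (month 7). The marginal presence probability in month `m` follows
#' `logit p = intercept + slope*m + urban + interaction*m*urban`; within a
#' bird, presence is monotone (once gone, gone for good), achieved by a
#' single-uniform coupling against the running minimum of the monthly
#' probabilities, so the monthly marginals still follow the logistic model
#' whenever it is monotone decreasing in time.
#'
#' @param chicks Data frame with at least `chick_id` and `habitat`.
#' @param config An [sim_config()] object.
#' @param months Integer vector of months covered (default 1:7).
#' @return Data frame with one row per bird-month: `chick_id`, `habitat`,
#'   `month`, `present` (0/1).
#' @export
simulate_attendance <- function(chicks, config, months = 1:7) {
  validate_config(config)
  if (!is.data.frame(chicks) || nrow(chicks) == 0)
    stop("'chicks' must be a non-empty data frame")
  with_config_seed(config, 404)
  n <- nrow(chicks)
  urban <- as.numeric(chicks$habitat == "urban")
  u <- stats::runif(n)
  rows <- vector("list", length(months))
  pmin_run <- rep(1, n)
  for (k in seq_along(months)) {
    m <- months[k]
    eta <- config$attendance_intercept +
      config$attendance_time_slope * m +
      config$attendance_urban_effect * urban +
      config$attendance_interaction * m * urban
    pmin_run <- pmin(pmin_run, stats::plogis(eta))
    rows[[k]] <- data.frame(chick_id = chicks$chick_id,
                            habitat = chicks$habitat,
                            month = m,
                            present = as.integer(u < pmin_run),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate capture-mark-recapture encounter histories
#'
#' Standard Cormack-Jolly-Seber generative process for birds marked as
#' chicks: the first interval after marking is survived with the
#' habitat-specific juvenile survival, later intervals with adult survival;
#' both are shifted on the logit scale by the body-condition and family-unit
#' effects in the config. Live birds are detected at each occasion after
#' marking with the effort-specific recapture probability. Histories start
#' with a 1 at the marking occasion; marking occasions are staggered
#' uniformly over occasions `1..n_occasions-1` unless `mark_occasion` says
#' otherwise.
#'
#' @param chicks Data frame with `chick_id`, `habitat` and optionally
#'   `condition` and `born_in_family_unit` (missing columns default to 0 /
#'   `FALSE`).
#' @param config An [sim_config()] object.
#' @param n_occasions Number of capture occasions (>= 2).
#' @param effort_levels Character vector of `"low"`/`"high"` per occasion;
#'   default: first two occasions low, rest high.
#' @param mark_occasion Optional integer vector of marking occasions per
#'   chick.
#' @return Data frame of encounter histories: `individual_id`, `history`
#'   (character, e.g. `"0110100"`), `first` (marking occasion), `habitat`,
#'   `born_in_family_unit`, `body_condition`.
#' @export
simulate_encounter_histories <- function(chicks, config, n_occasions = 10,
                                         effort_levels = NULL,
                                         mark_occasion = NULL) {
  validate_config(config)
  if (n_occasions < 2) stop("'n_occasions' must be at least 2")
  if (!is.data.frame(chicks) || nrow(chicks) == 0)
    stop("'chicks' must be a non-empty data frame")
  if (is.null(effort_levels))
    effort_levels <- c(rep("low", min(2, n_occasions)),
                       rep("high", max(0, n_occasions - 2)))
  if (length(effort_levels) != n_occasions)
    stop("'effort_levels' must have one entry per occasion")
  if (!all(effort_levels %in% c("low", "high")))
    stop("'effort_levels' entries must be 'low' or 'high'")
  with_config_seed(config, 505)
  n <- nrow(chicks)
  cond <- if ("condition" %in% names(chicks)) chicks$condition else rep(0, n)
  fu <- if ("born_in_family_unit" %in% names(chicks))
    chicks$born_in_family_unit else rep(FALSE, n)
  if (is.null(mark_occasion))
    mark_occasion <- sample.int(n_occasions - 1, n, replace = TRUE)
  stopifnot(length(mark_occasion) == n,
            all(mark_occasion >= 1), all(mark_occasion <= n_occasions))
  cond_c <- cond - mean(cond)
  p_occ <- ifelse(effort_levels == "high",
                  config$p_recapture_high, config$p_recapture_low)
  phi_juv <- stats::plogis(
    stats::qlogis(ifelse(chicks$habitat == "urban",
                         config$phi_juv_urban, config$phi_juv_rural)) +
      config$phi_condition_effect * cond_c + config$phi_family_effect * fu)
  phi_ad <- stats::plogis(stats::qlogis(config$phi_adult) +
                            config$phi_condition_effect * cond_c +
                            config$phi_family_effect * fu)
  ch <- matrix(0L, n, n_occasions)
  ch[cbind(seq_len(n), mark_occasion)] <- 1L
  alive <- rep(TRUE, n)
  for (t in seq_len(n_occasions - 1)) {
    started <- mark_occasion <= t
    phi_t <- ifelse(mark_occasion == t, phi_juv, phi_ad)
    alive <- alive & (!started | (stats::runif(n) < phi_t))
    det <- started & alive & (stats::runif(n) < p_occ[t + 1])
    ch[det, t + 1] <- 1L
  }
  data.frame(
    individual_id = chicks$chick_id,
    history = apply(ch, 1, paste0, collapse = ""),
    first = mark_occasion,
    habitat = chicks$habitat,
    born_in_family_unit = fu,
    body_condition = cond,
    stringsAsFactors = FALSE
  )
}

#' Simulate natal dispersal distances
#'
#' Delayed dispersers recruit very close to the natal nest: distances are
#' uniform on `[0, delayed_max_m]` (matching the observed 0-413 m range).
#' First-year dispersers draw from a heavier-tailed log-normal. Only the
#' ordering and ranges of the two distributions are constrained by the study
#' system; the shapes are stand-ins.
#'
#' @param config An [sim_config()] object.
#' @param n_delayed,n_dispersed Record counts per strategy (>= 0).
#' @return Data frame: `individual_id`, `strategy`
#'   (`"delayed"`/`"dispersed"`), `natal_dispersal_m`.
#' @export
simulate_dispersal <- function(config, n_delayed = 14, n_dispersed = 208) {
  validate_config(config)
  if (n_delayed < 0 || n_dispersed < 0) stop("counts must be non-negative")
  with_config_seed(config, 606)
  data.frame(
    individual_id = sprintf("D%04d", seq_len_safe(n_delayed + n_dispersed)),
    strategy = rep(c("delayed", "dispersed"), c(n_delayed, n_dispersed)),
    natal_dispersal_m = c(stats::runif(n_delayed, 0, config$delayed_max_m),
                          stats::rlnorm(n_dispersed, config$dispersed_meanlog,
                                        config$dispersed_sdlog)),
    stringsAsFactors = FALSE
  )
}

#' Pedigree of simulated family units
#'
#' Builds the pedigree the genotype simulator consumes: each family unit has
#' a breeding pair (founders), one delayer (an offspring of the pair born the
#' previous season that stayed at the natal nest), and the current season's
#' chicks. By default all chicks are sired by the breeding male; with
#' `delayer_sires = TRUE` the delayer fathers the brood instead, emulating
#' the rare within-family fertilisation.
#'
#' @param n_families Number of family units.
#' @param chicks_per_family Chicks in the current brood of each family.
#' @param delayer_sires Logical (scalar or per family): does the delayer
#'   father the brood?
#' @return Data frame: `id`, `mother`, `father` (`NA` for founders),
#'   `family`, `role` (`"father"`, `"mother"`, `"delayer"`, `"chick"`).
#' @export
simulate_family_pedigree <- function(n_families = 14, chicks_per_family = 3,
                                     delayer_sires = FALSE) {
  stopifnot(n_families >= 1, chicks_per_family >= 0)
  delayer_sires <- rep_len(delayer_sires, n_families)
  rows <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    fa <- sprintf("F%02d_sire", f); mo <- sprintf("F%02d_dam", f)
    de <- sprintf("F%02d_delayer", f)
    ch <- if (chicks_per_family > 0)
      sprintf("F%02d_chick%d", f, seq_len(chicks_per_family)) else character(0)
    sire <- if (delayer_sires[f]) de else fa
    rows[[f]] <- data.frame(
      id = c(fa, mo, de, ch),
      mother = c(NA, NA, mo, rep(mo, length(ch))),
      father = c(NA, NA, fa, rep(sire, length(ch))),
      family = f,
      role = c("father", "mother", "delayer", rep("chick", length(ch))),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Simulate diploid microsatellite genotypes down a pedigree
#'
#' Founders (individuals with no listed parents) draw both alleles from
#' Hardy-Weinberg proportions at each locus; every other individual inherits
#' one allele from each parent uniformly at random. Afterwards each recorded
#' allele is independently replaced by a random frequency-weighted allele
#' with probability `genotyping_error` — the package's genotyping-error
#' model throughout.
#'
#' @param pedigree Data frame with columns `id`, `mother`, `father` (`NA`
#'   for founders), parents listed before their offspring.
#' @param config An [sim_config()] object (supplies `n_loci`,
#'   `alleles_per_locus`, `genotyping_error`, `seed`).
#' @param freqs Optional allele frequencies (list of named numeric vectors,
#'   one per locus, each summing to 1); generated from the config when `NULL`.
#' @return A [genotype_table()] object.
#' @export
simulate_genotypes <- function(pedigree, config, freqs = NULL) {
  validate_config(config)
  stopifnot(all(c("id", "mother", "father") %in% names(pedigree)))
  with_config_seed(config, 707)
  if (is.null(freqs)) {
    freqs <- replicate(config$n_loci, {
      w <- stats::rexp(config$alleles_per_locus) + 0.2
      stats::setNames(w / sum(w),
                      sprintf("%02d", seq_len(config$alleles_per_locus)))
    }, simplify = FALSE)
    names(freqs) <- sprintf("Locus%02d", seq_len(config$n_loci))
  }
  check_freqs(freqs)
  L <- length(freqs)
  n <- nrow(pedigree)
  geno <- array(NA_character_, dim = c(n, L, 2),
                dimnames = list(pedigree$id, names(freqs), NULL))
  row_of <- stats::setNames(seq_len(n), pedigree$id)
  for (i in seq_len(n)) {
    mo <- pedigree$mother[i]; fa <- pedigree$father[i]
    for (l in seq_len(L)) {
      al <- names(freqs[[l]])
      a1 <- if (is.na(mo)) sample(al, 1, prob = freqs[[l]]) else
        geno[row_of[[mo]], l, sample.int(2, 1)]
      a2 <- if (is.na(fa)) sample(al, 1, prob = freqs[[l]]) else
        geno[row_of[[fa]], l, sample.int(2, 1)]
      geno[i, l, ] <- c(a1, a2)
    }
  }
  e <- config$genotyping_error
  if (e > 0) {
    for (l in seq_len(L)) {
      al <- names(freqs[[l]])
      for (k in 1:2) {
        flip <- stats::runif(n) < e
        if (any(flip))
          geno[flip, l, k] <- sample(al, sum(flip), replace = TRUE,
                                     prob = freqs[[l]])
      }
    }
  }
  genotype_table(ids = pedigree$id, geno = geno, freqs = freqs)
}
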