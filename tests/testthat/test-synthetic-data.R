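test_that("config validation enforces ranges", {
  expect_s3_class(sim_config(), "owl_config")
  expect_error(sim_config(p_family_urban = 1.2), "probability")
  expect_error(sim_config(phi_adult = 0), "inside")
  expect_error(sim_config(extent_km = -1), "positive")
  expect_error(sim_config(n_nests_urban = 0, n_nests_rural = 0),
               "at least one nest")
})

test_that("landscape generator is seeded and habitat-aware", {
  cfg <- sim_config(seed = 1)
  a <- simulate_landscape(cfg)
  b <- simulate_landscape(cfg)
  expect_identical(a, b)

  only_urban <- simulate_landscape(sim_config(n_nests_rural = 0, seed = 2))
  expect_true(all(only_urban$habitat == "urban"))
  expect_equal(nrow(only_urban), 200)
  expect_true(all(only_urban$x_km >= 0 & only_urban$x_km <= 20))
  expect_false(any(duplicated(only_urban$nest_id)))
})

test_that("urban nests are more aggregated than rural ones", {
  cfg <- sim_config(n_nests_urban = 500, n_nests_rural = 500, seed = 3)
  nests <- simulate_landscape(cfg)
  S <- aggregation_index(nests)$S
  expect_gt(mean(S[nests$habitat == "urban"]),
            mean(S[nests$habitat == "rural"]))
})

test_that("family-unit occurrence follows the configured probabilities", {
  nests <- simulate_landscape(sim_config(seed = 4))
  zero <- sim_config(p_family_urban = 0, p_family_rural = 0,
                     density_effect = 0, productivity_effect = 0, seed = 4)
  ev0 <- simulate_breeding_seasons(nests, zero)
  expect_true(all(ev0$unit_type == "pair"))
  expect_true(all(ev0$n_extra_adults == 0))

  sim <- default_sim()
  ev <- sim$events
  urb <- ev$habitat == "urban"
  frac_u <- mean(ev$unit_type[urb] == "family")
  se_u <- sqrt(0.07 * 0.93 / sum(urb))
  expect_lt(abs(frac_u - 0.07), 3 * se_u)
  frac_r <- mean(ev$unit_type[!urb] == "family")
  se_r <- sqrt(0.03 * 0.97 / sum(!urb))
  expect_lt(abs(frac_r - 0.03), 3 * se_r)
  # pair <=> no extra adults
  expect_true(all((ev$unit_type == "pair") == (ev$n_extra_adults == 0)))
})

test_that("zero inflation and productivity behave at the limits", {
  nests <- simulate_landscape(sim_config(seed = 5))
  allzero <- simulate_breeding_seasons(nests, sim_config(
    zero_inflation_prob = 1, seed = 5))
  expect_true(all(allzero$productivity == 0))
  ev <- default_sim()$events
  expect_true(all(ev$productivity >= 0))
})

test_that("chick morphometrics follow the allometric model", {
  sim <- default_sim()
  noiseless_cfg <- sim_config(condition_sd = 0, condition_family_effect = 0,
                              seed = 6)
  ch0 <- simulate_chicks(sim$events, noiseless_cfg)
  expect_equal(body_condition(ch0$mass_g, ch0$wing_mm),
               rep(0, nrow(ch0)), tolerance = 1e-10)

  ch <- sim$chicks
  expect_true(all(ch$wing_mm > 0) && all(ch$mass_g > 0))
  resid <- body_condition(ch$mass_g, ch$wing_mm)
  diff_fu <- mean(resid[ch$born_in_family_unit]) -
    mean(resid[!ch$born_in_family_unit])
  se <- sim$cfg$condition_sd *
    sqrt(1 / sum(ch$born_in_family_unit) / 0.99)
  expect_lt(abs(diff_fu - 0.02), 4 * se)

  null_cfg <- sim_config(condition_family_effect = 0, seed = 7)
  chn <- simulate_chicks(sim$events, null_cfg)
  rn <- body_condition(chn$mass_g, chn$wing_mm)
  d0 <- mean(rn[chn$born_in_family_unit]) - mean(rn[!chn$born_in_family_unit])
  expect_lt(abs(d0), 4 * se)
})

test_that("attendance is monotone within birds and marginally logistic", {
  sim <- default_sim()
  set.seed(8)
  chicks <- sim$chicks[sample(nrow(sim$chicks), 300), ]
  att <- simulate_attendance(chicks, sim$cfg)
  expect_identical(att, simulate_attendance(chicks, sim$cfg))

  # monotone: once absent, never present again
  by_bird <- split(att$present[order(att$chick_id, att$month)],
                   att$chick_id[order(att$chick_id, att$month)])
  expect_true(all(vapply(by_bird, function(p) all(diff(p) <= 0), logical(1))))

  # a very large negative slope empties the nests after month 1
  gone <- simulate_attendance(chicks, sim_config(
    attendance_time_slope = -50, seed = 8))
  expect_true(all(gone$present[gone$month > 1] == 0))

  # GLM recovery of the urban attendance effect (generating value 1.37)
  fit <- stats::glm(present ~ month * factor(habitat,
                                             c("rural", "urban")),
                    data = att, family = stats::binomial())
  urban_hat <- stats::coef(fit)[[3]]
  expect_lt(abs(urban_hat - 1.37), 0.5)
})

test_that("encounter histories follow the CJS generative process", {
  chicks <- data.frame(chick_id = sprintf("c%03d", 1:200),
                       habitat = rep(c("urban", "rural"), 100))
  sure <- sim_config(phi_juv_urban = 1 - 1e-12, phi_juv_rural = 1 - 1e-12,
                     phi_adult = 1 - 1e-12, p_recapture_low = 1 - 1e-12,
                     p_recapture_high = 1 - 1e-12, seed = 9)
  eh <- simulate_encounter_histories(chicks, sure, n_occasions = 6)
  ch <- parse_histories(eh)$ch
  for (i in 1:200) {
    f <- parse_histories(eh)$first[i]
    expect_true(all(ch[i, f:6] == 1))
  }

  dead <- sim_config(phi_juv_urban = 0.001, phi_juv_rural = 0.001,
                     phi_adult = 0.001, seed = 9)
  eh2 <- simulate_encounter_histories(chicks, dead, n_occasions = 6)
  expect_true(all(rowSums(parse_histories(eh2)$ch) == 1))

  expect_error(simulate_encounter_histories(chicks, sure, n_occasions = 1),
               "at least 2")
  expect_error(simulate_encounter_histories(chicks, sure, n_occasions = 5,
                                            effort_levels = c("low", "high")),
               "one entry per occasion")
})

test_that("dispersal distances have the configured ordering", {
  cfg <- sim_config(seed = 10)
  d <- simulate_dispersal(cfg, n_delayed = 200, n_dispersed = 200)
  expect_identical(d, simulate_dispersal(cfg, 200, 200))
  expect_true(all(d$natal_dispersal_m >= 0))
  expect_true(all(d$natal_dispersal_m[d$strategy == "delayed"] <= 413))
  expect_lt(median(d$natal_dispersal_m[d$strategy == "delayed"]),
            median(d$natal_dispersal_m[d$strategy == "dispersed"]))

  only_disp <- simulate_dispersal(cfg, n_delayed = 0, n_dispersed = 10)
  expect_true(all(only_disp$strategy == "dispersed"))
})

test_that("genotype simulation respects Mendel and Hardy-Weinberg", {
  ped <- simulate_family_pedigree(n_families = 8, chicks_per_family = 3)
  cfg0 <- sim_config(genotyping_error = 0, seed = 11)
  gt <- simulate_genotypes(ped, cfg0)
  expect_identical(gt$geno, simulate_genotypes(ped, cfg0)$geno)

  # error-free offspring share an allele with each parent at every locus
  for (f in 1:8) {
    kid <- get_genotype(gt, sprintf("F%02d_chick1", f))
    for (par in c(sprintf("F%02d_sire", f), sprintf("F%02d_dam", f))) {
      pg <- get_genotype(gt, par)
      share <- vapply(seq_len(nrow(kid)), function(l)
        length(intersect(kid[l, ], pg[l, ])) > 0, logical(1))
      expect_true(all(share))
    }
  }

  # forced homozygosity: AA x AA -> AA offspring
  ped1 <- data.frame(id = c("m", "f", "o"), mother = c(NA, NA, "m"),
                     father = c(NA, NA, "f"))
  freqs1 <- list(L1 = c(A = 0.999999, B = 1e-6))
  gt1 <- simulate_genotypes(ped1, sim_config(n_loci = 1, seed = 12),
                            freqs = freqs1)
  expect_true(all(gt1$geno[, 1, ] == "A"))

  # Hardy-Weinberg proportions among founders at a 50/50 biallelic locus
  ped2 <- data.frame(id = sprintf("i%04d", 1:1000),
                     mother = NA_character_, father = NA_character_)
  gt2 <- simulate_genotypes(ped2, sim_config(n_loci = 1, seed = 13),
                            freqs = list(L1 = c(A = 0.5, B = 0.5)))
  g <- apply(gt2$geno[, 1, ], 1, function(a) paste(sort(a), collapse = ""))
  props <- table(factor(g, c("AA", "AB", "BB"))) / 1000
  expect_lt(abs(props[["AA"]] - 0.25), 3 * sqrt(0.25 * 0.75 / 1000))
  expect_lt(abs(props[["AB"]] - 0.50), 3 * sqrt(0.5 * 0.5 / 1000))
})
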