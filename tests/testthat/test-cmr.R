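test_that("history parsing and the m-array tally releases correctly", {
  h <- data.frame(history = c("11010", "00110", "10000", "01111", "00011"))
  parsed <- parse_histories(h)
  expect_equal(parsed$first, c(1, 3, 1, 2, 4))
  expect_equal(parsed$last, c(4, 4, 1, 5, 5))

  ma <- m_array(h)
  expect_equal(ma$released, c(2, 2, 2, 4))
  # hand tally: first recaptures
  expect_equal(ma$next_2[1], 1)  # "11010"
  expect_equal(ma$next_4[2], 1)  # "11010" released at 2, next at 4
  expect_equal(ma$next_4[3], 2)  # "00110" and "01111" both seen 3 -> 4
  expect_equal(ma$next_5[4], 2)
  expect_equal(ma$released, rowSums(ma[, grep("next_", names(ma))]) +
                 ma$never_seen)

  single <- m_array(data.frame(history = "11"))
  expect_equal(single$released, 1)
  expect_equal(single$next_2, 1)
  expect_equal(single$never_seen, 0)

  expect_error(parse_histories(data.frame(history = c("101", "10"))),
               "equal length")
  expect_error(parse_histories(data.frame(history = "000")),
               "at least one detection")
})

test_that("CJS likelihood matches hand-enumerated path probabilities", {
  expect_equal(cjs_loglik(data.frame(history = "11"), 1, 1), 0)
  expect_equal(cjs_loglik(data.frame(history = "10"), 0.8, 0.5), log(0.6))
  expect_equal(cjs_loglik(data.frame(history = "101"), 0.8, 0.5), log(0.16))
})

test_that("CJS likelihood equals the enumeration oracle and probabilities sum to 1", {
  set.seed(14)
  for (T_ in c(3, 4, 6)) {
    phi <- runif(T_ - 1, 0.2, 0.9)
    p <- runif(T_, 0.2, 0.9)
    for (f in c(1, 2)) {
      hs <- all_histories(T_, f)
      probs <- vapply(hs, enum_history_prob, numeric(1), phi = phi, p = p)
      expect_equal(sum(probs), 1, tolerance = 1e-10)
      for (h in hs[probs > 0]) {
        ll <- cjs_loglik(data.frame(history = h),
                         matrix(phi, 1, T_ - 1, byrow = TRUE),
                         matrix(p, 1, T_, byrow = TRUE))
        expect_equal(ll, log(probs[[h]]), tolerance = 1e-10)
      }
    }
  }
})

test_that("likelihood is invariant to history order and relabeling", {
  sim <- default_sim()
  set.seed(15)
  eh <- simulate_encounter_histories(sim$chicks[sample(nrow(sim$chicks),
                                                       150), ],
                                     sim$cfg, n_occasions = 6)
  ll1 <- cjs_loglik(eh, 0.5, 0.4)
  shuffled <- eh[sample(nrow(eh)), ]
  shuffled$individual_id <- paste0("relabel", seq_len(nrow(shuffled)))
  expect_equal(cjs_loglik(shuffled, 0.5, 0.4), ll1, tolerance = 1e-10)
})

test_that("fit_cjs recovers boundary and closed-form cases", {
  ones <- data.frame(history = rep("1111", 40))
  fit1 <- suppressWarnings(fit_cjs(ones, phi = ~1, p = ~1))
  expect_true(fit1$boundary)
  expect_gt(plogis(fit1$estimates[[1]]), 0.99)
  expect_gt(plogis(fit1$estimates[[2]]), 0.99)

  # with perfect detection the survival MLE matches a 1-d profile oracle
  chicks <- data.frame(chick_id = sprintf("c%03d", 1:400), habitat = "urban")
  cfg <- sim_config(phi_juv_urban = 0.6, phi_adult = 0.6,
                    p_recapture_low = 0.999999,
                    p_recapture_high = 0.999999, seed = 16)
  eh <- simulate_encounter_histories(chicks, cfg, n_occasions = 5)
  fit <- suppressWarnings(fit_cjs(eh, phi = ~1, p = ~1))
  phi_hat <- plogis(fit$estimates[[1]])
  oracle <- optimize(function(phi)
    cjs_loglik(eh, phi, 1 - 1e-9), c(0.01, 0.99), maximum = TRUE)$maximum
  expect_equal(phi_hat, oracle, tolerance = 1e-3)
})

test_that("fit_cjs recovers age-class survival on the default cohort", {
  eh <- default_histories()
  fit <- fit_cjs(eh, phi = ~ ageclass, p = ~ effort)
  nd <- data.frame(ageclass = factor(c("JuvU", "JuvR", "Ad"),
                                     levels = c("JuvU", "JuvR", "Ad")))
  pr <- predict_cjs(fit, nd)
  expect_lt(abs(pr$estimate[1] - 0.29), 0.03)
  expect_lt(abs(pr$estimate[2] - 0.21), 0.03)
  expect_lt(abs(pr$estimate[3] - 0.71), 0.03)
  expect_true(all(pr$ci_low < pr$estimate & pr$estimate < pr$ci_high))
  # recapture by effort should bracket the generating 0.3/0.6
  pe <- predict_cjs(fit, data.frame(effort = factor(c("low", "high"),
                                                    c("low", "high"))),
                    type = "p")
  expect_lt(abs(pe$estimate[1] - 0.3), 0.1)
  expect_lt(abs(pe$estimate[2] - 0.6), 0.05)
})

test_that("a constant-zero covariate adds a parameter but no information", {
  sim <- default_sim()
  set.seed(17)
  chicks <- sim$chicks[sample(nrow(sim$chicks), 200), ]
  chicks$condition <- 0
  eh <- simulate_encounter_histories(chicks, sim$cfg, n_occasions = 5)
  base <- fit_cjs(eh, phi = ~ 1, p = ~ 1)
  aug <- suppressWarnings(fit_cjs(eh, phi = ~ condition, p = ~ 1))
  expect_equal(aug$loglik, base$loglik, tolerance = 1e-6)
  expect_equal(aug$k, base$k + 1)
})

test_that("model averaging of survival estimates follows the weight formula", {
  eh <- default_histories()
  f1 <- fit_cjs(eh, phi = ~ ageclass, p = ~ effort)
  ident <- cjs_model_average(list(f1), data.frame(
    ageclass = factor("Ad", c("JuvU", "JuvR", "Ad"))))
  direct <- predict_cjs(f1, data.frame(
    ageclass = factor("Ad", c("JuvU", "JuvR", "Ad"))))
  expect_equal(ident$estimate, direct$estimate, tolerance = 1e-9)

  # hand formula with two stub fits of equal weight and zero variance
  stub <- function(est) {
    structure(list(name = paste0("s", est), estimates = c(`(Intercept)` =
                                                            qlogis(est)),
                   vcov = matrix(0, 1, 1), loglik = -50, k = 1, n = 100,
                   aicc = 102, kphi = 1,
                   phi_terms = terms(~1), p_terms = terms(~1),
                   phi_xlev = list(), p_xlev = list()),
              class = "owl_cjs")
  }
  avg <- cjs_model_average(list(stub(0.3), stub(0.5)),
                           data.frame(dummy = 1))
  expect_equal(avg$estimate, 0.4, tolerance = 1e-9)
})

test_that("chi-square tail probabilities are correct", {
  expect_equal(round(chisq_gof_p(34.34, 43), 3), 0.824)
  expect_equal(chisq_gof_p(0, 7), 1)
  expect_equal(chisq_gof_p(2, 2), exp(-1), tolerance = 1e-12)
  expect_error(chisq_gof_p(-1, 2), "non-negative")
  expect_error(chisq_gof_p(1, 0), "df")
})

test_that("parametric-bootstrap GOF is calm under the generating model", {
  sim <- default_sim()
  set.seed(18)
  chicks <- sim$chicks[sample(nrow(sim$chicks), 250), ]
  eh <- simulate_encounter_histories(chicks, sim$cfg, n_occasions = 6)
  fit <- fit_cjs(eh, phi = ~ ageclass, p = ~ 1)
  expect_warning(bootstrap_gof(fit, n_rep = 10, seed = 1), "50")
  g <- bootstrap_gof(fit, n_rep = 60, seed = 2)
  expect_true(g$p >= 0 && g$p <= 1)
  expect_gt(g$p, 0.05)         # data came from the fitted model itself
  expect_lt(abs(g$c_hat - 1), 0.25)
})
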