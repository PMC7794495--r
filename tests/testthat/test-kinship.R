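test_that("allele frequencies are counted per locus", {
  geno <- array(NA_character_, dim = c(3, 2, 2),
                dimnames = list(c("a", "b", "c"), c("L1", "L2"), NULL))
  geno[, 1, 1] <- c("A", "A", "B"); geno[, 1, 2] <- c("A", "B", "B")
  geno[, 2, 1] <- "A"; geno[, 2, 2] <- "A"
  gt <- genotype_table(c("a", "b", "c"), geno)
  f <- allele_frequencies_from_sample(gt)
  expect_equal(f$L1, c(A = 0.5, B = 0.5))
  expect_equal(f$L2, c(A = 1))

  # LLN recovery from a Hardy-Weinberg sample
  ped <- data.frame(id = sprintf("i%03d", 1:500), mother = NA_character_,
                    father = NA_character_)
  gt2 <- simulate_genotypes(ped, sim_config(n_loci = 1, genotyping_error = 0,
                                            seed = 40),
                            freqs = list(L1 = c(A = 0.7, B = 0.3)))
  f2 <- allele_frequencies_from_sample(gt2)
  expect_lt(abs(f2$L1[["A"]] - 0.7), 0.05)

  geno[, 2, ] <- NA
  gt3 <- genotype_table(c("a", "b", "c"), geno)
  expect_error(allele_frequencies_from_sample(gt3), "no typed")
})

test_that("pair likelihoods match HWE products and gamete enumeration", {
  freqs <- list(L1 = c(A = 0.5, B = 0.5))
  gAA <- gmat(c("A", "A"))
  gBB <- gmat(c("B", "B"))
  gAB <- gmat(c("A", "B"))

  # unrelated: product of HWE genotype probabilities
  expect_equal(pair_likelihood(gAA, gAA, freqs, "U"), log(0.25 * 0.25),
               tolerance = 1e-12)

  # parent-offspring Mendelian exclusion is guarded, not -Inf
  llex <- pair_likelihood(gAA, gBB, freqs, "PO")
  expect_true(is.finite(llex))
  expect_lt(llex, -600)

  # full-sib likelihood against exhaustive gamete enumeration,
  # across several frequency settings and genotype pairs
  for (pA in c(0.5, 0.7, 0.9)) {
    fr <- list(L1 = c(A = pA, B = 1 - pA))
    for (pair in list(list(gAA, gAA), list(gAA, gAB), list(gAB, gAB),
                      list(gAA, gBB))) {
      enum <- enum_fullsib_locus(pair[[1]][1, ], pair[[2]][1, ], fr$L1)
      got <- exp(pair_likelihood(pair[[1]], pair[[2]], fr, "FS"))
      expect_equal(got, enum, tolerance = 1e-10)
    }
  }

  # likelihoods are symmetric in the two individuals
  fr3 <- list(L1 = c(A = 0.2, B = 0.3, C = 0.5))
  gAC <- gmat(c("A", "C"))
  for (cl in c("U", "HS", "FS", "PO"))
    expect_equal(pair_likelihood(gAB, gAC, fr3, cl, error_rate = 0.02),
                 pair_likelihood(gAC, gAB, fr3, cl, error_rate = 0.02),
                 tolerance = 1e-12)

  expect_error(pair_likelihood(gmat(c(NA, NA)), gAB, freqs, "U"),
               "no shared typed loci")
})

test_that("relationship classification recovers simulated kin structure", {
  cfg <- sim_config(seed = 41)  # 17 loci, 5 alleles, error 0.01
  # pedigree with known PO, FS, HS and U pairs
  ped <- list()
  for (f in 1:25) {
    sire <- sprintf("S%02d", f); dam1 <- sprintf("D%02da", f)
    dam2 <- sprintf("D%02db", f)
    ped[[f]] <- data.frame(
      id = c(sire, dam1, dam2, sprintf("O%02d_%d", f, 1:3)),
      mother = c(NA, NA, NA, dam1, dam1, dam2),
      father = c(NA, NA, NA, sire, sire, sire))
  }
  ped <- do.call(rbind, ped)
  gt <- simulate_genotypes(ped, cfg)
  tables <- owlfam:::kinship_tables(gt$freqs, 0.01)

  classify <- function(id1, id2)
    ml_relationship(get_genotype(gt, id1), get_genotype(gt, id2),
                    gt$freqs, 0.01, tables = tables)
  top2 <- function(res, truth) truth %in% res$ranking[1:2]

  po <- fs <- hs <- un <- logical(25)
  r_un <- numeric(25)
  for (f in 1:25) {
    po[f] <- top2(classify(sprintf("S%02d", f), sprintf("O%02d_1", f)), "PO")
    fs[f] <- top2(classify(sprintf("O%02d_1", f), sprintf("O%02d_2", f)), "FS")
    hs[f] <- top2(classify(sprintf("O%02d_1", f), sprintf("O%02d_3", f)), "HS")
    other <- f %% 25 + 1
    res_u <- classify(sprintf("O%02d_1", f), sprintf("O%02d_2", other))
    un[f] <- top2(res_u, "U")
    r_un[f] <- res_u$r
  }
  expect_gte(mean(c(po, fs, hs, un)), 0.9)
  expect_lte(mean(r_un), 0.1)   # unrelated pairs get low relatedness

  # r follows the k-coefficients of the best class
  expect_equal(owlfam:::relationship_r("PO"), 0.5)
  expect_equal(owlfam:::relationship_r("HS"), 0.25)
  expect_equal(owlfam:::relationship_r("U"), 0)
})

test_that("parentage LOD separates true parents from unrelated candidates", {
  freqs <- list(L1 = c(A = 0.5, B = 0.5))
  # exclusion: offspring BB cannot come from an AA parent
  expect_lt(parentage_lod(gmat(c("B", "B")), gmat(c("A", "A")), freqs), -600)

  # single-locus enumeration oracle: offspring AB, candidate AA
  lod <- parentage_lod(gmat(c("A", "B")), gmat(c("A", "A")), freqs)
  p_off_given_parent <- enum_po_locus(c("A", "B"), c("A", "A"), freqs$L1)
  p_off <- 2 * 0.5 * 0.5
  expect_equal(lod, log(p_off_given_parent / p_off), tolerance = 1e-12)

  # richer locus, same oracle
  fr <- list(L1 = c(A = 0.2, B = 0.3, C = 0.5))
  for (cand in list(c("A", "B"), c("A", "C"), c("C", "C"))) {
    off <- c("A", "C")
    lod <- parentage_lod(gmat(off), gmat(cand), fr)
    num <- enum_po_locus(off, cand, fr$L1)
    den <- 2 * fr$L1[["A"]] * fr$L1[["C"]]
    expect_equal(lod, log(num / den), tolerance = 1e-12)
  }

  # simulated trios: true fathers get positive LOD virtually always
  cfg <- sim_config(seed = 42)
  ped <- simulate_family_pedigree(n_families = 50, chicks_per_family = 2)
  gt <- simulate_genotypes(ped, cfg)
  tables <- owlfam:::kinship_tables(gt$freqs, 0.01)
  lods <- lods_trio <- numeric(50)
  for (f in 1:50) {
    off <- get_genotype(gt, sprintf("F%02d_chick1", f))
    sire <- get_genotype(gt, sprintf("F%02d_sire", f))
    dam <- get_genotype(gt, sprintf("F%02d_dam", f))
    lods[f] <- parentage_lod(off, sire, gt$freqs, 0.01, tables = tables)
    lods_trio[f] <- parentage_lod(off, sire, gt$freqs, 0.01,
                                  known_parent = dam, tables = tables)
  }
  expect_gte(mean(lods > 0), 0.99)
  expect_gte(mean(lods_trio > 0), 0.99)
})

test_that("delayers are placed as offspring, not sires, unless they breed", {
  cfg <- sim_config(seed = 43)
  ped <- simulate_family_pedigree(n_families = 12, chicks_per_family = 3)
  gt <- simulate_genotypes(ped, cfg)
  tables <- owlfam:::kinship_tables(gt$freqs, 0.01)
  better <- logical(12)
  rel <- character(12)
  for (f in 1:12) {
    off <- get_genotype(gt, sprintf("F%02d_chick1", f))
    sire <- get_genotype(gt, sprintf("F%02d_sire", f))
    dam <- get_genotype(gt, sprintf("F%02d_dam", f))
    delayer <- get_genotype(gt, sprintf("F%02d_delayer", f))
    lod_sire <- parentage_lod(off, sire, gt$freqs, 0.01, known_parent = dam,
                              tables = tables)
    lod_del <- parentage_lod(off, delayer, gt$freqs, 0.01,
                             known_parent = dam, tables = tables)
    better[f] <- lod_sire > lod_del
    rel[f] <- ml_relationship(delayer, sire, gt$freqs, 0.01,
                              tables = tables)$best
  }
  expect_gte(mean(better), 0.8)
  # the delayer is first-degree kin of the breeding male
  expect_true(all(rel %in% c("PO", "FS")))

  # when the simulator grants the delayer the fertilisation, the trio LOD
  # favours the delayer instead
  ped2 <- simulate_family_pedigree(n_families = 12, chicks_per_family = 3,
                                   delayer_sires = TRUE)
  gt2 <- simulate_genotypes(ped2, cfg)
  tables2 <- owlfam:::kinship_tables(gt2$freqs, 0.01)
  del_wins <- logical(12)
  for (f in 1:12) {
    off <- get_genotype(gt2, sprintf("F%02d_chick1", f))
    sire <- get_genotype(gt2, sprintf("F%02d_sire", f))
    dam <- get_genotype(gt2, sprintf("F%02d_dam", f))
    delayer <- get_genotype(gt2, sprintf("F%02d_delayer", f))
    del_wins[f] <- parentage_lod(off, delayer, gt2$freqs, 0.01,
                                 known_parent = dam, tables = tables2) >
      parentage_lod(off, sire, gt2$freqs, 0.01, known_parent = dam,
                    tables = tables2)
  }
  expect_gte(mean(del_wins), 0.7)
})

test_that("assignment confidence thresholds behave like the simulation design", {
  cfg <- sim_config(seed = 44)
  ped <- data.frame(id = sprintf("f%02d", 1:10), mother = NA_character_,
                    father = NA_character_)
  gt <- simulate_genotypes(ped, cfg)

  res <- assignment_confidence(gt$freqs, n_sim = 2000, seed = 1)
  expect_lte(res$thresholds[["relaxed"]], res$thresholds[["strict"]])
  # bounded by the sampling proportion of true parents (0.7) up to noise
  expect_true(res$assignment_rate > 0.5 && res$assignment_rate < 0.75)

  # perfect information: every offspring is assigned to its true parent
  full <- assignment_confidence(gt$freqs, n_sim = 2000,
                                prop_candidates_sampled = 1, error_rate = 0,
                                seed = 2)
  expect_gt(full$assignment_rate, 0.95)

  expect_error(assignment_confidence(gt$freqs, n_sim = 10), "1000")
})
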