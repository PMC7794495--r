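#' Diploid microsatellite genotype table
#'
#' Container for unordered diploid genotypes at a panel of loci. Alleles are
#' stored as character codes; `NA` marks an untyped allele/locus.
#'
#' @param ids Character vector of individual identifiers.
#' @param geno 3-d character array `[individual, locus, 2]` of allele codes
#'   (dimnames: ids, locus names).
#' @param freqs Optional list of per-locus allele frequencies (named numeric
#'   vectors summing to 1).
#' @return Object of class `owl_genotypes`.
#' @export
genotype_table <- function(ids, geno, freqs = NULL) {
  stopifnot(is.array(geno), length(dim(geno)) == 3, dim(geno)[3] == 2,
            dim(geno)[1] == length(ids))
  if (!is.null(freqs)) check_freqs(freqs)
  structure(list(ids = ids, loci = dimnames(geno)[[2]], geno = geno,
                 freqs = freqs),
            class = "owl_genotypes")
}

#' @export
print.owl_genotypes <- function(x, ...) {
  cat(sprintf("<owl_genotypes> %d individuals x %d loci\n",
              length(x$ids), length(x$loci)))
  invisible(x)
}

#' Extract one individual's genotype matrix
#'
#' @param gt An `owl_genotypes` object.
#' @param id Individual identifier.
#' @return Character matrix `loci x 2` of allele codes.
#' @export
get_genotype <- function(gt, id) {
  i <- match(id, gt$ids)
  if (is.na(i)) stop(sprintf("unknown individual '%s'", id))
  m <- gt$geno[i, , , drop = FALSE]
  dim(m) <- dim(gt$geno)[2:3]
  rownames(m) <- gt$loci
  m
}

check_freqs <- function(freqs, tol = 1e-9) {
  if (!is.list(freqs) || length(freqs) == 0)
    stop("allele frequencies must be a non-empty list of named vectors")
  for (l in seq_along(freqs)) {
    f <- freqs[[l]]
    if (is.null(names(f)) || any(f <= 0))
      stop("allele frequencies must be positive and named")
    if (abs(sum(f) - 1) > tol)
      stop(sprintf("allele frequencies at locus %d do not sum to 1", l))
  }
  invisible(freqs)
}

#' Estimate allele frequencies from a genotype sample
#'
#' Simple allele-count estimator per locus; untyped alleles are ignored.
#'
#' @param gt An `owl_genotypes` object.
#' @return List of named per-locus frequency vectors (each summing to 1).
#' @export
allele_frequencies_from_sample <- function(gt) {
  stopifnot(inherits(gt, "owl_genotypes"))
  L <- length(gt$loci)
  out <- vector("list", L)
  names(out) <- gt$loci
  for (l in seq_len(L)) {
    al <- c(gt$geno[, l, 1], gt$geno[, l, 2])
    al <- al[!is.na(al)]
    if (length(al) == 0)
      stop(sprintf("locus '%s' has no typed individuals", gt$loci[l]))
    tab <- table(al)
    out[[l]] <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  out
}

# ---- relationship classes ---------------------------------------------------

# IBD (k0, k1, k2) coefficients of the four relationship classes considered:
# unrelated, half-sib (also grandparent/avuncular), full-sib, parent-offspring.
relationship_k <- function(label) {
  switch(label,
         U  = c(1, 0, 0),
         HS = c(0.5, 0.5, 0),
         FS = c(0.25, 0.5, 0.25),
         PO = c(0, 1, 0),
         stop(sprintf("unknown relationship class '%s'", label)))
}

relationship_r <- function(label) {
  k <- relationship_k(label)
  k[2] / 2 + k[3]
}

# ---- per-locus likelihood machinery ----------------------------------------

# Catalog of unordered genotypes at one locus plus every matrix the
# likelihoods need: HWE probabilities Pg, the one-IBD transition T1 (also the
# parent-offspring transition), the two-parent transition T2, and the
# observation-error mixing matrix E (per-allele substitution by a
# frequency-weighted allele with probability e). All pair likelihood matrices
# are ng x ng over observed genotypes.
locus_tables <- function(f, error_rate) {
  al <- names(f)
  na <- length(al)
  gi <- which(upper.tri(matrix(0, na, na), diag = TRUE), arr.ind = TRUE)
  gi <- gi[order(gi[, 1], gi[, 2]), , drop = FALSE]  # pairs (i <= j)
  ng <- nrow(gi)
  glab <- paste(al[gi[, 1]], al[gi[, 2]], sep = "/")
  p <- as.numeric(f)
  Pg <- ifelse(gi[, 1] == gi[, 2], p[gi[, 1]]^2, 2 * p[gi[, 1]] * p[gi[, 2]])

  # P(g2 | g1, exactly one pair of alleles IBD) — the classic transition.
  T1 <- matrix(0, ng, ng)
  for (a in seq_len(ng)) {
    i <- gi[a, 1]; j <- gi[a, 2]
    for (b in seq_len(ng)) {
      k <- gi[b, 1]; m <- gi[b, 2]
      val <- 0
      # share allele i (transmitted), partner allele from population
      if (i == j) {            # g1 homozygote ii
        if (k == i) val <- val + p[m]
        if (m == i && k != i) val <- val + p[k]
      } else {                 # g1 heterozygote ij: each allele IBD w.p. 1/2
        if (k == i) val <- val + 0.5 * p[m]
        if (m == i && k != i) val <- val + 0.5 * p[k]
        if (k == j) val <- val + 0.5 * p[m]
        if (m == j && k != j) val <- val + 0.5 * p[k]
      }
      T1[a, b] <- val
    }
  }

  # P(offspring | mother genotype a, father genotype b): average over the
  # four equally likely transmitted-allele pairs.
  T2 <- array(0, dim = c(ng, ng, ng))
  for (a in seq_len(ng)) for (b in seq_len(ng)) {
    ma <- gi[a, ]; fa <- gi[b, ]
    for (x in 1:2) for (y in 1:2) {
      o <- sort(c(ma[x], fa[y]))
      ob <- which(gi[, 1] == o[1] & gi[, 2] == o[2])
      T2[a, b, ob] <- T2[a, b, ob] + 0.25
    }
  }

  # Observation model: each recorded allele is the true allele w.p. 1-e,
  # otherwise a random frequency-weighted allele. E[obs, true].
  E <- diag(ng)
  if (error_rate > 0) {
    e <- error_rate
    pa_obs <- function(o, t) (1 - e) * (o == t) + e * p[o]
    E <- matrix(0, ng, ng)
    for (b in seq_len(ng)) {       # true genotype
      x <- gi[b, 1]; y <- gi[b, 2]
      for (a in seq_len(ng)) {     # observed genotype
        u <- gi[a, 1]; v <- gi[a, 2]
        E[a, b] <- if (u == v) pa_obs(u, x) * pa_obs(u, y)
        else pa_obs(u, x) * pa_obs(v, y) + pa_obs(v, x) * pa_obs(u, y)
      }
    }
  }

  mats <- list()
  for (cl in c("U", "HS", "FS", "PO")) {
    k <- relationship_k(cl)
    Lt <- k[1] * (Pg %o% Pg) + k[2] * (Pg * T1) + k[3] * diag(Pg)
    mats[[cl]] <- E %*% Lt %*% t(E)
  }
  Pg_obs <- as.vector(E %*% Pg)

  list(alleles = al, pairs = gi, labels = glab, ng = ng, Pg = Pg,
       Pg_obs = Pg_obs, T1 = T1, T2 = T2, E = E, pairL = mats,
       lod_po = log(pmax(mats$PO, 1e-300)) - log(pmax(mats$U, 1e-300)))
}

# Build (and lightly cache on the frequency list) per-locus tables.
kinship_tables <- function(freqs, error_rate) {
  check_freqs(freqs)
  lapply(freqs, locus_tables, error_rate = error_rate)
}

# Map one individual's loci x 2 allele matrix to genotype catalog indices.
geno_to_index <- function(g, tables) {
  L <- length(tables)
  if (is.list(g)) g <- do.call(rbind, g)
  stopifnot(is.matrix(g), nrow(g) == L, ncol(g) == 2)
  idx <- rep(NA_integer_, L)
  for (l in seq_len(L)) {
    a <- g[l, ]
    if (any(is.na(a))) next
    tb <- tables[[l]]
    i <- match(a[1], tb$alleles); j <- match(a[2], tb$alleles)
    if (is.na(i) || is.na(j))
      stop(sprintf("allele outside the frequency set at locus %d", l))
    o <- sort(c(i, j))
    idx[l] <- which(tb$pairs[, 1] == o[1] & tb$pairs[, 2] == o[2])
  }
  idx
}

LOG_GUARD <- log(1e-300)

#' Pairwise relationship log-likelihood
#'
#' Log-likelihood of two individuals' multilocus genotypes under a
#' relationship class, modelled as the IBD-coefficient mixture
#' `L = k0 P(g1)P(g2) + k1 P(g1) T(g2|g1) + k2 P(g1) [g1 = g2]` per locus,
#' with loci independent (linkage equilibrium) and genotyping error folded in
#' through the per-allele substitution observation model. A Mendelian-
#' impossible locus under `PO` with zero error contributes the guarded value
#' `log(1e-300)` instead of `-Inf`.
#'
#' @param g1,g2 Genotypes: `loci x 2` character matrices of allele codes
#'   (as from [get_genotype()]); `NA` rows are skipped.
#' @param freqs Per-locus allele frequencies (list of named vectors).
#' @param relationship One of `"U"`, `"HS"`, `"FS"`, `"PO"`.
#' @param error_rate Per-allele substitution probability.
#' @param tables Optional precomputed kinship tables (for batch work).
#' @return Scalar log-likelihood (sum over shared typed loci).
#' @export
pair_likelihood <- function(g1, g2, freqs, relationship = "U",
                            error_rate = 0, tables = NULL) {
  if (is.null(tables)) tables <- kinship_tables(freqs, error_rate)
  i1 <- geno_to_index(g1, tables)
  i2 <- geno_to_index(g2, tables)
  keep <- !is.na(i1) & !is.na(i2)
  if (!any(keep)) stop("no shared typed loci between the two individuals")
  ll <- 0
  for (l in which(keep)) {
    v <- tables[[l]]$pairL[[relationship]][i1[l], i2[l]]
    ll <- ll + if (v > 0) log(v) else LOG_GUARD
  }
  ll
}

#' Maximum-likelihood relationship classification
#'
#' Evaluates the pairwise likelihood under the four relationship classes
#' (unrelated, half-sib, full-sib, parent-offspring) and returns the most
#' likely class together with its implied relatedness
#' r = k1/2 + k2 (U: 0, HS: 0.25, FS: 0.5, PO: 0.5).
#'
#' @inheritParams pair_likelihood
#' @return List with elements `best` (class label), `r`, `loglik` (named
#'   vector, decreasing), `ranking` (class labels by decreasing likelihood)
#'   and `tie` (labels within 1e-9 of the maximum).
#' @export
ml_relationship <- function(g1, g2, freqs, error_rate = 0, tables = NULL) {
  if (is.null(tables)) tables <- kinship_tables(freqs, error_rate)
  ll <- vapply(c(U = "U", HS = "HS", FS = "FS", PO = "PO"),
               function(cl) pair_likelihood(g1, g2, freqs, cl, error_rate,
                                            tables),
               numeric(1))
  ord <- order(ll, decreasing = TRUE)
  best <- names(ll)[ord[1]]
  tie <- names(ll)[ll >= ll[ord[1]] - 1e-9]
  list(best = best, r = relationship_r(best), loglik = ll[ord],
       ranking = names(ll)[ord], tie = tie)
}

#' Parentage LOD score
#'
#' Log-likelihood ratio that `candidate` is a parent of `offspring` rather
#' than unrelated. Without a known parent the single-parent transition is
#' used; with `known_parent` the full trio likelihood is compared against
#' "known parent is the parent, candidate unrelated". Genotyping error enters
#' through the same per-allele substitution model as everywhere else; a
#' Mendelian exclusion at zero error yields a large negative (guarded)
#' contribution rather than `-Inf`.
#'
#' @param offspring,candidate Genotype matrices (`loci x 2`).
#' @param freqs Per-locus allele frequencies.
#' @param error_rate Per-allele substitution probability.
#' @param known_parent Optional genotype matrix of the already-known parent.
#' @param tables Optional precomputed kinship tables.
#' @return Scalar LOD (natural log).
#' @export
parentage_lod <- function(offspring, candidate, freqs, error_rate = 0,
                          known_parent = NULL, tables = NULL) {
  if (is.null(tables)) tables <- kinship_tables(freqs, error_rate)
  io <- geno_to_index(offspring, tables)
  ic <- geno_to_index(candidate, tables)
  im <- if (!is.null(known_parent)) geno_to_index(known_parent, tables)
  lod <- 0
  for (l in seq_along(tables)) {
    if (is.na(io[l]) || is.na(ic[l])) next
    tb <- tables[[l]]
    if (is.null(im) || is.na(im[l])) {
      num <- tb$pairL$PO[ic[l], io[l]]
      den <- tb$pairL$U[ic[l], io[l]]
    } else {
      # trio: sum over true genotypes of mother, candidate, offspring
      Em <- tb$E[im[l], ]; Ec <- tb$E[ic[l], ]; Eo <- tb$E[io[l], ]
      w <- apply(tb$T2, c(1, 2), function(v) sum(v * Eo))
      num <- sum((tb$Pg * Em) %o% (tb$Pg * Ec) * w)
      den_mo <- sum((tb$Pg * Em) * as.vector(tb$T1 %*% Eo))
      den <- den_mo * tb$Pg_obs[ic[l]]
    }
    lod <- lod + (if (num > 0) log(num) else LOG_GUARD) -
      (if (den > 0) log(den) else LOG_GUARD)
  }
  lod
}

#' Simulated confidence thresholds for parentage assignment
#'
#' Emulates the simulation stage of likelihood-based parentage assignment:
#' offspring are simulated from Hardy-Weinberg parents, a candidate-parent
#' set is assembled in which the true parent is present with probability
#' `prop_candidates_sampled`, each locus is typed with probability
#' `prop_loci_typed`, and genotyping error is applied throughout. The
#' assignment statistic is Delta, the gap between the best and second-best
#' candidate LOD. The returned thresholds are the smallest Delta values at
#' which the success rate among assignments meeting the threshold reaches the
#' strict (95%) and relaxed (80%) targets.
#'
#' @param freqs Per-locus allele frequencies.
#' @param n_sim Number of simulated offspring (>= 1000; default 10000).
#' @param prop_candidates_sampled Probability that the true parent is among
#'   the candidates (default 0.7).
#' @param prop_loci_typed Per-locus typing probability (default 0.99).
#' @param error_rate Per-allele substitution probability (default 0.01).
#' @param n_candidates Size of each candidate set (default 20).
#' @param levels Named confidence targets (default strict 0.95, relaxed 0.80).
#' @param seed Optional integer seed.
#' @return List: `thresholds` (named numeric, one per confidence level),
#'   `assignment_rate` (proportion of simulations whose top candidate is the
#'   true parent), `deltas` (data frame of Delta and correctness).
#' @export
assignment_confidence <- function(freqs, n_sim = 10000,
                                  prop_candidates_sampled = 0.7,
                                  prop_loci_typed = 0.99,
                                  error_rate = 0.01,
                                  n_candidates = 20,
                                  levels = c(strict = 0.95, relaxed = 0.80),
                                  seed = NULL) {
  if (n_sim < 1000) stop("'n_sim' must be at least 1000")
  if (!is.null(seed)) set.seed(seed)
  tables <- kinship_tables(freqs, error_rate)
  L <- length(tables)

  sample_idx <- function(n, prob) sample.int(length(prob), n, TRUE, prob)
  apply_error <- function(true_idx, tb) {
    if (error_rate == 0) return(true_idx)
    out <- integer(length(true_idx))
    for (g in unique(true_idx)) {
      sel <- true_idx == g
      out[sel] <- sample_idx(sum(sel), tb$E[, g])
    }
    out
  }

  off <- fa <- matrix(NA_integer_, n_sim, L)
  cand <- array(NA_integer_, dim = c(n_sim, n_candidates, L))
  for (l in seq_len(L)) {
    tb <- tables[[l]]
    fa_t <- sample_idx(n_sim, tb$Pg)
    mo_t <- sample_idx(n_sim, tb$Pg)
    off_t <- integer(n_sim)
    key <- paste(fa_t, mo_t)
    for (kk in unique(key)) {
      sel <- key == kk
      ab <- as.integer(strsplit(kk, " ")[[1]])
      off_t[sel] <- sample_idx(sum(sel), tb$T2[ab[2], ab[1], ])
    }
    off[, l] <- apply_error(off_t, tb)
    fa[, l] <- apply_error(fa_t, tb)
    for (j in seq_len(n_candidates - 1))
      cand[, j, l] <- sample_idx(n_sim, tb$Pg_obs)
    cand[, n_candidates, l] <- fa[, l]  # slot of the true father
  }
  father_sampled <- stats::runif(n_sim) < prop_candidates_sampled
  if (any(!father_sampled)) {
    for (l in seq_len(L))
      cand[!father_sampled, n_candidates, l] <-
        sample_idx(sum(!father_sampled), tables[[l]]$Pg_obs)
  }
  typed_off <- matrix(stats::runif(n_sim * L) < prop_loci_typed, n_sim, L)

  lod <- matrix(0, n_sim, n_candidates)
  for (l in seq_len(L)) {
    lm_ <- tables[[l]]$lod_po
    ok <- typed_off[, l]
    for (j in seq_len(n_candidates)) {
      v <- lm_[cbind(cand[, j, l], off[, l])]
      lod[ok, j] <- lod[ok, j] + v[ok]
    }
  }
  top <- max.col(lod, ties.method = "first")
  lod_sorted <- t(apply(lod, 1, sort, decreasing = TRUE))
  delta <- lod_sorted[, 1] - lod_sorted[, 2]
  correct <- father_sampled & (top == n_candidates)

  ord <- order(delta, decreasing = TRUE)
  rate <- cumsum(correct[ord]) / seq_len(n_sim)
  thresholds <- vapply(levels, function(target) {
    ok <- which(rate >= target)
    if (length(ok) == 0) return(max(delta))
    delta[ord][max(ok)]
  }, numeric(1))
  # quantile monotonicity: a stricter confidence target can never yield a
  # lower threshold; enforce against simulation noise at the boundary
  if (length(thresholds) > 1) {
    o <- order(levels)                       # ascending confidence
    thresholds[o] <- cummax(thresholds[o])
  }

  list(thresholds = thresholds,
       assignment_rate = mean(correct),
       deltas = data.frame(delta = delta, correct = correct))
}
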