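# Independent oracles used across the suite. These deliberately avoid the
# package's own likelihood code paths: probabilities are obtained by explicit
# enumeration so the fast implementations can be checked against them.

# Probability of a single encounter history by exhaustive enumeration over
# the (unobserved) last-alive occasion. phi: vector over intervals 1..T-1,
# p: vector over occasions 1..T (entry 1 unused).
enum_history_prob <- function(history, phi, p) {
  h <- as.integer(strsplit(history, "")[[1]])
  T_ <- length(h)
  f <- which(h == 1)[1]
  dets <- which(h == 1)
  l <- dets[length(dets)]
  total <- 0
  for (a in l:T_) {  # alive through occasion a, dead afterwards
    pr <- 1
    if (a > f) for (t in f:(a - 1)) pr <- pr * phi[t]
    if (a < T_) pr <- pr * (1 - phi[a])
    if (a > f) for (t in (f + 1):a)
      pr <- pr * if (h[t] == 1) p[t] else (1 - p[t])
    # detections after death are impossible
    if (l > a) pr <- 0
    total <- total + pr
  }
  total
}

# All histories of length T starting with a 1 at occasion f.
all_histories <- function(T_, f) {
  tail_len <- T_ - f
  if (tail_len == 0) return(paste(rep(0, f - 1), collapse = ""))
  tails <- expand.grid(rep(list(0:1), tail_len))
  apply(tails, 1, function(z)
    paste0(paste(rep(0, f - 1), collapse = ""), "1",
           paste(z, collapse = "")))
}

# Exact permutation p-value by full enumeration of pool subsets.
enum_permutation_p <- function(delayed, pool, statistic = stats::median) {
  m <- length(delayed)
  obs <- statistic(delayed)
  combs <- utils::combn(pool, m)
  nulls <- apply(combs, 2, statistic)
  mean(nulls <= obs)
}

# Closed-form OLS through the normal equations (textbook oracle).
ols_by_hand <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  c(intercept = a, slope = b)
}

# Brute-force aggregation indices by double loop.
brute_S <- function(x, y) {
  n <- length(x)
  S <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    S[i] <- S[i] + exp(-sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
  S
}
brute_P <- function(x, y, prod) {
  n <- length(x)
  P <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    P[i] <- P[i] + prod[j] * exp(-sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
  P
}

# Full-sib pair likelihood at one biallelic locus by exhaustive enumeration
# over ordered parental genotypes and independent gamete draws (error-free).
enum_fullsib_locus <- function(g1, g2, p) {
  al <- names(p)
  tot <- 0
  key <- function(g) paste(sort(g), collapse = "")
  for (m1 in al) for (m2 in al) for (f1 in al) for (f2 in al) {
    pg <- p[[m1]] * p[[m2]] * p[[f1]] * p[[f2]]
    pr1 <- 0; pr2 <- 0
    for (gm in c(m1, m2)) for (gf in c(f1, f2)) {
      if (key(c(gm, gf)) == key(g1)) pr1 <- pr1 + 0.25
      if (key(c(gm, gf)) == key(g2)) pr2 <- pr2 + 0.25
    }
    tot <- tot + pg * pr1 * pr2
  }
  tot
}

# Single-parent offspring probability at one locus by enumeration over
# transmitted alleles (error-free).
enum_po_locus <- function(g_off, g_par, p) {
  key <- function(g) paste(sort(g), collapse = "")
  tot <- 0
  for (tr in g_par) for (oth in names(p)) {
    if (key(c(tr, oth)) == key(g_off)) tot <- tot + 0.5 * p[[oth]]
  }
  tot
}

# Simple genotype matrix constructor: one locus per row.
gmat <- function(..., loci = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  if (!is.null(loci)) rownames(m) <- loci
  m
}
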