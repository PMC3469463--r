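# Shared test helpers: independent oracles and small utilities.

# Gene-dropping oracle for additive relationship coefficients: drop two
# distinct allele labels per founder through the pedigree and estimate, for
# each pair, twice the probability that randomly drawn alleles are identical
# by descent (= expected additive relationship).
gene_drop_relationship <- function(ped, n_rep = 2e4, seed = 42) {
  set.seed(seed)
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  # process parents before children
  depth <- integer(n)
  repeat {
    d <- pmax(ifelse(is.na(fa), 0L, depth[fa] + 1L),
              ifelse(is.na(mo), 0L, depth[mo] + 1L))
    if (identical(d, depth)) break
    depth <- d
  }
  ord <- order(depth)
  acc <- matrix(0, n, n)
  next_label <- 2L * n  # founder labels 1..2n unique
  for (r in seq_len(n_rep)) {
    al1 <- integer(n); al2 <- integer(n)
    lab <- 0L
    for (i in ord) {
      if (is.na(fa[i])) { al1[i] <- (lab <- lab + 1L) }
      else al1[i] <- if (stats::runif(1) < 0.5) al1[fa[i]] else al2[fa[i]]
      if (is.na(mo[i])) { al2[i] <- (lab <- lab + 1L) }
      else al2[i] <- if (stats::runif(1) < 0.5) al1[mo[i]] else al2[mo[i]]
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      # 2 * kinship(i, j): average IBD of one random allele from each
      k <- mean(c(al1[i] == al1[j], al1[i] == al2[j],
                  al2[i] == al1[j], al2[i] == al2[j]))
      acc[i, j] <- acc[i, j] + 2 * k
    }
  }
  acc / n_rep
}

# Binomial 3-standard-error band for an empirical proportion.
three_se <- function(p, n) 3 * sqrt(pmax(p * (1 - p), 1e-12) / n)

# Hanley-McNeil standard error of an empirical AUC.
auc_se <- function(a, n1, n0) {
  n1 <- as.numeric(n1); n0 <- as.numeric(n0)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
         (n1 * n0))
}

# Monte-Carlo estimate of one pattern probability from raw liability draws
# (independent of the package's simulator internals beyond rnorm).
mc_pattern_prob <- function(spec, A, pattern, n_draw = 1e5, seed = 99) {
  set.seed(seed)
  n <- nrow(A)
  cov <- spec$h2 * A + spec$c2 + (1 - spec$h2 - spec$c2) * diag(n)
  L <- chol(cov)
  liab <- matrix(rnorm(n_draw * n), n_draw, n) %*% L
  aff <- liab >= spec$threshold
  mean(apply(aff, 1L, function(x) all(x == (pattern == 1))))
}
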