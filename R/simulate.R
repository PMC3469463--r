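#' Forward-simulate liabilities and disease statuses for a pedigree
#'
#' Draws replicate families from the model: genetic components jointly
#' normal with covariance `h2 * A`, one shared environmental component per
#' family with variance `c2`, and i.i.d. residuals with variance
#' `1 - h2 - c2`.  The index's measured genetic liability is the fraction
#' `v = pi * h2` of liability variance captured by SNPs: it equals
#' `(v / h2) * g_index` plus independent noise so that its variance is `v`
#' and its covariance with the index's genetic value is `v`.
#'
#' This simulator is the package's independent oracle: every analytic
#' quantity (pattern probabilities, classifier AUCs, LR fractions) has an
#' empirical counterpart estimated from its output.
#'
#' @param spec A [disease_spec()].
#' @param ped A [pedigree()].
#' @param n_replicates Number of replicate families.
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @return List with
#'   * `status`: `n_replicates` x `n` 0/1 matrix of lifetime disease
#'     statuses (columns in pedigree order, index first);
#'   * `liability`: matching matrix of total liabilities;
#'   * `measured_g`: vector of the index's measured genetic liability;
#'   * `spec`, `ped`.
#' @examples
#' sim <- simulate_families(disease_spec(f = 0.1, h2 = 0.8), ped_trio(),
#'                          n_replicates = 1e4, seed = 1)
#' mean(sim$status[, 1])  # close to f
#' @export
simulate_families <- function(spec, ped, n_replicates, seed) {
  stopifnot(inherits(spec, "disease_spec"), inherits(ped, "pedigree"),
            n_replicates >= 1)
  set.seed(as.integer(seed))
  n <- nrow(ped)
  A <- relationship_matrix(ped)

  g <- if (spec$h2 > 0) {
    # symmetric factorization; eigenvalue clipping guards the rank-one
    # shared term and near-singular pedigree structures
    eg <- eigen(spec$h2 * A, symmetric = TRUE)
    if (min(eg$values) < -1e-10)
      stop("genetic covariance is not positive semidefinite")
    L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)
    matrix(stats::rnorm(n_replicates * n), n_replicates, n) %*% t(L)
  } else matrix(0, n_replicates, n)

  shared <- if (spec$c2 > 0)
    stats::rnorm(n_replicates, sd = sqrt(spec$c2)) else numeric(n_replicates)
  res_var <- 1 - spec$h2 - spec$c2
  e <- if (res_var > 0)
    matrix(stats::rnorm(n_replicates * n, sd = sqrt(res_var)),
           n_replicates, n) else matrix(0, n_replicates, n)

  liab <- g + shared + e
  status <- (liab >= spec$threshold) * 1L
  colnames(status) <- colnames(liab) <- ped$id

  v <- spec$v
  measured_g <- if (v > 0) {
    resid_sd <- sqrt(max(v * (1 - v / spec$h2), 0))
    (v / spec$h2) * g[, 1L] + stats::rnorm(n_replicates, sd = resid_sd)
  } else numeric(n_replicates)

  list(status = status, liability = liab, measured_g = measured_g,
       spec = spec, ped = ped)
}

#' Empirical pattern frequencies from a simulation
#'
#' Tabulates simulated disease-status patterns in the same binary-counting
#' order as [pattern_distribution()] (index individual = lowest-order bit).
#'
#' @param sim Output of [simulate_families()].
#' @return Vector of `2^n` empirical pattern frequencies.
#' @export
empirical_pattern_freq <- function(sim) {
  n <- ncol(sim$status)
  code <- as.integer(sim$status %*% 2^(seq_len(n) - 1L))
  tabulate(code + 1L, nbins = 2^n) / nrow(sim$status)
}

#' Rank-statistic AUC of simulated scores
#'
#' Empirical probability that a random case scores above a random control,
#' with the standard half-credit tie correction (a Wilcoxon/Mann-Whitney
#' estimate).
#'
#' @param score Numeric risk scores.
#' @param status 0/1 disease statuses of the same length.
#' @return Empirical AUC.
#' @export
empirical_auc <- function(score, status) {
  status <- as.integer(status)
  n1 <- as.numeric(sum(status == 1L))
  n0 <- as.numeric(sum(status == 0L))
  if (n1 == 0L || n0 == 0L)
    stop("need both cases and controls to estimate an AUC")
  r <- rank(score)  # midranks handle ties with half credit
  (sum(r[status == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score simulated families with a fitted classifier
#'
#' Assigns each simulated replicate the risk its relative pattern (and,
#' for `kind = "snp"`, its measured genetic liability) would receive.
#'
#' @param sim Output of [simulate_families()].
#' @param kind `"complete"`, `"restricted"`, or `"snp"`.
#' @param dist A [pattern_distribution()] for the same spec/pedigree
#'   (required for the family-history scorers).
#' @return Numeric vector of risk scores, one per replicate.
#' @export
score_simulation <- function(sim, kind = c("complete", "restricted", "snp"),
                             dist = NULL) {
  kind <- match.arg(kind)
  if (kind == "snp")
    return(risk_given_g(sim$spec, sim$measured_g))
  stopifnot(inherits(dist, "pattern_distribution"))
  n <- ncol(sim$status)
  rel_code <- as.integer(sim$status[, -1L, drop = FALSE] %*%
                           2^(seq_len(n - 1L) - 1L)) + 1L
  if (kind == "complete") return(dist$index_risk[rel_code])
  summary <- first_degree_summary(sim$ped)
  cat_id <- summary(dist$rel_patterns)
  p_aff <- dist$index_risk * dist$rel_prob
  class_risk <- as.numeric(tapply(p_aff, cat_id, sum)) /
    as.numeric(tapply(dist$rel_prob, cat_id, sum))
  names(class_risk) <- names(tapply(dist$rel_prob, cat_id, sum))
  class_risk[as.character(cat_id[rel_code])]
}
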