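#' Conditional joint liability given the index's measured genetic liability
#'
#' Decompose each family member's genetic liability into a component
#' measured by the index's SNP panel and a remainder.  The measured
#' components across the family are jointly normal with covariance `v * A`
#' (`v = pi * h2`), so conditioning the total liabilities on the index's
#' measured value `g` follows from the standard conditional-Gaussian
#' formulas: the mean becomes `A[, 1] * g` and the covariance loses the
#' rank-one term `v * A[, 1] %*% t(A[1, ])`.  The index's conditional
#' variance is `1 - v`, so its marginal risk matches [risk_given_g()].
#'
#' @param spec A [disease_spec()] with `pi > 0`.
#' @param ped A [pedigree()].
#' @param g Measured genetic liability of the index individual.
#' @return A `liability_joint` (see [assemble_covariance()]) with nonzero
#'   mean, usable with [orthant_probability()] and [pattern_distribution()].
#' @export
conditional_joint <- function(spec, ped, g) {
  stopifnot(inherits(spec, "disease_spec"), inherits(ped, "pedigree"))
  if (spec$v <= 0)
    stop("conditional_joint requires a measured genetic component (pi * h2 > 0)")
  A <- relationship_matrix(ped)
  joint <- assemble_covariance(spec, A)
  a1 <- A[, 1L]
  cov <- joint$cov - spec$v * tcrossprod(a1)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("conditional covariance lost positive semidefiniteness ",
         "(smallest eigenvalue ", signif(min(ev), 3), ")")
  structure(list(mean = unname(a1 * g), cov = cov,
                 threshold = spec$threshold, n = joint$n, g = g),
            class = "liability_joint")
}

#' Combined family-history and SNP risk classifier
#'
#' Joint classifier over (family-history pattern, measured genetic
#' liability) pairs.  The continuous distribution of the index's measured
#' genetic liability `g ~ N(0, v)` is discretized into `K` equal-probability
#' cells, each represented by its conditional mean
#' `g_k = sqrt(v) * K * (phi(z_(k-1)) - phi(z_k))` (with `z_k` the standard
#' normal `k/K` quantiles) and weight `1/K`; for each grid point the
#' pedigree's pattern distribution is recomputed under the conditional
#' joint, and every (pattern, grid point) pair becomes a classifier item
#' with risk `P(index affected | pattern, g_k)`.  This construction accounts for the
#' non-independence of family history and SNP evidence without heuristics:
#' family history partly reflects the same genetic variance the panel
#' measures.
#'
#' Cost is `K * 2^n` MVN integrals; a guard refuses configurations beyond
#' `max_integrals`.
#'
#' @param spec A [disease_spec()]; `pi = 0` returns the complete
#'   family-history classifier (conditioning on nothing).
#' @param ped A [pedigree()].
#' @param K Grid size (default 200).
#' @param max_integrals Cost guard on `K * 2^n`.
#' @param abseps Per-integral tolerance.
#' @return A [risk_classifier()].
#' @examples
#' \donttest{
#' spec <- disease_spec(f = 0.1, h2 = 0.8, pi = 0.3)
#' cl <- combined_classifier(spec, ped_trio(), K = 50)
#' auc(roc(cl))
#' }
#' @export
combined_classifier <- function(spec, ped, K = 200L,
                                max_integrals = 2e5, abseps = 1e-6) {
  stopifnot(inherits(spec, "disease_spec"), inherits(ped, "pedigree"),
            K >= 2L)
  if (spec$v <= 0)
    return(complete_classifier(pattern_distribution(spec, ped,
                                                    abseps = abseps)))
  n <- nrow(ped)
  if (K * 2^n > max_integrals)
    stop("combined model needs ", K * 2^n, " MVN integrals, above the ",
         "budget of ", max_integrals, "; reduce K or the pedigree size")
  zb <- stats::qnorm(seq(0, 1, length.out = K + 1))
  gk <- sqrt(spec$v) * K * (stats::dnorm(zb[-(K + 1)]) - stats::dnorm(zb[-1]))
  risks <- numeric(0)
  probs <- numeric(0)
  for (g in gk) {
    pd <- pattern_distribution(spec, ped,
                               joint = conditional_joint(spec, ped, g),
                               abseps = abseps)
    risks <- c(risks, pd$index_risk)
    probs <- c(probs, pd$rel_prob / K)
  }
  risk_classifier(risk = risks, prob = probs, prior = spec$f)
}

#' Overlap in explained heritability between family history and SNPs
#'
#' Converts the AUC of a family-history model, a SNP model, and their
#' combination into equivalent proportions of heritability explained (via
#' [equivalent_pi()]) and reports the overlap
#' `pi_fh + pi_snp - pi_combined`: the fraction of heritability both
#' sources capture, i.e. the non-independence between them.
#'
#' @param f Lifetime morbid risk.
#' @param h2 Heritability of liability.
#' @param auc_fh,auc_snp,auc_combined AUCs in (0.5, 1).
#' @return List with `pi_fh`, `pi_snp`, `pi_combined`, and `overlap`
#'   (clipped at 0 with a warning if the combined model explains more than
#'   the parts sum to, which can only arise from noise in the inputs).
#' @export
shared_variance_explained <- function(f, h2, auc_fh, auc_snp, auc_combined) {
  pi_fh <- equivalent_pi(f, h2, auc_fh)
  pi_snp <- equivalent_pi(f, h2, auc_snp)
  pi_comb <- equivalent_pi(f, h2, auc_combined)
  overlap <- pi_fh + pi_snp - pi_comb
  if (overlap < 0) {
    warning("combined model explains more heritability than the sum of ",
            "its parts; clipping negative overlap to 0")
    overlap <- 0
  }
  list(pi_fh = pi_fh, pi_snp = pi_snp, pi_combined = pi_comb,
       overlap = overlap)
}
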