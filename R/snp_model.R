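#' Case/control moments of the measured genetic liability
#'
#' Let `g` be the measured genetic component of liability, with variance
#' `v = pi * h2`, and let `T = qnorm(1 - f)`.  By genetic selection theory
#' (truncated-normal moments of the unit-variance liability), with
#' `i_case = dnorm(T) / f` and `i_control = -dnorm(T) / (1 - f)`:
#' `mu = v * i` and `var = v * (1 - v * i * (i - T))` in each group.
#'
#' @param spec A [disease_spec()] with `pi > 0`.
#' @return List with `mu_case`, `var_case`, `mu_control`, `var_control`,
#'   and `v`.  Degenerate (`v = 0`) specs return zero means and variances
#'   with a `degenerate` flag.
#' @examples
#' snp_moments(disease_spec(f = 0.005, h2 = 0.56, pi = 0.135))
#' @export
snp_moments <- function(spec) {
  stopifnot(inherits(spec, "disease_spec"))
  v <- spec$v
  if (v == 0)
    return(list(mu_case = 0, var_case = 0, mu_control = 0, var_control = 0,
                v = 0, degenerate = TRUE))
  T <- spec$threshold
  i_case <- stats::dnorm(T) / spec$f
  i_ctrl <- -stats::dnorm(T) / (1 - spec$f)
  list(mu_case = v * i_case,
       var_case = v * (1 - v * i_case * (i_case - T)),
       mu_control = v * i_ctrl,
       var_control = v * (1 - v * i_ctrl * (i_ctrl - T)),
       v = v, degenerate = FALSE)
}

#' Closed-form AUC of a SNP-based risk model
#'
#' Predicted risk is strictly increasing in the measured genetic liability
#' `g`, so the AUC is the probability that a random case's `g` exceeds a
#' random control's.  Approximating the case and control distributions of
#' `g` as normal with the selection-theory moments gives
#' `AUC = pnorm((mu_case - mu_control) / sqrt(var_case + var_control))`.
#'
#' @param spec A [disease_spec()]; `spec$pi` is the proportion of
#'   heritability the SNP panel explains.
#' @return AUC in \[0.5, 1\); 0.5 when `pi = 0`.
#' @examples
#' snp_auc(disease_spec(f = 0.402, h2 = 0.49, pi = 0.069))  # 0.584
#' @export
snp_auc <- function(spec) {
  m <- snp_moments(spec)
  if (m$v == 0) return(0.5)
  stats::pnorm((m$mu_case - m$mu_control) / sqrt(m$var_case + m$var_control))
}

#' Parametric ROC curve of a SNP-based risk model
#'
#' Sweeping a threshold `t` on the measured genetic liability gives the
#' parametric ROC: `sens(t) = 1 - pnorm((t - mu_case) / sd_case)` against
#' `fpr(t) = 1 - pnorm((t - mu_control) / sd_control)`.
#'
#' @param spec A [disease_spec()] with `pi > 0`.
#' @param n_points Number of threshold points in the sweep.
#' @return A `roc_curve` data frame with columns `fpr` and `sens`, anchored
#'   at (0, 0) and (1, 1).
#' @export
snp_roc <- function(spec, n_points = 512L) {
  m <- snp_moments(spec)
  if (m$v == 0)
    return(structure(data.frame(fpr = c(0, 1), sens = c(0, 1)),
                     class = c("roc_curve", "data.frame")))
  sd_c <- sqrt(m$var_case); sd_u <- sqrt(m$var_control)
  lo <- min(m$mu_case - 8 * sd_c, m$mu_control - 8 * sd_u)
  hi <- max(m$mu_case + 8 * sd_c, m$mu_control + 8 * sd_u)
  t <- seq(hi, lo, length.out = n_points)
  curve <- data.frame(fpr = c(0, 1 - stats::pnorm((t - m$mu_control) / sd_u), 1),
                      sens = c(0, 1 - stats::pnorm((t - m$mu_case) / sd_c), 1))
  structure(curve, class = c("roc_curve", "data.frame"))
}

#' Posterior disease risk given measured genetic liability
#'
#' Conditional on `g`, the remaining liability is normal with mean `g` and
#' variance `1 - v`, so `r(g) = 1 - pnorm((T - g) / sqrt(1 - v))`.  When the
#' panel captures all liability variance (`v = 1`) the risk is a step
#' function at the threshold.
#'
#' @param spec A [disease_spec()].
#' @param g Measured genetic liability (vectorized), on the liability scale.
#' @return Posterior risk(s) in \[0, 1\]; constant `f` when `v = 0`.
#' @export
risk_given_g <- function(spec, g) {
  stopifnot(inherits(spec, "disease_spec"))
  v <- spec$v
  if (v == 0) return(rep(spec$f, length(g)))
  if (v >= 1) return(as.numeric(g >= spec$threshold))
  1 - stats::pnorm((spec$threshold - g) / sqrt(1 - v))
}

#' Likelihood ratio given measured genetic liability
#'
#' `LR(g)` is the post-test over pre-test odds implied by [risk_given_g()];
#' it is strictly increasing in `g`.
#'
#' @inheritParams risk_given_g
#' @return Likelihood ratio(s).
#' @export
lr_given_g <- function(spec, g) {
  r <- risk_given_g(spec, g)
  f <- spec$f
  ifelse(r >= 1, Inf, (r / (1 - r)) / (f / (1 - f)))
}

#' Population fraction with extreme likelihood ratios under a SNP model
#'
#' Fraction of the population whose measured genetic liability confers at
#' least `x`-fold increased or decreased odds of disease.  Since `LR(g)` is
#' strictly increasing, the set is two tails of `g ~ N(0, v)`: the roots of
#' `LR(g) = x` and `LR(g) = 1/x` are found by bracketed root-finding and the
#' corresponding normal tail masses summed.  An unattainable tail (e.g.
#' `1/x` below the infimum of `LR`) contributes 0.
#'
#' @param spec A [disease_spec()] with `pi > 0`.
#' @param x Odds multiplier, greater than 1.
#' @return Population fraction in \[0, 1\].
#' @examples
#' crohn <- disease_spec(f = 0.005, h2 = 0.56, pi = 0.135)
#' extreme_lr_fraction_continuous(crohn, 5)   # about 0.082
#' extreme_lr_fraction_continuous(crohn, 10)  # about 0.017
#' @export
extreme_lr_fraction_continuous <- function(spec, x) {
  stopifnot(inherits(spec, "disease_spec"), x > 1)
  v <- spec$v
  if (v == 0) return(0)
  sdv <- sqrt(v)
  solve_lr <- function(target) {
    h <- function(g) log(lr_given_g(spec, g)) - log(target)
    width <- 12
    repeat {
      lo <- -width * sdv; hi <- width * sdv
      flo <- h(lo); fhi <- h(hi)
      if (is.finite(flo) && is.finite(fhi) && flo * fhi <= 0)
        return(stats::uniroot(h, c(lo, hi), tol = 1e-12)$root)
      if (width > 40) return(NA_real_)  # target unattainable
      width <- width * 2
    }
  }
  g_hi <- solve_lr(x)
  g_lo <- solve_lr(1 / x)
  upper <- if (is.na(g_hi)) 0 else 1 - stats::pnorm(g_hi / sdv)
  lower <- if (is.na(g_lo)) 0 else stats::pnorm(g_lo / sdv)
  upper + lower
}

#' Proportion of heritability needed to reach a target AUC
#'
#' Inverts the closed-form SNP-model AUC in `pi` at fixed disease frequency
#' and heritability.  This converts any model's AUC (for instance a
#' family-history model's) into the fraction of heritability a SNP panel
#' would have to explain to match it — the "equivalent heritability
#' explained" scale.
#'
#' @param f Lifetime morbid risk.
#' @param h2 Heritability of liability.
#' @param auc_target Target AUC in \[0.5, 1).
#' @param tol Root-finding tolerance on `pi`.
#' @return The proportion `pi` in \[0, 1\].
#' @examples
#' equivalent_pi(0.402, 0.49, 0.665)  # about 0.263
#' @export
equivalent_pi <- function(f, h2, auc_target, tol = 1e-8) {
  stopifnot(auc_target >= 0.5, auc_target < 1)
  if (auc_target == 0.5) return(0)
  ceiling_auc <- snp_auc(disease_spec(f = f, h2 = h2, pi = 1))
  if (auc_target > ceiling_auc)
    stop("target AUC ", auc_target, " exceeds the maximum attainable ",
         signif(ceiling_auc, 4), " at pi = 1 for f = ", f, ", h2 = ", h2)
  stats::uniroot(function(p) snp_auc(disease_spec(f = f, h2 = h2, pi = p)) -
                   auc_target,
                 interval = c(0, 1), tol = tol)$root
}
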