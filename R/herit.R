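#' Read a SNP association table
#'
#' Whitespace- or tab-delimited table with header columns `id`,
#' `risk_allele`, `freq` (risk-allele frequency), `OR` (allelic odds
#' ratio), `pval`, `n_cases`, `n_controls`, and optionally `se`
#' (standard error of the log odds ratio).
#'
#' @param path Path to the TSV file.
#' @return Data frame of associations with an added `eff_n` column, the
#'   effective sample size (harmonic mean of case and control counts).
#' @export
read_assoc <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  needed <- c("id", "freq", "OR", "pval", "n_cases", "n_controls")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("association table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(tab$freq <= 0 | tab$freq >= 1))
    stop("risk-allele frequencies must lie strictly in (0, 1)")
  if (any(tab$OR <= 0)) stop("odds ratios must be positive")
  tab$eff_n <- 2 / (1 / tab$n_cases + 1 / tab$n_controls)
  tab
}

#' Greedy selection of approximately independent associations
#'
#' Drops associations above the significance threshold, orders the rest by
#' effective sample size (harmonic mean of case and control counts,
#' descending; ties broken by smaller p-value), and accepts each in turn
#' only if its pairwise r-squared with every previously accepted SNP is at
#' most `r2_max`.
#'
#' @param assocs Association data frame from [read_assoc()] (or with the
#'   same columns).
#' @param r2 Square symmetric matrix of pairwise linkage-disequilibrium
#'   r-squared values, dimnames matching `assocs$id`; `NULL` means all SNPs
#'   are treated as independent (r-squared 0).  A missing entry is treated
#'   as 1 (conservative exclusion) with a warning.
#' @param r2_max Maximum allowed pairwise r-squared (default 0.005).
#' @param alpha Significance threshold on `pval` (default the genome-wide
#'   5e-8).
#' @return The selected rows of `assocs`, in selection order.
#' @export
greedy_select <- function(assocs, r2 = NULL, r2_max = 0.005, alpha = 5e-8) {
  stopifnot(alpha > 0, alpha < 1, r2_max >= 0)
  if (!"eff_n" %in% names(assocs))
    assocs$eff_n <- 2 / (1 / assocs$n_cases + 1 / assocs$n_controls)
  assocs <- assocs[assocs$pval <= alpha, , drop = FALSE]
  if (nrow(assocs) == 0L) return(assocs)
  assocs <- assocs[order(-assocs$eff_n, assocs$pval), , drop = FALSE]

  lookup_r2 <- function(a, b) {
    if (is.null(r2)) return(0)
    if (!a %in% rownames(r2) || !b %in% colnames(r2)) {
      warning("missing r2 entry for (", a, ", ", b, "); treating as 1")
      return(1)
    }
    r2[a, b]
  }
  accepted <- integer(0)
  for (i in seq_len(nrow(assocs))) {
    ok <- all(vapply(accepted, function(j)
      lookup_r2(assocs$id[i], assocs$id[j]) <= r2_max, logical(1L)))
    if (ok) accepted <- c(accepted, i)
  }
  assocs[accepted, , drop = FALSE]
}

#' Winner's-curse correction of a reported log odds ratio
#'
#' A reported effect conditioned on reaching genome-wide significance is
#' biased away from zero.  Modeling the observed z-score as a normal with
#' unit variance truncated to `|z| >= c`, `c = qnorm(1 - alpha / 2)`, the
#' corrected effect solves for the truncation-mean identity
#' `mu + (dnorm(c - mu) - dnorm(c + mu)) / (pnorm(mu - c) + pnorm(-mu - c))
#' = b / s` in `mu`, returning `mu * s`.  The correction is odd-symmetric
#' and always shrinks the magnitude toward zero.
#'
#' @param b Reported log odds ratio.
#' @param se Standard error of `b`; if `NA`, back-computed from the
#'   two-sided `p_value` as `abs(b) / qnorm(1 - p_value / 2)`.
#' @param alpha Significance threshold used for reporting (default 5e-8).
#' @param p_value Two-sided p-value, used only when `se` is missing.
#' @return The bias-corrected log odds ratio.
#' @examples
#' winners_curse_correct(log(1.2), se = log(1.2) / 5.6)  # shrinks toward 0
#' @export
winners_curse_correct <- function(b, se = NA, alpha = 5e-8, p_value = NULL) {
  if (is.na(se)) {
    if (is.null(p_value))
      stop("either `se` or `p_value` must be supplied")
    se <- abs(b) / stats::qnorm(1 - p_value / 2)
  }
  stopifnot(se > 0)
  if (b == 0) return(0)
  cc <- stats::qnorm(1 - alpha / 2)
  z <- abs(b) / se
  if (z < cc)
    stop("association is not significant at alpha = ", alpha,
         " (|z| = ", signif(z, 4), " < ", signif(cc, 4),
         "); the truncation correction is undefined")
  # E[z | |z| > c; mu] for z ~ N(mu, 1)
  trunc_mean <- function(mu) {
    denom <- stats::pnorm(mu - cc) + stats::pnorm(-mu - cc)
    mu + (stats::dnorm(cc - mu) - stats::dnorm(cc + mu)) / denom
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - z,
                       lower = 0, upper = z, tol = 1e-10,
                       extendInt = "upX")$root
  sign(b) * mu * se
}

#' Liability-scale variance explained by one SNP association
#'
#' Following the So-style liability-threshold approach: under
#' Hardy-Weinberg genotype frequencies `((1-p)^2, 2p(1-p), p^2)` and
#' multiplicative allelic odds (`1, R, R^2` relative odds across genotype
#' classes), the genotype-specific lifetime risks `f_j` are obtained by
#' solving the normalization `sum q_j f_j = f`.  Each genotype then shifts
#' the liability distribution by `m_j = T - qnorm(1 - f_j)`, and the raw
#' between-genotype variance `V = sum q_j m_j^2 - (sum q_j m_j)^2` is
#' rescaled to the unit-variance liability scale as `V / (1 + V)`.
#'
#' @param freq Risk-allele frequency `p` in (0, 1).
#' @param or Allelic odds ratio `R` (> 0).
#' @param spec A [disease_spec()] (only `f` is used here).
#' @return Variance explained on the unit liability scale (0 at `R = 1`);
#'   invariant to swapping allele labels (`p -> 1 - p`, `R -> 1 / R`).
#' @export
snp_variance_explained <- function(freq, or, spec) {
  stopifnot(inherits(spec, "disease_spec"), freq > 0, freq < 1, or > 0)
  f <- spec$f
  if (or == 1) return(0)
  q <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
  # genotype risks under multiplicative allelic odds: odds_j = odds0 * R^j
  risk_given_odds0 <- function(o0) {
    odds <- o0 * or^(0:2)
    odds / (1 + odds)
  }
  # solve sum q_j f_j = f for the baseline odds (monotone in o0)
  h <- function(lo0) sum(q * risk_given_odds0(exp(lo0))) - f
  lo <- stats::uniroot(h, lower = log(f / (1 - f)) - 4 * abs(log(or)) - 1,
                       upper = log(f / (1 - f)) + 4 * abs(log(or)) + 1,
                       tol = 1e-12, extendInt = "upX")$root
  fj <- risk_given_odds0(exp(lo))
  if (any(fj <= 0 | fj >= 1))
    stop("genotype risks fall outside (0, 1); odds ratio ", or,
         " is incompatible with f = ", f)
  mj <- spec$threshold - stats::qnorm(1 - fj)
  V <- sum(q * mj^2) - sum(q * mj)^2
  V / (1 + V)
}

#' Total proportion of heritability explained by a SNP list
#'
#' Sums the per-SNP liability-scale variances of an (approximately
#' independent) association list and divides by the heritability of
#' liability.  Reported both with the raw odds ratios and with
#' winner's-curse-corrected ones.
#'
#' @param assocs Association data frame (see [read_assoc()]); typically the
#'   output of [greedy_select()].
#' @param spec A [disease_spec()] supplying `f` and `h2`.
#' @param alpha Significance threshold assumed for the winner's-curse
#'   truncation.
#' @return Object of class `variance_explained_report`: list with
#'   `per_snp` (data frame: id, raw and corrected OR and variance),
#'   `total_variance_raw`, `total_variance_corrected`, `pi_raw`,
#'   `pi_corrected`.  `pi` values above 1 are clipped with a warning.
#' @export
total_pi <- function(assocs, spec, alpha = 5e-8) {
  stopifnot(inherits(spec, "disease_spec"))
  n <- nrow(assocs)
  if (n == 0L)
    return(structure(list(per_snp = data.frame(), total_variance_raw = 0,
                          total_variance_corrected = 0, pi_raw = 0,
                          pi_corrected = 0),
                     class = "variance_explained_report"))
  se <- if ("se" %in% names(assocs)) assocs$se else rep(NA_real_, n)
  or_corr <- vapply(seq_len(n), function(i)
    exp(winners_curse_correct(log(assocs$OR[i]), se = se[i], alpha = alpha,
                              p_value = assocs$pval[i])), numeric(1L))
  v_raw <- vapply(seq_len(n), function(i)
    snp_variance_explained(assocs$freq[i], assocs$OR[i], spec), numeric(1L))
  v_corr <- vapply(seq_len(n), function(i)
    snp_variance_explained(assocs$freq[i], or_corr[i], spec), numeric(1L))

  clip_pi <- function(v) {
    p <- v / spec$h2
    if (p > 1) {
      warning("estimated pi = ", signif(p, 4), " exceeds 1; clipping ",
              "(variance explained exceeds the stated heritability)")
      p <- 1
    }
    p
  }
  structure(list(
    per_snp = data.frame(id = assocs$id, or_raw = assocs$OR,
                         or_corrected = or_corr, var_raw = v_raw,
                         var_corrected = v_corr),
    total_variance_raw = sum(v_raw),
    total_variance_corrected = sum(v_corr),
    pi_raw = clip_pi(sum(v_raw)),
    pi_corrected = clip_pi(sum(v_corr))),
    class = "variance_explained_report")
}

#' @export
print.variance_explained_report <- function(x, ...) {
  cat(sprintf("Variance explained by %d SNP(s):\n", nrow(x$per_snp)))
  cat(sprintf("  raw ORs       : V = %.5f, pi = %.3f\n",
              x$total_variance_raw, x$pi_raw))
  cat(sprintf("  bias-corrected: V = %.5f, pi = %.3f\n",
              x$total_variance_corrected, x$pi_corrected))
  invisible(x)
}
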