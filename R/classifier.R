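#' Risk classifier: the common currency for accuracy metrics
#'
#' A risk classifier is a finite set of items, each carrying a predicted
#' risk `r_j`, the probability of the item among cases
#' `p_case_j = r_j * P(item_j) / f`, and among controls
#' `p_control_j = (1 - r_j) * P(item_j) / (1 - f)`.  Every family-history,
#' SNP-grid, or combined model in the package reduces to this form, from
#' which ROC curves, AUC, predictive values, and likelihood-ratio
#' distributions follow.
#'
#' Items whose risks agree within `tie_tol` are merged into a single item
#' (they generate one ROC segment under the trapezoid rule, so merging
#' changes no metric).
#'
#' @param risk Vector of predicted risks in \[0, 1\].
#' @param prob Population probability of each item (sums to 1).
#' @param prior Population risk `f`.
#' @param tie_tol Risks closer than this are merged.
#' @return Object of class `risk_classifier`: list with `items` (data frame
#'   with columns `risk`, `prob`, `p_case`, `p_control`, sorted by
#'   non-increasing risk) and `prior`.
#' @export
risk_classifier <- function(risk, prob, prior, tie_tol = 1e-12) {
  stopifnot(length(risk) == length(prob), all(risk >= -1e-12 & risk <= 1 + 1e-12),
            all(prob >= -1e-12), prior > 0, prior < 1)
  risk <- pmin(pmax(risk, 0), 1)
  prob <- pmax(prob, 0)
  tot <- sum(prob)
  if (abs(tot - 1) > 1e-4)
    warning("item probabilities sum to ", signif(tot, 6), "; renormalizing")
  prob <- prob / tot

  if (any(prob > 0)) {
    risk <- risk[prob > 0]
    prob <- prob[prob > 0]
  }
  o <- order(risk, decreasing = TRUE)
  risk <- risk[o]; prob <- prob[o]
  # merge ties (probability-weighted, so the merged risk is the
  # class-conditional risk of the pooled item)
  grp <- cumsum(c(TRUE, diff(risk) < -tie_tol))
  mprob <- as.numeric(tapply(prob, grp, sum))
  mrisk <- as.numeric(tapply(risk * prob, grp, sum)) / mprob

  items <- data.frame(risk = mrisk, prob = mprob,
                      p_case = mrisk * mprob / prior,
                      p_control = (1 - mrisk) * mprob / (1 - prior))
  structure(list(items = items, prior = prior), class = "risk_classifier")
}

#' @export
print.risk_classifier <- function(x, ...) {
  cat(sprintf("Risk classifier: %d item(s), prior f = %g, AUC = %.4f\n",
              nrow(x$items), x$prior, auc(roc(x))))
  print(utils::head(x$items, 10L), ...)
  if (nrow(x$items) > 10L) cat("  ...", nrow(x$items) - 10L, "more item(s)\n")
  invisible(x)
}
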