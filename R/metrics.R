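#' ROC curve of a risk classifier
#'
#' With items sorted by non-increasing risk, the ROC vertices are the
#' cumulative case mass (sensitivity) against the cumulative control mass
#' (1 - specificity): vertex `k` corresponds to the thresholding rule that
#' labels the `k` highest-risk items positive.  Operating points between
#' vertices are realizable by randomizing between the adjacent threshold
#' rules, so the curve is completed by linear interpolation.
#'
#' @param classifier A [risk_classifier()].
#' @return Object of class `roc_curve`: data frame with columns `fpr`
#'   (1 - specificity) and `sens`, anchored at (0, 0) and (1, 1), both
#'   coordinates nondecreasing.
#' @export
roc <- function(classifier) {
  stopifnot(inherits(classifier, "risk_classifier"))
  it <- classifier$items  # already sorted by non-increasing risk
  curve <- data.frame(fpr = c(0, cumsum(it$p_control)),
                      sens = c(0, cumsum(it$p_case)))
  curve$fpr[nrow(curve)] <- 1
  curve$sens[nrow(curve)] <- 1
  structure(curve, class = c("roc_curve", "data.frame"))
}

#' Area under the ROC curve
#'
#' Trapezoidal area, equal to the probability that a randomly chosen case
#' receives a higher predicted risk than a randomly chosen control (ties
#' counted half).
#'
#' @param curve A `roc_curve` from [roc()].
#' @return AUC in \[0, 1\].
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (utils::head(curve$sens, -1L) + utils::tail(curve$sens, -1L)) / 2)
}

#' Specificity, PPV, and NPV at a target sensitivity
#'
#' Finds the operating point at the requested sensitivity on the ROC curve
#' (linear interpolation between vertices, realizable by a randomized
#' threshold rule) and evaluates the predictive values at the classifier's
#' prior:
#' `PPV = sens * f / (sens * f + (1 - spec) * (1 - f))` and
#' `NPV = spec * (1 - f) / (spec * (1 - f) + (1 - sens) * f)`.
#'
#' @param classifier A [risk_classifier()].
#' @param sensitivity Target sensitivity in \[0, 1\].
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
operating_point <- function(classifier, sensitivity) {
  stopifnot(inherits(classifier, "risk_classifier"),
            sensitivity >= 0, sensitivity <= 1)
  curve <- roc(classifier)
  f <- classifier$prior
  fpr <- stats::approx(curve$sens, curve$fpr, xout = sensitivity,
                       ties = min)$y
  spec <- 1 - fpr
  ppv <- if (sensitivity == 0 && fpr == 0) f else
    sensitivity * f / (sensitivity * f + fpr * (1 - f))
  npv <- if (sensitivity == 1 && spec == 0) 1 - f else
    spec * (1 - f) / (spec * (1 - f) + (1 - sensitivity) * f)
  list(sensitivity = sensitivity, specificity = spec, ppv = ppv, npv = npv)
}

#' Likelihood-ratio distribution of a risk classifier
#'
#' The likelihood ratio of an item with risk `r` is the post-test odds over
#' the pre-test odds, `LR = (r / (1 - r)) / (f / (1 - f))`.  Together with
#' the population probability of each item this describes the distribution
#' of evidence strengths the test delivers.  Boundary risks yield `LR = 0`
#' (risk 0) or `Inf` (risk 1).
#'
#' @param classifier A [risk_classifier()].
#' @return Object of class `lr_table`: data frame with columns `lr`, `prob`
#'   (population mass), and `risk`.
#' @export
lr_table <- function(classifier) {
  stopifnot(inherits(classifier, "risk_classifier"))
  it <- classifier$items
  f <- classifier$prior
  lr <- ifelse(it$risk >= 1, Inf,
               (it$risk / (1 - it$risk)) / (f / (1 - f)))
  structure(data.frame(lr = lr, prob = it$prob, risk = it$risk),
            class = c("lr_table", "data.frame"))
}

#' Population fraction with extreme likelihood ratios
#'
#' Fraction of the population receiving at least `x`-fold increased or
#' decreased odds of disease from the classifier, i.e. total mass of items
#' with `LR >= x` or `LR <= 1/x`.
#'
#' @param table An `lr_table` from [lr_table()].
#' @param x Odds multiplier threshold, greater than 1 (at `x = 1` every
#'   individual qualifies).
#' @return Population fraction in \[0, 1\].
#' @export
extreme_lr_fraction <- function(table, x) {
  stopifnot(inherits(table, "lr_table"), x >= 1)
  sum(table$prob[table$lr >= x | table$lr <= 1 / x])
}
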