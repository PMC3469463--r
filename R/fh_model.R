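#' Complete family-history risk classifier
#'
#' The complete model predicts, for an index individual with family-history
#' pattern `FH_j` (the vector of lifetime disease statuses of the
#' relatives), exactly the conditional risk `P(index affected | FH_j)`.  It
#' is the accuracy ceiling among all predictors that use only the pattern of
#' disease occurrence in the family.
#'
#' @param dist A [pattern_distribution()].
#' @return A [risk_classifier()] with one item per relative pattern (ties in
#'   risk merged).
#' @examples
#' \donttest{
#' pd <- pattern_distribution(disease_spec(f = 0.1, h2 = 0.8), ped_trio())
#' auc(roc(complete_classifier(pd)))
#' }
#' @export
complete_classifier <- function(dist) {
  stopifnot(inherits(dist, "pattern_distribution"))
  risk_classifier(risk = dist$index_risk, prob = dist$rel_prob,
                  prior = dist$spec$f)
}

#' Summary function: thresholded count of affected first-degree relatives
#'
#' Maps each relative pattern to the number of affected first-degree
#' relatives of the index (parents, full siblings, and children, identified
#' from the pedigree links), thresholded at 2 (categories 0, 1, >1) as in
#' the Gail breast-cancer model's family-history component.
#'
#' @param ped A [pedigree()].
#' @param max_count Counts at or above this collapse into the top category.
#' @return A function taking a `2^(n-1)` x `(n-1)` matrix of relative
#'   patterns and returning an integer category per row.
#' @export
first_degree_summary <- function(ped, max_count = 2L) {
  stopifnot(inherits(ped, "pedigree"))
  idx <- ped$id[ped$is_index]
  fa <- ped$father_id[ped$is_index]
  mo <- ped$mother_id[ped$is_index]
  rel <- ped[!ped$is_index, , drop = FALSE]
  is_parent <- rel$id %in% c(fa, mo)
  is_child <- !is.na(rel$father_id) & rel$father_id == idx |
              !is.na(rel$mother_id) & rel$mother_id == idx
  is_fullsib <- !is.na(fa) & !is.na(mo) &
                !is.na(rel$father_id) & rel$father_id == fa &
                !is.na(rel$mother_id) & rel$mother_id == mo
  first_degree <- is_parent | is_child | is_fullsib
  function(rel_patterns) {
    stopifnot(ncol(rel_patterns) == length(first_degree))
    counts <- as.integer(rel_patterns %*% first_degree)
    pmin(counts, max_count)
  }
}

#' Restricted family-history risk classifier
#'
#' A restricted model condenses the full family-history pattern into a
#' summary statistic before predicting risk: all patterns in an equivalence
#' class share the class-conditional risk
#' `sum_j P(FH_j, index affected) / sum_j P(FH_j)` over the class.  The
#' default summary is the thresholded number (0, 1, >1) of affected
#' first-degree relatives, mirroring how family history enters clinical
#' models when a detailed pedigree is unavailable.
#'
#' By the data-processing inequality the restricted AUC never exceeds the
#' complete model's.
#'
#' @param dist A [pattern_distribution()].
#' @param summary A summary function as produced by
#'   [first_degree_summary()]; defaults to the first-degree count summary
#'   for the distribution's pedigree.
#' @return A [risk_classifier()] with one item per non-empty summary
#'   category.
#' @export
restricted_classifier <- function(dist, summary = NULL) {
  stopifnot(inherits(dist, "pattern_distribution"))
  if (is.null(summary)) summary <- first_degree_summary(dist$ped)
  if (ncol(dist$rel_patterns) == 0L)
    return(risk_classifier(risk = dist$spec$f, prob = 1, prior = dist$spec$f))
  cat_id <- summary(dist$rel_patterns)
  stopifnot(length(cat_id) == nrow(dist$rel_patterns))
  p_aff <- dist$index_risk * dist$rel_prob
  class_prob <- as.numeric(tapply(dist$rel_prob, cat_id, sum))
  class_aff <- as.numeric(tapply(p_aff, cat_id, sum))
  nonempty <- class_prob > 0
  if (!all(nonempty))
    warning(sum(!nonempty), " empty summary class(es) dropped")
  risk_classifier(risk = class_aff[nonempty] / class_prob[nonempty],
                  prob = class_prob[nonempty], prior = dist$spec$f)
}

#' One-call family-history accuracy summary
#'
#' Convenience wrapper computing the pattern distribution and both
#' family-history classifiers for a pedigree and disease.
#'
#' @param spec A [disease_spec()].
#' @param ped A [pedigree()].
#' @return List with `distribution`, `complete`, `restricted`, and their
#'   AUCs `auc_complete`, `auc_restricted`.
#' @export
fh_metrics <- function(spec, ped) {
  dist <- pattern_distribution(spec, ped)
  cc <- complete_classifier(dist)
  rc <- restricted_classifier(dist)
  list(distribution = dist, complete = cc, restricted = rc,
       auc_complete = auc(roc(cc)), auc_restricted = auc(roc(rc)))
}
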