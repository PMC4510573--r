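# Rating-based ROC evaluation of annotation evidence sources: empirical ROC
# points, trapezoidal (Mann-Whitney) area, accuracy/sensitivity/specificity
# at an operating threshold, and cross-source averaging.

#' Construct rating cases
#'
#' Each case is a binary truth label (1 truly positive, 0 truly negative)
#' with an ordinal confidence rating (general scale 1-5; the observed coding
#' in practice is often 2-5).
#'
#' @param truth vector of 0/1 labels.
#' @param rating integer ordinal ratings.
#' @param case_id optional identifiers.
#' @return data.frame with class `rating_cases`.
#' @export
rating_cases <- function(truth, rating, case_id = NULL) {
  truth <- as.integer(truth)
  if (!all(truth %in% c(0L, 1L))) stop("truth must be 0 or 1")
  rating <- as.integer(rating)
  if (is.null(case_id)) case_id <- seq_along(truth)
  df <- data.frame(case_id = case_id, truth = truth, rating = rating,
                   stringsAsFactors = FALSE)
  class(df) <- c("rating_cases", "data.frame")
  df
}

#' Empirical ROC points from rating cases
#'
#' One operating point per distinct rating threshold t (predict positive iff
#' rating >= t), plus the (0,0) and (1,1) endpoints, ordered by
#' non-decreasing false-positive rate.
#'
#' @param cases a [rating_cases()] table.
#' @return data.frame with columns `FPR`, `TPR`.
#' @export
roc_points <- function(cases) {
  n_pos <- sum(cases$truth == 1L)
  n_neg <- sum(cases$truth == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("need at least one positive and one negative case")
  thresholds <- sort(unique(cases$rating), decreasing = TRUE)
  pts <- t(vapply(thresholds, function(t) {
    pred <- cases$rating >= t
    c(FPR = sum(pred & cases$truth == 0L) / n_neg,
      TPR = sum(pred & cases$truth == 1L) / n_pos)
  }, c(FPR = 0, TPR = 0)))
  pts <- rbind(c(FPR = 0, TPR = 0), pts, c(FPR = 1, TPR = 1))
  pts <- as.data.frame(pts)
  pts <- unique(pts[order(pts$FPR, pts$TPR), , drop = FALSE])
  rownames(pts) <- NULL
  pts
}

#' Empirical area under the ROC curve
#'
#' Trapezoidal area over the empirical points; equal to the Mann-Whitney
#' concordance statistic (concordant pairs plus half the ties, over all
#' positive x negative pairs), hence invariant under strictly monotone
#' re-coding of the rating scale.
#'
#' @param x a [rating_cases()] table or a point data.frame from
#'   [roc_points()].
#' @return area in `[0, 1]`.
#' @export
empiric_auc <- function(x) {
  pts <- if (is.data.frame(x) && all(c("FPR", "TPR") %in% names(x)) &&
             !inherits(x, "rating_cases")) x else roc_points(x)
  sum(diff(pts$FPR) * (utils::head(pts$TPR, -1) + utils::tail(pts$TPR, -1)) / 2)
}

confusion_at <- function(cases, t) {
  pred <- cases$rating >= t
  list(TP = sum(pred & cases$truth == 1L),
       FP = sum(pred & cases$truth == 0L),
       TN = sum(!pred & cases$truth == 0L),
       FN = sum(!pred & cases$truth == 1L))
}

#' Accuracy, sensitivity and specificity at a rating threshold
#'
#' Predicted positive iff rating >= t. When `t` is omitted the
#' Youden-optimal threshold (maximizing sensitivity + specificity - 1, ties
#' resolved toward the lower threshold) is used.
#'
#' @param cases a [rating_cases()] table.
#' @param t operating rating threshold (optional).
#' @param source label carried into the summary.
#' @return one-row data.frame: `source`, `n_cases`, `operating_threshold`,
#'   `accuracy`, `sensitivity`, `specificity`, `empiric_area`.
#' @export
summary_at_threshold <- function(cases, t = NULL, source = "source") {
  if (is.null(t)) {
    cand <- sort(unique(cases$rating))
    j <- vapply(cand, function(tt) {
      cm <- confusion_at(cases, tt)
      sens <- if (cm$TP + cm$FN > 0) cm$TP / (cm$TP + cm$FN) else 0
      spec <- if (cm$TN + cm$FP > 0) cm$TN / (cm$TN + cm$FP) else 0
      sens + spec - 1
    }, 0)
    t <- cand[which(j == max(j))[1L]]
  }
  cm <- confusion_at(cases, t)
  n <- nrow(cases)
  data.frame(
    source = source, n_cases = n, operating_threshold = t,
    accuracy = (cm$TP + cm$TN) / n,
    sensitivity = if (cm$TP + cm$FN > 0) cm$TP / (cm$TP + cm$FN) else NA_real_,
    specificity = if (cm$TN + cm$FP > 0) cm$TN / (cm$TN + cm$FP) else NA_real_,
    empiric_area = empiric_auc(cases),
    stringsAsFactors = FALSE
  )
}

#' Mean accuracy across evidence sources
#'
#' Unweighted arithmetic mean of the per-source accuracies.
#'
#' @param summaries data.frame of per-source summaries (needs an `accuracy`
#'   column) or a list of such one-row frames.
#' @return fraction in `[0, 1]`.
#' @export
mean_accuracy <- function(summaries) {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, summaries)
  if (nrow(summaries) == 0L) stop("no summaries")
  mean(summaries$accuracy)
}
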