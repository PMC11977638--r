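#' ROC curve and AUC from labeled scores
#'
#' The AUC is the pairwise-comparison (Mann-Whitney) statistic: the fraction
#' of positive-negative pairs where the positive scores higher, ties counting
#' one half. It is verified internally against the trapezoidal area of the
#' threshold-sweep curve to 1e-9 (the two are algebraically identical when
#' the sweep visits every unique score); both values are returned. Curve
#' points are computed at every unique score with the classification rule
#' "positive iff score > threshold".
#'
#' @param scores Numeric score vector (e.g. Z scores).
#' @param labels Character/factor vector, `"positive"` / `"negative"`,
#'   parallel to `scores`.
#' @return A `roc_curve`: list with `points` (threshold, sensitivity,
#'   specificity, precision), `auc`, `auc_trapezoid`, `n_pos`, `n_neg`.
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("positive", "negative")))
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("need at least one positive and one negative score")
  }
  np <- length(pos); nn <- length(neg)
  r <- rank(c(pos, neg))  # midranks handle ties as 1/2
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)

  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(ths, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(ths, function(t) mean(neg > t), numeric(1))
  auc_trap <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  stopifnot(abs(auc - auc_trap) < 1e-9)

  tp <- vapply(ths, function(t) sum(pos > t), numeric(1))
  fp <- vapply(ths, function(t) sum(neg > t), numeric(1))
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  points <- data.frame(threshold = ths, sensitivity = tpr,
                       specificity = 1 - fpr, precision = precision)
  structure(list(points = points, auc = auc, auc_trapezoid = auc_trap,
                 n_pos = np, n_neg = nn),
            class = "roc_curve")
}

#' @method print roc_curve
#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Choose the Z-score threshold at a specificity constraint
#'
#' The operating threshold is the smallest observed negative score such that
#' the fraction of negatives strictly above it is at most
#' `1 - min_specificity` — i.e. the lowest data-driven threshold that keeps
#' specificity at or above the constraint under the classification rule
#' "positive iff Z > threshold". No interpolation: candidate thresholds are
#' the observed negative scores, which makes the operating point reproducible
#' from the label set alone.
#'
#' @param negative_scores Numeric vector of negative-label scores (>= 1).
#' @param min_specificity Specificity constraint in (0, 1], default 0.95.
#' @param positive_scores Optional positive-label scores; if given, the
#'   achieved sensitivity at the threshold is recorded.
#' @return A `threshold_decision`: list with z_threshold, min_specificity,
#'   achieved_specificity, achieved_sensitivity, n_negatives.
#' @export
choose_threshold <- function(negative_scores, min_specificity = 0.95,
                             positive_scores = NULL) {
  if (length(negative_scores) == 0L) stop("no negative scores supplied")
  stopifnot(all(is.finite(negative_scores)),
            min_specificity > 0, min_specificity <= 1)
  cand <- sort(unique(negative_scores))
  nn <- length(negative_scores)
  # fraction of negatives strictly above each candidate
  n_le <- cumsum(tabulate(match(sort(negative_scores), cand), nbins = length(cand)))
  frac_above <- (nn - n_le) / nn
  idx <- which(frac_above <= 1 - min_specificity)[1]  # exists: last cand has 0
  thr <- cand[idx]
  achieved <- mean(negative_scores <= thr)
  stopifnot(achieved >= min_specificity)
  sens <- if (is.null(positive_scores)) NA_real_ else mean(positive_scores > thr)
  structure(list(z_threshold = thr, min_specificity = min_specificity,
                 achieved_specificity = achieved,
                 achieved_sensitivity = sens,
                 n_negatives = nn),
            class = "threshold_decision")
}

#' @method print threshold_decision
#' @export
print.threshold_decision <- function(x, ...) {
  cat(sprintf(paste0("<threshold_decision> Z > %.4f (specificity %.4f >= %.2f",
                     " on %d negatives%s)\n"),
              x$z_threshold, x$achieved_specificity, x$min_specificity,
              x$n_negatives,
              if (is.na(x$achieved_sensitivity)) "" else
                sprintf("; sensitivity %.4f", x$achieved_sensitivity)))
  invisible(x)
}

#' Classify samples at a fixed threshold
#'
#' Positive iff Z strictly exceeds the threshold (a sample sitting exactly on
#' the threshold is negative, consistent with how the threshold was chosen).
#'
#' @param z_scores Numeric vector of Z scores.
#' @param decision A `threshold_decision`.
#' @return Character vector, `"positive"` / `"negative"`.
#' @export
classify_samples <- function(z_scores, decision) {
  stopifnot(inherits(decision, "threshold_decision"))
  ifelse(z_scores > decision$z_threshold, "positive", "negative")
}
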