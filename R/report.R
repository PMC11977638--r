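#' Cohort-level detection and tumor-fraction summary
#'
#' Per clinical group: the detection rate (positives / samples) and the
#' median and IQR of the estimated tumor fraction among ctDNA-positive
#' samples (absent, not zero, for groups without positives). Tumor fractions
#' are compared between group pairs with two-sided Wilcoxon rank-sum tests
#' restricted to positives, mirroring how such studies report TF contrasts.
#'
#' @param results data.frame with columns `sample_id`, `group`, `tf`, `call`
#'   (and optionally `z`).
#' @return A `cohort_summary`: list with `group_summary` and `tf_tests`
#'   data.frames.
#' @export
summarize_cohort <- function(results) {
  stopifnot(all(c("sample_id", "group", "tf", "call") %in% names(results)))
  groups <- unique(results$group)
  rows <- lapply(groups, function(g) {
    r <- results[results$group == g, ]
    pos_tf <- r$tf[r$call == "positive"]
    data.frame(group = g, n = nrow(r), n_positive = length(pos_tf),
               detection_rate = length(pos_tf) / nrow(r),
               tf_median = if (length(pos_tf)) stats::median(pos_tf) else NA_real_,
               tf_q25 = if (length(pos_tf))
                 unname(stats::quantile(pos_tf, 0.25)) else NA_real_,
               tf_q75 = if (length(pos_tf))
                 unname(stats::quantile(pos_tf, 0.75)) else NA_real_)
  })
  group_summary <- do.call(rbind, rows)
  pairs <- if (length(groups) >= 2L) utils::combn(groups, 2, simplify = FALSE)
           else list()
  tests <- lapply(pairs, function(pr) {
    x <- results$tf[results$group == pr[1] & results$call == "positive"]
    y <- results$tf[results$group == pr[2] & results$call == "positive"]
    if (length(x) < 1L || length(y) < 1L) return(NULL)
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    data.frame(group_a = pr[1], group_b = pr[2], n_a = length(x),
               n_b = length(y), statistic = unname(wt$statistic),
               p_value = wt$p.value)
  })
  tests <- tests[!vapply(tests, is.null, logical(1))]
  tf_tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(group_a = character(), group_b = character(),
               n_a = integer(), n_b = integer(),
               statistic = numeric(), p_value = numeric())
  structure(list(group_summary = group_summary, tf_tests = tf_tests),
            class = "cohort_summary")
}

#' @method print cohort_summary
#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$group_summary, row.names = FALSE)
  if (nrow(x$tf_tests)) {
    cat("TF rank-sum tests (positives only):\n")
    print(x$tf_tests, row.names = FALSE)
  }
  invisible(x)
}

# Cohen's kappa for two parallel binary call vectors
.cohen_kappa <- function(a, b) {
  po <- mean(a == b)
  if (po == 1) return(1)
  lv <- union(unique(a), unique(b))
  pa <- table(factor(a, lv)) / length(a)
  pb <- table(factor(b, lv)) / length(b)
  pe <- sum(pa * pb)
  (po - pe) / (1 - pe)
}

#' Agreement between the WGS classifier and an orthogonal assay
#'
#' Computes percent agreement, Cohen's kappa, an exact McNemar test on the
#' discordant pairs (two-sided binomial, appropriate for the small discordant
#' counts of such comparisons), and the Pearson correlation between
#' log10(tf) and log10(orthogonal_vaf) restricted to samples called positive
#' by both assays (the log scale reflects that these quantities span orders
#' of magnitude).
#'
#' @param results data.frame with columns `call`, `orthogonal_call`, `tf`,
#'   `orthogonal_vaf`; rows with a missing orthogonal call are dropped.
#' @return An `assay_agreement`: list with n, agreement, kappa,
#'   mcnemar_p (with discordant counts b, c), pearson_r and n_double_positive.
#' @export
compare_assays <- function(results) {
  stopifnot(all(c("call", "orthogonal_call", "tf", "orthogonal_vaf")
                %in% names(results)))
  r <- results[!is.na(results$orthogonal_call) & !is.na(results$call), ]
  if (nrow(r) < 2L) stop("need >= 2 samples with both assay calls")
  agreement <- mean(r$call == r$orthogonal_call)
  kappa <- .cohen_kappa(r$call, r$orthogonal_call)
  b <- sum(r$call == "positive" & r$orthogonal_call == "negative")
  cc <- sum(r$call == "negative" & r$orthogonal_call == "positive")
  mcnemar_p <- if (b + cc > 0)
    stats::binom.test(b, b + cc, p = 0.5)$p.value else NA_real_
  dp <- r[r$call == "positive" & r$orthogonal_call == "positive" &
            r$tf > 0 & r$orthogonal_vaf > 0, ]
  pearson_r <- if (nrow(dp) >= 2L)
    stats::cor(log10(dp$tf), log10(dp$orthogonal_vaf)) else NA_real_
  structure(list(n = nrow(r), agreement = agreement, kappa = kappa,
                 mcnemar_b = b, mcnemar_c = cc, mcnemar_p = mcnemar_p,
                 pearson_r = pearson_r, n_double_positive = nrow(dp)),
            class = "assay_agreement")
}

#' @method print assay_agreement
#' @export
print.assay_agreement <- function(x, ...) {
  cat(sprintf(paste0("<assay_agreement> n = %d: agreement %.3f, kappa %.3f, ",
                     "McNemar p = %.3g (b = %d, c = %d), r = %.3f on %d ",
                     "double positives\n"),
              x$n, x$agreement, x$kappa, x$mcnemar_p, x$mcnemar_b,
              x$mcnemar_c, x$pearson_r, x$n_double_positive))
  invisible(x)
}

#' Simulate an orthogonal deep-targeted assay
#'
#' Emulates the per-sample output of a 16-plex deep-targeted sequencing
#' assay: each target is sequenced to very high depth, a target is detected
#' when it accumulates at least `min_reads` variant reads, the sample is
#' called positive when at least `min_targets` targets are detected, and the
#' reported level is the mean VAF over all targets including undetected ones.
#'
#' @param true_tf Vector of true plasma tumor fractions, one per sample.
#' @param n_targets Number of targeted variants per patient.
#' @param depth Raw depth per target.
#' @param min_reads Variant reads required to call one target detected.
#' @param min_targets Detected targets required to call the sample positive.
#' @param seed Optional integer seed.
#' @return data.frame with `orthogonal_call` and `orthogonal_vaf`.
#' @export
simulate_orthogonal_assay <- function(true_tf, n_targets = 16, depth = 1e5,
                                      min_reads = 3, min_targets = 2,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(true_tf, function(tf) {
    reads <- stats::rbinom(n_targets, depth, tf)
    c(detected = sum(reads >= min_reads), vaf = mean(reads) / depth)
  }, numeric(2))
  data.frame(orthogonal_call = ifelse(out["detected", ] >= min_targets,
                                      "positive", "negative"),
             orthogonal_vaf = out["vaf", ])
}
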