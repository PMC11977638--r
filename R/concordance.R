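#' Call genotypes from SNP read counts
#'
#' Banding rules on the B-allele fraction f = b_allele_count / depth:
#' sites with depth <= 10 are excluded; sites deeper than 300 reads are
#' first downsampled to 300 by seeded hypergeometric sampling of the allele
#' counts; then f >= 0.85 is homozygous-alternate, f <= 0.15
#' homozygous-reference (mirrored band), 0.35 <= f <= 0.65 heterozygous, and
#' anything else is excluded as uninformative.
#'
#' @param obs data.frame/data.table with columns `site_id`, `depth`,
#'   `b_allele_count`.
#' @param seed Optional seed for the downsampling of >300x sites.
#' @return data.table with `site_id`, `call` (HOM_REF/HET/HOM_ALT/EXCLUDED)
#'   and `allele_fraction` (NA where depth-excluded).
#' @export
call_genotype <- function(obs, seed = NULL) {
  stopifnot(all(c("site_id", "depth", "b_allele_count") %in% names(obs)))
  depth <- as.integer(obs$depth)
  b <- as.integer(obs$b_allele_count)
  stopifnot(all(b >= 0), all(b <= depth))
  if (!is.null(seed)) set.seed(seed)
  depth_used <- depth
  b_used <- b
  cap <- which(depth > 300L)
  if (length(cap) > 0L) {
    b_used[cap] <- stats::rhyper(length(cap), m = b[cap],
                                 n = depth[cap] - b[cap], k = 300L)
    depth_used[cap] <- 300L
  }
  f <- ifelse(depth_used > 0L, b_used / depth_used, NA_real_)
  call <- rep("EXCLUDED", length(depth))
  call[f >= 0.85] <- "HOM_ALT"
  call[f <= 0.15] <- "HOM_REF"
  call[f >= 0.35 & f <= 0.65] <- "HET"
  call[depth <= 10L] <- "EXCLUDED"
  f[depth <= 10L] <- NA_real_
  data.table::data.table(site_id = obs$site_id, call = call,
                         allele_fraction = f)
}

#' SNP concordance score between two samples
#'
#' The SNP score is the fraction of mutually accepted sites (neither call
#' EXCLUDED) where the two samples carry the identical genotype call; a
#' HET-vs-HOM pair counts as discordant.
#'
#' @param calls_a,calls_b Genotype call tables from [call_genotype()],
#'   matched by `site_id`.
#' @param sample_a,sample_b Optional sample identifiers for reporting.
#' @return A `concordance_result`: list with snp_score, n_sites_used,
#'   n_concordant and the sample ids.
#' @export
snp_score <- function(calls_a, calls_b, sample_a = "A", sample_b = "B") {
  m <- merge(data.table::as.data.table(calls_a)[, c("site_id", "call")],
             data.table::as.data.table(calls_b)[, c("site_id", "call")],
             by = "site_id", suffixes = c("_a", "_b"))
  usable <- m$call_a != "EXCLUDED" & m$call_b != "EXCLUDED"
  n_used <- sum(usable)
  if (n_used == 0L) stop("no informative sites shared by ", sample_a,
                         " and ", sample_b)
  n_conc <- sum(m$call_a[usable] == m$call_b[usable])
  structure(list(sample_a = sample_a, sample_b = sample_b,
                 snp_score = n_conc / n_used,
                 n_sites_used = n_used, n_concordant = n_conc),
            class = "concordance_result")
}

#' @method print concordance_result
#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> %s vs %s: SNP score %.4f (%d/%d sites)\n",
              x$sample_a, x$sample_b, x$snp_score, x$n_concordant,
              x$n_sites_used))
  invisible(x)
}

#' Coherence check of a patient's sample set
#'
#' A patient's sample set is coherent when the reference sample scores above
#' `within_min` (default 0.8) against every other sample of the same patient
#' and below `cross_max` (default 0.7) against representative samples of all
#' other patients. Violating comparisons are listed.
#'
#' @param within_scores Named numeric vector of SNP scores against the same
#'   patient's samples.
#' @param cross_scores Named numeric vector of SNP scores against other
#'   patients' representative samples.
#' @param within_min,cross_max Coherence thresholds.
#' @return A `coherence_report`: list with `coherent` flag and a
#'   `violations` data.frame (type, comparison, score).
#' @export
coherence_check <- function(within_scores, cross_scores,
                            within_min = 0.8, cross_max = 0.7) {
  stopifnot(length(within_scores) >= 1L, length(cross_scores) >= 1L)
  nm_w <- if (is.null(names(within_scores)))
    paste0("within_", seq_along(within_scores)) else names(within_scores)
  nm_c <- if (is.null(names(cross_scores)))
    paste0("cross_", seq_along(cross_scores)) else names(cross_scores)
  bad_w <- which(!(within_scores > within_min))
  bad_c <- which(!(cross_scores < cross_max))
  violations <- rbind(
    if (length(bad_w)) data.frame(type = "within_patient",
                                  comparison = nm_w[bad_w],
                                  score = unname(within_scores[bad_w])),
    if (length(bad_c)) data.frame(type = "cross_patient",
                                  comparison = nm_c[bad_c],
                                  score = unname(cross_scores[bad_c])))
  if (is.null(violations)) {
    violations <- data.frame(type = character(), comparison = character(),
                             score = numeric())
  }
  structure(list(coherent = nrow(violations) == 0L, violations = violations,
                 within_min = within_min, cross_max = cross_max),
            class = "coherence_report")
}

#' @method print coherence_report
#' @export
print.coherence_report <- function(x, ...) {
  cat(sprintf("<coherence_report> %s (%d violation(s))\n",
              if (x$coherent) "coherent" else "INCOHERENT",
              nrow(x$violations)))
  if (nrow(x$violations) > 0L) print(x$violations)
  invisible(x)
}
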