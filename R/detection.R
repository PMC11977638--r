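#' Load a site-level evidence table
#'
#' Reads a TSV with columns chrom, pos, ref, alt, depth, alt_count (1-based
#' positions matching the compendium VCF). Rows are validated; a malformed
#' row aborts with its line number.
#'
#' @param path TSV file path.
#' @return A data.table of validated evidence rows (possibly empty).
#' @export
load_evidence <- function(path) {
  if (!file.exists(path)) stop("no such evidence file: ", path)
  ev <- data.table::fread(path, sep = "\t", header = TRUE)
  req <- c("chrom", "pos", "ref", "alt", "depth", "alt_count")
  if (!all(req %in% names(ev))) {
    stop("evidence table must have columns: ", paste(req, collapse = ", "))
  }
  ev <- ev[, req, with = FALSE]
  for (col in c("chrom", "ref", "alt")) {
    data.table::set(ev, j = col, value = as.character(ev[[col]]))
  }
  if (nrow(ev) == 0L) return(ev)
  # +1 for the header line
  bad <- which(!is.finite(ev$depth) | !is.finite(ev$alt_count) |
                 ev$depth < 0 | ev$alt_count < 0 |
                 ev$pos < 1 | is.na(ev$chrom))
  if (length(bad) > 0L) {
    stop(sprintf("malformed evidence row at line %d of %s", bad[1] + 1L, path))
  }
  over <- which(ev$alt_count > ev$depth)
  if (length(over) > 0L) {
    stop(sprintf("alt_count exceeds depth at line %d of %s", over[1] + 1L, path))
  }
  ev
}

#' Score plasma evidence against a compendium
#'
#' Joins the evidence to the compendium by (chrom, pos, alt); compendium
#' sites absent from the evidence count as depth 0, and evidence rows outside
#' the compendium are ignored (their count is reported in the result). The
#' detection statistics are: R, the total reads covering compendium sites;
#' cov, the mean depth over covered sites (R / n_covered); and M, either the
#' total variant-supporting reads (`mode = "reads"`, default — det_rate is
#' then a proper per-read rate, matching the noise-rate definition of errors
#' per read evaluated) or the number of sites with at least one variant read
#' (`mode = "sites"`). det_rate = M / R (0 when R = 0, flagged).
#'
#' @param compendium An `snv_compendium`.
#' @param evidence Evidence data.table (chrom, pos, ref, alt, depth,
#'   alt_count).
#' @param mode `"reads"` or `"sites"`.
#' @return A `detection_result`: list with M, R, cov, n_covered, det_rate,
#'   mode, n_sites, n_ignored and a `zero_coverage` flag.
#' @export
compute_detection <- function(compendium, evidence, mode = c("reads", "sites")) {
  mode <- if (missing(mode)) "reads" else match.arg(mode)
  if (!inherits(compendium, "snv_compendium")) {
    stop("compendium must be an snv_compendium")
  }
  s <- compendium$sites
  n <- compendium$N
  # fast path: evidence rows exactly aligned to compendium sites (as produced
  # by simulate_evidence); otherwise a key join
  aligned <- nrow(evidence) == n &&
    identical(evidence$pos, s$pos) &&
    identical(evidence$chrom, s$chrom) &&
    identical(evidence$alt, s$alt)
  if (aligned) {
    depth <- evidence$depth
    alt_count <- evidence$alt_count
    n_ignored <- 0L
  } else {
    ev_key <- paste(evidence$chrom, evidence$pos, evidence$alt)
    idx <- match(compendium$site_key, ev_key)
    depth <- ifelse(is.na(idx), 0L, evidence$depth[idx])
    alt_count <- ifelse(is.na(idx), 0L, evidence$alt_count[idx])
    n_ignored <- sum(!(ev_key %in% compendium$site_key))
  }
  if (any(alt_count > depth)) stop("alt_count exceeds depth in evidence")
  R <- sum(depth)
  n_covered <- sum(depth >= 1L)
  cov <- if (n_covered > 0L) R / n_covered else 0
  M <- if (mode == "reads") sum(alt_count) else sum(alt_count >= 1L)
  structure(list(M = M, R = R, cov = cov, n_covered = n_covered,
                 det_rate = if (R > 0) M / R else 0,
                 mode = mode, n_sites = n, n_ignored = n_ignored,
                 zero_coverage = R == 0),
            class = "detection_result")
}

#' @method print detection_result
#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(paste0("<detection_result> M = %d, R = %d, cov = %.2f, ",
                     "det_rate = %.3g (%s mode, %d/%d sites covered)\n"),
              x$M, x$R, x$cov, x$det_rate, x$mode, x$n_covered, x$n_sites))
  invisible(x)
}
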