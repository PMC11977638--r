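#' Construct an SNV compendium object
#'
#' @param patient_id Patient identifier.
#' @param sites data.frame/data.table with columns chrom, pos, ref, alt,
#'   tumor_vaf (and optionally is_artifact); unique by (chrom, pos, alt).
#' @param tissue `"FF"` or `"FFPE"`.
#' @return An object of class `snv_compendium`.
#' @export
new_compendium <- function(patient_id, sites, tissue = c("FF", "FFPE")) {
  tissue <- match.arg(tissue)
  sites <- data.table::as.data.table(sites)
  req <- c("chrom", "pos", "ref", "alt", "tumor_vaf")
  if (!all(req %in% names(sites))) {
    stop("compendium sites need columns: ", paste(req, collapse = ", "))
  }
  if (!"is_artifact" %in% names(sites)) sites$is_artifact <- NA
  stopifnot(all(sites$pos >= 1), all(sites$ref != sites$alt),
            all(nchar(sites$ref) == 1L), all(nchar(sites$alt) == 1L),
            all(sites$tumor_vaf > 0), all(sites$tumor_vaf <= 1))
  key <- paste(sites$chrom, sites$pos, sites$alt)
  if (anyDuplicated(key)) {
    sites <- sites[!duplicated(key)]
    key <- key[!duplicated(key)]
  }
  structure(list(patient_id = patient_id, tissue = tissue, sites = sites,
                 N = nrow(sites), site_key = key),
            class = "snv_compendium")
}

#' @method print snv_compendium
#' @export
print.snv_compendium <- function(x, ...) {
  cat(sprintf("<snv_compendium> patient %s, %s tissue, N = %d sites\n",
              x$patient_id, x$tissue, x$N))
  invisible(x)
}

#' Write a compendium as VCF
#'
#' Minimal VCF 4.2 with one record per SNV and the tumor VAF in the INFO
#' field (`VAF=<float>`), 1-based positions.
#'
#' @param compendium An `snv_compendium`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_compendium_vcf <- function(compendium, path) {
  stopifnot(inherits(compendium, "snv_compendium"))
  s <- compendium$sites
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=cfMRD;patient=%s;tissue=%s",
            compendium$patient_id, compendium$tissue),
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Tumor variant allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tVAF=%.8g",
            s$chrom, s$pos, s$ref, s$alt, s$tumor_vaf))
  writeLines(lines, path)
  invisible(path)
}

#' Load a patient SNV compendium from VCF
#'
#' Multi-allelic records are split into one row per alternate allele,
#' non-SNV records are skipped (count reported via message), and duplicate
#' (chrom, pos, alt) sites are collapsed to the first occurrence. Every
#' record must carry a `VAF` INFO tag.
#'
#' @param path VCF file path.
#' @param patient_id Patient identifier (default: file name stem).
#' @param tissue `"FF"` or `"FFPE"`.
#' @return An `snv_compendium`.
#' @export
load_compendium_vcf <- function(path, patient_id = NULL,
                                tissue = c("FF", "FFPE")) {
  tissue <- match.arg(tissue)
  if (!file.exists(path)) stop("no such VCF: ", path)
  if (is.null(patient_id)) patient_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("empty compendium VCF: ", path)
  vaf_raw <- vcfR::extract.info(v, element = "VAF")
  chrom <- fix$CHROM
  pos <- as.integer(fix$POS)
  ref <- fix$REF
  alt <- fix$ALT
  rows <- vector("list", nrow(fix))
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    if (is.na(vaf_raw[i])) {
      stop(sprintf("record %s:%d %s>%s has no VAF INFO tag",
                   chrom[i], pos[i], ref[i], alt[i]))
    }
    vafs <- suppressWarnings(as.numeric(strsplit(vaf_raw[i], ",", fixed = TRUE)[[1]]))
    vafs <- rep_len(vafs, length(alts))
    snv <- nchar(ref[i]) == 1L & nchar(alts) == 1L & alts != ref[i] &
      alts %in% .BASES
    n_skipped <- n_skipped + sum(!snv)
    if (!any(snv)) next
    rows[[i]] <- data.table::data.table(chrom = chrom[i], pos = pos[i],
                                        ref = ref[i], alt = alts[snv],
                                        tumor_vaf = vafs[snv])
  }
  sites <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (n_skipped > 0L) {
    message(sprintf("load_compendium_vcf: skipped %d non-SNV allele(s)", n_skipped))
  }
  if (nrow(sites) == 0L) stop("compendium empty after SNV filtering: ", path)
  n_dup <- sum(duplicated(paste(sites$chrom, sites$pos, sites$alt)))
  if (n_dup > 0L) {
    message(sprintf("load_compendium_vcf: collapsed %d duplicate site(s)", n_dup))
  }
  new_compendium(patient_id, sites, tissue)
}

# univariate k-component Gaussian mixture by EM; k-means initialization
.fit_gmm1d <- function(x, k = 2L, tol = 1e-6, max_iter = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 5L)
  mu <- as.numeric(km$centers)
  sd_ <- vapply(seq_len(k), function(j) {
    s <- stats::sd(x[km$cluster == j])
    if (!is.finite(s) || s < 1e-4) 1e-4 else s
  }, numeric(1))
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / length(x)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sd_[j]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / length(x)
    mu <- colSums(resp * x) / nk
    sd_ <- sqrt(colSums(resp * (x - rep(mu, each = length(x)))^2) / nk)
    sd_[!is.finite(sd_) | sd_ < 1e-6] <- 1e-6
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      o <- order(mu)
      return(list(weight = w[o], mean = mu[o], sd = sd_[o],
                  loglik = ll, n_iter = it, converged = TRUE))
    }
    ll_old <- ll
  }
  stop(sprintf("Gaussian mixture EM did not converge after %d iterations", max_iter))
}

#' Fit a VAF threshold separating FFPE artifacts from genuine somatic VAFs
#'
#' Fits a two-component univariate Gaussian mixture to the compendium VAF
#' distribution by EM (tolerance 1e-6, at most 500 iterations, k-means
#' initialization under a fixed seed). The lower-mean component is taken as
#' the artifact component. The threshold is the smallest VAF on a 1e-4-step
#' grid above the artifact-component mean where the posterior probability of
#' the artifact component drops to at most `target_fp_rate` — i.e. the VAF
#' above which a retained site has at most a 10% (by default) chance of being
#' an artifact.
#'
#' @param vafs Numeric vector of tumor VAFs (>= 50 values, nonzero spread).
#' @param target_fp_rate Maximum posterior artifact probability at the
#'   threshold (default 0.10).
#' @param seed Seed for the k-means initialization.
#' @param tol,max_iter EM convergence controls.
#' @return A `vaf_threshold`: list with `threshold`, `components`
#'   (data.frame weight/mean/sd ordered by mean), `target_fp_rate`, and EM
#'   diagnostics.
#' @export
fit_artifact_vaf_threshold <- function(vafs, target_fp_rate = 0.10, seed = 1L,
                                       tol = 1e-6, max_iter = 500L) {
  vafs <- vafs[is.finite(vafs)]
  if (length(vafs) < 50L) {
    stop("need at least 50 VAFs to fit an artifact threshold, got ", length(vafs))
  }
  if (stats::sd(vafs) == 0) stop("no mixture structure: all VAFs identical")
  stopifnot(target_fp_rate > 0, target_fp_rate < 1)
  fit <- .fit_gmm1d(vafs, k = 2L, tol = tol, max_iter = max_iter, seed = seed)
  grid <- seq(fit$mean[1], max(fit$mean[2], max(vafs)), by = 1e-4)
  d1 <- fit$weight[1] * stats::dnorm(grid, fit$mean[1], fit$sd[1])
  d2 <- fit$weight[2] * stats::dnorm(grid, fit$mean[2], fit$sd[2])
  post1 <- d1 / (d1 + d2)
  hit <- which(post1 <= target_fp_rate)
  if (length(hit) == 0L) {
    stop("no VAF threshold reaches the target artifact posterior of ",
         target_fp_rate)
  }
  structure(list(threshold = grid[hit[1]],
                 components = data.frame(weight = fit$weight, mean = fit$mean,
                                         sd = fit$sd),
                 target_fp_rate = target_fp_rate,
                 loglik = fit$loglik, n_iter = fit$n_iter),
            class = "vaf_threshold")
}

#' @method print vaf_threshold
#' @export
print.vaf_threshold <- function(x, ...) {
  cat(sprintf(paste0("<vaf_threshold> %.4f (artifact posterior <= %.2f; ",
                     "components mu = %.3f/%.3f)\n"),
              x$threshold, x$target_fp_rate,
              x$components$mean[1], x$components$mean[2]))
  invisible(x)
}

#' Filter an FFPE compendium at a fitted VAF threshold
#'
#' Restricts the compendium to sites with `tumor_vaf` strictly above the
#' threshold. Only meaningful for FFPE tissue, whose compendia carry the
#' low-VAF artifact component; FF compendia are rejected so they pass through
#' the pipeline untouched.
#'
#' @param compendium An `snv_compendium` with `tissue == "FFPE"`.
#' @param vt A `vaf_threshold`.
#' @return The filtered `snv_compendium`; filter statistics in
#'   `attr(, "ffpe_filter_stats")`.
#' @export
apply_ffpe_filter <- function(compendium, vt) {
  stopifnot(inherits(compendium, "snv_compendium"),
            inherits(vt, "vaf_threshold"))
  if (compendium$tissue != "FFPE") {
    stop("FFPE filter applies only to FFPE compendia (tissue is ",
         compendium$tissue, ")")
  }
  keep <- compendium$sites$tumor_vaf > vt$threshold
  if (!any(keep)) stop("compendium exhausted by FFPE filter")
  out <- new_compendium(compendium$patient_id, compendium$sites[keep],
                        compendium$tissue)
  attr(out, "ffpe_filter_stats") <- list(n_before = compendium$N,
                                         n_removed = sum(!keep),
                                         threshold = vt$threshold)
  out
}
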