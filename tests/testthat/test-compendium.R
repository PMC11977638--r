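test_that("compendium VCFs round-trip through write and load", {
  comp <- simulate_compendium(300, seed = 21)
  path <- tempfile(fileext = ".vcf")
  write_compendium_vcf(comp, path)
  back <- load_compendium_vcf(path, patient_id = comp$patient_id)
  expect_identical(back$N, comp$N)
  expect_identical(back$sites$chrom, comp$sites$chrom)
  expect_identical(back$sites$pos, comp$sites$pos)
  expect_identical(back$sites$alt, comp$sites$alt)
  expect_equal(back$sites$tumor_vaf, comp$sites$tumor_vaf, tolerance = 1e-6)
  unlink(path)
})

test_that("VCF loading splits alleles, skips non-SNVs and collapses duplicates", {
  vcf <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"VAF\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           "chr1\t100\t.\tA\tT\t.\tPASS\tVAF=0.4",
           "chr1\t200\t.\tC\tG\t.\tPASS\tVAF=0.3",
           "chr1\t300\t.\tG\tA\t.\tPASS\tVAF=0.2",
           "chr1\t400\t.\tGT\tG\t.\tPASS\tVAF=0.5")   # indel, skipped
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_message(comp <- load_compendium_vcf(path), "skipped 1 non-SNV")
  expect_identical(comp$N, 3L)

  vcf_dup <- c(vcf[1:4], "chr1\t100\t.\tA\tT\t.\tPASS\tVAF=0.4")
  writeLines(vcf_dup, path)
  expect_message(comp <- load_compendium_vcf(path), "collapsed 1 duplicate")
  expect_identical(comp$N, 1L)

  vcf_novaf <- c(vcf[1:3], "chr1\t100\t.\tA\tT\t.\tPASS\tDP=10")
  writeLines(vcf_novaf, path)
  expect_error(load_compendium_vcf(path), "no VAF INFO tag")

  # multi-allelic record splits into one site per alternate allele
  vcf_ma <- c(vcf[1:3], "chr1\t100\t.\tA\tT,G\t.\tPASS\tVAF=0.4,0.2")
  writeLines(vcf_ma, path)
  comp <- load_compendium_vcf(path)
  expect_identical(comp$N, 2L)
  expect_setequal(comp$sites$alt, c("T", "G"))
  unlink(path)
})

test_that("the fitted VAF threshold matches the analytic mixture crossing", {
  set.seed(31)
  x <- c(rnorm(1000, 0.05, 0.01), rnorm(1000, 0.40, 0.05))
  vt <- fit_artifact_vaf_threshold(x, target_fp_rate = 0.10, seed = 7)

  # oracle: posterior crossing of the generating mixture density
  g <- seq(0.05, 0.40, by = 1e-4)
  post <- 0.5 * dnorm(g, 0.05, 0.01) /
    (0.5 * dnorm(g, 0.05, 0.01) + 0.5 * dnorm(g, 0.40, 0.05))
  oracle <- g[which(post <= 0.10)[1]]
  expect_gt(vt$threshold, 0.08)
  expect_lt(vt$threshold, 0.30)
  expect_lt(abs(vt$threshold - oracle), 0.03)

  # independent EM engine agrees on the component means
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(unname(mc$parameters$mean)), vt$components$mean,
               tolerance = 0.02)
})

test_that("degenerate VAF inputs are rejected and the threshold is monotone", {
  expect_error(fit_artifact_vaf_threshold(rep(0.4, 100)), "no mixture structure")
  expect_error(fit_artifact_vaf_threshold(runif(20)), "at least 50")

  set.seed(32)
  x <- c(rnorm(500, 0.05, 0.01), rnorm(500, 0.40, 0.05))
  t10 <- fit_artifact_vaf_threshold(x, target_fp_rate = 0.10, seed = 1)
  t50 <- fit_artifact_vaf_threshold(x, target_fp_rate = 0.50, seed = 1)
  expect_lte(t50$threshold, t10$threshold)
})

test_that("FFPE filtering keeps sites strictly above the threshold", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L), ref = "A",
                      alt = "T", tumor_vaf = c(0.1, 0.25, 0.5))
  comp <- new_compendium("P", sites, "FFPE")
  vt <- structure(list(threshold = 0.2, components = NULL,
                       target_fp_rate = 0.1), class = "vaf_threshold")
  filt <- apply_ffpe_filter(comp, vt)
  expect_identical(filt$N, 2L)
  expect_true(all(filt$sites$tumor_vaf > 0.2))

  vt0 <- structure(list(threshold = 0), class = "vaf_threshold")
  expect_identical(apply_ffpe_filter(comp, vt0)$N, 3L)

  vt_hi <- structure(list(threshold = 0.9), class = "vaf_threshold")
  expect_error(apply_ffpe_filter(comp, vt_hi), "exhausted")

  ff <- new_compendium("P", sites, "FF")
  expect_error(apply_ffpe_filter(ff, vt), "only to FFPE")
})

test_that("the fitted filter separates artifact from real sites in simulation", {
  comp <- simulate_compendium(10000, vaf_dist = c(0.4, 0.1), ffpe = TRUE,
                              artifact_fraction = 0.3,
                              artifact_vaf_dist = c(0.05, 0.01), seed = 33)
  vt <- fit_artifact_vaf_threshold(comp$sites$tumor_vaf, seed = 33)
  filt <- apply_ffpe_filter(comp, vt)
  n_art <- sum(comp$sites$is_artifact)
  n_real <- comp$N - n_art
  art_removed <- 1 - sum(filt$sites$is_artifact) / n_art
  real_removed <- 1 - sum(!filt$sites$is_artifact) / n_real
  expect_gte(art_removed, 0.90)
  expect_lte(real_removed, 0.10)
  expect_lte(filt$N, comp$N)
})
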