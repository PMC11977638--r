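test_that("compendium simulation enforces size, VAF range and uniqueness", {
  comp <- simulate_compendium(5000, ffpe = FALSE, seed = 1)
  expect_s3_class(comp, "snv_compendium")
  expect_identical(comp$N, 5000L)
  expect_true(all(comp$sites$tumor_vaf > 0 & comp$sites$tumor_vaf < 1))
  expect_false(anyDuplicated(paste(comp$sites$chrom, comp$sites$pos)) > 0)
  expect_error(simulate_compendium(0), "empty compendium")

  comp2 <- simulate_compendium(5000, ffpe = FALSE, seed = 1)
  expect_identical(comp$sites, comp2$sites)
})

test_that("FFPE compendia are bimodal with recoverable component means", {
  comp <- simulate_compendium(10000, vaf_dist = c(0.4, 0.1), ffpe = TRUE,
                              artifact_fraction = 0.3,
                              artifact_vaf_dist = c(0.05, 0.01), seed = 2)
  expect_equal(mean(comp$sites$is_artifact), 0.3, tolerance = 0.01)
  vt <- fit_artifact_vaf_threshold(comp$sites$tumor_vaf, seed = 2)
  expect_equal(vt$components$mean[1], 0.05, tolerance = 0.05)
  expect_equal(vt$components$mean[2], 0.40, tolerance = 0.05)
})

test_that("evidence tables are binomial around tf + artifact and deterministic", {
  comp <- simulate_compendium(200, seed = 3)
  ev0 <- simulate_evidence(comp, true_tf = 0, artifact_rate = 0, seed = 4)
  expect_true(all(ev0$alt_count == 0))

  ev_a <- simulate_evidence(comp, 1e-3, depth_mean = 20, seed = 5)
  ev_b <- simulate_evidence(comp, 1e-3, depth_mean = 20, seed = 5)
  expect_identical(ev_a, ev_b)

  big <- simulate_compendium(20000, seed = 6)
  ev <- simulate_evidence(big, true_tf = 1e-3, depth_mean = 20,
                          artifact_rate = 0, seed = 7)
  rate <- sum(ev$alt_count) / sum(ev$depth)
  se <- sqrt(1e-3 * (1 - 1e-3) / sum(ev$depth))
  expect_lt(abs(rate - 1e-3), 3 * se)

  expect_error(simulate_evidence(comp, 0.8, artifact_rate = 0.3),
               "must lie in")
})

test_that("log-normal TF parameterization hits the configured median and IQR", {
  expect_error(lognorm_params(3.1e-4, c(4e-4, 1.3e-3)), "impossible")
  lp <- lognorm_params(3.1e-4, c(9.5e-5, 1.3e-3))
  q <- qlnorm(c(0.25, 0.5, 0.75), lp$meanlog, lp$sdlog)
  expect_equal(q[2], 3.1e-4, tolerance = 1e-12)
  # quartile ratio is matched exactly; individual quartiles to the extent a
  # two-parameter log-normal can
  expect_equal(q[3] / q[1], 1.3e-3 / 9.5e-5, tolerance = 1e-12)

  set.seed(1)
  draws <- rlnorm(500, lp$meanlog, lp$sdlog)
  expect_lt(abs(median(draws) - 3.1e-4) / 3.1e-4, 0.15)
})

test_that("simulated cohorts have the configured composition and truth labels", {
  cfg <- sim_config(n_patients_per_group = c(CRC = 93L, sAD = 22L, aAD = 20L),
                    n_controls = 40L, compendium_size_range = c(60L, 120L),
                    seed = 8L)
  cohort <- simulate_cohort(cfg)
  expect_length(cohort$patients, 135L)
  expect_length(cohort$controls, 40L)
  expect_identical(nrow(cohort$manifest), 175L)
  expect_identical(sum(cohort$manifest$role == "plasma"), 135L)

  tr <- cohort$truth
  expect_true(all(tr$true_tf[tr$is_control] == 0))
  expect_true(all(tr$true_tf[!tr$is_control] > 0))
  expect_identical(sum(tr$group == "sAD"), 22L)

  # every control table covers the union of all compendium sites
  n_union <- sum(vapply(cohort$patients, function(p) p$compendium$N, numeric(1)))
  expect_identical(nrow(cohort$controls[[1]]), as.integer(n_union))

  # rerun under the same config reproduces the cohort
  cohort2 <- simulate_cohort(cfg)
  expect_identical(cohort$truth, cohort2$truth)
  expect_identical(cohort$controls[[3]], cohort2$controls[[3]])
})

test_that("a cohort without controls is still written; noise modelling then fails", {
  cfg <- sim_config(n_patients_per_group = c(CRC = 2L, sAD = 0L, aAD = 0L),
                    n_controls = 0L, compendium_size_range = c(50L, 50L),
                    seed = 9L)
  cohort <- simulate_cohort(cfg)
  expect_null(cohort$controls)
  expect_length(cohort$patients, 2L)
  expect_error(build_noise_model(cohort$patients[[1]]$compendium, list()),
               "insufficient controls")
})

test_that("written cohorts round-trip through the file interface", {
  cfg <- sim_config(n_patients_per_group = c(CRC = 2L, sAD = 1L, aAD = 1L),
                    n_controls = 2L, compendium_size_range = c(60L, 80L),
                    seed = 10L)
  cohort <- simulate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  ev <- load_evidence(file.path(dir, "evidence", "C001.tsv"))
  expect_identical(nrow(ev), nrow(cohort$controls[[1]]))
  comp <- load_compendium_vcf(file.path(dir, "compendia", "P001.vcf"))
  expect_identical(comp$N, cohort$patients[[1]]$compendium$N)
  unlink(dir, recursive = TRUE)
})
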