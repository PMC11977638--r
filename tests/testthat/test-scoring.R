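test_that("noise models summarize control detection rates", {
  nm <- noise_model(c(1e-5, 3e-5))
  expect_equal(nm$mu, 2e-5)
  expect_equal(nm$sigma, sqrt(2) * 1e-5, tolerance = 1e-6)
  expect_identical(nm$n_controls, 2L)
  expect_false(nm$sigma_floored)

  expect_warning(nm0 <- noise_model(rep(1e-5, 5)), "floored")
  expect_true(nm0$sigma_floored)
  expect_equal(nm0$sigma, 1e-12)

  expect_error(noise_model(1e-5), "insufficient controls")
})

test_that("build_noise_model recovers the artifact rate from simulated controls", {
  comp <- simulate_compendium(20000, seed = 51)
  set.seed(52)
  ctrl <- lapply(1:40, function(i) {
    simulate_evidence(comp, 0, depth_mean = 20, artifact_rate = 1e-5)
  })
  nm <- build_noise_model(comp, ctrl)
  expect_identical(nm$n_controls, 40L)
  se <- sqrt(1e-5 / (20000 * 20)) / sqrt(40)
  expect_lt(abs(nm$mu - 1e-5), 3 * se)
})

test_that("the Z score is the standardized detection rate", {
  nm <- noise_model(c(1e-5, 3e-5))
  det <- structure(list(M = 1L, R = 1L, cov = 1, n_covered = 1L,
                        det_rate = nm$mu, mode = "reads", n_sites = 1L,
                        n_ignored = 0L, zero_coverage = FALSE),
                   class = "detection_result")
  expect_equal(z_score(det, nm)$value, 0)

  nm2 <- structure(list(compendium_id = "x", control_det_rates = NULL,
                        mu = 1e-5, sigma = 2e-6, n_controls = 40L,
                        sigma_floored = FALSE), class = "noise_model")
  det$det_rate <- 1.4e-5
  expect_equal(z_score(det, nm2)$value, 2.0)

  # strictly increasing in det_rate
  det_lo <- det; det_lo$det_rate <- 1.2e-5
  expect_lt(z_score(det_lo, nm2)$value, z_score(det, nm2)$value)
})

test_that("tumor fraction follows (M - mu R) / (N cov) with clipping", {
  comp <- tiny_compendium(1000, vaf = 0.4)
  det <- structure(list(M = 20L, R = 20000L, cov = 20, n_covered = 1000L,
                        det_rate = 20 / 20000, mode = "reads",
                        n_sites = 1000L, n_ignored = 0L,
                        zero_coverage = FALSE), class = "detection_result")
  nm0 <- structure(list(mu = 0, sigma = 1e-6, n_controls = 40L,
                        sigma_floored = FALSE), class = "noise_model")
  tfe <- estimate_tf(det, nm0, comp)
  expect_equal(tfe$tf, 1e-3)

  # M exactly at the expected noise level -> TF 0
  nm_eq <- structure(list(mu = det$M / det$R, sigma = 1e-6, n_controls = 40L,
                          sigma_floored = FALSE), class = "noise_model")
  expect_equal(estimate_tf(det, nm_eq, comp)$tf, 0)
  expect_equal(estimate_tf(det, nm_eq, comp)$tf_raw, 0)

  # below the noise level: clipped TF but signed raw value
  nm_hi <- structure(list(mu = 2 * det$M / det$R, sigma = 1e-6,
                          n_controls = 40L, sigma_floored = FALSE),
                     class = "noise_model")
  tfe_neg <- estimate_tf(det, nm_hi, comp)
  expect_equal(tfe_neg$tf, 0)
  expect_lt(tfe_neg$tf_raw, 0)

  det0 <- det; det0$R <- 0L
  expect_error(estimate_tf(det0, nm0, comp), "no coverage")
})

test_that("TF reduces to det_rate - mu when every site is covered", {
  comp <- simulate_compendium(500, seed = 53)
  ev <- simulate_evidence(comp, 1e-2, depth_mean = 30, seed = 54)
  ev$depth[ev$depth == 0L] <- 1L  # guarantee full coverage
  det <- compute_detection(comp, ev)
  nm <- noise_model(c(1e-5, 2e-5, 3e-5))
  expect_identical(det$n_covered, comp$N)
  expect_equal(estimate_tf(det, nm, comp)$tf_raw, det$det_rate - nm$mu,
               tolerance = 1e-12)
})
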