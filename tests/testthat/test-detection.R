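test_that("detection statistics follow the M, R, cov, det_rate definitions", {
  comp <- tiny_compendium(2)
  ev <- evidence_for(comp, depth = c(10, 30), alt_count = c(1, 2))
  det <- compute_detection(comp, ev, mode = "reads")
  expect_identical(det$M, 3L)
  expect_identical(det$R, 40L)
  expect_equal(det$cov, 20)
  expect_equal(det$det_rate, 0.075)
  expect_equal(det$cov * det$n_covered, det$R)

  det_sites <- compute_detection(comp, ev, mode = "sites")
  expect_identical(det_sites$M, 2L)
  expect_gte(det$M, det_sites$M)

  ev0 <- evidence_for(comp, depth = c(10, 30), alt_count = c(0, 0))
  det0 <- compute_detection(comp, ev0)
  expect_identical(det0$M, 0L)
  expect_equal(det0$det_rate, 0)
})

test_that("missing sites count as depth 0 and foreign rows are ignored", {
  comp <- tiny_compendium(3)
  # only the first two sites present, plus one row outside the compendium
  ev <- data.table::data.table(chrom = c("chr1", "chr1", "chr9"),
                               pos = c(100L, 200L, 5L),
                               ref = "A", alt = "T",
                               depth = c(10L, 10L, 50L),
                               alt_count = c(1L, 0L, 50L))
  det <- compute_detection(comp, ev)
  expect_identical(det$R, 20L)
  expect_identical(det$n_covered, 2L)
  expect_identical(det$M, 1L)
  expect_identical(det$n_ignored, 1L)
  expect_equal(det$cov, 10)

  # no coverage at all: det_rate 0 and flagged
  none <- data.table::data.table(chrom = "chr9", pos = 1L, ref = "A",
                                 alt = "T", depth = 10L, alt_count = 0L)
  det_none <- compute_detection(comp, none)
  expect_true(det_none$zero_coverage)
  expect_equal(det_none$det_rate, 0)
})

test_that("det_rate is invariant to evidence row order", {
  comp <- simulate_compendium(500, seed = 41)
  ev <- simulate_evidence(comp, 1e-2, depth_mean = 20, seed = 42)
  shuffled <- ev[sample(nrow(ev)), ]
  expect_equal(compute_detection(comp, shuffled)$det_rate,
               compute_detection(comp, ev)$det_rate)
})

test_that("read- and site-mode M coincide iff no site has two variant reads", {
  comp <- simulate_compendium(2000, seed = 43)
  ev <- simulate_evidence(comp, 5e-3, depth_mean = 20, seed = 44)
  m_reads <- compute_detection(comp, ev, "reads")$M
  m_sites <- compute_detection(comp, ev, "sites")$M
  expect_gte(m_reads, m_sites)
  expect_identical(m_reads == m_sites, all(ev$alt_count <= 1L))
})

test_that("mean det_rate matches the binomial oracle across seeds", {
  comp <- simulate_compendium(20000, seed = 45)
  p <- 1e-4
  rates <- vapply(1:50, function(s) {
    ev <- simulate_evidence(comp, true_tf = p, depth_mean = 20,
                            artifact_rate = 0, seed = 1000 + s)
    compute_detection(comp, ev)$det_rate
  }, numeric(1))
  se <- sqrt(p / (20000 * 20)) / sqrt(50)
  expect_lt(abs(mean(rates) - p), 3 * se)
})

test_that("evidence loading validates schema and counts", {
  path <- write_lines_tsv(c("chrom\tpos\tref\talt\tdepth\talt_count",
                            "chr1\t100\tA\tT\t10\t1",
                            "chr1\t200\tC\tG\t20\t0",
                            "chr2\t300\tG\tA\t5\t5"))
  ev <- load_evidence(path)
  expect_identical(nrow(ev), 3L)

  bad <- write_lines_tsv(c("chrom\tpos\tref\talt\tdepth\talt_count",
                           "chr1\t100\tA\tT\t10\t1",
                           "chr1\t200\tC\tG\t3\t5"))
  expect_error(load_evidence(bad), "line 3")

  empty <- write_lines_tsv("chrom\tpos\tref\talt\tdepth\talt_count")
  expect_identical(nrow(load_evidence(empty)), 0L)

  expect_error(load_evidence(write_lines_tsv("chrom\tpos\tref")), "columns")
})
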