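#' Log-normal parameters from a median and interquartile range
#'
#' A log-normal distribution is parameterized so that its median equals
#' `median` and the ratio of its quartiles equals `iqr[2] / iqr[1]`. The
#' log-scale spread is solved from the quartile ratio through the normal
#' quantile: `sdlog = log(iqr[2] / iqr[1]) / (2 * qnorm(0.75))`. This is the
#' natural parameterization when a study reports only medians and IQRs of a
#' heavily right-skewed quantity such as plasma tumor fraction.
#'
#' @param median Distribution median (> 0).
#' @param iqr Length-2 numeric, the lower and upper quartile. Must straddle
#'   the median.
#' @return A list with `meanlog` and `sdlog`.
#' @export
lognorm_params <- function(median, iqr) {
  stopifnot(is.numeric(median), length(median) == 1L, median > 0,
            is.numeric(iqr), length(iqr) == 2L, all(iqr > 0))
  if (!(iqr[1] < median && median < iqr[2])) {
    stop("impossible (median, IQR) combination: quartiles [", iqr[1], ", ",
         iqr[2], "] must straddle the median ", median)
  }
  list(meanlog = log(median),
       sdlog = log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75)))
}

#' Simulation configuration for a synthetic ctDNA cohort
#'
#' Defaults encode the study design this package targets: 93 colorectal
#' cancer (CRC) patients, 22 symptomatic (sAD) and 20 asymptomatic (aAD)
#' adenoma patients, 40 healthy controls; ~20x plasma coverage; per-group
#' plasma tumor-fraction distributions log-normal around the reported group
#' medians; per-compendium artifact rates log-normal around 1e-5 errors per
#' read.
#'
#' @param n_patients_per_group Named integer vector of patients per clinical
#'   group. Names are the group labels; `CRC` is the threshold-training
#'   (cohort 1) group, every other group forms cohort 2.
#' @param n_controls Number of healthy-control plasma samples.
#' @param compendium_size_range Length-2 integer range; each patient's
#'   mutation load N is drawn uniformly from it.
#' @param plasma_depth_mean Mean plasma sequencing depth per site (Poisson).
#' @param tumor_depth_mean Nominal tumor sequencing depth (recorded as cohort
#'   metadata; compendium VAFs are drawn directly from the configured
#'   distributions).
#' @param tf_lognormal_params Per-group list of `list(median, iqr)` for the
#'   plasma tumor-fraction distribution.
#' @param artifact_rate_lognormal `list(median, sdlog)` for the per-compendium
#'   artifactual detection probability per read.
#' @param ffpe_fraction Fraction of patients whose tumor tissue is FFPE; their
#'   compendia receive an injected low-VAF artifact component.
#' @param ffpe_artifact_fraction Fraction of sites in an FFPE compendium drawn
#'   from the artifact VAF component.
#' @param vaf_dist Mean and SD of the (truncated normal) tumor VAF
#'   distribution of genuine somatic sites.
#' @param artifact_vaf_dist Mean and SD of the artifact VAF component.
#' @param seed Integer seed for cohort generation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients_per_group = c(CRC = 93L, sAD = 22L, aAD = 20L),
                       n_controls = 40L,
                       compendium_size_range = c(1000L, 10000L),
                       plasma_depth_mean = 20,
                       tumor_depth_mean = 30,
                       tf_lognormal_params = list(
                         CRC = list(median = 3.1e-4, iqr = c(9.5e-5, 1.3e-3)),
                         sAD = list(median = 5.9e-5, iqr = c(4.0e-5, 6.3e-5)),
                         aAD = list(median = 7.8e-6, iqr = c(7.6e-6, 8.4e-6))),
                       artifact_rate_lognormal = list(median = 1e-5, sdlog = 0.25),
                       ffpe_fraction = 0.15,
                       ffpe_artifact_fraction = 0.3,
                       vaf_dist = c(0.4, 0.1),
                       artifact_vaf_dist = c(0.05, 0.01),
                       seed = 1L) {
  stopifnot(length(n_patients_per_group) >= 1L,
            !is.null(names(n_patients_per_group)),
            all(n_patients_per_group >= 0),
            n_controls >= 0,
            length(compendium_size_range) == 2L,
            all(compendium_size_range >= 1),
            compendium_size_range[1] <= compendium_size_range[2],
            plasma_depth_mean >= 1, tumor_depth_mean >= 1,
            ffpe_fraction >= 0, ffpe_fraction <= 1,
            ffpe_artifact_fraction >= 0, ffpe_artifact_fraction < 1)
  groups <- names(n_patients_per_group)
  if (!all(groups %in% names(tf_lognormal_params))) {
    stop("tf_lognormal_params must cover every group in n_patients_per_group")
  }
  for (g in groups) {
    p <- tf_lognormal_params[[g]]
    stopifnot(p$median >= 0, p$median < 1)
    lognorm_params(p$median, p$iqr)  # validates the (median, IQR) combination
  }
  stopifnot(artifact_rate_lognormal$median >= 0,
            artifact_rate_lognormal$median < 1)
  structure(list(n_patients_per_group = n_patients_per_group,
                 n_controls = as.integer(n_controls),
                 compendium_size_range = as.integer(compendium_size_range),
                 plasma_depth_mean = plasma_depth_mean,
                 tumor_depth_mean = tumor_depth_mean,
                 tf_lognormal_params = tf_lognormal_params,
                 artifact_rate_lognormal = artifact_rate_lognormal,
                 ffpe_fraction = ffpe_fraction,
                 ffpe_artifact_fraction = ffpe_artifact_fraction,
                 vaf_dist = vaf_dist,
                 artifact_vaf_dist = artifact_vaf_dist,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# truncated-normal draws on (lo, hi) by rejection
.rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  eps <- 1e-9
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo + eps | x >= hi - eps)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lo + eps | x[bad] >= hi - eps]
  }
  x
}

.BASES <- c("A", "C", "G", "T")

# unique random genomic sites; the site space is large enough that collisions
# are rare and resolved by redraw
.random_sites <- function(n) {
  chrom <- paste0("chr", sample.int(22L, n, replace = TRUE))
  pos <- sample.int(2.4e8, n, replace = TRUE)
  key <- paste(chrom, pos)
  dup <- which(duplicated(key))
  while (length(dup) > 0L) {
    chrom[dup] <- paste0("chr", sample.int(22L, length(dup), replace = TRUE))
    pos[dup] <- sample.int(2.4e8, length(dup), replace = TRUE)
    key <- paste(chrom, pos)
    dup <- which(duplicated(key))
  }
  ref_i <- sample.int(4L, n, replace = TRUE)
  alt_i <- ((ref_i - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
  list(chrom = chrom, pos = pos, ref = .BASES[ref_i], alt = .BASES[alt_i])
}

#' Simulate a patient-specific somatic SNV compendium
#'
#' Draws `n_snvs` distinct genomic sites with tumor VAFs from a truncated
#' normal distribution. In FFPE mode a configurable fraction of sites is drawn
#' instead from a low-VAF artifact component, mimicking the erroneous SNV
#' calls that formalin fixation introduces into tumor-derived compendia; those
#' sites are flagged in the `is_artifact` column (ground truth, not available
#' to downstream filtering).
#'
#' @param n_snvs Number of SNV sites (mutation load N), >= 1.
#' @param vaf_dist `c(mean, sd)` of the genuine somatic VAF component.
#' @param ffpe Logical; inject an artifact VAF component?
#' @param artifact_fraction Fraction of sites drawn from the artifact
#'   component when `ffpe = TRUE`.
#' @param artifact_vaf_dist `c(mean, sd)` of the artifact component.
#' @param patient_id Patient identifier.
#' @param tissue Tissue type, `"FF"` or `"FFPE"`; defaults to match `ffpe`.
#' @param seed Optional integer seed (omit to use the current RNG stream).
#' @return An `snv_compendium`: list with `patient_id`, `tissue`, `sites`
#'   (data.table: chrom, pos, ref, alt, tumor_vaf, is_artifact) and `N`.
#' @export
simulate_compendium <- function(n_snvs, vaf_dist = c(0.4, 0.1), ffpe = FALSE,
                                artifact_fraction = 0.3,
                                artifact_vaf_dist = c(0.05, 0.01),
                                patient_id = "P001",
                                tissue = if (ffpe) "FFPE" else "FF",
                                seed = NULL) {
  if (!is.numeric(n_snvs) || length(n_snvs) != 1L || n_snvs < 1) {
    stop("empty compendium: n_snvs must be >= 1")
  }
  stopifnot(vaf_dist[1] > 0, vaf_dist[1] < 1)
  if (!is.null(seed)) set.seed(seed)
  n_snvs <- as.integer(n_snvs)
  s <- .random_sites(n_snvs)
  n_art <- if (ffpe) round(artifact_fraction * n_snvs) else 0L
  is_artifact <- rep(FALSE, n_snvs)
  if (n_art > 0L) is_artifact[sample.int(n_snvs, n_art)] <- TRUE
  vaf <- numeric(n_snvs)
  vaf[!is_artifact] <- .rtruncnorm(n_snvs - n_art, vaf_dist[1], vaf_dist[2])
  if (n_art > 0L) {
    vaf[is_artifact] <- .rtruncnorm(n_art, artifact_vaf_dist[1],
                                    artifact_vaf_dist[2])
  }
  sites <- data.table::data.table(chrom = s$chrom, pos = s$pos, ref = s$ref,
                                  alt = s$alt, tumor_vaf = vaf,
                                  is_artifact = is_artifact)
  data.table::setorder(sites, chrom, pos)
  new_compendium(patient_id, sites, tissue)
}

#' Simulate a site-level plasma evidence table
#'
#' Count-level stand-in for scanning plasma WGS at compendium sites: per site
#' the depth is Poisson around the target coverage and the variant-supporting
#' read count is binomial with success probability `true_tf + artifact_rate`
#' (tumor-derived and artifactual variant reads merged into one rate, a
#' second-order approximation that is exact in expectation at TF << 1).
#'
#' @param compendium An `snv_compendium`.
#' @param true_tf Expected variant-allele fraction of tumor-derived molecules
#'   at compendium sites; scalar or per-site vector (0 for controls).
#' @param depth_mean Mean sequencing depth per site.
#' @param artifact_rate Artifactual variant-read probability per read.
#' @param seed Optional integer seed.
#' @return A data.table with columns chrom, pos, ref, alt, depth, alt_count,
#'   one row per compendium site (rows with depth 0 are kept).
#' @export
simulate_evidence <- function(compendium, true_tf, depth_mean = 20,
                              artifact_rate = 0, seed = NULL) {
  if (!inherits(compendium, "snv_compendium")) {
    stop("compendium must be an snv_compendium")
  }
  p <- true_tf + artifact_rate
  if (any(p >= 1) || any(true_tf < 0) || any(artifact_rate < 0)) {
    stop("true_tf + artifact_rate must lie in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- compendium$N
  depth <- stats::rpois(n, depth_mean)
  ev <- list(chrom = compendium$sites$chrom,
             pos = compendium$sites$pos,
             ref = compendium$sites$ref,
             alt = compendium$sites$alt,
             depth = depth,
             alt_count = stats::rbinom(n, depth, rep_len(p, n)))
  data.table::setDT(ev)
  ev[]
}

#' Simulate a full two-cohort study
#'
#' Generates, per patient: a mutation load N uniform over
#' `compendium_size_range`, a plasma tumor fraction from the group's
#' log-normal, a per-compendium artifact rate, an (optionally FFPE) compendium
#' and a plasma evidence table. Plasma evidence at injected FFPE artifact
#' sites carries no tumor signal (those sites are not real somatic variants).
#' Controls are pure-noise plasma: each control evidence table covers the
#' union of all compendium sites, with per-site artifact rates inherited from
#' the compendium a site belongs to, so one control can be scored under every
#' patient's compendium.
#'
#' @param config A `sim_config`.
#' @param materialize_controls Logical; build the (large) per-control
#'   union-of-sites evidence tables. Set `FALSE` to skip them when controls
#'   will be regenerated lazily (as `run_pipeline()` does).
#' @return A `ctdna_cohort`: list with `patients` (each holding compendium,
#'   plasma evidence and truth values), `controls` (list of evidence tables or
#'   NULL), `manifest` and `truth` data.tables, and the config.
#' @export
simulate_cohort <- function(config = sim_config(), materialize_controls = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rng <- config$compendium_size_range
  art <- config$artifact_rate_lognormal
  patients <- list()
  idx <- 0L
  for (g in names(config$n_patients_per_group)) {
    ng <- config$n_patients_per_group[[g]]
    if (ng == 0L) next
    lp <- lognorm_params(config$tf_lognormal_params[[g]]$median,
                         config$tf_lognormal_params[[g]]$iqr)
    for (k in seq_len(ng)) {
      idx <- idx + 1L
      pid <- sprintf("P%03d", idx)
      n_snvs <- if (rng[1] == rng[2]) rng[1] else
        sample(seq(rng[1], rng[2]), 1L)
      ffpe <- stats::runif(1) < config$ffpe_fraction
      tf <- stats::rlnorm(1, lp$meanlog, lp$sdlog)
      a <- stats::rlnorm(1, log(art$median), art$sdlog)
      comp <- simulate_compendium(n_snvs, vaf_dist = config$vaf_dist,
                                  ffpe = ffpe,
                                  artifact_fraction = config$ffpe_artifact_fraction,
                                  artifact_vaf_dist = config$artifact_vaf_dist,
                                  patient_id = pid)
      tf_site <- ifelse(comp$sites$is_artifact, 0, tf)
      plasma <- simulate_evidence(comp, tf_site, config$plasma_depth_mean, a)
      patients[[pid]] <- list(patient_id = pid, group = g,
                              tissue = comp$tissue, true_tf = tf,
                              artifact_rate = a, compendium = comp,
                              plasma = plasma)
    }
  }
  controls <- NULL
  if (materialize_controls && config$n_controls > 0L) {
    controls <- lapply(seq_len(config$n_controls), function(i) {
      data.table::rbindlist(lapply(patients, function(p) {
        simulate_evidence(p$compendium, 0, config$plasma_depth_mean,
                          p$artifact_rate)
      }))
    })
    names(controls) <- sprintf("C%03d", seq_len(config$n_controls))
  }
  manifest <- data.table::rbindlist(c(
    lapply(patients, function(p) data.table::data.table(
      sample_id = paste0(p$patient_id, "_plasma"), patient_id = p$patient_id,
      group = p$group, role = "plasma", tissue = p$tissue)),
    lapply(seq_len(config$n_controls), function(i) data.table::data.table(
      sample_id = sprintf("C%03d", i), patient_id = NA_character_,
      group = "control", role = "control", tissue = NA_character_))))
  truth <- data.table::rbindlist(c(
    lapply(patients, function(p) data.table::data.table(
      sample_id = paste0(p$patient_id, "_plasma"), patient_id = p$patient_id,
      group = p$group, true_tf = p$true_tf,
      true_artifact_rate = p$artifact_rate, is_control = FALSE)),
    lapply(seq_len(config$n_controls), function(i) data.table::data.table(
      sample_id = sprintf("C%03d", i), patient_id = NA_character_,
      group = "control", true_tf = 0,
      true_artifact_rate = NA_real_, is_control = TRUE))))
  structure(list(config = config, patients = patients, controls = controls,
                 manifest = manifest, truth = truth),
            class = "ctdna_cohort")
}

#' Write a simulated cohort to disk
#'
#' Persists one VCF per patient compendium (INFO tag `VAF`), one evidence TSV
#' per plasma/control sample, plus `manifest.tsv` and `truth.tsv`.
#'
#' @param cohort A `ctdna_cohort` (controls must be materialized).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ctdna_cohort"))
  dir.create(file.path(dir, "compendia"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "evidence"), recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) {
    write_compendium_vcf(p$compendium,
                         file.path(dir, "compendia", paste0(p$patient_id, ".vcf")))
    data.table::fwrite(p$plasma,
                       file.path(dir, "evidence", paste0(p$patient_id, "_plasma.tsv")),
                       sep = "\t")
  }
  for (cid in names(cohort$controls)) {
    data.table::fwrite(cohort$controls[[cid]],
                       file.path(dir, "evidence", paste0(cid, ".tsv")), sep = "\t")
  }
  data.table::fwrite(cohort$manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  data.table::fwrite(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}

#' Simulate germline genotypes at a SNP panel
#'
#' Draws biallelic genotypes under Hardy-Weinberg equilibrium at the given
#' alternate-allele frequency; genotype is coded as the expected B-allele
#' fraction (0, 0.5, 1).
#'
#' @param n_sites Panel size (the concordance design targets ~1200 sites).
#' @param alt_freq Population alternate-allele frequency.
#' @param seed Optional integer seed.
#' @return data.table with `site_id` and `genotype`.
#' @export
simulate_snp_genotypes <- function(n_sites = 1200, alt_freq = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- alt_freq
  g <- sample(c(0, 0.5, 1), n_sites, replace = TRUE,
              prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  data.table::data.table(site_id = sprintf("snp%04d", seq_len(n_sites)),
                         genotype = g)
}

#' Simulate read counts over a SNP panel
#'
#' Per site, depth is Poisson and the B-allele count binomial around the
#' genotype's allele fraction, with a small per-read error pulling homozygous
#' fractions off 0/1.
#'
#' @param genotypes Output of [simulate_snp_genotypes()] (or any data.table
#'   with `site_id`, `genotype`).
#' @param depth_mean Mean depth per site.
#' @param error_rate Per-read substitution error rate.
#' @param seed Optional integer seed.
#' @return data.table with `site_id`, `depth`, `b_allele_count`.
#' @export
simulate_snp_reads <- function(genotypes, depth_mean = 30, error_rate = 0.005,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  depth <- stats::rpois(n, depth_mean)
  p <- genotypes$genotype * (1 - 2 * error_rate) + error_rate
  data.table::data.table(site_id = genotypes$site_id, depth = depth,
                         b_allele_count = stats::rbinom(n, depth, p))
}
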