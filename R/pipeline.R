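#' Default end-to-end run configuration
#'
#' Every analysis constant sits here with its study default: the 95%
#' specificity constraint, the read-level detection mode, the 10% GMM
#' false-positive target for the FFPE VAF filter, and the 0.8 / 0.7 SNP
#' coherence thresholds, alongside the synthetic-cohort configuration.
#'
#' @param sim A [sim_config()].
#' @param min_specificity Specificity constraint for threshold selection.
#' @param detection_mode `"reads"` or `"sites"` (see [compute_detection()]).
#' @param gmm_target_fp_rate Posterior artifact probability targeted by the
#'   FFPE VAF threshold.
#' @param concordance_within,concordance_cross SNP coherence thresholds.
#' @param simulate_orthogonal Attach a simulated deep-targeted assay to the
#'   threshold-training group for assay comparison?
#' @param seed Integer master seed for the run.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(sim = sim_config(),
                               min_specificity = 0.95,
                               detection_mode = "reads",
                               gmm_target_fp_rate = 0.10,
                               concordance_within = 0.8,
                               concordance_cross = 0.7,
                               simulate_orthogonal = TRUE,
                               seed = 1L) {
  stopifnot(inherits(sim, "sim_config"),
            min_specificity > 0, min_specificity <= 1,
            detection_mode %in% c("reads", "sites"),
            gmm_target_fp_rate > 0, gmm_target_fp_rate < 1)
  structure(list(sim = sim, min_specificity = min_specificity,
                 detection_mode = detection_mode,
                 gmm_target_fp_rate = gmm_target_fp_rate,
                 concordance_within = concordance_within,
                 concordance_cross = concordance_cross,
                 simulate_orthogonal = simulate_orthogonal,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Nested keys mirror the arguments of [default_run_config()] and
#' [sim_config()]; absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configurations")
  }
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$n_patients_per_group)) {
    sim_args$n_patients_per_group <- unlist(sim_args$n_patients_per_group)
  }
  if (!is.null(sim_args$compendium_size_range)) {
    sim_args$compendium_size_range <- unlist(sim_args$compendium_size_range)
  }
  sim <- do.call(sim_config, sim_args)
  top <- y[setdiff(names(y), "sim")]
  do.call(default_run_config, c(list(sim = sim), top))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simulate patients of the requested groups under the current RNG stream
.sim_patients <- function(sim, groups, id_offset = 0L) {
  rng <- sim$compendium_size_range
  art <- sim$artifact_rate_lognormal
  patients <- list()
  idx <- id_offset
  for (g in groups) {
    ng <- sim$n_patients_per_group[[g]]
    if (ng == 0L) next
    lp <- lognorm_params(sim$tf_lognormal_params[[g]]$median,
                         sim$tf_lognormal_params[[g]]$iqr)
    for (k in seq_len(ng)) {
      idx <- idx + 1L
      pid <- sprintf("P%03d", idx)
      n_snvs <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
      ffpe <- stats::runif(1) < sim$ffpe_fraction
      patients[[pid]] <- list(
        patient_id = pid, group = g,
        true_tf = stats::rlnorm(1, lp$meanlog, lp$sdlog),
        artifact_rate = stats::rlnorm(1, log(art$median), art$sdlog),
        compendium = simulate_compendium(
          n_snvs, vaf_dist = sim$vaf_dist, ffpe = ffpe,
          artifact_fraction = sim$ffpe_artifact_fraction,
          artifact_vaf_dist = sim$artifact_vaf_dist, patient_id = pid))
    }
  }
  patients
}

# FFPE-filter, noise-model and score one patient; controls are generated
# lazily per (compendium, control) pair — site sets are patient-specific and
# disjoint, so per-pair generation is distributionally identical to slicing
# one genome-wide control sample
.score_patient <- function(p, config, stage_wrap) {
  sim <- config$sim
  comp <- p$compendium
  if (comp$tissue == "FFPE") {
    comp <- stage_wrap("ffpe_filter", p$patient_id, {
      vt <- fit_artifact_vaf_threshold(comp$sites$tumor_vaf,
                                       target_fp_rate = config$gmm_target_fp_rate,
                                       seed = NULL)
      apply_ffpe_filter(comp, vt)
    })
  }
  ctrl_ev <- lapply(seq_len(sim$n_controls), function(i) {
    simulate_evidence(comp, 0, sim$plasma_depth_mean, p$artifact_rate)
  })
  nm <- stage_wrap("noise_model", p$patient_id,
                   build_noise_model(comp, ctrl_ev, mode = config$detection_mode))
  tf_site <- ifelse(p$compendium$sites$is_artifact %in% TRUE, 0, p$true_tf)
  plasma <- simulate_evidence(p$compendium, tf_site, sim$plasma_depth_mean,
                              p$artifact_rate)
  det <- compute_detection(comp, plasma, mode = config$detection_mode)
  z <- stage_wrap("score", p$patient_id, z_score(det, nm))
  tfe <- stage_wrap("score", p$patient_id, estimate_tf(det, nm, comp))
  neg_z <- (nm$control_det_rates - nm$mu) / nm$sigma
  list(patient_id = p$patient_id, group = p$group, z = z$value,
       tf = tfe$tf, tf_raw = tfe$tf_raw, det_rate = det$det_rate,
       N = comp$N, negative_z = neg_z)
}

#' Run the full two-cohort analysis
#'
#' Chains simulation, FFPE filtering, noise modelling, scoring, threshold
#' selection and classification. The threshold-training group (`CRC`)
#' together with the controls forms cohort 1: each training compendium scores
#' its own plasma (one positive label) and every control (one negative label
#' per compendium-control pair). The Z threshold chosen at the specificity
#' constraint on those labels is then applied to every sample, including the
#' remaining groups (cohort 2). All randomness flows from `config$seed`
#' through one sequential RNG stream, so a rerun with the same config is
#' identical.
#'
#' @param config A `run_config` from [default_run_config()].
#' @param out_dir Optional directory; when given, labels, decision, ROC
#'   points, per-sample results, group summary and a run manifest are written
#'   there.
#' @return A list with `labels` (data.table of labeled Z scores), `roc`,
#'   `decision`, `results` (per-sample data.table), `summary`, `agreement`
#'   (orthogonal-assay block or NULL), `truth` and the config.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  stage_wrap <- function(stage, sample_id, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline failed at stage '%s' for sample '%s': %s",
                   stage, sample_id, conditionMessage(e)), call. = FALSE)
    })
  }
  set.seed(config$seed)
  groups <- names(sim$n_patients_per_group)
  train_group <- if ("CRC" %in% groups) "CRC" else groups[1]
  patients <- .sim_patients(sim, c(train_group, setdiff(groups, train_group)))

  scored <- lapply(patients, .score_patient, config = config,
                   stage_wrap = stage_wrap)
  names(scored) <- names(patients)

  train <- scored[vapply(scored, function(s) s$group == train_group, logical(1))]
  labels <- data.table::rbindlist(lapply(train, function(s) {
    data.table::data.table(
      score = c(s$z, s$negative_z),
      label = c("positive", rep("negative", length(s$negative_z))),
      patient_id = s$patient_id,
      control_id = c(NA_character_, sprintf("C%03d", seq_along(s$negative_z))))
  }))
  neg <- labels$score[labels$label == "negative"]
  pos <- labels$score[labels$label == "positive"]
  roc <- stage_wrap("roc", train_group, compute_auc(labels$score, labels$label))
  decision <- stage_wrap("threshold", train_group,
                         choose_threshold(neg, config$min_specificity, pos))

  results <- data.table::rbindlist(lapply(scored, function(s) {
    data.table::data.table(sample_id = paste0(s$patient_id, "_plasma"),
                           patient_id = s$patient_id, group = s$group,
                           z = s$z, tf = s$tf, tf_raw = s$tf_raw,
                           det_rate = s$det_rate, N = s$N)
  }))
  results$call <- classify_samples(results$z, decision)

  agreement <- NULL
  if (isTRUE(config$simulate_orthogonal)) {
    tr <- results$group == train_group
    ortho <- simulate_orthogonal_assay(
      vapply(patients[results$patient_id[tr]], function(p) p$true_tf, numeric(1)))
    results$orthogonal_call <- NA_character_
    results$orthogonal_vaf <- NA_real_
    results$orthogonal_call[tr] <- ortho$orthogonal_call
    results$orthogonal_vaf[tr] <- ortho$orthogonal_vaf
    agreement <- stage_wrap("assay_comparison", train_group,
                            compare_assays(results[tr, ]))
  }

  summary <- summarize_cohort(results)
  truth <- data.table::rbindlist(lapply(patients, function(p) {
    data.table::data.table(sample_id = paste0(p$patient_id, "_plasma"),
                           patient_id = p$patient_id, group = p$group,
                           true_tf = p$true_tf,
                           true_artifact_rate = p$artifact_rate,
                           tissue = p$compendium$tissue)
  }))

  out <- list(labels = labels, roc = roc, decision = decision,
              results = results, summary = summary, agreement = agreement,
              truth = truth, config = config)
  if (!is.null(out_dir)) .write_run(out, out_dir)
  out
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(run$labels, file.path(out_dir, "labels.tsv"), sep = "\t")
  data.table::fwrite(run$results, file.path(out_dir, "results.tsv"), sep = "\t")
  data.table::fwrite(run$roc$points, file.path(out_dir, "roc_points.tsv"),
                     sep = "\t")
  data.table::fwrite(run$summary$group_summary,
                     file.path(out_dir, "group_summary.tsv"), sep = "\t")
  jsonlite::write_json(
    list(z_threshold = run$decision$z_threshold,
         min_specificity = run$decision$min_specificity,
         achieved_specificity = run$decision$achieved_specificity,
         achieved_sensitivity = run$decision$achieved_sensitivity,
         auc = run$roc$auc),
    file.path(out_dir, "decision.json"), auto_unbox = TRUE, digits = NA)
  cfg_hash <- if (requireNamespace("rlang", quietly = TRUE))
    rlang::hash(run$config) else NA_character_
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("cfMRD")),
         seed = run$config$seed, config_hash = cfg_hash,
         n_labels = nrow(run$labels)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
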