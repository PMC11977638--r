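#' Construct a noise model from control detection rates
#'
#' The per-compendium noise model is the empirical distribution of the
#' artifactual detection rate obtained by scoring healthy-control plasma
#' under the patient's compendium: mu is its mean, sigma its sample standard
#' deviation (n - 1 denominator). A degenerate sigma of 0 is floored at
#' 1e-12 and flagged so downstream Z scores remain finite but marked.
#'
#' @param control_det_rates Numeric vector of per-control detection rates
#'   (>= 2 values).
#' @param compendium_id Identifier of the compendium the model belongs to.
#' @return A `noise_model`: list with control_det_rates, mu, sigma,
#'   n_controls and a `sigma_floored` flag.
#' @export
noise_model <- function(control_det_rates, compendium_id = NA_character_) {
  if (length(control_det_rates) < 2L) {
    stop("insufficient controls: need >= 2, got ", length(control_det_rates))
  }
  stopifnot(all(is.finite(control_det_rates)))
  mu <- mean(control_det_rates)
  sigma <- stats::sd(control_det_rates)
  floored <- sigma == 0
  if (floored) {
    warning("control detection rates are identical; sigma floored at 1e-12")
    sigma <- 1e-12
  }
  structure(list(compendium_id = compendium_id,
                 control_det_rates = control_det_rates,
                 mu = mu, sigma = sigma,
                 n_controls = length(control_det_rates),
                 sigma_floored = floored),
            class = "noise_model")
}

#' Build the noise model for a compendium from control evidence
#'
#' Runs [compute_detection()] for each control evidence table under the
#' compendium and summarizes the resulting detection rates into a
#' [noise_model()].
#'
#' @param compendium An `snv_compendium`.
#' @param control_evidence List of >= 2 control evidence tables.
#' @param mode Detection mode passed to [compute_detection()].
#' @return A `noise_model`.
#' @export
build_noise_model <- function(compendium, control_evidence,
                              mode = c("reads", "sites")) {
  mode <- match.arg(mode)
  if (length(control_evidence) < 2L) {
    stop("insufficient controls: need >= 2, got ", length(control_evidence))
  }
  rates <- vapply(control_evidence, function(ev) {
    compute_detection(compendium, ev, mode = mode)$det_rate
  }, numeric(1))
  noise_model(rates, compendium_id = compendium$patient_id)
}

#' @method print noise_model
#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> compendium %s: mu = %.3g, sigma = %.3g (%d controls%s)\n",
              x$compendium_id, x$mu, x$sigma, x$n_controls,
              if (x$sigma_floored) ", sigma floored" else ""))
  invisible(x)
}

#' Z score of a plasma detection rate against the noise model
#'
#' Z = (det_rate - mu) / sigma, unclipped. A sample is eventually called
#' ctDNA-positive when its Z exceeds the specificity-constrained threshold.
#'
#' @param detection A `detection_result`.
#' @param noise A `noise_model`.
#' @return A `z_score`: list with value, det_rate, mu, sigma and the
#'   propagated `sigma_floored` flag.
#' @export
z_score <- function(detection, noise) {
  stopifnot(inherits(detection, "detection_result"),
            inherits(noise, "noise_model"))
  structure(list(value = (detection$det_rate - noise$mu) / noise$sigma,
                 det_rate = detection$det_rate, mu = noise$mu,
                 sigma = noise$sigma, sigma_floored = noise$sigma_floored),
            class = "z_score")
}

#' @method print z_score
#' @export
print.z_score <- function(x, ...) {
  cat(sprintf("<z_score> %.3f (det_rate = %.3g, mu = %.3g, sigma = %.3g)\n",
              x$value, x$det_rate, x$mu, x$sigma))
  invisible(x)
}

#' Estimate the plasma tumor fraction
#'
#' TF is the expected variant-allele fraction of tumor-derived molecules at
#' compendium sites: the observed variant evidence M, corrected for the
#' expected artifactual evidence mu * R, normalized by the number of
#' informative trials N * cov,
#' \deqn{TF_{raw} = (M - \mu R) / (N \, cov), \qquad TF = \max(0, TF_{raw}).}
#' When every compendium site is covered, N * cov = R and TF_raw reduces to
#' det_rate - mu. The signed raw value is reported alongside the clipped TF
#' because cohort-level calibration checks need the negative excursions.
#'
#' @param detection A `detection_result` with R > 0.
#' @param noise A `noise_model` supplying mu.
#' @param compendium The `snv_compendium` supplying N.
#' @return A `tf_estimate`: list with tf, tf_raw and components (M, R, N,
#'   cov, mu).
#' @export
estimate_tf <- function(detection, noise, compendium) {
  stopifnot(inherits(detection, "detection_result"),
            inherits(noise, "noise_model"),
            inherits(compendium, "snv_compendium"))
  if (detection$R == 0) stop("no coverage over compendium: R = 0")
  tf_raw <- (detection$M - noise$mu * detection$R) /
    (compendium$N * detection$cov)
  structure(list(tf = max(0, tf_raw), tf_raw = tf_raw,
                 M = detection$M, R = detection$R, N = compendium$N,
                 cov = detection$cov, mu = noise$mu),
            class = "tf_estimate")
}

#' @method print tf_estimate
#' @export
print.tf_estimate <- function(x, ...) {
  cat(sprintf("<tf_estimate> TF = %.3g (raw %.3g; M = %d, R = %d, N = %d, cov = %.2f)\n",
              x$tf, x$tf_raw, x$M, x$R, x$N, x$cov))
  invisible(x)
}
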