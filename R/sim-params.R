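#' Simulation parameters for the synthetic-subject generator
#'
#' Bundles the population-level calibration of the synthetic behavioral
#' dataset. Defaults reproduce the dispersion statistics of the study
#' protocol: per-subject localization noise SDs of 7.5 deg (acoustic
#' unisensory), 2.8 deg (visual unisensory), 5.8 deg (acoustic bisensory) and
#' 3.1 deg (visual bisensory); a fusion weight calibrated so that the pooled
#' SD of acoustic non-coincident responses is 9.5 deg (visual capture); and
#' log-normal decision times ordered acoustic > visual and unisensory >
#' bisensory.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param n_reps Repetitions per stimulus pair (default 15; 450 trials per
#'   subject and task).
#' @param bias_sd Between-subject SD of the shared sensorimotor bias (deg).
#' @param task_bias_sd Between-subject SD of the small task-specific
#'   (modality-specific) response offset (deg). The shared bias component is
#'   removed by normalization; half of the differential component survives it.
#' @param sigma_a_uni,sigma_v_uni,sigma_a_bi,sigma_v_bi Population means of
#'   the localization noise SDs (deg) per task x mode cell.
#' @param sigma_sd_frac Between-subject SD of each noise SD, as a fraction of
#'   its population mean.
#' @param w_mean,w_sd Population mean and between-subject SD of the fusion
#'   weight applied to the audio-visual discrepancy in the acoustic task;
#'   per-subject draws are clipped to `[0, 1]`.
#' @param mu_logT Named numeric vector of log-scale decision-time locations
#'   (log-seconds) for the four task x mode cells `a_uni`, `a_bi`, `v_uni`,
#'   `v_bi`.
#' @param delta_ecc Log-scale decision-time increment for acoustic-task trials
#'   whose secondary stimulus is maximally eccentric (|xs| = 20 deg).
#' @param delta_ecc_primary Log-scale decision-time increment for maximally
#'   eccentric primaries; 0 by default (the eccentricity effect on decision
#'   time is confined to the secondary stimulus).
#' @param sigma_logT Within-subject SD of log decision time.
#' @param t_offset_sd Between-subject SD of the log-scale decision-time
#'   random effect.
#' @param movement_duration Mean pointer movement duration (s).
#' @param movement_duration_cv Log-scale SD of the per-trial movement
#'   duration (condition-independent).
#' @param sample_rate Trajectory sampling rate (Hz).
#' @param seed Integer seed; mandatory for dataset generation.
#' @return An object of class `avl_params` (a validated list).
#' @export
sim_params <- function(n_subjects = 10L,
                       n_reps = 15L,
                       bias_sd = 3,
                       task_bias_sd = 2,
                       sigma_a_uni = 7.5,
                       sigma_v_uni = 2.8,
                       sigma_a_bi = 5.8,
                       sigma_v_bi = 3.1,
                       sigma_sd_frac = 0.1,
                       w_mean = 0.972,
                       w_sd = 0.15,
                       mu_logT = c(a_uni = log(0.95), a_bi = log(0.80),
                                   v_uni = log(0.75), v_bi = log(0.62)),
                       delta_ecc = 0.10,
                       delta_ecc_primary = 0,
                       sigma_logT = 0.41,
                       t_offset_sd = 0.02,
                       movement_duration = 1.0,
                       movement_duration_cv = 0.15,
                       sample_rate = 100,
                       seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects), n_reps = as.integer(n_reps),
            bias_sd = bias_sd, task_bias_sd = task_bias_sd,
            sigma_a_uni = sigma_a_uni, sigma_v_uni = sigma_v_uni,
            sigma_a_bi = sigma_a_bi, sigma_v_bi = sigma_v_bi,
            sigma_sd_frac = sigma_sd_frac,
            w_mean = w_mean, w_sd = w_sd,
            mu_logT = mu_logT, delta_ecc = delta_ecc,
            delta_ecc_primary = delta_ecc_primary,
            sigma_logT = sigma_logT, t_offset_sd = t_offset_sd,
            movement_duration = movement_duration,
            movement_duration_cv = movement_duration_cv,
            sample_rate = sample_rate, seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "avl_params"
  p
}

validate_sim_params <- function(p) {
  stopifnot(p$n_subjects >= 1, p$n_reps >= 1)
  sds <- c(p$sigma_a_uni, p$sigma_v_uni, p$sigma_a_bi, p$sigma_v_bi,
           p$sigma_logT)
  if (any(sds <= 0)) stop("localization and log-time SDs must be > 0")
  if (p$w_mean < 0 || p$w_mean > 1.5) stop("'w_mean' out of range")
  if (is.null(names(p$mu_logT)) ||
      !all(c("a_uni", "a_bi", "v_uni", "v_bi") %in% names(p$mu_logT)))
    stop("'mu_logT' must be named a_uni, a_bi, v_uni, v_bi")
  if (p$movement_duration <= 0 || p$sample_rate <= 0)
    stop("movement duration and sample rate must be > 0")
  invisible(p)
}

#' @export
print.avl_params <- function(x, ...) {
  cat("Synthetic-subject simulation parameters\n")
  cat(sprintf("  %d subjects, %d reps (%d trials/subject/task)\n",
              x$n_subjects, x$n_reps, 30L * x$n_reps))
  cat(sprintf("  noise SD (deg): a-uni %.1f, v-uni %.1f, a-bi %.1f, v-bi %.1f\n",
              x$sigma_a_uni, x$sigma_v_uni, x$sigma_a_bi, x$sigma_v_bi))
  cat(sprintf("  fusion weight: %.3f (SD %.2f); sigma_logT %.2f; seed %d\n",
              x$w_mean, x$w_sd, x$sigma_logT, x$seed))
  invisible(x)
}
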