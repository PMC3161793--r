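# Pointer range (deg); responses are clipped to the physical stop positions.
POINTER_RANGE <- c(-40, 40)
POINTER_NEUTRAL <- 40

#' Draw one synthetic subject profile
#'
#' Samples per-subject parameters around the population calibration: a shared
#' sensorimotor bias, small task-specific response offsets, task x mode
#' localization noise SDs, a fusion weight (clipped to `[0, 1]`) and a
#' log-scale decision-time random effect.
#'
#' @param params An [sim_params()] object.
#' @return A list of class `avl_profile`.
#' @export
draw_subject_profile <- function(params) {
  validate_sim_params(params)
  jit <- function(m) pmax(m + stats::rnorm(1L, 0, params$sigma_sd_frac * m),
                          0.05 * m)
  prof <- list(
    bias = stats::rnorm(1L, 0, params$bias_sd),
    task_bias = stats::rnorm(2L, 0, params$task_bias_sd), # [acoustic, visual]
    sigma_a_uni = jit(params$sigma_a_uni),
    sigma_v_uni = jit(params$sigma_v_uni),
    sigma_a_bi  = jit(params$sigma_a_bi),
    sigma_v_bi  = jit(params$sigma_v_bi),
    w = min(max(stats::rnorm(1L, params$w_mean, params$w_sd), 0), 1),
    mu_logT = params$mu_logT,
    delta_ecc = params$delta_ecc,
    delta_ecc_primary = params$delta_ecc_primary,
    sigma_logT = params$sigma_logT,
    subject_T_offset = stats::rnorm(1L, 0, params$t_offset_sd)
  )
  class(prof) <- "avl_profile"
  prof
}

percept_noise_sd <- function(profile, task, bimodal) {
  if (task == 0L) {
    if (bimodal) profile$sigma_a_bi else profile$sigma_a_uni
  } else {
    if (bimodal) profile$sigma_v_bi else profile$sigma_v_uni
  }
}

#' Simulate one raw localization response
#'
#' In the visual task and on unimodal trials the percept is centered on the
#' primary position (segregation); in the acoustic task with a secondary
#' stimulus the center is shifted toward the visual distractor by the
#' subject's fusion weight (visual capture). Gaussian response noise with the
#' task x mode SD and the subject's sensorimotor offsets are added, and the
#' result is clipped to the pointer range.
#'
#' @param profile An `avl_profile`.
#' @param task 0 (acoustic) or 1 (visual).
#' @param xp Primary position (deg, on the design grid).
#' @param xs Secondary position (deg) or `NA` for unimodal trials.
#' @param n Number of independent draws.
#' @return Raw localization(s) in degrees.
#' @export
simulate_percept <- function(profile, task, xp, xs, n = 1L) {
  if (!xp %in% primary_positions()) stop("'xp' is off the design grid")
  bimodal <- !is.na(xs)
  if (bimodal && !(xs - xp) %in% secondary_offsets())
    stop("'xs' is off the design grid")
  center <- xp
  if (bimodal && task == 0L) center <- xp + profile$w * (xs - xp)
  center <- center + profile$bias + profile$task_bias[task + 1L]
  raw <- center + stats::rnorm(n, 0, percept_noise_sd(profile, task, bimodal))
  pmin(pmax(raw, POINTER_RANGE[1L]), POINTER_RANGE[2L])
}

#' Simulate one decision time
#'
#' Decision time (stimulus onset to movement onset) is log-normal with a
#' location depending on task and mode of presentation, a bump for maximally
#' eccentric secondary stimuli in the acoustic task, and the subject's
#' log-scale random effect.
#'
#' @inheritParams simulate_percept
#' @param mode 0 (unisensory) or 1 (bisensory); must be consistent with `xs`.
#' @return Decision time(s) in seconds (> 0).
#' @export
simulate_decision_time <- function(profile, task, mode, xs, xp = 0, n = 1L) {
  if ((mode == 0L) != is.na(xs))
    stop("inconsistent mode/xs: mode must be 0 iff xs is the unimodal sentinel")
  cell <- paste0(if (task == 0L) "a" else "v",
                 if (mode == 0L) "_uni" else "_bi")
  eta <- profile$mu_logT[[cell]] + profile$subject_T_offset
  if (task == 0L && !is.na(xs) && abs(xs) == 20) eta <- eta + profile$delta_ecc
  if (abs(xp) == 10 && profile$delta_ecc_primary != 0)
    eta <- eta + profile$delta_ecc_primary
  exp(stats::rnorm(n, eta, profile$sigma_logT))
}

#' Simulate a pointer trajectory
#'
#' The pointer rests at the 40-deg neutral stop until `decision_time`, then
#' follows a minimum-jerk profile to the endpoint over `movement_duration`,
#' and holds there.
#'
#' @param endpoint Final pointer position (deg, within the pointer range).
#' @param decision_time Seconds from stimulus onset to movement onset.
#' @param movement_duration Movement duration (s, > 0).
#' @param sample_rate Sampling rate (Hz, > 0).
#' @param total_time Total recorded duration (s); defaults to
#'   `decision_time + movement_duration + 0.5`.
#' @return A data.frame of class `avl_trajectory` with columns `time` (s) and
#'   `position` (deg).
#' @export
simulate_trajectory <- function(endpoint, decision_time, movement_duration,
                                sample_rate = 100,
                                total_time = decision_time + movement_duration + 0.5) {
  if (movement_duration <= 0 || sample_rate <= 0)
    stop("movement duration and sample rate must be > 0")
  if (endpoint < POINTER_RANGE[1L] || endpoint > POINTER_RANGE[2L])
    stop("endpoint outside the pointer range")
  t <- seq(0, total_time, by = 1 / sample_rate)
  s <- pmin(pmax((t - decision_time) / movement_duration, 0), 1)
  # minimum-jerk position profile: 10 s^3 - 15 s^4 + 6 s^5
  shape <- 10 * s^3 - 15 * s^4 + 6 * s^5
  out <- data.frame(time = t,
                    position = POINTER_NEUTRAL +
                      (endpoint - POINTER_NEUTRAL) * shape)
  class(out) <- c("avl_trajectory", "data.frame")
  out
}

shuffle_within <- function(n) sample.int(n)

#' Simulate a full behavioral dataset
#'
#' Composes the design enumeration, subject profiles, percept and
#' decision-time generators into one trial table, shuffled within each
#' subject x task block. Fully reproducible from `params$seed`.
#'
#' @param params An [sim_params()] object.
#' @return A data.frame of class `avl_trials` with columns `subject`, `task`,
#'   `mode`, `xp`, `xs`, `response_raw`, `decision_time`, `movement_time`.
#' @examples
#' trials <- simulate_dataset(sim_params(n_subjects = 2, n_reps = 2, seed = 7))
#' nrow(trials)  # 2 subjects x 2 tasks x 60 trials
#' @export
simulate_dataset <- function(params = sim_params()) {
  validate_sim_params(params)
  set.seed(params$seed, kind = "Mersenne-Twister")
  design <- build_design(params$n_subjects, params$n_reps)

  profiles <- lapply(seq_len(params$n_subjects),
                     function(i) draw_subject_profile(params))

  n <- nrow(design)
  resp <- numeric(n); dtime <- numeric(n)
  for (i in seq_len(n)) {
    prof <- profiles[[design$subject[i]]]
    resp[i] <- simulate_percept(prof, design$task[i], design$xp[i], design$xs[i])
    dtime[i] <- simulate_decision_time(prof, design$task[i], design$mode[i],
                                       design$xs[i], design$xp[i])
  }
  mtime <- exp(stats::rnorm(n, log(params$movement_duration),
                            params$movement_duration_cv))

  out <- data.frame(subject = design$subject, task = design$task,
                    mode = design$mode, xp = design$xp, xs = design$xs,
                    response_raw = resp, decision_time = dtime,
                    movement_time = mtime)
  # shuffle trial order within each subject x task block
  blocks <- split(seq_len(n), list(out$subject, out$task))
  ord <- unlist(lapply(blocks, function(ix) ix[shuffle_within(length(ix))]),
                use.names = FALSE)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "params") <- params
  attr(out, "profiles") <- profiles
  class(out) <- c("avl_trials", "data.frame")
  out
}

#' @export
print.avl_trials <- function(x, ...) {
  cat(sprintf("Behavioral trial table: %d trials, %d subjects, %d tasks\n",
              nrow(x), length(unique(x$subject)), length(unique(x$task))))
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}
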