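traj_speed <- function(traj) {
  pos <- traj$position
  n <- length(pos)
  if (n < 3L) stop("trajectory needs at least 3 samples")
  dt <- diff(traj$time)
  if (max(abs(dt - dt[1L])) > 1e-9 * max(dt[1L], 1))
    stop("trajectory must be uniformly sampled")
  dt <- dt[1L]
  # light 3-sample moving-average smooth, then centered differences
  sm <- pos
  sm[2:(n - 1L)] <- (pos[1:(n - 2L)] + pos[2:(n - 1L)] + pos[3:n]) / 3
  v <- rep(0, n)
  v[2:(n - 1L)] <- (sm[3:n] - sm[1:(n - 2L)]) / (2 * dt)
  v[1L] <- (sm[2L] - sm[1L]) / dt
  v[n] <- (sm[n] - sm[n - 1L]) / dt
  abs(v)
}

#' Detect movement onset from a pointer trajectory
#'
#' Movement onset is the first sample at which the (lightly smoothed,
#' centered-difference) pointer speed exceeds the velocity threshold.
#'
#' @param traj An `avl_trajectory` (uniformly sampled, >= 3 samples).
#' @param v_thresh Velocity cutoff in deg/s (default 1.5).
#' @return Onset time in seconds, or `NA_real_` when the speed never exceeds
#'   the threshold.
#' @export
detect_movement_onset <- function(traj, v_thresh = 1.5) {
  v <- traj_speed(traj)
  ix <- which(v > v_thresh)
  if (length(ix) == 0L) return(NA_real_)
  traj$time[ix[1L]]
}

#' Detect movement end from a pointer trajectory
#'
#' Movement end is the first sample after peak speed at which the speed falls
#' below the threshold and stays below it for the remainder of the hold
#' window.
#'
#' @inheritParams detect_movement_onset
#' @return End time in seconds, or `NA_real_` when no movement is detected.
#' @export
detect_movement_end <- function(traj, v_thresh = 1.5) {
  v <- traj_speed(traj)
  if (!any(v > v_thresh)) return(NA_real_)
  peak <- which.max(v)
  n <- length(v)
  below <- v <= v_thresh
  # first index after the peak from which speed stays below threshold
  stays <- rev(cumprod(rev(below))) > 0
  ix <- which(stays & seq_len(n) > peak)
  if (length(ix) == 0L) return(NA_real_)
  traj$time[ix[1L]]
}

#' Extract decision time, movement time and endpoint from a trajectory
#'
#' @inheritParams detect_movement_onset
#' @param stimulus_time Stimulus onset time (s) on the trajectory clock.
#' @return A list with `decision_time` (onset - stimulus), `movement_time`
#'   (end - onset) and `endpoint` (median position over the hold phase).
#' @export
extract_features <- function(traj, stimulus_time = 0, v_thresh = 1.5) {
  onset <- detect_movement_onset(traj, v_thresh)
  end <- detect_movement_end(traj, v_thresh)
  if (is.na(onset) || is.na(end))
    stop("no movement detected: pointer speed never exceeded the threshold")
  hold <- traj$position[traj$time >= end]
  list(decision_time = onset - stimulus_time,
       movement_time = end - onset,
       endpoint = stats::median(hold))
}

#' Normalize localizations by each subject's unisensory mean
#'
#' Subtracts, per subject, the mean raw response over that subject's
#' unisensory trials (pooled across both tasks). Since the design positions
#' average to zero, this removes the subject's sensorimotor bias estimate and
#' turns the response into an approximate observation of the spatial percept.
#' Idempotent on its own output.
#'
#' @param trials A trial table with columns `subject`, `mode`, `response_raw`.
#' @return The table with an added (or recomputed) `response_norm` column.
#' @export
normalize_localizations <- function(trials) {
  stopifnot(all(c("subject", "mode", "response_raw") %in% names(trials)))
  src <- if ("response_norm" %in% names(trials)) trials$response_norm else
    trials$response_raw
  uni <- trials$mode == 0L
  if (!all(unique(trials$subject) %in% unique(trials$subject[uni])))
    stop("every subject needs unisensory trials for normalization")
  m <- tapply(src[uni], trials$subject[uni], mean)
  trials$response_norm <- src - as.numeric(m[as.character(trials$subject)])
  trials
}

offset_of <- function(xp, xs) ifelse(is.na(xs), NA_real_, xs - xp)

#' Condition-wise summary of localization and decision time
#'
#' Means and SDs of normalized localization and decision time per (task,
#' mode, primary position, secondary offset) cell, pooled across subjects,
#' together with the across-subject average of per-subject SDs (the
#' dispersion statistic quoted for the protocol).
#'
#' @param trials A normalized trial table (see [normalize_localizations()]).
#' @return A data.frame of class `avl_summary`, one row per condition cell,
#'   with columns `task`, `mode`, `xp`, `xs_offset`, `n`,
#'   `response_mean`, `response_sd` (pooled), `response_sd_subj` (average of
#'   per-subject SDs), `dtime_mean`, `dtime_sd`, `dtime_sd_subj`.
#' @export
summarize_conditions <- function(trials) {
  stopifnot(all(c("response_norm", "decision_time") %in% names(trials)))
  key <- data.frame(task = trials$task, mode = trials$mode, xp = trials$xp,
                    xs_offset = offset_of(trials$xp, trials$xs))
  kstr <- paste(key$task, key$mode, key$xp, key$xs_offset, sep = "|")
  cells <- !duplicated(kstr)
  out <- key[cells, , drop = FALSE]
  out <- out[order(out$task, out$mode, out$xp, out$xs_offset), ]
  rownames(out) <- NULL

  per_subject_sd <- function(v, subj) mean(tapply(v, subj, stats::sd),
                                           na.rm = TRUE)
  stats_for <- function(sel) {
    r <- trials$response_norm[sel]; t <- trials$decision_time[sel]
    s <- trials$subject[sel]
    c(n = sum(sel), response_mean = mean(r), response_sd = stats::sd(r),
      response_sd_subj = per_subject_sd(r, s),
      dtime_mean = mean(t), dtime_sd = stats::sd(t),
      dtime_sd_subj = per_subject_sd(t, s))
  }
  ostr <- paste(out$task, out$mode, out$xp, out$xs_offset, sep = "|")
  m <- t(vapply(ostr, function(k) stats_for(kstr == k), numeric(7L)))
  out <- cbind(out, as.data.frame(m))
  rownames(out) <- NULL
  class(out) <- c("avl_summary", "data.frame")
  out
}
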