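#' Stimulus grids of the localization protocol
#'
#' Primary stimuli occur at five azimuthal positions; the secondary stimulus,
#' when present, is placed at a signed offset from the primary, so that its
#' possible positions span -20..20 deg in 5-deg steps. Unimodal trials carry a
#' sentinel secondary position.
#'
#' @name stimulus-grids
#' @keywords internal
NULL

# sentinel for "no secondary stimulus" (unimodal trial)
XS_SENTINEL <- NA_real_

#' Primary stimulus positions (deg)
#' @return Numeric vector of the five primary positions.
#' @export
primary_positions <- function() c(-10, -5, 0, 5, 10)

#' Secondary stimulus offsets (deg), 0 = spatially coincident
#' @return Numeric vector of the five secondary offsets.
#' @export
secondary_offsets <- function() c(-10, -5, 0, 5, 10)

#' Enumerate the full-factorial experimental design
#'
#' Builds the trial list of the localization protocol for both tasks: per
#' subject and task, `n_reps` repetitions of each of 5 unimodal stimuli,
#' 5 spatially coincident bimodal pairs, and 20 non-coincident pairs (offsets
#' -10, -5, +5, +10 deg from the primary). With the default 15 repetitions this
#' yields 450 trials per subject and task: 75 unimodal, 75 coincident and 300
#' non-coincident.
#'
#' @param n_subjects Number of subjects (>= 1; the study used 10).
#' @param n_reps Repetitions per distinct stimulus pair (>= 1; the study used 15).
#' @return A data.frame of class `avl_design` with columns `subject`, `task`
#'   (0 acoustic, 1 visual), `xp` (primary position, deg), `xs` (secondary
#'   position, deg; `NA` on unimodal trials), `mode` (0 unisensory,
#'   1 bisensory) and `rep`, in deterministic order.
#' @examples
#' d <- build_design(1, 15)
#' table(d$mode) / 2  # 75 unimodal, 375 bimodal per task
#' @export
build_design <- function(n_subjects = 10L, n_reps = 15L) {
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 1)
    stop("'n_subjects' must be a positive integer")
  if (length(n_reps) != 1L || is.na(n_reps) || n_reps < 1)
    stop("'n_reps' must be a positive integer")
  n_subjects <- as.integer(n_subjects)
  n_reps <- as.integer(n_reps)

  xp <- primary_positions()
  pairs <- rbind(
    data.frame(xp = xp, xs_off = NA_real_),                # unimodal
    expand.grid(xp = xp, xs_off = secondary_offsets())     # bimodal
  )
  pairs$xs <- ifelse(is.na(pairs$xs_off), XS_SENTINEL,
                     pairs$xp + pairs$xs_off)
  pairs$xs_off <- NULL

  base <- expand.grid(rep = seq_len(n_reps), pair = seq_len(nrow(pairs)),
                      task = c(0L, 1L), subject = seq_len(n_subjects))
  out <- data.frame(
    subject = base$subject,
    task    = base$task,
    xp      = pairs$xp[base$pair],
    xs      = pairs$xs[base$pair],
    rep     = base$rep
  )
  out$mode <- ifelse(is.na(out$xs), 0L, 1L)
  out <- out[, c("subject", "task", "xp", "xs", "mode", "rep")]
  class(out) <- c("avl_design", "data.frame")
  out
}

#' @export
print.avl_design <- function(x, ...) {
  cat(sprintf("Localization design: %d subjects x %d tasks x %d trials\n",
              length(unique(x$subject)), length(unique(x$task)),
              nrow(x) / (length(unique(x$subject)) * length(unique(x$task)))))
  invisible(x)
}
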