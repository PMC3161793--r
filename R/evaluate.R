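#' Leave-one-subject-out folds
#'
#' @param subject_ids Vector of subject identifiers.
#' @param K Number of folds; must equal the number of distinct subjects
#'   (exact leave-one-subject-out partition).
#' @return List of folds, each with `train` and `test` subject vectors.
#' @export
make_folds <- function(subject_ids, K = 10L) {
  subjects <- sort(unique(subject_ids))
  if (K != length(subjects))
    stop("K must equal the number of subjects (leave-one-subject-out)")
  lapply(subjects, function(s) list(train = setdiff(subjects, s), test = s))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with `SS_tot` about the mean of the observations;
#' may be negative and is reported as-is.
#'
#' @param predicted,observed Equal-length numeric vectors (>= 2 cells).
#' @return R-squared (unitless).
#' @export
r2 <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(observed) < 2L) stop("need at least 2 cells")
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

# presentation-mode grouping: 0 unisensory, 1 bisensory coincident,
# 2 bisensory non-coincident
mode3_of <- function(xp, xs) ifelse(is.na(xs), 0L, ifelse(xs == xp, 1L, 2L))

cell_means <- function(trials, value, by) {
  keys <- config_key(trials[, by, drop = FALSE])
  agg <- tapply(trials[[value]], keys, mean)
  cfg <- trials[!duplicated(keys), by, drop = FALSE]
  cfg$key <- keys[!duplicated(keys)]
  cfg$obs <- as.numeric(agg[cfg$key])
  cfg[order(cfg$key), , drop = FALSE]
}

fit_t_grouped <- function(trials) {
  g <- mode3_of(trials$xp, trials$xs)
  keys <- paste(trials$task, g, sep = "|")
  sp <- split(log(trials$decision_time), keys)
  data.frame(key = names(sp),
             mean = vapply(sp, mean, numeric(1L)),
             sd = vapply(sp, stats::sd, numeric(1L)),
             n = lengths(sp), stringsAsFactors = FALSE)
}

lognormal_point <- function(mean, sd, type) {
  shift <- switch(type, mode = -sd^2, median = 0, mean = sd^2 / 2)
  exp(mean + shift)
}

#' Leave-one-subject-out cross-validation of the generative model
#'
#' Per fold, fits the factorization on the training subjects and predicts,
#' for every condition cell of the design, the MAP percept and a point
#' decision-time prediction; observations are the held-out subject's cell
#' means. Decision times are evaluated both at condition-cell resolution
#' (task x primary x secondary) and collapsed into 2 tasks x 3 modes of
#' presentation (unisensory / bisensory coincident / bisensory
#' non-coincident), the latter with the time factor refitted on the grouped
#' variable.
#'
#' @param trials Normalized trial table.
#' @param K Number of folds (= number of subjects).
#' @param fact Factorization to fit (default [canonical_factorization()]).
#' @param dt_type Point summary of the log-normal decision-time conditional
#'   used for prediction: `"mean"` (conditional expectation; default, the
#'   unbiased predictor of an observed cell mean), `"median"` or `"mode"`.
#' @return An object of class `avl_cv` with data.frames `percept`, `dtime`
#'   (per fold x condition cell: `pred`, `obs`) and `dtime_grouped` (per
#'   fold x task x mode), plus the fold list.
#' @export
crossvalidate <- function(trials, K = length(unique(trials$subject)),
                          fact = canonical_factorization(),
                          dt_type = c("mean", "median", "mode")) {
  dt_type <- match.arg(dt_type)
  stopifnot("response_norm" %in% names(trials))
  folds <- make_folds(trials$subject, K)
  percept <- list(); dtime <- list(); grouped <- list()

  for (k in seq_along(folds)) {
    fold <- folds[[k]]
    train <- trials[trials$subject %in% fold$train, , drop = FALSE]
    test <- trials[trials$subject == fold$test, , drop = FALSE]
    model <- fit_model(train, fact)

    oc <- cell_means(test, "response_norm", c("task", "xp", "xs"))
    oc$pred <- mapply(function(s, xp, xs) map_percept(model, s, xp, xs),
                      oc$task, oc$xp, oc$xs)
    percept[[k]] <- data.frame(fold = k, oc[, c("task", "xp", "xs")],
                               pred = oc$pred, obs = oc$obs)

    ot <- cell_means(test, "decision_time", c("task", "xp", "xs"))
    ot$pred <- mapply(function(s, xs) map_decision_time(model, s, xs,
                                                        type = dt_type),
                      ot$task, ot$xs)
    dtime[[k]] <- data.frame(fold = k, ot[, c("task", "xp", "xs")],
                             pred = ot$pred, obs = ot$obs)

    gt <- fit_t_grouped(train)
    test$mode3 <- mode3_of(test$xp, test$xs)
    og <- cell_means(test, "decision_time", c("task", "mode3"))
    gi <- match(paste(og$task, og$mode3, sep = "|"), gt$key)
    og$pred <- lognormal_point(gt$mean[gi], gt$sd[gi], dt_type)
    grouped[[k]] <- data.frame(fold = k, og[, c("task", "mode3")],
                               pred = og$pred, obs = og$obs)
  }

  out <- list(percept = do.call(rbind, percept),
              dtime = do.call(rbind, dtime),
              dtime_grouped = do.call(rbind, grouped),
              folds = folds, dt_type = dt_type)
  class(out) <- "avl_cv"
  out
}

fold_mean_r2 <- function(df) {
  mean(vapply(split(df, df$fold), function(d) r2(d$pred, d$obs),
              numeric(1L)))
}

#' Cross-validated R-squared summaries
#'
#' Mean across folds of the per-fold coefficient of determination between
#' predictions and held-out cell means, pooled over both tasks: for the
#' percept, for the decision time at condition-cell resolution, and for the
#' decision time collapsed into modes of presentation.
#'
#' @param cv An [crossvalidate()] result.
#' @return Named list `r2_percept`, `r2_decision_time`,
#'   `r2_decision_time_collapsed`.
#' @export
cv_r2 <- function(cv) {
  list(r2_percept = fold_mean_r2(cv$percept),
       r2_decision_time = fold_mean_r2(cv$dtime),
       r2_decision_time_collapsed = fold_mean_r2(cv$dtime_grouped))
}

#' Per-primary-position R-squared table
#'
#' Mean across folds of the R-squared restricted to each primary position's
#' condition cells (both tasks pooled), separately for percept and decision
#' time.
#'
#' @param cv An [crossvalidate()] result.
#' @return Data.frame with columns `xp`, `r2_percept`, `r2_decision_time`.
#' @export
r2_by_position <- function(cv) {
  pos <- sort(unique(cv$percept$xp))
  data.frame(
    xp = pos,
    r2_percept = vapply(pos, function(p)
      fold_mean_r2(cv$percept[cv$percept$xp == p, ]), numeric(1L)),
    r2_decision_time = vapply(pos, function(p)
      fold_mean_r2(cv$dtime[cv$dtime$xp == p, ]), numeric(1L)))
}

#' Collapsed-mode decision-time R-squared
#'
#' @param cv An [crossvalidate()] result.
#' @return Mean across folds of the R-squared over the 2 tasks x 3 modes of
#'   presentation decision-time groups.
#' @export
r2_collapsed_modes <- function(cv) fold_mean_r2(cv$dtime_grouped)

#' Closed-form R-squared expectation
#'
#' First-order expectation of the cross-validated R-squared when predictions
#' are unbiased for the observed cell means:
#' `E[R2] ~ v_between / (v_between + sigma_obs2)`, with `sigma_obs2` the
#' observation noise (within-cell variance over the per-cell count, plus any
#' between-subject offset variance). Used to calibrate the decision-time
#' dispersion defaults.
#'
#' @param v_between Variance of the true cell means.
#' @param within_var Within-cell observation variance.
#' @param n_cell Observations per cell.
#' @param offset_var Between-subject offset variance (not captured by the
#'   model).
#' @return Expected R-squared.
#' @export
r2_expected <- function(v_between, within_var, n_cell, offset_var = 0) {
  sigma_obs2 <- within_var / n_cell + offset_var
  v_between / (v_between + sigma_obs2)
}

#' Write / read a machine-readable evaluation report
#'
#' The report records the headline R-squared values, the per-position table,
#' per-fold detail, and the seed/calibration metadata, as JSON.
#'
#' @param cv An [crossvalidate()] result.
#' @param path Output file.
#' @param meta Optional named list of run metadata (seed, thresholds, ...).
#' @return `path`, invisibly.
#' @export
write_report <- function(cv, path, meta = list()) {
  fold_detail <- lapply(split(cv$percept, cv$percept$fold), function(d) {
    k <- d$fold[1L]
    list(fold = k,
         r2_percept = r2(d$pred, d$obs),
         r2_decision_time = with(cv$dtime[cv$dtime$fold == k, ],
                                 r2(pred, obs)),
         r2_decision_time_collapsed =
           with(cv$dtime_grouped[cv$dtime_grouped$fold == k, ],
                r2(pred, obs)))
  })
  report <- list(summary = cv_r2(cv),
                 by_position = r2_by_position(cv),
                 folds = unname(fold_detail),
                 dt_type = cv$dt_type,
                 meta = meta)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
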