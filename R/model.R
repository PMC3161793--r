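var_column <- function(var) {
  c(s = "task", m = "mode", xp = "xp", xs = "xs",
    xhat = "response_norm", t = "decision_time")[[var]]
}

config_key <- function(df) {
  if (ncol(df) == 0L) return(rep("()", nrow(df)))
  do.call(paste, c(lapply(df, function(v) ifelse(is.na(v), "NA",
                                                 format(v, trim = TRUE))),
                   sep = "|"))
}

#' Fit the generative model by maximum likelihood
#'
#' Estimates every factor of the supplied factorization from a (training)
#' trial table: multinomial tables (empirical frequencies) for the discrete
#' variables, a Gaussian for the normalized localization per parent
#' configuration (sample mean and SD), and a log-normal for the decision
#' time per parent configuration (mean and SD of log seconds). Parent
#' configurations with fewer than two observations are flagged and inference
#' on them is refused.
#'
#' @param trials Normalized trial table.
#' @param fact An [canonical_factorization()]-style factorization.
#' @return An object of class `avl_model`: per-factor parameter tables plus
#'   flagged-configuration bookkeeping.
#' @export
fit_model <- function(trials, fact = canonical_factorization()) {
  stopifnot(inherits(fact, "avl_factorization"))
  factors <- list()
  for (f in fact) {
    v <- f$var
    vals <- trials[[var_column(v)]]
    pdf <- as.data.frame(lapply(f$parents,
                                function(p) trials[[var_column(p)]]))
    if (length(f$parents)) names(pdf) <- f$parents
    keys <- if (length(f$parents)) config_key(pdf) else
      rep("()", length(vals))
    kind <- switch(v, xhat = "gaussian", t = "lognormal", "multinomial")
    if (kind == "multinomial") {
      tab <- table(key = keys, value = ifelse(is.na(vals), "NA",
                                              format(vals, trim = TRUE)))
      prob <- prop.table(tab, margin = 1L)
      cfg <- if (length(f$parents))
        unique(data.frame(pdf, key = keys, stringsAsFactors = FALSE))
      else data.frame(key = unique(keys), stringsAsFactors = FALSE)
      factors[[v]] <- list(var = v, parents = f$parents, kind = kind,
                           prob = prob, configs = cfg,
                           n = as.vector(table(keys)[rownames(prob)]))
    } else {
      y <- if (kind == "lognormal") log(vals) else vals
      sp <- split(y, keys)
      cfgrows <- pdf[!duplicated(keys), , drop = FALSE]
      rownames(cfgrows) <- keys[!duplicated(keys)]
      est <- data.frame(key = names(sp),
                        mean = vapply(sp, mean, numeric(1L)),
                        sd = vapply(sp, stats::sd, numeric(1L)),
                        n = lengths(sp), stringsAsFactors = FALSE)
      est$flagged <- est$n < 2L
      factors[[v]] <- list(var = v, parents = f$parents, kind = kind,
                           est = est, configs = cfgrows[est$key, ,
                                                        drop = FALSE])
    }
  }
  out <- list(factors = factors, fact = fact)
  class(out) <- "avl_model"
  out
}

#' @export
print.avl_model <- function(x, ...) {
  cat("Fitted generative model\n")
  for (f in x$factors) {
    extra <- if (f$kind == "multinomial")
      sprintf("%d configs", nrow(f$prob))
    else sprintf("%d configs%s", nrow(f$est),
                 if (any(f$est$flagged)) sprintf(" (%d flagged)",
                                                 sum(f$est$flagged)) else "")
    cat(sprintf("  %-4s %-11s parents: %-10s %s\n", f$var, f$kind,
                paste(f$parents, collapse = ","), extra))
  }
  invisible(x)
}

lookup_est <- function(factor, pvals) {
  key <- config_key(as.data.frame(pvals))
  row <- factor$est[match(key, factor$est$key), ]
  if (anyNA(row$mean))
    stop(sprintf("unseen parent configuration for '%s': %s",
                 factor$var, key))
  if (any(row$flagged))
    stop(sprintf("flagged parent configuration for '%s' (n < 2): %s",
                 factor$var, key))
  row
}

#' MAP percept prediction
#'
#' The maximum-a-posteriori percept given task and stimulus positions: the
#' mode of the fitted Gaussian conditional, i.e. its mean.
#'
#' @param model An [fit_model()] result.
#' @param s Task (0 acoustic, 1 visual).
#' @param xp Primary position (deg).
#' @param xs Secondary position (deg) or `NA` (unimodal).
#' @return Predicted localization (deg).
#' @export
map_percept <- function(model, s, xp, xs) {
  lookup_est(model$factors[["xhat"]], list(s = s, xp = xp, xs = xs))$mean
}

#' MAP decision-time prediction
#'
#' Point prediction of the decision time given task and secondary position,
#' from the fitted log-normal conditional with location `mu` and scale
#' `sigma` (log-seconds):
#' \describe{
#'   \item{mode}{`exp(mu - sigma^2)` — the density maximum of the log-normal.}
#'   \item{median}{`exp(mu)` — the mode/median on the log scale,
#'     back-transformed.}
#'   \item{mean}{`exp(mu + sigma^2/2)` — the conditional expectation, the
#'     unbiased predictor of an observed arithmetic cell mean.}
#' }
#'
#' @inheritParams map_percept
#' @param type Point summary of the conditional (see Details).
#' @return Predicted decision time (s).
#' @export
map_decision_time <- function(model, s, xs,
                              type = c("mode", "median", "mean")) {
  type <- match.arg(type)
  row <- lookup_est(model$factors[["t"]], list(s = s, xs = xs))
  shift <- switch(type, mode = -row$sd^2, median = 0, mean = row$sd^2 / 2)
  exp(row$mean + shift)
}

#' Log-likelihood of a trial table under the fitted model
#'
#' Sum over trials of the log factor densities (discrete pmfs, Gaussian
#' density for the normalized localization, log-normal density for the
#' decision time). Trials hitting unseen or flagged parent configurations
#' contribute a fixed penalty of `log(1e-12)` per factor; their count is
#' attached as attribute `n_flagged`.
#'
#' @param model An `avl_model`.
#' @param trials Normalized trial table.
#' @return Total log-likelihood (natural log), with attribute `n_flagged`.
#' @export
log_likelihood <- function(model, trials) {
  penalty <- log(1e-12)
  total <- 0
  n_flagged <- 0L
  for (f in model$factors) {
    vals <- trials[[var_column(f$var)]]
    pdf <- as.data.frame(lapply(f$parents,
                                function(p) trials[[var_column(p)]]))
    if (length(f$parents)) names(pdf) <- f$parents
    keys <- if (length(f$parents)) config_key(pdf) else
      rep("()", length(vals))
    if (f$kind == "multinomial") {
      vkey <- ifelse(is.na(vals), "NA", format(vals, trim = TRUE))
      ri <- match(keys, rownames(f$prob))
      ci <- match(vkey, colnames(f$prob))
      p <- rep(NA_real_, length(vals))
      ok <- !is.na(ri) & !is.na(ci)
      p[ok] <- f$prob[cbind(ri[ok], ci[ok])]
      bad <- !ok | is.na(p) | p <= 0
      total <- total + sum(log(p[!bad])) + penalty * sum(bad)
      n_flagged <- n_flagged + sum(bad)
    } else {
      ri <- match(keys, f$est$key)
      bad <- is.na(ri)
      row <- f$est[ri, ]
      bad <- bad | row$flagged | is.na(row$sd) | row$sd <= 0
      y <- vals
      ll <- rep(penalty, length(vals))
      if (f$kind == "gaussian") {
        ll[!bad] <- stats::dnorm(y[!bad], row$mean[!bad], row$sd[!bad],
                                 log = TRUE)
      } else {
        ll[!bad] <- stats::dlnorm(y[!bad], row$mean[!bad], row$sd[!bad],
                                  log = TRUE)
      }
      total <- total + sum(ll)
      n_flagged <- n_flagged + sum(bad)
    }
  }
  structure(total, n_flagged = n_flagged)
}
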