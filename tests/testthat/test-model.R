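test_that("ML fitting recovers noiseless generator means exactly", {
  tr <- normalize_localizations(simulate_dataset(noiseless_params(
    seed = 30L, w_mean = 0.9)))
  m <- fit_model(tr)
  # acoustic bimodal cell: mean = xp + w (xs - xp); unimodal: xp
  expect_equal(map_percept(m, 0L, 0, 10), 9, tolerance = 1e-6)
  expect_equal(map_percept(m, 0L, 5, -5), 5 + 0.9 * (-10), tolerance = 1e-6)
  expect_equal(map_percept(m, 0L, -10, NA), -10, tolerance = 1e-6)
  expect_equal(map_percept(m, 1L, 5, 15), 5, tolerance = 1e-6)
  # log-normal location is the mean of log decision times (definitional)
  sel <- tr$task == 0L & is.na(tr$xs)
  loc <- m$factors[["t"]]$est
  expect_equal(loc$mean[loc$key == "0|NA"], mean(log(tr$decision_time[sel])))
})

test_that("fitted Gaussian cells track the generator means on defaults", {
  tr <- fixture_trials()
  train <- tr[tr$subject != 10L, ]
  m <- fit_model(train)
  cells <- unique(train[, c("task", "xp", "xs")])
  pred <- mapply(function(s, xp, xs) map_percept(m, s, xp, xs),
                 cells$task, cells$xp, cells$xs)
  # generator cell means for the training population: fusion shift plus the
  # task-specific response offsets that survive normalization
  profs <- attr(tr, "profiles")[unique(train$subject)]
  w_bar <- mean(vapply(profs, `[[`, numeric(1L), "w"))
  shift_a <- mean(vapply(profs, function(p)
    (p$task_bias[1L] - mean(p$task_bias)), numeric(1L)))
  truth <- ifelse(cells$task == 0L & !is.na(cells$xs),
                  cells$xp + w_bar * (cells$xs - cells$xp), cells$xp) +
    ifelse(cells$task == 0L, shift_a, -shift_a)
  err <- abs(pred - truth)
  expect_lt(mean(err), 0.75)   # parameter recovery below the 1-deg scale
  expect_lt(max(err), 2.5)
  # MAP percept equals the training-cell sample mean (Gaussian mode identity)
  k <- paste(train$task, train$xp, ifelse(is.na(train$xs), "NA", train$xs))
  mu <- tapply(train$response_norm, k, mean)
  expect_equal(as.numeric(pred),
               as.numeric(mu[paste(cells$task, cells$xp,
                                   ifelse(is.na(cells$xs), "NA",
                                          cells$xs))]),
               tolerance = 1e-9)
})

test_that("MAP percepts show segregation in the visual task, fusion in the acoustic", {
  tr <- fixture_trials()
  m <- fit_model(tr)
  for (xp in c(-10, 0, 10)) {
    vis <- vapply(c(xp - 5, xp, xp + 5),
                  function(xs) map_percept(m, 1L, xp, xs), numeric(1L))
    expect_lt(mean(abs(vis - mean(vis))), 0.75)
  }
  w_bar <- mean(vapply(attr(tr, "profiles"), `[[`, numeric(1L), "w"))
  shift <- map_percept(m, 0L, 0, 10) - map_percept(m, 0L, 0, NA)
  expect_equal(shift, w_bar * 10, tolerance = 2)
})

test_that("decision-time point predictions follow the log-normal algebra", {
  m <- structure(list(factors = list(
    t = list(var = "t", parents = c("s", "xs"), kind = "lognormal",
             est = data.frame(key = c("0|10", "0|NA"),
                              mean = c(log(0.8), log(0.9)),
                              sd = c(0.3, 0), n = c(10L, 10L),
                              flagged = c(FALSE, FALSE),
                              stringsAsFactors = FALSE)))),
    class = "avl_model")
  expect_equal(map_decision_time(m, 0L, 10, "mode"),
               0.8 * exp(-0.09), tolerance = 1e-9)
  expect_equal(map_decision_time(m, 0L, 10, "median"), 0.8)
  expect_equal(map_decision_time(m, 0L, 10, "mean"), 0.8 * exp(0.045))
  # zero scale collapses all three summaries
  expect_equal(map_decision_time(m, 0L, NA, "mode"), 0.9)
  # mode < median strictly for positive scale
  expect_lt(map_decision_time(m, 0L, 10, "mode"),
            map_decision_time(m, 0L, 10, "median"))
  expect_error(map_decision_time(m, 1L, 10), "unseen")
})

test_that("flagged configurations are refused", {
  tr <- fixture_trials()[1:40, ]
  tr1 <- rbind(tr, transform(tr[1L, ], task = 1 - task))
  tr1$xp[nrow(tr1)] <- 10; tr1$xs[nrow(tr1)] <- 20
  m <- fit_model(tr1)
  est <- m$factors[["xhat"]]$est
  expect_true(any(est$flagged))
  bad <- est[est$flagged, ][1L, ]
  expect_error(map_percept(m, 1, 10, 20), "flagged|unseen")
})

test_that("log-likelihood matches a brute-force per-trial computation", {
  tr <- fixture_trials()[1:800, ]
  m <- fit_model(tr)
  toy <- tr[1:10, ]
  got <- log_likelihood(m, toy)
  # independent recomputation of every factor term
  oracle <- 0
  for (i in seq_len(10L)) {
    r <- toy[i, ]
    ps <- mean(tr$task == r$task)
    pm <- mean(tr$mode == r$mode)
    pxp <- mean(tr$xp == r$xp)
    sel_m <- tr$mode == r$mode
    pxs <- mean(ifelse(is.na(tr$xs[sel_m]), "NA", tr$xs[sel_m]) ==
                  ifelse(is.na(r$xs), "NA", r$xs))
    cell <- tr$task == r$task & tr$xp == r$xp &
      (ifelse(is.na(tr$xs), "NA", tr$xs) == ifelse(is.na(r$xs), "NA", r$xs))
    gx <- dnorm(r$response_norm, mean(tr$response_norm[cell]),
                sd(tr$response_norm[cell]), log = TRUE)
    tcell <- tr$task == r$task &
      (ifelse(is.na(tr$xs), "NA", tr$xs) == ifelse(is.na(r$xs), "NA", r$xs))
    lt <- log(tr$decision_time[tcell])
    gt <- dlnorm(r$decision_time, mean(lt), sd(lt), log = TRUE)
    oracle <- oracle + log(ps) + log(pm) + log(pxp) + log(pxs) + gx + gt
  }
  expect_equal(as.numeric(log_likelihood(m, toy)), oracle, tolerance = 1e-8)
  expect_equal(attr(got, "n_flagged"), 0L)

  # ML optimality: perturbing a fitted mean lowers the training likelihood
  m2 <- m
  m2$factors[["xhat"]]$est$mean <- m2$factors[["xhat"]]$est$mean + 0.5
  expect_lt(as.numeric(log_likelihood(m2, tr)),
            as.numeric(log_likelihood(m, tr)))
  # permuted labels score worse than the training data
  perm <- tr
  set.seed(33)
  perm$response_norm <- sample(perm$response_norm)
  expect_lt(as.numeric(log_likelihood(m, perm)),
            as.numeric(log_likelihood(m, tr)))
})

test_that("the discretized joint factorization is a proper distribution", {
  # input table with xp and xs sampled independently, so that the product
  # P(xp) P(xs|m) describes the actual input distribution
  set.seed(55)
  n <- 4000
  mo <- sample(0:1, n, TRUE)
  tr <- data.frame(
    task = sample(0:1, n, TRUE), mode = mo,
    xp = sample(c(-10, -5, 0, 5, 10), n, TRUE),
    xs = ifelse(mo == 0L, NA, sample(seq(-20, 20, 5), n, TRUE)),
    response_norm = rnorm(n, 0, 5),
    decision_time = rlnorm(n, log(0.8), 0.4))
  m <- fit_model(tr)
  xh <- binning_for("xhat")
  tb <- binning_for("t", t_max = as.numeric(
    quantile(tr$decision_time, 0.99)))
  gauss_mass <- function(mu, sd) {
    lo <- c(-Inf, xh$edges[-c(1L, length(xh$edges))])
    hi <- c(xh$edges[-c(1L, length(xh$edges))], Inf)
    sum(pnorm(hi, mu, sd) - pnorm(lo, mu, sd))
  }
  lnorm_mass <- function(mu, sd) {
    lo <- tb$edges[-length(tb$edges)]
    hi <- tb$edges[-1L]
    sum(plnorm(hi, mu, sd) - plnorm(lo, mu, sd)) +
      (1 - plnorm(tb$edges[length(tb$edges)], mu, sd))   # overflow bin
  }
  ps <- m$factors[["s"]]$prob; pm <- m$factors[["m"]]$prob
  pxp <- m$factors[["xp"]]$prob; pxs <- m$factors[["xs"]]$prob
  gx <- m$factors[["xhat"]]$est; gt <- m$factors[["t"]]$est
  total <- 0
  for (s in colnames(ps)) for (mo in colnames(pm))
    for (xp in colnames(pxp)) for (xs in colnames(pxs)) {
      pdisc <- ps["()", s] * pm["()", mo] * pxp["()", xp] * pxs[mo, xs]
      if (pdisc == 0) next
      kx <- paste(s, xp, xs, sep = "|")
      kt <- paste(s, xs, sep = "|")
      gxr <- gx[gx$key == kx, ]; gtr <- gt[gt$key == kt, ]
      total <- total + pdisc * gauss_mass(gxr$mean, gxr$sd) *
        lnorm_mass(gtr$mean, gtr$sd)
    }
  expect_equal(total, 1, tolerance = 1e-8)
  # every multinomial row is itself a distribution
  for (f in m$factors) {
    if (f$kind == "multinomial")
      expect_true(all(abs(rowSums(f$prob) - 1) < 1e-12))
  }
})
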