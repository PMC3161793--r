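# small synthetic tables over the binary/grid variables for targeted
# structure tests (columns reuse the canonical variable kinds)
chain_table <- function(n = 6000, seed = 12) {
  set.seed(seed)
  z <- sample(c(-10, 10), n, TRUE)
  flip <- function(b, p) ifelse(runif(n) < p, 1L - b, b)
  data.frame(task = flip(as.integer(z > 0), 0.1),
             mode = flip(as.integer(z > 0), 0.1),
             xp = z)
}

collider_table <- function(n = 6000, seed = 13) {
  set.seed(seed)
  s <- sample(0:1, n, TRUE)
  m <- sample(0:1, n, TRUE)
  # both parents load on the child, parents mutually independent
  data.frame(task = s, mode = m, xp = c(-10, 0, 10)[s + m + 1L])
}

test_that("normalized MI equals the brute-force double sum", {
  joint <- matrix(c(0.4, 0.1, 0.1, 0.4), 2)
  xy <- sample_from_pmf(joint, 1000)
  vals_x <- c(0, 1)[xy[, 1L]]; vals_y <- c(0, 1)[xy[, 2L]]
  bs <- binning_for("s"); bm <- binning_for("m")
  got <- normalized_mi(vals_x, vals_y, bs, bm)
  expect_equal(got, oracle_nmi(joint), tolerance = 1e-10)
  expect_lt(abs(got - 0.1615), 1e-3)
  # symmetry
  expect_equal(normalized_mi(vals_y, vals_x, bm, bs), got, tolerance = 1e-12)
  # identical two-level variables: I = H(X,Y) = 1 bit
  expect_equal(normalized_mi(vals_x, vals_x, bs, bs), 1)
  # independent uniform joint
  ind <- sample_from_pmf(matrix(0.25, 2, 2), 400)
  expect_equal(normalized_mi(c(0, 1)[ind[, 1L]], c(0, 1)[ind[, 2L]], bs, bm),
               0, tolerance = 1e-10)
  expect_error(normalized_mi(vals_x, vals_y[-1L], bs, bm), "equal length")
})

test_that("normalized MI stays in [0,1] and matches oracle on real data", {
  tr <- fixture_trials()[1:2000, ]
  bx <- binning_for("xp"); by <- binning_for("xs")
  got <- normalized_mi(tr$xp, tr$xs, bx, by)
  j <- joint_histogram(list(tr$xp, tr$xs), list(bx, by))
  expect_equal(got, oracle_nmi(j$prob), tolerance = 1e-10)
  expect_gte(got, 0); expect_lte(got, 1)
})

test_that("conditional MI obeys the entropy identity and chain logic", {
  tr <- chain_table()
  bs <- binning_for("s"); bm <- binning_for("m"); bp <- binning_for("xp")
  # identity: I(X;Y|Z) = H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z), normalized by
  # H(X,Y|Z); recomputed here from joint histograms
  hxz <- entropy(joint_histogram(list(tr$task, tr$xp), list(bs, bp)))
  hyz <- entropy(joint_histogram(list(tr$mode, tr$xp), list(bm, bp)))
  hz <- entropy(histogram_density(tr$xp, bp))
  hxyz <- entropy(joint_histogram(list(tr$task, tr$mode, tr$xp),
                                  list(bs, bm, bp)))
  oracle <- (hxz + hyz - hz - hxyz) / (hxyz - hz)
  got <- conditional_mi(tr$task, tr$mode, tr$xp, bs, bm, bp)
  expect_equal(got, oracle, tolerance = 1e-10)
  # X = Y = Z: conditioning removes all shared information
  x <- tr$task
  expect_equal(conditional_mi(x, x, x, bs, bs, bs), 0, tolerance = 1e-12)
})

test_that("common-cause dependence vanishes under conditioning", {
  # explicit 2x2x2 pmf: z -> x, z -> y with 10% flip noise; exact-proportion
  # sample so the plug-in equals the closed form
  p <- array(0, c(2, 2, 2))
  for (z in 0:1) for (x in 0:1) for (y in 0:1) {
    px <- ifelse(x == z, 0.9, 0.1); py <- ifelse(y == z, 0.9, 0.1)
    p[x + 1, y + 1, z + 1] <- 0.5 * px * py
  }
  xyz <- sample_from_pmf(p, 2000)
  x <- xyz[, 1L] - 1L; y <- xyz[, 2L] - 1L; z <- c(-10, 10)[xyz[, 3L]]
  bs <- binning_for("s"); bm <- binning_for("m"); bp <- binning_for("xp")
  mi_xy <- normalized_mi(x, y, bs, bm)
  joint_xy <- apply(p, c(1, 2), sum)
  expect_equal(mi_xy, oracle_nmi(joint_xy), tolerance = 1e-10)
  set.seed(91)
  expect_gt(mi_xy, mi_threshold(bs, bm, length(x)))
  expect_lt(conditional_mi(x, y, z, bs, bm, bp), 1e-10)
  # and genuinely independent triples test independent
  set.seed(92)
  xi <- sample(0:1, 2e4, TRUE); yi <- sample(0:1, 2e4, TRUE)
  zi <- sample(c(-10, 10), 2e4, TRUE)
  expect_lt(conditional_mi(xi, yi, zi, bs, bm, bp),
            cmi_threshold(bs, bm, bp, 2e4, reps = 50))
})

test_that("null thresholds are seed-deterministic and shrink with n", {
  bs <- binning_for("s"); bm <- binning_for("m")
  set.seed(14); a <- mi_threshold(bs, bm, 4500, reps = 100)
  set.seed(14); b <- mi_threshold(bs, bm, 4500, reps = 100)
  expect_identical(a, b)
  # magnitude consistent with the plug-in bias (|X|-1)(|Y|-1)/(2 n ln 2)
  expect_lt(a, 0.01); expect_gt(a, 1e-5)
  set.seed(15); big <- mi_threshold(bs, bm, 2e5, reps = 30)
  expect_lt(big, a)
  expect_lt(big, 1e-3)
  expect_error(mi_threshold(bs, bm, 100, quantile = 1.5), "quantile")
})

test_that("skeleton learning recovers the dependence structure", {
  tr <- fixture_trials()
  set.seed(16)
  sk <- learn_skeleton(tr)
  keys <- apply(sk$edges[, c("x", "y")], 1L, function(r)
    paste(sort(r), collapse = "~"))
  must_have <- c("xhat~xp", "xhat~xs", "s~xhat", "m~xs", "s~t", "t~xs")
  expect_true(all(must_have %in% keys))
  expect_false(any(c("s~xp", "m~xp", "xp~xs") %in% keys))
  # the design-coupled pair is detected when not excluded a priori
  set.seed(17)
  sk_all <- learn_skeleton(tr[1:3000, ], exclude = NULL,
                           vars = c("xp", "xs"))
  expect_equal(nrow(sk_all$edges), 1L)
  expect_gt(sk_all$edges$mi[1L], 0.05)
  expect_error(learn_skeleton(data.frame(task = 1)), "columns")
})

test_that("an all-noise table yields an (almost surely) empty skeleton", {
  set.seed(18)
  n <- 4000
  noise <- data.frame(
    task = sample(0:1, n, TRUE), mode = sample(0:1, n, TRUE),
    xp = sample(c(-10, -5, 0, 5, 10), n, TRUE),
    xs = sample(c(seq(-20, 20, 5), NA), n, TRUE),
    response_norm = runif(n, -40, 40),
    decision_time = runif(n, 0.2, 2))
  sk <- learn_skeleton(noise, exclude = NULL)
  expect_equal(nrow(sk$edges), 0L)
})

test_that("CMI pruning removes screened-off and redundant edges", {
  tr <- fixture_trials()
  set.seed(19)
  pr <- prune_by_cmi(learn_skeleton(tr))
  rem <- vapply(pr$removals, function(r)
    paste(sort(c(r$x, r$y)), collapse = "~"), character(1L))
  # mode--time is redundant with the secondary position (sentinel bin)
  if ("m~t" %in% rem) {
    r <- pr$removals[[which(rem == "m~t")]]
    expect_true("xs" %in% r$sep)
  }
  keys <- apply(pr$edges[, c("x", "y")], 1L, function(r)
    paste(sort(r), collapse = "~"))
  expect_false("m~t" %in% keys)
  expect_false("t~xhat" %in% keys)
  expect_true(all(c("s~t", "t~xs", "m~xs") %in% keys))

  # explicit chain x -> z -> y: the indirect edge goes, the separator is z
  ch <- chain_table()
  set.seed(20)
  prc <- prune_by_cmi(learn_skeleton(ch, exclude = NULL,
                                     vars = c("s", "m", "xp")))
  keysc <- apply(prc$edges[, c("x", "y")], 1L, function(r)
    paste(sort(r), collapse = "~"))
  expect_false("m~s" %in% keysc)
  expect_true(all(c("s~xp", "m~xp") %in% keysc))

  # pure collider: no edge is removable
  co <- collider_table()
  set.seed(21)
  prco <- prune_by_cmi(learn_skeleton(co, exclude = NULL,
                                      vars = c("s", "m", "xp")))
  expect_length(prco$removals, 0L)
  expect_equal(nrow(prco$edges), 2L)
})

test_that("orientation applies the collider rule and propagation", {
  co <- collider_table()
  set.seed(22)
  pd <- orient_edges(prune_by_cmi(learn_skeleton(co, exclude = NULL,
                                                 vars = c("s", "m", "xp"))))
  expect_setequal(pd$edges$direction, c("s->xp", "m->xp"))

  # chain: z lies in the separator, so no v-structure; edges stay undirected
  ch <- chain_table()
  set.seed(23)
  pdc <- orient_edges(prune_by_cmi(learn_skeleton(ch, exclude = NULL,
                                                  vars = c("s", "m", "xp"))))
  expect_true(all(pdc$edges$direction == "undirected"))
})

test_that("the elicited network matches the generative structure", {
  tr <- fixture_trials()
  set.seed(24)
  pd <- elicit_structure(tr)
  sig <- sort(ifelse(pd$edges$direction == "undirected",
                     paste0(pmin(pd$edges$x, pd$edges$y), "~",
                            pmax(pd$edges$x, pd$edges$y)),
                     pd$edges$direction))
  expect_equal(sig, sort(c("s->xhat", "s->t", "m~xs", "xp->xhat",
                           "xs->xhat", "xs->t")))
})

test_that("context-specific local networks expose fusion vs segregation", {
  tr <- fixture_trials()
  adj_has <- function(pd, a, b)
    any((pd$edges$x == a & pd$edges$y == b) |
          (pd$edges$x == b & pd$edges$y == a))
  set.seed(25)
  mn <- csi_local_networks(tr, "s")
  expect_true(adj_has(mn$nets[["0"]], "xs", "xhat"))   # acoustic: fusion
  expect_true(adj_has(mn$nets[["0"]], "xp", "xhat"))
  expect_false(adj_has(mn$nets[["1"]], "xs", "xhat"))  # visual: segregation
  expect_true(adj_has(mn$nets[["1"]], "xp", "xhat"))
  set.seed(26)
  mu <- csi_local_networks(tr, "m")
  g0 <- mu$nets[["0"]]
  expect_false(any(g0$edges$x == "xs" | g0$edges$y == "xs"))  # xs constant
  expect_true(adj_has(g0, "s", "t"))
  expect_error(csi_local_networks(tr[tr$mode == 1L, ], "m"), "empty context")
})

test_that("factorization reads parent sets off the PDAG", {
  tr <- fixture_trials()
  set.seed(27)
  fac <- factorization(elicit_structure(tr))
  pars <- lapply(fac, `[[`, "parents")
  names(pars) <- vapply(fac, `[[`, character(1L), "var")
  expect_setequal(pars$xhat, c("s", "xp", "xs"))
  expect_setequal(pars$t, c("s", "xs"))
  expect_equal(pars$xs, "m")
  expect_length(pars$s, 0L)
  expect_length(pars$m, 0L)
  expect_length(pars$xp, 0L)

  # empty graph: product of marginals
  empty <- list(nodes = c("s", "m"), amat = matrix(0L, 2, 2,
    dimnames = list(c("s", "m"), c("s", "m"))))
  class(empty) <- "avl_pdag"
  fe <- factorization(empty, resolve = list())
  expect_true(all(lengths(lapply(fe, `[[`, "parents")) == 0L))

  # directed cycle is refused
  cyc <- empty
  cyc$amat["s", "m"] <- 1L
  cyc$amat["m", "s"] <- 1L
  expect_error(factorization(cyc, resolve = list()), "unresolved")
  cyc$amat["m", "s"] <- 0L
  cyc2 <- empty
  cyc2$nodes <- c("s", "m", "xp")
  cyc2$amat <- matrix(0L, 3, 3, dimnames = list(cyc2$nodes, cyc2$nodes))
  cyc2$amat["s", "m"] <- 1L; cyc2$amat["m", "xp"] <- 1L
  cyc2$amat["xp", "s"] <- 1L
  expect_error(factorization(cyc2, resolve = list()), "cycle")
})
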