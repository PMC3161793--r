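STRUCTURE_VARS <- c("s", "m", "xp", "xs", "xhat", "t")

#' Discretize a trial table with the canonical binnings
#'
#' Maps the six model variables (task `s`, mode `m`, primary `xp`, secondary
#' `xs`, normalized localization `xhat`, decision time `t`) to integer bin
#' codes under the fixed binning schemes. The decision-time grid extends to
#' the empirical 99th percentile, with an overflow bin above.
#'
#' @param trials A normalized trial table (see [normalize_localizations()]).
#' @param vars Variables to discretize (default all six).
#' @return A list with `codes` (data.frame of integer codes), `binnings` and
#'   `nlev` (named level counts).
#' @export
discretize_trials <- function(trials, vars = STRUCTURE_VARS) {
  cols <- list(s = "task", m = "mode", xp = "xp", xs = "xs",
               xhat = "response_norm", t = "decision_time")
  missing_cols <- setdiff(unlist(cols[vars]), names(trials))
  if (length(missing_cols) > 0L)
    stop("trial table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  binnings <- list()
  codes <- list()
  for (v in vars) {
    b <- if (v == "t") {
      binning_for("t", t_max = as.numeric(
        stats::quantile(trials$decision_time, 0.99)))
    } else binning_for(v)
    vals <- trials[[cols[[v]]]]
    if (v == "xhat")
      vals <- pmin(pmax(vals, POINTER_RANGE[1L]), POINTER_RANGE[2L])
    binnings[[v]] <- b
    codes[[v]] <- bin_index(vals, b)
  }
  list(codes = as.data.frame(codes),
       binnings = binnings,
       nlev = vapply(binnings, function(b) b$n_bins, integer(1L)))
}

# --- plug-in information measures on integer codes -------------------------

ent_counts <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

compose_codes <- function(code_list, nlev) {
  flat <- code_list[[1L]]
  mult <- 1L
  for (k in seq_along(code_list)[-1L]) {
    mult <- mult * nlev[k - 1L]
    flat <- flat + (code_list[[k]] - 1L) * mult
  }
  flat
}

nmi_codes <- function(ix, iy, nx, ny) {
  hx <- ent_counts(tabulate(ix, nx))
  hy <- ent_counts(tabulate(iy, ny))
  hxy <- ent_counts(tabulate(ix + (iy - 1L) * nx, nx * ny))
  if (hxy == 0) return(0)
  max((hx + hy - hxy) / hxy, 0)
}

cmi_codes <- function(ix, iy, iz, nx, ny, nz) {
  hz <- ent_counts(tabulate(iz, nz))
  hxz <- ent_counts(tabulate(ix + (iz - 1L) * nx, nx * nz))
  hyz <- ent_counts(tabulate(iy + (iz - 1L) * ny, ny * nz))
  hxyz <- ent_counts(tabulate(ix + (iy - 1L) * nx +
                                (iz - 1L) * nx * ny, nx * ny * nz))
  cmi <- hxz + hyz - hz - hxyz       # I(X;Y|Z), bits
  hxy_z <- hxyz - hz                 # H(X,Y|Z)
  if (hxy_z == 0) return(0)
  max(cmi / hxy_z, 0)
}

#' Normalized mutual information between two discretized variables
#'
#' Plug-in mutual information normalized by the joint entropy,
#' `I(X;Y) / H(X,Y)`, a dependence score in `[0, 1]` comparable across
#' variable pairs. Returns 0 for a degenerate (zero-entropy) joint.
#'
#' @param x,y Equal-length value vectors.
#' @param binning_x,binning_y Their [binning_for()] schemes.
#' @return Normalized MI in `[0, 1]`.
#' @export
normalized_mi <- function(x, y, binning_x, binning_y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  nmi_codes(bin_index(x, binning_x), bin_index(y, binning_y),
            binning_x$n_bins, binning_y$n_bins)
}

#' Normalized conditional mutual information
#'
#' `I(X;Y|Z) / H(X,Y|Z)` from the plug-in joint histogram; `z` may be a
#' single vector or a list of one or two vectors (the conditioning set is
#' treated as one composite variable).
#'
#' @inheritParams normalized_mi
#' @param z Conditioning values: vector or list of vectors.
#' @param binning_z Matching scheme or list of schemes.
#' @return Normalized CMI (>= 0).
#' @export
conditional_mi <- function(x, y, z, binning_x, binning_y, binning_z) {
  if (!is.list(z)) { z <- list(z); binning_z <- list(binning_z) }
  if (length(x) != length(y) || any(lengths(z) != length(x)))
    stop("all variables must have equal length")
  iz <- mapply(bin_index, z, binning_z, SIMPLIFY = FALSE)
  nz <- vapply(binning_z, function(b) b$n_bins, integer(1L))
  cmi_codes(bin_index(x, binning_x), bin_index(y, binning_y),
            compose_codes(iz, nz),
            binning_x$n_bins, binning_y$n_bins, prod(nz))
}

# --- null-calibrated thresholds --------------------------------------------

#' Null threshold for normalized MI
#'
#' Calibrates the independence decision: draws `reps` datasets of `n` iid
#' samples from discrete uniforms over each variable's bins (artificial
#' independent variables) and returns the chosen quantile of the resulting
#' normalized-MI values. Values above the threshold are declared dependent.
#'
#' @param binning_x,binning_y [binning_for()] schemes (only their level
#'   counts matter).
#' @param n Sample size of the dataset being tested.
#' @param reps Number of null replicates (default 100).
#' @param quantile Null quantile used as the threshold (default 0.95).
#' @return Threshold on the normalized-MI scale.
#' @export
mi_threshold <- function(binning_x, binning_y, n, reps = 100L,
                         quantile = 0.95) {
  if (n < 1 || reps < 1) stop("'n' and 'reps' must be positive")
  if (quantile <= 0 || quantile > 1) stop("invalid quantile")
  nx <- binning_x$n_bins; ny <- binning_y$n_bins
  vals <- vapply(seq_len(reps), function(r) {
    nmi_codes(sample.int(nx, n, replace = TRUE),
              sample.int(ny, n, replace = TRUE), nx, ny)
  }, numeric(1L))
  as.numeric(stats::quantile(vals, quantile, names = FALSE))
}

#' Null threshold for normalized CMI
#'
#' As [mi_threshold()], with the conditioning variable(s) also drawn uniform.
#'
#' @inheritParams mi_threshold
#' @param binning_z Scheme or list of schemes for the conditioning set.
#' @return Threshold on the normalized-CMI scale.
#' @export
cmi_threshold <- function(binning_x, binning_y, binning_z, n, reps = 100L,
                          quantile = 0.95) {
  if (!is.list(binning_z) || inherits(binning_z, "avl_binning"))
    binning_z <- list(binning_z)
  nx <- binning_x$n_bins; ny <- binning_y$n_bins
  nz <- prod(vapply(binning_z, function(b) b$n_bins, integer(1L)))
  vals <- vapply(seq_len(reps), function(r) {
    cmi_codes(sample.int(nx, n, replace = TRUE),
              sample.int(ny, n, replace = TRUE),
              sample.int(nz, n, replace = TRUE), nx, ny, nz)
  }, numeric(1L))
  as.numeric(stats::quantile(vals, quantile, names = FALSE))
}

# --- skeleton learning ------------------------------------------------------

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "~")

#' Pairs whose dependence is imposed by the experimental design
#'
#' The protocol yokes the secondary stimulus to the primary (offsets of
#' 0/±5/±10 deg), so the primary and secondary positions are strongly
#' dependent by construction. That coupling describes the stimulus-delivery
#' protocol, not the perception process, and is excluded from the candidate
#' edge set by default (recorded as a non-edge with an empty separator).
#'
#' @return List of character pairs.
#' @export
design_coupled_pairs <- function() list(c("xp", "xs"))

#' Learn the undirected dependence skeleton
#'
#' Computes pairwise normalized MI for every candidate variable pair and
#' retains an edge when the value exceeds its pair-specific null-calibrated
#' threshold.
#'
#' @param trials Normalized trial table.
#' @param reps,quantile Null-threshold policy (see [mi_threshold()]).
#' @param exclude List of variable pairs excluded from the candidate edge set
#'   (default: the design-coupled primary/secondary pair); use `NULL` to test
#'   every pair.
#' @param vars Variables to include (default all six).
#' @param disc Optional precomputed [discretize_trials()] result.
#' @return An object of class `avl_skeleton`: fields `nodes`, `edges` (data
#'   frame of retained edges with MI and threshold), `decisions` (all
#'   independence decisions), `sep` (separators for non-adjacent pairs, with
#'   relative decision margins), `disc` and `n`.
#' @export
learn_skeleton <- function(trials, reps = 100L, quantile = 0.95,
                           exclude = design_coupled_pairs(),
                           vars = STRUCTURE_VARS, disc = NULL) {
  if (is.null(disc)) disc <- discretize_trials(trials, vars)
  codes <- disc$codes; nlev <- disc$nlev
  n <- nrow(codes)
  excl_keys <- vapply(exclude %||% list(), function(p) pair_key(p[1L], p[2L]),
                      character(1L))

  pairs <- utils::combn(vars, 2L, simplify = FALSE)
  thr_cache <- new.env(parent = emptyenv())
  edges <- list(); decisions <- list(); sep <- list()

  for (p in pairs) {
    key <- pair_key(p[1L], p[2L])
    if (key %in% excl_keys) {
      # design-imposed coupling: treated as a non-edge with empty separator
      sep[[key]] <- list(set = character(0L), margin = 1, how = "design")
      next
    }
    ck <- paste(sort(nlev[p]), collapse = "x")
    if (is.null(thr_cache[[ck]]))
      thr_cache[[ck]] <- mi_threshold(disc$binnings[[p[1L]]],
                                      disc$binnings[[p[2L]]],
                                      n, reps, quantile)
    thr <- thr_cache[[ck]]
    stat <- nmi_codes(codes[[p[1L]]], codes[[p[2L]]],
                      nlev[[p[1L]]], nlev[[p[2L]]])
    dep <- stat > thr
    decisions[[length(decisions) + 1L]] <-
      data.frame(x = p[1L], y = p[2L], cond = "", stat = stat,
                 threshold = thr, verdict = ifelse(dep, "dependent",
                                                   "independent"))
    if (dep) {
      edges[[length(edges) + 1L]] <- data.frame(x = p[1L], y = p[2L],
                                                mi = stat, threshold = thr)
    } else {
      sep[[key]] <- list(set = character(0L),
                         margin = if (thr > 0) (thr - stat) / thr else 0,
                         how = "marginal")
    }
  }

  out <- list(nodes = vars,
              edges = if (length(edges)) do.call(rbind, edges) else
                data.frame(x = character(), y = character(),
                           mi = numeric(), threshold = numeric()),
              decisions = do.call(rbind, decisions),
              sep = sep, disc = disc, n = n,
              policy = list(reps = reps, quantile = quantile,
                            exclude = exclude))
  class(out) <- "avl_skeleton"
  out
}

#' @export
print.avl_skeleton <- function(x, ...) {
  cat(sprintf("Dependence skeleton: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    cat(paste0("  ", x$edges$x, " -- ", x$edges$y,
               sprintf("  (MI %.4f > %.4f)", x$edges$mi, x$edges$threshold),
               collapse = "\n"), "\n")
  invisible(x)
}

# adjacency list from an edge data.frame
adj_of <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$x[i]]] <- c(adj[[edges$x[i]]], edges$y[i])
    adj[[edges$y[i]]] <- c(adj[[edges$y[i]]], edges$x[i])
  }
  adj
}

# Variables the perception process outputs; conditioning-set candidates are
# drawn from the input/context tier only. Conditioning an edge test on an
# output (a common effect of the inputs) invites selection bias, and the
# high-resolution output binnings would inflate the plug-in bias of the
# tests without adding separating power.
OUTPUT_VARS <- c("xhat", "t")

cond_candidates <- function(adj, x, y, max_order) {
  pools <- list(setdiff(setdiff(adj[[x]], y), OUTPUT_VARS),
                setdiff(setdiff(adj[[y]], x), OUTPUT_VARS))
  sets <- list()
  for (pool in pools) {
    for (ord in seq_len(min(max_order, length(pool)))) {
      for (cmb in utils::combn(pool, ord, simplify = FALSE)) {
        sets[[length(sets) + 1L]] <- sort(cmb)
      }
    }
  }
  unique(sets)
}

#' Prune skeleton edges by conditional mutual information
#'
#' Tests every remaining edge against null-calibrated CMI thresholds over
#' conditioning sets drawn from the endpoints' adjacencies (orders 1 to
#' `max_order`). Removals are greedy in ascending order of the normalized
#' CMI statistic, so the most decisively screened-off edge goes first;
#' separators are recorded for the orientation stage. A conditioning
#' variable `z` is vetoed for edge `x--y` when the edge between `z` and an
#' endpoint was itself removed with the other endpoint as separator:
#' mutually redundant variables (such as the presentation mode and the
#' secondary position, whose sentinel bin encodes the mode) would otherwise
#' screen each other off and disconnect both.
#'
#' @param skeleton An [learn_skeleton()] result.
#' @param max_order Largest conditioning-set size (default 2).
#' @param reps,quantile Null-threshold policy; defaults inherited from the
#'   skeleton.
#' @return An `avl_skeleton` with pruned `edges`, extended `decisions` and
#'   `sep`, and a `removals` log (edge, separator, statistic, threshold).
#' @export
prune_by_cmi <- function(skeleton, max_order = 2L, reps = NULL,
                         quantile = NULL) {
  reps <- reps %||% skeleton$policy$reps
  quantile <- quantile %||% skeleton$policy$quantile
  disc <- skeleton$disc; codes <- disc$codes; nlev <- disc$nlev
  n <- skeleton$n
  edges <- skeleton$edges
  sep <- skeleton$sep
  decisions <- list(skeleton$decisions)
  removals <- list()
  thr_cache <- new.env(parent = emptyenv())
  stat_cache <- new.env(parent = emptyenv())

  # edges removed with a separator containing the other endpoint, per node
  vetoed <- function(x, y, set) {
    for (z in set) {
      for (r in removals) {
        if (setequal(c(r$x, r$y), c(x, z)) && y %in% r$sep) return(TRUE)
        if (setequal(c(r$x, r$y), c(y, z)) && x %in% r$sep) return(TRUE)
      }
    }
    FALSE
  }

  test_set <- function(x, y, set) {
    skey <- paste(x, y, paste(set, collapse = ","), sep = "|")
    if (!is.null(stat_cache[[skey]])) return(stat_cache[[skey]])
    iz <- compose_codes(codes[set], nlev[set])
    nz <- prod(nlev[set])
    stat <- cmi_codes(codes[[x]], codes[[y]], iz,
                      nlev[[x]], nlev[[y]], nz)
    tk <- paste(c(sort(nlev[c(x, y)]), nz), collapse = "x")
    if (is.null(thr_cache[[tk]]))
      thr_cache[[tk]] <- cmi_threshold(disc$binnings[[x]],
                                       disc$binnings[[y]],
                                       disc$binnings[set], n, reps, quantile)
    res <- list(stat = stat, thr = thr_cache[[tk]])
    stat_cache[[skey]] <- res
    res
  }

  repeat {
    adj <- adj_of(edges, skeleton$nodes)
    best <- NULL
    for (i in seq_len(nrow(edges))) {
      x <- edges$x[i]; y <- edges$y[i]
      for (set in cond_candidates(adj, x, y, max_order)) {
        if (vetoed(x, y, set)) next
        res <- test_set(x, y, set)
        margin <- res$stat - res$thr
        decisions[[length(decisions) + 1L]] <-
          data.frame(x = x, y = y, cond = paste(set, collapse = ","),
                     stat = res$stat, threshold = res$thr,
                     verdict = ifelse(res$stat > res$thr, "dependent",
                                      "independent"))
        better <- res$stat <= res$thr &&
          (is.null(best) || res$stat < best$stat ||
             (res$stat == best$stat && margin < best$margin))
        if (better) {
          best <- list(i = i, x = x, y = y, set = set, stat = res$stat,
                       thr = res$thr, margin = margin)
        }
      }
    }
    if (is.null(best)) break
    removals[[length(removals) + 1L]] <-
      list(x = best$x, y = best$y, sep = best$set,
           stat = best$stat, threshold = best$thr)
    sep[[pair_key(best$x, best$y)]] <-
      list(set = best$set,
           margin = if (best$thr > 0) (best$thr - best$stat) / best$thr else 0,
           how = "cmi")
    edges <- edges[-best$i, , drop = FALSE]
  }

  out <- skeleton
  out$edges <- edges
  out$decisions <- unique(do.call(rbind, decisions))
  out$sep <- sep
  out$removals <- removals
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
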