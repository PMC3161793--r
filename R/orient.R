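# Partially directed acyclic graph produced by the orientation stage.
# Adjacency matrix convention (bnlearn-style): amat[x, y] = 1 & amat[y, x] = 0
# encodes x -> y; both 1 encodes an undirected edge.

#' Orient a pruned skeleton into a PDAG
#'
#' Applies the collider rule — for every unshielded triple `x - z - y` with
#' `z` outside the recorded separator of `(x, y)`, orient `x -> z <- y` —
#' followed by the standard propagation (Meek) rules to exhaustion.
#' Collider candidates are processed in decreasing order of the separation
#' margin (how decisively the pair tested independent), so orientations
#' backed by unambiguous independences are applied first; any candidate that
#' would reverse an existing arrow is skipped and reported in `conflicts`
#' rather than silently resolved.
#'
#' @param skeleton A pruned [prune_by_cmi()] skeleton.
#' @return An object of class `avl_pdag`: `nodes`, `amat`, `edges` (with a
#'   `direction` column), `vstructs`, `conflicts` and the inherited
#'   separator table.
#' @export
orient_edges <- function(skeleton) {
  nodes <- skeleton$nodes
  k <- length(nodes)
  amat <- matrix(0L, k, k, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(skeleton$edges))) {
    amat[skeleton$edges$x[i], skeleton$edges$y[i]] <- 1L
    amat[skeleton$edges$y[i], skeleton$edges$x[i]] <- 1L
  }
  sep <- skeleton$sep
  adjacent <- function(a, b) amat[a, b] == 1L || amat[b, a] == 1L

  # collider candidates over unshielded triples
  cand <- list()
  for (z in nodes) {
    nb <- nodes[amat[z, ] == 1L | amat[, z] == 1L]
    if (length(nb) < 2L) next
    for (pq in utils::combn(nb, 2L, simplify = FALSE)) {
      x <- pq[1L]; y <- pq[2L]
      if (adjacent(x, y)) next
      s <- sep[[pair_key(x, y)]]
      if (is.null(s)) next
      if (!(z %in% s$set))
        cand[[length(cand) + 1L]] <- list(x = x, z = z, y = y,
                                          margin = s$margin)
    }
  }
  conflicts <- list()
  vstructs <- list()
  if (length(cand)) {
    ord <- order(vapply(cand, function(c) -c$margin, numeric(1L)))
    for (c in cand[ord]) {
      # applying x -> z <- y must not reverse an existing arrow
      rev1 <- amat[c$x, c$z] == 0L && amat[c$z, c$x] == 1L
      rev2 <- amat[c$y, c$z] == 0L && amat[c$z, c$y] == 1L
      if (rev1 || rev2) {
        conflicts[[length(conflicts) + 1L]] <- c
        next
      }
      amat[c$z, c$x] <- 0L
      amat[c$z, c$y] <- 0L
      vstructs[[length(vstructs) + 1L]] <- c
    }
  }

  directed <- function(a, b) amat[a, b] == 1L && amat[b, a] == 0L
  undirected <- function(a, b) amat[a, b] == 1L && amat[b, a] == 1L

  # Meek propagation rules
  repeat {
    changed <- FALSE
    for (a in nodes) for (b in nodes) {
      if (!undirected(a, b)) next
      # R1: c -> a - b with c, b nonadjacent  =>  a -> b
      for (cc in nodes) {
        if (directed(cc, a) && !adjacent(cc, b) && cc != b) {
          amat[b, a] <- 0L; changed <- TRUE; break
        }
      }
      if (!undirected(a, b)) next
      # R2: a -> c -> b with a - b  =>  a -> b
      for (cc in nodes) {
        if (directed(a, cc) && directed(cc, b)) {
          amat[b, a] <- 0L; changed <- TRUE; break
        }
      }
      if (!undirected(a, b)) next
      # R3: a - c1 -> b, a - c2 -> b, c1, c2 nonadjacent  =>  a -> b
      cs <- nodes[vapply(nodes, function(cc)
        undirected(a, cc) && directed(cc, b), logical(1L))]
      if (length(cs) >= 2L) {
        pairs <- utils::combn(cs, 2L, simplify = FALSE)
        if (any(vapply(pairs, function(p) !adjacent(p[1L], p[2L]),
                       logical(1L)))) {
          amat[b, a] <- 0L; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  edges <- skeleton$edges
  edges$direction <- vapply(seq_len(nrow(edges)), function(i) {
    x <- edges$x[i]; y <- edges$y[i]
    if (amat[x, y] == 1L && amat[y, x] == 0L) paste0(x, "->", y)
    else if (amat[y, x] == 1L && amat[x, y] == 0L) paste0(y, "->", x)
    else "undirected"
  }, character(1L))

  out <- list(nodes = nodes, amat = amat, edges = edges,
              vstructs = vstructs, conflicts = conflicts,
              sep = skeleton$sep, disc = skeleton$disc, n = skeleton$n)
  class(out) <- "avl_pdag"
  out
}

#' @export
print.avl_pdag <- function(x, ...) {
  cat(sprintf("PDAG: %d nodes, %d edges (%d conflicts reported)\n",
              length(x$nodes), nrow(x$edges), length(x$conflicts)))
  if (nrow(x$edges)) {
    lab <- ifelse(x$edges$direction == "undirected",
                  paste(x$edges$x, "--", x$edges$y), x$edges$direction)
    cat(paste0("  ", lab, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Elicit the full network from a trial table
#'
#' Convenience wrapper chaining [learn_skeleton()], [prune_by_cmi()] and
#' [orient_edges()].
#'
#' @inheritParams learn_skeleton
#' @param max_order Largest conditioning-set size for pruning.
#' @return An `avl_pdag`.
#' @export
elicit_structure <- function(trials, reps = 100L, quantile = 0.95,
                             exclude = design_coupled_pairs(),
                             vars = STRUCTURE_VARS, max_order = 2L) {
  sk <- learn_skeleton(trials, reps, quantile, exclude, vars)
  orient_edges(prune_by_cmi(sk, max_order))
}

#' Context-specific-independence multinet
#'
#' Fixes a binary context variable to each of its values, restricts the
#' table, drops the context column and re-runs the full elicitation over the
#' remaining five variables. The local networks expose independences that
#' hold only in one context (e.g. fusion of the secondary stimulus into the
#' percept in the acoustic task but not the visual one).
#'
#' @param trials Normalized trial table.
#' @param context_var `"s"` (task) or `"m"` (mode of presentation).
#' @inheritParams elicit_structure
#' @return An object of class `avl_multinet`: a list of `avl_pdag` local
#'   networks indexed by context value (`"0"`, `"1"`).
#' @export
csi_local_networks <- function(trials, context_var = c("s", "m"),
                               reps = 100L, quantile = 0.95,
                               exclude = design_coupled_pairs(),
                               max_order = 2L) {
  context_var <- match.arg(context_var)
  col <- c(s = "task", m = "mode")[[context_var]]
  vars <- setdiff(STRUCTURE_VARS, context_var)
  nets <- list()
  for (val in c(0L, 1L)) {
    sub <- trials[trials[[col]] == val, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty context subset for ", col, " = ", val)
    nets[[as.character(val)]] <-
      elicit_structure(sub, reps, quantile, exclude, vars, max_order)
  }
  out <- list(context = context_var, nets = nets)
  class(out) <- "avl_multinet"
  out
}

#' @export
print.avl_multinet <- function(x, ...) {
  cat(sprintf("Multinet over context '%s'\n", x$context))
  for (v in names(x$nets)) {
    cat(sprintf("-- context %s = %s --\n", x$context, v))
    print(x$nets[[v]])
  }
  invisible(x)
}

#' Topological factorization of a PDAG
#'
#' Reads off the joint-probability factorization implied by the directed
#' part of the graph. Remaining undirected edges must be resolved by the
#' `resolve` argument (by default the mode-of-presentation edge is oriented
#' mode -> secondary position, matching the conditional `P(xs | m)` of the
#' generative model).
#'
#' @param pdag An `avl_pdag`.
#' @param resolve List of `c(from, to)` orientations for undirected edges.
#' @return A list of class `avl_factorization`: per variable (in topological
#'   order) a list with `var` and `parents`.
#' @export
factorization <- function(pdag, resolve = list(c("m", "xs"))) {
  amat <- pdag$amat
  for (r in resolve) {
    if (amat[r[1L], r[2L]] == 1L && amat[r[2L], r[1L]] == 1L)
      amat[r[2L], r[1L]] <- 0L
  }
  und <- which(amat == 1L & t(amat) == 1L, arr.ind = TRUE)
  if (nrow(und) > 0L)
    stop("unresolved undirected edges remain; extend 'resolve'")
  nodes <- pdag$nodes
  parents <- lapply(nodes, function(v) nodes[amat[, v] == 1L])
  names(parents) <- nodes
  # Kahn topological order
  order <- character(0L)
  remaining <- nodes
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v)
      all(parents[[v]] %in% order), logical(1L))]
    if (!length(ready)) stop("directed cycle in PDAG")
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  out <- lapply(order, function(v) list(var = v, parents = parents[[v]]))
  class(out) <- "avl_factorization"
  out
}

#' The canonical factorization of the elicited model
#'
#' `P(s) P(m) P(xp) P(xs|m) P(xhat|s,xp,xs) P(t|s,xs)`: task, mode and
#' primary position are exogenous; the secondary position depends on the
#' mode (sentinel on unisensory trials); the percept depends on task and
#' both stimulus positions; the decision time depends on task and secondary
#' position.
#'
#' @return An `avl_factorization`.
#' @export
canonical_factorization <- function() {
  out <- list(list(var = "s", parents = character(0L)),
              list(var = "m", parents = character(0L)),
              list(var = "xp", parents = character(0L)),
              list(var = "xs", parents = "m"),
              list(var = "xhat", parents = c("s", "xp", "xs")),
              list(var = "t", parents = c("s", "xs")))
  class(out) <- "avl_factorization"
  out
}

#' @export
print.avl_factorization <- function(x, ...) {
  terms <- vapply(x, function(f) {
    if (length(f$parents)) sprintf("P(%s|%s)", f$var,
                                   paste(f$parents, collapse = ","))
    else sprintf("P(%s)", f$var)
  }, character(1L))
  cat("Factorization:", paste(terms, collapse = " "), "\n")
  invisible(x)
}
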