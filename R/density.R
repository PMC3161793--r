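#' Histogram binning schemes for the model variables
#'
#' Fixed discretizations used throughout the information-theoretic analysis:
#' \describe{
#'   \item{xp}{5 bins of width 5 centered on the primary positions.}
#'   \item{xs}{9 width-5 bins centered on -20..20 plus one sentinel bin for
#'     unimodal trials (10 bins).}
#'   \item{xhat}{15 bins: 13 width-5 bins centered on -30..30 and two
#'     boundary bins covering \[-40, -32.5) and (32.5, 40\].}
#'   \item{s, m}{two bins centered on 0 and 1.}
#'   \item{t}{width-0.2 bins centered on 0.1 + 0.2k covering \[0, t_max\],
#'     plus one overflow bin for larger values.}
#' }
#' Bin assignment uses half-open intervals `[edge_i, edge_{i+1})` with the
#' last regular bin closed; values at the 32.5-deg boundaries belong to the
#' inner width-5 bins.
#'
#' @param kind One of `"xp"`, `"xs"`, `"xhat"`, `"s"`, `"m"`, `"t"`.
#' @param t_max Upper bound of the regular decision-time grid (s); required
#'   for `kind = "t"` (a data-driven 99th percentile is the usual choice).
#' @return An object of class `avl_binning` with fields `kind`, `edges`,
#'   `centers`, `n_bins`, and the indices `sentinel_bin` / `overflow_bin`
#'   where applicable.
#' @examples
#' binning_for("xhat")$n_bins  # 15
#' @export
binning_for <- function(kind = c("xp", "xs", "xhat", "s", "m", "t"),
                        t_max = NULL) {
  kind <- match.arg(kind)
  b <- switch(kind,
    xp = list(edges = seq(-12.5, 12.5, by = 5),
              centers = seq(-10, 10, by = 5)),
    xs = list(edges = seq(-22.5, 22.5, by = 5),
              centers = seq(-20, 20, by = 5), sentinel = TRUE),
    xhat = list(edges = c(-40, seq(-32.5, 32.5, by = 5), 40),
                centers = c(-36.25, seq(-30, 30, by = 5), 36.25)),
    s = list(edges = c(-0.5, 0.5, 1.5), centers = c(0, 1)),
    m = list(edges = c(-0.5, 0.5, 1.5), centers = c(0, 1)),
    t = {
      if (is.null(t_max) || !is.finite(t_max) || t_max <= 0)
        stop("'t_max' (a positive range bound) is required for the T binning")
      k <- max(1L, ceiling((t_max - 0.2) / 0.2))
      list(edges = seq(0, by = 0.2, length.out = k + 2L),
           centers = seq(0.1, by = 0.2, length.out = k + 1L),
           overflow = TRUE)
    })
  edges <- b$edges
  centers <- b$centers
  n_bins <- length(centers) + isTRUE(b$sentinel) + isTRUE(b$overflow)
  out <- list(kind = kind, edges = edges, centers = centers, n_bins = n_bins,
              sentinel_bin = if (isTRUE(b$sentinel)) n_bins else NA_integer_,
              overflow_bin = if (isTRUE(b$overflow)) n_bins else NA_integer_)
  class(out) <- "avl_binning"
  out
}

#' @export
print.avl_binning <- function(x, ...) {
  cat(sprintf("Binning '%s': %d bins", x$kind, x$n_bins))
  if (!is.na(x$sentinel_bin)) cat(" (incl. sentinel)")
  if (!is.na(x$overflow_bin)) cat(" (incl. overflow)")
  cat("\n")
  invisible(x)
}

#' Map values to bin indices
#'
#' @param values Numeric values (`NA` encodes the unimodal sentinel and is
#'   only admissible for binnings with a sentinel bin).
#' @param binning An [binning_for()] scheme.
#' @return Integer bin indices in `1..n_bins`.
#' @export
bin_index <- function(values, binning) {
  ix <- findInterval(values, binning$edges, rightmost.closed = TRUE,
                     left.open = FALSE)
  n_reg <- length(binning$centers)
  if (binning$kind == "xhat") {
    # the 32.5-deg boundary belongs to the inner width-5 bin, not the edge bin
    up <- !is.na(values) & values == binning$edges[length(binning$edges) - 1L]
    ix[up] <- n_reg - 1L
  }
  bad <- !is.na(values) & (ix < 1L | ix > n_reg)
  if (!is.na(binning$overflow_bin)) {
    over <- !is.na(values) & values >= binning$edges[length(binning$edges)]
    ix[over] <- binning$overflow_bin
    bad <- bad & !over
  }
  if (any(bad)) stop("values outside the binning range: ",
                     paste(utils::head(values[bad], 3L), collapse = ", "))
  if (anyNA(values)) {
    if (is.na(binning$sentinel_bin))
      stop("NA values are only admissible for binnings with a sentinel bin")
    ix[is.na(values)] <- binning$sentinel_bin
  }
  as.integer(ix)
}

#' Histogram (plug-in) probability mass estimate
#'
#' Maximum-likelihood pmf estimate: bin counts divided by the sample size.
#'
#' @param values Numeric values mappable under `binning`.
#' @param binning An [binning_for()] scheme.
#' @return An object of class `avl_hist` with fields `binnings`, `prob`
#'   (a vector, or an array for joints) and `n`.
#' @export
histogram_density <- function(values, binning) {
  if (length(values) == 0L) stop("empty sample")
  ix <- bin_index(values, binning)
  p <- tabulate(ix, nbins = binning$n_bins) / length(values)
  out <- list(binnings = list(binning), prob = p, n = length(values))
  class(out) <- "avl_hist"
  out
}

#' Joint histogram over two or three variables
#'
#' @param columns A list of 2 or 3 equal-length numeric vectors.
#' @param binnings A list of matching [binning_for()] schemes.
#' @return An `avl_hist` whose `prob` is a 2- or 3-way array; marginalizing
#'   any axis reproduces the corresponding 1-D histogram exactly.
#' @export
joint_histogram <- function(columns, binnings) {
  stopifnot(is.list(columns), is.list(binnings),
            length(columns) %in% c(2L, 3L),
            length(columns) == length(binnings))
  n <- unique(lengths(columns))
  if (length(n) != 1L) stop("columns must have equal length")
  if (n == 0L) stop("empty sample")
  ix <- mapply(bin_index, columns, binnings, SIMPLIFY = FALSE)
  dims <- vapply(binnings, function(b) b$n_bins, integer(1L))
  counts <- array(0L, dim = dims)
  flat <- ix[[1L]]
  mult <- 1L
  for (k in seq_along(ix)[-1L]) {
    mult <- mult * dims[k - 1L]
    flat <- flat + (ix[[k]] - 1L) * mult
  }
  tab <- tabulate(flat, nbins = prod(dims))
  counts[] <- tab
  out <- list(binnings = binnings, prob = counts / n, n = n)
  class(out) <- "avl_hist"
  out
}

#' Shannon entropy of a histogram (bits)
#'
#' Plug-in entropy with the convention `0 * log(0) = 0`.
#'
#' @param hist An `avl_hist`, or a bare (joint) probability array.
#' @return Entropy in bits.
#' @export
entropy <- function(hist) {
  p <- if (inherits(hist, "avl_hist")) hist$prob else hist
  p <- as.numeric(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}
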