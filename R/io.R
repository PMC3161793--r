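UNIMODAL_TOKEN <- "NA_UNIMODAL"

#' Write / read a trial table as delimited text
#'
#' Comma-separated with header; the unimodal sentinel in `xs` is serialized
#' as the literal token `NA_UNIMODAL`.
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `path` (write) or the trial table (read).
#' @export
write_trials <- function(trials, path) {
  out <- as.data.frame(trials)
  out$xs <- ifelse(is.na(out$xs), UNIMODAL_TOKEN,
                   format(out$xs, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject", "task", "mode", "xp", "xs")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols))
    stop("malformed trial table, missing columns: ",
         paste(missing_cols, collapse = ", "))
  out$xs <- suppressWarnings(
    ifelse(out$xs == UNIMODAL_TOKEN, NA_real_, as.numeric(out$xs)))
  class(out) <- c("avl_trials", "data.frame")
  out
}

#' Write / read a flat key=value configuration file
#'
#' Mirrors [sim_params()]: scalar fields as `name = value`, the four
#' decision-time locations as `mu_logT_a_uni` etc.
#'
#' @param params An `avl_params` object.
#' @param path File path.
#' @return `path` (write) or an `avl_params` (read).
#' @export
write_config <- function(params, path) {
  flat <- params
  mu <- flat$mu_logT
  flat$mu_logT <- NULL
  for (nm in names(mu)) flat[[paste0("mu_logT_", nm)]] <- mu[[nm]]
  lines <- sprintf("%s = %.17g", names(flat), as.numeric(unlist(flat)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(
    lapply(kv, function(p) as.numeric(p[2L])),
    vapply(kv, `[`, character(1L), 1L))
  mu_names <- grep("^mu_logT_", names(vals), value = TRUE)
  args <- vals[setdiff(names(vals), mu_names)]
  if (length(mu_names)) {
    mu <- unlist(vals[mu_names])
    names(mu) <- sub("^mu_logT_", "", mu_names)
    args$mu_logT <- mu
  }
  if (is.null(args$seed)) stop("config must set 'seed'")
  do.call(sim_params, args)
}

#' Export a graph as edge-list text and DOT
#'
#' @param graph An `avl_skeleton` or `avl_pdag`.
#' @param path Output path for the edge list (`node,node,direction,mi`); a
#'   companion `.dot` file is written next to it.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path) {
  edges <- graph$edges
  direction <- if ("direction" %in% names(edges)) edges$direction else
    rep("undirected", nrow(edges))
  df <- data.frame(from = edges$x, to = edges$y, direction = direction,
                   mi = edges$mi)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  dot <- c("digraph avlocnet {",
           paste0("  ", graph$nodes, ";"),
           vapply(seq_len(nrow(df)), function(i) {
             arrow <- if (df$direction[i] == "undirected") "dir=none"
             else ""
             from <- df$from[i]; to <- df$to[i]
             if (grepl("->", df$direction[i])) {
               ft <- strsplit(df$direction[i], "->", fixed = TRUE)[[1L]]
               from <- ft[1L]; to <- ft[2L]
             }
             sprintf("  %s -> %s [label=\"%.4f\"%s];", from, to, df$mi[i],
                     if (nzchar(arrow)) paste0(", ", arrow) else "")
           }, character(1L)),
           "}")
  writeLines(dot, sub("\\.[^.]*$", ".dot", path))
  invisible(path)
}
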