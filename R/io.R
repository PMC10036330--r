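# File I/O: hyperedge-list text format, pairwise edge lists, GraphML, CSV
# results with JSON provenance sidecars.

#' Read and write the hyperedge-list text format
#'
#' One hyperedge per line, whitespace-separated integer node IDs (0-based on
#' disk): two IDs form an edge, three a triangle. Lines starting with `#` are
#' comments; a header comment `#n=<N>` fixes the node count (otherwise
#' `n = max ID + 1`). Duplicate hyperedges are deduplicated with a warning;
#' repeated nodes within a hyperedge or non-integer IDs are hard errors naming
#' the offending line.
#'
#' @param path file path.
#' @return `read_hyperedges()` returns a [hypergraph()];
#'   `write_hyperedges()` returns `path` invisibly.
#' @export
read_hyperedges <- function(path) {
  lines <- readLines(path)
  n_fixed <- NA_integer_
  hdr <- grep("^#\\s*n\\s*=", lines)
  if (length(hdr)) {
    n_fixed <- as.integer(sub("^#\\s*n\\s*=\\s*", "", lines[hdr[1]]))
  }
  edges <- vector("list", length(lines))
  triangles <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (!nzchar(s) || startsWith(s, "#")) next
    toks <- strsplit(s, "\\s+")[[1]]
    ids <- suppressWarnings(as.numeric(toks))
    if (anyNA(ids) || any(ids != floor(ids)) || any(ids < 0)) {
      stop(sprintf("line %d: non-integer or negative node ID", ln), call. = FALSE)
    }
    if (anyDuplicated(ids)) {
      stop(sprintf("line %d: repeated node within a hyperedge", ln), call. = FALSE)
    }
    if (length(ids) == 2) edges[[ln]] <- ids
    else if (length(ids) == 3) triangles[[ln]] <- ids
    else stop(sprintf("line %d: hyperedge must have 2 or 3 nodes, found %d",
                      ln, length(ids)), call. = FALSE)
  }
  e <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])
  t <- do.call(rbind, triangles[!vapply(triangles, is.null, logical(1))])
  max_id <- max(c(-1, e, t))
  n <- if (is.na(n_fixed)) as.integer(max_id + 1) else n_fixed
  if (n < max_id + 1) stop("header node count smaller than max node ID + 1", call. = FALSE)
  e <- dedupe_rows(e + 1, "edge")
  t <- dedupe_rows(t + 1, "triangle")
  hypergraph(n, edges = e, triangles = t)
}

dedupe_rows <- function(x, what) {
  if (is.null(x) || length(x) == 0) return(NULL)
  x <- sort_within_rows(x)
  dup <- duplicated(x)
  if (any(dup)) {
    warning(sprintf("%d duplicate %s(s) removed", sum(dup), what), call. = FALSE)
    x <- x[!dup, , drop = FALSE]
  }
  x
}

#' @rdname read_hyperedges
#' @param H a [hypergraph()].
#' @export
write_hyperedges <- function(H, path) {
  stopifnot(is_hypergraph(H))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#n=%d", H$n), con)
  if (nrow(H$edges)) {
    writeLines(paste(H$edges[, 1] - 1, H$edges[, 2] - 1), con)
  }
  if (nrow(H$triangles)) {
    writeLines(paste(H$triangles[, 1] - 1, H$triangles[, 2] - 1,
                     H$triangles[, 3] - 1), con)
  }
  invisible(path)
}

#' Read a pairwise graph from an edge list or GraphML
#'
#' Edge-list files are two whitespace-separated 0-based integer IDs per line
#' (`#` comments allowed); GraphML is read through igraph (the connectome use
#' case). The result is returned as a triangle-free [hypergraph()] so it can
#' flow directly into [flag_complex()]-style constructions via
#' [as_igraph()] or into the stability machinery.
#'
#' @param path file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return a [hypergraph()] with no triangles.
#' @export
read_pairwise_graph <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
    el <- igraph::as_edgelist(g, names = FALSE)
    return(hypergraph(igraph::vcount(g), edges = if (nrow(el)) el else NULL))
  }
  H <- read_hyperedges(path)
  if (nrow(H$triangles)) stop("edge list contains 3-node lines", call. = FALSE)
  H
}

#' Convert the pairwise layer of a hypergraph to an igraph graph
#'
#' @param H a [hypergraph()].
#' @return an igraph undirected simple graph on the same node set.
#' @export
as_igraph <- function(H) {
  stopifnot(is_hypergraph(H))
  g <- igraph::graph_from_edgelist(H$edges, directed = FALSE)
  igraph::add_vertices(g, max(0L, H$n - igraph::vcount(g)))
}

# CSV writer (single tabular dialect: comma-separated, '.' decimal, header
# row, no index column) plus a JSON provenance sidecar sufficient to
# regenerate the file.
write_result_csv <- function(df, path, provenance) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- paste0(path, ".json")
  provenance$package_version <- as.character(utils::packageVersion("triadsync"))
  jsonlite::write_json(provenance, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(csv = path, sidecar = sidecar))
}
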