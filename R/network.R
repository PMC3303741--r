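#' Construct a directed gene network
#'
#' A `grn_network` is a node set plus a set of directed edges. During Bayesian
#' scoring the structure must be a DAG (`acyclic = TRUE`); the final united
#' network produced by [unite()] permits cycles (`acyclic = FALSE`).
#'
#' @param nodes Character vector of gene identifiers (opaque strings, no case
#'   folding), order preserved.
#' @param edges A data frame with columns `from` and `to`, or `NULL` for an
#'   edgeless network. Self-loops and duplicate ordered pairs are rejected.
#' @param acyclic If `TRUE` (default) the edge set must be acyclic.
#'
#' @return An object of class `grn_network` with fields `nodes`, `edges`
#'   (a tibble with columns `from`, `to`) and `acyclic`.
#' @examples
#' grn_network(c("a", "b", "c"), data.frame(from = "a", to = "b"))
#' @export
grn_network <- function(nodes, edges = NULL, acyclic = TRUE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    abort(paste0("duplicate node id: ", nodes[duplicated(nodes)][1]))
  }
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(from = character(), to = character())
  }
  edges <- as_tibble(edges)[, c("from", "to")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  unknown <- setdiff(c(edges$from, edges$to), nodes)
  if (length(unknown) > 0) {
    abort(paste0("edge endpoint not in node set: ", unknown[1]))
  }
  if (any(edges$from == edges$to)) {
    abort("self-loops are not allowed")
  }
  if (anyDuplicated(paste(edges$from, edges$to))) {
    abort("duplicate directed edge")
  }
  net <- structure(
    list(nodes = nodes, edges = edges, acyclic = isTRUE(acyclic)),
    class = "grn_network"
  )
  if (net$acyclic && !is_acyclic(net)) {
    abort("edge set contains a directed cycle but acyclic = TRUE")
  }
  net
}

#' Test whether a network's edge set is acyclic
#'
#' @param net A [grn_network()].
#' @return `TRUE` if the directed edge set contains no cycle.
#' @export
is_acyclic <- function(net) {
  adjacency_is_acyclic(network_adjacency(net))
}

# 0/1 adjacency matrix in node order
network_adjacency <- function(net) {
  n <- length(net$nodes)
  adj <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    adj[cbind(
      match(net$edges$from, net$nodes),
      match(net$edges$to, net$nodes)
    )] <- 1L
  }
  adj
}

# canonical sorted edge tibble, used for equality and reproducible output
sorted_edges <- function(net) {
  arrange(net$edges, .data$from, .data$to)
}

#' Compare two networks for structural equality
#'
#' Node sets (as sets) and directed edge sets must coincide; node order and
#' the acyclicity flag are ignored.
#'
#' @param a,b [grn_network()] objects.
#' @return Logical scalar.
#' @export
network_equal <- function(a, b) {
  setequal(a$nodes, b$nodes) &&
    nrow(a$edges) == nrow(b$edges) &&
    identical(
      paste(sorted_edges(a)$from, sorted_edges(a)$to),
      paste(sorted_edges(b)$from, sorted_edges(b)$to)
    )
}

#' @export
print.grn_network <- function(x, ...) {
  cat(
    "<grn_network> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges",
    if (x$acyclic) " (DAG)" else " (cycles permitted)", "\n",
    sep = ""
  )
  if (nrow(x$edges) > 0) {
    e <- sorted_edges(x)
    cat("  ", paste(e$from, "->", e$to), sep = "\n  ")
  }
  invisible(x)
}

#' Write a network to file
#'
#' Supported formats: `"edge-list"` (two tab-separated columns, no header),
#' `"sif"` (Cytoscape SIF, `source regulates target`, isolated nodes on their
#' own line) and `"graphml"`. Edge-list and SIF rows are sorted
#' lexicographically by (source, target) so outputs diff reproducibly.
#'
#' @param net A [grn_network()].
#' @param path Output file path.
#' @param format One of `"edge-list"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge-list", "sif", "graphml")) {
  if (!is.character(format) || !all(format %in% c("edge-list", "sif", "graphml"))) {
    abort(paste0("unknown network format: ", format[1]))
  }
  format <- match.arg(format)
  e <- sorted_edges(net)
  if (format == "edge-list") {
    lines <- paste(e$from, e$to, sep = "\t")
    writeLines(lines, path)
  } else if (format == "sif") {
    lines <- paste(e$from, "regulates", e$to, sep = "\t")
    isolated <- setdiff(net$nodes, unique(c(e$from, e$to)))
    writeLines(c(lines, isolated), path)
  } else {
    g <- igraph::graph_from_data_frame(
      as.data.frame(e),
      directed = TRUE,
      vertices = data.frame(name = net$nodes)
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network from file
#'
#' Inverse of [write_network()] for the same three formats. Edge-list files
#' do not carry isolated nodes; pass `nodes` to restore the full node set.
#'
#' @param path Input file path.
#' @param format One of `"edge-list"`, `"sif"`, `"graphml"`.
#' @param nodes Optional character vector of node ids; defaults to the nodes
#'   present in the file.
#' @param acyclic Acyclicity flag for the returned network.
#' @return A [grn_network()].
#' @export
read_network <- function(path, format = c("edge-list", "sif", "graphml"),
                         nodes = NULL, acyclic = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("network file not found: ", path))
  }
  if (!is.character(format) || !all(format %in% c("edge-list", "sif", "graphml"))) {
    abort(paste0("unknown network format: ", format[1]))
  }
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    e <- igraph::as_data_frame(g, what = "edges")
    found <- igraph::V(g)$name
    edges <- tibble(from = e$from, to = e$to)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (format == "sif") {
      is_edge <- lengths(parts) >= 3
      edges <- tibble(
        from = map_chr(parts[is_edge], 1),
        to = map_chr(parts[is_edge], 3)
      )
      found <- unique(c(unlist(map(parts[!is_edge], 1)), edges$from, edges$to))
    } else {
      bad <- which(lengths(parts) != 2)
      if (length(bad) > 0) {
        abort(paste0("malformed edge-list line ", bad[1], " in ", path))
      }
      edges <- tibble(
        from = map_chr(parts, 1),
        to = map_chr(parts, 2)
      )
      found <- unique(c(edges$from, edges$to))
    }
  }
  grn_network(nodes %||% found, edges, acyclic = acyclic)
}

#' Plot a directed network
#'
#' Nodes are laid out on a circle; edges are drawn as arrows, with reciprocal
#' pairs slightly curved apart so 2-cycles stay visible.
#'
#' @param object A [grn_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grn_network <- function(object, ...) {
  n <- length(object$nodes)
  theta <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  layout <- tibble(
    gene = object$nodes,
    x = cos(theta),
    y = sin(theta)
  )
  p <- ggplot2::ggplot(layout, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(object$edges) > 0) {
    seg <- object$edges |>
      left_join(layout, by = c("from" = "gene")) |>
      rename(x0 = "x", y0 = "y") |>
      left_join(layout, by = c("to" = "gene")) |>
      mutate(
        # shorten segments so arrowheads stop at the node label
        x0s = .data$x0 + 0.12 * (.data$x - .data$x0),
        y0s = .data$y0 + 0.12 * (.data$y - .data$y0),
        x1s = .data$x - 0.12 * (.data$x - .data$x0),
        y1s = .data$y - 0.12 * (.data$y - .data$y0)
      )
    p <- p + ggplot2::geom_curve(
      data = seg,
      ggplot2::aes(x = .data$x0s, y = .data$y0s, xend = .data$x1s, yend = .data$y1s),
      curvature = 0.08,
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      linewidth = 0.5
    )
  }
  p +
    ggplot2::geom_label(ggplot2::aes(label = .data$gene)) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void()
}
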