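#' Read a typed edge list
#'
#' Reads one layer of the heterogeneous network from a tab-separated file with
#' at least two columns (source ID, target ID). Lines starting with `#` and
#' blank lines are ignored; extra columns are ignored; IDs are kept verbatim
#' as opaque strings.
#'
#' Edges are undirected: a line repeating an already-seen pair in either
#' orientation is dropped. For the bipartite layers the first-seen orientation
#' fixes which endpoint carries the layer's first type (column 1 =
#' `source_type`, column 2 = `target_type` of [network_layers()]); for the
#' `gene-gene` layer endpoints are stored with `source <= target`
#' lexicographically. Self-loops are dropped with a message.
#'
#' @param path Path to a TSV file.
#' @param layer One of the four layer labels of [network_layers()].
#' @return A tibble with columns `source`, `target`, `layer`, deduplicated.
#' @export
read_edge_list <- function(path, layer) {
  layer_types(layer)  # validates the label
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble::tibble(source = character(), target = character(),
                          layer = character()))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- vapply(parts, function(p) sum(nzchar(p[seq_len(min(2, length(p)))])),
                   integer(1))
  bad <- which(lengths(parts) < 2 | nfield < 2)
  if (length(bad) > 0) {
    abort(paste0("malformed edge line ", idx[bad[1]], " in '", path,
                 "': expected >= 2 tab-separated fields"))
  }
  edges <- tibble::tibble(
    source = vapply(parts, `[[`, character(1), 1),
    target = vapply(parts, `[[`, character(1), 2),
    layer = layer
  )
  canonicalize_edges(edges)
}

# Drops self-loops, orients gene-gene edges source <= target, and removes
# duplicate undirected pairs (first orientation seen wins for bipartite
# layers, so column position keeps its type meaning).
canonicalize_edges <- function(edges) {
  stopifnot(all(c("source", "target", "layer") %in% names(edges)))
  loops <- edges$source == edges$target
  if (any(loops)) {
    inform(paste0("dropping ", sum(loops), " self-loop edge(s)"))
    edges <- edges[!loops, , drop = FALSE]
  }
  same_type <- vapply(edges$layer, function(l) {
    tp <- layer_types(l); tp[1] == tp[2]
  }, logical(1))
  swap <- same_type & edges$source > edges$target
  if (any(swap)) {
    tmp <- edges$source[swap]
    edges$source[swap] <- edges$target[swap]
    edges$target[swap] <- tmp
  }
  key <- paste(edges$layer,
               pmin(edges$source, edges$target),
               pmax(edges$source, edges$target), sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  dplyr::arrange(tibble::as_tibble(edges), .data$layer, .data$source, .data$target)
}

#' Write a typed edge list
#'
#' Writes one layer back to the TSV dialect read by [read_edge_list()], in
#' canonical order (lexicographic by source then target), so that
#' read-then-write round-trips deduplicated content byte-for-byte.
#'
#' @param edges A tibble with `source`, `target` (and optionally `layer`,
#'   which must then be a single value).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  if ("layer" %in% names(edges) && length(unique(edges$layer)) > 1) {
    abort("write_edge_list() writes one layer per file; split by layer first")
  }
  edges <- dplyr::arrange(edges, .data$source, .data$target)
  writeLines(paste(edges$source, edges$target, sep = "\t"), path)
  invisible(path)
}

#' Assemble the heterogeneous network
#'
#' Builds the typed node registry and typed adjacency from per-layer edge
#' tibbles. Endpoint types are implied by each edge's layer (column position,
#' see [read_edge_list()]); a node appearing with two different types across
#' layers is a hard error naming the node.
#'
#' @param edges A tibble of typed edges (`source`, `target`, `layer`),
#'   typically `dplyr::bind_rows()` of [read_edge_list()] calls.
#' @param nodes Optional tibble (`id`, `type`) registering isolated nodes.
#' @return An object of class `hetero_network`: list with `nodes` (tibble
#'   `id`, `type`), `edges` (canonical tibble), `adj` (per-node list of
#'   per-type sorted neighbor vectors) and `layer_edge_counts`.
#' @examples
#' edges <- tibble::tibble(
#'   source = c("D1", "M1"), target = c("M1", "G1"),
#'   layer = c("disease-mirna", "mirna-gene"))
#' net <- build_network(edges)
#' transition_candidates(net, "M1", "disease")
#' @export
build_network <- function(edges, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(source = character(), target = character(),
                            layer = character())
  }
  edges <- canonicalize_edges(edges)

  src_t <- vapply(edges$layer, function(l) layer_types(l)[1], character(1),
                  USE.NAMES = FALSE)
  tgt_t <- vapply(edges$layer, function(l) layer_types(l)[2], character(1),
                  USE.NAMES = FALSE)
  node_tbl <- tibble::tibble(
    id = c(edges$source, edges$target),
    type = c(src_t, tgt_t)
  )
  if (!is.null(nodes)) {
    stopifnot(all(c("id", "type") %in% names(nodes)))
    bad <- setdiff(nodes$type, node_types())
    if (length(bad) > 0) abort(paste0("unknown node type(s): ",
                                      paste(bad, collapse = ", ")))
    node_tbl <- dplyr::bind_rows(node_tbl, nodes[, c("id", "type")])
  }
  node_tbl <- dplyr::distinct(node_tbl)
  dup <- node_tbl$id[duplicated(node_tbl$id)]
  if (length(dup) > 0) {
    abort(paste0("node '", dup[1],
                 "' appears with two different types across layers"))
  }
  node_tbl <- dplyr::arrange(node_tbl, .data$id)

  type_of <- setNames(node_tbl$type, node_tbl$id)
  # both directions of every undirected edge
  long <- tibble::tibble(
    node = c(edges$source, edges$target),
    nb   = c(edges$target, edges$source)
  )
  long$nb_type <- unname(type_of[long$nb])
  adj <- lapply(setNames(node_tbl$id, node_tbl$id), function(id) {
    lapply(setNames(node_types(), node_types()), function(t) character(0))
  })
  if (nrow(long) > 0) {
    sp <- split(long$nb, list(long$node, long$nb_type), sep = "\r", drop = TRUE)
    for (k in names(sp)) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      adj[[parts[1]]][[parts[2]]] <- sort(unique(sp[[k]]))
    }
  }
  counts <- setNames(integer(length(network_layers()$layer)),
                     network_layers()$layer)
  tab <- table(edges$layer)
  counts[names(tab)] <- as.integer(tab)

  structure(
    list(nodes = node_tbl, edges = edges, adj = adj,
         layer_edge_counts = counts),
    class = "hetero_network"
  )
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("<hetero_network>\n")
  tt <- table(factor(x$nodes$type, levels = node_types()))
  cat("  nodes:", nrow(x$nodes),
      sprintf("(%s)", paste(names(tt), tt, sep = "=", collapse = ", ")), "\n")
  cat("  edges:", sum(x$layer_edge_counts), "\n")
  for (l in names(x$layer_edge_counts)) {
    cat(sprintf("    %-14s %d\n", l, x$layer_edge_counts[[l]]))
  }
  invisible(x)
}

#' @method as_tibble hetero_network
#' @export
as_tibble.hetero_network <- function(x, ...) x$edges

#' Typed neighbors of a node
#'
#' Returns the set of neighbors of `current` having type `next_type`,
#' pooled over all layers — the candidate set of a meta-path-constrained
#' random-walk step. Sampling uniformly from the returned vector realizes the
#' walker's transition law: probability `1/|N|` for each typed neighbor and 0
#' for every other node. An empty vector means the walk is stuck.
#'
#' @param network A [build_network()] object.
#' @param current A node ID present in the network.
#' @param next_type A node type (see [node_types()]).
#' @return Character vector of neighbor IDs, sorted (possibly empty).
#' @export
transition_candidates <- function(network, current, next_type) {
  stopifnot(inherits(network, "hetero_network"))
  if (!next_type %in% node_types()) abort(paste0("unknown node type '", next_type, "'"))
  a <- network$adj[[current]]
  if (is.null(a)) abort(paste0("node '", current, "' is not in the network"))
  a[[next_type]]
}

#' Node IDs of one type
#' @param network A [build_network()] object.
#' @param type A node type.
#' @return Sorted character vector of IDs.
#' @export
nodes_of_type <- function(network, type) {
  stopifnot(inherits(network, "hetero_network"))
  sort(network$nodes$id[network$nodes$type == type])
}

#' Write all four layers of a network to a directory
#'
#' One TSV per layer, named `<layer>.tsv` (layer label with `-` replaced by
#' `_`), in the canonical dialect of [write_edge_list()].
#'
#' @param network A [build_network()] object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_network <- function(network, dir) {
  stopifnot(inherits(network, "hetero_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (l in network_layers()$layer) {
    e <- network$edges[network$edges$layer == l, , drop = FALSE]
    p <- file.path(dir, paste0(gsub("-", "_", l), ".tsv"))
    write_edge_list(e, p)
    paths[l] <- p
  }
  invisible(paths)
}
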