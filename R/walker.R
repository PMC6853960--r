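# Integer-indexed view of a network for the C++ walker: node i is
# network$nodes$id[i] (ids are kept sorted), types are coded by position in
# node_types(), and adjacency holds 1-based neighbor indices per type.
network_index <- function(network) {
  ids <- network$nodes$id
  type_code <- match(network$nodes$type, node_types())
  adj_idx <- lapply(ids, function(id) {
    lapply(node_types(), function(t) {
      match(network$adj[[id]][[t]], ids)
    })
  })
  list(ids = ids, type_code = type_code, adj = adj_idx)
}

#' A single meta-path-constrained random walk
#'
#' Starting from `start`, repeatedly traverses the (symmetric) meta-path's
#' type pattern: at each step the next node is drawn uniformly from the
#' current node's neighbors of the required type. If no neighbor of the
#' required type exists the walk stops early (`completed = FALSE`).
#'
#' @param network A [build_network()] object.
#' @param start Node ID whose type must equal the meta-path's first type.
#' @param metapath A [metapath()] (or built-in name); must be symmetric.
#' @param steps Meta-path repetitions per walk; a never-stuck walk has
#'   [walk_length()] nodes (251 for M1 at 50 steps).
#' @param seed Integer seed (the walk is fully determined by it).
#' @return A list with `nodes` (character vector) and `completed` (logical).
#' @export
random_walk <- function(network, start, metapath, steps = 50, seed = 1) {
  mp <- as_metapath(metapath)
  if (!mp$symmetric) abort("random walks require a symmetric meta-path")
  idx <- network_index(network)
  si <- match(start, idx$ids)
  if (is.na(si)) abort(paste0("start node '", start, "' is not in the network"))
  if (idx$type_code[si] != match(mp$types[1], node_types())) {
    abort(paste0("start node '", start, "' has type '",
                 network$nodes$type[si], "' but meta-path ", mp$name,
                 " starts at '", mp$types[1], "'"))
  }
  pattern <- match(mp$types[-1], node_types())
  res <- cpp_generate_walks(idx$adj, si, pattern, as.integer(steps), 1L,
                            as.double(seed))
  list(nodes = idx$ids[res$walks[[1]]], completed = res$completed[1])
}

#' Generate a walk corpus
#'
#' Attempts `walks_per_node` walks from every node of the meta-path's start
#' type (in sorted ID order), with one seeded generator consumed in
#' node-then-walk order, so the corpus is byte-identical across runs with the
#' same seed. Walks that get stuck immediately (a single node) carry no
#' context and are dropped; longer truncated walks are kept with
#' `completed = FALSE`.
#'
#' @inheritParams random_walk
#' @param walks_per_node Walks attempted per start node.
#' @return A `walk_corpus`: tibble with columns `metapath`, `walk_id`,
#'   `start`, `completed`, `nodes` (list of character vectors), plus
#'   attributes recording the meta-path, steps, walks per node, seed, number
#'   of attempts and number of dropped single-node walks.
#' @examples
#' net <- fixture_network("chain_M3")
#' corp <- generate_corpus(net, "M3", steps = 1, walks_per_node = 2, seed = 7)
#' corp$nodes[[1]]
#' @export
generate_corpus <- function(network, metapath, steps = 50,
                            walks_per_node = 1000, seed = 1) {
  mp <- as_metapath(metapath)
  if (!mp$symmetric) abort("random walks require a symmetric meta-path")
  if (steps < 1) abort("`steps` must be a positive integer")
  if (walks_per_node < 0) abort("`walks_per_node` must be >= 0")
  if (nrow(network$nodes) == 0) abort("the network is empty")
  idx <- network_index(network)
  starts <- which(idx$type_code == match(mp$types[1], node_types()))
  if (length(starts) == 0) {
    abort(paste0("no node of start type '", mp$types[1], "' in the network"))
  }
  pattern <- match(mp$types[-1], node_types())
  if (walks_per_node == 0) {
    walks <- list(); completed <- logical(0); start_idx <- integer(0)
  } else {
    res <- cpp_generate_walks(idx$adj, starts, pattern, as.integer(steps),
                              as.integer(walks_per_node), as.double(seed))
    walks <- res$walks; completed <- res$completed; start_idx <- res$start
  }
  lens <- lengths(walks)
  keep <- lens >= 2
  out <- tibble::tibble(
    metapath = mp$name,
    walk_id = seq_along(walks)[keep],
    start = idx$ids[start_idx[keep]],
    completed = completed[keep],
    nodes = lapply(walks[keep], function(w) idx$ids[w])
  )
  structure(out, class = c("walk_corpus", class(out)),
            metapath = mp, steps = as.integer(steps),
            walks_per_node = as.integer(walks_per_node),
            seed = as.integer(seed),
            attempts = length(walks), dropped = sum(!keep))
}

#' @export
print.walk_corpus <- function(x, ...) {
  mp <- attr(x, "metapath")
  cat("<walk_corpus> ", nrow(x), " walks (", attr(x, "dropped"),
      " dropped), meta-path ", mp$name, ", ", attr(x, "steps"),
      " steps, seed ", attr(x, "seed"), "\n", sep = "")
  NextMethod()
}

#' Write / read a walk corpus
#'
#' One walk per line, space-separated node IDs. Header comment lines record
#' the meta-path, steps and seed so a corpus file is self-describing.
#'
#' @param corpus A [generate_corpus()] result.
#' @param path File path.
#' @return `write_corpus()`: `path` invisibly; `read_corpus()`: a
#'   `walk_corpus` tibble (completion is re-derived from the walk lengths).
#' @export
write_corpus <- function(corpus, path) {
  mp <- attr(corpus, "metapath")
  header <- c(
    paste0("# metapath=", mp$name),
    paste0("# types=", paste(mp$types, collapse = ",")),
    paste0("# steps=", attr(corpus, "steps")),
    paste0("# seed=", attr(corpus, "seed"))
  )
  body <- vapply(corpus$nodes, paste, character(1), collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(m) == 0) NULL else sub(paste0("^# ", key, "="), "", m[1])
  }
  types <- get("types")
  mp <- if (!is.null(types)) {
    metapath(get("metapath") %||% "custom", strsplit(types, ",")[[1]])
  } else {
    NULL
  }
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  nodes <- strsplit(body, " ", fixed = TRUE)
  steps <- as.integer(get("steps") %||% NA)
  expected <- if (!is.null(mp) && !is.na(steps)) {
    walk_length(mp, steps)
  } else {
    if (length(nodes)) max(lengths(nodes)) else 0L
  }
  out <- tibble::tibble(
    metapath = if (is.null(mp)) NA_character_ else mp$name,
    walk_id = seq_along(nodes),
    start = vapply(nodes, `[[`, character(1), 1),
    completed = lengths(nodes) == expected,
    nodes = nodes
  )
  structure(out, class = c("walk_corpus", class(out)),
            metapath = mp, steps = steps,
            walks_per_node = NA_integer_,
            seed = as.integer(get("seed") %||% NA),
            attempts = length(nodes), dropped = NA_integer_)
}
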