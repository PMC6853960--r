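#' Enumerate meta-path instances between two diseases
#'
#' Exhaustive, deterministic depth-first enumeration of concrete node chains
#' conforming to a meta-path and connecting `disease_a` to `disease_b` —
#' the mechanistic subnetworks behind an inferred comorbidity (e.g. every
#' disease-miRNA-gene-gene-miRNA-disease chain). Deterministic enumeration
#' is a superset of what stochastic walk sampling can discover. Instances
#' are emitted in lexicographic order of their node sequences; `limit` caps
#' the count.
#'
#' @param network A [build_network()] object.
#' @param disease_a,disease_b Disease node IDs present in the network.
#' @param metapath A [metapath()] whose first and last types are `disease`.
#' @param limit Maximum number of instances (default unlimited).
#' @return A tibble with one row per instance: `disease_a`, `disease_b`,
#'   `nodes` (list of node-ID vectors), `path` (nodes joined by `" -> "`).
#' @examples
#' net <- fixture_network("chain_M1")
#' enumerate_instances(net, "D1", "D2", "M1")
#' @export
enumerate_instances <- function(network, disease_a, disease_b,
                                metapath = "M1", limit = Inf) {
  mp <- as_metapath(metapath)
  L <- length(mp$types)
  if (mp$types[1] != "disease" || mp$types[L] != "disease") {
    abort("meta-path endpoints must be disease-typed")
  }
  for (d in c(disease_a, disease_b)) {
    i <- match(d, network$nodes$id)
    if (is.na(i)) abort(paste0("disease '", d, "' is not in the network"))
    if (network$nodes$type[i] != "disease") {
      abort(paste0("node '", d, "' is not disease-typed"))
    }
  }
  res <- list()
  rec <- function(path, pos) {
    if (length(res) >= limit) return(invisible())
    if (pos == L) {
      res[[length(res) + 1]] <<- path
      return(invisible())
    }
    for (nb in transition_candidates(network, path[pos], mp$types[pos + 1])) {
      if (length(res) >= limit) break
      if (pos + 1 == L && nb != disease_b) next
      rec(c(path, nb), pos + 1)
    }
  }
  rec(disease_a, 1)
  tibble::tibble(
    disease_a = disease_a, disease_b = disease_b,
    nodes = res,
    path = vapply(res, paste, character(1), collapse = " -> ")
  )
}

#' Shared miRNA neighbors of two diseases
#'
#' The intersection of the two diseases' miRNA neighbor sets in the
#' disease-miRNA layer — the "overlapping miRNAs" of a comorbid pair. A
#' disease absent from the network contributes the empty set.
#'
#' @inheritParams enumerate_instances
#' @return Sorted character vector of miRNA IDs.
#' @export
shared_mirnas <- function(network, disease_a, disease_b) {
  nb <- function(d) {
    if (is.null(network$adj[[d]])) character(0)
    else network$adj[[d]][["mirna"]]
  }
  sort(intersect(nb(disease_a), nb(disease_b)))
}

#' Write meta-path instances to TSV
#' @param instances An [enumerate_instances()] tibble.
#' @param path File path; one instance per line, nodes tab-separated.
#' @return `path`, invisibly.
#' @export
write_instances <- function(instances, path) {
  writeLines(vapply(instances$nodes, paste, character(1), collapse = "\t"),
             path)
  invisible(path)
}
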