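#' Node types and network layers
#'
#' The heterogeneous network has exactly three node types. Proteins in the
#' interactome are identified with the genes encoding them, so protein-protein
#' interaction (PPI) edges are stored as `gene`-`gene` edges and no fourth
#' type is needed.
#'
#' @format `node_types()` returns a character vector of the three type labels.
#'   `network_layers()` returns a tibble with one row per layer: `layer`,
#'   `source_type`, `target_type`.
#' @export
node_types <- function() c("disease", "mirna", "gene")

#' @rdname node_types
#' @export
network_layers <- function() {
  tibble::tibble(
    layer       = c("disease-mirna", "mirna-gene", "disease-gene", "gene-gene"),
    source_type = c("disease", "mirna", "disease", "gene"),
    target_type = c("mirna", "gene", "gene", "gene")
  )
}

layer_types <- function(layer) {
  ly <- network_layers()
  i <- match(layer, ly$layer)
  if (is.na(i)) {
    abort(paste0("unknown layer '", layer, "'; must be one of: ",
                 paste(ly$layer, collapse = ", ")))
  }
  c(ly$source_type[i], ly$target_type[i])
}

#' Meta-path declarations
#'
#' A meta-path is an ordered sequence of node types constraining which edges a
#' random walk may traverse at each step. Three meta-paths are built in:
#'
#' * `M1`: disease-miRNA-gene-gene-miRNA-disease
#' * `M2`: disease-miRNA-gene-gene-gene-miRNA-disease
#' * `M3`: disease-gene-gene-disease
#'
#' A meta-path is *symmetric* when its first and last types coincide; only
#' symmetric meta-paths can be repeated recursively by the walker, so the
#' walker requires symmetry.
#'
#' @param name One of `"M1"`, `"M2"`, `"M3"`, or any label when `types` is
#'   given explicitly.
#' @param types Optional character vector of node types (each in
#'   `node_types()`), length >= 2. Ignored for the built-in names.
#' @return An object of class `metapath`: a list with `name`, `types` and
#'   `symmetric`.
#' @examples
#' metapath("M1")
#' metapath("DMD", c("disease", "mirna", "disease"))
#' @export
metapath <- function(name, types = NULL) {
  builtin <- list(
    M1 = c("disease", "mirna", "gene", "gene", "mirna", "disease"),
    M2 = c("disease", "mirna", "gene", "gene", "gene", "mirna", "disease"),
    M3 = c("disease", "gene", "gene", "disease")
  )
  if (is.null(types)) {
    if (!name %in% names(builtin)) {
      abort(paste0("no built-in meta-path '", name,
                   "'; supply `types` for a custom meta-path"))
    }
    types <- builtin[[name]]
  }
  if (length(types) < 2) abort("a meta-path needs at least 2 node types")
  bad <- setdiff(types, node_types())
  if (length(bad) > 0) {
    abort(paste0("unknown node type(s) in meta-path: ", paste(bad, collapse = ", ")))
  }
  structure(
    list(name = name, types = types,
         symmetric = types[1] == types[length(types)]),
    class = "metapath"
  )
}

#' @export
print.metapath <- function(x, ...) {
  cat("<metapath ", x$name, "> ", paste(x$types, collapse = "-"),
      if (x$symmetric) "  (symmetric)" else "  (non-symmetric)", "\n", sep = "")
  invisible(x)
}

as_metapath <- function(x) {
  if (inherits(x, "metapath")) return(x)
  if (is.character(x) && length(x) == 1) return(metapath(x))
  abort("expected a metapath object or a built-in meta-path name")
}

#' Expected node count of a completed walk
#'
#' A walk repeats a symmetric meta-path of `L` types `steps` times; each
#' repetition appends `L - 1` nodes to the single start node, so a completed
#' walk holds `steps * (L - 1) + 1` nodes (251 for M1 at 50 steps).
#'
#' @param metapath A [metapath()] (or built-in name).
#' @param steps Number of meta-path repetitions.
#' @return Integer node count.
#' @export
walk_length <- function(metapath, steps) {
  mp <- as_metapath(metapath)
  as.integer(steps * (length(mp$types) - 1L) + 1L)
}
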