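#' miRNA-overlap (Jaccard) similarity
#'
#' The baseline disease-disease similarity: the Jaccard index
#' `|A ∩ B| / |A ∪ B|` of the two diseases' associated miRNA sets. Both sets
#' empty returns 0 ("no evidence", not "identical").
#'
#' @param a,b Character vectors (sets of miRNA IDs; duplicates ignored).
#' @return A number in `[0, 1]`.
#' @examples
#' overlap_similarity(c("m1", "m2"), c("m2", "m3"))  # 1/3
#' @export
overlap_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  un <- length(union(a, b))
  if (un == 0) return(0)
  length(intersect(a, b)) / un
}

#' Cosine similarity
#'
#' `x . y / (||x|| ||y||)`; if either vector has zero norm (e.g. a disease
#' that never entered a walk corpus and so carries a zero block), the
#' similarity is 0 — no embedding signal, no similarity.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) abort("cosine_similarity(): dimension mismatch")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

#' Concatenate per-meta-path embeddings
#'
#' Fuses embeddings learned under different meta-paths by concatenating each
#' node's vectors in the declared order. A node missing from one matrix gets
#' a zero block of that matrix's dimension there, keeping it rankable.
#'
#' @param embeddings A (named) list of `node_embedding` objects.
#' @param order Optional character vector giving the concatenation order
#'   (defaults to list order).
#' @return A `node_embedding` over the union of node IDs, with dimension
#'   equal to the sum of input dimensions.
#' @export
concatenate_embeddings <- function(embeddings, order = NULL) {
  if (length(embeddings) == 0) abort("no embeddings to concatenate")
  if (!is.null(order)) {
    if (!all(order %in% names(embeddings)))
      abort("`order` names an embedding that was not supplied")
    embeddings <- embeddings[order]
  }
  ids <- sort(unique(unlist(lapply(embeddings, function(e) rownames(e$vectors)))))
  blocks <- lapply(embeddings, function(e) {
    d <- ncol(e$vectors)
    B <- matrix(0, nrow = length(ids), ncol = d, dimnames = list(ids, NULL))
    common <- intersect(ids, rownames(e$vectors))
    B[common, ] <- e$vectors[common, , drop = FALSE]
    B
  })
  types <- character(0)
  for (e in rev(embeddings)) types[names(e$types)] <- unname(e$types)
  structure(list(vectors = do.call(cbind, blocks), types = types[ids],
                 config = NULL, objective = numeric(0)),
            class = "node_embedding")
}

# canonical unordered pair orientation: disease_a < disease_b lexicographic
orient_pairs <- function(a, b) {
  swap <- a > b
  tibble::tibble(disease_a = ifelse(swap, b, a),
                 disease_b = ifelse(swap, a, b))
}

#' Disease-disease cosine similarity table
#'
#' Scores every unordered pair of diseases by the cosine of their embedding
#' vectors. Diseases without a vector can be included via `diseases` (scored
#' 0 against everything, per the zero-vector rule).
#'
#' @param embedding A `node_embedding` (possibly concatenated).
#' @param diseases Optional character vector of disease IDs to score;
#'   defaults to all disease-typed nodes in the embedding.
#' @param metapaths Optional character vector recorded in the `metapaths`
#'   column (provenance).
#' @return A tibble (`disease_a`, `disease_b`, `score`, `method`,
#'   `metapaths`) with `disease_a < disease_b`, one row per unordered pair.
#' @export
disease_similarity <- function(embedding, diseases = NULL, metapaths = NULL) {
  if (is.null(diseases)) {
    if (is.null(embedding$types)) {
      abort("embedding carries no node types; supply `diseases`")
    }
    diseases <- sort(names(embedding$types)[embedding$types == "disease"])
  } else {
    diseases <- sort(unique(diseases))
  }
  if (length(diseases) < 2) abort("need at least 2 diseases to score pairs")
  d <- ncol(embedding$vectors)
  V <- matrix(0, nrow = length(diseases), ncol = d,
              dimnames = list(diseases, NULL))
  common <- intersect(diseases, rownames(embedding$vectors))
  V[common, ] <- embedding$vectors[common, , drop = FALSE]
  nrm <- sqrt(rowSums(V^2))
  Vn <- V / ifelse(nrm > 0, nrm, 1)
  S <- tcrossprod(Vn)
  iu <- which(upper.tri(S), arr.ind = TRUE)
  tibble::tibble(
    disease_a = diseases[iu[, 1]],
    disease_b = diseases[iu[, 2]],
    score = S[iu],
    method = "metapath-embedding",
    metapaths = paste(metapaths %||% NA_character_, collapse = "+")
  ) |>
    dplyr::arrange(.data$disease_a, .data$disease_b)
}

#' miRNA-overlap similarity table
#'
#' The Jaccard baseline over every unordered disease pair in a network, using
#' each disease's miRNA neighbor set from the disease-miRNA layer.
#'
#' @param network A [build_network()] object.
#' @param diseases Optional disease IDs (defaults to all disease nodes).
#' @return A tibble in the same shape as [disease_similarity()], with
#'   `method = "mirna-overlap"` and scores in `[0, 1]`.
#' @export
overlap_similarity_table <- function(network, diseases = NULL) {
  if (is.null(diseases)) diseases <- nodes_of_type(network, "disease")
  diseases <- sort(unique(diseases))
  if (length(diseases) < 2) abort("need at least 2 diseases to score pairs")
  sets <- lapply(setNames(diseases, diseases), function(d) {
    transition_candidates(network, d, "mirna")
  })
  pairs <- utils::combn(diseases, 2)
  tibble::tibble(
    disease_a = pairs[1, ],
    disease_b = pairs[2, ],
    score = vapply(seq_len(ncol(pairs)), function(i) {
      overlap_similarity(sets[[pairs[1, i]]], sets[[pairs[2, i]]])
    }, numeric(1)),
    method = "mirna-overlap",
    metapaths = NA_character_
  )
}

#' Top-k similarity pairs
#'
#' Sorts a similarity table by descending score, breaking ties
#' lexicographically by (`disease_a`, `disease_b`), and keeps the first `k`
#' rows — e.g. the top 300 pairs used to draw comorbidity networks.
#'
#' @param table A similarity tibble with `disease_a`, `disease_b`, `score`.
#' @param k Number of pairs to keep (at most `nrow(table)`).
#' @return The sorted, truncated tibble.
#' @export
rank_pairs <- function(table, k = nrow(table)) {
  if (k > nrow(table)) abort("`k` exceeds the number of scored pairs")
  table |>
    dplyr::arrange(dplyr::desc(.data$score), .data$disease_a, .data$disease_b) |>
    head(k)
}

#' Write a similarity table
#'
#' Four tab-separated columns: `disease_a`, `disease_b`, `score`, `method`
#' (plus `metapaths` when present), with a header row.
#'
#' @param table A similarity tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(table, path) {
  cols <- intersect(c("disease_a", "disease_b", "score", "method", "metapaths"),
                    names(table))
  tb <- table[, cols]
  tb$score <- format(tb$score, digits = 17, trim = TRUE, scientific = FALSE)
  lines <- c(paste(cols, collapse = "\t"),
             do.call(paste, c(unname(as.list(tb)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}
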