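#' Skip-gram training configuration
#'
#' Hyper-parameters of the heterogeneous skip-gram model. Defaults follow
#' word2vec/metapath2vec conventions: 128 dimensions, a 5-position context
#' window each side, 5 negatives per positive drawn from the context type's
#' unigram distribution raised to 0.75, initial learning rate 0.025 decayed
#' linearly to `min_learning_rate` over all training pairs, and vectors
#' initialized uniformly in `[-0.5/d, 0.5/d]`. Logits inside the sigmoid are
#' clamped to `[-logit_max, logit_max]` so updates never overflow.
#'
#' @param dimension Embedding dimension (positive integer).
#' @param window Context radius in walk positions.
#' @param negatives Negative samples per positive pair.
#' @param epochs Passes over the corpus; 0 returns the initialization.
#' @param learning_rate Initial SGD learning rate.
#' @param min_learning_rate Floor of the linear decay.
#' @param noise_exponent Exponent on typed unigram counts, in (0, 1].
#' @param logit_max Clamp bound for logits inside the sigmoid.
#' @param seed Integer seed; training is deterministic given it.
#' @return A `skipgram_config` list.
#' @export
skipgram_config <- function(dimension = 128, window = 5, negatives = 5,
                            epochs = 5, learning_rate = 0.025,
                            min_learning_rate = 1e-4, noise_exponent = 0.75,
                            logit_max = 6, seed = 1) {
  if (dimension < 1) abort("`dimension` must be a positive integer")
  if (window < 1) abort("`window` must be a positive integer")
  if (negatives < 1) abort("`negatives` must be a positive integer")
  if (epochs < 0) abort("`epochs` must be >= 0")
  if (learning_rate <= 0 || min_learning_rate <= 0)
    abort("learning rates must be positive")
  if (noise_exponent <= 0 || noise_exponent > 1)
    abort("`noise_exponent` must be in (0, 1]")
  structure(list(dimension = as.integer(dimension), window = as.integer(window),
                 negatives = as.integer(negatives), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 min_learning_rate = min_learning_rate,
                 noise_exponent = noise_exponent, logit_max = logit_max,
                 seed = as.integer(seed)),
            class = "skipgram_config")
}

# Node type of every node in a corpus, derived from walk positions and the
# meta-path's cyclic type pattern.
corpus_types <- function(corpus) {
  mp <- attr(corpus, "metapath")
  if (is.null(mp)) abort("corpus has no meta-path attribute; cannot type nodes")
  cyc <- mp$types[-length(mp$types)]
  out <- new.env(parent = emptyenv())
  for (w in corpus$nodes) {
    tps <- cyc[((seq_along(w) - 1) %% length(cyc)) + 1]
    for (i in seq_along(w)) {
      prev <- out[[w[i]]]
      if (is.null(prev)) {
        assign(w[i], tps[i], envir = out)
      } else if (prev != tps[i]) {
        abort(paste0("node '", w[i], "' appears with two types in the corpus"))
      }
    }
  }
  ids <- sort(ls(out))
  setNames(vapply(ids, function(i) out[[i]], character(1)), ids)
}

#' Enumerate (center, context) training pairs
#'
#' For every walk position, emits one pair per node within `window` positions
#' on either side, tagged with the context node's type — the typed context
#' sets the skip-gram objective sums over. This is the reference enumeration;
#' the trainer iterates the same windows internally.
#'
#' @param corpus A [generate_corpus()] result (or any `walk_corpus`).
#' @param window Context radius.
#' @return A tibble with columns `center`, `context`, `context_type`.
#' @examples
#' net <- fixture_network("chain_M3")
#' corp <- generate_corpus(net, "M3", steps = 1, walks_per_node = 1, seed = 1)
#' extract_contexts(corp, window = 1)
#' @export
extract_contexts <- function(corpus, window = 5) {
  if (nrow(corpus) == 0) abort("corpus is empty")
  types <- corpus_types(corpus)
  res <- purrr::map(corpus$nodes, function(w) {
    T <- length(w)
    if (T < 2) return(NULL)
    center <- character(0); context <- character(0)
    for (i in seq_len(T)) {
      js <- setdiff(max(1, i - window):min(T, i + window), i)
      center <- c(center, rep(w[i], length(js)))
      context <- c(context, w[js])
    }
    tibble::tibble(center = center, context = context)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(center = character(), context = character(),
                          context_type = character()))
  }
  out$context_type <- unname(types[out$context])
  out
}

#' Draw typed negative samples
#'
#' Draws node IDs from one type's vocabulary with probability proportional to
#' `counts^noise_exponent` — the pre-defined per-type noise distribution of
#' the heterogeneous skip-gram objective. As `noise_exponent` approaches 0
#' the draw becomes uniform over the vocabulary.
#'
#' @param counts Named numeric vector: corpus occurrence counts of the nodes
#'   in the context type's vocabulary (names are node IDs).
#' @param n Number of draws.
#' @param noise_exponent Exponent in (0, 1].
#' @param seed Optional integer seed (global RNG state is preserved).
#' @return Character vector of `n` node IDs.
#' @export
negative_sample <- function(counts, n = 1, noise_exponent = 0.75, seed = NULL) {
  if (length(counts) == 0) abort("empty vocabulary for the context type")
  w <- counts^noise_exponent
  draw <- function() sample(names(counts), n, replace = TRUE, prob = w)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' One negative-sampling SGD step
#'
#' Applies the analytic gradient of the per-pair negative-sampling objective
#' `log sigma(x_c . x_v) + sum_m log sigma(-x_u_m . x_v)` as a single
#' simultaneous ascent step with rate `learning_rate`: the positive context
#' moves by `lr * (1 - sigma(x_c . x_v)) * x_v`, each negative by
#' `-lr * sigma(x_u . x_v) * x_v`, and the center by the summed reverse
#' terms. This is exactly the update the trainer applies per pair.
#'
#' @param X Numeric matrix, one row per node (rownames are node IDs).
#' @param center,context Node IDs (rownames of `X`).
#' @param negatives Character vector of negative node IDs.
#' @param learning_rate Step size; 0 leaves `X` unchanged.
#' @param logit_max Clamp bound for logits (use a large value to disable).
#' @return The updated matrix.
#' @export
sgd_step <- function(X, center, context, negatives, learning_rate,
                     logit_max = 6) {
  ids <- rownames(X)
  if (is.null(ids)) abort("`X` must have node IDs as rownames")
  iv <- match(c(center, context, negatives), ids)
  if (anyNA(iv)) abort("unknown node ID in sgd_step()")
  Y <- cpp_sgd_step(X, iv[1], iv[2], iv[-(1:2)], learning_rate, logit_max)
  dimnames(Y) <- dimnames(X)
  Y
}

#' Train heterogeneous skip-gram embeddings
#'
#' Learns one embedding vector per node occurring in the corpus by SGD over
#' sliding-window (center, context) pairs, contrasting each positive context
#' against `negatives` noise nodes of the same type. Fully deterministic
#' given `config$seed`.
#'
#' @param corpus A `walk_corpus`.
#' @param config A [skipgram_config()].
#' @return A `node_embedding`: list with `vectors` (nodes x dimension matrix,
#'   rownames = node IDs), `types` (named character), `config`, and
#'   `objective` (held-out mean objective at initialization and after each
#'   epoch).
#' @examples
#' net <- fixture_network("two_cliques")
#' corp <- generate_corpus(net, "M1", steps = 3, walks_per_node = 10, seed = 1)
#' emb <- train_embeddings(corp, skipgram_config(dimension = 8, epochs = 2))
#' glance(emb)
#' @export
train_embeddings <- function(corpus, config = skipgram_config()) {
  stopifnot(inherits(config, "skipgram_config"))
  if (nrow(corpus) == 0) abort("corpus is empty")
  types <- corpus_types(corpus)
  ids <- names(types)
  counts <- table(factor(unlist(corpus$nodes), levels = ids))
  walks_idx <- lapply(corpus$nodes, function(w) match(w, ids))
  res <- cpp_train_skipgram(
    walks_idx, match(unname(types), node_types()),
    as.numeric(counts)^config$noise_exponent,
    config$dimension, config$window, config$negatives, config$epochs,
    config$learning_rate, config$min_learning_rate,
    as.double(config$seed), config$logit_max
  )
  vectors <- res$embedding
  rownames(vectors) <- ids
  structure(list(vectors = vectors, types = types, config = config,
                 objective = as.numeric(res$objective)),
            class = "node_embedding")
}

#' @export
print.node_embedding <- function(x, ...) {
  cat("<node_embedding> ", nrow(x$vectors), " nodes x ", ncol(x$vectors),
      " dims\n", sep = "")
  tt <- table(factor(x$types, levels = node_types()))
  cat("  ", paste(names(tt), tt, sep = "=", collapse = ", "), "\n", sep = "")
  if (length(x$objective) > 1) {
    cat(sprintf("  held-out objective: %.4f -> %.4f\n",
                x$objective[1], x$objective[length(x$objective)]))
  }
  invisible(x)
}

#' @describeIn train_embeddings Tidy per-node table: `node`, `type`, then one
#'   column per embedding dimension (`e1`, `e2`, ...).
#' @param x A `node_embedding`.
#' @param ... Unused.
#' @method tidy node_embedding
#' @export
tidy.node_embedding <- function(x, ...) {
  V <- x$vectors
  colnames(V) <- paste0("e", seq_len(ncol(V)))
  dplyr::bind_cols(
    tibble::tibble(node = rownames(V), type = unname(x$types[rownames(V)])),
    tibble::as_tibble(V)
  )
}

#' @describeIn train_embeddings One-row summary: node count, dimension,
#'   epochs, and held-out objective before/after training.
#' @method glance node_embedding
#' @export
glance.node_embedding <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$vectors), dimension = ncol(x$vectors),
    epochs = x$config$epochs %||% NA_integer_,
    objective_initial = x$objective[1],
    objective_final = x$objective[length(x$objective)]
  )
}

#' Write / read an embedding table
#'
#' TSV with a `#dim=<d>` header line, a `#types=` header recording node
#' types, then one row per node: node ID followed by `d` float columns.
#'
#' @param embedding A `node_embedding`.
#' @param path File path.
#' @return `write_embeddings()`: `path` invisibly; `read_embeddings()`: a
#'   `node_embedding` (without training metadata).
#' @export
write_embeddings <- function(embedding, path) {
  V <- embedding$vectors
  ids <- rownames(V)
  header <- c(
    paste0("#dim=", ncol(V)),
    paste0("#types=", paste(ids, unname(embedding$types[ids]),
                            sep = ":", collapse = ","))
  )
  body <- vapply(seq_len(nrow(V)), function(i) {
    paste(c(ids[i], format(V[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  dim_line <- grep("^#dim=", hdr, value = TRUE)
  if (length(dim_line) == 0) abort("missing #dim= header in embedding file")
  d <- as.integer(sub("^#dim=", "", dim_line[1]))
  types <- NULL
  tl <- grep("^#types=", hdr, value = TRUE)
  if (length(tl) > 0) {
    kv <- strsplit(strsplit(sub("^#types=", "", tl[1]), ",")[[1]], ":")
    types <- setNames(vapply(kv, `[[`, character(1), 2),
                      vapply(kv, `[[`, character(1), 1))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  V <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  if (d == 1) V <- matrix(V, ncol = 1)
  rownames(V) <- ids
  structure(list(vectors = V, types = types, config = NULL,
                 objective = numeric(0)),
            class = "node_embedding")
}
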