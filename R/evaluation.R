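#' Read / write labeled disease pairs
#'
#' TSV with columns `disease_a`, `disease_b`, `label` (header optional;
#' labels are `positive`/`negative`, or `1`/`0`).
#'
#' @param path File path.
#' @return A tibble (`disease_a`, `disease_b`, `label`) with canonical pair
#'   orientation and unique unordered pairs.
#' @export
read_labeled_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) > 0 && identical(parts[[1]][1], "disease_a")) {
    parts <- parts[-1]
  }
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) abort(paste0("malformed label line ", bad[1]))
  lab <- vapply(parts, `[[`, character(1), 3)
  lab <- ifelse(lab %in% c("positive", "1", "TRUE"), "positive",
         ifelse(lab %in% c("negative", "0", "FALSE"), "negative", NA))
  if (anyNA(lab)) abort("labels must be positive/negative (or 1/0)")
  out <- orient_pairs(vapply(parts, `[[`, character(1), 1),
                      vapply(parts, `[[`, character(1), 2))
  out$label <- lab
  dplyr::distinct(out)
}

#' @rdname read_labeled_pairs
#' @param labels A labeled-pair tibble.
#' @export
write_labeled_pairs <- function(labels, path) {
  writeLines(c("disease_a\tdisease_b\tlabel",
               paste(labels$disease_a, labels$disease_b, labels$label,
                     sep = "\t")),
             path)
  invisible(path)
}

#' Seeded negative disease pairs
#'
#' ROC/PR evaluation needs an explicit negative class; this helper samples
#' random unordered disease pairs that are not in the positive set, 1:1 with
#' the positives by default, under a recorded seed. The composition of the
#' negative class materially changes AUROC, so it is never sampled silently
#' by [evaluate_predictions()].
#'
#' @param diseases Character vector of candidate disease IDs.
#' @param positives Tibble of positive pairs (`disease_a`, `disease_b`).
#' @param n Number of negatives (default: one per positive).
#' @param seed Integer seed.
#' @return Tibble (`disease_a`, `disease_b`, `label = "negative"`).
#' @export
make_negative_pairs <- function(diseases, positives, n = nrow(positives),
                                seed = 1) {
  diseases <- sort(unique(diseases))
  pos <- orient_pairs(positives$disease_a, positives$disease_b)
  pos_key <- paste(pos$disease_a, pos$disease_b, sep = "\r")
  all_pairs <- utils::combn(diseases, 2)
  key <- paste(all_pairs[1, ], all_pairs[2, ], sep = "\r")
  cand <- which(!key %in% pos_key)
  if (length(cand) < n) abort("not enough non-positive pairs to sample from")
  pick <- withr::with_seed(seed, sample(cand, n))
  pick <- sort(pick)
  tibble::tibble(disease_a = all_pairs[1, pick], disease_b = all_pairs[2, pick],
                 label = "negative")
}

#' Evaluate a similarity table against labeled pairs
#'
#' Matches each labeled unordered pair to its score, then computes the ROC
#' and precision-recall curves. AUROC is the tie-corrected Mann-Whitney rank
#' statistic (identical to the trapezoidal ROC integral); AUPR is the
#' non-interpolated step estimator over distinct score thresholds. Both are
#' invariant to strictly monotone transforms of the scores. Labeled pairs
#' whose diseases are absent from the similarity table are dropped with a
#' message.
#'
#' @param sims A similarity tibble ([disease_similarity()] or
#'   [overlap_similarity_table()]).
#' @param labels A labeled-pair tibble (both classes must be present).
#' @return A `curve_result`: list with `points` (curve coordinates), `auroc`,
#'   `aupr`, `n_pos`, `n_neg`, `n_dropped`, `method`.
#' @export
evaluate_predictions <- function(sims, labels) {
  lab <- orient_pairs(labels$disease_a, labels$disease_b)
  lab$label <- labels$label
  lab <- dplyr::distinct(lab)
  sc <- orient_pairs(sims$disease_a, sims$disease_b)
  sc$score <- sims$score
  m <- dplyr::inner_join(lab, sc, by = c("disease_a", "disease_b"))
  n_dropped <- nrow(lab) - nrow(m)
  if (n_dropped > 0) {
    inform(paste0("dropped ", n_dropped,
                  " labeled pair(s) without a score (unknown diseases)"))
  }
  y <- m$label == "positive"
  P <- sum(y); N <- sum(!y)
  if (P == 0 || N == 0) {
    abort("both positive and negative labeled pairs are required")
  }
  s <- m$score

  # tie-corrected Mann-Whitney AUROC
  r <- rank(s, ties.method = "average")
  auroc <- (sum(r[y]) - P * (P + 1) / 2) / (P * N)

  # curve points over distinct thresholds, descending
  ord <- order(-s)
  s_ord <- s[ord]; y_ord <- y[ord]
  grp <- cumsum(!duplicated(s_ord))
  tp <- cumsum(y_ord); fp <- cumsum(!y_ord)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tp <- tp[last]; fp <- fp[last]; thr <- s_ord[last]
  tpr <- tp / P; fpr <- fp / N
  precision <- tp / (tp + fp); recall <- tpr
  aupr <- sum(diff(c(0, recall)) * precision)

  points <- dplyr::bind_rows(
    tibble::tibble(curve = "roc", threshold = c(Inf, thr),
                   x = c(0, fpr), y = c(0, tpr)),
    tibble::tibble(curve = "pr", threshold = thr, x = recall, y = precision)
  )
  structure(list(points = points, auroc = auroc, aupr = aupr,
                 n_pos = P, n_neg = N, n_dropped = n_dropped,
                 method = if ("method" %in% names(sims)) sims$method[1] else NA_character_,
                 aupr_estimator = "step (non-interpolated)"),
            class = "curve_result")
}

#' @export
print.curve_result <- function(x, ...) {
  cat(sprintf("<curve_result> AUROC %.4f, AUPR %.4f (%d positives, %d negatives)\n",
              x$auroc, x$aupr, x$n_pos, x$n_neg))
  invisible(x)
}

#' @describeIn evaluate_predictions Curve coordinates: `curve` ("roc"/"pr"),
#'   `threshold`, `x` (FPR or recall), `y` (TPR or precision).
#' @param x A `curve_result`.
#' @param ... Unused.
#' @method tidy curve_result
#' @export
tidy.curve_result <- function(x, ...) x$points

#' @describeIn evaluate_predictions One-row summary with `auroc`, `aupr`,
#'   `n_pos`, `n_neg`, `n_dropped`.
#' @method glance curve_result
#' @export
glance.curve_result <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, aupr = x$aupr, n_pos = x$n_pos,
                 n_neg = x$n_neg, n_dropped = x$n_dropped)
}

#' @describeIn evaluate_predictions ROC and PR curves side by side.
#' @param object A `curve_result`.
#' @method autoplot curve_result
#' @export
autoplot.curve_result <- function(object, ...) {
  pts <- object$points
  pts$curve <- factor(pts$curve, levels = c("roc", "pr"),
                      labels = c(sprintf("ROC (AUROC = %.3f)", object$auroc),
                                 sprintf("PR (AUPR = %.3f)", object$aupr)))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~curve, scales = "free") +
    ggplot2::labs(x = "FPR / recall", y = "TPR / precision") +
    ggplot2::theme_minimal()
}

#' Export a comorbidity network for Gephi
#'
#' Writes the top-scoring disease pairs as a GEXF file (undirected edges
#' weighted by score, optional `category` node attribute) and, optionally,
#' the same pairs as an edge-list TSV.
#'
#' @param pairs A similarity tibble (typically [rank_pairs()] output).
#' @param path Output GEXF path.
#' @param tsv Optional path for a TSV copy of the pairs.
#' @param annotations Optional tibble (`node`, `category`) of disease
#'   category labels.
#' @return `path`, invisibly.
#' @export
export_network <- function(pairs, path, tsv = NULL, annotations = NULL) {
  doc <- xml2::xml_new_root("gexf", xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  if (!is.null(annotations)) {
    attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
    xml2::xml_add_child(attrs, "attribute", id = "0", title = "category",
                        type = "string")
  }
  nodes_el <- xml2::xml_add_child(graph, "nodes")
  ids <- sort(unique(c(pairs$disease_a, pairs$disease_b)))
  cat_of <- if (is.null(annotations)) NULL else {
    setNames(annotations$category, annotations$node)
  }
  for (id in ids) {
    nd <- xml2::xml_add_child(nodes_el, "node", id = id, label = id)
    if (!is.null(cat_of) && !is.na(cat_of[id])) {
      av <- xml2::xml_add_child(nd, "attvalues")
      xml2::xml_add_child(av, "attvalue", `for` = "0",
                          value = unname(cat_of[id]))
    }
  }
  edges_el <- xml2::xml_add_child(graph, "edges")
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      xml2::xml_add_child(edges_el, "edge", id = as.character(i - 1),
                          source = pairs$disease_a[i],
                          target = pairs$disease_b[i],
                          weight = format(pairs$score[i], digits = 10))
    }
  }
  xml2::write_xml(doc, path)
  if (!is.null(tsv)) write_similarity(pairs, tsv)
  invisible(path)
}

#' Read a similarity TSV back
#' @param path A file written by [write_similarity()].
#' @return A similarity tibble.
#' @export
read_similarity <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cols <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  out <- tibble::as_tibble(setNames(
    lapply(seq_along(cols), function(i) vapply(parts, `[[`, character(1), i)),
    cols
  ))
  out$score <- as.numeric(out$score)
  out
}

#' 2-D embedding projection
#'
#' Projects disease vectors to two dimensions with t-SNE (seeded, via Rtsne)
#' for visual inspection of pathobiological clustering. Plumbing for
#' visualization only; no quantitative claims attach to the layout.
#'
#' @param embedding A `node_embedding`.
#' @param type Node type to project (default diseases).
#' @param seed Integer seed; coordinates are reproducible given it.
#' @param perplexity t-SNE perplexity; defaults to
#'   `min(30, floor((n - 1) / 3))`.
#' @return A tibble (`node`, `x`, `y`).
#' @export
project_2d <- function(embedding, type = "disease", seed = 1,
                       perplexity = NULL) {
  ids <- if (is.null(embedding$types)) rownames(embedding$vectors) else {
    sort(names(embedding$types)[embedding$types == type])
  }
  V <- embedding$vectors[ids, , drop = FALSE]
  n <- nrow(V)
  if (n < 3) abort("need at least 3 nodes with vectors to project")
  if (is.null(perplexity)) perplexity <- max(1, min(30, floor((n - 1) / 3)))
  fit <- withr::with_seed(seed, Rtsne::Rtsne(
    V, dims = 2, perplexity = perplexity, check_duplicates = FALSE,
    pca = FALSE, max_iter = 500
  ))
  tibble::tibble(node = ids, x = fit$Y[, 1], y = fit$Y[, 2])
}

#' Scatter plot of a 2-D projection
#' @param projection A [project_2d()] tibble.
#' @param annotations Optional tibble (`node`, `category`) for coloring.
#' @return A ggplot.
#' @export
plot_projection <- function(projection, annotations = NULL) {
  if (!is.null(annotations)) {
    projection <- dplyr::left_join(projection, annotations, by = "node")
    ggplot2::ggplot(projection,
                    ggplot2::aes(.data$x, .data$y, color = .data$category)) +
      ggplot2::geom_point() + ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(projection, ggplot2::aes(.data$x, .data$y)) +
      ggplot2::geom_point() + ggplot2::theme_minimal()
  }
}
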