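# Independent brute-force oracles used across the suite. None of these call
# the code paths they check.

# Jaccard by raw set arithmetic
oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(unique(c(a, b)))
  if (u == 0) 0 else sum(unique(a) %in% b) / u
}

# AUROC by exhaustive concordant-pair counting (ties count 1/2)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# distinct typed neighbors of a node, recounted from the raw edge tibble
oracle_typed_neighbors <- function(edges, types, node, type) {
  nb <- c(edges$target[edges$source == node], edges$source[edges$target == node])
  sort(unique(nb[types[nb] == type]))
}

# node type registry from a raw edge tibble (column position semantics)
oracle_types <- function(edges) {
  ly <- comorbnet::network_layers()
  st <- ly$source_type[match(edges$layer, ly$layer)]
  tt <- ly$target_type[match(edges$layer, ly$layer)]
  tp <- c(stats::setNames(st, edges$source), stats::setNames(tt, edges$target))
  tp[!duplicated(names(tp))]
}

# sliding-window context enumeration by explicit double loop
oracle_contexts <- function(walk, window) {
  out <- list()
  for (i in seq_along(walk)) {
    for (j in seq_along(walk)) {
      if (i != j && abs(i - j) <= window) {
        out[[length(out) + 1]] <- c(walk[i], walk[j])
      }
    }
  }
  do.call(rbind, out)
}

# negative-sampling objective for one (center, context, negatives) tuple;
# plain R, no clamping
oracle_ns_objective <- function(X, center, context, negatives) {
  sig <- function(x) 1 / (1 + exp(-x))
  v <- X[center, ]
  o <- log(sig(sum(X[context, ] * v)))
  for (u in negatives) o <- o + log(sig(-sum(X[u, ] * v)))
  o
}

# full-softmax skip-gram (single node type), batch gradient ascent on the
# exact likelihood sum_(v,c) log softmax(x_c . x_v) over the given pairs
oracle_softmax_embed <- function(pairs, n_nodes, dim = 8, iters = 300,
                                 lr = 0.5, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n_nodes * dim, -0.5 / dim, 0.5 / dim), n_nodes, dim)
  counts <- matrix(0, n_nodes, n_nodes)  # counts[v, c] = pair multiplicity
  for (k in seq_len(nrow(pairs))) {
    counts[pairs[k, 1], pairs[k, 2]] <- counts[pairs[k, 1], pairs[k, 2]] + 1
  }
  n_pairs <- sum(counts)
  for (it in seq_len(iters)) {
    S <- X %*% t(X)                      # S[v, u] = x_u . x_v
    E <- exp(S - apply(S, 1, max))
    P <- E / rowSums(E)                  # softmax over contexts per center
    # d/dX_c: sum_v counts[v,c] x_v - sum_v rowcount[v] P[v,c] x_v
    rowcount <- rowSums(counts)
    Gc <- t(counts) %*% X - t(P * rowcount) %*% X
    # d/dX_v: sum_c counts[v,c] x_c - rowcount[v] * sum_u P[v,u] x_u
    Gv <- counts %*% X - rowcount * (P %*% X)
    X <- X + lr / n_pairs * (Gc + Gv)
  }
  X
}

# hand-built walk_corpus from explicit walks (for unit-level skipgram tests)
make_corpus <- function(walks, mp) {
  mp <- if (inherits(mp, "metapath")) mp else comorbnet::metapath(mp)
  out <- tibble::tibble(
    metapath = mp$name, walk_id = seq_along(walks),
    start = vapply(walks, `[[`, character(1), 1),
    completed = NA, nodes = walks
  )
  structure(out, class = c("walk_corpus", class(out)), metapath = mp,
            steps = NA_integer_, walks_per_node = NA_integer_,
            seed = NA_integer_, attempts = length(walks), dropped = 0L)
}

# spearman rank correlation
spearman <- function(x, y) stats::cor(x, y, method = "spearman")

two_cliques_net <- function() comorbnet::fixture_network("two_cliques")
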