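#' Synthetic network specification
#'
#' Parameters of the planted-partition generator used to benchmark the whole
#' pipeline without any external data. Diseases are split into clusters;
#' each cluster owns a private pool of miRNAs and genes, and disease-layer
#' edges attach preferentially within the cluster, so same-cluster disease
#' pairs are the planted positives. The `channel` selects which layer
#' carries the cluster signal:
#'
#' * `"mirna-mediated"`: disease-miRNA edges follow the cluster structure;
#'   disease-gene edges are pure background noise.
#' * `"gene-mediated"`: disease-gene edges follow the cluster structure;
#'   each disease gets a small *private* miRNA set shared with no other
#'   disease, so the miRNA-overlap baseline is exactly uninformative while
#'   the gene layers still connect the cluster.
#' * `"both"`: both disease layers follow the cluster structure.
#'
#' Default sizes (2 clusters of 5 diseases, 30 miRNAs, 40 genes) keep the
#' benchmark at desk scale while leaving every walk step well-populated.
#'
#' @param n_disease_clusters,diseases_per_cluster Cluster layout.
#' @param n_mirnas,n_genes Pool sizes, split evenly across clusters.
#' @param p_within,p_cross Bernoulli edge probabilities for the structured
#'   disease layers, within and across clusters.
#' @param p_mirna_gene_within,p_mirna_gene_cross miRNA-target probabilities
#'   to own-cluster and other-cluster genes.
#' @param ppi_edge_probability,ppi_cross_probability Gene-gene (PPI) edge
#'   probabilities within and across cluster gene pools. Each cluster's PPI
#'   subgraph additionally keeps a cycle backbone so no gene is PPI-isolated
#'   (walks through gene-gene steps can always proceed).
#' @param channel Which layer carries the planted signal (see above).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_disease_clusters = 2, diseases_per_cluster = 5,
                           n_mirnas = 30, n_genes = 40,
                           p_within = 0.6, p_cross = 0.05,
                           p_mirna_gene_within = 0.5,
                           p_mirna_gene_cross = 0.05,
                           ppi_edge_probability = 0.3,
                           ppi_cross_probability = 0.02,
                           channel = c("mirna-mediated", "gene-mediated",
                                       "both"),
                           seed = 1) {
  channel <- match.arg(channel)
  probs <- c(p_within, p_cross, p_mirna_gene_within, p_mirna_gene_cross,
             ppi_edge_probability, ppi_cross_probability)
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]")
  counts <- c(n_disease_clusters, diseases_per_cluster, n_mirnas, n_genes)
  if (any(counts < 1)) abort("counts must be positive")
  n_dis <- n_disease_clusters * diseases_per_cluster
  if (channel == "gene-mediated" && n_mirnas < n_dis) {
    abort("gene-mediated channel needs at least one private miRNA per disease")
  }
  structure(list(
    n_disease_clusters = n_disease_clusters,
    diseases_per_cluster = diseases_per_cluster,
    n_mirnas = n_mirnas, n_genes = n_genes,
    p_within = p_within, p_cross = p_cross,
    p_mirna_gene_within = p_mirna_gene_within,
    p_mirna_gene_cross = p_mirna_gene_cross,
    ppi_edge_probability = ppi_edge_probability,
    ppi_cross_probability = ppi_cross_probability,
    channel = channel, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Bernoulli bipartite edges between two ID vectors at probability p.
bern_edges <- function(from, to, p, layer) {
  if (p == 0 || length(from) == 0 || length(to) == 0) {
    return(tibble::tibble(source = character(), target = character(),
                          layer = character()))
  }
  g <- expand.grid(source = from, target = to, stringsAsFactors = FALSE)
  keep <- runif(nrow(g)) < p
  tibble::tibble(source = g$source[keep], target = g$target[keep],
                 layer = layer)
}

#' Generate a synthetic heterogeneous network with planted comorbidities
#'
#' Draws the four layers per [synthetic_spec()], guaranteeing that every
#' disease has at least one edge in each structured layer and that each
#' cluster's gene pool stays PPI-connected. Positives of the labeled set are
#' all same-cluster disease pairs; negatives are cross-cluster pairs sampled
#' 1:1 with the positives under the generator seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `network` ([build_network()]), `labels` (labeled-pair
#'   tibble) and `membership` (tibble `node`, `type`, `cluster`).
#' @examples
#' sim <- generate_synthetic(synthetic_spec(seed = 42))
#' sim$network
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_synthetic_impl(spec))
}

generate_synthetic_impl <- function(spec) {
  K <- spec$n_disease_clusters
  dis <- sprintf("D%02d", seq_len(K * spec$diseases_per_cluster))
  dis_cl <- rep(seq_len(K), each = spec$diseases_per_cluster)
  mir <- sprintf("m%03d", seq_len(spec$n_mirnas))
  mir_cl <- sort(rep_len(seq_len(K), spec$n_mirnas))
  gen <- sprintf("G%03d", seq_len(spec$n_genes))
  gen_cl <- sort(rep_len(seq_len(K), spec$n_genes))

  edges <- list()

  # disease-miRNA layer
  if (spec$channel == "gene-mediated") {
    # private, non-shared miRNA sets: split the pool across diseases
    owner <- sort(rep_len(seq_along(dis), spec$n_mirnas))
    mir_cl <- dis_cl[owner]  # a private miRNA belongs to its owner's cluster
    edges$dm <- tibble::tibble(source = dis[owner], target = mir,
                               layer = "disease-mirna")
  } else {
    dm <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
      dplyr::bind_rows(
        bern_edges(dis[dis_cl == k], mir[mir_cl == k], spec$p_within,
                   "disease-mirna"),
        bern_edges(dis[dis_cl == k], mir[mir_cl != k], spec$p_cross,
                   "disease-mirna")
      )
    }))
    # guarantee one within-cluster miRNA per disease
    for (i in seq_along(dis)) {
      if (!dis[i] %in% dm$source) {
        pool <- mir[mir_cl == dis_cl[i]]
        dm <- dplyr::bind_rows(dm, tibble::tibble(
          source = dis[i], target = pool[sample.int(length(pool), 1)],
          layer = "disease-mirna"))
      }
    }
    edges$dm <- dm
  }

  # disease-gene layer
  if (spec$channel == "mirna-mediated") {
    edges$dg <- bern_edges(dis, gen, spec$p_cross, "disease-gene")
  } else {
    dg <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
      dplyr::bind_rows(
        bern_edges(dis[dis_cl == k], gen[gen_cl == k], spec$p_within,
                   "disease-gene"),
        bern_edges(dis[dis_cl == k], gen[gen_cl != k], spec$p_cross,
                   "disease-gene")
      )
    }))
    for (i in seq_along(dis)) {
      if (!dis[i] %in% dg$source) {
        pool <- gen[gen_cl == dis_cl[i]]
        dg <- dplyr::bind_rows(dg, tibble::tibble(
          source = dis[i], target = pool[sample.int(length(pool), 1)],
          layer = "disease-gene"))
      }
    }
    edges$dg <- dg
  }

  # miRNA-gene layer: miRNAs target own-cluster genes preferentially
  mg <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
    dplyr::bind_rows(
      bern_edges(mir[mir_cl == k], gen[gen_cl == k], spec$p_mirna_gene_within,
                 "mirna-gene"),
      bern_edges(mir[mir_cl == k], gen[gen_cl != k], spec$p_mirna_gene_cross,
                 "mirna-gene")
    )
  }))
  for (i in seq_along(mir)) {
    if (!mir[i] %in% mg$source) {
      pool <- gen[gen_cl == mir_cl[i]]
      mg <- dplyr::bind_rows(mg, tibble::tibble(
        source = mir[i], target = pool[sample.int(length(pool), 1)],
        layer = "mirna-gene"))
    }
  }
  edges$mg <- mg

  # gene-gene (PPI): within-cluster Bernoulli + cycle backbone, sparse cross
  gg <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
    pool <- gen[gen_cl == k]
    pairs <- utils::combn(pool, 2)
    keep <- runif(ncol(pairs)) < spec$ppi_edge_probability
    ring <- tibble::tibble(source = pool,
                           target = pool[c(seq_along(pool)[-1], 1)],
                           layer = "gene-gene")
    dplyr::bind_rows(
      tibble::tibble(source = pairs[1, keep], target = pairs[2, keep],
                     layer = "gene-gene"),
      ring
    )
  }))
  if (K > 1 && spec$ppi_cross_probability > 0) {
    cross <- dplyr::bind_rows(lapply(seq_len(K - 1), function(k) {
      bern_edges(gen[gen_cl == k], gen[gen_cl > k],
                 spec$ppi_cross_probability, "gene-gene")
    }))
    gg <- dplyr::bind_rows(gg, cross)
  }
  edges$gg <- gg

  network <- build_network(dplyr::bind_rows(edges))

  # planted labels
  pos <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
    p <- utils::combn(dis[dis_cl == k], 2)
    tibble::tibble(disease_a = p[1, ], disease_b = p[2, ], label = "positive")
  }))
  cross_pairs <- utils::combn(dis, 2)
  cl_a <- dis_cl[match(cross_pairs[1, ], dis)]
  cl_b <- dis_cl[match(cross_pairs[2, ], dis)]
  cross_pairs <- cross_pairs[, cl_a != cl_b, drop = FALSE]
  n_neg <- min(nrow(pos), ncol(cross_pairs))
  pick <- sort(sample.int(ncol(cross_pairs), n_neg))
  neg <- tibble::tibble(disease_a = cross_pairs[1, pick],
                        disease_b = cross_pairs[2, pick], label = "negative")

  membership <- tibble::tibble(
    node = c(dis, mir, gen),
    type = rep(c("disease", "mirna", "gene"),
               c(length(dis), length(mir), length(gen))),
    cluster = c(dis_cl, mir_cl, gen_cl)
  )
  list(network = network, labels = dplyr::bind_rows(pos, neg),
       membership = membership)
}

#' Built-in hand-written fixture networks
#'
#' Small deterministic networks (at most 30 nodes) used throughout the test
#' suite and examples:
#'
#' * `"chain_M3"`: the 4-node chain D1-G1-G2-D2 (one M3 instance).
#' * `"chain_M1"`: the 6-node chain D1-M1-G1-G2-M2-D2 (one M1 instance).
#' * `"chain_M2"`: the 7-node chain with a G1-G2-G3 middle segment.
#' * `"star3"`: one disease with exactly three miRNA neighbors (uniform
#'   transition fixture).
#' * `"two_cliques"`: 2 clusters x 5 diseases with cluster-private miRNA and
#'   gene pools, fully wired within each cluster.
#'
#' @param name Fixture name.
#' @return A `hetero_network`.
#' @export
fixture_network <- function(name = c("chain_M3", "chain_M1", "chain_M2",
                                     "star3", "two_cliques")) {
  name <- match.arg(name)
  build_network(fixture_edges(name))
}

fixture_edges <- function(name) {
  e <- function(source, target, layer) tibble::tibble(
    source = source, target = target, layer = layer)
  switch(name,
    chain_M3 = dplyr::bind_rows(
      e("D1", "G1", "disease-gene"), e("G1", "G2", "gene-gene"),
      e("D2", "G2", "disease-gene")),
    chain_M1 = dplyr::bind_rows(
      e("D1", "M1", "disease-mirna"), e("M1", "G1", "mirna-gene"),
      e("G1", "G2", "gene-gene"), e("M2", "G2", "mirna-gene"),
      e("D2", "M2", "disease-mirna")),
    chain_M2 = dplyr::bind_rows(
      e("D1", "M1", "disease-mirna"), e("M1", "G1", "mirna-gene"),
      e("G1", "G2", "gene-gene"), e("G2", "G3", "gene-gene"),
      e("M2", "G3", "mirna-gene"), e("D2", "M2", "disease-mirna")),
    star3 = e(rep("D1", 3), c("mA", "mB", "mC"), "disease-mirna"),
    two_cliques = {
      cl <- function(k) {
        dis <- sprintf("D%d%d", k, 1:5)
        mir <- sprintf("m%d%d", k, 1:3)
        gen <- sprintf("G%d%d", k, 1:4)
        gp <- utils::combn(gen, 2)
        dplyr::bind_rows(
          e(rep(dis, each = 3), rep(mir, 5), "disease-mirna"),
          e(rep(dis, each = 4), rep(gen, 5), "disease-gene"),
          e(rep(mir, each = 4), rep(gen, 3), "mirna-gene"),
          e(gp[1, ], gp[2, ], "gene-gene")
        )
      }
      dplyr::bind_rows(cl(1), cl(2))
    }
  )
}

#' @rdname fixture_network
#' @return `fixture_suite()`: a named list of every fixture network.
#' @export
fixture_suite <- function() {
  names <- c("chain_M3", "chain_M1", "chain_M2", "star3", "two_cliques")
  setNames(lapply(names, fixture_network), names)
}

#' Cluster membership labels of the `two_cliques` fixture
#'
#' All same-cluster disease pairs labeled positive and all cross-cluster
#' pairs labeled negative (deterministic, no sampling).
#'
#' @return A labeled-pair tibble.
#' @export
fixture_labels_two_cliques <- function() {
  d1 <- sprintf("D1%d", 1:5); d2 <- sprintf("D2%d", 1:5)
  pos <- cbind(utils::combn(d1, 2), utils::combn(d2, 2))
  neg <- expand.grid(disease_a = d1, disease_b = d2,
                     stringsAsFactors = FALSE)
  dplyr::bind_rows(
    tibble::tibble(disease_a = pos[1, ], disease_b = pos[2, ],
                   label = "positive"),
    tibble::tibble(disease_a = neg$disease_a, disease_b = neg$disease_b,
                   label = "negative")
  )
}
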