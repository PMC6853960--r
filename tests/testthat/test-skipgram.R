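test_that("context extraction enumerates typed window pairs exactly", {
  corp <- make_corpus(list(c("D1", "M1", "G1")), "M1")
  got <- extract_contexts(corp, window = 1)
  expect_equal(
    got[order(got$center, got$context), ],
    tibble::tibble(center = c("D1", "G1", "M1", "M1"),
                   context = c("M1", "M1", "D1", "G1"),
                   context_type = c("mirna", "mirna", "disease", "gene")) |>
      dplyr::arrange(center, context))

  # window-2 case checked against a brute-force double loop
  walk <- c("D1", "M1", "G1", "G2", "M2", "D2")
  got2 <- extract_contexts(make_corpus(list(walk), "M1"), window = 2)
  ora <- oracle_contexts(walk, 2)
  expect_equal(nrow(got2), nrow(ora))
  g1 <- got2[got2$center == "G1", ]
  expect_setequal(g1$context, c("D1", "M1", "G2", "M2"))
  expect_setequal(g1$context_type[g1$context %in% c("M1", "M2")], "mirna")

  # window larger than the walk emits only in-bounds pairs
  expect_equal(nrow(extract_contexts(make_corpus(list(walk), "M1"), 50)),
               nrow(oracle_contexts(walk, 50)))
  # a single-node walk yields no pairs
  expect_equal(nrow(extract_contexts(make_corpus(list("D1"), "M1"), 5)), 0)
})

test_that("negative sampling follows the powered unigram distribution", {
  expect_equal(unique(negative_sample(c(m1 = 5), n = 50)), "m1")
  expect_error(negative_sample(numeric(0)), "empty vocabulary")

  # counts 8:1 at exponent 1 -> draw ratio ~ 8:1 (binomial oracle)
  draws <- negative_sample(c(a = 8, b = 1), n = 10000, noise_exponent = 1,
                           seed = 42)
  p_hat <- mean(draws == "a")
  expect_lt(abs(p_hat - 8 / 9), 3 * sqrt(8 / 9 * 1 / 9 / 10000))

  # exponent -> 0 limit: uniform regardless of counts
  draws0 <- negative_sample(c(a = 1000, b = 1), n = 10000,
                            noise_exponent = 1e-9, seed = 43)
  expect_lt(abs(mean(draws0 == "a") - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("one SGD step matches hand-derived sigmoid factors", {
  X <- matrix(0, nrow = 3, ncol = 4,
              dimnames = list(c("v", "c", "u"), NULL))
  X["c", ] <- c(1, 2, -1, 0.5)
  # x_v = 0 so every dot is 0: positive factor 1 - sigma(0) = 0.5
  Y <- sgd_step(X, "v", "c", "u", learning_rate = 0.1)
  expect_equal(Y["v", ], 0.1 * 0.5 * X["c", ])
  expect_equal(Y["c", ], X["c", ])  # moved by g * x_v = 0
  # zero learning rate leaves everything unchanged
  expect_identical(sgd_step(X, "v", "c", "u", learning_rate = 0), X)
})

test_that("analytic gradients match central finite differences", {
  set.seed(101)
  max_rel <- 0
  for (case in 1:100) {
    n <- 6; d <- 5
    X <- matrix(rnorm(n * d, sd = 0.4), n, d,
                dimnames = list(paste0("n", 1:n), NULL))
    picks <- sample(n, 5)
    center <- rownames(X)[picks[1]]; context <- rownames(X)[picks[2]]
    negs <- rownames(X)[picks[3:5]]
    lr <- 0.05
    G <- (sgd_step(X, center, context, negs, lr, logit_max = 1e9) - X) / lr
    h <- 1e-5
    num <- matrix(0, n, d)
    for (i in seq_len(n)) for (j in seq_len(d)) {
      Xp <- X; Xp[i, j] <- Xp[i, j] + h
      Xm <- X; Xm[i, j] <- Xm[i, j] - h
      ip <- match(c(center, context, negs), rownames(X))
      num[i, j] <- (oracle_ns_objective(Xp, ip[1], ip[2], ip[3:5]) -
                    oracle_ns_objective(Xm, ip[1], ip[2], ip[3:5])) / (2 * h)
    }
    rel <- max(abs(G - num)) / max(1e-12, max(abs(num)))
    max_rel <- max(max_rel, rel)
  }
  expect_lt(max_rel, 1e-5)
})

test_that("training is deterministic, typed, and ascends its objective", {
  # a realistically sized vocabulary: on very small vocabularies the noise
  # rate exceeds every context rate and the optimum sits at the origin
  net <- generate_synthetic(synthetic_spec(seed = 3))$network
  corp <- generate_corpus(net, "M1", steps = 4, walks_per_node = 15, seed = 2)
  cfg <- skipgram_config(dimension = 12, epochs = 4, seed = 7)
  emb1 <- train_embeddings(corp, cfg)
  emb2 <- train_embeddings(corp, cfg)
  expect_identical(emb1$vectors, emb2$vectors)
  expect_true(all(is.finite(emb1$vectors)))
  # every corpus node has one vector of the shared dimension
  expect_setequal(rownames(emb1$vectors), unique(unlist(corp$nodes)))
  expect_equal(ncol(emb1$vectors), 12)
  # types recovered from walk positions agree with the network registry
  types <- oracle_types(net$edges)
  expect_equal(unname(types[rownames(emb1$vectors)]), unname(emb1$types))
  # held-out objective improves from initialization to final epoch
  expect_gt(emb1$objective[length(emb1$objective)], emb1$objective[1])

  # epochs = 0 returns the (seeded, bounded) initialization unchanged
  emb0 <- train_embeddings(corp, skipgram_config(dimension = 12, epochs = 0,
                                                 seed = 7))
  expect_true(all(abs(emb0$vectors) <= 0.5 / 12))
  expect_length(emb0$objective, 1)
})

test_that("planted disease cliques separate in embedding space", {
  net <- two_cliques_net()
  corp <- generate_corpus(net, "M1", steps = 6, walks_per_node = 40, seed = 3)
  emb <- train_embeddings(corp, skipgram_config(dimension = 16, epochs = 5,
                                                seed = 11))
  d1 <- sprintf("D1%d", 1:5); d2 <- sprintf("D2%d", 1:5)
  cos <- function(a, b) cosine_similarity(emb$vectors[a, ], emb$vectors[b, ])
  within <- c(apply(utils::combn(d1, 2), 2, function(p) cos(p[1], p[2])),
              apply(utils::combn(d2, 2), 2, function(p) cos(p[1], p[2])))
  between <- as.vector(outer(d1, d2, Vectorize(cos)))
  expect_gt(mean(within), mean(between))
})

test_that("negative-sampling rankings track the full-softmax solution", {
  # ten nodes of one type, walks from two loosely linked 5-cliques
  set.seed(5)
  nodes <- sprintf("D%02d", 1:10)
  clique <- list(nodes[1:5], nodes[6:10])
  walks <- lapply(1:60, function(k) {
    cl <- clique[[(k %% 2) + 1]]
    cur <- sample(cl, 1)
    out <- cur
    for (s in 1:20) {
      cur <- sample(setdiff(cl, cur), 1)
      out <- c(out, cur)
    }
    out
  })
  mp <- metapath("DD", c("disease", "disease"))
  corp <- make_corpus(walks, mp)
  emb <- train_embeddings(corp, skipgram_config(dimension = 8, window = 2,
                                                epochs = 5, seed = 9))
  ctx <- extract_contexts(corp, window = 2)
  pairs <- cbind(match(ctx$center, nodes), match(ctx$context, nodes))
  Xo <- oracle_softmax_embed(pairs, 10, dim = 8, iters = 300, seed = 2)
  pair_idx <- utils::combn(10, 2)
  cos_ns <- apply(pair_idx, 2, function(p)
    cosine_similarity(emb$vectors[nodes[p[1]], ], emb$vectors[nodes[p[2]], ]))
  cos_sm <- apply(pair_idx, 2, function(p)
    cosine_similarity(Xo[p[1], ], Xo[p[2], ]))
  expect_gt(spearman(cos_ns, cos_sm), 0.7)
})

test_that("embeddings round-trip through the TSV format", {
  net <- two_cliques_net()
  corp <- generate_corpus(net, "M3", steps = 3, walks_per_node = 5, seed = 4)
  emb <- train_embeddings(corp, skipgram_config(dimension = 6, epochs = 1))
  f <- withr::local_tempfile()
  write_embeddings(emb, f)
  expect_match(readLines(f, n = 1), "^#dim=6$")
  back <- read_embeddings(f)
  expect_equal(back$vectors, emb$vectors, tolerance = 1e-12)
  expect_equal(back$types, emb$types)
})

test_that("config validation rejects out-of-range settings", {
  expect_error(skipgram_config(dimension = 0), "dimension")
  expect_error(skipgram_config(epochs = -1), "epochs")
  expect_error(skipgram_config(noise_exponent = 0), "noise_exponent")
  expect_error(skipgram_config(noise_exponent = 1.5), "noise_exponent")
})
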