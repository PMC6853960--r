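test_that("miRNA-overlap similarity equals brute-force Jaccard", {
  expect_equal(overlap_similarity(c("m1", "m2"), c("m2", "m3")), 1 / 3)
  expect_equal(overlap_similarity(c("m1", "m2"), c("m2", "m1")), 1)
  expect_equal(overlap_similarity(character(0), character(0)), 0)
  expect_equal(overlap_similarity(character(0), "m1"), 0)

  set.seed(7)
  pool <- sprintf("m%03d", 1:50)
  for (k in 1:1000) {
    a <- sample(pool, sample(0:12, 1))
    b <- sample(pool, sample(0:12, 1))
    expect_identical(overlap_similarity(a, b), oracle_jaccard(a, b))
    expect_identical(overlap_similarity(a, b), overlap_similarity(b, a))
    expect_true(overlap_similarity(a, b) >= 0 && overlap_similarity(a, b) <= 1)
  }
})

test_that("cosine similarity handles identity, opposition and zero vectors", {
  x <- c(1, 2, 3)
  expect_equal(cosine_similarity(x, x), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(x, -x), -1)
  expect_equal(cosine_similarity(c(0, 0), x[1:2]), 0)
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "dimension")
  set.seed(8)
  for (k in 1:200) {
    a <- rnorm(6); b <- rnorm(6)
    s <- cosine_similarity(a, b)
    expect_true(s >= -1 - 1e-12 && s <= 1 + 1e-12)
    expect_equal(s, cosine_similarity(b, a))
  }
})

test_that("concatenation stacks blocks, zero-fills the missing, keeps cosines", {
  mk <- function(ids, d, seed) {
    set.seed(seed)
    structure(list(
      vectors = matrix(rnorm(length(ids) * d), length(ids), d,
                       dimnames = list(ids, NULL)),
      types = setNames(rep("disease", length(ids)), ids),
      config = NULL, objective = numeric(0)), class = "node_embedding")
  }
  e1 <- mk(c("Da", "Db", "Dc"), 4, 1)
  e2 <- mk(c("Da", "Db"), 3, 2)
  fused <- concatenate_embeddings(list(M1 = e1, M3 = e2), order = c("M1", "M3"))
  expect_equal(ncol(fused$vectors), 7)
  expect_equal(fused$vectors["Dc", 5:7], c(0, 0, 0))
  expect_equal(fused$vectors["Da", 1:4], e1$vectors["Da", ])

  single <- concatenate_embeddings(list(M1 = e1))
  expect_equal(single$vectors, e1$vectors)

  # per-meta-path cosine is preserved when the other block is zero for both
  fc <- cosine_similarity(fused$vectors["Dc", ], fused$vectors["Dc", ] * 2)
  expect_equal(fc, 1)
  e3 <- mk("Dd", 3, 3)
  fused2 <- concatenate_embeddings(list(A = e1, B = e3))
  expect_equal(
    cosine_similarity(fused2$vectors["Da", ], fused2$vectors["Db", ]),
    cosine_similarity(e1$vectors["Da", ], e1$vectors["Db", ]))

  expect_error(concatenate_embeddings(list()), "no embeddings")
  expect_error(concatenate_embeddings(list(A = e1), order = "Z"), "order")
})

test_that("similarity tables hold unique oriented pairs and rank deterministically", {
  tb <- tibble::tibble(
    disease_a = c("A", "A", "B"), disease_b = c("B", "C", "C"),
    score = c(0.9, 0.5, 0.1))
  top <- rank_pairs(tb, 2)
  expect_equal(top$score, c(0.9, 0.5))
  expect_error(rank_pairs(tb, 4), "exceeds")
  expect_equal(nrow(rank_pairs(tb)), 3)

  ties <- tibble::tibble(disease_a = c("B", "A", "A"),
                         disease_b = c("C", "C", "B"),
                         score = c(0.5, 0.5, 0.5))
  expect_equal(rank_pairs(ties, 3)$disease_a, c("A", "A", "B"))
  expect_equal(rank_pairs(ties, 3)$disease_b, c("B", "C", "C"))

  net <- two_cliques_net()
  ov <- overlap_similarity_table(net)
  expect_equal(nrow(ov), choose(10, 2))
  expect_true(all(ov$disease_a < ov$disease_b))
  expect_true(all(ov$score >= 0 & ov$score <= 1))
})

test_that("gene-sharing diseases without shared miRNAs are found by M3 but not overlap", {
  # two diseases tied only through genes; two unrelated diseases elsewhere
  e <- function(s, t, l) tibble::tibble(source = s, target = t, layer = l)
  net <- build_network(dplyr::bind_rows(
    e(rep(c("D1", "D2"), each = 3), rep(c("G1", "G2", "G3"), 2), "disease-gene"),
    e(rep(c("D3", "D4"), each = 3), rep(c("G4", "G5", "G6"), 2), "disease-gene"),
    e(c("G1", "G2", "G1"), c("G2", "G3", "G3"), "gene-gene"),
    e(c("G4", "G5", "G4"), c("G5", "G6", "G6"), "gene-gene"),
    e(c("D1", "D2", "D3", "D4"), c("mA", "mB", "mC", "mD"), "disease-mirna")
  ))
  ov <- overlap_similarity_table(net)
  expect_true(all(ov$score == 0))
  corp <- generate_corpus(net, "M3", steps = 5, walks_per_node = 50, seed = 13)
  emb <- train_embeddings(corp, skipgram_config(dimension = 12, epochs = 5,
                                                seed = 14))
  sims <- disease_similarity(emb)
  linked <- sims$score[sims$disease_a == "D1" & sims$disease_b == "D2"]
  expect_gt(linked, stats::median(sims$score))
})

test_that("diseases without vectors stay rankable at zero similarity", {
  ids <- c("Da", "Db")
  emb <- structure(list(
    vectors = matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
                     dimnames = list(ids, NULL)),
    types = setNames(rep("disease", 2), ids),
    config = NULL, objective = numeric(0)), class = "node_embedding")
  sims <- disease_similarity(emb, diseases = c("Da", "Db", "Dmissing"))
  expect_equal(nrow(sims), 3)
  miss <- sims$score[sims$disease_a == "Da" & sims$disease_b == "Dmissing"]
  expect_equal(miss, 0)
})
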