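sim_table <- function(a, b, s) {
  tibble::tibble(disease_a = a, disease_b = b, score = s,
                 method = "test", metapaths = NA_character_)
}

rand_labeled_case <- function(n_pos, n_neg, tie_prob = 0.3) {
  n <- n_pos + n_neg
  ids_a <- sprintf("A%02d", 1:n)
  ids_b <- sprintf("B%02d", 1:n)
  scores <- round(runif(n), digits = if (runif(1) < tie_prob) 1 else 6)
  list(sims = sim_table(ids_a, ids_b, scores),
       labels = tibble::tibble(disease_a = ids_a, disease_b = ids_b,
                               label = rep(c("positive", "negative"),
                                           c(n_pos, n_neg))))
}

test_that("AUROC matches exhaustive concordant-pair counting (with ties)", {
  set.seed(31)
  for (k in 1:40) {
    case <- rand_labeled_case(sample(2:10, 1), sample(2:10, 1))
    res <- evaluate_predictions(case$sims, case$labels)
    expect_equal(res$auroc,
                 oracle_auroc(case$sims$score,
                              case$labels$label == "positive"),
                 tolerance = 1e-9)
  }
})

test_that("AUROC equals the trapezoidal ROC integral and pROC agrees", {
  set.seed(32)
  for (k in 1:20) {
    case <- rand_labeled_case(15, 20)
    res <- evaluate_predictions(case$sims, case$labels)
    roc <- res$points[res$points$curve == "roc", ]
    trap <- sum(diff(roc$x) * (head(roc$y, -1) + roc$y[-1]) / 2)
    expect_equal(res$auroc, trap, tolerance = 1e-9)
    p <- as.numeric(pROC::auc(pROC::roc(
      response = case$labels$label, predictor = case$sims$score,
      levels = c("negative", "positive"), direction = "<", quiet = TRUE)))
    expect_equal(res$auroc, p, tolerance = 1e-9)
  }
})

test_that("degenerate and null score configurations behave as expected", {
  perfect <- sim_table(sprintf("A%d", 1:6), sprintf("B%d", 1:6),
                       c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))
  labels <- tibble::tibble(disease_a = perfect$disease_a,
                           disease_b = perfect$disease_b,
                           label = rep(c("positive", "negative"), each = 3))
  res <- evaluate_predictions(perfect, labels)
  expect_equal(res$auroc, 1)
  expect_equal(res$aupr, 1)

  set.seed(33)
  big <- rand_labeled_case(1000, 1000, tie_prob = 0)
  expect_lt(abs(evaluate_predictions(big$sims, big$labels)$auroc - 0.5), 0.05)

  # all scores tied: rank statistic gives exactly 1/2
  tied <- sim_table(sprintf("A%d", 1:4), sprintf("B%d", 1:4), rep(0.5, 4))
  tl <- tibble::tibble(disease_a = tied$disease_a, disease_b = tied$disease_b,
                       label = c("positive", "positive", "negative", "negative"))
  expect_equal(evaluate_predictions(tied, tl)$auroc, 0.5)

  single <- tl; single$label <- "positive"
  expect_error(evaluate_predictions(tied, single), "both positive and negative")
})

test_that("evaluation is invariant to strictly monotone score transforms", {
  set.seed(34)
  case <- rand_labeled_case(12, 12)
  base <- evaluate_predictions(case$sims, case$labels)
  for (f in list(function(s) 2 * s + 1, exp, function(s) s^3)) {
    tr <- case$sims; tr$score <- f(tr$score)
    res <- evaluate_predictions(tr, case$labels)
    expect_equal(res$auroc, base$auroc, tolerance = 1e-12)
    expect_equal(res$aupr, base$aupr, tolerance = 1e-12)
  }
})

test_that("labeled pairs with unknown diseases are dropped with a count", {
  case <- rand_labeled_case(3, 3)
  labels <- dplyr::bind_rows(
    case$labels,
    tibble::tibble(disease_a = "Zq", disease_b = "Zr", label = "positive"))
  expect_message(res <- evaluate_predictions(case$sims, labels), "dropped 1")
  expect_equal(res$n_dropped, 1)
  expect_equal(res$n_pos, 3)
  # pair orientation does not matter for matching
  flipped <- case$labels
  flipped[1, c("disease_a", "disease_b")] <- flipped[1, c("disease_b", "disease_a")]
  expect_equal(evaluate_predictions(case$sims, flipped)$auroc,
               evaluate_predictions(case$sims, case$labels)$auroc)
})

test_that("negative-pair sampling avoids positives and is seed-stable", {
  dis <- sprintf("D%02d", 1:12)
  pos <- tibble::tibble(disease_a = dis[1:5], disease_b = dis[2:6])
  neg <- make_negative_pairs(dis, pos, n = 10, seed = 99)
  expect_equal(nrow(neg), 10)
  key <- function(tb) paste(pmin(tb$disease_a, tb$disease_b),
                            pmax(tb$disease_a, tb$disease_b))
  expect_length(intersect(key(neg), key(pos)), 0)
  expect_identical(neg, make_negative_pairs(dis, pos, n = 10, seed = 99))
  expect_false(identical(neg, make_negative_pairs(dis, pos, n = 10, seed = 100)))
  expect_error(make_negative_pairs(dis[1:3], pos[1:2, ], n = 50), "not enough")
})

test_that("GEXF export carries the pairs and the TSV round-trips", {
  set.seed(35)
  tb <- rank_pairs(sim_table(sprintf("Da%d", 1:8), sprintf("Db%d", 1:8),
                             runif(8)), 5)
  gexf <- withr::local_tempfile(fileext = ".gexf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(tb, gexf, tsv = tsv,
                 annotations = tibble::tibble(node = "Da1", category = "cancer"))
  doc <- xml2::read_xml(gexf)
  edges <- xml2::xml_find_all(doc, ".//*[local-name()='edge']")
  expect_length(edges, 5)
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='node']")
  expect_length(nodes, length(unique(c(tb$disease_a, tb$disease_b))))
  back <- read_similarity(tsv)
  expect_equal(back$disease_a, tb$disease_a)
  expect_equal(back$score, tb$score, tolerance = 1e-12)

  empty <- withr::local_tempfile(fileext = ".gexf")
  export_network(tb[0, ], empty)
  expect_length(xml2::xml_find_all(xml2::read_xml(empty),
                                   ".//*[local-name()='edge']"), 0)
})

test_that("2-D projection is seeded and separates planted clusters", {
  set.seed(36)
  ids <- sprintf("D%02d", 1:20)
  V <- rbind(matrix(rnorm(10 * 8, mean = 3), 10, 8),
             matrix(rnorm(10 * 8, mean = -3), 10, 8))
  rownames(V) <- ids
  emb <- structure(list(vectors = V,
                        types = setNames(rep("disease", 20), ids),
                        config = NULL, objective = numeric(0)),
                   class = "node_embedding")
  pr <- project_2d(emb, seed = 4)
  expect_equal(nrow(pr), 20)
  expect_identical(pr, project_2d(emb, seed = 4))
  d2 <- function(i, j) sqrt((pr$x[i] - pr$x[j])^2 + (pr$y[i] - pr$y[j])^2)
  within <- c(utils::combn(1:10, 2, function(p) d2(p[1], p[2])),
              utils::combn(11:20, 2, function(p) d2(p[1], p[2])))
  between <- as.vector(outer(1:10, 11:20, Vectorize(d2)))
  expect_lt(mean(within), mean(between))

  few <- emb; few$vectors <- few$vectors[1:2, ]; few$types <- few$types[1:2]
  expect_error(project_2d(few), "at least 3")
})

test_that("tidy/glance/autoplot expose the curve result", {
  set.seed(37)
  case <- rand_labeled_case(8, 8)
  res <- evaluate_predictions(case$sims, case$labels)
  td <- tidy(res)
  expect_setequal(unique(td$curve), c("roc", "pr"))
  gl <- glance(res)
  expect_equal(gl$auroc, res$auroc)
  expect_s3_class(autoplot(res), "ggplot")
})
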