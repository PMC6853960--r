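#' Read a pipeline configuration
#'
#' YAML (or JSON) with the fields accepted by [run_pipeline()]:
#'
#' ```yaml
#' layers:
#'   disease-mirna: dm.tsv
#'   mirna-gene:    mg.tsv
#'   disease-gene:  dg.tsv
#'   gene-gene:     gg.tsv
#' metapaths: [M1, M3]
#' walk:     {steps: 50, walks_per_node: 1000}
#' skipgram: {dimension: 128, window: 5, negatives: 5, epochs: 5}
#' labels:   labels.tsv      # optional
#' out_dir:  results
#' seed:     7
#' ```
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  cfg$layers <- lapply(cfg$layers, function(p) {
    if (file.exists(p)) p else file.path(base, p)
  })
  if (!is.null(cfg$labels) && !file.exists(cfg$labels)) {
    cfg$labels <- file.path(base, cfg$labels)
  }
  cfg
}

validate_pipeline_config <- function(config) {
  if (is.null(config$network)) {
    if (is.null(config$layers) || length(config$layers) == 0) {
      abort("config needs `layers` (named file paths) or a `network` object")
    }
    bad <- setdiff(names(config$layers), network_layers()$layer)
    if (length(bad) > 0) abort(paste0("unknown layer(s): ",
                                      paste(bad, collapse = ", ")))
    missing <- unlist(config$layers)[!file.exists(unlist(config$layers))]
    if (length(missing) > 0) abort(paste0("layer file not found: ", missing[1]))
  }
  mps <- config$metapaths %||% c("M1", "M3")
  if (anyDuplicated(mps)) abort("meta-path names must be unique")
  if (is.character(config$labels) && !file.exists(config$labels)) {
    abort(paste0("labels file not found: ", config$labels))
  }
  invisible(config)
}

# Atomically commit a file: stages write to <path>.partial, then rename.
commit_file <- function(partial, path) {
  file.rename(partial, path)
  path
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the four-step comorbidity pipeline
#'
#' Integrates the network layers, generates one walk corpus and trains one
#' embedding per meta-path, concatenates the per-meta-path disease vectors,
#' scores every disease pair by cosine similarity, and (when labels are
#' supplied) evaluates ROC/PR. One global seed deterministically derives
#' per-stage seeds (`seed + stage index`), so two runs with the same
#' configuration produce byte-identical similarity tables. Each output file
#' is written to `<name>.partial` and renamed on success, so a failed stage
#' leaves only `.partial` files behind.
#'
#' @param config A configuration list (see [read_pipeline_config()]); may
#'   carry a prebuilt `network` element instead of `layers`.
#' @return The run manifest (also written to `out_dir/manifest.json`):
#'   versions, seeds, parameters and SHA-256 digests of the outputs.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1)
  mps <- config$metapaths %||% c("M1", "M3")
  walk_cfg <- utils::modifyList(list(steps = 50, walks_per_node = 1000),
                                config$walk %||% list())
  sg_args <- utils::modifyList(
    list(dimension = 128, window = 5, negatives = 5, epochs = 5),
    config$skipgram %||% list())

  network <- run_stage("integrate", {
    if (!is.null(config$network)) config$network
    else {
      edges <- dplyr::bind_rows(lapply(names(config$layers), function(l) {
        read_edge_list(config$layers[[l]], l)
      }))
      build_network(edges)
    }
  })

  stage_seeds <- list()
  stage_i <- 0L
  embeddings <- list()
  files <- character(0)
  for (mp in mps) {
    stage_i <- stage_i + 1L
    walk_seed <- seed + stage_i
    stage_seeds[[paste0("walk_", mp)]] <- walk_seed
    corpus <- run_stage(paste0("walk:", mp), generate_corpus(
      network, mp, steps = walk_cfg$steps,
      walks_per_node = walk_cfg$walks_per_node, seed = walk_seed))
    stage_i <- stage_i + 1L
    train_seed <- seed + stage_i
    stage_seeds[[paste0("train_", mp)]] <- train_seed
    emb <- run_stage(paste0("train:", mp), train_embeddings(
      corpus, do.call(skipgram_config, c(sg_args, list(seed = train_seed)))))
    emb_path <- file.path(out_dir, paste0("emb_", mp, ".tsv"))
    write_embeddings(emb, paste0(emb_path, ".partial"))
    files[paste0("emb_", mp)] <- commit_file(paste0(emb_path, ".partial"),
                                             emb_path)
    embeddings[[mp]] <- emb
  }

  fused <- run_stage("concatenate", concatenate_embeddings(
    embeddings, order = config$fusion_order %||% mps))
  sims <- run_stage("score", disease_similarity(
    fused, diseases = nodes_of_type(network, "disease"), metapaths = mps))
  sims_path <- file.path(out_dir, "sims.tsv")
  write_similarity(sims, paste0(sims_path, ".partial"))
  files["sims"] <- commit_file(paste0(sims_path, ".partial"), sims_path)

  metrics <- NULL
  if (!is.null(config$labels)) {
    labels <- if (is.character(config$labels)) {
      read_labeled_pairs(config$labels)
    } else {
      config$labels
    }
    curves <- run_stage("evaluate", evaluate_predictions(sims, labels))
    metrics <- list(auroc = curves$auroc, aupr = curves$aupr,
                    n_pos = curves$n_pos, n_neg = curves$n_neg,
                    seed = seed, aupr_estimator = curves$aupr_estimator)
    metrics_path <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(metrics, paste0(metrics_path, ".partial"),
                         auto_unbox = TRUE, digits = NA)
    files["metrics"] <- commit_file(paste0(metrics_path, ".partial"),
                                    metrics_path)
  }

  manifest <- list(
    package = "comorbnet",
    version = as.character(utils::packageVersion("comorbnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    stage_seeds = stage_seeds,
    parameters = list(metapaths = mps, walk = walk_cfg, skipgram = sg_args,
                      fused_dimension = ncol(fused$vectors)),
    metrics = metrics,
    files = lapply(as.list(files), function(p) {
      list(path = p, sha256 = digest::digest(file = p, algo = "sha256"))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paste0(manifest_path, ".partial"),
                       auto_unbox = TRUE, digits = NA)
  commit_file(paste0(manifest_path, ".partial"), manifest_path)
  invisible(manifest)
}
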