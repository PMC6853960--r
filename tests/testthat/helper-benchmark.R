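# End-to-end planted-partition benchmark: walk + train per meta-path, fuse,
# score, and evaluate both the embedding method and the overlap baseline
# against the planted labels.
run_benchmark <- function(channel, seed = 1, dimension = 32, steps = 10,
                          walks_per_node = 200,
                          metapaths = c("M1", "M3")) {
  sim <- comorbnet::generate_synthetic(
    comorbnet::synthetic_spec(channel = channel, seed = seed))
  embs <- list()
  for (i in seq_along(metapaths)) {
    mp <- metapaths[i]
    corp <- comorbnet::generate_corpus(sim$network, mp, steps = steps,
                                       walks_per_node = walks_per_node,
                                       seed = seed + i)
    embs[[mp]] <- comorbnet::train_embeddings(
      corp, comorbnet::skipgram_config(dimension = dimension,
                                       seed = seed + 10 + i))
  }
  fused <- comorbnet::concatenate_embeddings(embs, order = metapaths)
  sims <- comorbnet::disease_similarity(
    fused, diseases = comorbnet::nodes_of_type(sim$network, "disease"),
    metapaths = metapaths)
  ov <- comorbnet::overlap_similarity_table(sim$network)
  list(
    metapath = comorbnet::evaluate_predictions(sims, sim$labels),
    overlap = comorbnet::evaluate_predictions(ov, sim$labels)
  )
}
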