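layers:
  disease-mirna: disease_mirna.tsv
  mirna-gene: mirna_gene.tsv
  disease-gene: disease_gene.tsv
  gene-gene: gene_gene.tsv
metapaths:
- M1
- M3
walk:
  steps: 10.0
  walks_per_node: 50.0
skipgram:
  dimension: 16.0
  window: 5.0
  negatives: 5.0
  epochs: 3.0
labels: labels.tsv
out_dir: results
seed: 7.0
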