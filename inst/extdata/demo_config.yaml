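# Demo cohort: scaled-down two-genotype study with the preset contrasts.
genome_length: 40000
gc_content: 0.42
n_germline: 30
mean_depth: 150
purity: 0.8
seed: 20260927
groups:
  wt_like:
    n_tumors: 2
    mutations_per_tumor: 150
  ki_like:
    n_tumors: 2
    mutations_per_tumor: 250
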