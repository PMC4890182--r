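#!/usr/bin/env Rscript
# Generate the synthetic paired fimbrial/proximal study: a 20,000-probe
# beta-value matrix for 30 carrier and 30 control subjects (one fimbrial and
# one proximal sample each), detection p-values, probe annotation, toy gene
# sets, chromatin-mark peak tracks, and the planted ground truth.
suppressMessages(library(fimbmeth))

cfg <- sim_config(seed = 20160524L)
sim <- simulate_dataset(cfg)
tracks <- simulate_peak_tracks(sim$annotation, sim$truth, cfg)
gene_sets <- simulate_gene_sets(sim$annotation, cfg)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
write_meth_dataset(sim$dataset, "results/data")
write_annotation(sim$annotation, "results/data/annotation.tsv")
write_peak_tracks(tracks, "results/data/tracks")
write_gmt(gene_sets, "results/data/gene_sets.gmt")
jsonlite::write_json(
  list(spiked_mut_only = sim$truth$spiked_mut_only,
       spiked_shared = sim$truth$spiked_shared,
       direction = as.list(sim$truth$direction),
       enriched_tissue_marks = sim$truth$enriched_tissue_marks),
  "results/data/ground_truth.json")

cat(sprintf("simulated %d probes x %d samples; %d MUT-only and %d shared spiked CpGs\n",
            nrow(sim$dataset$beta), ncol(sim$dataset$beta),
            length(sim$truth$spiked_mut_only),
            length(sim$truth$spiked_shared)))
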