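#!/usr/bin/env Rscript
# Regulatory-region enrichment: the top-1000 hypo- and hypermethylated DMPs
# are overlapped with each (tissue, mark) peak track; 1,000 background probe
# sets matched on gene- and CpG-island-relationship annotation give the
# pooled binomial enrichment p, BY-corrected across tracks.
suppressMessages(library(fimbmeth))

dmps <- as.data.frame(data.table::fread("results/dmp/dmp_table.tsv"))
ann <- read_annotation("results/data/annotation.tsv")
tracks <- read_peak_tracks("results/data/tracks")
cfg <- sim_config(seed = 20160524L)  # must match analysis/01_simulate.R

dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)
for (stratum in c("hyper", "hypo")) {
  probes <- suppressWarnings(select_top_probes(dmps, n = 1000,
                                               direction = stratum))
  if (length(probes) == 0) next
  enr <- region_enrichment(probes, tracks, ann, n_sets = 1000,
                           seed = cfg$seed + 31L)
  data.table::fwrite(enr, sprintf("results/enrichment/enrichment_%s.tsv",
                                  stratum), sep = "\t")
  cat(sprintf("%s (%d probes): significant tracks at BY q < 0.05:\n",
              stratum, length(probes)))
  sig <- enr[enr$significant, c("tissue", "mark", "observed_overlap",
                                "background_mean", "neg_log10_p", "q")]
  print(sig, row.names = FALSE)
}
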