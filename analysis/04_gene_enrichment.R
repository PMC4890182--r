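#!/usr/bin/env Rscript
# Gene-level inference: per-gene binomial tests for an excess of significant
# CpGs (separately for hyper- and hypomethylated strata), then one-sided
# Fisher gene-set enrichment of the significant genes.
suppressMessages(library(fimbmeth))

dmps <- as.data.frame(data.table::fread("results/dmp/dmp_table.tsv"))
ann <- read_annotation("results/data/annotation.tsv")
gene_sets <- read_gmt("results/data/gene_sets.gmt")
universe_genes <- unique(unlist(strsplit(ann$genes[ann$genes != ""], ";",
                                         fixed = TRUE)))

dir.create("results/gsea", showWarnings = FALSE, recursive = TRUE)
for (stratum in c("hyper", "hypo")) {
  gt <- gene_binomial_test(dmps, ann, stratum)
  data.table::fwrite(gt, sprintf("results/gsea/gene_tests_%s.tsv", stratum),
                     sep = "\t")
  sig_genes <- gt$gene[gt$q < 0.05]
  gs <- fisher_gsea(sig_genes, universe_genes, gene_sets)
  data.table::fwrite(gs, sprintf("results/gsea/gsea_%s.tsv", stratum),
                     sep = "\t")
  cat(sprintf("%s: %d significant genes, %d enriched gene sets (q < 0.05)\n",
              stratum, length(sig_genes), sum(gs$q < 0.05)))
}
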