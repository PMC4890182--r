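#!/usr/bin/env Rscript
# Paired differential methylation per group (moderated paired t, BH FDR),
# set-difference DMP calling (significant in carriers, not in controls,
# |median delta-beta| > 0.03), and the per-volunteer heterogeneity summary.
suppressMessages(library(fimbmeth))

ds <- read_meth_dataset("results/qc")
stats_mut <- dmp_group_stats(ds, "MUT")
stats_ctrl <- dmp_group_stats(ds, "control")
dmps <- call_dmps(stats_mut, stats_ctrl)

dir.create("results/dmp", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(dmps, "results/dmp/dmp_table.tsv", sep = "\t")
writeLines(dmps$probe_id[dmps$dmp & dmps$direction == "hyper"],
           "results/dmp/dmps_hyper.txt")
writeLines(dmps$probe_id[dmps$dmp & dmps$direction == "hypo"],
           "results/dmp/dmps_hypo.txt")

cat(sprintf("significant CpGs: %d in carriers, %d in controls (ratio %.2f)\n",
            sum(dmps$sig_mut), sum(dmps$sig_ctrl),
            sum(dmps$sig_mut) / sum(dmps$sig_ctrl)))
cat(sprintf("retained DMPs: %d (%.0f%% hypo / %.0f%% hyper)\n",
            sum(dmps$dmp),
            100 * mean(dmps$direction[dmps$dmp] == "hypo"),
            100 * mean(dmps$direction[dmps$dmp] == "hyper")))
het <- heterogeneity_summary(attr(stats_mut, "diffs"), dmps)
cat(sprintf("volunteers exceeding delta-beta 0.1 / 0.2 at called DMPs: %.0f%% / %.0f%%\n",
            100 * het[["frac_gt_0.1"]], 100 * het[["frac_gt_0.2"]]))
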