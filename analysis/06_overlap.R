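#!/usr/bin/env Rscript
# Cross-cohort overlap: simulate a second, cancer-like cohort that shares
# the planted reprogrammed CpGs, contrast fimbrial carriers vs controls in
# both cohorts by group medians, and test the top-5000 increase/decrease
# lists for overlap with Fisher's exact test (odds ratio with 95% CI).
suppressMessages(library(fimbmeth))

cfg <- sim_config(seed = 20160524L)  # must match analysis/01_simulate.R
ds1 <- read_meth_dataset("results/qc")
truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)
truth$direction <- unlist(truth$direction)
class(truth) <- "ground_truth"

cfg2 <- cfg
cfg2$seed <- cfg$seed + 1L
sim2 <- simulate_dataset(cfg2, truth = truth)
ds2 <- knn_impute(qc_filter(sim2$dataset), k = 5)

universe <- intersect(rownames(ds1$beta), rownames(ds2$beta))
eff <- lapply(list(ds1, ds2), function(ds) {
  s <- ds$samples
  contrast_effects(
    ds$beta[universe, s$sample_id[s$site == "fimbrial" & s$group == "MUT"]],
    ds$beta[universe, s$sample_id[s$site == "fimbrial" & s$group == "control"]])
})

k <- min(5000L, length(universe))
res <- do.call(rbind, lapply(c("increase", "decrease"), function(sg) {
  fisher_overlap(top_k_by_delta(eff[[1]], k, sg),
                 top_k_by_delta(eff[[2]], k, sg), universe,
                 name_a = paste0("fimbrial_", sg),
                 name_b = paste0("cancer_", sg))
}))
dir.create("results/overlap", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(res, "results/overlap/overlap.tsv", sep = "\t")
print(res[, c("list_a_name", "list_b_name", "overlap", "odds_ratio",
              "ci_low", "ci_high", "p")], row.names = FALSE)
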