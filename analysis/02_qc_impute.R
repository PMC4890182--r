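#!/usr/bin/env Rscript
# Quality control and imputation: drop samples with < 80% probe coverage,
# then probes with < 95% sample coverage (detection p <= 0.05 counts as
# covered), and replace the remaining failed entries by 5-nearest-probe KNN
# imputation.
suppressMessages(library(fimbmeth))

ds <- read_meth_dataset("results/data")
cat(sprintf("input: %d probes x %d samples\n", nrow(ds$beta), ncol(ds$beta)))
ds <- qc_filter(ds)
ds <- knn_impute(ds, k = 5)
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write_meth_dataset(ds, "results/qc")
cat(sprintf("after QC: %d probes x %d samples\n", nrow(ds$beta), ncol(ds$beta)))
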