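# fimbmeth

Paired fimbrial-proximal DNA-methylation reprogramming analysis for
Illumina 450k-style beta-value data.

## The problem

High-grade serous "ovarian" carcinomas in *BRCA1/2* mutation carriers
originate in the fimbrial (ovary-adjacent) end of the fallopian tube and
not in its proximal (uterus-adjacent) end. Comparing the methylomes of the
two ends *within* each subject cancels person-level epigenetic background,
so an excess of fimbrial-vs-proximal differentially methylated CpGs (DMPs)
in mutation carriers over controls measures site-specific pre-malignant
epigenetic reprogramming. `fimbmeth` implements the full inference chain
for epidemiologists and computational biologists working with such paired
450k designs, and ships a synthetic-data generator with planted ground
truth so the whole pipeline is testable without any external download.

The chain, per stage:

1. **QC / imputation** — entries with detection p ≤ 0.05 count as covered;
   samples with < 80% coverage are removed, then probes with < 95%
   coverage; remaining failures are KNN-imputed (probe-space, *k* = 5).
2. **Paired differential methylation** — per group, a one-sample
   empirical-Bayes moderated t on the per-subject differences
   *d<sub>gs</sub>* = β<sup>fimb</sup> − β<sup>prox</sup>: posterior
   variance *s̃²* = (d₀s₀² + (n−1)s²)/(d₀ + n − 1) with the prior (d₀, s₀²)
   from closed-form log-variance moment matching; BH FDR per group.
3. **Set-difference DMP calling** — CpGs with q < 0.05 in carriers and not
   in controls, retained when |median Δβ| > 0.03 across carrier subjects,
   split into hyper/hypo by the median's sign; per-volunteer exceedance
   summaries at Δβ > 0.1 and > 0.2.
4. **Gene / gene-set enrichment** — one-sided per-gene binomial tests
   P(X ≥ x | n, π) against the stratum background rate π, and one-sided
   Fisher exact tests of significant genes against GMT gene sets; BH
   across genes / sets.
5. **Region enrichment** — the top-1000 hypo/hyper DMPs are overlapped
   with chromatin-mark peak tracks (BED); 1,000 background probe sets
   matched on gene- and CpG-island-relationship annotation give a pooled
   binomial upper-tail p, BY-corrected across (tissue, mark) tracks.
6. **Cross-list overlap** — top-5,000 probes by group-median contrast in
   two cohorts, Fisher exact overlap p with sample odds ratio and 95%
   Woolf CI.

## Worked example

The `analysis/` directory holds the numbered drivers of the full study
(`01_simulate.R` … `06_overlap.R`), which write their tables under
`results/`. In brief:

```r
library(fimbmeth)

cfg <- sim_config(seed = 20160524)        # 30+30 subjects, 20k probes
sim <- simulate_dataset(cfg)              # dataset + annotation + truth
ds  <- knn_impute(qc_filter(sim$dataset))
dmp <- call_dmps(dmp_group_stats(ds, "MUT"),
                 dmp_group_stats(ds, "control"))
sum(dmp$sig_mut); sum(dmp$sig_ctrl); sum(dmp$dmp)
```

Running the drivers end-to-end prints, for the default seed:

```
significant CpGs: 791 in carriers, 260 in controls (ratio 3.04)
retained DMPs: 521 (82% hypo / 18% hyper)
volunteers exceeding delta-beta 0.1 / 0.2 at called DMPs: 48% / 6%
```

— the carrier excess of site-differential CpGs (~3-fold), its strong skew
towards hypomethylation, and the heterogeneity of the signal across
subjects. The region-enrichment driver then flags exactly the planted
(tissue, mark) track:

```
hypo (429 probes): significant tracks at BY q < 0.05:
 tissue    mark observed_overlap background_mean neg_log10_p            q
    T01 H3K4me1              131          43.307    30.84232 1.371583e-29
```

and the overlap driver shows that a second cohort sharing the planted
CpGs reproduces a significant top-5,000 list overlap (decrease lists:
OR 1.44, 95% CI 1.34-1.55, p ≈ 9e-24) while the increase direction, which
carries only 19% of the spikes, stays near the null.

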