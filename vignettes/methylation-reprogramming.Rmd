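---
title: "Detecting paired fimbrial-proximal methylation reprogramming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting paired fimbrial-proximal methylation reprogramming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

High-grade serous "ovarian" carcinomas in *BRCA1/2* mutation carriers arise
from the fimbrial (distal, ovary-adjacent) end of the fallopian tube, not
from its proximal (uterus-adjacent) end. Comparing the DNA methylome of the
two ends *within* each woman cancels person-level epigenetic background
(age, exposures), so an excess of fimbrial-vs-proximal differentially
methylated CpGs in carriers relative to controls is a readout of
site-specific pre-malignant epigenetic reprogramming. This package
implements that inference chain for Illumina 450k-style beta-value matrices
and exercises it end-to-end on synthetic data with planted ground truth.

## The model and procedure

**Input and QC.** Beta values $\beta \in [0,1]$ are taken as
background-corrected, without further normalization. An entry is *covered*
when its detection p-value is $\le 0.05$. Samples with $<80\%$ coverage are
removed first; probes with $<95\%$ coverage across the remaining samples
second — the order matters, and `qc_filter()` fixes it as samples-then-probes.
Remaining failed entries are replaced by KNN imputation with $k=5$:
neighbours are *probes*, distance is Euclidean between probe rows over the
samples where the target row is observed, and the imputed value is the mean
of the $k$ nearest probes' values in the affected sample. The neighbour
space and metric are conventions (the standard microarray choice); they are
isolated inside `knn_impute()`, and distance ties are broken by probe-id
order so results are reproducible.

**Paired moderated t.** For each group (carriers, controls) separately, the
per-subject difference $d_{gs} = \beta^{fimb}_{gs} - \beta^{prox}_{gs}$ is
formed for subjects with both sites. With complete pairs, a two-group model
with subject blocking is equivalent to a one-sample test on the
differences, and the difference form is exactly testable, so that is what
`moderated_paired_test()` fits: per probe $g$ with $n$ pairs, mean
$\bar d_g$ and unbiased variance $s_g^2$, an empirical-Bayes prior
$s_g^2 \sim s_0^2 \chi^{-2}_{d_0}$ estimated by the closed-form log-variance
moment matching (with $z_g=\log s_g^2$ and $d=n-1$,
$e_g = z_g - \psi(d/2) + \log(d/2)$ has mean $\log\sigma_g^2$ and excess
dispersion $\psi'(d_0/2)$), posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$, moderated
$t_g = \bar d_g / (\tilde s_g/\sqrt n)$, and two-sided p-values on
$d_0 + d$ degrees of freedom.

Two numerical corners are worth stating. When the excess dispersion of
$e_g$ is not positive there is no spread prior to fit: we set $d_0=\infty$
with $s_0^2 = \exp(\overline{\log s^2})$, the geometric mean, which is the
continuous $d_0\to\infty$ limit of the finite formula and reduces exactly
to the common variance when all $s_g^2$ are equal (so the moderated t then
*equals* the ordinary t, as it should when there is nothing to shrink).
And forcing $d_0 = 0$ recovers the ordinary paired t, which the tests use
as a limit contract. The trigamma inverse is solved by Newton iteration;
the test suite cross-checks p-values against an independent
re-implementation (bisection-based) at $10^{-10}$ and against `limma`.

**Set-difference DMP calling.** Within each group, q-values are
Benjamini-Hochberg over all probes; `sig` means $q < 0.05$ (strict, as are
all thresholds here). `mut_not_ctrl = sig_mut & !sig_ctrl` — the control
FDR is computed over *all* probes (the standard choice; computing it only
over carrier-significant probes would make the control list depend on the
carrier one). Retained DMPs additionally require
$|\mathrm{median}_s\, d_{gs}| > 0.03$ across carrier subjects; the median's
sign assigns the `hyper`/`hypo` direction. `heterogeneity_summary()`
reports, per threshold $\theta \in \{0.1, 0.2\}$, the mean over DMPs of the
fraction of subjects exceeding $\theta$ in the DMP's direction — the
between-volunteer heterogeneity view of the same signal. For single-array
cell-line contrasts, `cellline_delta_dmps()` applies a plain strict
delta-beta threshold (0.3 down to 0.07 depending on the line).

**Gene and gene-set enrichment.** With background rate $\pi$ = (significant
CpGs in a direction stratum)/(all CpGs), each gene with $n$ CpGs and $x$
significant gets the one-sided binomial tail $P(X \ge x \mid n, \pi)$, BH
across genes. Probes annotated to several genes count for each; intergenic
probes enter only the universe. Gene sets are then tested one-sidedly by
Fisher's exact test (hypergeometric upper tail) over the universe of genes
with at least one CpG on the array (the paper-scale alternative — all
annotated genes — is a superset that only dilutes; genes with no CpGs can
never be called). BH is used for both stages; BY is reserved for the
region enrichment where it is the named procedure.

**Region (chromatin-mark) enrichment.** For a test list (by default the
top-1000 probes by $|\mathrm{median}\ \Delta\beta|$ per direction), 1,000
background sets are drawn with exactly the test list's per-bin composition
over the gene-relationship × CpG-island-relationship annotation cross,
uniformly without replacement within bins and excluding the test probes
themselves (excluding them avoids a self-overlap bias; including them
would only shift the background rate by a few per mille). Overlap counting
uses half-open 0-based BED semantics: a probe at 1-based position $p$ hits
$[start, end)$ iff $p-1$ lies in it. The enrichment p-value is the
binomial upper tail at the pooled background rate
$\hat p = \sum_b O_b / (B \cdot n)$ — the "binomial p-value" construction;
an empirical rank test against the $B$ background counts is a swappable
alternative, and the background mean/sd are reported for diagnostics
either way. Benjamini-Yekutieli q-values are assigned across all (tissue,
mark) tests of one input list — one family per list — and $q<0.05$ flags
significance.

**Cross-list overlap.** Contrasts between groups are summarized per probe
by the difference of group medians (a one-sample arm reduces to that
sample). The top-5,000 probes by increase or decrease in two contrasts are
tested for overlap over the probes surviving QC in both datasets with the
one-sided Fisher exact test; the odds ratio is the sample OR with
Haldane-Anscombe 0.5 correction on zero cells and a 95% Woolf logit
interval (the conditional-likelihood interval is a defensible alternative;
Woolf is chosen and isolated inside `fisher_overlap()`).

## What the generator emulates — and what it does not

`simulate_dataset()` draws, per probe, a baseline mean from
Beta(0.35, 0.35) (U-shaped, like real 450k betas) and per-(probe, site,
group) observations from a beta distribution with that mean and a common
precision $\phi = 100$, giving bounded, heteroscedastic noise
(sd $\approx 0.05$ at $\beta = 0.5$). No study-reported per-probe variance
structure exists to copy; $\phi$ is a free parameter documented here and
in the configuration. Spiked probes shift the *fimbrial* mean by
$\pm 0.10$ — in carriers only (500 probes) or in both groups (250 probes,
so the carrier:control count of significant CpGs lands near the threefold
excess the real cohort shows). The direction split is 81% hypo / 19%
hyper. Spiked baselines are drawn mid-range (0.2-0.8) so the full shift is
realized without boundary clipping. Detection failures are entry-wise
independent at rate 0.002, plus 3% of samples receive a contiguous failed
block driving them under the 80% coverage rule — exercising both QC
passes. The genome is a single synthetic chromosome with strictly
increasing probe positions (gaps ≥ 500 bp), sufficient for interval
overlap without liftover complexity; peak tracks place one 200 bp interval
around each independently covered probe (baseline coverage 0.1, enriched
track 3×the baseline on spiked probes).

Deliberately *not* modelled: chip/batch effects, age trends, cellular
heterogeneity, probe cross-reactivity, spatial correlation of methylation,
and gene-level clustering of spikes. The last point means the per-gene
binomial and gene-set stages typically (and correctly) return null results
on synthetic data — spikes scatter uniformly over genes, so no gene
accumulates an excess; those stages are validated by exact enumeration
oracles instead. Passing tests therefore demonstrate the statistical
machinery and its calibration, not robustness to the technical artefacts
real cohorts carry.

## Problem sizes used by tests and the acceptance script

The default study is 30 + 30 subjects (both sites each) and 20,000 probes
— the spiked-recovery checks use five such cohorts; enrichment
calibration/power use 20 seeds with 1,000 matched background sets; the
overlap checks use 10 seed pairs of full-size cohorts (missingness off
where imputation is not the property under test); the moderated-t null
uses 2,000 probes × 10 pairs with variances drawn from the scaled
inverse-chi-square hierarchy — the null under which the moderated t is
exactly t-distributed (under an equal-variance null its p-values are
mildly non-uniform by construction, which is a property of the estimator,
not a bug). These sizes are the package's chosen balance between
statistical resolution and a test suite that runs in minutes.

## Known limitations

- The moderated model assumes exchangeable per-probe variances; gross
  variance strata (e.g. type I vs type II probes) are not modelled.
- The pooled binomial construction for region enrichment understates
  uncertainty in $\hat p$ when backgrounds are few; with the default 1,000
  sets this is negligible, and the empirical background moments are
  reported alongside.
- KNN imputation borrows across probes, not samples; with very high
  missingness the neighbour pool of complete probes shrinks and the
  implementation refuses to run rather than degrade silently.
- Direction assignment uses the carrier median's sign; probes with median
  exactly zero cannot pass the delta threshold and are labelled hypo by
  convention.
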