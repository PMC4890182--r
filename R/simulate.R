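#' Simulation configuration for a synthetic paired methylation study
#'
#' Builds and validates the configuration driving [simulate_dataset()],
#' [simulate_peak_tracks()] and [simulate_gene_sets()]. The defaults describe
#' the study design the analysis assumes: two groups (`MUT` mutation carriers
#' and `control`), one fimbrial and one proximal sample per subject, bounded
#' beta values with per-probe baselines, a set of spiked CpGs whose
#' fimbrial-minus-proximal mean is shifted by `delta_spike` in the designated
#' group(s), entry-wise detection-p failures, and occasional low-coverage
#' samples.
#'
#' @param n_subjects_mut,n_subjects_ctrl Number of subjects per group; each
#'   subject contributes a fimbrial and a proximal sample.
#' @param n_probes Number of CpG probes on the synthetic array.
#' @param n_spiked_mut_only Number of probes differentially methylated
#'   (fimbrial vs proximal) only in the `MUT` group.
#' @param n_spiked_shared Number of probes differential in both groups.
#' @param delta_spike Fimbrial-minus-proximal mean shift for spiked probes, in
#'   beta units; must lie in (0, 0.5).
#' @param base_alpha,base_beta Shape parameters of the beta distribution from
#'   which per-probe baseline means are drawn (U-shaped by default, as for
#'   450k arrays).
#' @param precision Common precision of the per-(probe, site, group) beta
#'   noise distribution: an observation with mean `m` is drawn from
#'   `Beta(m * precision, (1 - m) * precision)`.
#' @param hypo_fraction Fraction of spiked probes that are hypomethylated
#'   (negative fimbrial-minus-proximal shift); defaults to 0.81.
#' @param missing_rate Entry-wise probability of a failed measurement
#'   (detection p > 0.05); must lie in \[0, 1).
#' @param dropout_sample_rate Fraction of samples simulated with < 80% probe
#'   coverage by failing a contiguous probe block.
#' @param n_genes Number of gene symbols available for annotation.
#' @param multi_gene_rate Fraction of gene-linked probes annotated to two
#'   genes.
#' @param n_gene_sets,gene_set_size Number of synthetic gene sets and the
#'   (min, max) range of their sizes.
#' @param n_tissues,n_marks Dimensions of the peak-track grid.
#' @param peak_coverage Baseline probability that a track covers a probe.
#' @param peak_enrichment_factor Relative coverage of spiked probes by the
#'   designated enriched (tissue, mark) track; 1 means no enrichment.
#' @param seed Integer RNG seed; every emitted object is reproducible from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects_mut = 30L, n_subjects_ctrl = 30L,
                       n_probes = 20000L,
                       n_spiked_mut_only = 500L, n_spiked_shared = 250L,
                       delta_spike = 0.10,
                       base_alpha = 0.35, base_beta = 0.35,
                       precision = 100,
                       hypo_fraction = 0.81,
                       missing_rate = 0.002,
                       dropout_sample_rate = 0.03,
                       n_genes = 1500L,
                       multi_gene_rate = 0.05,
                       n_gene_sets = 50L,
                       gene_set_size = c(10L, 200L),
                       n_tissues = 5L, n_marks = 5L,
                       peak_coverage = 0.10,
                       peak_enrichment_factor = 3,
                       seed = 1L) {
  cfg <- list(n_subjects_mut = as.integer(n_subjects_mut),
              n_subjects_ctrl = as.integer(n_subjects_ctrl),
              n_probes = as.integer(n_probes),
              n_spiked_mut_only = as.integer(n_spiked_mut_only),
              n_spiked_shared = as.integer(n_spiked_shared),
              delta_spike = delta_spike,
              base_alpha = base_alpha, base_beta = base_beta,
              precision = precision,
              hypo_fraction = hypo_fraction,
              missing_rate = missing_rate,
              dropout_sample_rate = dropout_sample_rate,
              n_genes = as.integer(n_genes),
              multi_gene_rate = multi_gene_rate,
              n_gene_sets = as.integer(n_gene_sets),
              gene_set_size = as.integer(gene_set_size),
              n_tissues = as.integer(n_tissues), n_marks = as.integer(n_marks),
              peak_coverage = peak_coverage,
              peak_enrichment_factor = peak_enrichment_factor,
              seed = as.integer(seed))
  count_fields <- c("n_subjects_mut", "n_subjects_ctrl", "n_probes",
                    "n_genes", "n_gene_sets", "n_tissues", "n_marks")
  for (f in count_fields)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("invalid '", f, "': must be a positive count", call. = FALSE)
  for (f in c("n_spiked_mut_only", "n_spiked_shared"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop("invalid '", f, "': must be a non-negative count", call. = FALSE)
  if (cfg$n_spiked_mut_only + cfg$n_spiked_shared > cfg$n_probes)
    stop("invalid 'n_spiked_mut_only'/'n_spiked_shared': spiked probes exceed n_probes",
         call. = FALSE)
  if (!is.finite(cfg$delta_spike) || cfg$delta_spike <= 0 || cfg$delta_spike >= 0.5)
    stop("invalid 'delta_spike': must lie in (0, 0.5)", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid 'missing_rate': must lie in [0, 1)", call. = FALSE)
  if (cfg$dropout_sample_rate < 0 || cfg$dropout_sample_rate >= 1)
    stop("invalid 'dropout_sample_rate': must lie in [0, 1)", call. = FALSE)
  if (cfg$hypo_fraction < 0 || cfg$hypo_fraction > 1)
    stop("invalid 'hypo_fraction': must lie in [0, 1]", call. = FALSE)
  if (cfg$precision <= 0)
    stop("invalid 'precision': must be positive", call. = FALSE)
  if (cfg$base_alpha <= 0 || cfg$base_beta <= 0)
    stop("invalid 'base_alpha'/'base_beta': must be positive", call. = FALSE)
  if (cfg$peak_coverage <= 0 || cfg$peak_coverage > 1)
    stop("invalid 'peak_coverage': must lie in (0, 1]", call. = FALSE)
  if (cfg$peak_enrichment_factor < 1)
    stop("invalid 'peak_enrichment_factor': must be >= 1", call. = FALSE)
  if (length(cfg$gene_set_size) != 2L || any(cfg$gene_set_size < 1L) ||
      cfg$gene_set_size[1] > cfg$gene_set_size[2])
    stop("invalid 'gene_set_size': must be an increasing pair of counts",
         call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

mark_names <- function(n) {
  base <- c("H3K4me1", "H3K27me3", "H3K36me3", "H3K4me3", "H3K9me3")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("MK%02d", seq.int(length(base) + 1L, n)))
}

#' Simulate a paired fimbrial/proximal methylation dataset
#'
#' Draws a beta-value matrix with one fimbrial and one proximal sample per
#' subject in two groups. Each probe has a baseline mean drawn from
#' `Beta(base_alpha, base_beta)`; observed values are drawn from a beta
#' distribution with that mean and a common precision, so they are bounded
#' and heteroscedastic like 450k betas. Spiked probes have their fimbrial
#' mean shifted by `+/- delta_spike` in the designated group(s) (`MUT` only,
#' or both for shared spikes), with the hypo/hyper direction split given by
#' `hypo_fraction`. A detection-p matrix marks entry-wise failures at
#' `missing_rate`, and a fraction `dropout_sample_rate` of samples receive a
#' contiguous failed probe block driving their coverage below 80%.
#'
#' @param config A [sim_config()] object.
#' @param truth Optional `ground_truth` from a previous call; when supplied,
#'   the same spiked probe identities and directions are re-planted (the
#'   probe universe must have the same size), which is how correlated
#'   "cancer" datasets sharing reprogrammed CpGs are produced.
#'
#' @return A list with elements `dataset` (a [meth_dataset()]), `annotation`
#'   (probe annotation data frame: `probe_id`, `chrom`, `pos`, `genes`,
#'   `gene_relation`, `cgi_relation`) and `truth` (a `ground_truth` list with
#'   `spiked_mut_only`, `spiked_shared`, `direction`, `enriched_tissue_marks`).
#' @export
simulate_dataset <- function(config, truth = NULL) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  set.seed(config$seed)
  np <- config$n_probes
  probe_id <- sprintf("cg%08d", seq_len(np))

  ## annotation: one synthetic chromosome, strictly increasing positions with
  ## gaps >= 500 bp so simulated peak intervals never touch neighbours
  pos <- cumsum(sample(500:1500, np, replace = TRUE))
  gene_rel_levels <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                       "3'UTR", "Intergenic")
  gene_rel_probs <- c(0.12, 0.10, 0.10, 0.05, 0.33, 0.05, 0.25)
  cgi_levels <- c("Island", "Shore", "Shelf", "OpenSea")
  cgi_probs <- c(0.31, 0.23, 0.10, 0.36)
  gene_relation <- sample(gene_rel_levels, np, TRUE, gene_rel_probs)
  cgi_relation <- sample(cgi_levels, np, TRUE, cgi_probs)
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  gene_w <- stats::rgamma(config$n_genes, shape = 2)
  genes <- character(np)
  nonint <- gene_relation != "Intergenic"
  g1 <- sample(gene_ids, sum(nonint), TRUE, prob = gene_w)
  g2 <- sample(gene_ids, sum(nonint), TRUE, prob = gene_w)
  two <- stats::runif(sum(nonint)) < config$multi_gene_rate & g1 != g2
  genes[nonint] <- ifelse(two, paste(g1, g2, sep = ";"), g1)
  annotation <- data.frame(probe_id = probe_id, chrom = "chrS1", pos = pos,
                           genes = genes, gene_relation = gene_relation,
                           cgi_relation = cgi_relation,
                           stringsAsFactors = FALSE)

  ## ground truth: disjoint spiked sets with a hypo-skewed direction split
  n_spike <- config$n_spiked_mut_only + config$n_spiked_shared
  if (is.null(truth)) {
    sp <- if (n_spike > 0) sample(probe_id, n_spike) else character(0)
    mut_only <- sp[seq_len(config$n_spiked_mut_only)]
    shared <- setdiff(sp, mut_only)
    direction <- stats::setNames(
      ifelse(stats::runif(n_spike) < config$hypo_fraction, "hypo", "hyper"), sp)
    enriched <- if (config$peak_enrichment_factor > 1 && n_spike > 0)
      data.frame(tissue = "T01", mark = mark_names(config$n_marks)[1],
                 stringsAsFactors = FALSE)
    else
      data.frame(tissue = character(0), mark = character(0))
    truth <- structure(list(spiked_mut_only = mut_only,
                            spiked_shared = shared,
                            direction = direction,
                            enriched_tissue_marks = enriched),
                       class = "ground_truth")
  } else {
    missing_probes <- setdiff(c(truth$spiked_mut_only, truth$spiked_shared),
                              probe_id)
    if (length(missing_probes) > 0)
      stop("supplied ground truth names ", length(missing_probes),
           " probes absent from this probe universe")
  }

  ## per-probe baselines; spiked probes get mid-range baselines so the full
  ## +/- delta shift is realized without boundary clipping
  m <- pmin(pmax(stats::rbeta(np, config$base_alpha, config$base_beta),
                 0.03), 0.97)
  spiked_all <- c(truth$spiked_mut_only, truth$spiked_shared)
  sp_idx <- match(spiked_all, probe_id)
  if (length(sp_idx) > 0)
    m[sp_idx] <- stats::runif(length(sp_idx), 0.20, 0.80)
  shift <- numeric(np)
  if (length(sp_idx) > 0)
    shift[sp_idx] <- ifelse(truth$direction[spiked_all] == "hyper", 1, -1) *
      config$delta_spike

  subjects <- c(sprintf("M%03d", seq_len(config$n_subjects_mut)),
                sprintf("C%03d", seq_len(config$n_subjects_ctrl)))
  group <- rep(c("MUT", "control"),
               c(config$n_subjects_mut, config$n_subjects_ctrl))
  samples <- data.frame(
    sample_id = paste0(rep(subjects, each = 2L), c("_F", "_P")),
    subject_id = rep(subjects, each = 2L),
    site = rep(c("fimbrial", "proximal"), length(subjects)),
    group = rep(group, each = 2L),
    stringsAsFactors = FALSE)
  ns <- nrow(samples)

  ## mean matrix: proximal at baseline; fimbrial shifted at spiked probes in
  ## the designated group(s)
  mut_only_idx <- match(truth$spiked_mut_only, probe_id)
  mu <- matrix(m, nrow = np, ncol = ns)
  fimb <- samples$site == "fimbrial"
  for (j in which(fimb)) {
    sh <- shift
    if (samples$group[j] == "control" && length(mut_only_idx) > 0)
      sh[mut_only_idx] <- 0
    mu[, j] <- pmin(pmax(m + sh, 0.01), 0.99)
  }

  phi <- config$precision
  beta <- matrix(stats::rbeta(np * ns, as.vector(mu) * phi,
                              (1 - as.vector(mu)) * phi),
                 nrow = np, ncol = ns,
                 dimnames = list(probe_id, samples$sample_id))
  beta <- pmin(pmax(beta, 0), 1)

  detp <- matrix(stats::runif(np * ns, 0, 0.01), nrow = np, ncol = ns,
                 dimnames = dimnames(beta))
  if (config$missing_rate > 0) {
    fail <- stats::runif(np * ns) < config$missing_rate
    detp[fail] <- stats::runif(sum(fail), 0.051, 1)
  }
  n_drop <- round(config$dropout_sample_rate * ns)
  if (n_drop > 0) {
    drop_j <- sample(ns, n_drop)
    block <- ceiling(0.25 * np)
    for (j in drop_j) {
      start <- sample(np - block + 1L, 1L)
      detp[start:(start + block - 1L), j] <- stats::runif(block, 0.051, 1)
    }
  }

  list(dataset = meth_dataset(beta, detp, samples),
       annotation = annotation,
       truth = truth)
}

#' Simulate chromatin-mark peak tracks over a probe annotation
#'
#' For each (tissue, mark) pair a set of non-overlapping half-open intervals
#' is generated by covering each probe independently with probability
#' `peak_coverage` and placing a 200 bp interval around covered probes.
#' Tracks listed in `truth$enriched_tissue_marks` cover spiked probes at
#' `peak_enrichment_factor` times the baseline probability; all other tracks
#' ignore spike status.
#'
#' @param annotation Probe annotation with `probe_id`, `chrom`, `pos`.
#' @param truth A `ground_truth` object (spiked probe ids and the enriched
#'   (tissue, mark) designation).
#' @param config A [sim_config()].
#' @return A `peak_track_set`: list with `tracks` (named list of
#'   [GenomicRanges::GRanges], keyed `"tissue|mark"`) and `manifest`
#'   (data frame `tissue`, `mark`, `key`).
#' @export
simulate_peak_tracks <- function(annotation, truth, config) {
  if (is.null(annotation) || nrow(annotation) == 0)
    stop("empty annotation")
  set.seed(config$seed + 104729L)
  np <- nrow(annotation)
  spiked <- c(truth$spiked_mut_only, truth$spiked_shared)
  is_sp <- annotation$probe_id %in% spiked
  tissues <- sprintf("T%02d", seq_len(config$n_tissues))
  marks <- mark_names(config$n_marks)
  enr <- truth$enriched_tissue_marks
  tracks <- list()
  manifest <- data.frame(tissue = character(0), mark = character(0),
                         key = character(0), stringsAsFactors = FALSE)
  for (ti in tissues) {
    for (mk in marks) {
      p_cov <- rep(config$peak_coverage, np)
      if (nrow(enr) > 0 && any(enr$tissue == ti & enr$mark == mk))
        p_cov[is_sp] <- min(1, config$peak_enrichment_factor *
                              config$peak_coverage)
      covered <- stats::runif(np) < p_cov
      gr <- GenomicRanges::GRanges(
        annotation$chrom[covered],
        IRanges::IRanges(start = annotation$pos[covered] - 100L,
                         end = annotation$pos[covered] + 99L))
      gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
      key <- paste(ti, mk, sep = "|")
      tracks[[key]] <- gr
      manifest <- rbind(manifest,
                        data.frame(tissue = ti, mark = mk, key = key,
                                   stringsAsFactors = FALSE))
    }
  }
  structure(list(tracks = tracks, manifest = manifest),
            class = "peak_track_set")
}

#' Simulate toy gene-set definitions
#'
#' Draws `n_gene_sets` gene sets of sizes uniform in `gene_set_size` from the
#' genes present in the annotation, standing in for curated collections such
#' as MSigDB (whose content is not redistributable).
#'
#' @inheritParams simulate_peak_tracks
#' @return A named list of character vectors of gene symbols.
#' @export
simulate_gene_sets <- function(annotation, config) {
  set.seed(config$seed + 7919L)
  genes <- unique(unlist(strsplit(annotation$genes[annotation$genes != ""],
                                  ";", fixed = TRUE)))
  sizes <- sample(seq.int(config$gene_set_size[1],
                          min(config$gene_set_size[2], length(genes))),
                  config$n_gene_sets, replace = TRUE)
  sets <- lapply(sizes, function(sz) sample(genes, sz))
  names(sets) <- sprintf("GS%03d", seq_len(config$n_gene_sets))
  sets
}
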