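#' Pipeline configuration
#'
#' Collects all stage thresholds with their standard defaults (80% sample /
#' 95% probe coverage at detection p 0.05; KNN k = 5; FDR q < 0.05; median
#' delta-beta > 0.03; top-1000 probes against 1000 matched background sets
#' with BY q < 0.05; top-5000 overlap lists) together with a simulation
#' configuration and an output directory.
#'
#' @param sim A [sim_config()] describing the synthetic study.
#' @param out_dir Output directory for all stage artifacts.
#' @param sample_min_coverage,probe_min_coverage,detection_threshold QC
#'   thresholds, see [qc_filter()].
#' @param knn_k Imputation neighbours, see [knn_impute()].
#' @param q_threshold,delta_threshold DMP thresholds, see [call_dmps()].
#' @param top_n_enrich,n_background_sets Region-enrichment sizes, see
#'   [region_enrichment()].
#' @param top_k_overlap List size for the cross-contrast overlap stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir = "pipeline_out",
                            sample_min_coverage = 0.80,
                            probe_min_coverage = 0.95,
                            detection_threshold = 0.05,
                            knn_k = 5L,
                            q_threshold = 0.05, delta_threshold = 0.03,
                            top_n_enrich = 1000L,
                            n_background_sets = 1000L,
                            top_k_overlap = 5000L) {
  stopifnot(inherits(sim, "sim_config"))
  if (sample_min_coverage <= 0 || sample_min_coverage > 1 ||
      probe_min_coverage <= 0 || probe_min_coverage > 1)
    stop("coverage thresholds must lie in (0, 1]")
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must lie in (0, 1)")
  if (delta_threshold < 0 || delta_threshold >= 1)
    stop("delta_threshold must lie in [0, 1)")
  structure(list(sim = sim, out_dir = out_dir,
                 sample_min_coverage = sample_min_coverage,
                 probe_min_coverage = probe_min_coverage,
                 detection_threshold = detection_threshold,
                 knn_k = as.integer(knn_k),
                 q_threshold = q_threshold,
                 delta_threshold = delta_threshold,
                 top_n_enrich = as.integer(top_n_enrich),
                 n_background_sets = as.integer(n_background_sets),
                 top_k_overlap = as.integer(top_k_overlap)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  message("[", name, "] started")
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message("[", name, "] done")
  res
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate -> qc -> dmp -> gsea -> enrich -> overlap on the
#' configured synthetic study, writing every stage's artifacts under
#' `out_dir` and a `manifest.json` listing each file with its MD5 content
#' hash; re-running with the same configuration reproduces the hashes. A
#' stage failure aborts with the stage name and leaves earlier outputs in
#' place.
#'
#' The overlap stage simulates a second, "cancer-like" cohort that re-plants
#' the same ground-truth spikes (seed offset by one), contrasts fimbrial
#' carriers against fimbrial controls in both cohorts, and tests the top-k
#' increase and decrease lists for overlap over the probes surviving QC in
#' both.
#'
#' @param config A [pipeline_config()].
#' @return The manifest as a data frame (`file`, `md5`), invisibly; also
#'   written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  add <- function(...) artifacts <<- c(artifacts, file.path(out, c(...)))

  sim <- run_stage("simulate", {
    sim <- simulate_dataset(config$sim)
    write_meth_dataset(sim$dataset, file.path(out, "input"))
    write_annotation(sim$annotation, file.path(out, "input", "annotation.tsv"))
    tracks <- simulate_peak_tracks(sim$annotation, sim$truth, config$sim)
    write_peak_tracks(tracks, file.path(out, "input", "tracks"))
    gene_sets <- simulate_gene_sets(sim$annotation, config$sim)
    write_gmt(gene_sets, file.path(out, "input", "gene_sets.gmt"))
    jsonlite::write_json(
      list(spiked_mut_only = sim$truth$spiked_mut_only,
           spiked_shared = sim$truth$spiked_shared,
           direction = as.list(sim$truth$direction),
           enriched_tissue_marks = sim$truth$enriched_tissue_marks),
      file.path(out, "input", "ground_truth.json"))
    c(sim, list(tracks = tracks, gene_sets = gene_sets))
  })
  add(file.path("input", c("beta.tsv", "detection_p.tsv", "samples.tsv",
                           "annotation.tsv", "gene_sets.gmt",
                           "ground_truth.json")))
  add(file.path("input", "tracks",
                c("manifest.tsv",
                  paste0(gsub("[^A-Za-z0-9]+", "_",
                              sim$tracks$manifest$key), ".bed"))))

  qc <- run_stage("qc", {
    ds <- qc_filter(sim$dataset,
                    sample_min_coverage = config$sample_min_coverage,
                    probe_min_coverage = config$probe_min_coverage,
                    detection_threshold = config$detection_threshold)
    ds <- knn_impute(ds, k = config$knn_k,
                     detection_threshold = config$detection_threshold)
    write_matrix_tsv(ds$beta, file.path(out, "beta_qc.tsv"))
    ds
  })
  add("beta_qc.tsv")

  dmp <- run_stage("dmp", {
    stats_mut <- dmp_group_stats(qc, "MUT")
    stats_ctrl <- dmp_group_stats(qc, "control")
    dmps <- call_dmps(stats_mut, stats_ctrl,
                      q_threshold = config$q_threshold,
                      delta_threshold = config$delta_threshold)
    data.table::fwrite(dmps, file.path(out, "dmp_table.tsv"), sep = "\t")
    writeLines(dmps$probe_id[dmps$dmp & dmps$direction == "hyper"],
               file.path(out, "dmps_hyper.txt"))
    writeLines(dmps$probe_id[dmps$dmp & dmps$direction == "hypo"],
               file.path(out, "dmps_hypo.txt"))
    het <- if (any(dmps$dmp))
      heterogeneity_summary(attr(stats_mut, "diffs"), dmps)
    else c(frac_gt_0.1 = NA_real_, frac_gt_0.2 = NA_real_)
    data.table::fwrite(data.frame(threshold = names(het), mean_fraction = het),
                       file.path(out, "heterogeneity.tsv"), sep = "\t")
    list(dmps = dmps, diffs_mut = attr(stats_mut, "diffs"))
  })
  add("dmp_table.tsv", "dmps_hyper.txt", "dmps_hypo.txt", "heterogeneity.tsv")

  run_stage("gsea", {
    universe_genes <- unique(unlist(strsplit(
      sim$annotation$genes[sim$annotation$genes != ""], ";", fixed = TRUE)))
    for (stratum in c("hyper", "hypo")) {
      gt <- gene_binomial_test(dmp$dmps, sim$annotation, stratum)
      data.table::fwrite(gt, file.path(out, paste0("gene_tests_", stratum,
                                                   ".tsv")), sep = "\t")
      sig_genes <- gt$gene[gt$q < config$q_threshold]
      gs <- fisher_gsea(sig_genes, universe_genes, sim$gene_sets)
      data.table::fwrite(gs, file.path(out, paste0("gsea_", stratum, ".tsv")),
                         sep = "\t")
    }
  })
  add(paste0("gene_tests_", c("hyper", "hypo"), ".tsv"),
      paste0("gsea_", c("hyper", "hypo"), ".tsv"))

  run_stage("enrich", {
    for (stratum in c("hyper", "hypo")) {
      probes <- suppressWarnings(
        select_top_probes(dmp$dmps, n = config$top_n_enrich,
                          direction = stratum))
      if (length(probes) == 0) {
        message("[enrich] no ", stratum, " probes; skipping")
        next
      }
      enr <- region_enrichment(probes, sim$tracks, sim$annotation,
                               n_sets = config$n_background_sets,
                               seed = config$sim$seed + 31L)
      data.table::fwrite(enr, file.path(out, paste0("enrichment_", stratum,
                                                    ".tsv")), sep = "\t")
    }
  })
  add(paste0("enrichment_", c("hyper", "hypo"), ".tsv"))

  run_stage("overlap", {
    sim2_cfg <- config$sim
    sim2_cfg$seed <- config$sim$seed + 1L
    sim2 <- simulate_dataset(sim2_cfg, truth = sim$truth)
    ds2 <- knn_impute(qc_filter(sim2$dataset,
                                config$sample_min_coverage,
                                config$probe_min_coverage,
                                config$detection_threshold),
                      k = config$knn_k,
                      detection_threshold = config$detection_threshold)
    universe <- intersect(rownames(qc$beta), rownames(ds2$beta))
    eff1 <- fimbrial_group_contrast(qc, universe)
    eff2 <- fimbrial_group_contrast(ds2, universe)
    k <- min(config$top_k_overlap, length(universe))
    res <- do.call(rbind, lapply(c("increase", "decrease"), function(sg) {
      fisher_overlap(top_k_by_delta(eff1, k, sg),
                     top_k_by_delta(eff2, k, sg), universe,
                     name_a = paste0("fimbrial_", sg),
                     name_b = paste0("cancer_", sg))
    }))
    data.table::fwrite(res, file.path(out, "overlap.tsv"), sep = "\t")
  })
  add("overlap.tsv")

  artifacts <- unique(artifacts[file.exists(artifacts)])
  manifest <- data.frame(file = sub(paste0("^", out, "/?"), "", artifacts),
                         md5 = unname(tools::md5sum(artifacts)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  message("run_pipeline: wrote ", nrow(manifest), " artifacts to ", out)
  invisible(manifest)
}

## carrier-vs-control contrast of fimbrial samples over a probe universe
fimbrial_group_contrast <- function(dataset, universe) {
  s <- dataset$samples
  a <- dataset$beta[universe,
                    s$sample_id[s$site == "fimbrial" & s$group == "MUT"],
                    drop = FALSE]
  b <- dataset$beta[universe,
                    s$sample_id[s$site == "fimbrial" & s$group == "control"],
                    drop = FALSE]
  contrast_effects(a, b)
}
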