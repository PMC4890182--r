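#' Per-gene binomial test for excess significant CpGs
#'
#' Within one direction stratum (`hyper` or `hypo`), the background rate is
#' `pi = (retained DMPs in the stratum) / (all CpGs in the universe)`. Each
#' gene with `n` CpGs of which `x` are significant gets the one-sided
#' binomial p-value `P(X >= x | n, pi)`, BH-adjusted across genes. Probes
#' annotated to several genes count once for each; intergenic probes enter
#' the CpG universe but no gene.
#'
#' @param dmps DMP table from [call_dmps()]; its probes define the universe.
#' @param annotation Probe annotation (`probe_id`, `genes`).
#' @param stratum `"hyper"` or `"hypo"`.
#' @return Data frame with `gene`, `n_cpgs_total`, `n_cpgs_significant`,
#'   `p`, `q`, `stratum`.
#' @export
gene_binomial_test <- function(dmps, annotation, stratum = c("hyper", "hypo")) {
  stratum <- match.arg(stratum)
  univ <- dmps$probe_id
  ann <- annotation[match(univ, annotation$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id))
    stop("annotation is missing ", sum(is.na(ann$probe_id)),
         " probes of the DMP universe")
  sig <- dmps$dmp & dmps$direction == stratum
  pi0 <- sum(sig) / length(univ)
  gl <- strsplit(ann$genes, ";", fixed = TRUE)
  gl[ann$genes == "" | is.na(ann$genes)] <- list(character(0))
  reps <- lengths(gl)
  gene <- unlist(gl, use.names = FALSE)
  probe_sig <- rep(sig, reps)
  n_tot <- tapply(rep(1L, length(gene)), gene, sum)
  n_sig <- tapply(as.integer(probe_sig), gene, sum)
  genes <- names(n_tot)
  n_tot <- as.integer(n_tot)
  n_sig <- as.integer(n_sig[genes])
  if (pi0 == 0) {
    message("gene_binomial_test: no significant CpGs in stratum '", stratum,
            "'; all p set to 1")
    p <- rep(1, length(genes))
  } else {
    p <- stats::pbinom(n_sig - 1L, n_tot, pi0, lower.tail = FALSE)
  }
  out <- data.frame(gene = genes, n_cpgs_total = n_tot,
                    n_cpgs_significant = n_sig, p = p, q = bh_fdr(p),
                    stratum = stratum, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), ]
  rownames(out) <- NULL
  out
}

#' One-sided Fisher gene-set enrichment
#'
#' For each gene set, a 2x2 table over the gene universe (in the set x
#' significant) is tested for enrichment with the one-sided Fisher exact
#' test (hypergeometric upper tail); the sample odds ratio is reported and
#' p-values are BH-adjusted across sets. Degenerate margins (empty set
#' within the universe, no significant genes, or all genes significant)
#' yield p = 1 with an undefined (NA) odds ratio, since no enrichment beyond
#' saturation is testable.
#'
#' @param significant_genes Character vector, subset of `universe`.
#' @param universe Character vector of all eligible gene symbols (genes with
#'   at least one CpG on the array).
#' @param collection Named list of gene sets (character vectors).
#' @return Data frame with `set`, `set_size`, `overlap`, `odds_ratio`, `p`,
#'   `q`.
#' @export
fisher_gsea <- function(significant_genes, universe, collection) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  significant_genes <- unique(significant_genes)
  if (!all(significant_genes %in% universe))
    stop("significant_genes must be a subset of the universe")
  U <- length(universe)
  S <- length(significant_genes)
  res <- lapply(names(collection), function(nm) {
    in_set <- intersect(collection[[nm]], universe)
    m <- length(in_set)
    k <- length(intersect(in_set, significant_genes))
    n11 <- k; n10 <- m - k; n01 <- S - k; n00 <- U - m - S + k
    if (m == 0 || m == U || S == 0 || S == U) {
      p <- 1
      or <- NA_real_
    } else {
      p <- stats::phyper(k - 1, S, U - S, m, lower.tail = FALSE)
      or <- (n11 * n00) / (n10 * n01)  # Inf = saturated overlap; NaN -> NA
      if (is.nan(or)) or <- NA_real_
    }
    data.frame(set = nm, set_size = m, overlap = k, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}
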