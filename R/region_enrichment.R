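#' Select the strongest DMPs in one direction
#'
#' Returns the `n` retained DMPs with the largest absolute carrier-group
#' median delta-beta in the requested direction. Boundary ties are broken by
#' probe-id lexicographic order so the selection is deterministic. When
#' fewer than `n` probes qualify, all of them are returned with a warning.
#'
#' @param dmps DMP table from [call_dmps()].
#' @param n Number of probes to select (default 1000).
#' @param direction `"hyper"` or `"hypo"`.
#' @return Character vector of probe ids.
#' @export
select_top_probes <- function(dmps, n = 1000L, direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  cand <- dmps[dmps$dmp & dmps$direction == direction, , drop = FALSE]
  if (nrow(cand) < n)
    warning("only ", nrow(cand), " qualifying ", direction,
            " probes (requested ", n, ")")
  if (nrow(cand) == 0) return(character(0))
  o <- order(-abs(cand$median_delta_mut), cand$probe_id)
  utils::head(cand$probe_id[o], n)
}

#' Annotation-matched background probe sets
#'
#' Generates `n_sets` background probe lists, each with exactly the test
#' list's size and its exact per-bin composition, where bins are the cross
#' of gene-relationship and CpG-island-relationship annotation categories.
#' Background probes are drawn uniformly without replacement within bins,
#' independently across sets, and never include test probes. A bin whose
#' non-test pool is smaller than the test list's demand raises an error
#' naming the bin and the deficit.
#'
#' @param test_probes Character vector of probe ids present in `annotation`.
#' @param annotation Probe annotation with `gene_relation` and
#'   `cgi_relation`.
#' @param n_sets Number of background sets (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return List of `n_sets` character vectors.
#' @export
matched_backgrounds <- function(test_probes, annotation, n_sets = 1000L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ti <- match(test_probes, annotation$probe_id)
  if (anyNA(ti))
    stop(sum(is.na(ti)), " test probes absent from annotation")
  bin <- paste(annotation$gene_relation, annotation$cgi_relation, sep = "|")
  demand <- table(bin[ti])
  is_test <- annotation$probe_id %in% test_probes
  out <- matrix(NA_character_, nrow = n_sets, ncol = length(test_probes))
  col <- 0L
  for (b in names(demand)) {
    pool <- annotation$probe_id[bin == b & !is_test]
    need <- as.integer(demand[[b]])
    if (length(pool) < need)
      stop("background bin '", b, "' has ", length(pool),
           " non-test probes but ", need, " are required (deficit ",
           need - length(pool), ")")
    draws <- vapply(seq_len(n_sets),
                    function(i) pool[sample.int(length(pool), need)],
                    character(need))
    out[, col + seq_len(need)] <- t(matrix(draws, nrow = need))
    col <- col + need
  }
  lapply(seq_len(n_sets), function(i) out[i, ])
}

#' Count probes overlapping a peak track
#'
#' A probe at 1-based position `p` overlaps a half-open 0-based interval
#' `[start, end)` iff `p - 1` lies in it (tracks read from BED are held as
#' 1-based closed `GRanges`, making this `start <= p <= end`). Each probe is
#' counted at most once; probes on chromosomes unknown to the track count as
#' non-overlapping with a message.
#'
#' @param probes Character vector of probe ids.
#' @param track A `GRanges` of peaks.
#' @param annotation Probe annotation with `chrom` and `pos`.
#' @return Integer overlap count.
#' @export
overlap_count <- function(probes, track, annotation) {
  i <- match(probes, annotation$probe_id)
  if (anyNA(i)) stop("probes missing from annotation")
  chrom <- annotation$chrom[i]
  unknown <- !(chrom %in% GenomeInfoDb::seqlevels(track))
  if (any(unknown))
    message("overlap_count: ", sum(unknown),
            " probe(s) on chromosomes absent from the track")
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(annotation$pos[i],
                                               annotation$pos[i]))
  hits <- suppressWarnings(GenomicRanges::countOverlaps(q, track))
  sum(hits > 0)
}

#' Binomial enrichment of an observed overlap against resampled backgrounds
#'
#' The pooled background proportion is `p_hat = sum(background counts) /
#' (n_sets * n_test)`; the enrichment p-value is the binomial upper tail
#' `P(X >= observed)` for `X ~ Binomial(n_test, p_hat)`. A zero `p_hat`
#' yields p = 1 when nothing overlaps and a machine-floor guard otherwise.
#' `neg_log10_p` is floored at 1e-300.
#'
#' @param observed Observed overlap count of the test set.
#' @param backgrounds Integer vector of background overlap counts.
#' @param n_test Test-set size.
#' @return List with `p`, `neg_log10_p`, `p_hat`.
#' @export
enrichment_test <- function(observed, backgrounds, n_test) {
  if (n_test <= 0) stop("n_test must be positive")
  if (length(backgrounds) < 1) stop("at least one background set is required")
  if (observed > n_test) stop("observed overlap exceeds the test-set size")
  p_hat <- sum(backgrounds) / (length(backgrounds) * n_test)
  if (p_hat == 0) {
    if (observed == 0) {
      p <- 1
    } else {
      message("enrichment_test: zero background rate with a positive ",
              "observed overlap; p floored at machine minimum")
      p <- .Machine$double.xmin
    }
  } else {
    p <- stats::pbinom(observed - 1, n_test, p_hat, lower.tail = FALSE)
  }
  list(p = p, neg_log10_p = -log10(max(p, 1e-300)), p_hat = p_hat)
}

#' Matched-background enrichment of a probe list against peak tracks
#'
#' End-to-end resampling enrichment: annotation-matched backgrounds are
#' drawn once, every (tissue, mark) track is overlapped with the test list
#' and with each background set, the pooled binomial upper-tail p-value is
#' computed per track, and Benjamini-Yekutieli q-values are assigned across
#' all tracks of this one input list (one family per list).
#'
#' @param test_probes Character vector of probe ids.
#' @param track_set A `peak_track_set`.
#' @param annotation Probe annotation.
#' @param n_sets Number of background sets (default 1000).
#' @param seed Optional integer seed.
#' @return Data frame with one row per (tissue, mark): `n_test`,
#'   `observed_overlap`, `background_mean`, `background_sd`, `p`,
#'   `neg_log10_p`, `q`, `significant` (BY q < 0.05).
#' @export
region_enrichment <- function(test_probes, track_set, annotation,
                              n_sets = 1000L, seed = NULL) {
  if (length(test_probes) == 0) stop("empty test probe list")
  bgs <- matched_backgrounds(test_probes, annotation, n_sets = n_sets,
                             seed = seed)
  n_test <- length(test_probes)
  bg_idx <- matrix(match(unlist(bgs), annotation$probe_id),
                   nrow = n_sets, byrow = TRUE)
  test_idx <- match(test_probes, annotation$probe_id)
  probe_gr <- GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(annotation$pos, annotation$pos))
  man <- track_set$manifest
  rows <- lapply(seq_len(nrow(man)), function(r) {
    track <- track_set$tracks[[man$key[r]]]
    cov <- suppressWarnings(
      GenomicRanges::countOverlaps(probe_gr, track)) > 0
    observed <- sum(cov[test_idx])
    bg_counts <- rowSums(matrix(cov[bg_idx], nrow = n_sets))
    et <- enrichment_test(observed, bg_counts, n_test)
    data.frame(tissue = man$tissue[r], mark = man$mark[r], n_test = n_test,
               observed_overlap = observed,
               background_mean = mean(bg_counts),
               background_sd = stats::sd(bg_counts),
               p = et$p, neg_log10_p = et$neg_log10_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- by_fdr(out$p)
  out$significant <- out$q < 0.05
  rownames(out) <- NULL
  out
}
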