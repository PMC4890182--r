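#' Coverage-based quality filtering of a methylation dataset
#'
#' An entry "covers" if its detection p-value is at most
#' `detection_threshold`. Samples with coverage below `sample_min_coverage`
#' across probes are removed first; probes with coverage below
#' `probe_min_coverage` across the *remaining* samples are removed second.
#' The two passes always run in that order (samples, then probes), and
#' retained entries are left untouched. When no detection-p matrix is
#' present every entry passes and the dataset is returned unchanged.
#'
#' @param dataset A [meth_dataset()].
#' @param sample_min_coverage Minimum fraction of covered probes a sample
#'   must have (default 0.80).
#' @param probe_min_coverage Minimum fraction of covered samples a probe
#'   must have (default 0.95).
#' @param detection_threshold Detection p-value at or below which an entry
#'   counts as covered (default 0.05).
#' @return The filtered [meth_dataset()].
#' @export
qc_filter <- function(dataset, sample_min_coverage = 0.80,
                      probe_min_coverage = 0.95,
                      detection_threshold = 0.05) {
  if (is.null(dataset$detection_p)) return(dataset)
  covers <- dataset$detection_p <= detection_threshold
  keep_s <- colMeans(covers) >= sample_min_coverage
  if (!any(keep_s))
    stop("qc_filter: sample-coverage pass removed every sample")
  if (any(!keep_s))
    message("qc_filter: removed ", sum(!keep_s),
            " sample(s) with coverage < ", sample_min_coverage)
  covers <- covers[, keep_s, drop = FALSE]
  keep_p <- rowMeans(covers) >= probe_min_coverage
  if (!any(keep_p))
    stop("qc_filter: probe-coverage pass removed every probe")
  if (any(!keep_p))
    message("qc_filter: removed ", sum(!keep_p),
            " probe(s) with coverage < ", probe_min_coverage)
  meth_dataset(dataset$beta[keep_p, keep_s, drop = FALSE],
               dataset$detection_p[keep_p, keep_s, drop = FALSE],
               dataset$samples[keep_s, , drop = FALSE])
}

#' KNN imputation of failed methylation entries
#'
#' Each entry with detection p above `detection_threshold` is replaced by the
#' mean, in the same sample, of the `k` nearest probes among probes with
#' complete data. Nearness is Euclidean distance between probe rows computed
#' over the samples where the target probe is observed (complete candidate
#' rows are observed everywhere). Distance ties are broken by probe-id
#' lexicographic order for determinism. Observed entries are untouched; the
#' output carries detection p = 0 at imputed entries so no failed entries
#' remain.
#'
#' @param dataset A [meth_dataset()], normally after [qc_filter()].
#' @param k Number of neighbour probes (default 5).
#' @param detection_threshold Entries with detection p above this are
#'   imputed (default 0.05).
#' @return The imputed [meth_dataset()].
#' @export
knn_impute <- function(dataset, k = 5L, detection_threshold = 0.05) {
  if (is.null(dataset$detection_p)) return(dataset)
  beta <- dataset$beta
  failed <- dataset$detection_p > detection_threshold
  if (!any(failed)) return(dataset)
  n_fail_per_probe <- rowSums(failed)
  complete <- n_fail_per_probe == 0
  if (sum(complete) < k)
    stop("knn_impute: only ", sum(complete),
         " complete probes available as neighbour candidates, need k = ", k)
  cand_ids <- rownames(beta)[complete]
  ## candidates in lexicographic order so that equal distances resolve to
  ## the lexicographically smallest probe ids
  cand_ord <- order(cand_ids)
  C <- beta[complete, , drop = FALSE][cand_ord, , drop = FALSE]
  Csq_t <- t(C^2)
  Ct <- t(C)
  targets <- which(!complete)
  detp <- dataset$detection_p
  chunk <- 1000L
  for (start in seq(1L, length(targets), by = chunk)) {
    idx <- targets[start:min(start + chunk - 1L, length(targets))]
    Tz <- beta[idx, , drop = FALSE]
    obs <- !failed[idx, , drop = FALSE]
    Tz[!obs] <- 0
    ## squared distance over observed samples of each target row:
    ## sum(t^2) + sum_obs(c^2) - 2 * sum(t * c)
    d2 <- matrix(rowSums(Tz^2), nrow = length(idx), ncol = nrow(C)) +
      (obs %*% Csq_t) - 2 * (Tz %*% Ct)
    for (r in seq_along(idx)) {
      g <- idx[r]
      nb <- order(d2[r, ])[seq_len(k)]  # ties: first = lexicographic
      miss_s <- which(failed[g, ])
      if (length(nb) == 1L) {
        beta[g, miss_s] <- C[nb, miss_s]
      } else if (length(miss_s) == 1L) {
        beta[g, miss_s] <- mean(C[nb, miss_s])
      } else {
        beta[g, miss_s] <- colMeans(C[nb, miss_s, drop = FALSE])
      }
      detp[g, miss_s] <- 0
    }
  }
  message("knn_impute: imputed ", sum(failed), " entries across ",
          length(targets), " probes (k = ", k, ")")
  meth_dataset(beta, detp, dataset$samples)
}
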