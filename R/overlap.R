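#' Group-median contrast effects per probe
#'
#' Per-probe effect of group A versus group B, computed as the difference of
#' within-group medians (a single-sample group reduces to that sample's
#' values, covering single-array cell-line arms).
#'
#' @param group_a_betas,group_b_betas Numeric matrices (probes x samples) on
#'   a common probe set; rownames are probe ids.
#' @return Named numeric vector of effects (A median minus B median).
#' @export
contrast_effects <- function(group_a_betas, group_b_betas) {
  if (is.vector(group_a_betas)) group_a_betas <- cbind(group_a_betas)
  if (is.vector(group_b_betas)) group_b_betas <- cbind(group_b_betas)
  if (is.null(rownames(group_a_betas)) || is.null(rownames(group_b_betas)) ||
      !identical(rownames(group_a_betas), rownames(group_b_betas)))
    stop("group matrices must share identical probe rownames")
  med_a <- apply(group_a_betas, 1, stats::median)
  med_b <- apply(group_b_betas, 1, stats::median)
  med_a - med_b
}

#' Top-k probes by signed effect
#'
#' The `k` probes with the largest effect (`sign = "increase"`) or the most
#' negative effect (`sign = "decrease"`); ties broken by probe-id
#' lexicographic order.
#'
#' @param effects Named numeric vector over the probe universe.
#' @param k Number of probes (default 5000); must not exceed the universe.
#' @param sign `"increase"` or `"decrease"`.
#' @return Character vector of `k` probe ids.
#' @export
top_k_by_delta <- function(effects, k = 5000L,
                           sign = c("increase", "decrease")) {
  sign <- match.arg(sign)
  if (is.null(names(effects))) stop("effects must be a named vector")
  if (k > length(effects))
    stop("k (", k, ") exceeds the probe universe (", length(effects), ")")
  o <- if (sign == "increase") order(-effects, names(effects))
       else order(effects, names(effects))
  names(effects)[o][seq_len(k)]
}

#' Fisher exact overlap of two probe lists
#'
#' Builds the 2x2 table of membership in `list_a` by membership in `list_b`
#' over the universe, tests enrichment one-sidedly via the hypergeometric
#' upper tail, and reports the sample odds ratio with a 95% Woolf logit
#' confidence interval; zero cells receive the Haldane-Anscombe 0.5
#' correction for the odds ratio and interval.
#'
#' @param list_a,list_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible probe ids.
#' @param name_a,name_b Labels carried into the result.
#' @return One-row data frame: `list_a_name`, `list_b_name`,
#'   `universe_size`, `a_size`, `b_size`, `overlap`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
fisher_overlap <- function(list_a, list_b, universe,
                           name_a = "A", name_b = "B") {
  universe <- unique(universe)
  list_a <- unique(list_a)
  list_b <- unique(list_b)
  bad <- sum(!(list_a %in% universe)) + sum(!(list_b %in% universe))
  if (bad > 0)
    stop(bad, " list member(s) are not in the universe")
  U <- length(universe)
  n11 <- length(intersect(list_a, list_b))
  n10 <- length(list_a) - n11
  n01 <- length(list_b) - n11
  n00 <- U - n11 - n10 - n01
  p <- stats::phyper(n11 - 1, length(list_a), U - length(list_a),
                     length(list_b), lower.tail = FALSE)
  cells <- c(n11, n10, n01, n00)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  data.frame(list_a_name = name_a, list_b_name = name_b,
             universe_size = U, a_size = length(list_a),
             b_size = length(list_b), overlap = n11,
             odds_ratio = or,
             ci_low = exp(log(or) - 1.96 * se),
             ci_high = exp(log(or) + 1.96 * se),
             p = p, stringsAsFactors = FALSE)
}
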