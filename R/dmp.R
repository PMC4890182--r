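#' Per-subject fimbrial-minus-proximal difference matrix
#'
#' For the subjects of one group having both a fimbrial and a proximal
#' sample, returns the probes-by-subjects matrix of paired beta differences
#' (sign convention: fimbrial minus proximal). Unpaired subjects are
#' excluded with a message stating the count.
#'
#' @param dataset A [meth_dataset()].
#' @param group Group label (`"MUT"` or `"control"`).
#' @return Numeric matrix, one column per paired subject.
#' @export
paired_differences <- function(dataset, group) {
  s <- dataset$samples[dataset$samples$group == group, , drop = FALSE]
  if (nrow(s) == 0) stop("no samples in group '", group, "'")
  fi <- s[s$site == "fimbrial", ]
  pr <- s[s$site == "proximal", ]
  subjects <- intersect(fi$subject_id, pr$subject_id)
  n_unpaired <- length(unique(s$subject_id)) - length(subjects)
  if (n_unpaired > 0)
    message("paired_differences: excluded ", n_unpaired,
            " unpaired subject(s) in group '", group, "'")
  if (length(subjects) < 3)
    stop("group '", group, "' has ", length(subjects),
         " paired subjects; at least 3 required")
  f_ids <- fi$sample_id[match(subjects, fi$subject_id)]
  p_ids <- pr$sample_id[match(subjects, pr$subject_id)]
  d <- dataset$beta[, f_ids, drop = FALSE] -
    dataset$beta[, p_ids, drop = FALSE]
  colnames(d) <- subjects
  d
}

trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes variance prior from per-probe sample variances
#'
#' Moment estimator on the log scale: with `z = log(s^2)` and residual
#' degrees of freedom `d`, `e = z - digamma(d/2) + log(d/2)` is an unbiased
#' estimate of the log true variance. Matching the excess dispersion of `e`
#' beyond `trigamma(d/2)` to `trigamma(d0/2)` gives the prior degrees of
#' freedom `d0`; the prior variance `s0^2` is recovered from the mean of
#' `e`. When the excess dispersion is not positive there is nothing to
#' shrink towards a spread prior: `d0 = Inf` and `s0^2 = exp(mean(log s^2))`
#' (the geometric mean, which equals the common variance when all `s^2` are
#' identical).
#'
#' @param s2 Per-probe unbiased sample variances.
#' @param df Residual degrees of freedom (pairs minus one).
#' @return List with `d0` and `s02`.
#' @export
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stop("degenerate variance distribution")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  G <- length(e)
  if (G < 2) return(list(d0 = Inf, s02 = exp(mean(z))))
  evar <- sum((e - emean)^2) / (G - 1) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(z))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated paired t-test across probes
#'
#' One-sample empirical-Bayes moderated t-test on a matrix of per-subject
#' paired differences: per probe `g` with `n` pairs, the posterior variance
#' is `(d0 * s0^2 + (n-1) * s_g^2) / (d0 + n - 1)` with the prior from
#' [fit_variance_prior()], the moderated t is `dbar_g / (s_tilde_g /
#' sqrt(n))`, and two-sided p-values use `d0 + n - 1` degrees of freedom.
#' With complete pairs this is equivalent to a two-group model with subject
#' blocking, and in the `d0 = 0` limit it reduces to the ordinary paired t.
#'
#' @param diffs Probes-by-subjects matrix of paired differences (at least 3
#'   columns).
#' @param prior Optional list with `d0` and `s02` overriding the estimated
#'   prior (e.g. `d0 = 0` forces the ordinary paired t).
#' @return List with per-probe `t`, `p`, `dbar`, `s2`, the residual `df`,
#'   total `df_total`, `n` and the `prior`.
#' @export
moderated_paired_test <- function(diffs, prior = NULL) {
  n <- ncol(diffs)
  if (is.null(n) || n < 3) stop("at least 3 paired subjects are required")
  dbar <- rowMeans(diffs)
  s2 <- rowSums((diffs - dbar)^2) / (n - 1)
  if (all(s2 == 0)) stop("degenerate variance distribution")
  if (is.null(prior)) prior <- fit_variance_prior(s2, df = n - 1)
  d0 <- prior$d0
  s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + (n - 1) * s2) / (d0 + (n - 1))
  tstat <- dbar / sqrt(s2_post / n)
  df_total <- d0 + n - 1
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  list(t = tstat, p = p, dbar = dbar, s2 = s2, df = n - 1,
       df_total = df_total, n = n, prior = prior)
}

#' Benjamini-Hochberg / Benjamini-Yekutieli q-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()]; `by_fdr` adds the
#' harmonic-sum penalty `c(m) = sum(1/i)` valid under arbitrary dependence,
#' so BY q-values dominate BH q-values element-wise.
#'
#' @param p Vector of p-values in \[0, 1\]; NA/NaN rejected.
#' @return Vector of q-values, `q >= p` element-wise.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' @rdname bh_fdr
#' @export
by_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Per-group DMP statistics table
#'
#' Convenience wrapper running [paired_differences()],
#' [moderated_paired_test()], [bh_fdr()] and the per-probe median paired
#' difference for one group.
#'
#' @inheritParams paired_differences
#' @return Data frame with `probe_id`, `n_pairs`, `mean_diff`, `s2`, `t`,
#'   `p`, `q`, `median_delta`, plus the difference matrix as attribute
#'   `"diffs"` and the prior as attribute `"prior"`.
#' @export
dmp_group_stats <- function(dataset, group) {
  diffs <- paired_differences(dataset, group)
  fit <- moderated_paired_test(diffs)
  out <- data.frame(probe_id = rownames(diffs),
                    n_pairs = fit$n,
                    mean_diff = fit$dbar,
                    s2 = fit$s2,
                    t = fit$t,
                    p = fit$p,
                    q = bh_fdr(fit$p),
                    median_delta = apply(diffs, 1, stats::median),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "diffs") <- diffs
  attr(out, "prior") <- fit$prior
  out
}

#' Set-difference DMP calling with a median delta-beta threshold
#'
#' Marks probes significant in the carrier group (`q_mut < q_threshold`) and
#' in controls (`q_ctrl < q_threshold`); `mut_not_ctrl` is their set
#' difference. Retained DMPs (`dmp`) additionally require the absolute
#' median paired difference across carrier subjects to exceed
#' `delta_threshold` (strict inequalities throughout). Direction is `hyper`
#' when the carrier median difference is positive, `hypo` otherwise.
#'
#' @param stats_mut,stats_ctrl Per-group tables from [dmp_group_stats()]
#'   over the same probe universe.
#' @param q_threshold FDR threshold (default 0.05).
#' @param delta_threshold Median delta-beta threshold (default 0.03).
#' @return A DMP table: one row per probe with per-group statistics,
#'   `sig_mut`, `sig_ctrl`, `mut_not_ctrl`, `dmp` and `direction`.
#' @export
call_dmps <- function(stats_mut, stats_ctrl, q_threshold = 0.05,
                      delta_threshold = 0.03) {
  if (!setequal(stats_mut$probe_id, stats_ctrl$probe_id))
    stop("probe universes differ between groups (symmetric difference: ",
         length(union(setdiff(stats_mut$probe_id, stats_ctrl$probe_id),
                      setdiff(stats_ctrl$probe_id, stats_mut$probe_id))),
         " probes)")
  stats_ctrl <- stats_ctrl[match(stats_mut$probe_id, stats_ctrl$probe_id), ]
  out <- data.frame(probe_id = stats_mut$probe_id,
                    n_pairs_mut = stats_mut$n_pairs,
                    t_mut = stats_mut$t, p_mut = stats_mut$p,
                    q_mut = stats_mut$q,
                    median_delta_mut = stats_mut$median_delta,
                    n_pairs_ctrl = stats_ctrl$n_pairs,
                    t_ctrl = stats_ctrl$t, p_ctrl = stats_ctrl$p,
                    q_ctrl = stats_ctrl$q,
                    median_delta_ctrl = stats_ctrl$median_delta,
                    stringsAsFactors = FALSE)
  out$sig_mut <- out$q_mut < q_threshold
  out$sig_ctrl <- out$q_ctrl < q_threshold
  out$mut_not_ctrl <- out$sig_mut & !out$sig_ctrl
  out$dmp <- out$mut_not_ctrl & abs(out$median_delta_mut) > delta_threshold
  out$direction <- ifelse(out$median_delta_mut > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

#' Per-volunteer exceedance of retained DMPs
#'
#' For each retained DMP, the fraction of subjects whose paired difference
#' exceeds each threshold *in the DMP's direction* (difference > theta for
#' hyper DMPs, < -theta for hypo DMPs); the mean of these fractions over
#' DMPs is reported per threshold. This summarizes between-volunteer
#' heterogeneity of the reprogramming signal.
#'
#' @param diffs Carrier-group difference matrix from [paired_differences()].
#' @param dmps DMP table from [call_dmps()].
#' @param thresholds Delta-beta thresholds (default `c(0.1, 0.2)`).
#' @return Named numeric vector of mean exceedance fractions.
#' @export
heterogeneity_summary <- function(diffs, dmps, thresholds = c(0.1, 0.2)) {
  sel <- dmps$probe_id[dmps$dmp]
  if (length(sel) == 0) stop("no retained DMPs to summarize")
  d <- diffs[sel, , drop = FALSE]
  sgn <- ifelse(dmps$direction[dmps$dmp] == "hyper", 1, -1)
  signed <- d * sgn
  out <- vapply(thresholds, function(th) mean(rowMeans(signed > th)),
                numeric(1))
  names(out) <- paste0("frac_gt_", thresholds)
  out
}

#' Delta-beta thresholded probe lists for single-sample contrasts
#'
#' For cell-line experiments with one treated and one control array,
#' probes are split into hypermethylated (`treated - control > threshold`)
#' and hypomethylated (`control - treated > threshold`) lists, with strict
#' inequalities.
#'
#' @param beta_treated,beta_control Named beta-value vectors on the same
#'   probe set.
#' @param threshold Delta-beta threshold (e.g. 0.3 for FT11, 0.07-0.15 for
#'   other lines).
#' @return List with `hyper` and `hypo` probe-id vectors.
#' @export
cellline_delta_dmps <- function(beta_treated, beta_control, threshold) {
  if (is.null(names(beta_treated)) || is.null(names(beta_control)) ||
      !setequal(names(beta_treated), names(beta_control)))
    stop("treated and control vectors must share the same probe set")
  beta_control <- beta_control[names(beta_treated)]
  d <- beta_treated - beta_control
  list(hyper = names(d)[d > threshold],
       hypo = names(d)[-d > threshold])
}
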