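# independent re-implementation of the moderated-t closed forms used as an
# oracle; the trigamma inverse is solved by bisection (uniroot), not Newton
oracle_moderated <- function(diffs) {
  n <- ncol(diffs)
  dbar <- apply(diffs, 1, mean)
  s2 <- apply(diffs, 1, var)
  d <- n - 1
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  stopifnot(evar > 0)
  half_d0 <- uniroot(function(y) trigamma(y) - evar,
                     c(1e-4, 1e8), tol = 1e-14)$root
  d0 <- 2 * half_d0
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  s2p <- (d0 * s02 + d * s2) / (d0 + d)
  tt <- dbar / sqrt(s2p / n)
  list(t = tt, p = 2 * pt(-abs(tt), d0 + d), d0 = d0, s02 = s02)
}

test_that("paired differences equal direct fimbrial-minus-proximal subtraction", {
  sim <- simulate_dataset(small_config(seed = 6, missing_rate = 0,
                                       dropout_sample_rate = 0))
  d <- paired_differences(sim$dataset, "MUT")
  s <- sim$dataset$samples
  for (subj in colnames(d)) {
    f <- s$sample_id[s$subject_id == subj & s$site == "fimbrial"]
    p <- s$sample_id[s$subject_id == subj & s$site == "proximal"]
    expect_identical(d[, subj], sim$dataset$beta[, f] - sim$dataset$beta[, p])
  }

  # degenerate constructions
  beta <- matrix(0.5, 10, 6, dimnames = list(sprintf("cg%03d", 1:10),
                                             sprintf("S%02d", 1:6)))
  ds <- tiny_dataset(beta, n_subjects = 3)
  expect_true(all(paired_differences(ds, "MUT") == 0))
  beta[, c(1, 3, 5)] <- 0.55  # fimbrial = proximal + 0.05 everywhere
  ds <- tiny_dataset(beta, n_subjects = 3)
  expect_true(all(abs(paired_differences(ds, "MUT") - 0.05) < 1e-15))
})

test_that("forcing d0 = 0 recovers the ordinary paired t-statistic", {
  set.seed(31)
  diffs <- matrix(rnorm(500 * 8, sd = 0.05), 500, 8,
                  dimnames = list(sprintf("cg%03d", 1:500), NULL))
  fit <- moderated_paired_test(diffs, prior = list(d0 = 0, s02 = 1))
  ordinary_t <- apply(diffs, 1, function(x) t.test(x)$statistic)
  ordinary_p <- apply(diffs, 1, function(x) t.test(x)$p.value)
  expect_equal(fit$t, ordinary_t, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fit$p, ordinary_p, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identical per-probe variances leave the t-statistic unshrunk", {
  set.seed(5)
  base <- rnorm(6, sd = 0.1)
  # rows are permutations of one vector: every probe has the same s^2
  diffs <- t(vapply(1:50, function(i) sample(base) + 0.01 * i,
                    numeric(6)))
  rownames(diffs) <- sprintf("cg%03d", 1:50)
  fit <- moderated_paired_test(diffs)
  expect_true(is.infinite(fit$prior$d0))
  expect_equal(fit$prior$s02, var(base), tolerance = 1e-12)
  ordinary_t <- rowMeans(diffs) / sqrt(var(base) / 6)
  expect_equal(fit$t, ordinary_t, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("moderated test matches an independent direct implementation and limma", {
  set.seed(17)
  n <- 10
  sigma <- sqrt(0.002 / rchisq(2000, df = 6) * 6)  # heterogeneous variances
  diffs <- matrix(rnorm(2000 * n, sd = sigma), 2000, n,
                  dimnames = list(sprintf("cg%05d", 1:2000), NULL))
  fit <- moderated_paired_test(diffs)
  orc <- oracle_moderated(diffs)
  expect_true(is.finite(fit$prior$d0))
  expect_equal(fit$prior$d0, orc$d0, tolerance = 1e-8)
  expect_lt(max(abs(fit$p - orc$p)), 1e-10)
  expect_lt(max(abs(fit$t - orc$t)), 1e-10)

  lf <- limma::eBayes(limma::lmFit(diffs, matrix(1, n, 1)))
  expect_equal(unname(fit$t), unname(lf$t[, 1]), tolerance = 1e-6)
  expect_equal(unname(fit$p), unname(lf$p.value[, 1]), tolerance = 1e-6)
  expect_equal(fit$prior$d0, lf$df.prior, tolerance = 1e-6)
})

test_that("null paired differences give uniform p-values", {
  # per-probe variances drawn from the scaled inverse-chi-square hierarchy,
  # the null under which the moderated t is exactly t-distributed
  set.seed(207)
  null_sd <- sqrt(0.002 * 8 / rchisq(2000, df = 8))
  diffs <- matrix(rnorm(2000 * 10, sd = null_sd), 2000, 10,
                  dimnames = list(sprintf("cg%05d", 1:2000), NULL))
  fit <- moderated_paired_test(diffs)
  ks <- suppressWarnings(ks.test(fit$p, "punif"))$statistic
  expect_lt(ks, 1.6276 / sqrt(2000))  # alpha = 0.01 critical value
})

test_that("degenerate inputs are rejected", {
  diffs <- matrix(0.2, 10, 5)
  expect_error(moderated_paired_test(diffs), "degenerate variance")
  expect_error(moderated_paired_test(matrix(rnorm(10), 5, 2)), "at least 3")
})

test_that("BH and BY q-values match hand step-up computations", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(by_fdr(0.37), 0.37)                   # c(1) = 1
  expect_equal(by_fdr(c(0.01, 0.04)), c(0.03, 0.06)) # c(2) = 1.5
  expect_equal(by_fdr(rep(1, 4)), rep(1, 4))
  expect_error(bh_fdr(c(0.1, NaN)), "finite")
  expect_error(by_fdr(c(0.1, NA)), "finite")
  # q >= p element-wise and BY dominates BH
  set.seed(1); p <- runif(100)
  expect_true(all(bh_fdr(p) >= p))
  expect_true(all(by_fdr(p) >= bh_fdr(p)))
})

test_that("set-difference DMP calling follows its definition", {
  ids <- sprintf("cg%03d", 1:4)
  mut <- fake_group_stats(ids, q = c(0.001, 0.01, 0.001, 0.20),
                          median_delta = c(0.05, 0.05, 0.02, 0.10))
  ctrl <- fake_group_stats(ids, q = c(0.001, 0.60, 0.60, 0.60),
                           median_delta = c(0.05, 0, 0, 0))
  dm <- call_dmps(mut, ctrl)
  # probe 1: significant in both -> excluded; probe 2: MUT-only, passes
  # delta; probe 3: MUT-only but |median| <= 0.03; probe 4: not significant
  expect_identical(dm$mut_not_ctrl, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(dm$dmp, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(dm$direction[2], "hyper")

  # shared significance cancels everywhere
  both <- call_dmps(fake_group_stats(ids, 0.001, 0.1),
                    fake_group_stats(ids, 0.001, 0.1))
  expect_false(any(both$mut_not_ctrl))

  expect_error(call_dmps(mut, fake_group_stats(sprintf("cg%03d", 2:5),
                                               0.5, 0)),
               "universes differ")
})

test_that("raising the delta threshold never enlarges the DMP set", {
  sim <- simulate_dataset(small_config(seed = 9, missing_rate = 0))
  sm <- dmp_group_stats(sim$dataset, "MUT")
  sc <- dmp_group_stats(sim$dataset, "control")
  prev <- NULL
  for (th in c(0, 0.03, 0.05, 0.08, 0.12)) {
    cur <- call_dmps(sm, sc, delta_threshold = th)
    cur_set <- cur$probe_id[cur$dmp]
    if (!is.null(prev)) expect_true(all(cur_set %in% prev))
    prev <- cur_set
  }
})

test_that("swapping fimbrial/proximal labels flips signs and exchanges lists", {
  sim <- simulate_dataset(small_config(seed = 14, missing_rate = 0,
                                       dropout_sample_rate = 0))
  swapped <- sim$dataset
  swapped$samples$site <- ifelse(swapped$samples$site == "fimbrial",
                                 "proximal", "fimbrial")
  a_mut <- dmp_group_stats(sim$dataset, "MUT")
  b_mut <- dmp_group_stats(swapped, "MUT")
  expect_equal(b_mut$median_delta, -a_mut$median_delta, tolerance = 1e-12)
  a <- call_dmps(a_mut, dmp_group_stats(sim$dataset, "control"))
  b <- call_dmps(b_mut, dmp_group_stats(swapped, "control"))
  expect_identical(a$probe_id[a$dmp & a$direction == "hyper"],
                   b$probe_id[b$dmp & b$direction == "hypo"])
  expect_identical(a$probe_id[a$dmp & a$direction == "hypo"],
                   b$probe_id[b$dmp & b$direction == "hyper"])
})

test_that("with zero spikes the mut-not-ctrl call rate stays at or below nominal", {
  rates <- vapply(1:20, function(seed) {
    sim <- simulate_dataset(small_config(
      seed = seed, n_probes = 2000L, n_subjects_mut = 8L,
      n_subjects_ctrl = 8L, n_spiked_mut_only = 0L, n_spiked_shared = 0L,
      missing_rate = 0, dropout_sample_rate = 0))
    sm <- dmp_group_stats(sim$dataset, "MUT")
    sc <- dmp_group_stats(sim$dataset, "control")
    dm <- call_dmps(sm, sc)
    mean(dm$mut_not_ctrl)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})

test_that("heterogeneity summary equals a brute-force count", {
  ids <- sprintf("cg%03d", 1:3)
  dmps <- fake_group_stats(ids, q = 0.001, median_delta = 0.05)
  dmps$sig_mut <- TRUE; dmps$sig_ctrl <- FALSE
  dmps$mut_not_ctrl <- TRUE; dmps$dmp <- TRUE; dmps$direction <- "hyper"
  d_const <- matrix(0.05, 3, 10, dimnames = list(ids, NULL))
  expect_equal(heterogeneity_summary(d_const, dmps),
               c(frac_gt_0.1 = 0, frac_gt_0.2 = 0))
  d_mid <- matrix(0.15, 3, 10, dimnames = list(ids, NULL))
  expect_equal(heterogeneity_summary(d_mid, dmps),
               c(frac_gt_0.1 = 1, frac_gt_0.2 = 0))

  sim <- simulate_dataset(small_config(seed = 23, missing_rate = 0))
  sm <- dmp_group_stats(sim$dataset, "MUT")
  dm <- call_dmps(sm, dmp_group_stats(sim$dataset, "control"))
  diffs <- attr(sm, "diffs")
  got <- heterogeneity_summary(diffs, dm, thresholds = c(0.1, 0.2))
  # two-loop oracle
  sel <- which(dm$dmp)
  for (ti in 1:2) {
    th <- c(0.1, 0.2)[ti]
    fracs <- numeric(0)
    for (i in sel) {
      row <- diffs[dm$probe_id[i], ]
      hits <- if (dm$direction[i] == "hyper") sum(row > th) else sum(row < -th)
      fracs <- c(fracs, hits / length(row))
    }
    expect_equal(unname(got[ti]), mean(fracs))
  }
})

test_that("cell-line delta thresholds use strict inequalities", {
  probes <- sprintf("cg%03d", 1:5)
  # boundary probes use binary-exact differences: cg003 sits exactly at
  # +threshold and cg005 exactly at -threshold, so both must be excluded
  tr <- setNames(c(0.500, 0.770, 0.750, 0.100, 0.500), probes)
  ct <- setNames(c(0.500, 0.500, 0.500, 0.450, 0.750), probes)
  out <- cellline_delta_dmps(tr, ct, threshold = 0.25)
  expect_identical(out$hyper, "cg002")
  expect_identical(out$hypo, "cg004")
  expect_identical(cellline_delta_dmps(tr, tr, 0.1),
                   list(hyper = character(0), hypo = character(0)))

  set.seed(77)
  a <- setNames(runif(200), sprintf("cg%03d", 1:200))
  b <- setNames(runif(200), sprintf("cg%03d", 1:200))
  out <- cellline_delta_dmps(a, b, 0.1)
  expect_identical(out$hyper, names(a)[a - b > 0.1])
  expect_identical(out$hypo, names(a)[b - a > 0.1])
  expect_error(cellline_delta_dmps(a[1:100], b[101:200], 0.1), "probe set")
})
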