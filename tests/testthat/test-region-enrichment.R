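make_dmp_table <- function(ids, delta, direction = NULL, dmp = TRUE) {
  out <- fake_group_stats(ids, q = 0.001, median_delta = delta)
  out$median_delta_mut <- delta
  out$sig_mut <- TRUE; out$sig_ctrl <- FALSE; out$mut_not_ctrl <- dmp
  out$dmp <- dmp
  out$direction <- if (is.null(direction)) ifelse(delta > 0, "hyper", "hypo")
                   else direction
  out
}

test_that("top-probe selection matches a full-sort oracle", {
  set.seed(55)
  ids <- sprintf("cg%04d", 1:500)
  delta <- -runif(500, 0.03, 0.4)
  dm <- make_dmp_table(ids, delta)
  got <- select_top_probes(dm, n = 100, direction = "hypo")
  oracle <- ids[order(-abs(delta), ids)][1:100]
  expect_identical(got, oracle)

  # n larger than the list -> whole list with a warning
  expect_warning(all_of_them <- select_top_probes(dm, n = 1000,
                                                  direction = "hypo"),
                 "only 500")
  expect_setequal(all_of_them, ids)
  # requesting the absent direction -> empty with a warning
  expect_warning(none <- select_top_probes(dm, n = 10, direction = "hyper"),
                 "only 0")
  expect_identical(none, character(0))
})

test_that("matched backgrounds preserve per-bin composition and exclude test probes", {
  sim <- simulate_dataset(small_config(seed = 19, n_probes = 2000L))
  ann <- sim$annotation
  test_probes <- sample(ann$probe_id, 150)
  bgs <- matched_backgrounds(test_probes, ann, n_sets = 50, seed = 3)
  bin <- paste(ann$gene_relation, ann$cgi_relation, sep = "|")
  names(bin) <- ann$probe_id
  target <- sort(table(bin[test_probes]))
  for (bg in bgs) {
    expect_length(bg, length(test_probes))
    expect_identical(sort(table(bin[bg])), target)
    expect_length(intersect(bg, test_probes), 0)
    expect_false(anyDuplicated(bg) > 0)
  }
})

test_that("under-populated bins are rejected with the bin named", {
  ann <- data.frame(probe_id = sprintf("cg%03d", 1:6), chrom = "chrS1",
                    pos = 1:6 * 1000, genes = "",
                    gene_relation = "Body",
                    cgi_relation = rep(c("Island", "OpenSea"), each = 3),
                    stringsAsFactors = FALSE)
  # all Island probes are test probes: empty non-test pool in that bin
  expect_error(matched_backgrounds(sprintf("cg%03d", 1:3), ann, n_sets = 5),
               "Body\\|Island")
})

test_that("single-bin backgrounds are uniform draws from the non-test pool", {
  ann <- data.frame(probe_id = sprintf("cg%04d", 1:300), chrom = "chrS1",
                    pos = 1:300 * 1000, genes = "", gene_relation = "Body",
                    cgi_relation = "OpenSea", stringsAsFactors = FALSE)
  test_probes <- ann$probe_id[1:50]
  pool <- ann$probe_id[51:300]
  bgs <- matched_backgrounds(test_probes, ann, n_sets = 1000, seed = 8)
  freq <- table(factor(unlist(bgs), levels = pool)) / 1000
  q <- 50 / 250
  se <- sqrt(q * (1 - q) / 1000)
  expect_true(all(abs(freq - q) < 4 * se))
})

test_that("probe-in-interval counting respects half-open BED semantics", {
  ann <- data.frame(probe_id = c("cgA", "cgB", "cgC"), chrom = "chrS1",
                    pos = c(101, 100, 200), genes = "",
                    gene_relation = "Body", cgi_relation = "OpenSea",
                    stringsAsFactors = FALSE)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrS1\t100\t200", bed)
  track <- read_bed(bed)
  expect_identical(overlap_count("cgA", track, ann), 1L)  # pos 101 inside
  expect_identical(overlap_count("cgB", track, ann), 0L)  # pos 100 outside
  expect_identical(overlap_count("cgC", track, ann), 1L)  # pos 200: idx 199
  # unknown chromosome counts as non-overlapping, with a note
  ann2 <- ann; ann2$chrom <- "chrZ"
  expect_message(n <- overlap_count("cgA", track, ann2), "absent")
  expect_identical(n, 0L)
})

test_that("overlap counting equals a naive double loop and is split-invariant", {
  set.seed(71)
  ann <- data.frame(probe_id = sprintf("cg%04d", 1:500), chrom = "chrS1",
                    pos = sort(sample(1:100000, 500)), genes = "",
                    gene_relation = "Body", cgi_relation = "OpenSea",
                    stringsAsFactors = FALSE)
  starts <- sort(sample(seq(1, 99000, by = 2000), 50))
  ends <- starts + sample(200:1500, 50, replace = TRUE)
  track <- GenomicRanges::reduce(GenomicRanges::GRanges(
    "chrS1", IRanges::IRanges(starts + 1, ends)))
  got <- overlap_count(ann$probe_id, track, ann)
  naive <- 0L
  for (p in ann$pos) {
    hit <- FALSE
    for (i in seq_along(starts))
      if (p - 1 >= starts[i] && p - 1 < ends[i]) hit <- TRUE
    naive <- naive + hit
  }
  expect_identical(got, as.integer(naive))

  # order invariance and adjacent-split invariance
  shuf <- track[sample(length(track))]
  expect_identical(overlap_count(ann$probe_id, shuf, ann), got)
  mid <- floor((GenomicRanges::start(track) + GenomicRanges::end(track)) / 2)
  split_track <- c(
    GenomicRanges::GRanges("chrS1",
      IRanges::IRanges(GenomicRanges::start(track), mid)),
    GenomicRanges::GRanges("chrS1",
      IRanges::IRanges(mid + 1, GenomicRanges::end(track))))
  expect_identical(overlap_count(ann$probe_id, split_track, ann), got)
})

test_that("pooled binomial enrichment p-values follow the closed forms", {
  expect_equal(enrichment_test(0, c(5, 7), 10)$p, 1)   # empty upper tail
  et <- enrichment_test(10, rep(5, 100), 10)           # p_hat = 0.5
  expect_equal(et$p, 2^-10, tolerance = 1e-12)
  expect_equal(et$neg_log10_p, -log10(2^-10), tolerance = 1e-12)
  # direct-summation oracle
  et2 <- enrichment_test(13, rep(4, 50), 40)           # p_hat = 0.1
  expect_equal(et2$p, enum_binom_upper(13, 40, 0.1), tolerance = 1e-12)
  # observed at the background expectation: tail stays large
  for (n_test in c(20, 50, 100)) {
    et3 <- enrichment_test(round(n_test * 0.3), rep(round(n_test * 0.3), 10),
                           n_test)
    expect_gte(et3$p, 0.3)
  }
  expect_error(enrichment_test(11, rep(5, 10), 10), "exceeds")
  # zero background rate
  expect_equal(enrichment_test(0, rep(0, 10), 10)$p, 1)
  expect_message(flo <- enrichment_test(3, rep(0, 10), 10), "floored")
  expect_lt(flo$p, 1e-300)
})

test_that("end-to-end region enrichment is deterministic and flags the planted track", {
  cfg <- small_config(seed = 33, n_probes = 4000L, n_spiked_mut_only = 300L,
                      n_spiked_shared = 0L, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  tracks <- simulate_peak_tracks(sim$annotation, sim$truth, cfg)
  test_probes <- sim$truth$spiked_mut_only
  a <- region_enrichment(test_probes, tracks, sim$annotation,
                         n_sets = 200, seed = 5)
  b <- region_enrichment(test_probes, tracks, sim$annotation,
                         n_sets = 200, seed = 5)
  expect_identical(a, b)
  planted <- a[a$tissue == "T01" & a$mark == "H3K4me1", ]
  expect_true(planted$significant)
  expect_true(all(a$q >= a$p))
})
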