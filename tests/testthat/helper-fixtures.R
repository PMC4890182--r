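# shared fixture builders; everything is generated in code, no stored data

small_config <- function(seed = 1L, ...) {
  defaults <- list(n_subjects_mut = 10L, n_subjects_ctrl = 10L,
                   n_probes = 3000L, n_spiked_mut_only = 100L,
                   n_spiked_shared = 50L, n_tissues = 2L, n_marks = 2L,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# minimal dataset built by hand: probes x samples matrices plus sheet
tiny_dataset <- function(beta, detp = NULL, n_subjects = ncol(beta) / 2) {
  samples <- data.frame(
    sample_id = colnames(beta),
    subject_id = rep(sprintf("S%02d", seq_len(n_subjects)), each = 2),
    site = rep(c("fimbrial", "proximal"), n_subjects),
    group = "MUT",
    stringsAsFactors = FALSE)
  meth_dataset(beta, detp, samples)
}

# minimal per-group stats table accepted by call_dmps()
fake_group_stats <- function(probe_id, q, median_delta,
                             p = q, t = 1, n_pairs = 10) {
  data.frame(probe_id = probe_id, n_pairs = n_pairs, mean_diff = median_delta,
             s2 = 0.01, t = t, p = p, q = q, median_delta = median_delta,
             stringsAsFactors = FALSE)
}

# hypergeometric upper-tail enumeration from first principles (choose only)
enum_overlap_p <- function(U, a, b, k) {
  if (a == 0 || b == 0) return(1)
  js <- seq.int(k, min(a, b))
  if (k > min(a, b)) return(0)
  sum(choose(a, js) * choose(U - a, b - js)) / choose(U, b)
}

# binomial upper tail by direct summation
enum_binom_upper <- function(x, n, prob) {
  if (x <= 0) return(1)
  ks <- seq.int(x, n)
  sum(choose(n, ks) * prob^ks * (1 - prob)^(n - ks))
}
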