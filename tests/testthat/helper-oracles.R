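# Independent oracles and small fixture builders used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# Brute-force oracle: the set of all substrings of the given lengths that
# contain the 1-based position p.
brute_force_windows <- function(seq, p, lengths = 8:11) {
  n <- nchar(seq)
  out <- character(0)
  for (L in lengths) {
    for (s in seq_len(max(n - L + 1L, 0L))) {
      e <- s + L - 1L
      if (s <= p && p <= e) out <- c(out, substr(seq, s, e))
    }
  }
  unique(out)
}

# Closed-form window count for one length (pre-deduplication).
window_count <- function(n, p, L) {
  cnt <- min(p, n - L + 1) - max(1, p - L + 1) + 1
  as.integer(max(cnt, 0))
}

# Exact one-sided rank-sum p-value by full enumeration of group-a
# assignments, written independently of the package implementation.
oracle_exact_p <- function(a, b, alternative = "a_greater") {
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a)
  u_obs <- sum(r[seq_along(a)]) - n_a * (n_a + 1) / 2
  sets <- utils::combn(length(pooled), n_a)
  u_all <- apply(sets, 2L, function(ix) sum(r[ix]) - n_a * (n_a + 1) / 2)
  if (alternative == "a_greater") mean(u_all >= u_obs)
  else mean(u_all <= u_obs)
}

# Permutation mid-p (half weight on the observed U) — the tail quantity the
# uncorrected normal approximation estimates.
oracle_mid_p <- function(a, b, alternative = "a_greater") {
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a)
  u_obs <- sum(r[seq_along(a)]) - n_a * (n_a + 1) / 2
  sets <- utils::combn(length(pooled), n_a)
  u_all <- apply(sets, 2L, function(ix) sum(r[ix]) - n_a * (n_a + 1) / 2)
  if (alternative == "a_greater") {
    mean(u_all > u_obs) + 0.5 * mean(u_all == u_obs)
  } else {
    mean(u_all < u_obs) + 0.5 * mean(u_all == u_obs)
  }
}

# Minimal valid variant data.frame in the package's canonical layout.
make_variants <- function(patient_id, gene, variant_class = "missense",
                          ref_base = NA, alt_base = NA, ref_aa = NA,
                          protein_pos = NA, alt_aa = NA) {
  df <- data.frame(patient_id = patient_id, gene = gene,
                   variant_class = variant_class,
                   ref_base = as.character(ref_base),
                   alt_base = as.character(alt_base),
                   ref_aa = as.character(ref_aa),
                   protein_pos = as.integer(protein_pos),
                   alt_aa = as.character(alt_aa),
                   stringsAsFactors = FALSE)
  df$protein_change <- format_protein_change(df$ref_aa, df$protein_pos,
                                             df$alt_aa)
  df
}

write_tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  path
}

fast_config <- function(...) {
  cohort_config(n_genes = 40, protein_length_range = c(50, 120), ...)
}
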