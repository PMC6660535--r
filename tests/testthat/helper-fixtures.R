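# hand-built fixtures used across test files

tiny_markers <- function() {
  tibble::tibble(
    marker_id = c("chr01:100", "chr01:500", "chr02:300"),
    chrom = c("chr01", "chr01", "chr02"),
    pos_bp = c(100L, 500L, 300L),
    allele_ref = c("A", "C", "G"),
    allele_alt = c("G", "T", "T")
  )
}

tiny_gm <- function() {
  calls <- rbind(
    s1 = c("AA", "CC", "GG"),
    s2 = c("AG", "CT", NA),
    s3 = c("GG", "TT", "GT")
  )
  geno_matrix(calls, tiny_markers(),
              tibble::tibble(sample_id = c("s1", "s2", "s3")))
}

# dosage-pattern matrix: every marker has MAF 0.5, full call rate, no hets
clean_gm <- function(n_samples = 40, n_markers = 20, seed = 1) {
  set.seed(seed)
  panel <- simulate_panel(n_markers, seed = seed)
  D <- matrix(rep_len(c(0, 2), n_samples * n_markers), n_samples, n_markers)
  geno_matrix(calls_from_dosage(D, panel), panel,
              tibble::tibble(sample_id = sprintf("s%02d", seq_len(n_samples))))
}
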