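# Builders for small in-code fixtures.

make_snps <- function(n, candidate = integer()) {
  data.frame(
    snp_id = sprintf("s%03d", seq_len(n)),
    chrom = "chr1",
    pos = 1000L * seq_len(n),
    allele_a = "A", allele_b = "G",
    is_candidate = seq_len(n) %in% candidate,
    stringsAsFactors = FALSE
  )
}

# panel from an explicit individuals x SNPs dosage matrix
panel_from_matrix <- function(dos, cohort_id = "X", candidate = integer()) {
  cohort_panel(cohort_id, make_snps(ncol(dos), candidate), dos)
}

# random clean panel: p drawn per SNP, no missingness unless requested
random_panel <- function(n_ind, n_snp, cohort_id = "X", missing_rate = 0,
                         seed = 1) {
  set.seed(seed)
  p <- runif(n_snp, 0.1, 0.9)
  dos <- matrix(rbinom(n_ind * n_snp, 2L, rep(p, each = n_ind)), n_ind, n_snp)
  if (missing_rate > 0) {
    dos[matrix(runif(length(dos)) < missing_rate, n_ind, n_snp)] <- NA_integer_
  }
  panel_from_matrix(dos, cohort_id)
}

# independent brute-force enumeration of 3-subset means (the oracle for the
# empirical-null counting path); same tie tolerance as the package routine
brute_force_count <- function(values, threshold, strict = FALSE) {
  sums <- colSums(utils::combn(values, 3L))
  if (strict) sum(sums < 3 * threshold - 1e-12)
  else sum(sums <= 3 * threshold + 1e-12)
}
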