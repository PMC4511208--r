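# Cross-cohort MAF-change test.
#
# For each SNP j the change in MAF between two cohorts is
#   delta_m[j] = m_a[j] - m_b[j],
# with the minor allele fixed in the reference cohort (so delta_m ranges over
# [-0.5, 1] when cohort b is the reference). The candidate-set statistic is
# the mean delta_m over the 3 candidate SNPs; its null distribution is the
# same mean over every one of the C(n, 3) subsets of the post-filter panel,
# and the empirical P is the proportion of subset means at least as small as
# the candidate mean. A Welch-type variance adjustment replaces delta_m by
#   t[j] = delta_m[j] / sqrt(s2_a/(4 n_a) + s2_b/(4 n_b)),
# the dosage variances converted to allele-frequency variances, which
# down-weights SNPs whose MAF is noisily estimated.

# Floating-point tie tolerance on subset-mean comparisons. Subset sums of
# identical value sets can differ in the last bit depending on summation
# order; ties within this absolute slack are treated as exact ties.
.TIE_EPS <- 1e-12

#' Exact binomial coefficient
#'
#' Integer-exact `choose(n, k)` by stepwise multiplicative evaluation: each
#' intermediate is itself a binomial coefficient, so every division is exact.
#' Returns a double (exact up to 2^53).
#'
#' @param n,k Non-negative integers with `k <= n`.
#' @return `C(n, k)` as a numeric scalar.
#' @examples
#' count_combinations(174, 3) # 862924
#' count_combinations(144, 3) # 487344
#' @export
count_combinations <- function(n, k) {
  stopifnot(length(n) == 1L, length(k) == 1L, n >= 0, k >= 0,
            n == floor(n), k == floor(k))
  if (k > n) stop("k must not exceed n")
  k <- min(k, n - k)
  r <- 1
  for (i in seq_len(k)) r <- (r * (n - k + i)) / i
  r
}

#' Per-SNP change in MAF between two cohorts
#'
#' `delta_m[j] = maf_a[j] - maf_b[j]` on the shared SNP set, carrying the
#' per-cohort dosage variances and genotype counts needed by [welch_t()].
#' Both tables must use the same (reference-cohort) minor-allele assignment.
#'
#' @param maf_a,maf_b `maf_table`s from [compute_maf()] over the same SNPs;
#'   `maf_a` is the cohort tested for frequency reduction.
#' @return Data frame of class `delta_table`: `snp_id`, `delta_m`, `m_a`,
#'   `m_b`, `s2_a`, `s2_b`, `n_a`, `n_b`, `t_stat` (filled by [welch_t()]).
#' @export
delta_maf <- function(maf_a, maf_b) {
  hit <- match(maf_a$snp_id, maf_b$snp_id)
  if (anyNA(hit)) {
    stop("SNP(s) missing from the second MAF table: ",
         paste(maf_a$snp_id[is.na(hit)], collapse = ", "))
  }
  extra <- setdiff(maf_b$snp_id, maf_a$snp_id)
  if (length(extra) > 0L) {
    stop("SNP(s) missing from the first MAF table: ",
         paste(extra, collapse = ", "))
  }
  b <- maf_b[hit, ]
  out <- data.frame(
    snp_id = maf_a$snp_id,
    delta_m = maf_a$maf - b$maf,
    m_a = maf_a$maf, m_b = b$maf,
    s2_a = maf_a$s2, s2_b = b$s2,
    n_a = maf_a$n_geno, n_b = b$n_geno,
    t_stat = NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Mean MAF change over a SNP set
#'
#' @param delta A `delta_table` from [delta_maf()].
#' @param snp_set Character vector of SNP ids (non-empty, all present).
#' @return Arithmetic mean of `delta_m` over the set.
#' @export
mean_delta <- function(delta, snp_set) {
  if (length(snp_set) == 0L) stop("snp_set is empty")
  hit <- match(snp_set, delta$snp_id)
  if (anyNA(hit)) {
    stop("SNP(s) not in delta table: ", paste(snp_set[is.na(hit)],
                                              collapse = ", "))
  }
  mean(delta$delta_m[hit])
}

#' Welch-type variance-adjusted MAF-change statistic
#'
#' Fills `t_stat = delta_m / sqrt(s2_a/(4 n_a) + s2_b/(4 n_b))`. The factor 4
#' converts the dosage variance `s2` into the variance of the estimated
#' allele frequency (`mhat = mean(dosage)/2`); because a common rescaling of
#' all variances cancels from the empirical P, the test is insensitive to
#' this convention. SNPs where both variances are zero get `t = 0` when
#' `delta_m = 0` and `sign(delta_m) * Inf` otherwise, flagged in
#' `t_degenerate`.
#'
#' @param delta A `delta_table` from [delta_maf()].
#' @return The `delta_table` with `t_stat` (and flag column `t_degenerate`)
#'   filled.
#' @export
welch_t <- function(delta) {
  if (any(delta$s2_a < 0, na.rm = TRUE) || any(delta$s2_b < 0, na.rm = TRUE)) {
    stop("negative dosage variance")
  }
  se2 <- delta$s2_a / (4 * delta$n_a) + delta$s2_b / (4 * delta$n_b)
  t <- delta$delta_m / sqrt(se2)
  degen <- !is.na(se2) & se2 == 0
  t[degen] <- ifelse(delta$delta_m[degen] == 0, 0,
                     sign(delta$delta_m[degen]) * Inf)
  delta$t_stat <- t
  delta$t_degenerate <- degen
  delta
}

# Count 3-subsets of `values` whose mean is <= threshold (or < threshold when
# strict). O(n^2 log n): sort, loop over pairs (i < j), binary-search the
# count of k > j with v[k] <= 3*threshold - v[i] - v[j]. Ties resolved with
# an absolute tolerance of .TIE_EPS on the sum.
.count_triples_below <- function(values, threshold, strict = FALSE) {
  v <- sort(values)
  n <- length(v)
  if (n < 3L) return(0)
  target <- 3 * threshold + if (strict) -.TIE_EPS else .TIE_EPS
  pr <- utils::combn(n - 1L, 2L) # pairs (i, j) with j <= n-1
  i <- pr[1L, ]
  j <- pr[2L, ]
  rem <- target - v[i] - v[j]
  cnt <- findInterval(rem, v) - j
  sum(pmax(0, cnt))
}

#' Exhaustive 3-SNP-subset empirical null
#'
#' Enumerates all `C(n, 3)` subsets of the post-filter SNP list (candidates
#' included in the enumeration universe) and reports the proportion of
#' subsets whose mean statistic is at least as small as the candidate-set
#' mean. With the default tie rule `"leq"` the candidate subset counts
#' itself, so `p >= 1/C(n, 3)`; the strict rule `"lt"` (used by the
#' drift-model test) allows `p = 0`.
#'
#' @param delta A `delta_table`; when `use_adjusted` the `t_stat` column from
#'   [welch_t()] is the statistic, otherwise `delta_m`.
#' @param candidate_set Exactly three SNP ids present in `delta`.
#' @param use_adjusted Use the Welch-adjusted statistic?
#' @param tie_rule `"leq"` (at least as small, default) or `"lt"` (strictly
#'   smaller).
#' @return A `selection_test_result`: `statistic_cd`, `n_subsets`,
#'   `n_at_least_as_small`, `p_empirical`, `adjusted`, `tie_rule`,
#'   `candidate_ids`, `n_snps`.
#' @export
empirical_p <- function(delta, candidate_set, use_adjusted = FALSE,
                        tie_rule = c("leq", "lt")) {
  tie_rule <- match.arg(tie_rule)
  if (length(candidate_set) != 3L) {
    stop("candidate_set must contain exactly 3 SNP ids")
  }
  n <- nrow(delta)
  if (n < 3L) stop("need at least 3 SNPs to enumerate 3-subsets")
  values <- if (use_adjusted) delta$t_stat else delta$delta_m
  if (use_adjusted && all(is.na(values))) {
    stop("t_stat not filled; call welch_t() first")
  }
  if (anyNA(values)) {
    stop("undefined statistic at SNP(s): ",
         paste(delta$snp_id[is.na(values)], collapse = ", "),
         " (exclude them upstream)")
  }
  hit <- match(candidate_set, delta$snp_id)
  if (anyNA(hit)) {
    stop("candidate SNP(s) not in delta table: ",
         paste(candidate_set[is.na(hit)], collapse = ", "))
  }
  stat_cd <- mean(values[hit])
  n_subsets <- count_combinations(n, 3L)
  n_small <- .count_triples_below(values, stat_cd, strict = tie_rule == "lt")
  structure(
    list(statistic_cd = stat_cd, n_subsets = n_subsets,
         n_at_least_as_small = n_small, p_empirical = n_small / n_subsets,
         adjusted = use_adjusted, tie_rule = tie_rule,
         candidate_ids = candidate_set, n_snps = n),
    class = "selection_test_result"
  )
}

#' @export
print.selection_test_result <- function(x, ...) {
  cat("<selection_test_result>\n")
  cat("  candidate SNPs: ", paste(x$candidate_ids, collapse = ", "), "\n",
      sep = "")
  cat(sprintf("  statistic (mean over candidates): %.6g%s\n", x$statistic_cd,
              if (isTRUE(x$adjusted)) "  [variance-adjusted]" else ""))
  cat(sprintf("  subsets enumerated: %s of %d SNPs\n",
              format(x$n_subsets, big.mark = ","), x$n_snps))
  cat(sprintf("  empirical P (%s): %.6g  (%s extreme subsets)\n",
              if (x$tie_rule == "leq") "<=" else "<",
              x$p_empirical, format(x$n_at_least_as_small, big.mark = ",")))
  invisible(x)
}
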