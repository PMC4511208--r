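# SNP filtering cascades.
#
# Both selection tests assume polymorphic, well-genotyped, approximately
# independent markers. Two cascades implement this: a pairwise cascade for
# the cross-cohort MAF test (SNPs removed outright) and a three-way cascade
# for the drift model (low-call-rate SNPs masked per cohort rather than
# removed, so partially observed SNPs still inform the drift fit). Stage
# order is fixed: call rate -> monomorphic -> LD pruning.

new_filter_report <- function(comparison_id, mode, n_input, stagewise, retained,
                              masked = list()) {
  removed <- vapply(stagewise, length, integer(1L))
  rep <- structure(
    list(comparison_id = comparison_id, mode = mode, n_input = n_input,
         removed_call_rate = removed[["call_rate"]],
         removed_monomorphic = removed[["monomorphic"]],
         removed_ld = removed[["ld"]],
         retained = retained, stagewise_removed_ids = stagewise,
         masked = masked),
    class = "filter_report"
  )
  stopifnot(rep$n_input - rep$removed_call_rate - rep$removed_monomorphic -
              rep$removed_ld == length(retained))
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> ", x$comparison_id, " (", x$mode, ")\n", sep = "")
  cat("  input SNPs:          ", x$n_input, "\n", sep = "")
  if (x$mode == "threeway") {
    cat("  masked (low call rate) in >=1 cohort: ",
        length(unique(unlist(x$masked))), "\n", sep = "")
  } else {
    cat("  removed, call rate:  ", x$removed_call_rate, "\n", sep = "")
  }
  cat("  removed, monomorphic:", x$removed_monomorphic, "\n", sep = "")
  cat("  removed, LD:         ", x$removed_ld, "\n", sep = "")
  cat("  retained:            ", length(x$retained), "\n", sep = "")
  invisible(x)
}

# Frequency of allele_b per SNP over nonmissing haplotypes; NA if no calls.
.freq_b <- function(panel, ids) {
  dos <- panel$dosages[, ids, drop = FALSE]
  n <- colSums(!is.na(dos))
  ifelse(n > 0L, colSums(dos, na.rm = TRUE) / (2 * n), NA_real_)
}

.call_rate <- function(panel, ids) {
  dos <- panel$dosages[, ids, drop = FALSE]
  colSums(!is.na(dos)) / nrow(dos)
}

# Monomorphic within one cohort: a single allele observed (or nothing).
.mono_in_cohort <- function(panel, ids) {
  f <- .freq_b(panel, ids)
  is.na(f) | f == 0 | f == 1
}

# Deterministic greedy LD pruning. r2_list: per-cohort r2 matrices over the
# same SNP ids (NA treated as 0). Pairs offend when r2 >= threshold in any
# cohort. Pairs are scanned in genome order; from each offending pair the
# later SNP (chrom, pos, panel order) is removed unless it is protected and
# its partner is not, in which case the partner goes. Two protected SNPs in
# LD are both kept with a warning (the candidate set must stay intact).
.ld_prune <- function(ids, r2_list, threshold, genome_rank, protected) {
  r2max <- Reduce(pmax, lapply(r2_list, function(m) {
    m <- m[ids, ids, drop = FALSE]
    m[is.na(m)] <- 0
    m
  }))
  ord <- order(genome_rank[ids])
  ids_ord <- ids[ord]
  keep <- rep(TRUE, length(ids_ord))
  names(keep) <- ids_ord
  n <- length(ids_ord)
  removed <- character(0L)
  for (i in seq_len(max(0L, n - 1L))) {
    if (!keep[i]) next
    for (j in seq.int(i + 1L, n)) {
      if (!keep[j]) next
      if (r2max[ids_ord[i], ids_ord[j]] >= threshold) {
        pi <- ids_ord[i] %in% protected
        pj <- ids_ord[j] %in% protected
        if (pi && pj) {
          warning("protected SNPs ", ids_ord[i], " and ", ids_ord[j],
                  " are in LD (r2 >= ", threshold, "); both kept")
        } else if (pj && !pi) {
          keep[i] <- FALSE
          removed <- c(removed, ids_ord[i])
          break # victim i is gone; stop scanning its row
        } else {
          keep[j] <- FALSE
          removed <- c(removed, ids_ord[j])
        }
      }
    }
  }
  survivors <- ids_ord[keep]
  # restore panel order
  list(retained = ids[ids %in% survivors], removed = removed)
}

.genome_rank <- function(snps) {
  r <- order(snps$chrom, snps$pos, seq_len(nrow(snps)))
  rank <- integer(nrow(snps))
  rank[r] <- seq_len(nrow(snps))
  names(rank) <- snps$snp_id
  rank
}

#' Pairwise filtering cascade for the cross-cohort MAF test
#'
#' Restricts to SNPs shared by both panels, then removes in order: SNPs with
#' genotype call rate below `call_threshold` in either cohort; SNPs
#' monomorphic in either cohort (a zero MAF gives the variance-adjusted
#' statistic nothing to work with); and, for approximate independence, one
#' SNP of every pair with LD r2 >= `r2_threshold` in either cohort
#' (greedy, deterministic; see Details).
#'
#' Candidate SNPs (`is_candidate` in either panel, or `protect`) are never
#' chosen as the LD victim when paired with a non-candidate.
#'
#' @param panel_a,panel_b [cohort_panel()] objects sharing a SNP set.
#' @param call_threshold Minimum genotype call rate (default 0.9).
#' @param r2_threshold LD pruning threshold (default 0.8).
#' @param protect Extra SNP ids to protect at the LD stage.
#' @return A `filter_report` with per-stage removal counts and the ordered
#'   retained SNP ids.
#' @export
filter_pairwise <- function(panel_a, panel_b, call_threshold = 0.9,
                            r2_threshold = 0.8, protect = character()) {
  stopifnot(inherits(panel_a, "cohort_panel"), inherits(panel_b, "cohort_panel"))
  shared <- intersect(panel_a$snps$snp_id, panel_b$snps$snp_id)
  if (length(shared) == 0L) stop("panels share no SNPs")
  comparison_id <- paste0(panel_a$cohort_id, "_vs_", panel_b$cohort_id)
  protected <- unique(c(
    protect,
    panel_a$snps$snp_id[panel_a$snps$is_candidate],
    panel_b$snps$snp_id[panel_b$snps$is_candidate]
  ))

  ids <- panel_a$snps$snp_id[panel_a$snps$snp_id %in% shared]
  low <- .call_rate(panel_a, ids) < call_threshold |
    .call_rate(panel_b, ids) < call_threshold
  removed_call <- ids[low]
  ids <- ids[!low]

  mono <- .mono_in_cohort(panel_a, ids) | .mono_in_cohort(panel_b, ids)
  removed_mono <- ids[mono]
  ids <- ids[!mono]

  sub_a <- .subset_panel(panel_a, ids)
  sub_b <- .subset_panel(panel_b, ids)
  pruned <- .ld_prune(ids, list(pairwise_r2(sub_a), pairwise_r2(sub_b)),
                      r2_threshold, .genome_rank(panel_a$snps), protected)

  new_filter_report(
    comparison_id, "pairwise", length(shared),
    list(call_rate = removed_call, monomorphic = removed_mono,
         ld = pruned$removed),
    pruned$retained
  )
}

.subset_panel <- function(panel, ids) {
  keep <- match(ids, panel$snps$snp_id)
  cohort_panel(panel$cohort_id, panel$snps[keep, , drop = FALSE],
               panel$dosages[, keep, drop = FALSE])
}

#' Three-way filtering cascade for the drift-model test
#'
#' Operates on the SNPs shared by the three role-labelled panels
#' (`G` = target, `C` = reference, `M` = third cohort). Unlike the pairwise
#' cascade, a SNP with call rate below `call_threshold` in one cohort is
#' *masked* (recorded as wholly missing for that cohort) rather than removed:
#' the drift model accepts SNPs observed in only one or two cohorts. SNPs
#' monomorphic across all three cohorts together (a single allele observed
#' anywhere) are removed, then LD pruning runs with r2 computed in each
#' cohort after masking.
#'
#' @param panels Named list of three [cohort_panel()] objects; names must be
#'   exactly `G`, `C`, `M` (any order).
#' @inheritParams filter_pairwise
#' @return A `filter_report` (mode `"threeway"`) whose `masked` field lists,
#'   per cohort, the retained-or-removed SNPs masked at the call-rate stage.
#' @export
filter_threeway <- function(panels, call_threshold = 0.9, r2_threshold = 0.8,
                            protect = character()) {
  if (!is.list(panels) || !setequal(names(panels), c("G", "C", "M")) ||
      length(panels) != 3L) {
    stop("panels must be a named list with roles exactly {G, C, M}")
  }
  panels <- panels[c("G", "C", "M")]
  lapply(panels, function(p) stopifnot(inherits(p, "cohort_panel")))
  shared <- Reduce(intersect, lapply(panels, function(p) p$snps$snp_id))
  if (length(shared) == 0L) stop("panels share no SNPs")
  ids <- panels$G$snps$snp_id[panels$G$snps$snp_id %in% shared]
  protected <- unique(c(
    protect, unlist(lapply(panels, function(p) p$snps$snp_id[p$snps$is_candidate]))
  ))

  # stage 1: per-cohort call-rate masking (no removal)
  masked <- lapply(panels, function(p) ids[.call_rate(p, ids) < call_threshold])
  panels_masked <- mapply(function(p, m) {
    if (length(m) > 0L) p$dosages[, m] <- NA_integer_
    p
  }, panels, masked, SIMPLIFY = FALSE)

  # stage 2: monomorphic across all three cohorts after masking
  pooled_x <- Reduce(`+`, lapply(panels_masked, function(p) {
    colSums(p$dosages[, ids, drop = FALSE], na.rm = TRUE)
  }))
  pooled_n <- Reduce(`+`, lapply(panels_masked, function(p) {
    2L * colSums(!is.na(p$dosages[, ids, drop = FALSE]))
  }))
  mono_all <- pooled_n == 0L | pooled_x == 0L | pooled_x == pooled_n
  removed_mono <- ids[mono_all]
  ids <- ids[!mono_all]

  # stage 3: LD pruning across all three cohorts
  r2s <- lapply(panels_masked, function(p) pairwise_r2(.subset_panel(p, ids)))
  pruned <- .ld_prune(ids, r2s, r2_threshold, .genome_rank(panels$G$snps),
                      protected)

  new_filter_report(
    paste(vapply(panels, function(p) p$cohort_id, character(1L)),
          collapse = "_"),
    "threeway", length(shared),
    list(call_rate = character(0L), monomorphic = removed_mono,
         ld = pruned$removed),
    pruned$retained,
    masked = masked
  )
}

#' Apply the three-way call-rate masking to the panels
#'
#' Sets every masked SNP (per `report$masked`) wholly missing in its cohort,
#' reproducing the genotype state the three-way cascade filtered on.
#'
#' @param panels Named list of panels as passed to [filter_threeway()].
#' @param report The `filter_report` from [filter_threeway()].
#' @return The list of panels with masked columns set to `NA`.
#' @export
apply_call_rate_mask <- function(panels, report) {
  stopifnot(inherits(report, "filter_report"), report$mode == "threeway")
  panels <- panels[c("G", "C", "M")]
  mapply(function(p, m) {
    m <- intersect(m, p$snps$snp_id)
    if (length(m) > 0L) p$dosages[, m] <- NA_integer_
    p
  }, panels, report$masked[c("G", "C", "M")], SIMPLIFY = FALSE)
}

#' SNPs usable for the drift-model empirical null
#'
#' From the retained SNPs of a three-way report, keeps those with nonzero
#' call data in every cohort after the call-rate masking step. Only these
#' fully observed SNPs enter the conditional tail probabilities and the
#' 3-subset enumeration (the rest still inform the drift fit).
#'
#' @param report `filter_report` from [filter_threeway()].
#' @param panels The same named panel list.
#' @return Character vector of SNP ids, in retained order.
#' @export
nonmissing_subset <- function(report, panels) {
  stopifnot(inherits(report, "filter_report"), report$mode == "threeway")
  panels_masked <- apply_call_rate_mask(panels, report)
  ids <- report$retained
  ok <- Reduce(`&`, lapply(panels_masked, function(p) {
    colSums(!is.na(p$dosages[, ids, drop = FALSE])) > 0L
  }))
  ids[ok]
}
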