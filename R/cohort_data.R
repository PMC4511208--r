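# Domain containers and per-cohort allele statistics.
#
# A cohort panel stores diploid genotypes for one cohort as a dosage matrix
# (individuals x SNPs) counting copies of allele_b at each SNP, with NA for
# missing calls, plus a SNP metadata table. All downstream statistics
# (minor-allele assignment, MAF, dosage variance, LD r^2) are derived from
# this container.

#' Construct a cohort genotype panel
#'
#' Bundles one cohort's diploid dosage matrix with its SNP metadata. Dosages
#' count copies of `allele_b` (0, 1, 2, or `NA` for a missing call); rows are
#' individuals, columns are SNPs in panel order.
#'
#' @param cohort_id Single string labelling the cohort (e.g. `"GAM"`).
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b` and optionally `is_candidate` (defaults to `FALSE`). `snp_id`
#'   must be unique, `allele_a != allele_b`, `pos >= 1`.
#' @param dosages Integer matrix, individuals x SNPs, values in
#'   `{0, 1, 2, NA}`. Column count must equal `nrow(snps)`.
#'
#' @return An object of class `cohort_panel` with fields `cohort_id`, `snps`,
#'   `dosages`, `n_individuals`.
#' @export
cohort_panel <- function(cohort_id, snps, dosages) {
  stopifnot(is.character(cohort_id), length(cohort_id) == 1L)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  missing_cols <- setdiff(req, names(snps))
  if (length(missing_cols) > 0L) {
    stop("snps table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!("is_candidate" %in% names(snps))) snps$is_candidate <- FALSE
  if (anyDuplicated(snps$snp_id)) {
    dup <- unique(snps$snp_id[duplicated(snps$snp_id)])
    stop("duplicate snp_id in panel: ", paste(dup, collapse = ", "))
  }
  if (any(snps$allele_a == snps$allele_b)) {
    stop("allele_a must differ from allele_b for every SNP")
  }
  if (any(snps$pos < 1L)) stop("pos must be >= 1 (1-based coordinates)")
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(snps)) {
    stop("dosage matrix has ", ncol(dosages), " columns but ", nrow(snps),
         " SNPs are declared")
  }
  if (nrow(dosages) < 1L) stop("panel needs at least one individual")
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) {
    idx <- which(bad)[1L]
    rc <- arrayInd(idx, dim(dosages))
    stop("invalid dosage value '", dosages[idx], "' at individual ", rc[1L],
         ", SNP ", snps$snp_id[rc[2L]], " (must be 0, 1, 2 or NA)")
  }
  storage.mode(dosages) <- "integer"
  colnames(dosages) <- snps$snp_id
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0(cohort_id, "_", seq_len(nrow(dosages)))
  }
  structure(
    list(cohort_id = cohort_id, snps = snps, dosages = dosages,
         n_individuals = nrow(dosages)),
    class = "cohort_panel"
  )
}

#' @export
print.cohort_panel <- function(x, ...) {
  cat("<cohort_panel> ", x$cohort_id, ": ", nrow(x$snps), " SNPs x ",
      x$n_individuals, " individuals\n", sep = "")
  ncand <- sum(x$snps$is_candidate)
  if (ncand > 0L) {
    cat("  candidate SNPs: ",
        paste(x$snps$snp_id[x$snps$is_candidate], collapse = ", "), "\n",
        sep = "")
  }
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing genotype rate: %.3f\n", miss))
  invisible(x)
}

#' Read a tabular genotype file
#'
#' Parses the TSV genotype interchange format: header
#' `snp_id chrom pos allele_a allele_b <ind1> <ind2> ...`, one row per SNP,
#' dosage tokens `0|1|2|NA`. Dosages count copies of `allele_b`.
#'
#' @param path Path to the TSV file.
#' @param cohort_id Cohort label for the returned panel.
#' @param candidate_ids Optional character vector of SNP ids to flag as the
#'   candidate set.
#' @return A [cohort_panel()].
#' @export
read_genotype_table <- function(path, cohort_id, candidate_ids = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  fixed <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  if (!identical(names(tab)[seq_along(fixed)], fixed)) {
    stop("malformed header: expected leading columns ",
         paste(fixed, collapse = " "))
  }
  ind_ids <- names(tab)[-seq_along(fixed)]
  if (length(ind_ids) == 0L) stop("no individual columns in ", path)
  dos_chr <- as.matrix(tab[, ind_ids, drop = FALSE])
  ok <- dos_chr %in% c("0", "1", "2", "NA") | is.na(dos_chr)
  if (!all(ok)) {
    idx <- which(!ok)[1L]
    rc <- arrayInd(idx, dim(dos_chr))
    stop("malformed dosage token '", dos_chr[idx], "' at row ", rc[1L],
         " (SNP ", tab$snp_id[rc[1L]], "), column ", ind_ids[rc[2L]])
  }
  dos <- matrix(suppressWarnings(as.integer(dos_chr)), nrow = nrow(dos_chr))
  dosages <- t(dos) # individuals x SNPs
  rownames(dosages) <- ind_ids
  snps <- data.frame(
    snp_id = tab$snp_id, chrom = tab$chrom, pos = as.integer(tab$pos),
    allele_a = tab$allele_a, allele_b = tab$allele_b,
    is_candidate = tab$snp_id %in% candidate_ids,
    stringsAsFactors = FALSE
  )
  cohort_panel(cohort_id, snps, dosages)
}

#' Write a panel to the tabular genotype format
#'
#' Inverse of [read_genotype_table()]: round-tripping reproduces dosages,
#' missingness and SNP metadata exactly (the candidate flag travels
#' separately).
#'
#' @param panel A [cohort_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(panel, path) {
  stopifnot(inherits(panel, "cohort_panel"))
  dos <- t(panel$dosages) # SNPs x individuals
  dos_chr <- matrix(as.character(dos), nrow = nrow(dos))
  dos_chr[is.na(dos_chr)] <- "NA"
  out <- cbind(panel$snps[, c("snp_id", "chrom", "pos", "allele_a", "allele_b")],
               as.data.frame(dos_chr, stringsAsFactors = FALSE))
  names(out) <- c("snp_id", "chrom", "pos", "allele_a", "allele_b",
                  rownames(panel$dosages))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort panel from VCF
#'
#' Reads a bi-allelic, diploid, GT-only VCF (4.2). REF maps to `allele_a`,
#' ALT to `allele_b`; the dosage counts ALT alleles. `./.` becomes `NA`.
#' Multi-allelic records are rejected rather than silently split.
#'
#' @inheritParams read_genotype_table
#' @return A [cohort_panel()].
#' @export
read_vcf <- function(path, cohort_id, candidate_ids = character()) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_vcf requires the VariantAnnotation package")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  if (any(n_alt != 1L)) {
    stop("multi-allelic record(s) not supported: ",
         paste(names(vcf)[n_alt != 1L], collapse = ", "))
  }
  geno <- VariantAnnotation::geno(vcf)
  if (!("GT" %in% names(geno))) stop("VCF has no GT field")
  gt <- geno$GT # SNPs x samples, strings like 0/1, 0|1, ./.
  gt_codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
                "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  known <- gt %in% names(gt_codes)
  miss <- gt %in% c("./.", ".|.", ".")
  if (any(!known & !miss)) {
    bad <- gt[!known & !miss][1L]
    stop("unsupported GT value '", bad, "' (diploid bi-allelic calls only)")
  }
  dos[known] <- gt_codes[gt[known]]
  rr <- SummarizedExperiment::rowRanges(vcf)
  snps <- data.frame(
    snp_id = names(vcf),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    allele_a = as.character(VariantAnnotation::ref(vcf)),
    allele_b = as.character(unlist(alt)),
    is_candidate = names(vcf) %in% candidate_ids,
    stringsAsFactors = FALSE
  )
  dosages <- t(dos)
  rownames(dosages) <- colnames(gt)
  cohort_panel(cohort_id, snps, dosages)
}

#' Write a cohort panel as VCF 4.2
#'
#' Emits a minimal GT-only, bi-allelic VCF readable by standard tooling
#' (`allele_a` as REF, `allele_b` as ALT, dosage = ALT count, `NA` as `./.`).
#' Heterozygotes are written unphased (`0/1`).
#'
#' @param panel A [cohort_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "cohort_panel"))
  gt_map <- c("0/0", "0/1", "1/1")
  dos <- t(panel$dosages) # SNPs x individuals
  gt <- matrix("./.", nrow = nrow(dos), ncol = ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_map[dos[ok] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=snpdrift",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(panel$dosages)), collapse = "\t")
  )
  body <- paste(panel$snps$chrom, panel$snps$pos, panel$snps$snp_id,
                panel$snps$allele_a, panel$snps$allele_b, ".", ".", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Assign minor alleles from a reference cohort
#'
#' The minor allele at each SNP is the less frequent allele in the reference
#' (EUR-role) cohort, computed over nonmissing haplotypes. Fixing the
#' definition in one cohort makes the minor allele comparable across cohorts:
#' in the reference every MAF is <= 0.5, elsewhere it may exceed 0.5. At an
#' exact 50/50 split the lexically smaller allele symbol is chosen and
#' flagged. At a monomorphic reference SNP the absent allele is the minor
#' allele (frequency 0).
#'
#' @param reference_panel The reference-cohort [cohort_panel()].
#' @return Data frame of class `minor_allele_map` with columns `snp_id`,
#'   `minor_allele`, `major_allele`, `tie_broken`.
#' @export
assign_minor_alleles <- function(reference_panel) {
  stopifnot(inherits(reference_panel, "cohort_panel"))
  dos <- reference_panel$dosages
  n_geno <- colSums(!is.na(dos))
  if (any(n_geno == 0L)) {
    stop("cannot define a minor allele at SNP(s) with zero nonmissing ",
         "genotypes in the reference cohort: ",
         paste(reference_panel$snps$snp_id[n_geno == 0L], collapse = ", "))
  }
  freq_b <- colSums(dos, na.rm = TRUE) / (2 * n_geno)
  a <- reference_panel$snps$allele_a
  b <- reference_panel$snps$allele_b
  tie <- abs(freq_b - 0.5) < .Machine$double.eps^0.5 &
    !(freq_b %in% c(0, 1))
  minor <- ifelse(freq_b < 0.5, b, a)
  minor[tie] <- pmin(a[tie], b[tie])
  major <- ifelse(minor == a, b, a)
  out <- data.frame(
    snp_id = reference_panel$snps$snp_id,
    minor_allele = minor, major_allele = major, tie_broken = tie,
    stringsAsFactors = FALSE
  )
  class(out) <- c("minor_allele_map", "data.frame")
  out
}

#' Per-SNP minor-allele statistics for one cohort
#'
#' Computes, for every SNP of `panel`, the minor-allele frequency `maf`
#' (`x_count / n_hap` over nonmissing haplotypes), the unbiased sample
#' variance `s2` of minor-allele dosage, the nonmissing genotype count
#' `n_geno`, the haplotype count `n_hap = 2 * n_geno` (diploid autosomes),
#' and the call rate. The minor allele comes from `minor_map`, so for a
#' non-reference cohort `maf` may exceed 0.5. SNPs with zero nonmissing
#' genotypes get `NA` frequency and variance.
#'
#' @param panel A [cohort_panel()].
#' @param minor_map A `minor_allele_map` from [assign_minor_alleles()]
#'   covering all SNPs of `panel`.
#' @return Data frame of class `maf_table` with columns `snp_id`, `cohort`,
#'   `minor_allele`, `major_allele`, `maf`, `s2`, `n_geno`, `x_count`,
#'   `n_hap`, `call_rate`.
#' @export
compute_maf <- function(panel, minor_map) {
  stopifnot(inherits(panel, "cohort_panel"))
  ids <- panel$snps$snp_id
  hit <- match(ids, minor_map$snp_id)
  if (anyNA(hit)) {
    stop("SNP(s) absent from minor allele map: ",
         paste(ids[is.na(hit)], collapse = ", "))
  }
  minor <- minor_map$minor_allele[hit]
  major <- minor_map$major_allele[hit]
  # internal dosage counts allele_b; flip where the minor allele is allele_a
  flip <- minor == panel$snps$allele_a
  dos <- panel$dosages
  dos[, flip] <- 2L - dos[, flip, drop = FALSE]
  n_geno <- colSums(!is.na(dos))
  x_count <- colSums(dos, na.rm = TRUE)
  n_hap <- 2L * n_geno
  maf <- ifelse(n_hap > 0L, x_count / n_hap, NA_real_)
  s2 <- apply(dos, 2L, function(col) stats::var(col[!is.na(col)]))
  out <- data.frame(
    snp_id = ids, cohort = panel$cohort_id,
    minor_allele = minor, major_allele = major,
    maf = maf, s2 = s2, n_geno = as.integer(n_geno),
    x_count = as.integer(x_count), n_hap = as.integer(n_hap),
    call_rate = n_geno / panel$n_individuals,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("maf_table", "data.frame")
  out
}

#' Write a MAF table to TSV
#'
#' @param maf A `maf_table` from [compute_maf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf_table <- function(maf, path) {
  cols <- c("snp_id", "cohort", "minor_allele", "maf", "s2", "n_geno",
            "call_rate")
  utils::write.table(maf[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pairwise LD (r-squared) within a cohort
#'
#' Composite (genotype-dosage) LD: the squared Pearson correlation of dosage
#' vectors over individuals nonmissing at both SNPs. Phase is not used, so
#' the measure is invariant to swapping minor/major labels at either SNP.
#' Pairs with fewer than two complete observations, or with a constant dosage
#' vector (monomorphic SNP), are undefined and returned as `NA`; downstream
#' LD pruning treats `NA` as r2 = 0.
#'
#' @param panel A [cohort_panel()] with at least 2 SNPs.
#' @return A symmetric SNP x SNP matrix of r2 values with `NA` where
#'   undefined; attribute `cohort_id` records the cohort.
#' @export
pairwise_r2 <- function(panel) {
  stopifnot(inherits(panel, "cohort_panel"))
  if (nrow(panel$snps) < 2L) stop("pairwise_r2 needs at least 2 SNPs")
  r <- suppressWarnings(
    stats::cor(panel$dosages, use = "pairwise.complete.obs")
  )
  r2 <- r * r
  attr(r2, "cohort_id") <- panel$cohort_id
  r2
}
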