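# Synthetic three-cohort genotype generation.
#
# The generator draws data from exactly the statistical world the drift
# model assumes: per SNP an ancestral frequency p_A (uniform on a truncated
# range), per cohort a present-day frequency p_X ~ Beta with mean p_A and
# variance d_X p_A (1 - p_A), then diploid genotypes binomial(2, p_X) per
# individual, with uniform missingness per cohort. Selection is emulated as
# an absolute downward shift of p_X at designated (SNP, cohort) pairs; LD is
# emulated by copying a block-seed SNP's genotypes and resampling a fraction
# of entries. Every stage draws from its own derived seed so adding stages
# never perturbs earlier draws.

# Derive a per-stage seed from the global seed; kept below 2^31.
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 7919 + h * 104729) %% 2147483647
}

.with_stage_seed <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.stage_seed(seed, stage))
  force(code)
}

#' Configuration for the three-cohort simulator
#'
#' Defaults emulate the study design the analysis targets: 214 SNPs over
#' cohorts of 241 (G role), 159 (C role) and 95 (M role) individuals, modest
#' genotype missingness, ancestral frequencies uniform on \[0.05, 0.95\]
#' (truncated so background SNPs rarely saturate at 0/1), and per-cohort
#' drift with the C-role (reference) cohort most diverged from the common
#' ancestor.
#'
#' @param n_snps Number of SNPs (default 214).
#' @param n_individuals Integer triple `(G, C, M)` (default 241, 159, 95).
#' @param drift Drift triple in \[0, 1) (default `c(0.02, 0.06, 0.02)`).
#' @param p_a_range Truncation range for the uniform ancestral frequency.
#' @param missing_rate Per-cohort missing-call probability (scalar or
#'   triple; default 0.02).
#' @param ld_blocks List of `list(size =, r2 =)` block specs; each block
#'   turns `size - 1` SNPs into near-copies of a block seed SNP targeting
#'   within-block r2 (requires `r2 <= 1`).
#' @param selection Data frame `snp_id`, `cohort` (one of `"G","C","M"`),
#'   `reduction` (absolute downward shift of the cohort frequency); or NULL.
#' @param candidate_ids Ids (among `snp1..snpN` or custom) flagged as the
#'   candidate set; default none.
#' @param seed Global integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 214L,
                       n_individuals = c(G = 241L, C = 159L, M = 95L),
                       drift = c(G = 0.02, C = 0.06, M = 0.02),
                       p_a_range = c(0.05, 0.95),
                       missing_rate = 0.02,
                       ld_blocks = list(),
                       selection = NULL,
                       candidate_ids = character(),
                       seed = 1L) {
  stopifnot(n_snps >= 1L, length(n_individuals) == 3L,
            all(n_individuals >= 1L), length(drift) == 3L,
            all(drift >= 0 & drift < 1),
            length(p_a_range) == 2L, p_a_range[1L] > 0, p_a_range[2L] < 1)
  missing_rate <- rep_len(missing_rate, 3L)
  stopifnot(all(missing_rate >= 0 & missing_rate <= 1))
  for (blk in ld_blocks) {
    if (blk$r2 > 1) stop("infeasible LD target r2 > 1")
  }
  names(n_individuals) <- names(drift) <- c("G", "C", "M")
  names(missing_rate) <- c("G", "C", "M")
  structure(
    list(n_snps = as.integer(n_snps), n_individuals = n_individuals,
         drift = drift, p_a_range = p_a_range, missing_rate = missing_rate,
         ld_blocks = ld_blocks, selection = selection,
         candidate_ids = candidate_ids, seed = seed),
    class = "sim_config"
  )
}

.default_snp_meta <- function(n_snps, candidate_ids) {
  ids <- sprintf("snp%04d", seq_len(n_snps))
  if (length(candidate_ids) > 0L) {
    # candidates occupy evenly spaced positions and keep their given names
    pos <- round(seq(1L, n_snps, length.out = length(candidate_ids) + 2L))
    pos <- pos[-c(1L, length(pos))]
    ids[pos] <- candidate_ids
  }
  data.frame(
    snp_id = ids,
    chrom = paste0("chr", 1L + (seq_len(n_snps) - 1L) %% 22L),
    pos = 1000L * (1L + (seq_len(n_snps) - 1L) %/% 22L),
    allele_a = "A", allele_b = "G",
    is_candidate = ids %in% candidate_ids,
    stringsAsFactors = FALSE
  )
}

#' Simulate three cohort panels under the drift model
#'
#' See the package overview for the generative model. Fully reproducible
#' from `config$seed`; each stage (ancestral frequencies, cohort
#' frequencies, selection, genotypes, LD blocks, missingness) draws from its
#' own derived seed. The returned list carries the simulated truth
#' (`p_a` and per-cohort `p_X`) in attribute `"truth"`.
#'
#' @param config A [sim_config()].
#' @return Named list of three [cohort_panel()] objects (`G`, `C`, `M`).
#' @export
simulate_three_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_snps
  meta <- .default_snp_meta(n, config$candidate_ids)

  p_a <- .with_stage_seed(config$seed, "ancestral", {
    stats::runif(n, config$p_a_range[1L], config$p_a_range[2L])
  })

  p_x <- matrix(NA_real_, n, 3L, dimnames = list(meta$snp_id, c("G", "C", "M")))
  for (role in c("G", "C", "M")) {
    d <- config$drift[[role]]
    p_x[, role] <- .with_stage_seed(config$seed, paste0("cohort_freq_", role), {
      if (d == 0) p_a else {
        stats::rbeta(n, p_a * (1 - d) / d, (1 - p_a) * (1 - d) / d)
      }
    })
  }

  if (!is.null(config$selection) && nrow(config$selection) > 0L) {
    sel <- config$selection
    for (i in seq_len(nrow(sel))) {
      row <- match(sel$snp_id[i], meta$snp_id)
      if (is.na(row)) stop("selection targets unknown SNP ", sel$snp_id[i])
      newp <- p_x[row, sel$cohort[i]] - sel$reduction[i]
      if (newp < 0) {
        warning("selection shift clipped at 0 for ", sel$snp_id[i])
        newp <- 0
      }
      p_x[row, sel$cohort[i]] <- newp
    }
  }

  override <- attr(config, "p_override")
  if (!is.null(override)) {
    ok <- !is.na(override)
    p_x[ok] <- override[ok]
  }

  panels <- list()
  for (role in c("G", "C", "M")) {
    ni <- config$n_individuals[[role]]
    dos <- .with_stage_seed(config$seed, paste0("genotypes_", role), {
      matrix(stats::rbinom(ni * n, 2L, rep(p_x[, role], each = ni)), ni, n)
    })
    panels[[role]] <- dos
  }

  # LD blocks: consecutive SNPs become near-copies of the block's first SNP
  if (length(config$ld_blocks) > 0L) {
    start <- 1L
    for (bi in seq_along(config$ld_blocks)) {
      blk <- config$ld_blocks[[bi]]
      members <- seq.int(start, length.out = blk$size)
      if (max(members) > n) stop("LD block extends past the SNP panel")
      f <- 1 - sqrt(blk$r2) # resample fraction: cor of copy ~ 1 - f
      for (role in c("G", "C", "M")) {
        ni <- config$n_individuals[[role]]
        panels[[role]][, members[-1L]] <-
          .with_stage_seed(config$seed, paste0("ld_", bi, "_", role), {
            sapply(members[-1L], function(mcol) {
              col <- panels[[role]][, members[1L]]
              swap <- stats::runif(ni) < f
              col[swap] <- stats::rbinom(sum(swap), 2L, p_x[members[1L], role])
              col
            })
          })
      }
      start <- start + blk$size
    }
  }

  for (role in c("G", "C", "M")) {
    rate <- config$missing_rate[[role]]
    if (rate > 0) {
      ni <- config$n_individuals[[role]]
      panels[[role]] <- .with_stage_seed(config$seed, paste0("missing_", role), {
        mask <- matrix(stats::runif(ni * n) < rate, ni, n)
        dos <- panels[[role]]
        dos[mask] <- NA_integer_
        dos
      })
    }
  }

  out <- lapply(c("G", "C", "M"), function(role) {
    cohort_panel(role, meta, panels[[role]])
  })
  names(out) <- c("G", "C", "M")
  attr(out, "truth") <- list(p_a = p_a, p_x = p_x)
  out
}

#' Engineer a fixture that exercises a filtering cascade exactly
#'
#' Builds a clean background simulation, then plants SNPs that each fail
#' exactly one filtering stage: low-call-rate SNPs (call rate forced to 0.85
#' in one cohort), monomorphic SNPs (dosage forced to 0 in the relevant
#' cohort(s)), and LD-removable SNPs (near-copies of distinct background
#' seeds, placed immediately after them so the copy is the deterministic LD
#' victim). Background SNPs are post-corrected so they cannot trip any stage
#' by chance (call rate floored at the threshold, monomorphism broken by a
#' single heterozygote). The manifest records which SNP plays which role.
#'
#' For `mode = "threeway"` the call-rate count plants SNPs that the cascade
#' *masks* in one cohort (rotating G, C, M) rather than removes, and
#' monomorphic SNPs are monomorphic in all three cohorts.
#'
#' @param target_counts Integer triple `(call_rate, monomorphic, ld)`:
#'   SNPs to plant per stage.
#' @param n_snps Total SNP count of the fixture.
#' @param mode `"pairwise"` (two panels, roles G and C) or `"threeway"`.
#' @param base_config A [sim_config()]; its `n_snps` is overridden.
#' @return List with `panels` (list of 2 or 3 [cohort_panel()]s), `manifest`
#'   (role id lists) and `config`.
#' @export
make_filter_fixture <- function(target_counts, n_snps = 214L,
                                mode = c("pairwise", "threeway"),
                                base_config = sim_config(seed = 20260909L)) {
  mode <- match.arg(mode)
  stopifnot(length(target_counts) == 3L, all(target_counts >= 0L))
  k_call <- target_counts[[1L]]
  k_mono <- target_counts[[2L]]
  k_ld <- target_counts[[3L]]
  if (3L + k_call + k_mono + 2L * k_ld > n_snps) {
    stop("target counts exceed the SNP panel (each LD-removable SNP also ",
         "needs a distinct seed SNP)")
  }
  cand <- c("cand1", "cand2", "cand3")
  cfg <- base_config
  cfg$n_snps <- as.integer(n_snps)
  cfg$candidate_ids <- cand
  cfg$ld_blocks <- list()
  cfg$selection <- NULL
  sims <- simulate_three_cohorts(cfg)
  roles_used <- if (mode == "pairwise") c("G", "C") else c("G", "C", "M")
  panels <- sims[roles_used]
  truth <- attr(sims, "truth")
  meta <- panels[[1L]]$snps
  thr <- 0.9

  avail <- which(!meta$is_candidate)
  take <- function(k) {
    got <- avail[seq_len(k)]
    avail <<- avail[-seq_len(k)]
    got
  }
  idx_call <- if (k_call > 0L) take(k_call) else integer(0L)
  idx_mono <- if (k_mono > 0L) take(k_mono) else integer(0L)
  # LD pairs: consecutive (seed, copy) so the copy follows in genome order
  idx_pairs <- matrix(if (k_ld > 0L) take(2L * k_ld) else integer(0L),
                      ncol = 2L, byrow = TRUE)
  background <- setdiff(seq_len(n_snps),
                        c(idx_call, idx_mono,
                          if (k_ld > 0L) idx_pairs[, 2L] else integer(0L)))

  # low call rate: 15% missing in one cohort (rotating); < 90% threshold
  for (t in seq_along(idx_call)) {
    role <- roles_used[1L + (t - 1L) %% length(roles_used)]
    ni <- nrow(panels[[role]]$dosages)
    n_miss <- ceiling(0.15 * ni)
    panels[[role]]$dosages[seq_len(n_miss), idx_call[t]] <- NA_integer_
  }

  # monomorphic: dosage 0 everywhere in one cohort (pairwise, rotating) or
  # in all cohorts (threeway)
  for (t in seq_along(idx_mono)) {
    tgt <- if (mode == "threeway") roles_used else
      roles_used[1L + (t - 1L) %% length(roles_used)]
    for (role in tgt) panels[[role]]$dosages[, idx_mono[t]] <- 0L
  }

  # LD-removable: copy the seed column, resample 2% of entries
  if (k_ld > 0L) {
    for (t in seq_len(k_ld)) {
      seed_i <- idx_pairs[t, 1L]
      copy_i <- idx_pairs[t, 2L]
      meta_pos <- meta$pos
      for (role in roles_used) {
        col <- panels[[role]]$dosages[, seed_i]
        ni <- length(col)
        swap <- .with_stage_seed(cfg$seed, paste0("fixld_", t, "_", role), {
          which(stats::runif(ni) < 0.02)
        })
        # nudge by one dosage unit so skewed columns keep r2 near 1
        col[swap] <- ifelse(is.na(col[swap]), NA_integer_,
                            col[swap] + ifelse(col[swap] == 0L, 1L, -1L))
        panels[[role]]$dosages[, copy_i] <- col
      }
      # give the copy the seed's locus so it sits next to it in genome order
      sm <- panels[[1L]]$snps
      for (role in roles_used) {
        panels[[role]]$snps$chrom[copy_i] <- sm$chrom[seed_i]
        panels[[role]]$snps$pos[copy_i] <- sm$pos[seed_i] + 1L
      }
    }
  }

  # background hygiene so no unplanned SNP trips a stage by chance: every
  # column except the planted low-call SNPs keeps call rate >= thr, and
  # every column except the planted monomorphic SNPs keeps a minor-allele
  # count of at least 3. The floor matters for exactness: two
  # near-monomorphic columns whose few carriers coincide would form an
  # accidental r2 >= 0.8 pair, so repaired heterozygotes are injected at
  # column-dependent individuals and columns are lifted clear of the
  # one-carrier regime altogether.
  for (role in roles_used) {
    dos <- panels[[role]]$dosages
    ni <- nrow(dos)
    for (cl in seq_len(n_snps)) {
      col <- dos[, cl]
      if (!(cl %in% idx_call)) {
        nm <- sum(is.na(col))
        if (nm / ni > 1 - thr) {
          refill <- which(is.na(col))[seq_len(nm - floor((1 - thr) * ni))]
          col[refill] <- 1L
        }
      }
      if (!(cl %in% idx_mono)) {
        if (all(is.na(col))) col[1L] <- 1L
        repeat {
          obs <- !is.na(col)
          x <- sum(col[obs])
          nh <- 2L * sum(obs)
          minor_is_b <- x <= nh - x
          mc <- if (minor_is_b) x else nh - x
          if (mc >= 3L) break
          from <- if (minor_is_b) 0L else 2L
          pool <- which(obs & col == from)
          if (length(pool) == 0L) break
          col[pool[1L + (cl * 7L) %% length(pool)]] <- 1L
        }
      }
      dos[, cl] <- col
    }
    panels[[role]]$dosages <- dos
  }

  # guard: a planted pair must actually exceed the pruning threshold in at
  # least one cohort; low-variance columns can dilute the copy's r2, in
  # which case fall back to an exact copy (r2 = 1)
  if (k_ld > 0L) {
    for (t in seq_len(k_ld)) {
      seed_i <- idx_pairs[t, 1L]
      copy_i <- idx_pairs[t, 2L]
      r2max <- max(vapply(roles_used, function(role) {
        suppressWarnings(stats::cor(
          panels[[role]]$dosages[, seed_i], panels[[role]]$dosages[, copy_i],
          use = "pairwise.complete.obs"
        ))^2
      }, numeric(1L)), na.rm = TRUE)
      if (!is.finite(r2max) || r2max < 0.85) {
        for (role in roles_used) {
          panels[[role]]$dosages[, copy_i] <- panels[[role]]$dosages[, seed_i]
        }
      }
    }
  }

  manifest <- list(
    candidates = meta$snp_id[meta$is_candidate],
    call_rate = meta$snp_id[idx_call],
    monomorphic = meta$snp_id[idx_mono],
    ld_removed = if (k_ld > 0L) meta$snp_id[idx_pairs[, 2L]] else character(0L),
    ld_seeds = if (k_ld > 0L) meta$snp_id[idx_pairs[, 1L]] else character(0L)
  )
  list(panels = panels, manifest = manifest, config = cfg)
}

#' Scenario emulating the published candidate-SNP frequencies
#'
#' Simulates a 214-SNP, three-cohort panel whose three candidate SNPs have
#' expected minor-allele frequencies matching the published worked example
#' (G role 0.09/0.18/0.12, M role 0.23/0.40/0.15, C role 0.29/0.46/0.43)
#' while background SNPs follow the common-drift null. Default sample sizes
#' give 482/318/190 haplotypes. Used for end-to-end power demonstrations.
#'
#' @param seed Integer seed.
#' @param n_snps Panel size (default 214).
#' @param n_individuals Cohort sizes (default 241, 159, 95).
#' @return List with `panels` (named list `G`, `C`, `M`), `candidates`
#'   (character ids) and `targets` (the frequency matrix aimed for).
#' @export
make_paper_like_scenario <- function(seed = 1L, n_snps = 214L,
                                     n_individuals = c(G = 241L, C = 159L,
                                                       M = 95L)) {
  cand <- c("rs12676", "rs2236225", "rs12325817")
  targets <- matrix(
    c(0.09, 0.18, 0.12,  # G role
      0.29, 0.46, 0.43,  # C role (reference; all <= 0.5)
      0.23, 0.40, 0.15), # M role
    nrow = 3L, dimnames = list(cand, c("G", "C", "M"))
  )
  cfg <- sim_config(n_snps = n_snps, n_individuals = n_individuals,
                    candidate_ids = cand, seed = seed)
  meta <- .default_snp_meta(n_snps, cand)
  override <- matrix(NA_real_, n_snps, 3L,
                     dimnames = list(meta$snp_id, c("G", "C", "M")))
  override[cand, ] <- targets
  attr(cfg, "p_override") <- override
  panels <- simulate_three_cohorts(cfg)
  list(panels = panels[c("G", "C", "M")], candidates = cand,
       targets = targets)
}
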