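# Beta-binomial population-drift model.
#
# The three cohorts (roles G, C, M) descend from a common ancestral
# population. At each SNP the ancestral minor-allele frequency p_A is
# unknown (uniform prior, integrated out numerically); each cohort's
# present-day frequency p_X is beta-distributed with mean p_A and variance
# d_X * p_A * (1 - p_A) (the Balding-Nichols parameterization, so
# alpha = p_A (1 - d)/d, beta = (1 - p_A)(1 - d)/d), and the sampled minor
# allele count X is binomial(n_X, p_X). Integrating p_X analytically gives a
# beta-binomial for X | p_A, d_X. The per-SNP joint likelihood is
#
#   Pr(x_G, x_C, x_M | d) = int_0^1 prod_X Pr(x_X | p_A, d_X) dp_A,
#
# maximized over a 3-D grid to estimate the drift triple, after which the
# evidence for frequency reduction in the target cohort at each SNP is the
# conditional tail probability
#
#   q = Pr(X_G <= x_G | x_C, x_M, d-hat)
#     = int Pr(X_G <= x_G) Pr(x_C) Pr(x_M) dp_A / int Pr(x_C) Pr(x_M) dp_A.
#
# All products run in log space with per-SNP rescaling; the uniform prior is
# integrated by fixed Gauss-Legendre quadrature on (0, 1).

#' Gauss-Legendre quadrature on (0, 1)
#'
#' Nodes and weights by the Golub-Welsch eigendecomposition of the Jacobi
#' matrix, mapped from \[-1, 1\] to \[0, 1\]. All nodes are interior, which the
#' beta-binomial integrand requires (it is singular at p = 0, 1 for small d).
#'
#' @param n Number of nodes (>= 1).
#' @return List with numeric vectors `nodes` and `weights` (weights sum to 1).
#' @export
gauss_legendre_01 <- function(n) {
  stopifnot(n >= 1L)
  if (n == 1L) return(list(nodes = 0.5, weights = 1))
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  x <- e$values[ord]
  w <- 2 * e$vectors[1L, ord]^2
  list(nodes = (x + 1) / 2, weights = w / 2)
}

#' Quadrature settings for integrating out the ancestral frequency
#'
#' @param n_nodes Initial Gauss-Legendre node count (default 256; must be
#'   >= 64 for the adaptive routines).
#' @param tol Relative-change tolerance for adaptive node doubling.
#' @param max_doublings Maximum number of doublings.
#' @return A `quadrature_spec` list.
#' @export
quadrature_spec <- function(n_nodes = 256L, tol = 1e-8, max_doublings = 3L) {
  stopifnot(n_nodes >= 64L, tol > 0, max_doublings >= 0L)
  structure(list(n_nodes = as.integer(n_nodes), tol = tol,
                 max_doublings = as.integer(max_doublings)),
            class = "quadrature_spec")
}

#' Beta-binomial log probability mass
#'
#' `Pr(X = x | n, p_a, d)` for the Balding-Nichols drift model: the
#' population frequency is beta with mean `p_a` and variance
#' `d p_a (1 - p_a)`, the count binomial given that frequency. Computed via
#' log-gamma for numerical stability. `d = 0` returns the binomial limit.
#' Vectorized over all arguments.
#'
#' @param x Minor-allele count(s), `0 <= x <= n`.
#' @param n Haplotype count(s).
#' @param p_a Ancestral frequency in (0, 1).
#' @param d Drift in \[0, 1).
#' @return Log probability, same length as the recycled arguments.
#' @export
betabinom_logpmf <- function(x, n, p_a, d) {
  if (any(p_a <= 0 | p_a >= 1)) stop("p_a must lie strictly inside (0, 1)")
  if (any(d < 0 | d >= 1)) stop("d must lie in [0, 1)")
  if (any(x < 0 | x > n)) stop("x must satisfy 0 <= x <= n")
  m <- max(length(x), length(n), length(p_a), length(d))
  x <- rep_len(x, m); n <- rep_len(n, m)
  p_a <- rep_len(p_a, m); d <- rep_len(d, m)
  out <- numeric(m)
  z <- d == 0
  if (any(z)) out[z] <- stats::dbinom(x[z], n[z], p_a[z], log = TRUE)
  if (any(!z)) {
    a <- p_a[!z] * (1 - d[!z]) / d[!z]
    b <- (1 - p_a[!z]) * (1 - d[!z]) / d[!z]
    out[!z] <- lchoose(n[!z], x[!z]) +
      lbeta(x[!z] + a, n[!z] - x[!z] + b) - lbeta(a, b)
  }
  out
}

.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# One evaluation of the per-SNP joint likelihood at fixed drift values and a
# fixed node count. counts_row: list/1-row df with x_g, n_g, x_c, n_c, x_m,
# n_m (NA pair = cohort missing at this SNP; its factor is dropped).
.joint_lik_fixed <- function(counts_row, d, gl) {
  lp <- rep(0, length(gl$nodes))
  used <- 0L
  for (role in c("g", "c", "m")) {
    x <- counts_row[[paste0("x_", role)]]
    n <- counts_row[[paste0("n_", role)]]
    if (is.na(x) || is.na(n)) next
    lp <- lp + betabinom_logpmf(x, n, gl$nodes, d[[role]])
    used <- used + 1L
  }
  if (used == 0L) stop("SNP has no observed cohort")
  m <- max(lp)
  if (!is.finite(m)) stop("non-finite integrand (all quadrature nodes ",
                          "underflowed); counts: ",
                          paste(unlist(counts_row), collapse = ","))
  exp(m) * sum(gl$weights * exp(lp - m))
}

#' Joint likelihood of one SNP's counts under the drift model
#'
#' Integrates the product of per-cohort beta-binomial terms over a uniform
#' ancestral frequency by Gauss-Legendre quadrature, doubling the node count
#' until the relative change drops below `quadrature$tol` (or the doubling
#' budget is spent). Cohorts with `NA` counts drop out of the product, so
#' partially observed SNPs still contribute.
#'
#' @param counts_row One row of a SNP-counts table: fields `x_g`, `n_g`,
#'   `x_c`, `n_c`, `x_m`, `n_m`.
#' @param d_g,d_c,d_m Drift values in \[0, 1).
#' @param quadrature A [quadrature_spec()].
#' @return The likelihood, a probability in (0, 1\].
#' @export
snp_joint_likelihood <- function(counts_row, d_g, d_c, d_m,
                                 quadrature = quadrature_spec()) {
  d <- list(g = d_g, c = d_c, m = d_m)
  nn <- quadrature$n_nodes
  val <- .joint_lik_fixed(counts_row, d, gauss_legendre_01(nn))
  for (i in seq_len(quadrature$max_doublings)) {
    nn <- 2L * nn
    val2 <- .joint_lik_fixed(counts_row, d, gauss_legendre_01(nn))
    done <- abs(val2 - val) <= quadrature$tol * max(abs(val2), 1e-300)
    val <- val2
    if (done) break
  }
  val
}

#' Extract per-SNP minor-allele counts for the drift model
#'
#' Builds the SNP-counts table (x = minor-allele count, n = nonmissing
#' haplotype count per cohort) from per-cohort `maf_table`s sharing a SNP
#' set. A cohort with zero nonmissing haplotypes at a SNP is recorded `NA`
#' (missing for that cohort).
#'
#' @param maf_g,maf_c,maf_m `maf_table`s from [compute_maf()] (roles:
#'   G = target, C = reference, M = third cohort).
#' @param snp_ids Optional subset/ordering of SNP ids.
#' @return Data frame of class `snp_counts`: `snp_id`, `x_g`, `n_g`, `x_c`,
#'   `n_c`, `x_m`, `n_m`.
#' @export
snp_counts <- function(maf_g, maf_c, maf_m, snp_ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- maf_g$snp_id
  pick <- function(maf, role) {
    hit <- match(snp_ids, maf$snp_id)
    if (anyNA(hit)) {
      stop("SNP(s) missing from ", role, " MAF table: ",
           paste(snp_ids[is.na(hit)], collapse = ", "))
    }
    x <- maf$x_count[hit]
    n <- maf$n_hap[hit]
    x[n == 0L] <- NA_integer_
    n[n == 0L] <- NA_integer_
    list(x = x, n = n)
  }
  g <- pick(maf_g, "G"); c_ <- pick(maf_c, "C"); m <- pick(maf_m, "M")
  out <- data.frame(snp_id = snp_ids,
                    x_g = g$x, n_g = g$n, x_c = c_$x, n_c = c_$n,
                    x_m = m$x, n_m = m$n, stringsAsFactors = FALSE)
  class(out) <- c("snp_counts", "data.frame")
  out
}

#' Geometric drift grid
#'
#' @param n Points per axis (default 40).
#' @param lower,upper Grid range (default `[1e-4, 0.5]`).
#' @return Increasing numeric vector of drift values.
#' @export
drift_grid <- function(n = 40L, lower = 1e-4, upper = 0.5) {
  stopifnot(n >= 2L, lower > 0, upper < 1, lower < upper)
  exp(seq(log(lower), log(upper), length.out = n))
}

# Per-cohort shifted pmf factors for one SNP over (drift grid x quadrature
# nodes). Returns exp(logpmf - shift) as an nd x nt matrix plus the shift;
# a missing cohort yields the all-ones matrix with shift 0 (factor dropped).
.snp_factor <- function(x, n, dvals, gl) {
  nd <- length(dvals); nt <- length(gl$nodes)
  if (is.na(x) || is.na(n)) {
    return(list(mat = matrix(1, nd, nt), shift = 0))
  }
  lp <- betabinom_logpmf(x, n,
                         rep(gl$nodes, each = nd),
                         rep.int(dvals, nt))
  lp <- matrix(lp, nd, nt)
  s <- max(lp)
  list(mat = exp(lp - s), shift = s)
}

# Log-likelihood surface over the Cartesian grid (dg x dc x dm), summed over
# SNPs. The contraction per SNP is a single matrix product:
#   T[a, (b,c)] = sum_t G[a, t] * (C[b, t] * M[c, t] * w[t]).
.grid_loglik <- function(counts, dg, dc, dm, gl) {
  ndg <- length(dg); ndc <- length(dc); ndm <- length(dm)
  nt <- length(gl$nodes)
  bidx <- rep.int(seq_len(ndc), ndm)        # C index for each (b,c) pair
  cidx <- rep(seq_len(ndm), each = ndc)     # M index for each (b,c) pair
  wmat <- matrix(gl$weights, ndc * ndm, nt, byrow = TRUE)
  acc <- matrix(0, ndg, ndc * ndm)
  shift_total <- 0
  for (s in seq_len(nrow(counts))) {
    fg <- .snp_factor(counts$x_g[s], counts$n_g[s], dg, gl)
    fc <- .snp_factor(counts$x_c[s], counts$n_c[s], dc, gl)
    fm <- .snp_factor(counts$x_m[s], counts$n_m[s], dm, gl)
    E <- fc$mat[bidx, , drop = FALSE] * fm$mat[cidx, , drop = FALSE] * wmat
    lik <- tcrossprod(fg$mat, E) # ndg x (ndc*ndm)
    acc <- acc + log(lik)
    shift_total <- shift_total + fg$shift + fc$shift + fm$shift
  }
  array(acc + shift_total, dim = c(ndg, ndc, ndm))
}

#' Grid maximum-likelihood estimation of the drift triple
#'
#' Maximizes the summed log joint likelihood of all SNPs over a Cartesian
#' 3-D grid of `(d_G, d_C, d_M)` (default: 40 geometric points per axis on
#' `[1e-4, 0.5]`), then optionally refines once with a finer local geometric
#' grid spanning the neighboring grid cells of the argmax. SNPs missing a
#' cohort contribute a two-factor (or one-factor) likelihood term.
#' Deterministic.
#'
#' @param counts A `snp_counts` table (>= 10 SNPs recommended).
#' @param grid Numeric vector of grid values per axis (see [drift_grid()]).
#' @param quadrature A [quadrature_spec()]; the fit uses the fixed initial
#'   node count (no adaptive doubling across the grid).
#' @param refine Run one local refinement pass (default `TRUE`)?
#' @param keep_surface Store the coarse log-likelihood surface?
#' @return A `drift_estimate`: `d_g`, `d_c`, `d_m`, `loglik_max`,
#'   `grid_spec`, `boundary` (TRUE if the coarse argmax sat on the grid
#'   edge, also signalled as a warning), optionally `loglik_surface`.
#' @export
fit_drift_mle <- function(counts, grid = drift_grid(),
                          quadrature = quadrature_spec(), refine = TRUE,
                          keep_surface = FALSE) {
  stopifnot(inherits(counts, "data.frame"), nrow(counts) >= 1L)
  obs <- function(x, n) !is.na(x) & !is.na(n)
  any_g <- any(obs(counts$x_g, counts$n_g))
  any_c <- any(obs(counts$x_c, counts$n_c))
  any_m <- any(obs(counts$x_m, counts$n_m))
  if (!any_g || !any_c || !any_m) {
    stop("a cohort has no observed SNPs; cannot estimate its drift")
  }
  gl <- gauss_legendre_01(quadrature$n_nodes)
  surf <- .grid_loglik(counts, grid, grid, grid, gl)
  am <- arrayInd(which.max(surf), dim(surf))
  idx <- as.integer(am[1L, ])
  nd <- length(grid)
  boundary <- any(idx == 1L | idx == nd)
  if (boundary) {
    warning("drift MLE lies on the grid boundary; widen the grid")
  }
  d_hat <- grid[idx]
  loglik <- surf[am]

  if (refine && !boundary) {
    local_axis <- function(i) {
      exp(seq(log(grid[i - 1L]), log(grid[i + 1L]), length.out = 9L))
    }
    ax <- lapply(idx, local_axis)
    surf2 <- .grid_loglik(counts, ax[[1L]], ax[[2L]], ax[[3L]], gl)
    am2 <- arrayInd(which.max(surf2), dim(surf2))
    if (surf2[am2] >= loglik) {
      d_hat <- c(ax[[1L]][am2[1L]], ax[[2L]][am2[2L]], ax[[3L]][am2[3L]])
      loglik <- surf2[am2]
    }
  }

  structure(
    list(d_g = d_hat[1L], d_c = d_hat[2L], d_m = d_hat[3L],
         loglik_max = loglik, grid_spec = grid, boundary = boundary,
         loglik_surface = if (keep_surface) surf else NULL,
         n_snps = nrow(counts)),
    class = "drift_estimate"
  )
}

#' @export
print.drift_estimate <- function(x, ...) {
  cat("<drift_estimate> fitted on", x$n_snps, "SNPs\n")
  cat(sprintf("  d_G = %.5g  d_C = %.5g  d_M = %.5g\n", x$d_g, x$d_c, x$d_m))
  cat(sprintf("  log-likelihood: %.4f%s\n", x$loglik_max,
              if (isTRUE(x$boundary)) "  [argmax on grid boundary]" else ""))
  invisible(x)
}

# Conditional tail probability for one SNP. target/cond roles are one-letter
# codes in {g, c, m}.
.tail_prob_one <- function(counts_row, d, target, gl) {
  roles <- c("g", "c", "m")
  cond <- setdiff(roles, target)
  get <- function(role, what) counts_row[[paste0(what, "_", role)]]
  for (role in roles) {
    if (is.na(get(role, "x")) || is.na(get(role, "n"))) {
      stop("SNP has missing counts in cohort ", toupper(role),
           "; tail probabilities need all three cohorts")
    }
  }
  lcond <- rep(0, length(gl$nodes))
  for (role in cond) {
    lcond <- lcond + betabinom_logpmf(get(role, "x"), get(role, "n"),
                                      gl$nodes, d[[role]])
  }
  xt <- get(target, "x"); nt_hap <- get(target, "n")
  # log CDF of the target count at each node
  lpmf <- betabinom_logpmf(rep(0:xt, times = length(gl$nodes)),
                           nt_hap,
                           rep(gl$nodes, each = xt + 1L),
                           d[[target]])
  lpmf <- matrix(lpmf, nrow = xt + 1L)
  cmax <- apply(lpmf, 2L, max)
  cdf <- exp(cmax) * colSums(exp(sweep(lpmf, 2L, cmax)))
  cdf <- pmin(cdf, 1) # guard against roundoff just above 1
  s <- max(lcond)
  base <- gl$weights * exp(lcond - s)
  den <- sum(base)
  if (den == 0) stop("conditional denominator underflowed")
  num <- sum(base * cdf)
  min(1, num / den)
}

#' Conditional tail probability for the target cohort at one SNP
#'
#' `q = Pr(X_G <= x_g | x_c, x_m, d-hat)`: the probability, under the fitted
#' neutral drift model and conditional on the counts sampled in the two
#' other cohorts, of a target-cohort minor-allele count no larger than the
#' one observed. Small q at a SNP means the target frequency is lower than
#' neutral drift predicts.
#'
#' @param counts_row One row of a `snp_counts` table (all cohorts observed).
#' @param drift A `drift_estimate` from [fit_drift_mle()].
#' @param quadrature A [quadrature_spec()].
#' @return Scalar q in \[0, 1\].
#' @export
gam_tail_prob <- function(counts_row, drift, quadrature = quadrature_spec()) {
  gl <- gauss_legendre_01(quadrature$n_nodes)
  .tail_prob_one(counts_row, list(g = drift$d_g, c = drift$d_c, m = drift$d_m),
                 "g", gl)
}

#' Conditional tail probabilities with any cohort in the tail position
#'
#' Recomputes the conditional tail probability with the chosen cohort as the
#' target and the other two conditioned on, for every SNP of `counts`. With
#' `target = "G"` this reproduces [gam_tail_prob()] SNP by SNP; `target =
#' "M"` yields the third-cohort analysis.
#'
#' @param counts A `snp_counts` table with all three cohorts observed at
#'   every row.
#' @param drift A `drift_estimate`.
#' @param target One of `"G"`, `"C"`, `"M"`.
#' @param quadrature A [quadrature_spec()].
#' @return Data frame of class `tail_prob_table`: `snp_id`, `q`, plus
#'   attributes `target` and `drift`.
#' @export
swap_target_cohort <- function(counts, drift, target = c("G", "C", "M"),
                               quadrature = quadrature_spec()) {
  target <- match.arg(target)
  gl <- gauss_legendre_01(quadrature$n_nodes)
  d <- list(g = drift$d_g, c = drift$d_c, m = drift$d_m)
  q <- vapply(seq_len(nrow(counts)), function(i) {
    .tail_prob_one(counts[i, ], d, tolower(target), gl)
  }, numeric(1L))
  out <- data.frame(snp_id = counts$snp_id, q = q, stringsAsFactors = FALSE)
  class(out) <- c("tail_prob_table", "data.frame")
  attr(out, "target") <- target
  attr(out, "drift") <- c(d_g = drift$d_g, d_c = drift$d_c, d_m = drift$d_m)
  out
}

#' Drift-model empirical null over 3-SNP subsets
#'
#' Averages the conditional tail probability q over the candidate triple and
#' compares it with the same average over every `C(n, 3)` subset of the
#' eligible (fully observed) SNPs. The empirical P is the proportion of
#' subset means *strictly* smaller than the candidate mean (so a candidate
#' triple with the smallest mean gives `p = 0`).
#'
#' @param tails A `tail_prob_table` from [swap_target_cohort()].
#' @param candidate_set Exactly three SNP ids present in `tails`.
#' @param tie_rule `"lt"` (default, strictly smaller) or `"leq"`.
#' @return A `selection_test_result` (see [empirical_p()]).
#' @export
method2_empirical_p <- function(tails, candidate_set, tie_rule = c("lt", "leq")) {
  tie_rule <- match.arg(tie_rule)
  if (length(candidate_set) != 3L) {
    stop("candidate_set must contain exactly 3 SNP ids")
  }
  hit <- match(candidate_set, tails$snp_id)
  if (anyNA(hit)) {
    stop("candidate SNP(s) not eligible (missing from tail table): ",
         paste(candidate_set[is.na(hit)], collapse = ", "))
  }
  n <- nrow(tails)
  if (n < 3L) stop("need at least 3 eligible SNPs")
  stat_cd <- mean(tails$q[hit])
  n_subsets <- count_combinations(n, 3L)
  n_small <- .count_triples_below(tails$q, stat_cd, strict = tie_rule == "lt")
  structure(
    list(statistic_cd = stat_cd, n_subsets = n_subsets,
         n_at_least_as_small = n_small, p_empirical = n_small / n_subsets,
         adjusted = FALSE, tie_rule = tie_rule,
         candidate_ids = candidate_set, n_snps = n),
    class = "selection_test_result"
  )
}
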