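# Beta-binomial drift model: pmf, joint likelihood, grid MLE, tail
# probabilities and the strict empirical null.

fast_quad <- quadrature_spec(n_nodes = 128L, max_doublings = 1L)

test_that("beta-binomial pmf: binomial limit, normalization, domain checks", {
  expect_equal(betabinom_logpmf(1, 2, 0.5, 0), log(0.5))
  expect_equal(betabinom_logpmf(3, 10, 0.3, 0),
               dbinom(3, 10, 0.3, log = TRUE))
  # normalization over a lattice of (n, p_a, d)
  for (n in c(5, 30)) for (p in c(0.1, 0.3, 0.7)) for (d in c(0.01, 0.1, 0.4)) {
    expect_equal(sum(exp(betabinom_logpmf(0:n, n, p, d))), 1,
                 tolerance = 1e-10)
  }
  expect_error(betabinom_logpmf(1, 2, 0, 0.1), "p_a")
  expect_error(betabinom_logpmf(1, 2, 0.5, 1), "d must")
  expect_error(betabinom_logpmf(3, 2, 0.5, 0.1), "x must")
})

test_that("beta-binomial pmf has the Balding-Nichols mean and variance", {
  # moments from the pmf itself vs the model's closed forms
  n <- 40; p <- 0.35; d <- 0.08
  pr <- exp(betabinom_logpmf(0:n, n, p, d))
  mu <- sum((0:n) * pr)
  v <- sum((0:n)^2 * pr) - mu^2
  expect_equal(mu, n * p, tolerance = 1e-10)
  # Var(X) = n p (1-p) (1 + (n-1) d) for the Balding-Nichols beta-binomial
  expect_equal(v, n * p * (1 - p) * (1 + (n - 1) * d), tolerance = 1e-8)
})

test_that("joint likelihood: closed form, convergence, symmetry", {
  row0 <- list(x_g = 0L, n_g = 2L, x_c = 0L, n_c = 2L, x_m = 0L, n_m = 2L)
  # all binomial (d = 0): integral of (1-p)^6 dp = 1/7
  expect_equal(snp_joint_likelihood(row0, 0, 0, 0), 1 / 7, tolerance = 1e-12)

  # doubling quadrature nodes barely moves a generic value
  row <- list(x_g = 12L, n_g = 60L, x_c = 30L, n_c = 80L, x_m = 9L, n_m = 40L)
  v1 <- snpdrift:::.joint_lik_fixed(row, list(g = .05, c = .1, m = .02),
                                    gauss_legendre_01(256))
  v2 <- snpdrift:::.joint_lik_fixed(row, list(g = .05, c = .1, m = .02),
                                    gauss_legendre_01(512))
  expect_lt(abs(v2 - v1) / v1, 1e-8)

  # global minor/major relabeling x -> n - x leaves the likelihood unchanged
  # (uniform prior symmetry)
  row_flip <- list(x_g = 48L, n_g = 60L, x_c = 50L, n_c = 80L,
                   x_m = 31L, n_m = 40L)
  expect_equal(snp_joint_likelihood(row, 0.05, 0.1, 0.02),
               snp_joint_likelihood(row_flip, 0.05, 0.1, 0.02),
               tolerance = 1e-10)

  # a cohort with NA counts drops out of the product
  row_na <- list(x_g = 12L, n_g = 60L, x_c = NA, n_c = NA, x_m = 9L, n_m = 40L)
  gl <- gauss_legendre_01(256)
  two_factor <- sum(gl$weights *
    exp(betabinom_logpmf(12, 60, gl$nodes, 0.05) +
        betabinom_logpmf(9, 40, gl$nodes, 0.02)))
  expect_equal(snp_joint_likelihood(row_na, 0.05, 0.1, 0.02), two_factor,
               tolerance = 1e-10)
})

test_that("quadrature nodes and weights are correct", {
  gl <- gauss_legendre_01(64)
  expect_equal(sum(gl$weights), 1, tolerance = 1e-12)
  # exact for polynomials up to degree 2*64 - 1
  for (k in c(1, 5, 20)) {
    expect_equal(sum(gl$weights * gl$nodes^k), 1 / (k + 1), tolerance = 1e-12)
  }
  expect_true(all(gl$nodes > 0 & gl$nodes < 1))
})

test_that("grid MLE recovers simulated drift and is exchangeable", {
  cfg <- sim_config(n_snps = 250, n_individuals = c(150, 150, 150),
                    drift = c(G = 0.05, C = 0.10, M = 0.02),
                    missing_rate = 0, seed = 17)
  sims <- simulate_three_cohorts(cfg)
  mm <- assign_minor_alleles(sims$C)
  mafs <- lapply(sims[c("G", "C", "M")], compute_maf, minor_map = mm)
  cnt <- snp_counts(mafs$G, mafs$C, mafs$M)
  fit <- fit_drift_mle(cnt, grid = drift_grid(n = 24), quadrature = fast_quad)
  expect_lt(abs(log(fit$d_g / 0.05)), log(1.5))
  expect_lt(abs(log(fit$d_c / 0.10)), log(1.5))
  expect_lt(abs(log(fit$d_m / 0.02)), log(1.5))
  expect_false(fit$boundary)

  # exchangeability: identically drifted cohorts get near-equal estimates
  cfg2 <- sim_config(n_snps = 250, n_individuals = c(150, 150, 150),
                     drift = c(G = 0.05, C = 0.05, M = 0.05),
                     missing_rate = 0, seed = 18)
  sims2 <- simulate_three_cohorts(cfg2)
  mm2 <- assign_minor_alleles(sims2$C)
  mafs2 <- lapply(sims2[c("G", "C", "M")], compute_maf, minor_map = mm2)
  fit2 <- fit_drift_mle(snp_counts(mafs2$G, mafs2$C, mafs2$M),
                        grid = drift_grid(n = 24), quadrature = fast_quad)
  expect_lt(abs(log(fit2$d_g / fit2$d_c)), log(1.8))
  expect_lt(abs(log(fit2$d_g / fit2$d_m)), log(1.8))
})

test_that("grid MLE smoke and error cases", {
  one <- data.frame(snp_id = "s", x_g = 10L, n_g = 20L, x_c = 10L, n_c = 20L,
                    x_m = 10L, n_m = 20L)
  # one balanced SNP pushes the argmax to the grid edge: warned and flagged
  expect_warning(
    fit <- fit_drift_mle(one, grid = drift_grid(n = 8), quadrature = fast_quad,
                         refine = FALSE),
    "boundary"
  )
  expect_true(fit$boundary)
  expect_true(is.finite(fit$loglik_max))

  allna <- one
  allna$x_m <- NA_integer_; allna$n_m <- NA_integer_
  expect_error(fit_drift_mle(allna, grid = drift_grid(n = 8),
                             quadrature = fast_quad),
               "no observed SNPs")
})

test_that("tail probability: bounds, monotonicity, target swapping", {
  dr <- structure(list(d_g = 0.06, d_c = 0.12, d_m = 0.03),
                  class = "drift_estimate")
  row_full <- list(x_g = 40L, n_g = 40L, x_c = 12L, n_c = 30L,
                   x_m = 8L, n_m = 24L)
  expect_equal(gam_tail_prob(row_full, dr, fast_quad), 1)

  q <- vapply(c(0L, 3L, 10L, 20L, 40L), function(x) {
    gam_tail_prob(list(x_g = x, n_g = 40L, x_c = 12L, n_c = 30L,
                       x_m = 8L, n_m = 24L), dr, fast_quad)
  }, numeric(1))
  expect_true(all(diff(q) > 0))
  expect_true(all(q >= 0 & q <= 1))

  cnt <- data.frame(snp_id = c("a", "b"),
                    x_g = c(3L, 9L), n_g = c(40L, 50L),
                    x_c = c(12L, 20L), n_c = c(30L, 60L),
                    x_m = c(8L, 5L), n_m = c(24L, 30L))
  # target G reproduces gam_tail_prob row by row
  tg <- swap_target_cohort(cnt, dr, "G", fast_quad)
  expect_equal(tg$q[1], gam_tail_prob(cnt[1, ], dr, fast_quad))
  expect_equal(tg$q[2], gam_tail_prob(cnt[2, ], dr, fast_quad))

  # relabeling symmetry: permute cohort roles and the target together
  cnt_perm <- data.frame(snp_id = cnt$snp_id,
                         x_g = cnt$x_m, n_g = cnt$n_m,
                         x_c = cnt$x_c, n_c = cnt$n_c,
                         x_m = cnt$x_g, n_m = cnt$n_g)
  dr_perm <- structure(list(d_g = dr$d_m, d_c = dr$d_c, d_m = dr$d_g),
                       class = "drift_estimate")
  tm <- swap_target_cohort(cnt, dr, "M", fast_quad)
  tg2 <- swap_target_cohort(cnt_perm, dr_perm, "G", fast_quad)
  expect_equal(tg2$q, tm$q, tolerance = 1e-12)

  # missing cohorts are rejected for tail probabilities
  cnt_na <- cnt; cnt_na$x_m[1] <- NA_integer_
  expect_error(swap_target_cohort(cnt_na, dr, "G", fast_quad), "missing")
})

test_that("drift-model empirical P uses the strict rule and the oracle agrees", {
  tails <- structure(
    data.frame(snp_id = sprintf("s%03d", 1:6),
               q = c(0.02, 0.05, 0.10, 0.4, 0.6, 0.9),
               stringsAsFactors = FALSE),
    class = c("tail_prob_table", "data.frame")
  )
  res <- method2_empirical_p(tails, c("s001", "s002", "s003"))
  # candidate mean is the strict minimum of all 20 subset means
  expect_identical(res$n_subsets, 20)
  expect_equal(res$p_empirical, 0)

  set.seed(4)
  q <- runif(9)
  tails2 <- structure(data.frame(snp_id = sprintf("s%03d", 1:9), q = q),
                      class = c("tail_prob_table", "data.frame"))
  cand <- c("s002", "s005", "s008")
  res2 <- method2_empirical_p(tails2, cand)
  expect_equal(res2$n_at_least_as_small,
               brute_force_count(q, mean(q[c(2, 5, 8)]), strict = TRUE))

  expect_error(method2_empirical_p(tails, c("s001", "s002", "zzz")),
               "not eligible")
})
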