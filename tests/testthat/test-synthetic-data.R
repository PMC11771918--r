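test_that("default truth reproduces the analytic loading values", {
  tr <- default_truth()
  expect_equal(round(tr$beta0, 3), c(0.620, 0.555, 0.555))
  expect_equal(round(tr$beta1, 3), c(0.577, 0.577, 0.577))
  expect_equal(tr$beta0, c(sqrt(5), 2, 2) / sqrt(13))
  expect_equal(round(tr$A, 5), 0.39115)
  expect_equal(round(tr$B, 5), 1.34090)
  # [A, B] is centred at the mean of u1 with half-width 1.645 sd(u1)
  set.seed(8)
  u1 <- rowSums(matrix(runif(3e5), 1e5, 3)) / sqrt(3)
  expect_equal(mean(u1), (tr$A + tr$B) / 2, tolerance = 3 * sd(u1) / sqrt(1e5))
  expect_equal(sd(u1), (tr$B - tr$A) / (2 * 1.645), tolerance = 1e-2)
})

test_that("the linear reference is anchored at the projection of m1", {
  tr <- default_truth()
  # m1 is even about the mean of u1, so the projected slope is exactly 0
  expect_equal(tr$projection$delta1, 0, tolerance = 1e-8)
  # projected intercept = E[m1(u1)], checked by Monte Carlo
  set.seed(9)
  u1 <- rowSums(matrix(runif(6e5), 2e5, 3)) / sqrt(3)
  m <- tr$m1(u1)
  expect_equal(tr$projection$delta0, mean(m), tolerance = 3 * sd(m) / sqrt(2e5))
  # the reference line used for tau-interpolation keeps the projected
  # mean level but a nonzero slope (identifiability under the null)
  expect_equal(tr$delta1, 0.5)
  expect_equal(tr$delta0 + tr$delta1 * sqrt(3) / 2, tr$projection$delta0,
               tolerance = 1e-10)
})

test_that("tau interpolation hits its endpoints", {
  u <- seq(0, sqrt(3), length.out = 41)
  tr1 <- default_truth(tau = 1)
  expect_equal(tr1$m1_tau(u), tr1$m1(u))
  tr0 <- default_truth(tau = 0)
  expect_equal(tr0$m1_tau(u), tr0$delta0 + tr0$delta1 * u)
  tr05 <- default_truth(tau = 0.5)
  expect_equal(tr05$m1_tau(u), 0.5 * tr05$m1(u) + 0.5 * tr0$m1_tau(u))
})

test_that("genotypes follow Hardy-Weinberg frequencies", {
  set.seed(10)
  g <- simulate_genotypes(1e5, maf = 0.3)
  freq <- tabulate(g + 1L, 3L) / 1e5
  want <- c(0.49, 0.42, 0.09)
  for (i in 1:3) {
    se <- sqrt(want[i] * (1 - want[i]) / 1e5)
    expect_lt(abs(freq[i] - want[i]), 3 * se)
  }
  set.seed(11)
  g5 <- simulate_genotypes(2e4, maf = 0.5)
  expect_equal(mean(g5 == 1), 0.5, tolerance = 3 * sqrt(0.25 / 2e4))
})

test_that("orthant probability matches the closed form at zero thresholds", {
  for (r in c(-0.8, -0.3, 0, 0.2, 0.5, 0.9)) {
    expect_equal(latent_bvn_prob(0, 0, r), 0.25 + asin(r) / (2 * pi),
                 tolerance = 1e-9)
  }
  # independence factorizes
  expect_equal(latent_bvn_prob(0.7, -0.3, 0),
               pnorm(0.7, lower.tail = FALSE) * pnorm(-0.3, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("latent correlation solve recovers the sin closed form", {
  # equal marginals 1/2: binary correlation rho_b needs latent
  # sin(pi rho_b / 2); at rho_b = 1/2 that is sqrt(2)/2
  sol <- latent_corr_solve(0.5, 0.5, 0.5)
  expect_equal(sol$rho, sqrt(2) / 2, tolerance = 1e-8)
  expect_false(sol$clipped)
  sol2 <- latent_corr_solve(0.5, 0.5, 0.25)
  expect_equal(sol2$rho, sin(pi * 0.25 / 2), tolerance = 1e-8)
  # infeasible target gets clipped
  sol3 <- latent_corr_solve(0.05, 0.95, 0.8)
  expect_true(sol3$clipped)
  expect_lt(sol3$rho, 1)
})

test_that("binary AR(1) sampler hits marginals and lag-1 correlation", {
  set.seed(12)
  reps <- 20000
  y <- matrix(0L, reps, 2)
  for (i in seq_len(reps)) y[i, ] <- binary_ar1_sample(c(0.5, 0.5), 0.5)
  expect_equal(mean(y[, 1]), 0.5, tolerance = 3 * sqrt(0.25 / reps))
  expect_equal(cor(y[, 1], y[, 2]), 0.5, tolerance = 0.02)
  # rho = 0 gives independent Bernoulli draws
  set.seed(13)
  y0 <- matrix(0L, reps, 2)
  for (i in seq_len(reps)) y0[i, ] <- binary_ar1_sample(c(0.3, 0.7), 0)
  expect_lt(abs(cor(y0[, 1], y0[, 2])), 0.025)
  expect_equal(mean(y0[, 2]), 0.7, tolerance = 3 * sqrt(0.21 / reps))
})

test_that("simulated datasets are deterministic given the seed", {
  tr <- default_truth(N = 40, T_visits = 5, maf = 0.3)
  set.seed(14); d1 <- simulate_dataset(tr, warn = FALSE)
  set.seed(14); d2 <- simulate_dataset(tr, warn = FALSE)
  expect_identical(d1$long, d2$long)
  set.seed(15); d3 <- simulate_dataset(tr, warn = FALSE)
  expect_false(identical(d1$long, d3$long))
})

test_that("simulated responses recover the model marginal means", {
  set.seed(16)
  tr <- default_truth(N = 60000, T_visits = 1, maf = 0.3)
  d <- simulate_dataset(tr, warn = FALSE)
  X <- do.call(rbind, d$X)
  pr <- plogis(tr$m0(X %*% tr$beta0) + tr$m1(X %*% tr$beta1) * d$G)
  y <- unlist(d$y)
  bins <- cut(pr, quantile(pr, 0:5 / 5), include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- bins == b
    se <- sqrt(mean(pr[idx]) * (1 - mean(pr[idx])) / sum(idx))
    expect_lt(abs(mean(y[idx]) - mean(pr[idx])), 3.5 * se)
  }
})
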