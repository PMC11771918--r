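test_that("QIF BIC formula and over-identification guard", {
  expect_equal(qif_bic(10, 36, 18, 500), 10 + 18 * log(500))
  expect_error(qif_bic(10, 18, 18, 500), "over-identification")
  # with h basis matrices, r - k = (h - 1) k
  dat <- small_data(N = 80, T_visits = 4, seed = 40)
  fit <- gfvicm_fit(dat, degree = 2, n_knots = 1, compute_se = FALSE)
  expect_equal(fit$r - fit$k, fit$k)
})

test_that("goodness-of-fit test uses the chi-square upper tail", {
  dat <- small_data(N = 80, T_visits = 4, seed = 41)
  fit <- gfvicm_fit(dat, degree = 2, n_knots = 1, compute_se = FALSE)
  gof <- goodness_of_fit(fit)
  expect_gte(gof$statistic, 0)
  expect_equal(gof$df, fit$r - fit$k)
  expect_equal(gof$p_value,
               pchisq(gof$statistic, gof$df, lower.tail = FALSE))
  ifit <- gfvicm_fit(dat, structure = "independence", degree = 2,
                     n_knots = 0, compute_se = FALSE)
  expect_error(goodness_of_fit(ifit), "r > k")
})

test_that("coverage intervals use the normal multiplier", {
  dat <- small_data(N = 150, T_visits = 4, seed = 42)
  fit <- gfvicm_fit(dat, degree = 2, n_knots = 1)
  ci <- coverage_interval(fit, level = 0.95)
  expect_equal((ci$upper - ci$estimate) / ci$se,
               rep(qnorm(0.975), fit$k), tolerance = 1e-10)
  expect_false(any(ci$degenerate[seq_len(6)]))
  expect_true(all(is.finite(fit$se)))
  expect_true(all(fit$se[1:6] > 0))
})

test_that("linearity test has df K + q - 1 and a nested null design", {
  dat <- small_data(N = 350, T_visits = 5, seed = 43, maf = 0.5)
  lt <- linearity_test(dat, degree = 2, n_knots = 3)
  expect_equal(lt$df, 4)
  expect_gte(lt$statistic, 0)
  expect_equal(lt$statistic, max(0, lt$null_fit$Q - lt$alt_fit$Q))
  # null fit really constrains the higher-order gamma1 terms to zero
  expect_equal(lt$null_fit$gamma1[3:6], rep(0, 4))
  expect_false(all(lt$alt_fit$gamma1[3:6] == 0))
  expect_equal(lt$p_value, pchisq(lt$statistic, 4, lower.tail = FALSE))
})

test_that("nested test statistic is invariant to subject relabeling", {
  dat <- small_data(N = 260, T_visits = 4, seed = 44, maf = 0.5)
  set.seed(45)
  long2 <- dat$long
  long2$subject <- sample(260)[long2$subject]
  dat2 <- as_gfvicm_data(long2)
  t1 <- nested_test(dat, constrain = 3:4, degree = 2, n_knots = 1)
  t2 <- nested_test(dat2, constrain = 3:4, degree = 2, n_knots = 1)
  # identical up to optimizer path noise (summation order changes)
  expect_lt(abs(t1$statistic - t2$statistic), 0.02)
  expect_equal(t1$df, 2)
})

test_that("spline configuration selection reports BIC for all candidates", {
  dat <- small_data(N = 100, T_visits = 4, seed = 46, maf = 0.5)
  one <- select_spline_config(dat, candidates = data.frame(degree = 2,
                                                           n_knots = 1))
  expect_equal(one$degree, 2)
  expect_equal(one$n_knots, 1)
  expect_equal(nrow(one$table), 1)
  sel <- select_spline_config(dat,
                              candidates = data.frame(degree = c(1, 2),
                                                      n_knots = c(0, 1)))
  expect_equal(nrow(sel$table), 2)
  expect_true(all(is.finite(sel$table$bic)))
  expect_equal(sel$table$bic[sel$table$degree == sel$degree &
                               sel$table$n_knots == sel$n_knots],
               min(sel$table$bic))
})

test_that("standard errors shrink roughly like 1/sqrt(N)", {
  # doubling the sample size should halve the asymptotic variance; checked
  # in ratio with generous Monte Carlo slack on two single fits
  dat1 <- small_data(N = 150, T_visits = 5, seed = 47, maf = 0.5)
  dat2 <- small_data(N = 600, T_visits = 5, seed = 47, maf = 0.5)
  f1 <- gfvicm_fit(dat1, degree = 2, n_knots = 0)
  f2 <- gfvicm_fit(dat2, degree = 2, n_knots = 0)
  ratio <- mean(f2$se[1:6] / f1$se[1:6])
  expect_gt(ratio, 0.3)
  expect_lt(ratio, 0.7)
})

test_that("the locally profiled linearity test detects the bump
           interaction", {
  # the default (fully re-estimated) null can hide nonlinearity by
  # rotating the index; the local profile blocks that and should reject
  # strongly nonlinear interactions most of the time
  rej <- 0
  for (s in 1:20) {
    set.seed(800 + s)
    d <- simulate_dataset(default_truth(N = 500, T_visits = 10, maf = 0.3,
                                        tau = 1), warn = FALSE)
    lt <- suppressWarnings(
      linearity_test(d, degree = 2, n_knots = 3, profile = "local",
                     control = gfvicm_control(theta_tol = 1e-4,
                                              obj_tol = 1e-7)))
    rej <- rej + (lt$p_value < 0.05)
  }
  expect_gte(rej / 20, 0.7)
})
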