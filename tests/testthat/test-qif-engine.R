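test_that("basis matrices have the defined structures", {
  m <- basis_matrices(4, "ar1")
  expect_length(m, 2)
  expect_equal(m[[1]], diag(4))
  expect_equal(m[[2]], rbind(c(0, 1, 0, 0), c(1, 0, 1, 0),
                             c(0, 1, 0, 1), c(0, 0, 1, 0)))
  me <- basis_matrices(3, "exchangeable")[[2]]
  expect_equal(diag(me), rep(0, 3))
  expect_equal(me[upper.tri(me)], rep(1, 3))
  expect_length(basis_matrices(3, "independence"), 1)
})

test_that("subject score vanishes at a perfect fit and handles n_i = 1", {
  pm <- random_params(seed = 11)
  set.seed(12)
  X_i <- matrix(runif(9), 3, 3)
  mu <- marginal_mean(pm, X_i, 1)
  sc <- subject_score(pm, y_i = mu, X_i = X_i, G_i = 1, structure = "ar1")
  expect_equal(sc[[1]], rep(0, pm$k), ignore_attr = TRUE)
  expect_equal(sc[[2]], rep(0, pm$k), ignore_attr = TRUE)
  # single visit: the AR(1) second basis matrix is the 1x1 zero matrix
  sc1 <- subject_score(pm, y_i = 1, X_i = X_i[1, , drop = FALSE], G_i = 1,
                       structure = "ar1")
  expect_equal(sc1[[2]], rep(0, pm$k), ignore_attr = TRUE)
  expect_false(all(sc1[[1]] == 0))
})

test_that("compiled QIF agrees with the dense R reference", {
  dat <- small_data(N = 50, T_visits = 4, seed = 13)
  for (structure in c("independence", "exchangeable", "ar1")) {
    pm <- random_params(seed = 14)
    ref <- ref_qif(pm, dat, structure)
    got <- qif_value(pm, dat, structure)
    expect_equal(got$gbar, ref$gbar, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(got$Cbar, ref$Cbar, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(got$Q, ref$Q, tolerance = 1e-8)
    expect_gte(got$Q, 0)
  }
})

test_that("duplicating every subject doubles Q", {
  dat <- small_data(N = 40, T_visits = 4, seed = 15)
  long2 <- dat$long
  long2$subject <- long2$subject + max(dat$long$subject)
  dat2 <- as_gfvicm_data(rbind(dat$long, long2))
  pm <- random_params(seed = 16)
  expect_equal(qif_value(pm, dat2, "ar1")$Q, 2 * qif_value(pm, dat, "ar1")$Q,
               tolerance = 1e-8)
})

test_that("Q is invariant to subject relabeling", {
  dat <- small_data(N = 30, T_visits = 4, seed = 17)
  set.seed(18)
  perm <- sample(30)
  long2 <- dat$long
  long2$subject <- perm[long2$subject]
  dat2 <- as_gfvicm_data(long2)
  pm <- random_params(seed = 19)
  expect_equal(qif_value(pm, dat2, "ar1")$Q, qif_value(pm, dat, "ar1")$Q,
               tolerance = 1e-9)
})

test_that("objective is invariant to a joint sign flip of the index", {
  # flipping beta -> -beta, mirroring the knots and re-expressing the
  # spline coefficients leaves m(u) and hence Q unchanged
  dat <- small_data(N = 40, T_visits = 4, seed = 20)
  pm <- random_params(seed = 21)
  mirror <- function(spec, gam) {
    kn <- sort(-spec$knots)
    spec2 <- spline_spec(spec$degree, kn)
    u <- seq(-2.2, 2.2, length.out = 400)
    gam2 <- qr.solve(basis_vector(-u, spec2),
                     drop(basis_vector(u, spec) %*% gam))
    list(spec = spec2, gamma = gam2)
  }
  m0 <- mirror(pm$spec0, pm$gamma0)
  m1 <- mirror(pm$spec1, pm$gamma1)
  pm2 <- pm
  pm2$loadings$beta0 <- -pm$loadings$beta0
  pm2$loadings$beta1 <- -pm$loadings$beta1
  pm2$gamma0 <- m0$gamma; pm2$spec0 <- m0$spec
  pm2$gamma1 <- m1$gamma; pm2$spec1 <- m1$spec
  expect_equal(qif_value(pm2, dat, "ar1")$Q, qif_value(pm, dat, "ar1")$Q,
               tolerance = 1e-5)
})

test_that("penalty matrix and penalized objective follow the block layout", {
  expect_equal(penalty_diag(3, 2, 3),
               c(rep(0, 9), rep(1, 3), rep(0, 3), rep(1, 3)))
  expect_length(penalty_diag(3, 2, 3), 18)
  # K = 0: no penalty for any lambda
  dat <- small_data(N = 30, T_visits = 3, seed = 22)
  pm <- model_params(index_loadings(c(1, 1, 1), c(1, 1, 1)),
                     c(0.2, -0.1, 0.3), c(0.1, 0, -0.2), spline_spec(2))
  expect_equal(penalized_objective(pm, dat, "ar1", lambda = 5),
               penalized_objective(pm, dat, "ar1", lambda = 0))
  # lambda = 0 equals Q / N
  pm2 <- random_params(seed = 23)
  expect_equal(penalized_objective(pm2, dat, "ar1", lambda = 0),
               qif_value(pm2, dat, "ar1")$Q / dat$N)
  # lambda > 0 adds exactly the squared knot coefficients
  lam <- 0.37
  knot_ss <- sum(pm2$gamma0[4:5]^2) + sum(pm2$gamma1[4:5]^2)
  expect_equal(penalized_objective(pm2, dat, "ar1", lambda = lam),
               qif_value(pm2, dat, "ar1")$Q / dat$N + lam * knot_ss)
})

test_that("analytic gradient of Q matches finite differences", {
  dat <- small_data(N = 400, T_visits = 4, seed = 24)
  flat <- gfvicm:::flatten_data(dat)
  set.seed(25)
  th <- c(rep(1, 3) / sqrt(3), rep(1, 3) / sqrt(3),
          rnorm(4, 0, 0.3), rnorm(4, 0, 0.3))
  kn0 <- 0.8; kn1 <- 0.9
  f <- function(th) {
    gfvicm:::qif_eval(th[1:3], th[4:6], th[7:10], th[11:14], flat, 2,
                      kn0, kn1, "ar1")$Q
  }
  gr <- drop(gfvicm:::qif_eval(th[1:3], th[4:6], th[7:10], th[11:14], flat, 2,
                               kn0, kn1, "ar1", grad_cols = 1:14)$grad)
  fd <- sapply(1:14, function(i) {
    h <- 1e-5
    e <- rep(0, 14); e[i] <- h
    (f(th + e) - f(th - e)) / (2 * h)
  })
  expect_equal(gr, fd, tolerance = 1e-4)
})

test_that("analytic score derivative matches finite differences of gbar", {
  dat <- small_data(N = 40, T_visits = 4, seed = 26)
  flat <- gfvicm:::flatten_data(dat)
  set.seed(27)
  th <- c(rep(1, 3) / sqrt(3), rep(1, 3) / sqrt(3),
          rnorm(4, 0, 0.3), rnorm(4, 0, 0.3))
  ev <- function(th, ...) {
    gfvicm:::qif_eval(th[1:3], th[4:6], th[7:10], th[11:14], flat, 2,
                      0.8, 0.9, "ar1", ...)
  }
  Gdot <- ev(th, gdot = TRUE)$Gdot
  fd <- sapply(1:14, function(i) {
    h <- 1e-6
    e <- rep(0, 14); e[i] <- h
    (ev(th + e)$gbar - ev(th - e)$gbar) / (2 * h)
  })
  expect_equal(Gdot, fd, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the just-identified fit drives Q to zero", {
  dat <- small_data(N = 80, T_visits = 4, seed = 28)
  fit <- gfvicm_fit(dat, structure = "independence", degree = 2,
                    n_knots = 0, compute_se = FALSE)
  expect_lte(fit$Q, 1e-6)
})

test_that("refitting from the optimum is a fixed point", {
  dat <- small_data(N = 100, T_visits = 4, seed = 29)
  fit <- gfvicm_fit(dat, degree = 2, n_knots = 1, compute_se = FALSE)
  expect_true(fit$converged)
  refit <- gfvicm_fit(dat, degree = 2, n_knots = 1, compute_se = FALSE,
                      init = list(beta0 = fit$beta0, beta1 = fit$beta1,
                                  gamma0 = fit$gamma0, gamma1 = fit$gamma1))
  expect_lt(abs(refit$objective - fit$objective),
            1e-8 * max(1, abs(fit$objective)))
  expect_equal(sum(fit$beta0^2), 1, tolerance = 1e-10)
  expect_equal(sum(fit$beta1^2), 1, tolerance = 1e-10)
  expect_gt(fit$beta0[1], 0)
  expect_gt(fit$beta1[1], 0)
})

test_that("fit refuses unidentified designs", {
  dat <- small_data(N = 30, T_visits = 3, seed = 30)
  long <- dat$long
  long$G <- 1
  expect_error(gfvicm_fit(as_gfvicm_data(long)), "constant")
  long2 <- dat$long
  long2$y <- 0
  expect_error(gfvicm_fit(as_gfvicm_data(long2)), "degenerate")
})

test_that("GCV effective df equals k at lambda 0 and shrinks by 2K at
           large lambda", {
  dat <- small_data(N = 500, T_visits = 4, seed = 31)
  fit0 <- gfvicm_fit(dat, degree = 2, n_knots = 1, lambda = 0,
                     compute_se = FALSE)
  expect_equal(effective_df(fit0), fit0$k, tolerance = 1e-6)
  # lambda large enough to shrink the knot coefficients completely but
  # still within the numerically stable range of the trace computation
  fit_inf <- gfvicm_fit(dat, degree = 2, n_knots = 1, lambda = 100,
                        compute_se = FALSE)
  expect_equal(effective_df(fit_inf), fit_inf$k - 2 * 1, tolerance = 1e-3)
})

test_that("gcv_select_lambda scores an admissible grid", {
  dat <- small_data(N = 250, T_visits = 4, seed = 32)
  sel <- gcv_select_lambda(dat, degree = 2, n_knots = 1,
                           lambda_grid = c(0, 1e-3, 1e-1))
  expect_true(sel$lambda %in% c(0, 1e-3, 1e-1))
  expect_true(all(is.finite(sel$table$gcv)))
  expect_equal(nrow(sel$table), 3)
  expect_true(is.finite(sel$df))
})
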