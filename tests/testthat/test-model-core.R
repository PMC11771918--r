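test_that("index loadings are normalized with positive first element", {
  il <- index_loadings(c(-2, -1, -2), c(3, 4, 0))
  expect_equal(sum(il$beta0^2), 1)
  expect_gt(il$beta0[1], 0)
  expect_equal(il$beta1, c(0.6, 0.8, 0))
  expect_error(index_loadings(c(0, 0, 0), c(1, 1, 1)), "nonzero")
})

test_that("linear predictor reduces correctly in degenerate cases", {
  s <- spline_spec(1)
  il <- index_loadings(c(1, 0, 0), c(1, 0, 0))
  pm <- model_params(il, gamma0 = c(0, 1), gamma1 = c(0, 0), spec0 = s)
  x <- c(0.4, 0.9, 0.1)
  expect_equal(linear_predictor(pm, x, G = 2), 0.4)
  # G = 0 removes any gamma1 dependence
  pm2 <- model_params(il, c(0, 1), c(5, -7), s)
  expect_equal(linear_predictor(pm2, x, G = 0), 0.4)
  pm0 <- model_params(il, c(0, 0), c(0, 0), s)
  expect_equal(linear_predictor(pm0, x, G = 1), 0)
})

test_that("marginal mean is a stable logistic transform", {
  s <- spline_spec(1)
  il <- index_loadings(c(1, 0, 0), c(1, 0, 0))
  pm <- model_params(il, gamma0 = c(log(3), 0), gamma1 = c(0, 0), s)
  expect_equal(marginal_mean(pm, c(0.5, 0, 0), 0), 0.75)
  pm0 <- model_params(il, c(0, 0), c(0, 0), s)
  expect_equal(marginal_mean(pm0, c(0.5, 0, 0), 1), 0.5)
  pm_big <- model_params(il, c(-50, 0), c(0, 0), s)
  m <- marginal_mean(pm_big, c(0.5, 0, 0), 0)
  expect_true(is.finite(m) && m > 0 && m < 1e-20)
})

test_that("mean jacobian matches finite differences of the marginal mean", {
  pm <- random_params(seed = 9)
  set.seed(10)
  X_i <- matrix(runif(12), 4, 3)
  G_i <- 2
  J <- mean_jacobian(pm, X_i, G_i)
  th <- c(pm$loadings$beta0, pm$loadings$beta1, pm$gamma0, pm$gamma1)
  p <- 3; d <- pm$spec0$basis_dim
  remake <- function(th) {
    pm2 <- pm
    pm2$loadings$beta0 <- th[1:p]
    pm2$loadings$beta1 <- th[p + 1:p]
    pm2$gamma0 <- th[2 * p + 1:d]
    pm2$gamma1 <- th[2 * p + d + 1:d]
    pm2
  }
  h <- 1e-6
  fd <- sapply(seq_along(th), function(j) {
    e <- rep(0, length(th)); e[j] <- h
    (marginal_mean(remake(th + e), X_i, G_i) -
       marginal_mean(remake(th - e), X_i, G_i)) / (2 * h)
  })
  expect_equal(J, fd, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("jacobian zero structure follows the model", {
  s <- spline_spec(2, c(0.4, 0.8))
  il <- index_loadings(c(1, 1, 1), c(1, 1, 1))
  pm <- model_params(il, rep(0, 5), rep(0, 5), s)
  set.seed(3)
  X_i <- matrix(runif(9), 3, 3)
  J <- mean_jacobian(pm, X_i, 1)
  # gamma = 0: mu = 0.5, beta blocks vanish, gamma blocks are 0.25 B
  expect_equal(J[, 1:6], matrix(0, 3, 6))
  expect_equal(J[, 7:11], 0.25 * basis_vector(drop(X_i %*% il$beta0), s))
  # G = 0: beta1 and gamma1 blocks vanish
  pm2 <- random_params(seed = 4)
  J2 <- mean_jacobian(pm2, X_i, 0)
  d <- pm2$spec0$basis_dim
  expect_equal(J2[, 4:6], matrix(0, 3, 3))
  expect_equal(J2[, (6 + d + 1):(6 + 2 * d)], matrix(0, 3, d))
})

test_that("CSV reader validates and round-trips long-format data", {
  dat <- small_data(N = 12, T_visits = 3, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_gfvicm_csv(dat, path)
  dat2 <- read_gfvicm_csv(path)
  expect_equal(dat2$G, dat$G, ignore_attr = TRUE)
  expect_equal(dat2$y, dat$y, ignore_attr = TRUE)
  expect_equal(dat2$X, dat$X, ignore_attr = TRUE)

  df <- dat$long
  df$y[3] <- 2
  expect_error(as_gfvicm_data(df), "non-binary")
  df <- dat$long
  df$G[1] <- 3
  expect_error(as_gfvicm_data(df), "0/1/2")
  df <- dat$long
  df$G[df$subject == 2][1] <- (df$G[df$subject == 2][1] + 1) %% 3
  expect_error(as_gfvicm_data(df), "varies within subject")
  expect_error(as_gfvicm_data(dat$long[, -3]), "missing columns")
})

test_that("visit order comes from the visit column, not row order", {
  dat <- small_data(N = 8, T_visits = 4, seed = 6)
  shuffled <- dat$long[sample(nrow(dat$long)), ]
  dat2 <- as_gfvicm_data(shuffled)
  expect_equal(dat2$y, dat$y, ignore_attr = TRUE)
})
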