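# Independent reference implementations used as oracles. These are written
# directly from the estimating-equation definitions with dense matrices and
# exported R building blocks only (no calls into the compiled engine), so
# they check the fast path rather than mirror it.

ref_subject_score <- function(params, y_i, X_i, G_i, structure) {
  X_i <- rbind(X_i)
  mu <- marginal_mean(params, X_i, G_i)
  A_half_inv <- diag(1 / sqrt(mu * (1 - mu)), nrow(X_i))
  md <- mean_jacobian(params, X_i, G_i)
  lapply(basis_matrices(nrow(X_i), structure), function(M) {
    drop(t(md) %*% A_half_inv %*% M %*% A_half_inv %*% (y_i - mu))
  })
}

ref_qif <- function(params, data, structure) {
  gs <- lapply(seq_len(data$N), function(i) {
    unlist(ref_subject_score(params, data$y[[i]], data$X[[i]], data$G[i],
                             structure))
  })
  G <- do.call(cbind, gs)
  gbar <- rowMeans(G)
  Cbar <- tcrossprod(G) / data$N
  Q <- data$N * drop(crossprod(gbar, solve(Cbar, gbar)))
  list(gbar = gbar, Cbar = Cbar, Q = Q)
}

# small synthetic dataset for engine-level tests
small_data <- function(N = 60, T_visits = 4, maf = 0.4, seed = 1,
                       rho = 0.4, tau = 1) {
  set.seed(seed)
  simulate_dataset(default_truth(N = N, T_visits = T_visits, maf = maf,
                                 rho = rho, tau = tau), warn = FALSE)
}

# random valid parameter set on given data dimensions
random_params <- function(p = 3, degree = 2, knots0 = c(0.4, 0.9),
                         knots1 = c(0.5, 1.1), seed = 2) {
  set.seed(seed)
  d <- degree + length(knots0) + 1
  model_params(
    index_loadings(abs(rnorm(p)) + 0.2, abs(rnorm(p)) + 0.2),
    gamma0 = rnorm(d, 0, 0.5), gamma1 = rnorm(d, 0, 0.5),
    spec0 = spline_spec(degree, knots0),
    spec1 = spline_spec(degree, knots1))
}
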