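#' Unit-norm index loading vectors
#'
#' The gFVICM combines the p environmental exposures into two scalar
#' indices `u0 = beta0' x` and `u1 = beta1' x`. For identifiability each
#' loading vector has unit Euclidean norm and a positive first element;
#' this constructor normalizes and sign-flips its arguments accordingly.
#'
#' @param beta0,beta1 numeric p-vectors (nonzero).
#' @return Object of class `index_loadings` with unit-norm `beta0`, `beta1`.
#' @export
index_loadings <- function(beta0, beta1) {
  fix <- function(b, nm) {
    b <- as.numeric(b)
    nb <- sqrt(sum(b^2))
    if (nb == 0) stop(nm, " must be nonzero")
    b <- b / nb
    if (b[1] < 0) b <- -b
    if (b[1] == 0) stop("first element of ", nm, " must be nonzero")
    b
  }
  beta0 <- fix(beta0, "beta0"); beta1 <- fix(beta1, "beta1")
  if (length(beta0) != length(beta1))
    stop("beta0 and beta1 must have the same length")
  structure(list(beta0 = beta0, beta1 = beta1), class = "index_loadings")
}

#' Full gFVICM parameter set
#'
#' Bundles the index loadings, the two spline coefficient vectors, and the
#' spline bases for the two indices. The bases share degree and knot count
#' but carry separate knot locations, because knots are placed over the
#' range of each index. The free parameter is
#' `theta = (beta0, beta1, gamma0, gamma1)` of length
#' `k = 2p + 2(q + K + 1)`, the block order used by the score Jacobian.
#'
#' @param loadings an [index_loadings()].
#' @param gamma0,gamma1 spline coefficient vectors of length `q + K + 1`.
#' @param spec0,spec1 [spline_spec()] objects for the `u0` and `u1` bases;
#'   `spec1` defaults to `spec0`.
#' @return Object of class `model_params`.
#' @export
model_params <- function(loadings, gamma0, gamma1, spec0, spec1 = spec0) {
  stopifnot(inherits(loadings, "index_loadings"),
            inherits(spec0, "spline_spec"), inherits(spec1, "spline_spec"))
  if (spec0$degree != spec1$degree ||
      length(spec0$knots) != length(spec1$knots))
    stop("spec0 and spec1 must share degree and knot count")
  d <- spec0$basis_dim
  if (length(gamma0) != d || length(gamma1) != d)
    stop("gamma vectors must have length ", d)
  p <- length(loadings$beta0)
  structure(list(loadings = loadings, gamma0 = as.numeric(gamma0),
                 gamma1 = as.numeric(gamma1), spec0 = spec0, spec1 = spec1,
                 p = p, k = 2L * p + 2L * d),
            class = "model_params")
}

theta_vector <- function(params) {
  c(params$loadings$beta0, params$loadings$beta1,
    params$gamma0, params$gamma1)
}

theta_labels <- function(p, d) {
  c(paste0("beta0", seq_len(p)), paste0("beta1", seq_len(p)),
    paste0("gamma0", seq_len(d) - 1), paste0("gamma1", seq_len(d) - 1))
}

#' Linear predictor of the gFVICM
#'
#' `eta = B(beta0' x)' gamma0 + B(beta1' x)' gamma1 * G`, the spline
#' approximation of `m0(u0) + m1(u1) G` on the link scale.
#'
#' @param params a [model_params()].
#' @param X numeric matrix (rows = observations) or single row vector.
#' @param G genotype value(s) in `{0, 1, 2}` (recycled across rows).
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor <- function(params, X, G) {
  X <- rbind(X)
  u0 <- drop(X %*% params$loadings$beta0)
  u1 <- drop(X %*% params$loadings$beta1)
  unname(drop(basis_vector(u0, params$spec0) %*% params$gamma0) +
           drop(basis_vector(u1, params$spec1) %*% params$gamma1) * G)
}

#' Marginal mean (disease probability) under the logit link
#'
#' @inheritParams linear_predictor
#' @return `P(y = 1 | x, G) = expit(eta)`, computed stably for large `|eta|`.
#' @export
marginal_mean <- function(params, X, G) {
  stats::plogis(linear_predictor(params, X, G))
}

#' Jacobian of a subject's mean vector in theta
#'
#' Row j is `mu_ij (1 - mu_ij)` times the derivative of the linear
#' predictor: blocks `[Bd(u0)'gamma0 * x', Bd(u1)'gamma1 * G * x',
#' B(u0)', B(u1)' G]`, the column order of `theta`.
#'
#' @param params a [model_params()].
#' @param X_i `n_i x p` covariate matrix for one subject.
#' @param G_i the subject's genotype (scalar).
#' @return `n_i x k` matrix.
#' @export
mean_jacobian <- function(params, X_i, G_i) {
  X_i <- rbind(X_i)
  u0 <- drop(X_i %*% params$loadings$beta0)
  u1 <- drop(X_i %*% params$loadings$beta1)
  B0 <- basis_vector(u0, params$spec0); B1 <- basis_vector(u1, params$spec1)
  Bd0 <- basis_derivative(u0, params$spec0)
  Bd1 <- basis_derivative(u1, params$spec1)
  eta <- drop(B0 %*% params$gamma0) + drop(B1 %*% params$gamma1) * G_i
  mu <- stats::plogis(eta)
  v <- mu * (1 - mu)
  c0 <- drop(Bd0 %*% params$gamma0); c1 <- drop(Bd1 %*% params$gamma1)
  v * cbind(X_i * c0, X_i * c1 * G_i, B0, G_i * B1)
}
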