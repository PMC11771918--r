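#' Working-correlation basis matrices
#'
#' The QIF replaces the inverse working correlation by a linear span of
#' fixed symmetric basis matrices. `M_1` is always the identity;
#' exchangeable adds the off-diagonal-ones matrix, AR(1) adds the matrix
#' with ones on its two subdiagonals.
#'
#' @param n matrix dimension (a subject's number of visits).
#' @param structure `"independence"`, `"exchangeable"` or `"ar1"`.
#' @return List of `h` symmetric `n x n` matrices (`h = 1` for
#'   independence, else 2).
#' @export
basis_matrices <- function(n, structure = c("ar1", "exchangeable",
                                            "independence")) {
  structure <- match.arg(structure)
  M1 <- diag(n)
  if (structure == "independence") return(list(M1))
  M2 <- if (structure == "exchangeable") {
    matrix(1, n, n) - diag(n)
  } else {
    m <- matrix(0, n, n)
    if (n >= 2) {
      idx <- seq_len(n - 1)
      m[cbind(idx, idx + 1)] <- 1
      m[cbind(idx + 1, idx)] <- 1
    }
    m
  }
  list(M1, M2)
}

structure_code <- function(structure) {
  match(match.arg(structure, c("independence", "exchangeable", "ar1")),
        c("independence", "exchangeable", "ar1")) - 1L
}

#' Extended-score contribution of one subject
#'
#' Computes the `h` stacked components
#' `mudot' A^{-1/2} M_l A^{-1/2} (y - mu)` for a single subject. Marginal
#' means numerically at 0 or 1 are clamped to `[1e-10, 1 - 1e-10]` with a
#' warning.
#'
#' @param params a [model_params()].
#' @param y_i binary response vector.
#' @param X_i `n_i x p` covariate matrix.
#' @param G_i genotype scalar.
#' @param structure working-correlation structure, see [basis_matrices()].
#' @return List of `h` numeric vectors of length `k`.
#' @export
subject_score <- function(params, y_i, X_i, G_i,
                          structure = c("ar1", "exchangeable",
                                        "independence")) {
  structure <- match.arg(structure)
  X_i <- rbind(X_i)
  mu <- marginal_mean(params, X_i, G_i)
  if (any(mu < 1e-10 | mu > 1 - 1e-10)) {
    warning("marginal means clamped away from {0,1}")
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  }
  md <- mean_jacobian(params, X_i, G_i)
  ah <- sqrt(mu * (1 - mu))
  resid <- (y_i - mu) / ah
  lapply(basis_matrices(nrow(X_i), structure),
         function(M) drop(t(md) %*% ((M %*% resid) / ah)))
}

# low-level bridge to the compiled engine
qif_eval <- function(beta0, beta1, gamma0, gamma1, flat, degree,
                     knots0, knots1, structure,
                     grad_cols = integer(0), gdot = FALSE,
                     scores = FALSE, hess = FALSE, C_fix = NULL) {
  if (is.null(C_fix)) C_fix <- matrix(0, 0, 0)
  qif_eval_cpp(beta0, beta1, gamma0, gamma1, flat$y, flat$X, flat$G,
               flat$ni, as.integer(degree), as.numeric(knots0),
               as.numeric(knots1), structure_code(structure),
               length(grad_cols) > 0L, as.integer(grad_cols) - 1L,
               gdot, scores, hess, C_fix)
}

#' Quadratic inference function at a parameter value
#'
#' Assembles the mean extended score `gbar`, its empirical second moment
#' `Cbar = N^{-1} sum g_i g_i'`, and `Q = N gbar' Cbar^{-1} gbar`
#' (solved with a ridge-jitter fallback if `Cbar` is numerically
#' singular; the event is reported in `$jitter`).
#'
#' @param params a [model_params()].
#' @param data a `gfvicm_data` object.
#' @param structure working-correlation structure.
#' @param gradient if `TRUE`, also return the analytic gradient of `Q`
#'   in `theta` (assembled from the exact derivative of each subject
#'   score, including the `Cbar` dependence).
#' @return List with `Q`, `gbar`, `Cbar`, `r`, `k`, `jitter`, `clamped`,
#'   and optionally `grad`.
#' @export
qif_value <- function(params, data,
                      structure = c("ar1", "exchangeable", "independence"),
                      gradient = FALSE) {
  structure <- match.arg(structure)
  flat <- flatten_data(data)
  k <- params$k
  res <- qif_eval(params$loadings$beta0, params$loadings$beta1,
                  params$gamma0, params$gamma1, flat, params$spec0$degree,
                  params$spec0$knots, params$spec1$knots, structure,
                  grad_cols = if (gradient) seq_len(k) else integer(0))
  h <- if (structure == "independence") 1L else 2L
  res$r <- h * k
  res$k <- k
  res
}

#' Knot-penalty indicator matrix
#'
#' Diagonal of the penalty matrix `D`: ones exactly at the knot
#' coefficients within each gamma block,
#' `diag(0_{2p+q+1}, 1_K, 0_{q+1}, 1_K)`.
#'
#' @param p number of covariates.
#' @param degree spline degree `q`.
#' @param K number of knots.
#' @return 0/1 vector of length `k = 2p + 2(q + K + 1)`.
#' @export
penalty_diag <- function(p, degree, K) {
  c(rep(0, 2 * p + degree + 1), rep(1, K), rep(0, degree + 1), rep(1, K))
}

#' Penalized QIF objective
#'
#' `N^{-1} Q_N(theta) + lambda theta' D theta`, the criterion minimized by
#' the estimator; the penalty shrinks only the knot coefficients.
#'
#' @inheritParams qif_value
#' @param lambda nonnegative penalty tuning parameter.
#' @return Scalar objective value.
#' @export
penalized_objective <- function(params, data,
                                structure = c("ar1", "exchangeable",
                                              "independence"),
                                lambda = 0) {
  structure <- match.arg(structure)
  qv <- qif_value(params, data, structure)
  th <- theta_vector(params)
  Dd <- penalty_diag(params$p, params$spec0$degree,
                     length(params$spec0$knots))
  qv$Q / data$N + lambda * sum(Dd * th^2)
}
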