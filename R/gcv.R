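#' Default penalty grid
#'
#' `{0}` together with half-decade steps from `1e-6` to `10`.
#'
#' @return Numeric vector of candidate penalty values.
#' @export
default_lambda_grid <- function() {
  c(0, 10^seq(-6, 1, by = 0.5))
}

#' Effective degrees of freedom under the knot penalty
#'
#' `df = tr{(Qddot + 2 N lambda D)^{-1} Qddot}` with the Gauss-Newton
#' approximation `Qddot = 2 N Gdot' Cbar^{-1} Gdot` evaluated at the
#' fitted optimum. Equals `k` at `lambda = 0` and tends to `k - 2K` as
#' `lambda` grows (knot coefficients fully shrunk).
#'
#' @param fit a `gfvicm_fit`.
#' @return Scalar effective degrees of freedom.
#' @export
effective_df <- function(fit) {
  Qdd <- 2 * fit$N * crossprod(fit$Gdot_e, solve_sympd(fit$Cbar, fit$Gdot_e))
  Qdd <- (Qdd + t(Qdd)) / 2
  Dd <- penalty_diag(fit$p, fit$degree, fit$n_knots)
  A <- Qdd + diag(2 * fit$N * fit$lambda * Dd, fit$k)
  sum(diag(solve_sympd(A, Qdd)))
}

#' Select the knot penalty by generalized cross-validation
#'
#' For each candidate `lambda` the model is refit (warm-started along the
#' grid) and scored by
#' `GCV(lambda) = N^{-1} Q / (1 - N^{-1} df)^2` with the effective
#' degrees of freedom of [effective_df()]. Candidates with
#' `1 - df/N <= 0` are excluded with a warning.
#'
#' @param data a `gfvicm_data` object.
#' @param structure working-correlation structure.
#' @param degree,n_knots spline configuration.
#' @param lambda_grid nonnegative candidate values.
#' @param control passed to [gfvicm_fit()].
#' @return List with `lambda`, `df` (at the selected value), `fit`, and
#'   the full `table` (`lambda`, `df`, `gcv`).
#' @export
gcv_select_lambda <- function(data,
                              structure = c("ar1", "exchangeable",
                                            "independence"),
                              degree = 2L, n_knots = 3L,
                              lambda_grid = default_lambda_grid(),
                              control = gfvicm_control()) {
  structure <- match.arg(structure)
  stopifnot(length(lambda_grid) >= 1L, all(lambda_grid >= 0))
  lambda_grid <- sort(unique(lambda_grid))
  fits <- vector("list", length(lambda_grid))
  tab <- data.frame(lambda = lambda_grid, df = NA_real_, gcv = NA_real_)
  init <- NULL
  for (i in seq_along(lambda_grid)) {
    fit <- gfvicm_fit(data, structure, degree, n_knots, lambda_grid[i],
                      init = init, control = control, compute_se = FALSE)
    fits[[i]] <- fit
    init <- list(beta0 = fit$beta0, beta1 = fit$beta1,
                 gamma0 = fit$gamma0, gamma1 = fit$gamma1)
    df <- effective_df(fit)
    tab$df[i] <- df
    denom <- 1 - df / fit$N
    if (denom <= 0) {
      warning("lambda = ", lambda_grid[i],
              " excluded: effective df reaches N")
      next
    }
    tab$gcv[i] <- (fit$Q / fit$N) / denom^2
  }
  if (all(is.na(tab$gcv))) stop("no admissible lambda in the grid")
  best <- which.min(tab$gcv)
  list(lambda = lambda_grid[best], df = tab$df[best], fit = fits[[best]],
       table = tab)
}
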