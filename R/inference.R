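#' Sandwich standard errors for a QIF fit
#'
#' Asymptotic covariance from the over-identified GMM sandwich,
#' `avar(theta) = (Gdot' Cbar^{-1} Gdot)^{-1} / N` with the
#' expectation form of `Gdot = d gbar / d theta` at the optimum (the
#' residual-dependent derivative terms, whose mean is zero, are dropped
#' as in standard QIF asymptotics). The
#' unit-norm constraint on the loadings is handled by the delta method
#' through a smooth chart of the unit sphere (equivalently, projection
#' onto its tangent space), so the reported per-component SEs for the
#' loadings are the projected ones.
#'
#' @param fit a `gfvicm_fit`.
#' @return List with `se` (length-k vector, theta order), `vcov`
#'   (projected covariance), and `se_unconstrained` (no sphere
#'   projection; `NA` if the unprojected information is singular).
#' @export
asymptotic_se <- function(fit) {
  k <- fit$k; p <- fit$p; d <- fit$d
  M <- fit$N * crossprod(fit$Gdot_e, solve_sympd(fit$Cbar, fit$Gdot_e))
  M <- (M + t(M)) / 2
  J0 <- beta_free_jacobian(free_from_beta(fit$beta0))
  J1 <- beta_free_jacobian(free_from_beta(fit$beta1))
  Tm <- matrix(0, k, k - 2L)
  Tm[seq_len(p), seq_len(p - 1)] <- J0
  Tm[p + seq_len(p), p - 1 + seq_len(p - 1)] <- J1
  diag_idx <- 2 * p + seq_len(2 * d)
  Tm[cbind(diag_idx, 2 * (p - 1) + seq_len(2 * d))] <- 1
  Mf <- crossprod(Tm, M %*% Tm)
  ev <- eigen(Mf, symmetric = TRUE)
  if (min(ev$values) < max(ev$values) * 1e-12) {
    dir <- abs(ev$vectors[, which.min(ev$values)])
    labs <- theta_labels(p, d)[-c(1, p + 1)]
    stop("singular QIF information; weakly identified direction loads on: ",
         paste(labs[order(-dir)[1:3]], collapse = ", "))
  }
  avar_free <- ev$vectors %*% (t(ev$vectors) / ev$values)
  vcov <- Tm %*% avar_free %*% t(Tm)
  se_un <- tryCatch(sqrt(pmax(0, diag(solve(M)))),
                    error = function(e) rep(NA_real_, k))
  list(se = sqrt(pmax(0, diag(vcov))), vcov = vcov,
       se_unconstrained = se_un)
}

#' Wald confidence intervals for the fitted parameters
#'
#' `theta_j +/- z_{1-alpha/2} SE_j` using the sphere-projected standard
#' errors. Zero-width intervals (degenerate SE) are flagged.
#'
#' @param fit a `gfvicm_fit` with standard errors.
#' @param level confidence level.
#' @return Data frame with `parameter`, `estimate`, `se`, `lower`,
#'   `upper`, `degenerate`.
#' @export
coverage_interval <- function(fit, level = 0.95) {
  if (is.null(fit$se)) stop("fit carries no standard errors")
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(parameter = names(fit$theta),
             estimate = unname(fit$theta), se = fit$se,
             lower = unname(fit$theta) - z * fit$se,
             upper = unname(fit$theta) + z * fit$se,
             degenerate = fit$se == 0)
}

#' BIC for a QIF model
#'
#' `Q(theta_hat) + (r - k) log N`, the Schwarz criterion with the QIF
#' objective standing in for twice the negative log-likelihood; with `h`
#' basis matrices the penalty uses r - k = (h - 1) k.
#'
#' @param q_value QIF objective at the optimum.
#' @param r number of estimating equations (`h k`).
#' @param k number of parameters.
#' @param N number of subjects.
#' @return Scalar BIC value.
#' @export
qif_bic <- function(q_value, r, k, N) {
  if (r <= k)
    stop("BIC requires over-identification (r > k); got r = ", r,
         ", k = ", k)
  q_value + (r - k) * log(N)
}

#' QIF goodness-of-fit test
#'
#' `Q(theta_hat)` is asymptotically chi-square with r - k degrees of
#' freedom when the mean model holds, giving an over-identification
#' goodness-of-fit test.
#'
#' @param fit a `gfvicm_fit` from an over-identified model (`h >= 2`).
#' @return Object of class `gfvicm_test`.
#' @export
goodness_of_fit <- function(fit) {
  if (fit$r <= fit$k) stop("goodness-of-fit requires r > k")
  df <- fit$r - fit$k
  structure(list(statistic = fit$Q, df = df,
                 p_value = stats::pchisq(fit$Q, df, lower.tail = FALSE),
                 method = "QIF goodness-of-fit (over-identification) test",
                 null_fit = NULL, alt_fit = fit), class = "gfvicm_test")
}

#' @export
print.gfvicm_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$null_fit))
    cat(sprintf("  Q_N(null) = %.4f, Q_N(full) = %.4f\n",
                x$null_fit$Q, x$alt_fit$Q))
  invisible(x)
}

#' QIF difference test for a nested null on the spline coefficients
#'
#' Tests `H0: psi = 0` for a subvector `psi` of `gamma1` by refitting
#' under the constraint and comparing QIF values:
#' `T = Q(theta_tilde) - Q(theta_hat)` is asymptotically chi-square with
#' `d1 = length(psi)` degrees of freedom. A small negative statistic
#' (numerical error) is floored at zero with a warning; a large negative
#' one signals an optimizer failure and raises an error.
#'
#' @param data a `gfvicm_data` object.
#' @param constrain indices of `gamma1` fixed to zero under the null.
#' @param structure,degree,n_knots,lambda,control passed to [gfvicm_fit()].
#' @param alt_fit optional pre-computed unconstrained fit (saves one fit).
#' @param profile `"global"` (default) re-estimates every remaining
#'   parameter freely under the null, so both Q values are minimizers of
#'   the QIF as defined; this statistic is well calibrated but can lose
#'   power because the constrained fit may rotate the interaction index
#'   to a direction in which the ridge function looks linear. `"local"`
#'   keeps the alternative's spline design and profiles the loadings only
#'   inside a box of half-width `10/sqrt(N)` (sphere chart) around the
#'   unconstrained estimate, which blocks that concealment: far more
#'   powerful, but its null distribution is anti-conservative in moderate
#'   samples (see the methods vignette).
#' @return Object of class `gfvicm_test` carrying both fits.
#' @export
nested_test <- function(data, constrain,
                        structure = c("ar1", "exchangeable", "independence"),
                        degree = 2L, n_knots = 3L, lambda = 0,
                        control = gfvicm_control(), alt_fit = NULL,
                        profile = c("global", "local")) {
  structure <- match.arg(structure)
  profile <- match.arg(profile)
  d <- degree + n_knots + 1L
  constrain <- sort(unique(as.integer(constrain)))
  if (!length(constrain) || any(constrain < 1L | constrain > d))
    stop("constrain must index gamma1 components (1..", d, ")")
  if (is.null(alt_fit))
    alt_fit <- gfvicm_fit(data, structure, degree, n_knots, lambda,
                          control = control, compute_se = FALSE)
  gfree <- setdiff(seq_len(d), constrain)
  if (profile == "global") {
    # the spline coefficients are re-initialized from the constrained
    # independence-working fit (not warm-started from the alternative):
    # starting at the unconstrained optimum traps the constrained search
    # in a worse basin and inflates the statistic
    null_fit <- gfvicm_fit(data, structure, degree, n_knots, lambda,
                           control = control, compute_se = FALSE,
                           gamma1_free = gfree,
                           init = list(beta0 = alt_fit$beta0,
                                       beta1 = alt_fit$beta1))
  } else {
    null_fit <- gfvicm_fit(data, structure, degree, n_knots, lambda,
                           control = control, compute_se = FALSE,
                           gamma1_free = gfree,
                           init = list(beta0 = alt_fit$beta0,
                                       beta1 = alt_fit$beta1),
                           fix_knots = list(knots0 = alt_fit$knots0,
                                            knots1 = alt_fit$knots1),
                           beta_box = 10 / sqrt(data$N))
  }
  stat <- null_fit$Q - alt_fit$Q
  if (stat < 0) {
    # with the weight matrix re-estimated at each fit, the constrained Q
    # can fall below the unconstrained one in finite samples (the weight
    # at a misspecified point absorbs the misfit); the difference carries
    # no evidence against the null, so it is floored at zero
    warning("negative QIF difference (", signif(stat, 3),
            ") floored at zero")
    stat <- 0
  }
  df <- length(constrain)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = "QIF difference test (nested spline coefficients)",
                 null_fit = null_fit, alt_fit = alt_fit),
            class = "gfvicm_test")
}

#' Test linearity of the gene-environment interaction function
#'
#' Tests `H0: m1(u) = gamma10 + gamma11 u` against the full spline
#' alternative by zeroing every higher-order and knot coefficient of
#' `gamma1` (the baseline function `m0` and both loading vectors are
#' re-estimated under the null). The statistic
#' `T_N = Q_N(theta_tilde) - Q_N(theta_hat)` is asymptotically chi-square
#' with `K + q - 1` degrees of freedom.
#'
#' @inheritParams nested_test
#' @return Object of class `gfvicm_test`.
#' @export
linearity_test <- function(data,
                           structure = c("ar1", "exchangeable",
                                         "independence"),
                           degree = 2L, n_knots = 3L, lambda = 0,
                           control = gfvicm_control(), alt_fit = NULL,
                           profile = c("global", "local")) {
  structure <- match.arg(structure)
  d <- degree + n_knots + 1L
  nested_test(data, constrain = 3:d, structure = structure,
              degree = degree, n_knots = n_knots, lambda = lambda,
              control = control, alt_fit = alt_fit,
              profile = match.arg(profile))
}

#' Select the spline configuration by BIC
#'
#' Fits every candidate `(q, K)` (with `lambda` chosen per candidate by
#' GCV when `lambda = "gcv"`) and returns the configuration minimizing
#' `Q(theta_hat) + (r - k) log N`.
#'
#' @param data a `gfvicm_data` object.
#' @param structure working-correlation structure (must be
#'   over-identified, i.e. not `"independence"`, for BIC to exist).
#' @param candidates data frame or matrix with columns `degree`, `n_knots`.
#' @param lambda fixed penalty, or `"gcv"` for per-candidate selection.
#' @param lambda_grid grid used when `lambda = "gcv"`.
#' @param control passed to [gfvicm_fit()].
#' @return List with `degree`, `n_knots`, `lambda`, `fit`, and a `table`
#'   of BIC values (one row per candidate, `NA` for failed fits).
#' @export
select_spline_config <- function(data,
                                 structure = c("ar1", "exchangeable"),
                                 candidates = expand.grid(degree = 1:3,
                                                          n_knots = 0:5),
                                 lambda = 0, lambda_grid = default_lambda_grid(),
                                 control = gfvicm_control()) {
  structure <- match.arg(structure)
  candidates <- as.data.frame(candidates)
  stopifnot(nrow(candidates) >= 1L,
            all(c("degree", "n_knots") %in% names(candidates)))
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    q <- candidates$degree[i]; K <- candidates$n_knots[i]
    out <- try({
      if (identical(lambda, "gcv")) {
        sel <- gcv_select_lambda(data, structure, q, K, lambda_grid,
                                 control = control)
        lam <- sel$lambda; fit <- sel$fit
      } else {
        lam <- lambda
        fit <- gfvicm_fit(data, structure, q, K, lam, control = control,
                          compute_se = FALSE)
      }
      list(fit = fit, lambda = lam,
           bic = qif_bic(fit$Q, fit$r, fit$k, fit$N),
           converged = fit$converged)
    }, silent = TRUE)
    if (inherits(out, "try-error"))
      list(fit = NULL, lambda = NA_real_, bic = NA_real_, converged = FALSE,
           error = attr(out, "condition")$message)
    else out
  })
  tab <- data.frame(degree = candidates$degree, n_knots = candidates$n_knots,
                    lambda = vapply(rows, function(r) r$lambda, 0),
                    bic = vapply(rows, function(r) r$bic, 0),
                    converged = vapply(rows, function(r) isTRUE(r$converged),
                                       TRUE))
  if (all(is.na(tab$bic)))
    stop("all candidate configurations failed to fit:\n",
         paste(vapply(rows, function(r) r$error %||% "?", ""),
               collapse = "\n"))
  best <- which.min(tab$bic)
  fit <- rows[[best]]$fit
  if (is.null(fit$se)) {
    se <- try(asymptotic_se(fit), silent = TRUE)
    if (!inherits(se, "try-error")) {
      fit$se <- se$se; fit$vcov <- se$vcov
      fit$se_unconstrained <- se$se_unconstrained
    }
  }
  list(degree = tab$degree[best], n_knots = tab$n_knots[best],
       lambda = tab$lambda[best], fit = fit, table = tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
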