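# counter-based replicate seeds: reproducible per (scenario, replicate)
# and independent of loop order; kept inside 32-bit integer range
replicate_seed <- function(master, scenario_idx, rep_idx) {
  as.integer((as.numeric(master) * 1000003 + scenario_idx * 131071 +
                rep_idx * 7919) %% 2147483629 + 1)
}

#' Monte Carlo estimation study (bias / SD / SE / coverage)
#'
#' Replicates the generator of [default_truth()] over a grid of
#' scenarios, fits each replicate by [gfvicm_fit()], and summarizes the
#' index loading estimates per component: Bias (mean estimate minus
#' truth), SD (standard deviation across replicates), SE (mean reported
#' sandwich standard error), and CP (percent of nominal 95% Wald
#' intervals covering the truth). Replicates whose fit fails or does not
#' converge are excluded and counted; a scenario losing more than 10% of
#' its replicates is flagged with a warning.
#'
#' @param scenarios data frame with columns `N`, `T_visits`, `maf`,
#'   `rho` (one row per scenario); an optional `n_knots` column
#'   overrides the knot count per scenario.
#' @param reps replicates per scenario (`>= 2`).
#' @param seed master seed; replicate seeds are derived from it by a
#'   counter scheme so scenarios are independently reproducible.
#' @param structure,degree,n_knots,lambda,control fitting configuration
#'   passed to [gfvicm_fit()].
#' @param level confidence level for the coverage intervals.
#' @param progress print a line per scenario.
#' @return List of class `gfvicm_study`: `summary` (one row per scenario
#'   and loading component, with both projected and unprojected
#'   SE/coverage), `estimates` (replicate-level estimates and SEs), and
#'   `failures`.
#' @export
run_estimation_study <- function(scenarios, reps = 200L, seed = 1L,
                                 structure = "ar1", degree = 2L,
                                 n_knots = 3L, lambda = 0,
                                 control = gfvicm_control(theta_tol = 1e-4,
                                                          obj_tol = 1e-7),
                                 level = 0.95, progress = FALSE) {
  scenarios <- as.data.frame(scenarios)
  stopifnot(all(c("N", "T_visits", "maf", "rho") %in% names(scenarios)),
            reps >= 2)
  if (reps < 30)
    warning("very small replicate count (", reps,
            "): Monte Carlo summaries will be noisy")
  z <- stats::qnorm(1 - (1 - level) / 2)
  all_est <- list(); all_sum <- list(); failures <- list()
  for (s in seq_len(nrow(scenarios))) {
    sc <- scenarios[s, ]
    K_s <- if ("n_knots" %in% names(scenarios)) sc$n_knots else n_knots
    truth <- default_truth(N = sc$N, T_visits = sc$T_visits,
                           maf = sc$maf, rho = sc$rho)
    true_beta <- c(truth$beta0, truth$beta1)
    comp <- theta_labels(truth$p, 1L)[seq_len(2 * truth$p)]
    est <- se <- seu <- matrix(NA_real_, reps, 2 * truth$p,
                               dimnames = list(NULL, comp))
    ok <- logical(reps)
    for (j in seq_len(reps)) {
      set.seed(replicate_seed(seed, s, j))
      res <- try({
        dat <- simulate_dataset(truth, warn = FALSE)
        gfvicm_fit(dat, structure, degree, K_s, lambda,
                   control = control)
      }, silent = TRUE)
      if (inherits(res, "try-error") || !res$converged ||
          is.null(res$se) || anyNA(res$se)) next
      ok[j] <- TRUE
      est[j, ] <- c(res$beta0, res$beta1)
      se[j, ] <- res$se[seq_len(2 * truth$p)]
      seu[j, ] <- (res$se_unconstrained %||%
                     rep(NA_real_, res$k))[seq_len(2 * truth$p)]
    }
    n_ok <- sum(ok)
    if (n_ok < 0.9 * reps)
      warning(sprintf("scenario %d: %d of %d replicates excluded",
                      s, reps - n_ok, reps))
    cover <- abs(est - matrix(true_beta, reps, 2 * truth$p,
                              byrow = TRUE)) <= z * se
    cover_u <- abs(est - matrix(true_beta, reps, 2 * truth$p,
                                byrow = TRUE)) <= z * seu
    all_sum[[s]] <- data.frame(
      N = sc$N, T_visits = sc$T_visits, maf = sc$maf, rho = sc$rho,
      component = comp, truth = true_beta,
      bias = colMeans(est[ok, , drop = FALSE]) - true_beta,
      sd = apply(est[ok, , drop = FALSE], 2, stats::sd),
      se = colMeans(se[ok, , drop = FALSE], na.rm = TRUE),
      cp = 100 * colMeans(cover[ok, , drop = FALSE], na.rm = TRUE),
      se_unconstrained = colMeans(seu[ok, , drop = FALSE], na.rm = TRUE),
      cp_unconstrained = 100 * colMeans(cover_u[ok, , drop = FALSE],
                                        na.rm = TRUE),
      n_used = n_ok, row.names = NULL)
    all_est[[s]] <- data.frame(scenario = s, rep = seq_len(reps), ok = ok,
                               est, se = se)
    failures[[s]] <- reps - n_ok
    if (progress)
      message(sprintf("scenario %d/%d done (%d/%d replicates used)",
                      s, nrow(scenarios), n_ok, reps))
  }
  structure(list(summary = do.call(rbind, all_sum),
                 estimates = do.call(rbind, all_est),
                 failures = unlist(failures), reps = reps, seed = seed),
            class = "gfvicm_study")
}

#' @export
print.gfvicm_study <- function(x, ...) {
  cat(sprintf("Monte Carlo estimation study: %d replicates per scenario\n",
              x$reps))
  df <- x$summary
  df[c("truth", "bias", "sd", "se")] <-
    lapply(df[c("truth", "bias", "sd", "se")], round, 4)
  df$cp <- round(df$cp, 1)
  print(df[c("N", "T_visits", "maf", "component", "truth", "bias", "sd",
             "se", "cp")], row.names = FALSE)
  invisible(x)
}

#' Monte Carlo size/power study for the linearity test
#'
#' Generates data under `H1_tau: m1 = m10 + tau (m1 - m10)` over a grid
#' of `tau` (with `tau = 0` the linear null, giving empirical size) and
#' records the rejection rate of [linearity_test()] at level `alpha`.
#'
#' @param tau_grid interpolation weights; must include 0.
#' @param scenario list or one-row data frame with `N`, `T_visits`,
#'   `maf`, `rho`.
#' @param reps replicates per `tau` (scalar, or vector along `tau_grid`).
#' @param alpha test level.
#' @param seed master seed (counter-derived per replicate).
#' @param structure,degree,n_knots,lambda,control fitting configuration.
#' @param progress print a line per `tau`.
#' @return List of class `gfvicm_power`: `rates` (`tau`,
#'   `rejection_rate`, `n_used`) and `details` (replicate-level
#'   statistics and p-values, for calibration checks).
#' @export
run_size_power_study <- function(tau_grid, scenario, reps = 200L,
                                 alpha = 0.05, seed = 1L,
                                 structure = "ar1", degree = 2L,
                                 n_knots = 3L, lambda = 0,
                                 control = gfvicm_control(theta_tol = 1e-4,
                                                          obj_tol = 1e-7),
                                 progress = FALSE) {
  stopifnot(0 %in% tau_grid, alpha > 0, alpha < 1)
  scenario <- as.list(as.data.frame(scenario))
  reps_tau <- rep_len(reps, length(tau_grid))
  det <- list()
  for (t_idx in seq_along(tau_grid)) {
    tau <- tau_grid[t_idx]
    reps <- reps_tau[t_idx]
    truth <- default_truth(N = scenario$N, T_visits = scenario$T_visits,
                           maf = scenario$maf, rho = scenario$rho,
                           tau = tau)
    stat <- pval <- rep(NA_real_, reps)
    for (j in seq_len(reps)) {
      set.seed(replicate_seed(seed, 1000L + t_idx, j))
      res <- try({
        dat <- simulate_dataset(truth, warn = FALSE)
        linearity_test(dat, structure, degree, n_knots, lambda,
                       control = control)
      }, silent = TRUE)
      if (inherits(res, "try-error")) next
      stat[j] <- res$statistic
      pval[j] <- res$p_value
    }
    det[[t_idx]] <- data.frame(tau = tau, rep = seq_len(reps),
                               statistic = stat, p_value = pval)
    if (progress)
      message(sprintf("tau = %g done (%d/%d replicates used)", tau,
                      sum(!is.na(pval)), reps))
  }
  details <- do.call(rbind, det)
  rates <- do.call(rbind, lapply(split(details, details$tau), function(d) {
    data.frame(tau = d$tau[1],
               rejection_rate = mean(d$p_value < alpha, na.rm = TRUE),
               n_used = sum(!is.na(d$p_value)))
  }))
  rownames(rates) <- NULL
  structure(list(rates = rates, details = details, alpha = alpha,
                 df = scenario_linearity_df(degree, n_knots),
                 seed = seed), class = "gfvicm_power")
}

scenario_linearity_df <- function(degree, n_knots) degree + n_knots - 1L

#' @export
print.gfvicm_power <- function(x, ...) {
  cat(sprintf(
    "Linearity test size/power study (alpha = %g, chi-square df = %d)\n",
    x$alpha, x$df))
  print(x$rates, row.names = FALSE)
  invisible(x)
}
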