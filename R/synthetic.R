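#' Configuration for the national-variety-testing-style MET data generator
#'
#' Declares a synthetic national-variety-testing scenario: environments are
#' the crossing of locations (assigned round-robin to regions) with years;
#' varieties enter in yearly cohorts and are retired by a survival process,
#' producing the moving window of connectivity typical of testing programs
#' (older and newer varieties never meet directly but are linked through
#' intermediate cohorts; a retired variety never returns).  Genetic effects
#' follow a factor analytic law of order `k_true`: first-factor loadings
#' are positive, higher factors are centred, and specific variances are
#' uniform on `psi_range`.  Trial error variances are log-uniform on
#' `error_var_range`, reproducing the orders-of-magnitude heterogeneity of
#' real programs, and each trial carries `replicates` complete blocks, so
#' a variety-mean record has error variance `error_var / replicates` and
#' weight `replicates / error_var`.
#'
#' @param n_locations,n_years,n_regions Layout of the program
#'   (`t = n_locations * n_years` environments).
#' @param m Total number of varieties across all cohorts.
#' @param k_true Order of the generating factor analytic model.
#' @param loading1_range Range of the (positive) first-factor loadings,
#'   t/ha per unit score.
#' @param loading_sd Standard deviation of loadings for factors 2..k.
#' @param psi_range Range of the specific variances, (t/ha)^2.
#' @param error_var_range Range of plot error variances, (t/ha)^2, sampled
#'   log-uniformly.
#' @param replicates Complete blocks per trial.
#' @param retention Per-year probability that a variety already in the
#'   system is kept for the next year, in (0, 1].
#' @param entry_rate New varieties entering each year after the first;
#'   defaults to about 15 percent of `m`.
#' @param trial_mean_range Range of true trial mean yields, t/ha.
#' @param loading_mean_cor If nonzero, mixes the first-factor loadings
#'   toward the (scaled) trial means with this correlation, emulating the
#'   tendency of high-yielding trials to discriminate varieties most.
#'   Default 0 (off).
#' @param seed Integer seed; every draw is deterministic given the config.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(n_locations = 5, n_years = 5, n_regions = 2,
                       m = 100, k_true = 2,
                       loading1_range = c(0.2, 0.7), loading_sd = 0.15,
                       psi_range = c(0.02, 0.1),
                       error_var_range = c(0.01, 2),
                       replicates = 3, retention = 0.75,
                       entry_rate = NULL,
                       trial_mean_range = c(1, 5),
                       loading_mean_cor = 0, seed = 1) {
  if (retention <= 0 || retention > 1) {
    stop_schema("retention must be in (0, 1]")
  }
  if (any(error_var_range <= 0) || any(psi_range < 0) ||
      any(loading1_range <= 0)) {
    stop_schema("variance and loading ranges must be positive")
  }
  if (replicates < 1) stop_schema("replicates must be >= 1")
  if (is.null(entry_rate)) entry_rate <- max(1L, round(0.15 * m))
  if (n_years > 1 && m - entry_rate * (n_years - 1) < 2) {
    stop_schema("m too small for the entry rate: initial cohort < 2")
  }
  structure(
    list(n_locations = n_locations, n_years = n_years,
         n_regions = n_regions, m = m, k_true = k_true,
         loading1_range = loading1_range, loading_sd = loading_sd,
         psi_range = psi_range, error_var_range = error_var_range,
         replicates = replicates, retention = retention,
         entry_rate = entry_rate, trial_mean_range = trial_mean_range,
         loading_mean_cor = loading_mean_cor, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a second-stage MET dataset with known truth
#'
#' Draws a complete synthetic dataset from a [sim_config()]: the true
#' loadings, specific variances and scores; the variety incidence from the
#' cohort entry/retention process; and the observed variety-mean records
#' `y_ij = trial_mean_j + u_ij + e_ij` with `var(e_ij) =
#' error_var_j / replicates` and weight `replicates / error_var_j`.
#'
#' @param config A [sim_config()] object.
#' @param fixed Optional named list holding any of `Lambda`, `psi`,
#'   `trial_means`, `error_vars` to hold fixed instead of drawing them --
#'   useful for replicated simulations from one set of true parameters
#'   (only scores, residuals, incidence and measurement noise re-drawn).
#' @return A list with `data` (a [met_data]) and `truth` (a `sim_truth`:
#'   `Lambda`, `psi`, `Ge`, `scores` (m x k), `u` (m x t), `trial_means`,
#'   `error_vars`, `incidence` (m x t logical)).
#' @export
simulate_met <- function(config, fixed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_met_impl(config, fixed))
}

simulate_met_impl <- function(cf, fixed = NULL) {
  t <- cf$n_locations * cf$n_years
  locations <- sprintf("Loc%02d", seq_len(cf$n_locations))
  regions <- sprintf("R%d", ((seq_len(cf$n_locations) - 1) %% cf$n_regions) + 1)
  years <- 2000L + seq_len(cf$n_years)
  env <- tidyr::expand_grid(location = locations, year = years) |>
    dplyr::mutate(
      region = regions[match(.data$location, locations)],
      env_id = paste(.data$location, .data$year, sep = "_")
    )

  # cohorts: initial block, then entry_rate new varieties per later year
  m <- cf$m
  entry_year <- rep(1L, m)
  if (cf$n_years > 1) {
    later <- rep(2:cf$n_years, each = cf$entry_rate)
    n_later <- min(length(later), m - 2L)
    entry_year[(m - n_later + 1):m] <- later[seq_len(n_later)]
  }
  var_ids <- sprintf("V%03d", seq_len(m))
  # survival: once dropped, never resurrected
  active <- matrix(FALSE, m, cf$n_years)
  for (i in seq_len(m)) {
    yr <- entry_year[i]
    active[i, yr] <- TRUE
    while (yr < cf$n_years && stats::runif(1) < cf$retention) {
      yr <- yr + 1L
      active[i, yr] <- TRUE
    }
  }

  Lambda <- matrix(0, t, cf$k_true)
  Lambda[, 1] <- stats::runif(t, cf$loading1_range[1], cf$loading1_range[2])
  if (cf$k_true > 1) {
    Lambda[, -1] <- stats::rnorm(t * (cf$k_true - 1), 0, cf$loading_sd)
  }
  trial_means <- stats::runif(t, cf$trial_mean_range[1],
                              cf$trial_mean_range[2])
  if (cf$loading_mean_cor != 0) {
    z <- as.numeric(scale(trial_means))
    l1 <- as.numeric(scale(Lambda[, 1]))
    rho <- cf$loading_mean_cor
    mix <- rho * z + sqrt(1 - rho^2) * l1
    Lambda[, 1] <- mean(Lambda[, 1]) + stats::sd(Lambda[, 1]) * mix
    Lambda[, 1] <- pmax(Lambda[, 1], 0.05)
  }
  psi <- stats::runif(t, cf$psi_range[1], cf$psi_range[2])
  error_vars <- exp(stats::runif(t, log(cf$error_var_range[1]),
                                 log(cf$error_var_range[2])))
  if (!is.null(fixed)) {
    if (!is.null(fixed$Lambda)) Lambda <- unname(as.matrix(fixed$Lambda))
    if (!is.null(fixed$psi)) psi <- unname(fixed$psi)
    if (!is.null(fixed$trial_means)) trial_means <- unname(fixed$trial_means)
    if (!is.null(fixed$error_vars)) error_vars <- unname(fixed$error_vars)
  }
  Ge <- tcrossprod(Lambda) + diag(psi, t)

  scores <- matrix(stats::rnorm(m * cf$k_true), m, cf$k_true)
  deltas <- matrix(stats::rnorm(m * t), m, t) %*% diag(sqrt(psi), t)
  u <- scores %*% t(Lambda) + deltas

  year_index <- match(env$year, years)
  incidence <- active[, year_index, drop = FALSE]
  dimnames(incidence) <- list(var_ids, env$env_id)
  obs <- which(incidence, arr.ind = TRUE)
  meas_sd <- sqrt(error_vars[obs[, 2]] / cf$replicates)
  rec <- tibble::tibble(
    variety = var_ids[obs[, 1]],
    env_id = env$env_id[obs[, 2]],
    mean = trial_means[obs[, 2]] + u[obs] + stats::rnorm(nrow(obs), 0, meas_sd),
    weight = cf$replicates / error_vars[obs[, 2]]
  ) |>
    dplyr::arrange(match(.data$env_id, env$env_id), .data$variety)

  env_reg <- env |>
    dplyr::mutate(trial_mean_yield = trial_means, error_ms = error_vars) |>
    dplyr::select("env_id", "location", "year", "region",
                  "trial_mean_yield", "error_ms")
  data <- met_data(rec, environments = env_reg)

  comps <- connectivity_components(met_connectivity(data))
  if (length(comps) > 1) {
    warning("simulated dataset is disconnected (", length(comps),
            " components); component sizes: ",
            paste(lengths(comps), collapse = ", "), call. = FALSE)
  }
  dimnames(u) <- list(var_ids, env$env_id)
  dimnames(scores) <- list(var_ids, paste0("fac", seq_len(cf$k_true)))
  dimnames(Ge) <- list(env$env_id, env$env_id)
  dimnames(Lambda) <- list(env$env_id, paste0("fac", seq_len(cf$k_true)))
  truth <- structure(
    list(Lambda = Lambda, psi = stats::setNames(psi, env$env_id), Ge = Ge,
         scores = scores, u = u,
         trial_means = stats::setNames(trial_means, env$env_id),
         error_vars = stats::setNames(error_vars, env$env_id),
         incidence = incidence, config = cf),
    class = "sim_truth"
  )
  list(data = data, truth = truth)
}

#' Simulate plot-level trial data consistent with a simulated truth
#'
#' Lays out each trial as a randomized complete block design with
#' `replicates` blocks over the varieties active in its year, and draws
#' `yield = trial_mean + u_true + block effect + plot error` with plot
#' error variance `error_var_j`.  Running [analyze_trial()] on the output
#' recovers variety means and weights consistent with the second-stage
#' records of [simulate_met()].
#'
#' @param config The [sim_config()] used for [simulate_met()].
#' @param truth The `sim_truth` it returned.
#' @return A tibble with columns `trial`, `replicate`, `variety`, `yield`.
#' @export
simulate_plots <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  withr::with_seed(config$seed + 1L, {
    env_ids <- colnames(truth$incidence)
    out <- purrr::map(seq_along(env_ids), function(j) {
      vars <- rownames(truth$incidence)[truth$incidence[, j]]
      if (length(vars) == 0) return(NULL)
      reps <- sprintf("B%d", seq_len(config$replicates))
      # block effects scale with the plot error so a noise-free trial is
      # recovered exactly by the first-stage analysis
      block_eff <- stats::setNames(
        stats::rnorm(length(reps), 0, 0.25 * sqrt(truth$error_vars[j])),
        reps
      )
      grid <- tidyr::expand_grid(replicate = reps, variety = vars)
      grid$trial <- env_ids[j]
      grid$yield <- truth$trial_means[j] + truth$u[grid$variety, j] +
        block_eff[grid$replicate] +
        stats::rnorm(nrow(grid), 0, sqrt(truth$error_vars[j]))
      grid[c("trial", "replicate", "variety", "yield")]
    })
    dplyr::bind_rows(out)
  })
}

# best orthogonal alignment of estimated loadings to the truth; FA loadings
# are identified only up to rotation
procrustes_rotation <- function(L_est, L_true) {
  sv <- svd(crossprod(L_est, L_true))
  sv$u %*% t(sv$v)
}

#' Recovery metrics of a fit against the simulated truth
#'
#' Compares a fitted model with the generating parameters: relative
#' Frobenius error of `G_e`, absolute error of the percentage of variance
#' accounted for, per-factor correlations between estimated and true
#' scores after orthogonal Procrustes alignment of the loadings (the FA
#' parametrization is rotation-identified only), and the empirical
#' accuracy of the total EBLUPs.  If the fitted order differs from the
#' true order (or the fit is not FA), only the `G_e` comparison is made.
#'
#' @param fit A `met_fit` object fitted to the simulated data.
#' @param truth The matching `sim_truth`.
#' @return A tibble with one row: `ge_frob_rel_error`, `vbar_error`,
#'   `score_cor_1` .. `score_cor_k`, `u_cor` (correlation of predicted
#'   with true effects over observed cells).
#' @export
recovery_report <- function(fit, truth) {
  stopifnot(inherits(fit, "met_fit"), inherits(truth, "sim_truth"))
  Ge_t <- truth$Ge[fit$env_ids, fit$env_ids]
  ge_err <- norm(fit$Ge - Ge_t, "F") / norm(Ge_t, "F")
  out <- tibble::tibble(ge_frob_rel_error = ge_err)
  obs <- fit$observed
  ut <- truth$u[fit$var_ids, fit$env_ids]
  out$u_cor <- stats::cor(fit$blups$u[obs], ut[obs])
  if (fit$model$kind == "fa") {
    ve <- variance_explained(fit)
    vbar_true <- 100 * sum(truth$Lambda[fit$env_ids, ]^2) /
      sum(diag(Ge_t))
    out$vbar_error <- ve$v_bar - vbar_true
    if (ncol(fit$estimates$Lambda) == ncol(truth$Lambda)) {
      Q <- procrustes_rotation(fit$estimates$Lambda,
                               truth$Lambda[fit$env_ids, ])
      f_al <- fit$blups$f %*% Q
      st <- truth$scores[fit$var_ids, , drop = FALSE]
      for (r in seq_len(ncol(f_al))) {
        out[[paste0("score_cor_", r)]] <- stats::cor(f_al[, r], st[, r])
      }
    }
  }
  out
}
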