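#' Percentage of genetic variance accounted for by the factors
#'
#' For an FA fit, the per-environment goodness of fit
#' `v_j = 100 * sum_r lambda_rj^2 / (sum_r lambda_rj^2 + psi_j)` and the
#' overall `v_bar = 100 * tr(Lambda Lambda') / tr(Lambda Lambda' + psi)`.
#' Both lie in \[0, 100\]; `v_bar` is the genetic-variance-weighted mean of
#' the `v_j`.  An environment with zero total genetic variance has an
#' undefined `v_j`, reported as `NA` with a warning.
#'
#' @param fit A `met_fit` with an FA structure, or a list with elements
#'   `Lambda` (t x k) and `psi` (length t).
#' @return A list with `v` (tibble `env_id`, `v`) and `v_bar`.
#' @export
variance_explained <- function(fit) {
  if (inherits(fit, "met_fit")) {
    if (fit$model$kind != "fa") {
      stop_validation("variance_explained requires an FA fit")
    }
    Lambda <- fit$estimates$Lambda
    psi <- fit$estimates$psi
    env_ids <- fit$env_ids
  } else {
    Lambda <- fit$Lambda
    psi <- fit$psi
    env_ids <- rownames(Lambda) %||% as.character(seq_len(nrow(Lambda)))
  }
  common <- rowSums(Lambda^2)
  tot <- common + psi
  v <- ifelse(tot > 0, 100 * common / tot, NA_real_)
  if (anyNA(v)) {
    warning("zero total genetic variance for environment(s) ",
            paste(env_ids[is.na(v)], collapse = ", "),
            "; v_j undefined", call. = FALSE)
  }
  list(v = tibble::tibble(env_id = env_ids, v = unname(v)),
       v_bar = 100 * sum(common) / sum(tot))
}

#' Sequential FA model-order selection
#'
#' Fits FA models of increasing order, each warm-started from the previous
#' solution, and stops at the first order whose overall percentage of
#' genetic variance accounted for reaches `vbar_threshold` (default 80), or
#' at `max_order`.  REMLRT against the previous order, AIC and BIC are
#' reported per order for inspection, but the threshold on `v_bar` decides:
#' REMLRT and AIC tend to pick unnecessarily high orders and BIC may
#' underfit.
#'
#' @param data A [met_data] object.
#' @param max_order Highest order to consider (must be below t).
#' @param vbar_threshold Stopping threshold for `v_bar`, percent.
#' @param control A [met_control()] list.
#' @return A `met_order_selection` object: list with `fits` (FA1..),
#'   `summary` (tibble per order: loglik, n_params, aic, bic, v_bar,
#'   REMLRT vs previous order), `chosen` (integer order),
#'   `threshold_reached` (logical).
#' @export
select_order <- function(data, max_order, vbar_threshold = 80,
                         control = met_control()) {
  stopifnot(inherits(data, "met_data"))
  t <- nrow(data$environments)
  if (max_order >= t) stop_schema("max_order must be below t = ", t)
  if (vbar_threshold <= 0 || vbar_threshold > 100) {
    stop_schema("vbar_threshold must be in (0, 100]")
  }
  fits <- list()
  rows <- list()
  chosen <- NA_integer_
  reached <- FALSE
  prev <- NULL
  for (k in seq_len(max_order)) {
    init <- NULL
    if (!is.null(prev)) {
      L <- cbind(prev$estimates$Lambda,
                 0.3 * sqrt(pmax(prev$estimates$psi, VAR_FLOOR)))
      L[fa_mask(t, k)] <- 0
      init <- list(Lambda = L, psi = pmax(0.9 * prev$estimates$psi,
                                          VAR_FLOOR))
      if (length(prev$model$peripheral) > 0) {
        init$sigma2_p <- prev$estimates$sigma2_p
      }
    }
    fit <- tryCatch(
      met_reml(data, vm_fa(k), init = init, control = control),
      error = function(e) e
    )
    if (inherits(fit, "error") || !fit$converged) {
      warning("FA", k, " did not converge; stopping order search",
              call. = FALSE)
      break
    }
    fits[[k]] <- fit
    ve <- variance_explained(fit)
    g <- glance(fit)
    lrt <- if (!is.null(prev)) remlrt(prev, fit) else
      tibble::tibble(statistic = NA_real_, df = NA_integer_,
                     p_value = NA_real_)
    rows[[k]] <- dplyr::mutate(g, v_bar = ve$v_bar,
                               remlrt_stat = lrt$statistic,
                               remlrt_df = lrt$df,
                               remlrt_p = lrt$p_value)
    prev <- fit
    if (ve$v_bar >= vbar_threshold) {
      chosen <- k
      reached <- TRUE
      break
    }
  }
  if (!reached && length(fits) > 0) chosen <- length(fits)
  if (length(fits) == 0) stop_validation("no FA model could be fitted")
  structure(
    list(fits = fits, summary = dplyr::bind_rows(rows), chosen = chosen,
         threshold_reached = reached, vbar_threshold = vbar_threshold),
    class = "met_order_selection"
  )
}

#' @export
print.met_order_selection <- function(x, ...) {
  cat("<met_order_selection> chosen order ", x$chosen,
      if (!x$threshold_reached) " (threshold not reached)", "\n", sep = "")
  print(x$summary[c("model", "loglik", "n_params", "aic", "bic", "v_bar")])
  invisible(x)
}

#' Rotate an FA solution to principal-component form
#'
#' The estimation constraint (zero upper triangle of Lambda) is convenient
#' for fitting but arbitrary for interpretation.  This rotates the loadings
#' and scores by the eigenvectors of `Lambda' Lambda`, so the first rotated
#' factor accounts for the maximum genetic covariance, the second the next
#' largest subject to orthogonality, and so on.  The sign of each rotated
#' factor is fixed so its loading sum is non-negative.  The PEV matrix of
#' the rotated scores is the orthogonal transform of the unrotated score
#' PEV -- identical to what a refit with the rotated loadings held fixed
#' would give, because the likelihood is invariant to the rotation.
#'
#' @param fit A converged FA `met_fit`.
#' @return A `met_rotation` object: `rotated_loadings` (t x k),
#'   `rotated_scores` (m x k), `rotation` (k x k orthogonal),
#'   `score_pev` (per-variety k x k blocks), `factor_variance_pct`
#'   (percent of total genetic variance per rotated factor), and
#'   `score_se` (tibble of rotated scores with standard errors).
#' @export
rotate_pc <- function(fit) {
  stopifnot(inherits(fit, "met_fit"))
  if (fit$model$kind != "fa") stop_validation("rotate_pc requires an FA fit")
  Lambda <- fit$estimates$Lambda
  psi <- fit$estimates$psi
  k <- ncol(Lambda)
  ev <- eigen(crossprod(Lambda), symmetric = TRUE)
  if (k > 1 && any(abs(diff(ev$values)) < 1e-10 * max(ev$values))) {
    warning("repeated eigenvalues: rotated factors are determined only up ",
            "to an orthonormal basis of the tied subspace", call. = FALSE)
  }
  V <- ev$vectors
  Lstar <- Lambda %*% V
  s <- sign(colSums(Lstar))
  s[s == 0] <- 1
  Lstar <- sweep(Lstar, 2, s, `*`)
  V <- sweep(V, 2, s, `*`)
  fstar <- fit$blups$f %*% V
  pev <- purrr::map(fit$blups$pev_f, function(p) crossprod(V, p %*% V))
  tot <- sum(Lambda^2) + sum(psi)
  colnames(Lstar) <- paste0("fac", seq_len(k))
  colnames(fstar) <- colnames(Lstar)
  score_se <- tibble::as_tibble(fstar, rownames = "variety") |>
    tidyr::pivot_longer(-"variety", names_to = "factor",
                        values_to = "score") |>
    dplyr::mutate(factor = as.integer(sub("^fac", "", .data$factor)))
  score_se$se <- purrr::map2_dbl(
    match(score_se$variety, fit$var_ids), score_se$factor,
    function(i, r) sqrt(max(pev[[i]][r, r], 0))
  )
  structure(
    list(
      rotated_loadings = Lstar,
      rotated_scores = fstar,
      rotation = V,
      score_pev = pev,
      factor_variance_pct = 100 * ev$values / tot,
      score_se = score_se,
      env_ids = fit$env_ids,
      var_ids = fit$var_ids
    ),
    class = "met_rotation"
  )
}

#' @export
print.met_rotation <- function(x, ...) {
  cat("<met_rotation> ", ncol(x$rotated_loadings),
      " factors; % of total genetic variance: ",
      paste(sprintf("%.1f", x$factor_variance_pct), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Variety predictions from a rotated FA fit
#'
#' Decomposes the EBLUP of every variety-by-environment effect as
#' `u = beta + delta`: the regression component `beta_ij = sum_r
#' lambda*_rj f*_ri` captures the repeatable part driven by the common
#' factors and is defined for every cell, observed or not, while the
#' genetic regression residual `delta` is environment-specific and zero
#' for unobserved cells.  Grower-facing reporting uses `beta`, which gives
#' compatible predictions for all environments; its prediction error
#' variance comes from the rotated-score PEV as
#' `V_beta = (Lambda* x I) V_f* (Lambda*' x I)` (variety-diagonal blocks),
#' ignoring uncertainty in the estimated loadings.
#'
#' @param fit A converged FA `met_fit`.
#' @param rotation A `met_rotation` from [rotate_pc()]; computed if absent.
#' @return A `met_predictions` object: tibble columns `variety`, `env_id`,
#'   `beta`, `delta`, `total`, `beta_se`, `observed` in `$table`, plus the
#'   rotated solution and per-variety `beta` PEV blocks.
#' @export
fa_predictions <- function(fit, rotation = NULL) {
  stopifnot(inherits(fit, "met_fit"))
  if (fit$model$kind != "fa") {
    stop_validation("fa_predictions requires an FA fit")
  }
  if (is.null(rotation)) rotation <- rotate_pc(fit)
  Lstar <- rotation$rotated_loadings
  fstar <- rotation$rotated_scores
  beta <- fstar %*% t(Lstar)
  delta <- fit$blups$delta
  total <- beta + delta
  beta_pev <- purrr::map(rotation$score_pev, function(p) {
    Lstar %*% p %*% t(Lstar)
  })
  beta_se <- do.call(rbind, purrr::map(beta_pev, function(p) {
    sqrt(pmax(diag(p), 0))
  }))
  dimnames(beta) <- list(fit$var_ids, fit$env_ids)
  dimnames(total) <- dimnames(beta)
  dimnames(beta_se) <- dimnames(beta)
  tab <- tibble::as_tibble(beta, rownames = "variety") |>
    tidyr::pivot_longer(-"variety", names_to = "env_id",
                        values_to = "beta")
  tab$delta <- as.vector(t(delta))
  tab$total <- as.vector(t(total))
  tab$beta_se <- as.vector(t(beta_se))
  tab$observed <- as.vector(t(fit$observed))
  structure(
    list(table = tab, beta = beta, delta = delta, total = total,
         beta_pev = beta_pev, observed = fit$observed,
         rotation = rotation, env_ids = fit$env_ids,
         var_ids = fit$var_ids, environments = fit$environments),
    class = "met_predictions"
  )
}

#' @export
print.met_predictions <- function(x, ...) {
  cat("<met_predictions> ", length(x$var_ids), " varieties x ",
      length(x$env_ids), " environments\n", sep = "")
  invisible(x)
}

#' @export
tidy.met_predictions <- function(x, ...) x$table

#' Genetic correlation matrix between environments
#'
#' Converts a between-environment genetic variance matrix to the
#' correlation matrix `C_e = D_e G_e D_e`, `D_e` the diagonal matrix of
#' reciprocal square roots of the genetic variances.  Pairs of environments
#' with low or negative genetic correlation re-rank the varieties.
#'
#' @param x A `met_fit`, or a symmetric positive (semi)definite matrix
#'   with strictly positive diagonal.
#' @return The correlation matrix with unit diagonal.
#' @export
genetic_correlation <- function(x) {
  G <- if (inherits(x, "met_fit")) x$Ge else as.matrix(x)
  if (nrow(G) != ncol(G)) stop_validation("G_e must be square")
  d <- diag(G)
  if (any(d <= 0)) {
    nm <- rownames(G) %||% as.character(seq_len(nrow(G)))
    stop_validation("zero genetic variance for environment ",
                    nm[which(d <= 0)[1]])
  }
  C <- stats::cov2cor(G)
  C[C > 1] <- 1
  C[C < -1] <- -1
  C
}

#' Accuracy of variety predictions
#'
#' The model-based accuracy of the total EBLUP of variety i in environment
#' j is the correlation between true and predicted effect,
#' `sqrt(1 - PEV(u_ij) / Ge[j, j])` -- the standard individual-prediction
#' accuracy of animal breeding.  Per-environment values average the
#' per-cell accuracies over the varieties grown in the environment.
#'
#' @param fit A `met_fit` object.
#' @return A list with `per_cell` (tibble `variety`, `env_id`, `accuracy`,
#'   `observed`) and `per_environment` (tibble `env_id`, `accuracy`: mean
#'   over varieties observed in the environment).
#' @export
prediction_accuracy <- function(fit) {
  stopifnot(inherits(fit, "met_fit"))
  gvar <- diag(fit$Ge)
  if (any(gvar <= 0)) {
    stop_validation("non-positive genetic variance for environment ",
                    fit$env_ids[which(gvar <= 0)[1]])
  }
  rel <- 1 - sweep(fit$blups$pev_u, 2, gvar, `/`)
  if (any(rel < -1e-8)) {
    warning("PEV exceeds genetic variance for some cells; accuracy clipped ",
            "to 0", call. = FALSE)
  }
  acc <- sqrt(pmax(rel, 0))
  dimnames(acc) <- list(fit$var_ids, fit$env_ids)
  per_cell <- tibble::as_tibble(acc, rownames = "variety") |>
    tidyr::pivot_longer(-"variety", names_to = "env_id",
                        values_to = "accuracy")
  per_cell$observed <- as.vector(t(fit$observed))
  per_env <- per_cell |>
    dplyr::filter(.data$observed) |>
    dplyr::group_by(.data$env_id) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop") |>
    dplyr::arrange(match(.data$env_id, fit$env_ids))
  list(per_cell = per_cell, per_environment = per_env)
}
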