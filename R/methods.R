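#' Information criteria for a fitted model
#'
#' `AIC = -2 l + 2 p` and `BIC = -2 l + p log(nu)`, where `l` is the
#' residual log-likelihood, `p` the number of free variance parameters and
#' `nu` the residual degrees of freedom `n - rank(X)` (records minus trial
#' means).  Smaller is better.  Note these criteria are reported for
#' completeness; model-order selection for FA structures uses the
#' percentage of genetic variance accounted for (see [select_order()]),
#' since likelihood-based criteria tend to select orders that are either
#' unnecessarily high (REMLRT, AIC) or too low (BIC).
#'
#' @param fit A `met_fit` object, or a list with elements `loglik` and
#'   `n_params`.
#' @param residual_df Residual degrees of freedom; defaults to `n - t` for
#'   a `met_fit`.
#' @return A tibble with columns `aic`, `bic`, `n_params`, `residual_df`.
#' @export
info_criteria <- function(fit, residual_df = NULL) {
  if (inherits(fit, "met_fit")) {
    if (is.null(residual_df)) {
      residual_df <- unname(fit$dims["n"] - fit$dims["t"])
    }
    ll <- fit$loglik
    p <- fit$n_params
  } else {
    ll <- fit$loglik
    p <- fit$n_params
  }
  if (is.null(residual_df) || residual_df <= 0) {
    stop_validation("residual_df must be positive")
  }
  tibble::tibble(
    aic = -2 * ll + 2 * p,
    bic = -2 * ll + p * log(residual_df),
    n_params = p,
    residual_df = residual_df
  )
}

# is spec0 nested in spec1?
vm_nested <- function(spec0, spec1) {
  if (identical(spec0$kind, spec1$kind)) {
    if (spec0$kind == "fa") return(spec0$k <= spec1$k)
    if (spec0$kind == "vc") {
      return(all(spec0$factors %in% spec1$factors))
    }
    return(TRUE)
  }
  switch(spec0$kind,
    diag = spec1$kind %in% c("fa", "us"),
    cs = spec1$kind %in% c("vc", "us"),
    vc = spec1$kind == "us",
    fa = spec1$kind == "us",
    FALSE
  )
}

#' Residual maximum likelihood ratio test
#'
#' Compares two nested variance structures fitted to the same data by the
#' statistic `2 (l_alt - l_null)`, floored at zero, against a chi-square
#' with degrees of freedom equal to the difference in the number of free
#' variance parameters.  When the null places parameters on the boundary
#' of the alternative's parameter space (as when comparing FA orders), the
#' true null distribution is a chi-square mixture; the plain chi-square
#' reference used here is then conservative.
#'
#' @param fit_null,fit_alt `met_fit` objects on the same data; the null
#'   structure must be nested in the alternative.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
remlrt <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "met_fit"), inherits(fit_alt, "met_fit"))
  if (!identical(fit_null$dims, fit_alt$dims)) {
    stop_validation("REMLRT requires fits on the same data")
  }
  if (!vm_nested(fit_null$model, fit_alt$model)) {
    stop_validation(vm_label(fit_null$model), " is not nested in ",
                    vm_label(fit_alt$model))
  }
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  df <- fit_alt$n_params - fit_null$n_params
  p <- if (df == 0) {
    if (stat <= 0) 1 else 0
  } else {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  tibble::tibble(statistic = stat, df = df, p_value = p)
}

#' One-row summary of a fitted MET model
#'
#' @param x A `met_fit` object.
#' @param ... Unused.
#' @return A tibble with model label, dimensions, residual log-likelihood,
#'   parameter count, AIC, BIC, percentage of genetic variance accounted
#'   for (FA models), and convergence information.
#' @export
glance.met_fit <- function(x, ...) {
  ic <- info_criteria(x)
  vbar <- if (x$model$kind == "fa") variance_explained(x)$v_bar else NA_real_
  tibble::tibble(
    model = vm_label(x$model),
    n = unname(x$dims["n"]), m = unname(x$dims["m"]), t = unname(x$dims["t"]),
    loglik = x$loglik, n_params = x$n_params,
    aic = ic$aic, bic = ic$bic, v_bar = vbar,
    converged = x$converged, n_iter = x$n_iter
  )
}

#' Variance parameter estimates in long format
#'
#' @param x A `met_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `env_id` (where applicable) and
#'   `estimate`: loadings and specific variances for FA models, genetic
#'   variances for DIAG, components for CS/VC, and the full `G_e` entries
#'   for US.
#' @export
tidy.met_fit <- function(x, ...) {
  p <- x$estimates
  out <- switch(x$model$kind,
    diag = tibble::tibble(term = "sigma2_g", env_id = x$env_ids,
                          estimate = p$sigma2),
    cs = tibble::tibble(term = c("sigma2_g", "sigma2_ge"),
                        env_id = NA_character_,
                        estimate = c(p$sigma2_g, p$sigma2_ge)),
    vc = tibble::tibble(
      term = c("sigma2_g", paste0("sigma2_", names(p$sigma2_vc)),
               "sigma2_ge"),
      env_id = NA_character_,
      estimate = c(p$sigma2_g, unname(p$sigma2_vc), p$sigma2_ge)
    ),
    fa = dplyr::bind_rows(
      tidyr::pivot_longer(
        tibble::as_tibble(p$Lambda, rownames = "env_id"),
        -"env_id", names_to = "term", values_to = "estimate"
      ) |> dplyr::mutate(term = sub("^fac", "lambda", .data$term)),
      tibble::tibble(env_id = x$env_ids, term = "psi", estimate = p$psi)
    ) |> dplyr::relocate("term"),
    us = {
      Ge <- x$Ge
      idx <- which(upper.tri(Ge, diag = TRUE), arr.ind = TRUE)
      tibble::tibble(
        term = "ge",
        env_id = paste(rownames(Ge)[idx[, 1]], colnames(Ge)[idx[, 2]],
                       sep = ":"),
        estimate = Ge[idx]
      )
    }
  )
  if (!is.null(p$sigma2_p)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("sigma2_p_", names(p$sigma2_p)),
      env_id = NA_character_, estimate = unname(p$sigma2_p)
    ))
  }
  out
}

#' EBLUP tables from a fitted model
#'
#' @param x A `met_fit` object.
#' @return A tibble with one row per variety x environment cell: the total
#'   EBLUP `u`, its prediction error variance, and (for FA fits) the
#'   genetic regression residual `delta`, plus an `observed` flag.
#' @export
met_blups <- function(x) {
  stopifnot(inherits(x, "met_fit"))
  out <- tibble::as_tibble(x$blups$u, rownames = "variety") |>
    tidyr::pivot_longer(-"variety", names_to = "env_id", values_to = "u")
  out$pev_u <- as.vector(t(x$blups$pev_u))
  if (!is.null(x$blups$f)) {
    out$delta <- as.vector(t(x$blups$delta))
  }
  out$observed <- as.vector(t(x$observed))
  out
}
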