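#' Dendrogram ordering of the genetic correlation matrix
#'
#' Orders the environments by agglomerative hierarchical clustering with
#' dissimilarity `1 - C_e`, so that highly correlated environments (little
#' cross-over interaction) sit together in the heatmap and poorly
#' correlated ones sit apart.  Average linkage by default; the linkage is
#' configurable since only the algorithm family and the dissimilarity are
#' canonical.
#'
#' @param C A genetic correlation matrix (e.g. [genetic_correlation()]).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A `met_ordered_correlation` object: `order` (permutation of the
#'   environment labels), `merge_tree` (the `hclust` object),
#'   `correlation` (the reordered matrix).
#' @export
order_correlation <- function(C, linkage = "average") {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop_validation("correlation matrix must be square")
  if (is.null(rownames(C))) {
    rownames(C) <- colnames(C) <- paste0("E", seq_len(nrow(C)))
  }
  d <- stats::as.dist(1 - C)
  hc <- stats::hclust(d, method = linkage)
  ord <- hc$order
  structure(
    list(order = rownames(C)[ord], merge_tree = hc,
         correlation = C[ord, ord]),
    class = "met_ordered_correlation"
  )
}

#' @export
print.met_ordered_correlation <- function(x, ...) {
  cat("<met_ordered_correlation> ", length(x$order), " environments\n",
      sep = "")
  invisible(x)
}

#' Latent regression data for one variety
#'
#' The rotated FA model expresses each variety's predictions as a multiple
#' regression of its effects on the rotated environment loadings, with the
#' rotated scores as slopes.  Plot `s` shows, against the factor-`s`
#' loadings, the regression component adjusted for the preceding factors:
#' the y-axis is `beta_ij` for `s = 1` and
#' `beta_ij - sum_{r<s} lambda*_rj f*_ri` for `s > 1`; the reference line
#' through the origin has slope `f*_si`.  Points are flagged by whether
#' the variety was grown in the environment; a variety observed only at
#' low loadings (a narrow x-range) has poorly determined scores and its
#' plot should be read with caution.
#'
#' @param preds A `met_predictions` object.
#' @param variety Variety label.
#' @param factor_index Which factor `s`, between 1 and k.
#' @param rotation Optional `met_rotation` (taken from `preds` by default).
#' @return A `met_latent_regression` object: `points` (tibble `env_id`,
#'   `x`, `y`, `observed`), `slope`, `variety`, `factor_index`,
#'   `narrow_coverage` (TRUE when the observed x-range covers less than
#'   half of the full loading range).
#' @export
latent_regression <- function(preds, variety, factor_index, rotation = NULL) {
  stopifnot(inherits(preds, "met_predictions"))
  rot <- rotation %||% preds$rotation
  k <- ncol(rot$rotated_loadings)
  if (factor_index < 1 || factor_index > k) {
    stop_validation("factor_index must be between 1 and ", k)
  }
  i <- match(variety, preds$var_ids)
  if (is.na(i)) stop_validation("unknown variety '", variety, "'")
  Lstar <- rot$rotated_loadings
  fstar <- rot$rotated_scores[i, ]
  y <- preds$beta[i, ]
  if (factor_index > 1) {
    prior <- seq_len(factor_index - 1)
    y <- y - drop(Lstar[, prior, drop = FALSE] %*% fstar[prior])
  }
  pts <- tibble::tibble(
    env_id = preds$env_ids,
    x = unname(Lstar[, factor_index]),
    y = unname(y),
    observed = unname(preds$observed[i, ])
  )
  xr_all <- range(pts$x)
  xr_obs <- range(pts$x[pts$observed])
  narrow <- diff(xr_obs) < 0.5 * diff(xr_all)
  structure(
    list(points = pts, slope = unname(fstar[factor_index]),
         variety = variety, factor_index = factor_index,
         narrow_coverage = narrow),
    class = "met_latent_regression"
  )
}

#' @export
print.met_latent_regression <- function(x, ...) {
  cat("<met_latent_regression> ", x$variety, ", factor ", x$factor_index,
      sprintf(": slope %.3f", x$slope),
      if (x$narrow_coverage) " [narrow loading coverage]", "\n", sep = "")
  invisible(x)
}

#' Regional (or grower-defined) averages of variety predictions
#'
#' Long-term group-level predictions are simple (optionally weighted)
#' averages of the regression components `beta` over the environments in
#' each group.  Weights, when given, are normalized to sum to one within
#' each group; assigning all weight to selected environments yields a
#' grower-specific selection index.  Standard errors use the full `V_beta`
#' block for the group, not just its diagonal.
#'
#' @param preds A `met_predictions` object.
#' @param env_groups Data frame with columns `env_id`, `group`; groups may
#'   partition or merely subset the environments.  Defaults to the region
#'   attribute of every environment.
#' @param weights Optional data frame with columns `env_id`, `weight`
#'   (non-negative).
#' @return A tibble with columns `group`, `variety`, `prediction`, `se`,
#'   `n_environments`.
#' @export
regional_predictions <- function(preds, env_groups = NULL, weights = NULL) {
  stopifnot(inherits(preds, "met_predictions"))
  if (is.null(env_groups)) {
    env_groups <- tibble::tibble(env_id = preds$environments$env_id,
                                 group = preds$environments$region)
  }
  env_groups <- tibble::as_tibble(env_groups)
  if (!all(c("env_id", "group") %in% names(env_groups))) {
    stop_schema("env_groups needs columns env_id, group")
  }
  unknown <- setdiff(env_groups$env_id, preds$env_ids)
  if (length(unknown) > 0) {
    stop_validation("unknown environment '", unknown[1], "' in env_groups")
  }
  w_lookup <- NULL
  if (!is.null(weights)) {
    weights <- tibble::as_tibble(weights)
    if (!all(c("env_id", "weight") %in% names(weights))) {
      stop_schema("weights needs columns env_id, weight")
    }
    if (any(weights$weight < 0)) stop_validation("weights must be >= 0")
    w_lookup <- stats::setNames(weights$weight, weights$env_id)
  }
  Lstar <- preds$rotation$rotated_loadings
  groups <- split(env_groups$env_id, env_groups$group)
  out <- purrr::imap(groups, function(envs, gname) {
    if (length(envs) == 0) stop_validation("empty group '", gname, "'")
    J <- match(envs, preds$env_ids)
    w <- if (is.null(w_lookup)) rep(1, length(J)) else {
      ww <- w_lookup[envs]
      ww[is.na(ww)] <- 0
      ww
    }
    if (sum(w) <= 0) {
      stop_validation("group '", gname, "' has zero total weight")
    }
    w <- w / sum(w)
    LJw <- drop(crossprod(Lstar[J, , drop = FALSE], w))   # k-vector
    pred <- drop(preds$beta[, J, drop = FALSE] %*% w)
    se <- purrr::map_dbl(preds$rotation$score_pev, function(p) {
      sqrt(max(drop(LJw %*% p %*% LJw), 0))
    })
    tibble::tibble(group = gname, variety = preds$var_ids,
                   prediction = unname(pred), se = unname(se),
                   n_environments = length(J))
  })
  dplyr::bind_rows(out)
}

#' Environment-level prediction panel for one region
#'
#' The grower-facing report: for every trial-site location in the region,
#' the predicted genetic values (regression components, t/ha) of each
#' variety in each year, with standard errors, a flag for whether the
#' variety was actually grown in the trial, and the trial mean yield as a
#' quantitative grading of the environment.
#'
#' @param preds A `met_predictions` object.
#' @param region Region label.
#' @param varieties Optional character vector restricting the varieties.
#' @return A `met_environment_panel`: long tibble with columns `location`,
#'   `year`, `env_id`, `variety`, `prediction`, `se`, `observed`,
#'   `trial_mean_yield`.
#' @export
environment_panel <- function(preds, region, varieties = NULL) {
  stopifnot(inherits(preds, "met_predictions"))
  env <- preds$environments
  env <- env[env$env_id %in% preds$env_ids, ]
  sel <- env[env$region == region, ]
  if (nrow(sel) == 0) stop_validation("unknown region '", region, "'")
  vars <- varieties %||% preds$var_ids
  bad <- setdiff(vars, preds$var_ids)
  if (length(bad) > 0) stop_validation("unknown variety '", bad[1], "'")
  tab <- preds$table |>
    dplyr::filter(.data$env_id %in% sel$env_id, .data$variety %in% vars) |>
    dplyr::left_join(
      sel[c("env_id", "location", "year", "trial_mean_yield")],
      by = "env_id"
    ) |>
    dplyr::transmute(
      location = .data$location, year = .data$year, env_id = .data$env_id,
      variety = .data$variety, prediction = .data$beta, se = .data$beta_se,
      observed = .data$observed,
      trial_mean_yield = .data$trial_mean_yield
    ) |>
    dplyr::arrange(.data$location, .data$year, .data$variety)
  structure(tab, class = c("met_environment_panel", class(tab)),
            region = region)
}
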