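#' First-stage analysis of a single trial
#'
#' Fits a two-way additive fixed-effects model, yield ~ replicate + variety,
#' by least squares to the plot data of one randomized-complete-block trial,
#' and reduces it to the quantities carried into the second-stage MET
#' analysis: the adjusted variety means, a statistical weight per mean (the
#' reciprocal of its squared standard error), the residual mean square, and
#' the F ratio for the (fixed) variety effects used by the dataset
#' inclusion rule.  This is a deliberately non-spatial first stage: the
#' second stage only requires means and diagonal weights.
#'
#' With a single replicate no F ratio exists; means and naive weights
#' (n/variance per variety) are returned with a warning, provided each
#' variety has at least two plots.  Zero residual degrees of freedom are an
#' error.
#'
#' @param plots A data frame with columns `replicate`, `variety`, `yield`
#'   (t/ha) for one trial; a `trial` column, if present, must be constant.
#' @return A `trial_summary` object: list with `trial`, `means` (tibble
#'   `variety`, `mean`, `weight`), `f_ratio`, `error_ms`, `trial_mean`.
#' @export
analyze_trial <- function(plots) {
  plots <- tibble::as_tibble(plots)
  need <- c("replicate", "variety", "yield")
  miss <- setdiff(need, names(plots))
  if (length(miss) > 0) {
    stop_schema("plot data missing column(s): ", paste(miss, collapse = ", "))
  }
  trial <- if ("trial" %in% names(plots)) {
    u <- unique(as.character(plots$trial))
    if (length(u) > 1) {
      stop_validation("analyze_trial expects a single trial, got: ",
                      paste(u, collapse = ", "))
    }
    u
  } else {
    NA_character_
  }
  plots$replicate <- factor(as.character(plots$replicate))
  plots$variety <- factor(as.character(plots$variety))
  if (anyDuplicated(plots[c("replicate", "variety")])) {
    stop_validation("duplicate (replicate, variety) plot in trial ", trial)
  }
  if (nlevels(plots$variety) < 2) {
    stop_validation("at least 2 varieties required in trial ", trial)
  }

  if (nlevels(plots$replicate) < 2) {
    warning("trial ", trial, ": fewer than 2 replicates; no F ratio, ",
            "weights taken from naive per-variety variances", call. = FALSE)
    per <- plots |>
      dplyr::group_by(.data$variety) |>
      dplyr::summarise(mean = mean(.data$yield), n = dplyr::n(),
                       v = stats::var(.data$yield), .groups = "drop")
    if (any(per$n < 2) || any(!is.finite(per$v)) || any(per$v <= 0)) {
      stop_validation("trial ", trial,
                      ": zero residual degrees of freedom for some variety")
    }
    means <- tibble::tibble(variety = as.character(per$variety),
                            mean = per$mean, weight = per$n / per$v)
    return(new_trial_summary(trial, means, f_ratio = NA_real_,
                             error_ms = mean(per$v),
                             trial_mean = mean(per$mean)))
  }

  fit <- stats::lm(yield ~ replicate + variety, data = plots)
  if (stats::df.residual(fit) <= 0) {
    stop_validation("trial ", trial, ": zero residual degrees of freedom")
  }
  an <- stats::anova(fit)
  f_ratio <- an["variety", "F value"]
  error_ms <- an["Residuals", "Mean Sq"]

  # adjusted mean of variety v = average of model predictions over replicates
  vlev <- levels(plots$variety)
  rlev <- levels(plots$replicate)
  grid <- expand.grid(replicate = factor(rlev, levels = rlev),
                      variety = factor(vlev, levels = vlev))
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid)
  lmat <- rowsum(mm, group = grid$variety) / length(rlev)
  lmat <- lmat[vlev, , drop = FALSE]
  est <- drop(lmat %*% stats::coef(fit))
  # se^2 of each adjusted mean; for balanced data this is error_ms / r
  se2 <- rowSums((lmat %*% stats::vcov(fit)) * lmat)
  if (any(se2 <= 0)) {
    # perfectly additive data: no residual noise, weights are infinite
    weight <- rep(Inf, length(est))
  } else {
    weight <- 1 / se2
  }
  means <- tibble::tibble(variety = vlev, mean = unname(est),
                          weight = unname(weight))
  new_trial_summary(trial, means, f_ratio = f_ratio, error_ms = error_ms,
                    trial_mean = mean(est))
}

new_trial_summary <- function(trial, means, f_ratio, error_ms, trial_mean) {
  structure(
    list(trial = trial, means = means, f_ratio = f_ratio,
         error_ms = error_ms, trial_mean = trial_mean),
    class = "trial_summary"
  )
}

#' @export
print.trial_summary <- function(x, ...) {
  cat("<trial_summary> ", x$trial, ": ", nrow(x$means), " varieties, ",
      sprintf("F = %.3g, error MS = %.4g, mean = %.3g t/ha\n",
              x$f_ratio, x$error_ms, x$trial_mean), sep = "")
  invisible(x)
}

#' @export
tidy.trial_summary <- function(x, ...) {
  dplyr::mutate(x$means, trial = x$trial, f_ratio = x$f_ratio,
                error_ms = x$error_ms, trial_mean = x$trial_mean,
                .before = 1)
}

#' First-stage analysis of many trials
#'
#' Splits plot-level data by trial and applies [analyze_trial()] to each.
#'
#' @param plots Data frame with columns `trial`, `replicate`, `variety`,
#'   `yield`.
#' @return A list of `trial_summary` objects, named by trial.
#' @export
analyze_trials <- function(plots) {
  plots <- tibble::as_tibble(plots)
  if (!"trial" %in% names(plots)) stop_schema("plot data missing column: trial")
  split(plots, as.character(plots$trial)) |>
    purrr::map(analyze_trial)
}

#' Assemble trial summaries into second-stage MET data
#'
#' Stacks the variety means and weights from individual trial analyses into
#' the combined vector analysed by the weighted second-stage mixed model,
#' ordered as varieties within environments, and attaches environment
#' metadata (location, year, region).
#'
#' @param summaries A list of `trial_summary` objects, or a single one.
#' @param metadata Data frame with columns `trial`, `location`, `year`,
#'   `region` (and optionally `mega_region`) covering every trial.
#' @return A [met_data] object; `trial_mean_yield`, `error_ms` and
#'   `f_ratio` from the summaries are carried on the environment register.
#' @export
summaries_to_met <- function(summaries, metadata) {
  if (inherits(summaries, "trial_summary")) summaries <- list(summaries)
  if (length(summaries) == 0) stop_validation("no data: empty summary list")
  metadata <- tibble::as_tibble(metadata)
  need <- c("trial", "location", "year", "region")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) {
    stop_schema("metadata missing column(s): ", paste(miss, collapse = ", "))
  }
  metadata$trial <- as.character(metadata$trial)

  rows <- purrr::map(summaries, tidy)
  df <- dplyr::bind_rows(rows)
  absent <- setdiff(unique(df$trial), metadata$trial)
  if (length(absent) > 0) {
    stop_validation("metadata missing for trial '", absent[1], "'")
  }
  df <- dplyr::left_join(df, metadata, by = "trial")
  env <- df |>
    dplyr::distinct(.data$trial, .keep_all = TRUE) |>
    dplyr::transmute(
      env_id = paste(.data$location, .data$year, sep = "_"),
      location = as.character(.data$location),
      year = .data$year,
      region = as.character(.data$region),
      mega_region = if ("mega_region" %in% names(df)) {
        as.character(.data$mega_region)
      } else {
        NA_character_
      },
      trial_mean_yield = .data$trial_mean,
      error_ms = .data$error_ms,
      f_ratio = .data$f_ratio
    )
  records <- df |>
    dplyr::transmute(
      variety = .data$variety,
      env_id = paste(.data$location, .data$year, sep = "_"),
      mean = .data$mean, weight = .data$weight
    ) |>
    dplyr::arrange(match(.data$env_id, env$env_id), .data$variety)
  met_data(records, environments = env)
}
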