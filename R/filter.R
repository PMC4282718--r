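#' Apply the MET dataset inclusion rules
#'
#' Trials (environments) are removed when they show no genetic variance:
#' either the fixed-variety F ratio from the individual-trial analysis is
#' below 1, or the diagonal-model genetic variance for the trial was
#' estimated at the zero boundary.  After trial removal, varieties are
#' removed when flagged as "filler" or when grown in fewer than
#' `min_trials` of the remaining trials.  The variety rule is applied in a
#' single pass after trial removal; environments left without records are
#' then dropped.  The whole procedure is idempotent for fixed flags.
#'
#' @param data A [met_data] object.
#' @param trial_stats Optional data frame with columns `env_id` and any of
#'   `f_ratio`, `gvar_zero`.  When `NULL`, `f_ratio` is taken from the
#'   environment register if present (environments with `NA` stats are
#'   never removed by the trial rules).
#' @param min_trials Minimum number of trials a variety must appear in
#'   (default 4).
#' @param remove_filler Drop varieties flagged `is_filler` (default TRUE).
#' @return A filtered [met_data] object with a `removal_log` attribute
#'   (tibble with columns `entity`, `id`, `rule`, `detail`); retrieve it
#'   with [removal_log()].
#' @export
filter_met <- function(data, trial_stats = NULL, min_trials = 4,
                       remove_filler = TRUE) {
  stopifnot(inherits(data, "met_data"))
  env <- data$environments
  if (is.null(trial_stats)) {
    trial_stats <- tibble::tibble(env_id = env$env_id)
    if ("f_ratio" %in% names(env)) trial_stats$f_ratio <- env$f_ratio
  }
  trial_stats <- tibble::as_tibble(trial_stats)
  if (!"env_id" %in% names(trial_stats)) {
    stop_schema("trial_stats must have an env_id column")
  }
  unknown <- setdiff(trial_stats$env_id, env$env_id)
  if (length(unknown) > 0) {
    stop_validation("trial_stats refers to unknown environment '",
                    unknown[1], "'")
  }
  if (!"f_ratio" %in% names(trial_stats)) trial_stats$f_ratio <- NA_real_
  if (!"gvar_zero" %in% names(trial_stats)) trial_stats$gvar_zero <- NA

  log <- tibble::tibble(entity = character(), id = character(),
                        rule = character(), detail = character())

  drop_f <- trial_stats$env_id[!is.na(trial_stats$f_ratio) &
                                 trial_stats$f_ratio < 1]
  if (length(drop_f) > 0) {
    fr <- trial_stats$f_ratio[match(drop_f, trial_stats$env_id)]
    log <- dplyr::bind_rows(log, tibble::tibble(
      entity = "environment", id = drop_f,
      rule = "no genetic variance (F < 1)",
      detail = sprintf("F = %.4g", fr)
    ))
  }
  drop_g <- trial_stats$env_id[!is.na(trial_stats$gvar_zero) &
                                 trial_stats$gvar_zero]
  drop_g <- setdiff(drop_g, drop_f)
  if (length(drop_g) > 0) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      entity = "environment", id = drop_g,
      rule = "no genetic variance (diagonal-model variance fixed at zero)",
      detail = ""
    ))
  }
  env_keep <- setdiff(env$env_id, c(drop_f, drop_g))
  out <- met_subset(data, env_keep = env_keep)

  # variety rules: one pass, after trial removal
  if (remove_filler) {
    fillers <- out$varieties$variety[out$varieties$is_filler]
  } else {
    fillers <- character()
  }
  counts <- dplyr::count(out$records, .data$variety)
  few <- counts$variety[counts$n < min_trials]
  few <- union(few, setdiff(out$varieties$variety, counts$variety))
  few <- setdiff(few, fillers)
  if (length(fillers) > 0) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      entity = "variety", id = fillers, rule = "filler variety", detail = ""
    ))
  }
  if (length(few) > 0) {
    n_in <- counts$n[match(few, counts$variety)]
    n_in[is.na(n_in)] <- 0L
    log <- dplyr::bind_rows(log, tibble::tibble(
      entity = "variety", id = few,
      rule = sprintf("grown in fewer than %d trials", min_trials),
      detail = sprintf("grown in %d", n_in)
    ))
  }
  out <- met_subset(out, var_keep = setdiff(out$varieties$variety,
                                            c(fillers, few)))

  empty <- setdiff(out$environments$env_id, unique(out$records$env_id))
  if (length(empty) > 0) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      entity = "environment", id = empty,
      rule = "no remaining records", detail = ""
    ))
    out <- met_subset(out, env_keep = setdiff(out$environments$env_id, empty))
  }

  if (nrow(out$records) == 0) {
    stop_validation("no data remain after filtering")
  }
  attr(out, "removal_log") <- log
  out
}

#' Removal log of a filtered dataset
#'
#' @param x A [met_data] returned by [filter_met()].
#' @return A tibble with one row per removed entity: `entity`
#'   ("environment" or "variety"), `id`, `rule`, `detail`.
#' @export
removal_log <- function(x) {
  log <- attr(x, "removal_log")
  if (is.null(log)) {
    tibble::tibble(entity = character(), id = character(),
                   rule = character(), detail = character())
  } else {
    log
  }
}
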