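#' Second-stage MET data
#'
#' A `met_data` object holds the inputs to the second stage of a two-stage
#' multi-environment trial (MET) analysis: one variety-mean record per
#' variety x environment cell, together with its statistical weight from the
#' individual-trial analysis, and registers of environments (trials) and
#' varieties.  An environment is a location--year combination; its identifier
#' is `location` and `year` joined by `"_"`.  Regions (and optional
#' mega-regions) are attributes of environments, never part of the key.
#'
#' @param records A data frame with columns `variety`, `env_id`, `mean`
#'   (variety mean yield, t/ha) and `weight` (positive; the reciprocal of the
#'   variance of the mean).
#' @param environments A data frame with columns `env_id`, `location`,
#'   `year`, `region` and optionally `mega_region`, `trial_mean_yield`,
#'   `error_ms`, `f_ratio`.  If `NULL`, a minimal register is synthesized
#'   from the distinct `env_id` values.
#' @param varieties A data frame with columns `variety` and optionally
#'   `is_filler`.  If `NULL`, synthesized from the records with
#'   `is_filler = FALSE`.
#'
#' @return An object of class `met_data`: a list of tibbles `records`,
#'   `environments`, `varieties`.
#' @seealso [as_met_data()], [read_met_csv()], [filter_met()]
#' @export
met_data <- function(records, environments = NULL, varieties = NULL) {
  records <- tibble::as_tibble(records)
  need <- c("variety", "env_id", "mean", "weight")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop_schema("records is missing column(s): ", paste(miss, collapse = ", "))
  }
  records <- records[union(need, names(records))]
  records$variety <- as.character(records$variety)
  records$env_id <- as.character(records$env_id)

  if (is.null(environments)) {
    environments <- tibble::tibble(
      env_id = unique(records$env_id),
      location = unique(records$env_id),
      year = NA_integer_,
      region = "all"
    )
  }
  environments <- tibble::as_tibble(environments)
  for (col in c("env_id", "location", "region")) {
    if (!col %in% names(environments)) {
      stop_schema("environments is missing column: ", col)
    }
    environments[[col]] <- as.character(environments[[col]])
  }
  if (!"year" %in% names(environments)) environments$year <- NA_integer_
  if (!"mega_region" %in% names(environments)) {
    environments$mega_region <- NA_character_
  }
  if (!"trial_mean_yield" %in% names(environments)) {
    environments$trial_mean_yield <- NA_real_
  }
  if (!"error_ms" %in% names(environments)) environments$error_ms <- NA_real_

  if (is.null(varieties)) {
    varieties <- tibble::tibble(variety = sort(unique(records$variety)),
                                is_filler = FALSE)
  }
  varieties <- tibble::as_tibble(varieties)
  if (!"variety" %in% names(varieties)) {
    stop_schema("varieties is missing column: variety")
  }
  varieties$variety <- as.character(varieties$variety)
  if (!"is_filler" %in% names(varieties)) varieties$is_filler <- FALSE

  x <- structure(
    list(records = records, environments = environments,
         varieties = varieties),
    class = "met_data"
  )
  validate_met_data(x)
}

#' Coerce a flat data frame to `met_data`
#'
#' Builds a [met_data] object from one row per variety-mean record.  The
#' environment identifier is synthesized as `location_year` and the
#' environment and variety registers are derived from the distinct values.
#'
#' @param x A data frame with columns `location`, `year`, `region`,
#'   `variety`, `mean`, `weight`, and optionally `filler` (logical),
#'   `mega_region`, `trial_mean_yield`, `error_ms`, `f_ratio`.
#' @param ... Unused.
#' @return A [met_data] object.
#' @export
as_met_data <- function(x, ...) {
  x <- tibble::as_tibble(x)
  need <- c("location", "year", "region", "variety", "mean", "weight")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop_schema("input is missing column(s): ", paste(miss, collapse = ", "))
  }
  for (col in need) {
    if (any(is.na(x[[col]]))) {
      stop_validation("missing values in mandatory column '", col, "' (row ",
                      which(is.na(x[[col]]))[1], ")")
    }
  }
  x$env_id <- paste(x$location, x$year, sep = "_")

  env_cols <- intersect(
    c("env_id", "location", "year", "region", "mega_region",
      "trial_mean_yield", "error_ms", "f_ratio"),
    names(x)
  )
  environments <- dplyr::distinct(x[env_cols], .data$env_id, .keep_all = TRUE)
  dup_env <- x |>
    dplyr::distinct(.data$env_id, .data$region) |>
    dplyr::count(.data$env_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_env) > 0) {
    stop_validation("environment ", dup_env$env_id[1],
                    " has inconsistent region labels")
  }

  var_tbl <- if ("filler" %in% names(x)) {
    x |>
      dplyr::group_by(variety = as.character(.data$variety)) |>
      dplyr::summarise(is_filler = any(as.logical(.data$filler)),
                       .groups = "drop")
  } else {
    NULL
  }
  met_data(
    records = x[c("variety", "env_id", "mean", "weight")],
    environments = environments,
    varieties = var_tbl
  )
}

#' Read a second-stage MET CSV file
#'
#' Reads a comma-separated file (header row required, UTF-8, `.` decimal
#' mark) with one variety-mean record per row and validates it into a
#' [met_data] object.  Missing values in mandatory columns are rejected.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping the canonical
#'   column names (`location`, `year`, `region`, `variety`, `mean`,
#'   `weight`, `filler`) to the names used in the file, e.g.
#'   `c(mean = "yield_mean")`.
#' @return A [met_data] object.
#' @export
read_met_csv <- function(path, schema = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) {
        stop_schema("schema maps '", canon, "' to absent column '", src, "'")
      }
      names(df)[names(df) == src] <- canon
    }
  }
  as_met_data(df)
}

validate_met_data <- function(x) {
  rec <- x$records
  # infinite weights (noise-free means) are permitted; zero/negative are not
  bad_w <- which(is.na(rec$weight) | rec$weight <= 0)
  if (length(bad_w) > 0) {
    stop_validation("non-positive weight in records row ", bad_w[1])
  }
  if (any(is.na(rec$mean))) {
    stop_validation("missing mean in records row ", which(is.na(rec$mean))[1])
  }
  key <- paste(rec$variety, rec$env_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    parts <- strsplit(d, "\r", fixed = TRUE)[[1]]
    stop_validation("duplicate record for variety '", parts[1],
                    "' in environment '", parts[2], "'")
  }
  if (anyDuplicated(x$environments$env_id)) {
    stop_validation("duplicate env_id in environment register")
  }
  unknown_env <- setdiff(rec$env_id, x$environments$env_id)
  if (length(unknown_env) > 0) {
    stop_validation("records refer to unregistered environment '",
                    unknown_env[1], "'")
  }
  unknown_var <- setdiff(rec$variety, x$varieties$variety)
  if (length(unknown_var) > 0) {
    stop_validation("records refer to unregistered variety '",
                    unknown_var[1], "'")
  }
  x
}

#' Dimensions of a MET dataset
#'
#' @param x A [met_data] object.
#' @return Named integer vector with `n` (records), `m` (varieties),
#'   `t` (environments).
#' @export
met_dims <- function(x) {
  stopifnot(inherits(x, "met_data"))
  c(n = nrow(x$records), m = nrow(x$varieties), t = nrow(x$environments))
}

#' @export
print.met_data <- function(x, ...) {
  d <- met_dims(x)
  cat("<met_data> ", d["n"], " records: ", d["m"], " varieties x ",
      d["t"], " environments\n", sep = "")
  yrs <- x$environments$year
  if (!all(is.na(yrs))) {
    cat("  years ", min(yrs, na.rm = TRUE), "-", max(yrs, na.rm = TRUE),
        ", regions: ", paste(sort(unique(x$environments$region)),
                             collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Flatten a MET dataset to one row per record
#'
#' @param x A [met_data] object.
#' @param ... Unused.
#' @return A tibble joining records with their environment attributes.
#' @export
tidy.met_data <- function(x, ...) {
  dplyr::left_join(x$records, x$environments, by = "env_id")
}

#' Write a MET dataset back to CSV
#'
#' Inverse of [read_met_csv()]: one row per record with environment
#' attributes and the filler flag.
#'
#' @param x A [met_data] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_met_csv <- function(x, path) {
  out <- tidy.met_data(x) |>
    dplyr::left_join(x$varieties, by = "variety") |>
    dplyr::rename(filler = "is_filler")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# restrict a met_data to given environments/varieties, keeping registers
met_subset <- function(x, env_keep = NULL, var_keep = NULL) {
  if (!is.null(env_keep)) {
    x$environments <- dplyr::filter(x$environments, .data$env_id %in% env_keep)
    x$records <- dplyr::filter(x$records, .data$env_id %in% env_keep)
  }
  if (!is.null(var_keep)) {
    x$varieties <- dplyr::filter(x$varieties, .data$variety %in% var_keep)
    x$records <- dplyr::filter(x$records, .data$variety %in% var_keep)
  }
  x
}

stop_schema <- function(...) {
  stop(rlang::error_cnd("metfa_schema_error", message = paste0(...)))
}
stop_validation <- function(...) {
  stop(rlang::error_cnd("metfa_validation_error", message = paste0(...)))
}
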