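#' Variety connectivity between trials
#'
#' Connectivity -- the number of varieties two trials have in common --
#' governs how much information the data carry about the genetic covariance
#' between the pair of environments.  This computes the t x t matrix of
#' pairwise common-variety counts and, optionally, its average over a
#' grouping of the trials (by region, or by region within year), mirroring
#' the usual connectivity displays for national testing programs.
#'
#' @param data A [met_data] object.
#' @param group_by One of `"trial"`, `"region"`, `"region_year"`.
#' @return A `met_connectivity` object: list with `pairwise_common`
#'   (t x t integer matrix, diagonal = per-trial variety counts),
#'   `group_average` (group x group matrix; off-diagonals are means over
#'   all cross-group trial pairs, the diagonal is the mean per-trial
#'   variety count within the group), `groups` (env_id -> group), and
#'   `group_by`.
#' @export
met_connectivity <- function(data, group_by = c("trial", "region",
                                                "region_year")) {
  stopifnot(inherits(data, "met_data"))
  group_by <- match.arg(group_by)
  env_ids <- data$environments$env_id
  var_ids <- data$varieties$variety
  inc <- matrix(FALSE, length(var_ids), length(env_ids),
                dimnames = list(var_ids, env_ids))
  inc[cbind(match(data$records$variety, var_ids),
            match(data$records$env_id, env_ids))] <- TRUE
  pairwise <- crossprod(inc * 1L)
  storage.mode(pairwise) <- "integer"

  grp <- switch(group_by,
    trial = env_ids,
    region = data$environments$region,
    region_year = paste(data$environments$region, data$environments$year,
                        sep = ":")
  )
  if (anyNA(grp)) stop_validation("grouping factor undefined for some trials")
  levels <- unique(grp)
  ga <- matrix(NA_real_, length(levels), length(levels),
               dimnames = list(levels, levels))
  for (a in seq_along(levels)) {
    for (b in seq_along(levels)) {
      ja <- which(grp == levels[a])
      jb <- which(grp == levels[b])
      if (a == b) {
        ga[a, b] <- mean(diag(pairwise)[ja])
      } else {
        ga[a, b] <- mean(pairwise[ja, jb, drop = FALSE])
      }
    }
  }
  structure(
    list(pairwise_common = pairwise, group_average = ga,
         groups = stats::setNames(grp, env_ids), group_by = group_by),
    class = "met_connectivity"
  )
}

#' @export
print.met_connectivity <- function(x, ...) {
  cat("<met_connectivity> ", nrow(x$pairwise_common), " trials, grouped by ",
      x$group_by, " (", nrow(x$group_average), " groups)\n", sep = "")
  invisible(x)
}

#' Long-format view of a connectivity table
#'
#' @param x A `met_connectivity` object.
#' @param ... Unused.
#' @return Tibble with columns `group_a`, `group_b`, `average_common`.
#' @export
tidy.met_connectivity <- function(x, ...) {
  ga <- x$group_average
  tibble::as_tibble(as.table(ga), .name_repair = "minimal") |>
    stats::setNames(c("group_a", "group_b", "average_common"))
}

#' Connected components of the trial connectivity graph
#'
#' Two trials are linked when they share at least `min_common` varieties.
#' A single connected component certifies that the whole dataset is
#' analysable as one mega-region; factor analytic models cannot be fitted
#' across completely disconnected subsets.  Indirect links count: a chain
#' of overlapping trials (a moving window of connectivity, as arises when
#' varieties enter and retire over years) keeps the graph connected even
#' when the extreme trials share no variety.
#'
#' @param conn A `met_connectivity` object (from [met_connectivity()] with
#'   `group_by = "trial"`), or a square named matrix of common counts.
#' @param min_common Minimum number of shared varieties for an edge
#'   (default 1; must be >= 1).
#' @return A list of character vectors of env_ids, one per component,
#'   largest first.
#' @export
connectivity_components <- function(conn, min_common = 1) {
  stopifnot(min_common >= 1)
  pc <- if (inherits(conn, "met_connectivity")) conn$pairwise_common else conn
  if (!is.matrix(pc) || nrow(pc) != ncol(pc)) {
    stop_validation("connectivity table must be a square matrix")
  }
  adj <- (pc >= min_common) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  ids <- rownames(pc)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(pc)))
  out <- split(ids, comp$membership)
  out[order(-lengths(out))]
}

#' Write connectivity matrices to CSV
#'
#' @param x A `met_connectivity` object.
#' @param path Output path for the group-average matrix (row/column labels
#'   in the first column).
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(x, path) {
  df <- tibble::as_tibble(x$group_average, rownames = "group")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
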