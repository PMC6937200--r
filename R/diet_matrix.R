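#' Build stomach-by-prey-group diet matrices
#'
#' Aggregates each stomach's identified prey into per-group wet weight and
#' count totals. Excluded categories (unidentified matter, parasites) are
#' dropped; empty stomachs keep an all-zero row because the vacuity index
#' needs them. Grouping labels (year, area, length group, station) are
#' attached per stomach when station records are supplied.
#'
#' @param stomachs `stomach_records` list.
#' @param stations optional `station_records` list used to label each
#'   stomach with `year` and `area`; every referenced station must exist.
#' @param groups prey-group columns, default [prey_groups()].
#' @return object of class `diet_matrix`: list with `weight` and `count`
#'   matrices (stomachs x groups) and a `labels` data.frame.
#' @export
build_diet_matrix <- function(stomachs, stations = NULL,
                              groups = prey_groups()) {
  n <- length(stomachs)
  if (n == 0) stop_validation("build_diet_matrix: no stomachs")
  ids <- vapply(stomachs, `[[`, character(1), "fish_id")
  st_ids <- vapply(stomachs, `[[`, character(1), "station_id")
  W <- matrix(0, n, length(groups), dimnames = list(ids, groups))
  N <- W
  for (i in seq_len(n)) {
    for (it in stomachs[[i]]$items) {
      if (it$excluded) next
      if (!it$prey_group %in% groups)
        stop_validation("fish '%s': prey group '%s' not in matrix columns",
                        ids[i], it$prey_group)
      W[i, it$prey_group] <- W[i, it$prey_group] + it$weight
      N[i, it$prey_group] <- N[i, it$prey_group] + it$count
    }
  }
  labels <- data.frame(
    fish_id = ids, station_id = st_ids,
    length_group = assign_length_group(vapply(stomachs, `[[`, numeric(1), "length")),
    stringsAsFactors = FALSE)
  if (!is.null(stations)) {
    skey <- vapply(stations, `[[`, character(1), "station_id")
    miss <- setdiff(unique(st_ids), skey)
    if (length(miss))
      stop_validation("stomach(s) reference unknown station(s): %s",
                      paste(miss, collapse = ", "))
    m <- match(st_ids, skey)
    labels$year <- vapply(stations, `[[`, integer(1), "year")[m]
    labels$area <- vapply(stations, `[[`, character(1), "area")[m]
  }
  structure(list(weight = W, count = N, labels = labels),
            class = "diet_matrix")
}

#' @export
print.diet_matrix <- function(x, ...) {
  cat(sprintf("<diet_matrix> %d stomachs x %d prey groups (%d empty rows)\n",
              nrow(x$weight), ncol(x$weight),
              sum(rowSums(x$weight) == 0 & rowSums(x$count) == 0)))
  invisible(x)
}

# Subset a diet_matrix by stomach rows, keeping labels in step.
subset_diet_matrix <- function(m, rows) {
  structure(list(weight = m$weight[rows, , drop = FALSE],
                 count = m$count[rows, , drop = FALSE],
                 labels = m$labels[rows, , drop = FALSE]),
            class = "diet_matrix")
}

#' Fourth-root transform a non-negative matrix
#'
#' The standard severe down-weighting transform of community ecology,
#' applied to gravimetric diet data before Bray-Curtis dissimilarities.
#'
#' @param x non-negative numeric matrix (or `diet_matrix`, whose weight
#'   matrix is transformed).
#' @return matrix of elementwise fourth roots.
#' @export
fourth_root <- function(x) {
  if (inherits(x, "diet_matrix")) x <- x$weight
  if (any(x < 0)) stop_validation("fourth_root: negative entries")
  x^0.25
}

#' Apply the modelling filters to linked stomach and station records
#'
#' Filters used before any comparative statistics, in this order:
#' first remove small fish (total length < 25 cm), then remove stations
#' left with fewer than 10 stomachs (the "more than 9 stomachs" rule).
#' The returned object records counts removed at each step and is flagged
#' so downstream model fits can insist on filtered input. Applying the
#' filters twice changes nothing (idempotence).
#'
#' @param stomachs `stomach_records` list.
#' @param stations `station_records` list; stations with no surviving
#'   stomachs are dropped too.
#' @param min_length cm, default 25.
#' @param min_stomachs_per_station default 10 (i.e. > 9).
#' @return list of class `filtered_survey`: `stomachs`, `stations`,
#'   `report` (counts removed per step).
#' @export
apply_model_filters <- function(stomachs, stations,
                                min_length = 25,
                                min_stomachs_per_station = 10) {
  n0 <- length(stomachs)
  len <- vapply(stomachs, `[[`, numeric(1), "length")
  keep_fish <- len >= min_length
  stomachs <- stomachs[keep_fish]
  n_after_length <- length(stomachs)
  st <- vapply(stomachs, `[[`, character(1), "station_id")
  counts <- table(st)
  good_stations <- names(counts)[counts >= min_stomachs_per_station]
  keep_station <- st %in% good_stations
  stomachs <- stomachs[keep_station]
  if (length(stomachs) == 0)
    stop_validation("apply_model_filters: no stomachs left after filtering (started with %d)", n0)
  skey <- vapply(stations, `[[`, character(1), "station_id")
  stations_kept <- stations[skey %in% good_stations]
  report <- list(
    n_input = n0,
    n_removed_small_fish = n0 - n_after_length,
    n_removed_sparse_stations = n_after_length - length(stomachs),
    n_retained = length(stomachs),
    n_stations_input = length(stations),
    n_stations_retained = length(stations_kept))
  out <- list(stomachs = structure(stomachs, class = "stomach_records"),
              stations = structure(stations_kept, class = "station_records"),
              report = report)
  class(out) <- "filtered_survey"
  out
}

#' @export
print.filtered_survey <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<filtered_survey> %d stomachs in; removed %d fish < 25 cm,",
                     " %d in sparse stations; %d retained at %d station(s)\n"),
              r$n_input, r$n_removed_small_fish, r$n_removed_sparse_stations,
              r$n_retained, r$n_stations_retained))
  invisible(x)
}

#' Build the per-stomach modelling table for the additive stomach-weight model
#'
#' Joins filtered stomach records with their station covariates into one
#' row per stomach: log stomach weight response plus all candidate
#' explanatory variables. The result carries attribute
#' `filtered = TRUE`, which [fit_additive_model()] requires.
#'
#' @param filtered a `filtered_survey` from [apply_model_filters()].
#' @return data.frame, one row per stomach.
#' @export
model_table <- function(filtered) {
  stopifnot(inherits(filtered, "filtered_survey"))
  stomachs <- filtered$stomachs
  stations <- filtered$stations
  skey <- vapply(stations, `[[`, character(1), "station_id")
  st <- vapply(stomachs, `[[`, character(1), "station_id")
  m <- match(st, skey)
  if (anyNA(m))
    stop_validation("model_table: stomach(s) reference unknown station(s): %s",
                    paste(unique(st[is.na(m)]), collapse = ", "))
  g <- function(f, what) vapply(stations, `[[`, f, what)[m]
  df <- data.frame(
    fish_id = vapply(stomachs, `[[`, character(1), "fish_id"),
    station_id = st,
    stomach_weight = vapply(stomachs, `[[`, numeric(1), "stomach_weight"),
    length = vapply(stomachs, `[[`, numeric(1), "length"),
    body_weight = vapply(stomachs, `[[`, numeric(1), "body_weight"),
    longitude = g(numeric(1), "longitude"),
    latitude = g(numeric(1), "latitude"),
    bottom_depth = g(numeric(1), "bottom_depth"),
    sst = g(numeric(1), "sst_0_50"),
    sss = g(numeric(1), "sss_0_50"),
    zooplankton = g(numeric(1), "zooplankton_biomass"),
    log_catch = log(g(numeric(1), "total_catch")),
    week = factor(g(integer(1), "week_number")),
    year = factor(g(integer(1), "year")),
    stringsAsFactors = FALSE)
  df$fulton_k <- fulton_k(df$body_weight, df$length)
  df$time_period <- factor(g(character(1), "time_period"),
                           levels = paste0("P", 1:4))
  df$shore_class <- factor(g(character(1), "distance_to_shore_class"),
                           levels = paste0("D", 1:4))
  df$log_stomach_weight <- log(df$stomach_weight)
  attr(df, "filtered") <- TRUE
  df
}
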