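#' Prey taxon groups used throughout the package
#'
#' The ten analysable prey groups of the Northeast Atlantic mackerel diet
#' study design, plus the two bookkeeping categories (`unidentified`,
#' `parasite`) that are recorded during stomach reading but excluded from
#' every diet statistic.
#'
#' @param include_excluded logical; also return the two excluded categories.
#' @return character vector of group names.
#' @export
prey_groups <- function(include_excluded = FALSE) {
  groups <- c("molluscs", "copepods", "amphipods", "euphausiids",
              "large_crustaceans", "small_crustaceans", "fish",
              "appendicularians", "chaetognaths", "ova")
  if (include_excluded) c(groups, "unidentified", "parasite") else groups
}

#' Prey groups excluded from diet analysis
#' @return character vector.
#' @export
excluded_prey_groups <- function() c("unidentified", "parasite")

#' Construct a prey item
#'
#' One identified prey entry from a stomach: a taxon assigned to one of the
#' survey's prey groups, with a (possibly subsample-expanded, hence
#' non-integer) count and a wet weight in grams.
#'
#' @param taxon_name taxon label (free text).
#' @param prey_group one of [prey_groups()] (including excluded categories).
#' @param count non-negative numeric count (real-valued after subsample
#'   expansion).
#' @param weight non-negative wet weight, g.
#' @param prey_length optional prey length, mm.
#' @return object of class `prey_item`.
#' @export
prey_item <- function(taxon_name, prey_group, count, weight,
                      prey_length = NA_real_) {
  prey_group <- match.arg(prey_group, prey_groups(include_excluded = TRUE))
  if (!is_number(count) || count < 0)
    stop_validation("prey count must be a non-negative number (taxon '%s')",
                    taxon_name)
  if (!is_number(weight) || weight < 0)
    stop_validation("prey weight must be a non-negative number (taxon '%s')",
                    taxon_name)
  if (count == 0 && weight == 0)
    stop_validation("prey item '%s' has both zero count and zero weight",
                    taxon_name)
  structure(
    list(taxon_name = as.character(taxon_name), prey_group = prey_group,
         count = as.numeric(count), weight = as.numeric(weight),
         prey_length = as.numeric(prey_length),
         excluded = prey_group %in% excluded_prey_groups()),
    class = "prey_item")
}

#' Construct a stomach record
#'
#' One fish: biometrics, the recorded stomach weight (organ including its
#' content), and the list of identified prey items. A stomach is empty when
#' it holds no non-excluded prey item (parasites and unidentified matter do
#' not count as food).
#'
#' @param fish_id,station_id identifiers.
#' @param length total length, cm. Plausibility bounds (10, 60) cm.
#' @param body_weight whole body weight, g.
#' @param stomach_weight stomach weight including content, g.
#' @param items list of [prey_item()] objects.
#' @param gonad_weight,sex,maturity,age optional biometrics.
#' @return object of class `stomach_record`.
#' @export
stomach_record <- function(fish_id, station_id, length, body_weight,
                           stomach_weight, items = list(),
                           gonad_weight = NA_real_, sex = NA_character_,
                           maturity = NA_character_, age = NA_real_) {
  if (!is_number(length) || length <= 10 || length >= 60)
    stop_validation("fish '%s': length %s cm outside plausibility bounds (10, 60)",
                    fish_id, format(length))
  if (!is_number(stomach_weight) || stomach_weight < 0)
    stop_validation("fish '%s': stomach_weight must be >= 0", fish_id)
  stopifnot(all(vapply(items, inherits, logical(1), "prey_item")))
  structure(
    list(fish_id = as.character(fish_id),
         station_id = as.character(station_id),
         length = as.numeric(length), body_weight = as.numeric(body_weight),
         gonad_weight = as.numeric(gonad_weight),
         sex = as.character(sex), maturity = as.character(maturity),
         age = as.numeric(age),
         stomach_weight = as.numeric(stomach_weight),
         items = items,
         is_empty = !any(!vapply(items, `[[`, logical(1), "excluded"))),
    class = "stomach_record")
}

#' Construct a station record
#'
#' One trawl station: position, time, hydrography averaged over 0-50 m,
#' zooplankton dry-weight biomass and total mackerel catch. The derived
#' labels (`area`, `time_period`, `distance_to_shore_class`) are functions
#' of position, local time and bottom depth respectively.
#'
#' @param station_id identifier.
#' @param longitude,latitude decimal degrees.
#' @param datetime `POSIXct` or ISO-8601 string.
#' @param year survey year.
#' @param week_number ISO week of sampling.
#' @param bottom_depth m.
#' @param sst_0_50 mean 0-50 m temperature, deg C.
#' @param sss_0_50 mean 0-50 m practical salinity.
#' @param zooplankton_biomass mg dry weight / m3.
#' @param total_catch mackerel catch in the haul, kg.
#' @param area optional sub-area label; computed from position via
#'   [assign_area()] when `NULL`.
#' @param polygons area polygon config for [assign_area()].
#' @return object of class `station_record`.
#' @export
station_record <- function(station_id, longitude, latitude, datetime, year,
                           week_number, bottom_depth, sst_0_50, sss_0_50,
                           zooplankton_biomass, total_catch,
                           area = NULL, polygons = default_area_polygons()) {
  datetime <- as.POSIXct(datetime, tz = "UTC")
  if (is.na(datetime)) stop_validation("station '%s': unparseable datetime",
                                       station_id)
  if (is.null(area)) area <- assign_area(longitude, latitude, polygons)
  structure(
    list(station_id = as.character(station_id),
         longitude = as.numeric(longitude), latitude = as.numeric(latitude),
         datetime = datetime, year = as.integer(year),
         week_number = as.integer(week_number),
         bottom_depth = as.numeric(bottom_depth),
         sst_0_50 = as.numeric(sst_0_50), sss_0_50 = as.numeric(sss_0_50),
         zooplankton_biomass = as.numeric(zooplankton_biomass),
         total_catch = as.numeric(total_catch),
         area = as.character(area),
         distance_to_shore_class = as.character(assign_shore_class(bottom_depth)),
         time_period = as.character(assign_time_period(datetime))),
    class = "station_record")
}

#' @export
print.stomach_record <- function(x, ...) {
  cat(sprintf("<stomach_record> fish %s (station %s): %.0f cm, %.1f g, stomach %.2f g, %d prey item(s)%s\n",
              x$fish_id, x$station_id, x$length, x$body_weight,
              x$stomach_weight, length(x$items),
              if (x$is_empty) " [empty]" else ""))
  invisible(x)
}

#' @export
print.station_record <- function(x, ...) {
  cat(sprintf("<station_record> %s: %.2fE %.2fN, %s, area %s, period %s\n",
              x$station_id, x$longitude, x$latitude,
              format(x$datetime, "%Y-%m-%d %H:%M"), x$area, x$time_period))
  invisible(x)
}

# Canonical column names of the prey-item (stomach) CSV dialect.
stomach_columns <- function() {
  c(fish_id = "fish_id", station_id = "station_id", length = "length",
    body_weight = "body_weight", stomach_weight = "stomach_weight",
    taxon_name = "taxon_name", prey_group = "prey_group",
    count = "count", weight = "weight", prey_length = "prey_length")
}

resolve_dialect <- function(header, dialect, required, what) {
  map <- stomach_columns()
  if (!is.null(dialect)) map[names(dialect)] <- unlist(dialect)
  missing <- setdiff(required, names(map)[map %in% header])
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(map[missing], collapse = ", ")), call. = FALSE)
  map
}

#' Read a stomach table (one prey-item row per line) into records
#'
#' The file holds one row per prey item, with the fish-level fields repeated
#' on each row; fish with no prey rows are represented by a single row with
#' empty taxon fields. Column names can be remapped through `dialect`
#' (`list(canonical = "file_column")`).
#'
#' @param path CSV path.
#' @param dialect optional named list remapping canonical column names to
#'   the file's column names.
#' @return list of [stomach_record()] objects (class `stomach_records`).
#' @export
read_stomach_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  map <- resolve_dialect(names(raw), dialect,
                         c("fish_id", "station_id", "length", "body_weight",
                           "stomach_weight", "taxon_name", "prey_group",
                           "count", "weight"),
                         sprintf("read_stomach_table('%s')", path))
  get_col <- function(canon, default = NA) {
    if (map[[canon]] %in% names(raw)) raw[[map[[canon]]]]
    else rep(default, nrow(raw))
  }
  df <- data.frame(fish_id = as.character(get_col("fish_id")),
                   station_id = as.character(get_col("station_id")),
                   length = as.numeric(get_col("length")),
                   body_weight = as.numeric(get_col("body_weight")),
                   stomach_weight = as.numeric(get_col("stomach_weight")),
                   taxon_name = as.character(get_col("taxon_name")),
                   prey_group = as.character(get_col("prey_group")),
                   count = get_col("count"),
                   weight = get_col("weight"),
                   prey_length = as.numeric(get_col("prey_length", NA_real_)),
                   stringsAsFactors = FALSE)
  has_item <- !is.na(df$taxon_name) & nzchar(df$taxon_name)
  bad <- which(has_item & (is.na(suppressWarnings(as.numeric(df$count))) |
                             is.na(suppressWarnings(as.numeric(df$weight)))))
  if (length(bad))
    stop_validation("unparseable count/weight at data row(s): %s",
                    paste(bad, collapse = ", "))
  df$count <- as.numeric(df$count)
  df$weight <- as.numeric(df$weight)
  neg <- which(has_item & (df$count < 0 | df$weight < 0))
  if (length(neg))
    stop_validation("negative count/weight at data row(s): %s",
                    paste(neg, collapse = ", "))
  records_from_tables(df)
}

# Build stomach_record objects from the long prey-row data.frame.
records_from_tables <- function(df) {
  idx <- split(seq_len(nrow(df)), factor(df$fish_id, levels = unique(df$fish_id)))
  recs <- lapply(idx, function(i) {
    first <- i[[1]]
    items <- list()
    for (j in i) {
      if (!is.na(df$taxon_name[j]) && nzchar(df$taxon_name[j])) {
        items[[length(items) + 1L]] <- prey_item(
          df$taxon_name[j], df$prey_group[j], df$count[j], df$weight[j],
          df$prey_length[j])
      }
    }
    stomach_record(df$fish_id[first], df$station_id[first],
                   df$length[first], df$body_weight[first],
                   df$stomach_weight[first], items)
  })
  structure(unname(recs), class = "stomach_records")
}

#' @export
print.stomach_records <- function(x, ...) {
  n_empty <- sum(vapply(x, `[[`, logical(1), "is_empty"))
  cat(sprintf("<stomach_records> %d stomachs (%d empty) from %d station(s)\n",
              length(x), n_empty,
              length(unique(vapply(x, `[[`, character(1), "station_id")))))
  invisible(x)
}

#' Write stomach records back to the long CSV dialect
#'
#' Inverse of [read_stomach_table()]: numeric fields are written with full
#' precision so that a write-then-read round trip reproduces the records.
#'
#' @param records `stomach_records` (or plain list of `stomach_record`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stomach_table <- function(records, path) {
  rows <- lapply(records, function(r) {
    base <- data.frame(fish_id = r$fish_id, station_id = r$station_id,
                       length = r$length, body_weight = r$body_weight,
                       stomach_weight = r$stomach_weight,
                       stringsAsFactors = FALSE)
    if (length(r$items) == 0) {
      cbind(base, data.frame(taxon_name = "", prey_group = "",
                             count = NA_real_, weight = NA_real_,
                             prey_length = NA_real_))
    } else {
      do.call(rbind, lapply(r$items, function(it)
        cbind(base, data.frame(taxon_name = it$taxon_name,
                               prey_group = it$prey_group,
                               count = it$count, weight = it$weight,
                               prey_length = it$prey_length))))
    }
  })
  df <- do.call(rbind, rows)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a station table
#'
#' @param path CSV with columns `station_id, longitude, latitude, datetime,
#'   year, week_number, bottom_depth, sst_0_50, sss_0_50,
#'   zooplankton_biomass, total_catch` and optionally `area`.
#' @param polygons area polygons for [assign_area()] when `area` is absent.
#' @return list of [station_record()] objects (class `station_records`).
#' @export
read_station_table <- function(path, polygons = default_area_polygons()) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "longitude", "latitude", "datetime", "year",
            "week_number", "bottom_depth", "sst_0_50", "sss_0_50",
            "zooplankton_biomass", "total_catch")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("read_station_table('%s'): missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  recs <- lapply(seq_len(nrow(df)), function(i)
    station_record(df$station_id[i], df$longitude[i], df$latitude[i],
                   df$datetime[i], df$year[i], df$week_number[i],
                   df$bottom_depth[i], df$sst_0_50[i], df$sss_0_50[i],
                   df$zooplankton_biomass[i], df$total_catch[i],
                   area = if ("area" %in% names(df)) df$area[i] else NULL,
                   polygons = polygons))
  structure(recs, class = "station_records")
}

#' Write station records as CSV
#' @param stations `station_records` list.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_station_table <- function(stations, path) {
  df <- do.call(rbind, lapply(stations, function(s)
    data.frame(station_id = s$station_id, longitude = s$longitude,
               latitude = s$latitude,
               datetime = format(s$datetime, "%Y-%m-%dT%H:%M:%S"),
               year = s$year, week_number = s$week_number,
               bottom_depth = s$bottom_depth, sst_0_50 = s$sst_0_50,
               sss_0_50 = s$sss_0_50,
               zooplankton_biomass = s$zooplankton_biomass,
               total_catch = s$total_catch, area = s$area,
               stringsAsFactors = FALSE)))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
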