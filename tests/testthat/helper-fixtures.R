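# Shared fixture builders (all data constructed in code).

item <- function(group, count, weight, taxon = paste0(group, "_sp"))
  prey_item(taxon, group, count, weight)

fish <- function(id, station = "st1", len = 35, items = list(),
                 stomach_weight = 2, body_weight = 400)
  stomach_record(id, station, len, body_weight, stomach_weight, items)

station <- function(id = "st1", lon = -21, lat = 63.5, dt = "2013-07-10 09:30",
                    year = 2013, depth = 300, sst = 10, zoopl = 12,
                    catch = 400, area = NULL)
  station_record(id, lon, lat, dt, year,
                 week_number = as.integer(format(as.POSIXct(dt, tz = "UTC"), "%V")),
                 bottom_depth = depth, sst_0_50 = sst, sss_0_50 = 34.8,
                 zooplankton_biomass = zoopl, total_catch = catch,
                 area = area)

# diet_matrix straight from weight/count matrices (bypasses record plumbing
# for randomized property tests)
dm_from_matrices <- function(W, N = W) {
  stopifnot(all(dim(W) == dim(N)))
  if (is.null(colnames(W))) {
    colnames(W) <- colnames(N) <- prey_groups()[seq_len(ncol(W))]
  }
  ids <- rownames(W) %||% paste0("f", seq_len(nrow(W)))
  rownames(W) <- rownames(N) <- ids
  structure(list(weight = W, count = N,
                 labels = data.frame(fish_id = ids,
                                     station_id = "st1",
                                     length_group = factor("M", c("S", "M", "L")),
                                     stringsAsFactors = FALSE)),
            class = "diet_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random complete diet matrix: every group observed somewhere, some zeros
random_diet_matrix <- function(n = 8, g = 4) {
  repeat {
    W <- matrix(rexp(n * g), n, g) * (matrix(runif(n * g), n, g) > 0.3)
    N <- ceiling(W * 10)
    if (all(colSums(W) > 0) && all(rowSums(W) > 0)) break
  }
  dm_from_matrices(W, N)
}

# small fast generator config for tests
tiny_config <- function(...) {
  generator_config(n_stations = 2, stomachs_per_station = 10,
                   areas = c("N", "E", "SW"), years = 2013L, ...)
}
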