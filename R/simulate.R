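# Synthetic survey generator.
#
# Emulates the statistical structure the analysis assumes: stations with
# position/time/hydrography/zooplankton/catch, ~10 stomachs per station,
# per-stomach prey compositions drawn from a Dirichlet around an
# area-by-year base vector, Bernoulli empty stomachs, counts derived from
# weights through per-group mean individual prey masses (so numerical and
# gravimetric compositions diverge realistically), and a parametric
# covariate truth for log stomach weight (sine effect of temperature,
# a time-period-4 offset, optional linear zooplankton effect).

#' Default area-level base diet compositions
#'
#' Copepod-dominated everywhere, euphausiids elevated in the east and
#' southeast, large crustaceans in the north: an illustrative (not fitted)
#' qualitative mimic of the surveyed spatial pattern.
#'
#' @return matrix areas x prey groups, rows summing to 1.
#' @export
default_base_composition <- function() {
  g <- prey_groups()
  comp <- rbind(
    N  = c(molluscs = 3, copepods = 45, amphipods = 8, euphausiids = 8,
           large_crustaceans = 16, small_crustaceans = 3, fish = 9,
           appendicularians = 3, chaetognaths = 3, ova = 2),
    E  = c(3, 50, 8, 20, 5, 3, 4, 3, 2, 2),
    SE = c(3, 52, 8, 17, 5, 4, 4, 3, 2, 2),
    SW = c(4, 60, 7, 7, 4, 8, 3, 3, 2, 2),
    W  = c(4, 62, 8, 6, 4, 5, 4, 3, 2, 2))
  colnames(comp) <- g
  sweep(comp, 1, rowSums(comp), "/")
}

#' Default mean individual prey mass per group (g)
#' @return named numeric vector.
#' @export
default_prey_mass <- function() {
  c(molluscs = 0.01, copepods = 0.0003, amphipods = 0.02,
    euphausiids = 0.1, large_crustaceans = 0.5, small_crustaceans = 0.005,
    fish = 5, appendicularians = 0.002, chaetognaths = 0.01, ova = 0.0005)
}

#' Generator configuration
#'
#' The stated world of the simulator. Defaults: 5 stations per area-year
#' cell, 10 stomachs per station, Dirichlet concentration 50 around the
#' area base composition, empty-stomach probability 0.083 (the surveyed
#' average vacuity of 8.3%), lognormal total content weight, and a
#' covariate truth for log stomach weight of
#' `intercept + A * sin(SST / 2) + period4 offset + b * log(zoopl) +
#' N(0, sigma_e)`.
#'
#' @param n_stations stations per area x year cell.
#' @param stomachs_per_station stomachs sampled per station.
#' @param areas,years design levels.
#' @param base_composition areas x groups matrix of base diet proportions.
#' @param concentration Dirichlet concentration around the base.
#' @param vacuity empty-stomach probability in \[0, 1).
#' @param fullness_meanlog,fullness_sdlog lognormal parameters of the
#'   total identified content weight (g) of a non-empty stomach.
#' @param mean_prey_mass per-group mean individual prey mass (g) used to
#'   turn group weights into (real-valued) counts.
#' @param year_effects optional named list (year -> named multiplier
#'   vector over groups) perturbing the base composition.
#' @param effects covariate truth: `intercept`, `sst_amplitude`,
#'   `zoopl_slope_log`, `period4_offset`, `sigma_e`.
#' @param length_mean,length_sd predator total-length distribution (cm),
#'   truncated to (20, 50).
#' @param condition_mean,condition_sd Fulton's K distribution giving body
#'   weight from length.
#' @param area_sst named base 0-50 m temperatures per area (deg C).
#' @param seed master seed; per-station sub-streams are keyed by station
#'   id so draws are stable under station re-ordering.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_stations = 5, stomachs_per_station = 10,
                             areas = c("N", "E", "SE", "SW", "W"),
                             years = 2011:2014,
                             base_composition = default_base_composition(),
                             concentration = 50,
                             vacuity = 0.083,
                             fullness_meanlog = log(3), fullness_sdlog = 0.8,
                             mean_prey_mass = default_prey_mass(),
                             year_effects = NULL,
                             effects = list(intercept = 0.7,
                                            sst_amplitude = 0.25,
                                            zoopl_slope_log = 0,
                                            period4_offset = -0.065,
                                            sigma_e = 0.3),
                             length_mean = 36, length_sd = 3.5,
                             condition_mean = 0.85, condition_sd = 0.05,
                             area_sst = c(N = 7, E = 8, SE = 10, SW = 11, W = 9),
                             seed = 1) {
  if (!is_number(vacuity) || vacuity < 0 || vacuity >= 1)
    stop_validation("vacuity must lie in [0, 1)")
  if (!is_number(concentration) || concentration <= 0 ||
      !is_number(fullness_sdlog) || fullness_sdlog <= 0 ||
      any(mean_prey_mass <= 0))
    stop_validation("scale parameters must be positive")
  base_composition <- base_composition[areas, prey_groups(), drop = FALSE]
  if (any(base_composition < 0) ||
      any(abs(rowSums(base_composition) - 1) > 1e-8))
    stop_validation("base_composition rows must be probability vectors")
  defaults <- list(intercept = 0.7, sst_amplitude = 0.25,
                   zoopl_slope_log = 0, period4_offset = -0.065,
                   sigma_e = 0.3)
  effects <- utils::modifyList(defaults, effects)
  structure(list(n_stations = n_stations,
                 stomachs_per_station = stomachs_per_station,
                 areas = areas, years = years,
                 base_composition = base_composition,
                 concentration = concentration, vacuity = vacuity,
                 fullness_meanlog = fullness_meanlog,
                 fullness_sdlog = fullness_sdlog,
                 mean_prey_mass = mean_prey_mass,
                 year_effects = year_effects, effects = effects,
                 length_mean = length_mean, length_sd = length_sd,
                 condition_mean = condition_mean,
                 condition_sd = condition_sd,
                 area_sst = area_sst, seed = seed),
            class = "generator_config")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1  # degenerate guard
  x / sum(x)
}

# composition expected for an area x year cell (base perturbed by year effect)
cell_composition <- function(config, area, year) {
  p <- config$base_composition[area, ]
  ye <- config$year_effects[[as.character(year)]]
  if (!is.null(ye)) {
    p[names(ye)] <- p[names(ye)] * ye
    p <- p / sum(p)
  }
  p
}

# the parametric covariate truth on the log-stomach-weight scale
truth_eta <- function(effects, sst, zoopl, time_period) {
  effects$intercept + effects$sst_amplitude * sin(sst / 2) +
    effects$zoopl_slope_log * log(zoopl) +
    effects$period4_offset * (time_period == "P4")
}

#' Generate a synthetic survey dataset
#'
#' Draws stations and stomachs under a [generator_config()]. Per-station
#' randomness runs in a sub-stream keyed by the station id, so the same
#' seed reproduces the dataset exactly regardless of generation order.
#'
#' @param config a `generator_config`.
#' @param out_dir optional directory; when given, `stomachs.csv`,
#'   `stations.csv` and `truth.json` are written there in the exact
#'   dialects the readers consume.
#' @return list of class `synthetic_survey`: `stomachs`
#'   (`stomach_records`), `stations` (`station_records`), `truth`
#'   (the manifest: config echo, per-cell expected compositions, the
#'   covariate truth functional form).
#' @export
generate <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  groups <- prey_groups()
  polys <- default_area_polygons()
  stations <- list(); stomachs <- list()
  cell_comps <- list()
  for (year in config$years) {
    for (area in config$areas) {
      p_cell <- cell_composition(config, area, year)
      cell_comps[[paste(year, area, sep = ":")]] <- p_cell
      for (i in seq_len(config$n_stations)) {
        sid <- sprintf("st_%d_%s_%02d", year, area, i)
        res <- with_seed(sub_seed(config$seed, sid), {
          box <- polys[[area]]
          lon <- runif(1, min(box[, 1]) + 0.5, max(box[, 1]) - 0.5)
          lat <- runif(1, min(box[, 2]) + 0.3, max(box[, 2]) - 0.3)
          day <- sample(0:45, 1)    # July 1 + 0..45 days
          hour <- sample(0:23, 1)
          dt <- as.POSIXct(sprintf("%d-07-01", year), tz = "UTC") +
            day * 86400 + hour * 3600 + sample(0:59, 1) * 60
          sst <- config$area_sst[[area]] + runif(1, -1.5, 1.5)
          station <- station_record(
            sid, lon, lat, dt, year,
            week_number = as.integer(format(dt, "%V")),
            bottom_depth = runif(1, 60, 1400),
            sst_0_50 = sst, sss_0_50 = runif(1, 34, 35.5),
            zooplankton_biomass = rlnorm(1, log(10), 0.6),
            total_catch = rlnorm(1, log(500), 0.8),
            area = area, polygons = polys)
          fish <- lapply(seq_len(config$stomachs_per_station), function(j) {
            len <- min(max(rnorm(1, config$length_mean, config$length_sd),
                           20.5), 49.5)
            kf <- max(rnorm(1, config$condition_mean, config$condition_sd),
                      0.5)
            bw <- kf * len^3 / 100
            eta <- truth_eta(config$effects, sst,
                             station$zooplankton_biomass,
                             station$time_period)
            sw <- exp(eta + rnorm(1, 0, config$effects$sigma_e))
            empty <- runif(1) < config$vacuity
            items <- list()
            if (!empty) {
              comp <- rdirichlet1(config$concentration * p_cell)
              total_w <- rlnorm(1, config$fullness_meanlog,
                                config$fullness_sdlog)
              w <- comp * total_w
              for (k in seq_along(groups)) {
                if (w[k] <= 0) next
                items[[length(items) + 1L]] <- prey_item(
                  paste0(groups[k], "_sp"), groups[k],
                  count = w[k] / config$mean_prey_mass[[groups[k]]],
                  weight = w[k])
              }
            }
            stomach_record(sprintf("%s_f%02d", sid, j), sid, len, bw, sw,
                           items)
          })
          list(station = station, fish = fish)
        })
        stations[[length(stations) + 1L]] <- res$station
        stomachs <- c(stomachs, res$fish)
      }
    }
  }
  truth <- list(
    config = config[setdiff(names(config), "base_composition")],
    base_composition = config$base_composition,
    cell_compositions = cell_comps,
    covariate_truth = list(
      form = "intercept + A*sin(SST/2) + b*log(zoopl) + c*1(period == P4)",
      parameters = config$effects))
  out <- structure(list(stomachs = structure(stomachs,
                                             class = "stomach_records"),
                        stations = structure(stations,
                                             class = "station_records"),
                        truth = truth),
                   class = "synthetic_survey")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stomach_table(out$stomachs, file.path(out_dir, "stomachs.csv"))
    write_station_table(out$stations, file.path(out_dir, "stations.csv"))
    tr <- truth
    tr$base_composition <- as.data.frame(tr$base_composition)
    jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  out
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat(sprintf("<synthetic_survey> %d stomachs at %d stations (seed %s)\n",
              length(x$stomachs), length(x$stations),
              format(x$truth$config$seed)))
  invisible(x)
}

#' Null configuration for a named factor
#'
#' Returns a config in which the named factor has no effect: for `area`,
#' every area shares the mean base composition and temperature; for
#' `year`, year effects are removed; for `length_group`, the generator is
#' already length-neutral; for covariates (`sst`, `zooplankton`,
#' `time_period`), the corresponding truth effect is zeroed.
#'
#' @param config a `generator_config`.
#' @param factor one of `"area"`, `"year"`, `"length_group"`, `"sst"`,
#'   `"zooplankton"`, `"time_period"`.
#' @return a modified `generator_config`.
#' @export
make_null_dataset <- function(config,
                              factor = c("area", "year", "length_group",
                                         "sst", "zooplankton",
                                         "time_period")) {
  stopifnot(inherits(config, "generator_config"))
  factor <- match.arg(factor)
  if (factor == "area") {
    mean_comp <- colMeans(config$base_composition)
    config$base_composition[] <- rep(mean_comp,
                                     each = nrow(config$base_composition))
    config$area_sst[] <- mean(config$area_sst)
  } else if (factor == "year") {
    config$year_effects <- NULL
  } else if (factor == "sst") {
    config$effects$sst_amplitude <- 0
  } else if (factor == "zooplankton") {
    config$effects$zoopl_slope_log <- 0
  } else if (factor == "time_period") {
    config$effects$period4_offset <- 0
  }
  # length_group: generator draws diet independently of length already
  config
}

#' Compare estimates from a synthetic dataset against its truth manifest
#'
#' Recomputes the headline quantities from the generated records and sets
#' them against the manifest: overall vacuity vs the configured rate,
#' pooled per-area gravimetric composition vs the expected (Dirichlet
#' mean) composition, and the covariate-truth coefficients re-estimated by
#' ordinary least squares on the true basis functions.
#'
#' @param survey a `synthetic_survey` from [generate()].
#' @return data.frame with columns `quantity`, `estimated`, `truth`,
#'   `abs_error`.
#' @export
recovery_report <- function(survey) {
  stopifnot(inherits(survey, "synthetic_survey"))
  cfg <- survey$truth$config
  rows <- list()
  add <- function(q, est, tru)
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = q, estimated = est, truth = tru,
      abs_error = abs(est - tru), stringsAsFactors = FALSE)

  empties <- vapply(survey$stomachs, `[[`, logical(1), "is_empty")
  add("vacuity_percent", vacuity_index(sum(empties), length(empties)),
      100 * cfg$vacuity)

  dm <- build_diet_matrix(survey$stomachs, survey$stations)
  for (area in unique(dm$labels$area)) {
    sub <- subset_diet_matrix(dm, dm$labels$area == area)
    pw <- composition(sub, "weight")
    expected <- 100 * Reduce(`+`, lapply(
      survey$truth$cell_compositions[grepl(paste0(":", area, "$"),
                                           names(survey$truth$cell_compositions))],
      identity)) / sum(grepl(paste0(":", area, "$"),
                             names(survey$truth$cell_compositions)))
    for (gname in names(pw))
      add(sprintf("percent_W[%s, %s]", area, gname), pw[[gname]],
          expected[[gname]])
  }

  # covariate truth re-estimated by OLS on the true basis
  skey <- vapply(survey$stations, `[[`, character(1), "station_id")
  st <- vapply(survey$stomachs, `[[`, character(1), "station_id")
  m <- match(st, skey)
  df <- data.frame(
    y = log(vapply(survey$stomachs, `[[`, numeric(1), "stomach_weight")),
    sin_sst = sin(vapply(survey$stations, `[[`, numeric(1), "sst_0_50")[m] / 2),
    log_zoopl = log(vapply(survey$stations, `[[`, numeric(1),
                           "zooplankton_biomass")[m]),
    p4 = as.numeric(vapply(survey$stations, `[[`, character(1),
                           "time_period")[m] == "P4"))
  fit <- stats::lm(y ~ sin_sst + log_zoopl + p4, data = df)
  cf <- stats::coef(fit)
  eff <- survey$truth$covariate_truth$parameters
  add("coef_intercept", unname(cf["(Intercept)"]), eff$intercept)
  add("coef_sst_amplitude", unname(cf["sin_sst"]), eff$sst_amplitude)
  add("coef_zoopl_slope_log", unname(cf["log_zoopl"]),
      eff$zoopl_slope_log)
  add("coef_period4_offset", unname(cf["p4"]), eff$period4_offset)
  do.call(rbind, rows)
}
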