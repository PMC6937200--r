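# End-to-end orchestration: simulate or ingest -> filter -> indices ->
# strategy coordinates -> area clustering -> PERMANOVA -> nonparametric
# length-group tests -> (optional) additive-model ranking, with every
# table written to an output directory plus a reproducibility manifest.

#' Run the full stomach-content analysis pipeline
#'
#' @param config list (or path to a JSON file) with entries:
#'   \describe{
#'     \item{seed}{integer; mandatory whenever a stochastic step
#'       (simulation or permutation tests) is requested.}
#'     \item{simulate}{optional list of [generator_config()] arguments;
#'       when absent, `stomach_csv` and `station_csv` paths are required.}
#'     \item{stomach_csv, station_csv}{input files when not simulating.}
#'     \item{analyses}{character subset of
#'       `c("indices", "strategy", "cluster", "permanova", "kruskal",
#'       "gam")`; default all.}
#'     \item{n_perm}{permutations for PERMANOVA (default 999).}
#'     \item{gam_pool, gam_factors}{candidate smooth pool / fixed factor
#'       terms for the model ranking (defaults
#'       `c("zooplankton", "sst", "depth")`, `c("time_period")`).}
#'     \item{out_dir}{output directory (required).}
#'   }
#' @return `out_dir`, invisibly; side effect: CSV/JSON/Newick outputs and
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% stop_validation("config needs out_dir")
  analyses <- config$analyses %||%
    c("indices", "strategy", "cluster", "permanova", "kruskal", "gam")
  stochastic <- !is.null(config$simulate) ||
    any(c("permanova", "gam") %in% analyses)
  if (stochastic && is.null(config$seed))
    stop_validation("config needs a seed: stochastic steps requested (%s)",
                    paste(intersect(analyses, c("permanova", "gam")),
                          collapse = ", "))
  n_perm <- config$n_perm %||% 999
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat("", file = log_path)
  stage <- "ingest"
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      gc_args <- config$simulate
      gc_args$seed <- gc_args$seed %||% config$seed
      cfg <- do.call(generator_config, gc_args)
      sim <- generate(cfg, out_dir = file.path(out_dir, "simulated"))
      stomachs <- sim$stomachs; stations <- sim$stations
      input_files <- c(file.path(out_dir, "simulated", "stomachs.csv"),
                       file.path(out_dir, "simulated", "stations.csv"))
      logf("simulated %d stomachs at %d stations (seed %s)",
           length(stomachs), length(stations), format(cfg$seed))
    } else {
      stomachs <- read_stomach_table(config$stomach_csv)
      stations <- read_station_table(config$station_csv)
      input_files <- c(config$stomach_csv, config$station_csv)
      logf("read %d stomachs, %d stations", length(stomachs),
           length(stations))
    }

    stage <- "filter"
    filtered <- apply_model_filters(stomachs, stations)
    r <- filtered$report
    logf("filter: %d in; removed %d fish < 25 cm; removed %d at sparse stations; %d retained",
         r$n_input, r$n_removed_small_fish, r$n_removed_sparse_stations,
         r$n_retained)
    jsonlite::write_json(r, file.path(out_dir, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA)
    dm <- build_diet_matrix(filtered$stomachs, filtered$stations)

    if ("indices" %in% analyses) {
      stage <- "indices"
      it <- index_table(dm)
      df <- as.data.frame(it)
      df$vacuity <- attr(it, "vacuity")
      write.csv(df, file.path(out_dir, "index_table.csv"),
                row.names = FALSE)
      logf("indices: %d prey groups, vacuity %.2f%%", nrow(it),
           attr(it, "vacuity"))
    }
    if ("strategy" %in% analyses) {
      stage <- "strategy"
      sp <- amundsen_points(dm)
      write.csv(as.data.frame(sp),
                file.path(out_dir, "strategy_points.csv"), row.names = FALSE)
      logf("strategy: %d points", nrow(sp))
    }
    if ("cluster" %in% analyses) {
      stage <- "cluster"
      # pool stomachs by area, then fourth-root Bray-Curtis + UPGMA
      pooled <- rowsum(dm$weight, dm$labels$area)
      tree <- upgma(bray_curtis(fourth_root(pooled)))
      writeLines(to_newick(tree), file.path(out_dir, "dendrogram.nwk"))
      sims <- data.frame(merge = seq_len(nrow(tree$merges)),
                         height = tree$merges$height,
                         percent_similarity = 100 * (1 - tree$merges$height))
      write.csv(sims, file.path(out_dir, "cluster_similarity.csv"),
                row.names = FALSE)
      logf("cluster: %d areas, similarity %.1f-%.1f%%", nrow(pooled),
           min(sims$percent_similarity), max(sims$percent_similarity))
    }
    if ("permanova" %in% analyses) {
      stage <- "permanova"
      # empty stomachs carry no composition; drop them before dissimilarity
      nonempty <- rowSums(dm$weight) > 0
      dmn <- subset_diet_matrix(dm, nonempty)
      logf("permanova: dropped %d empty stomach(s)", sum(!nonempty))
      D <- bray_curtis(fourth_root(dmn))
      area <- dmn$labels$area; year <- factor(dmn$labels$year)
      two <- permanova_twoway(D, area, year, n_perm = n_perm,
                              seed = config$seed)
      write.csv(as.data.frame(two),
                file.path(out_dir, "permanova_twoway.csv"),
                row.names = FALSE)
      pw <- permanova_pairwise(D, area, n_perm = n_perm,
                               seed = config$seed)
      write.csv(as.data.frame(pw),
                file.path(out_dir, "permanova_pairwise_area.csv"),
                row.names = FALSE)
      logf("permanova: two-way + %d pairwise rows (%d permutations)",
           nrow(pw), n_perm)
    }
    if ("kruskal" %in% analyses) {
      stage <- "kruskal"
      total_w <- rowSums(dm$weight)
      kw <- kruskal_wallis(total_w, dm$labels$length_group)
      kout <- data.frame(H = kw$H, df = kw$df, p = kw$p, n = kw$n)
      write.csv(kout, file.path(out_dir, "kruskal_lengthgroup.csv"),
                row.names = FALSE)
      if (kw$p < (config$alpha %||% 0.05)) {
        dn <- dunns_posthoc(total_w, dm$labels$length_group)
        write.csv(as.data.frame(dn),
                  file.path(out_dir, "dunn_lengthgroup.csv"),
                  row.names = FALSE)
        logf("kruskal: H = %.3f, p = %.4g; Dunn post hoc written", kw$H,
             kw$p)
      } else {
        logf("kruskal: H = %.3f, p = %.4g; no post hoc", kw$H, kw$p)
      }
    }
    if ("gam" %in% analyses) {
      stage <- "gam"
      mt <- model_table(filtered)
      # station-level covariates have one unique value per station; keep the
      # basis dimension below that
      k_use <- config$gam_k %||%
        max(3, min(10, length(unique(mt$station_id)) - 1L))
      ranking <- candidate_search(
        config$gam_pool %||% c("zooplankton", "sst", "depth"), mt,
        factors = config$gam_factors %||% "time_period", k = k_use)
      write.csv(as.data.frame(ranking),
                file.path(out_dir, "model_ranking.csv"), row.names = FALSE)
      best <- attr(ranking, "fits")[[ranking$model[1]]]
      if (!is.null(best$parametric_terms))
        write.csv(best$parametric_terms,
                  file.path(out_dir, "best_model_parametric.csv"),
                  row.names = FALSE)
      if (!is.null(best$smooth_terms))
        write.csv(best$smooth_terms,
                  file.path(out_dir, "best_model_smooths.csv"),
                  row.names = FALSE)
      logf("gam: best model %s (AIC %.2f)", ranking$model[1],
           ranking$AIC[1])
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("dietstat")),
      r_version = R.version.string,
      seed = config$seed,
      n_perm = n_perm,
      analyses = analyses,
      input_md5 = as.list(tools::md5sum(input_files)),
      config = config[setdiff(names(config), "out_dir")])
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    out_dir
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s (partial outputs kept in %s)",
                 stage, conditionMessage(e), out_dir), call. = FALSE)
  })
  invisible(result)
}

#' Render a human-readable report from pipeline outputs
#'
#' Collects the pipeline's tables into one plain-text summary (written as
#' `report.txt` in the output directory). Sections whose inputs are
#' missing are marked "not run". Regeneration is idempotent.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @return the report path, invisibly.
#' @export
render_reports <- function(out_dir) {
  if (!dir.exists(out_dir))
    stop_validation("render_reports: no such directory: %s", out_dir)
  path <- file.path(out_dir, "report.txt")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  band <- function(p) ifelse(is.na(p), "NA",
                      ifelse(p < 0.001, "<0.001", ifelse(p < 0.01, "<0.01",
                      ifelse(p < 0.05, "<0.05", ifelse(p > 0.1, ">0.1",
                             sprintf("%.3f", p))))))
  section <- function(title, file, fmt) {
    w("== %s ==", title)
    f <- file.path(out_dir, file)
    if (file.exists(f)) fmt(read.csv(f, stringsAsFactors = FALSE))
    else w("not run")
    w("")
  }
  w("dietstat pipeline report")
  w("========================")
  w("")
  section("Diet indices", "index_table.csv", function(df) {
    w("vacuity: %.1f%%", df$vacuity[1])
    for (i in seq_len(nrow(df)))
      w("  %-18s %%N %5.1f  %%W %5.1f  FO %5.1f  PW %5.1f  PN %5.1f  PSIRI %5.1f",
        df$prey_group[i], df$percent_N[i], df$percent_W[i], df$FO[i],
        df$PW[i], df$PN[i], df$PSIRI[i])
  })
  section("Feeding strategy", "strategy_points.csv", function(df) {
    for (i in seq_len(nrow(df)))
      w("  %-18s FO %5.1f  Pi %5.1f  -> %s", df$prey_group[i], df$FO[i],
        df$Pi[i], df$quadrant[i])
  })
  section("Area clustering", "cluster_similarity.csv", function(df) {
    nwk <- file.path(out_dir, "dendrogram.nwk")
    if (file.exists(nwk)) w("  %s", readLines(nwk)[1])
    for (i in seq_len(nrow(df)))
      w("  merge %d at %.1f%% similarity", df$merge[i],
        df$percent_similarity[i])
  })
  section("PERMANOVA", "permanova_twoway.csv", function(df) {
    for (i in seq_len(nrow(df)))
      w("  %-10s df %3d  SS %8.3f  pseudo-F %s  p %s", df$term[i],
        df$df[i], df$SS[i],
        ifelse(is.na(df$pseudo_F[i]), "   -  ",
               sprintf("%6.2f", df$pseudo_F[i])), band(df$p[i]))
    pwf <- file.path(out_dir, "permanova_pairwise_area.csv")
    if (file.exists(pwf)) {
      pw <- read.csv(pwf, stringsAsFactors = FALSE)
      for (i in seq_len(nrow(pw)))
        w("  pairwise %s-%s: F %.2f, p %s", pw$group1[i], pw$group2[i],
          pw$pseudo_F[i], band(pw$p[i]))
    }
  })
  section("Model ranking", "model_ranking.csv", function(df) {
    for (i in seq_len(nrow(df)))
      w("  %-30s AIC %9.2f  dAIC %6.2f  w %5.3f%s", df$model[i],
        df$AIC[i], df$delta_AIC[i], df$weight[i],
        ifelse(df$in_confidence_set[i], "  [95% set]", ""))
  })
  invisible(path)
}
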