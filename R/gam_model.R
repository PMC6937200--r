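# Additive modelling of log stomach weight.
#
# The penalized-spline/REML engine is deliberately delegated to mgcv::gam
# (Gaussian family, identity link, REML smoothness selection) behind the
# single entry point fit_additive_model(); design construction, candidate
# enumeration, AIC bookkeeping, Akaike weights and the confidence set are
# implemented here.

# canonical smooth-term pool: name -> mgcv formula fragment
smooth_term_pool <- function(k = 10) {
  c(zooplankton = sprintf("s(zooplankton, k = %d)", k),
    lonlat      = sprintf("s(longitude, latitude, k = %d)", 3 * k),
    depth       = sprintf("s(bottom_depth, k = %d)", k),
    sss         = sprintf("s(sss, k = %d)", k),
    sst         = sprintf("s(sst, k = %d)", k),
    log_catch   = sprintf("s(log_catch, k = %d)", k),
    fulton_k    = sprintf("s(fulton_k, k = %d)", k))
}

factor_term_pool <- function() {
  c(time_period = "time_period", shore = "shore_class",
    week = "week", year = "year")
}

#' Specify an additive model of log stomach weight
#'
#' The response is fixed to `log(stomach_weight)`; explanatory terms are
#' drawn from the survey's variable list: smooth terms over
#' `zooplankton`, `lonlat` (a joint isotropic surface), `depth`, `sss`,
#' `sst`, `log_catch`, `fulton_k`, and factor terms over `time_period`,
#' `shore`, `week`, `year`. The family is Gaussian with identity link and
#' smoothing parameters are selected by REML.
#'
#' @param smooth character vector of smooth-term names (possibly empty).
#' @param factors character vector of factor-term names (possibly empty).
#' @param k basis dimension per 1-D smooth (default 10; the 2-D surface
#'   gets 3k).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(smooth = character(), factors = character(), k = 10) {
  pool_s <- smooth_term_pool(k)
  pool_f <- factor_term_pool()
  bad <- setdiff(smooth, names(pool_s))
  if (length(bad)) stop_validation("unknown smooth term(s): %s",
                                   paste(bad, collapse = ", "))
  bad <- setdiff(factors, names(pool_f))
  if (length(bad)) stop_validation("unknown factor term(s): %s",
                                   paste(bad, collapse = ", "))
  rhs <- c(pool_s[smooth], pool_f[factors])
  formula_text <- paste("log_stomach_weight ~",
                        if (length(rhs)) paste(rhs, collapse = " + ") else "1")
  structure(list(smooth = smooth, factors = factors, k = k,
                 formula = stats::as.formula(formula_text),
                 formula_text = formula_text),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$formula_text, "\n")
  invisible(x)
}

# Pairwise-correlation collinearity screen over the numeric covariates a
# spec uses; exact duplicates are an error, high correlation a warning.
check_collinearity <- function(data, smooth, threshold = 0.95) {
  vars <- c(zooplankton = "zooplankton", depth = "bottom_depth",
            sss = "sss", sst = "sst", log_catch = "log_catch",
            fulton_k = "fulton_k")
  use <- intersect(unname(vars[intersect(names(vars), smooth)]), names(data))
  if (length(use) < 2) return(invisible(NULL))
  cm <- suppressWarnings(cor(data[use], use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  hits <- which(abs(cm) > threshold & upper.tri(cm), arr.ind = TRUE)
  if (nrow(hits)) {
    pairs <- apply(hits, 1, function(ix)
      sprintf("%s~%s (r = %.3f)", use[ix[1]], use[ix[2]], cm[ix[1], ix[2]]))
    if (any(abs(cm[hits]) > 1 - 1e-12))
      stop_validation("aliased (duplicated) covariates: %s",
                      paste(pairs, collapse = ", "))
    warning("collinear covariates: ", paste(pairs, collapse = ", "),
            call. = FALSE)
  }
  invisible(NULL)
}

#' Fit an additive model of log stomach weight
#'
#' Penalized-spline additive fit (Gaussian, identity link, REML smoothing
#' selection via mgcv) of log stomach weight on the terms of a
#' [model_spec()]. The data must have passed [apply_model_filters()] (the
#' [model_table()] output carries the required flag); pass
#' `assume_filtered = TRUE` to override for already-clean data.
#'
#' @param spec a `model_spec`.
#' @param data a [model_table()] data.frame.
#' @param assume_filtered skip the filtered-data check.
#' @param check_collinear run the pairwise collinearity screen.
#' @param ... passed to the spline engine (e.g. `sp` to fix smoothing
#'   parameters).
#' @return object of class `stomach_gam`: the mgcv fit plus `aic`,
#'   `deviance_explained` (fraction), `r_squared_adj`, `df` (model degrees
#'   of freedom), `spec`, and per-smooth significance in `smooth_terms`.
#' @export
fit_additive_model <- function(spec, data, assume_filtered = FALSE,
                               check_collinear = TRUE, ...) {
  stopifnot(inherits(spec, "model_spec"))
  if (!assume_filtered && !isTRUE(attr(data, "filtered")))
    stop_validation(paste0("data is not flagged as filtered; run ",
                           "apply_model_filters() + model_table() first ",
                           "(or set assume_filtered = TRUE)"))
  if (check_collinear) check_collinearity(data, spec$smooth)
  data <- droplevels(data)
  fit <- mgcv::gam(spec$formula, data = data, family = stats::gaussian(),
                   method = "REML", ...)
  sm <- summary(fit)
  smooth_terms <- if (length(spec$smooth)) {
    data.frame(term = rownames(sm$s.table), edf = sm$s.table[, "edf"],
               F = sm$s.table[, "F"], p = sm$s.table[, "p-value"],
               row.names = NULL, stringsAsFactors = FALSE)
  } else NULL
  structure(list(fit = fit, spec = spec,
                 aic = stats::AIC(fit),
                 deviance_explained = sm$dev.expl,
                 r_squared_adj = sm$r.sq,
                 df = sum(fit$edf) ,
                 smooth_terms = smooth_terms,
                 parametric_terms = if (!is.null(sm$p.table))
                   data.frame(term = rownames(sm$p.table),
                              estimate = sm$p.table[, 1], se = sm$p.table[, 2],
                              t = sm$p.table[, 3], p = sm$p.table[, 4],
                              row.names = NULL, stringsAsFactors = FALSE)
                 else NULL,
                 n = nrow(data)),
            class = "stomach_gam")
}

#' @export
print.stomach_gam <- function(x, ...) {
  cat(sprintf("Additive stomach-weight model: %s\n", x$spec$formula_text))
  cat(sprintf("  n = %d, AIC = %.2f, deviance explained = %.1f%%, adj-R2 = %.3f\n",
              x$n, x$aic, 100 * x$deviance_explained, x$r_squared_adj))
  if (!is.null(x$smooth_terms)) {
    cat("  smooth terms:\n")
    st <- x$smooth_terms
    for (i in seq_len(nrow(st)))
      cat(sprintf("    %-28s edf = %6.3f  F = %7.3f  p = %.3g\n",
                  st$term[i], st$edf[i], st$F[i], st$p[i]))
  }
  invisible(x)
}

#' Evaluate a fitted smooth on a grid with pointwise 95% bands
#'
#' @param model a `stomach_gam`.
#' @param term smooth term label as in `model$smooth_terms$term`
#'   (e.g. `"s(sst)"`).
#' @param n grid size.
#' @return data.frame with the covariate grid, `fit`, `lower`, `upper`.
#' @export
smooth_curve <- function(model, term, n = 100) {
  stopifnot(inherits(model, "stomach_gam"))
  fit <- model$fit
  labs <- vapply(fit$smooth, function(s) s$label, character(1))
  k <- match(term, labs)
  if (is.na(k)) stop_validation("no smooth term '%s' in model", term)
  vars <- fit$smooth[[k]]$term
  mf <- fit$model
  grid <- list()
  for (v in names(mf)) {
    col <- mf[[v]]
    grid[[v]] <- if (v %in% vars) seq(min(col), max(col), length.out = n)
    else if (is.factor(col)) factor(rep(levels(col)[1], n), levels(col))
    else rep(mean(col), n)
  }
  nd <- as.data.frame(grid, stringsAsFactors = FALSE)
  pr <- mgcv::predict.gam(fit, newdata = nd, type = "terms", se.fit = TRUE)
  est <- pr$fit[, term]
  se <- pr$se.fit[, term]
  out <- nd[vars]
  out$fit <- est
  out$lower <- est - 1.96 * se
  out$upper <- est + 1.96 * se
  out
}

#' Akaike ranking of candidate models
#'
#' From raw AIC values (or directly from printed Delta-AIC values),
#' computes `ΔAIC_i = AIC_i - min(AIC)`, Akaike weights
#' `w_i = exp(-ΔAIC_i / 2) / sum_j exp(-ΔAIC_j / 2)`, and the 95%
#' confidence-set flag (smallest weight-ordered subset with cumulative
#' weight >= level).
#'
#' @param aic numeric AIC values (ignored when `delta` is given).
#' @param delta optional Delta-AIC values taken at face value.
#' @param models optional model labels.
#' @param extra optional data.frame of per-model columns to carry along
#'   (deviance explained, adjusted R2, df, ...).
#' @param level confidence-set level (default 0.95).
#' @return data.frame of class `model_ranking`, sorted by weight, with
#'   columns `model`, `AIC`, `delta_AIC`, `weight`, `in_confidence_set`.
#' @export
akaike_table <- function(aic = NULL, delta = NULL, models = NULL,
                         extra = NULL, level = 0.95) {
  if (is.null(aic) && is.null(delta))
    stop_validation("akaike_table: supply aic or delta")
  if (is.null(delta)) {
    if (!length(aic)) stop_validation("akaike_table: empty candidate list")
    delta <- aic - min(aic)
  } else if (!length(delta)) {
    stop_validation("akaike_table: empty candidate list")
  }
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(
    model = models %||% paste0("model_", seq_along(delta)),
    AIC = if (is.null(aic)) NA_real_ else aic,
    delta_AIC = delta, weight = w, stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out <- out[order(-out$weight, out$delta_AIC), , drop = FALSE]
  rownames(out) <- NULL
  out$in_confidence_set <- confidence_set(out$weight, level = level)
  structure(out, class = c("model_ranking", "data.frame"), level = level)
}

#' 95% confidence set of models
#'
#' Flags the smallest prefix of weight-sorted models whose cumulative
#' Akaike weight reaches `level`.
#'
#' @param weights Akaike weights (any order; a `model_ranking` also works).
#' @param level cumulative-weight level in (0, 1\].
#' @return logical vector in the input order.
#' @export
confidence_set <- function(weights, level = 0.95) {
  if (inherits(weights, "model_ranking")) weights <- weights$weight
  stopifnot(level > 0, level <= 1)
  ord <- order(-weights)
  cum <- cumsum(weights[ord])
  k <- which(cum >= level * sum(weights) - 1e-12)[1]
  if (is.na(k)) k <- length(weights)
  flags <- logical(length(weights))
  flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' @export
print.model_ranking <- function(x, ...) {
  cat(sprintf("Model ranking (%d candidates, %.0f%% confidence set)\n",
              nrow(x), 100 * attr(x, "level")))
  y <- as.data.frame(x)
  y$weight <- round(y$weight, 4)
  y$delta_AIC <- round(y$delta_AIC, 3)
  if (all(is.na(y$AIC))) y$AIC <- NULL else y$AIC <- round(y$AIC, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Exhaustive candidate search over smooth-term subsets
#'
#' Fits every subset of the smooth-term pool (the joint lon/lat surface
#' counting as one term), each with the same fixed factor terms, and ranks
#' the fits by AIC. Enumeration order is reproducible (binary counting
#' over the pool in the order given).
#'
#' @param pool character vector of smooth-term names to search over.
#' @param data a [model_table()] data.frame.
#' @param factors factor terms included in every candidate.
#' @param k basis dimension passed to [model_spec()].
#' @param max_candidates guard on `2^length(pool)` (default 128).
#' @param assume_filtered passed to [fit_additive_model()].
#' @return a `model_ranking` with one row per subset (label =
#'   `+`-joined term names, `"(intercept)"` for the empty set) and columns
#'   `deviance_explained`, `r_squared_adj`, `df`; attribute `fits` holds
#'   the fitted models named by label.
#' @export
candidate_search <- function(pool, data, factors = character(), k = 10,
                             max_candidates = 128, assume_filtered = FALSE) {
  pool <- unique(pool)
  bad <- setdiff(pool, names(smooth_term_pool()))
  if (length(bad)) stop_validation("unknown smooth term(s): %s",
                                   paste(bad, collapse = ", "))
  n_cand <- 2^length(pool)
  if (n_cand > max_candidates)
    stop_validation("candidate_search: %d candidates exceed cap %d; shrink the pool",
                    n_cand, max_candidates)
  subsets <- lapply(seq_len(n_cand) - 1L, function(m)
    pool[bitwAnd(m, 2^(seq_along(pool) - 1L)) > 0])
  labels <- vapply(subsets, function(s)
    if (length(s)) paste(s, collapse = "+") else "(intercept)", character(1))
  fits <- lapply(subsets, function(s)
    fit_additive_model(model_spec(s, factors, k = k), data,
                       assume_filtered = assume_filtered,
                       check_collinear = FALSE))
  names(fits) <- labels
  ranking <- akaike_table(
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    models = labels,
    extra = data.frame(
      deviance_explained = vapply(fits, `[[`, numeric(1), "deviance_explained"),
      r_squared_adj = vapply(fits, `[[`, numeric(1), "r_squared_adj"),
      df = vapply(fits, `[[`, numeric(1), "df")))
  attr(ranking, "fits") <- fits
  ranking
}
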