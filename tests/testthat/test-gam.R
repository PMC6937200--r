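# shared filtered modelling table built once per file
sim_mt <- local({
  cfg <- generator_config(n_stations = 3, years = 2013:2014,
                          seed = 101,
                          effects = list(zoopl_slope_log = 0.15))
  sim <- generate(cfg)
  filt <- apply_model_filters(sim$stomachs, sim$stations)
  model_table(filt)
})

test_that("model_spec builds the additive formula from named terms", {
  sp <- model_spec(c("zooplankton", "sst"), "time_period")
  expect_match(sp$formula_text, "s\\(zooplankton")
  expect_match(sp$formula_text, "s\\(sst")
  expect_match(sp$formula_text, "time_period")
  expect_equal(model_spec()$formula_text, "log_stomach_weight ~ 1")
  expect_error(model_spec("salinity_typo"), "unknown smooth")
  expect_error(model_spec(factors = "moon_phase"), "unknown factor")
})

test_that("Akaike weights follow exp(-delta/2) normalisation", {
  tab <- akaike_table(delta = c(0, 1))
  expect_equal(tab$weight, c(1, exp(-0.5)) / (1 + exp(-0.5)),
               tolerance = 1e-12)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_equal(akaike_table(aic = 123.4)$weight, 1)
  # invariant to adding a constant to all AICs
  t1 <- akaike_table(aic = c(10, 12, 15))
  t2 <- akaike_table(aic = c(110, 112, 115))
  expect_equal(t1$weight, t2$weight, tolerance = 1e-12)
  expect_equal(min(t1$delta_AIC), 0)
  # weights decrease with delta
  expect_true(all(diff(t1$weight) <= 1e-15))
  expect_error(akaike_table(), "supply")
  expect_error(akaike_table(aic = numeric(0)), "empty")
})

test_that("confidence set is the smallest prefix reaching the level", {
  w <- c(0.58, 0.35, 0.06, 0.007)
  expect_equal(confidence_set(w), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(confidence_set(0.58, level = 0.95), TRUE)
  expect_equal(confidence_set(w, level = 1.0), rep(TRUE, 4))
  # monotone in level
  sets <- vapply(c(0.5, 0.8, 0.95, 0.999), function(l)
    sum(confidence_set(w, level = l)), numeric(1))
  expect_true(all(diff(sets) >= 0))
  # unsorted weights flag the right models
  expect_equal(confidence_set(c(0.06, 0.58, 0.007, 0.35)),
               c(TRUE, TRUE, FALSE, TRUE))
})

test_that("fit refuses unfiltered data and reports fit summaries", {
  df <- sim_mt
  attr(df, "filtered") <- NULL
  expect_error(fit_additive_model(model_spec("sst"), df), "filter")
  fit0 <- fit_additive_model(model_spec(), sim_mt)
  expect_equal(fit0$deviance_explained, 0, tolerance = 1e-12)
  fit1 <- fit_additive_model(model_spec("sst", "time_period"), sim_mt)
  expect_s3_class(fit1, "stomach_gam")
  expect_true(fit1$aic < fit0$aic)      # true SST effect helps
  expect_equal(nrow(fit1$smooth_terms), 1)
})

test_that("a pure-noise smooth shrinks toward edf 1 and near-zero deviance", {
  set.seed(51)
  n <- 200
  df <- data.frame(log_stomach_weight = rnorm(n), sst = runif(n, 6, 13))
  attr(df, "filtered") <- TRUE
  fit <- fit_additive_model(model_spec("sst"), df)
  expect_lt(fit$smooth_terms$edf[1], 3)
  expect_lt(fit$deviance_explained, 0.06)
})

test_that("a known smooth signal is recovered within the pointwise bands", {
  set.seed(52)
  n <- 400
  sst <- runif(n, 5.5, 12.5)
  f <- 0.4 * sin(sst / 1.5)
  df <- data.frame(log_stomach_weight = 1 + f + rnorm(n, 0, 0.2), sst = sst)
  attr(df, "filtered") <- TRUE
  fit <- fit_additive_model(model_spec("sst"), df)
  grid <- smooth_curve(fit, "s(sst)", n = 50)
  truth <- 0.4 * sin(grid$sst / 1.5)
  truth_centred <- truth - mean(0.4 * sin(sst / 1.5))  # smooths are centred
  cover <- mean(truth_centred >= grid$lower & truth_centred <= grid$upper)
  expect_gte(cover, 0.9)
})

test_that("infinite penalty collapses a smooth to the OLS line", {
  set.seed(53)
  n <- 150
  x <- runif(n, 0, 10)
  df <- data.frame(log_stomach_weight = 0.5 + 0.3 * x + rnorm(n, 0, 0.3),
                   sst = x)
  attr(df, "filtered") <- TRUE
  # name spec/data exactly so `sp` routes to the engine, not partial-matched
  fit <- fit_additive_model(spec = model_spec("sst"), data = df, sp = 1e10)
  ols <- lm(log_stomach_weight ~ sst, data = df)
  expect_equal(unname(fitted(fit$fit)), unname(fitted(ols)),
               tolerance = 1e-6)
})

test_that("candidate search enumerates all subsets and ranks consistently", {
  rk <- candidate_search(c("sst", "zooplankton", "depth"), sim_mt,
                         factors = "time_period")
  expect_equal(nrow(rk), 8)
  expect_true("(intercept)" %in% rk$model)
  expect_equal(rk$delta_AIC[1], 0)
  expect_equal(rk$weight[1], max(rk$weight))
  expect_equal(sum(rk$weight), 1, tolerance = 1e-12)
  expect_true(rk$in_confidence_set[1])
  expect_error(candidate_search(c("sst", "zooplankton"), sim_mt,
                                max_candidates = 2), "cap")
  expect_error(candidate_search("gibberish", sim_mt), "unknown")
})

test_that("fits are invariant to data row order", {
  set.seed(54)
  perm <- sample(nrow(sim_mt))
  shuffled <- sim_mt[perm, ]
  attr(shuffled, "filtered") <- TRUE
  f1 <- fit_additive_model(model_spec("sst"), sim_mt)
  f2 <- fit_additive_model(model_spec("sst"), shuffled)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
  expect_equal(f1$deviance_explained, f2$deviance_explained,
               tolerance = 1e-8)
})

test_that("collinearity screen catches aliased covariates", {
  df <- sim_mt
  df$bottom_depth <- df$sst            # exact alias
  attr(df, "filtered") <- TRUE
  expect_error(fit_additive_model(model_spec(c("sst", "depth")), df),
               "aliased")
})
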