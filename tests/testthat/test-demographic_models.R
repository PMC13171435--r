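test_that("noiseless growth data return the generative coefficients exactly", {
  gd <- make_growth_data(n = 300, seed = 1, noise_sd = 0)
  fit <- fit_growth(gd$data, "hoi")
  co <- coef_named(fit)
  for (term in names(gd$truth))
    expect_lt(abs(co[[term]] - gd$truth[[term]]), 1e-8)
  expect_false(fit$degenerate)
})

test_that("flipping a generative coefficient sign flips the estimate", {
  truth <- c(log_G = log(0.2), gamma = 0.4, alpha_ii = -0.03,
             alpha_ih = 0.015, beta_iii = -4e-4, beta_iih = 2e-4,
             beta_ihi = -1e-4, beta_ihh = 5e-5)
  flipped <- truth
  flipped["alpha_ii"] <- -truth["alpha_ii"]
  f1 <- fit_growth(make_growth_data(seed = 2, truth = truth)$data, "hoi")
  f2 <- fit_growth(make_growth_data(seed = 2, truth = flipped)$data, "hoi")
  expect_lt(coef_named(f1)[["alpha_ii"]], 0)
  expect_gt(coef_named(f2)[["alpha_ii"]], 0)
})

test_that("in-sample fit quality is monotone across the nested classes", {
  gd <- make_growth_data(n = 400, seed = 3, noise_sd = 0.5)
  fits <- lapply(c("null", "pair_only", "hoi"), fit_growth, data = gd$data)
  rss <- vapply(fits, function(f) sum(residuals(f$fit)^2), numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
  r <- vapply(fits, function(f)
    cor(log(gd$data$growth), fitted(f$fit)), numeric(1))
  expect_true(all(diff(r) >= -1e-12))
  # survival: log-likelihood never decreases with added terms
  set.seed(4)
  sd2 <- gd$data
  sd2$survived <- rbinom(nrow(sd2), 1, plogis(1 + 0.1 * sd2$dbh0 -
                                                0.05 * sd2$n_i))
  sfits <- lapply(c("null", "pair_only", "hoi"), fit_survival, data = sd2)
  ll <- vapply(sfits, function(f) as.numeric(logLik(f$fit)), numeric(1))
  expect_true(all(diff(ll) >= -1e-8))
})

test_that("survival orientation: negative alpha lowers survival probability", {
  gd <- make_growth_data(n = 1500, seed = 5, extent = 150)
  d <- gd$data
  set.seed(6)
  eta <- 2 - 0.1 * d$n_i           # conspecific competition
  d$survived <- rbinom(nrow(d), 1, plogis(eta))
  fit <- fit_survival(d, "pair_only")
  co <- coef_named(fit)
  expect_lt(co[["alpha_ii"]], 0)
  expect_false(fit$degenerate)
  # predicted survival under unit conspecific crowding < crowd-free baseline
  lp <- function(n_i) co[["lambda"]] + co[["gamma1"]] / d$dbh0[1] +
    co[["gamma2"]] * d$dbh0[1] + co[["gamma3"]] * d$dbh0[1]^2 +
    co[["alpha_ii"]] * n_i
  expect_lt(plogis(lp(1)), plogis(lp(0)))
})

test_that("constant survival outcomes are refused", {
  gd <- make_growth_data(n = 100, seed = 7)
  d <- gd$data
  d$survived <- 1L
  expect_error(fit_survival(d, "null"), "constant")
})

test_that("AIC support classification applies the two-unit rule", {
  expect_equal(classify_support(100, 97, 94)$best, "hoi")
  expect_equal(classify_support(100, 97, 99)$best, "pair_only")
  expect_equal(classify_support(100, 99, 98.5)$best, "null")
  # boundary: exactly two units is support
  expect_equal(classify_support(100, 98, 100)$best, "pair_only")
  expect_equal(classify_support(100, 100, 98)$best, "hoi")
  expect_equal(classify_support(100, 97, 95)$best, "hoi")
  expect_equal(classify_support(100, 97, 95.5)$best, "pair_only")
})

test_that("support summary percentages are exact", {
  sup <- data.frame(best = c("hoi", "hoi", "pair_only", "null"))
  s <- support_summary(sup)
  expect_equal(s$percent[s$model_class == "hoi"], 50)
  expect_equal(s$percent[s$model_class == "pair_only"], 25)
  expect_equal(s$percent[s$model_class == "null"], 25)
  expect_equal(sum(s$percent), 100)
})

test_that("all-zero crowding designs degrade gracefully", {
  gd <- make_growth_data(n = 120, seed = 8, noise_sd = 0.3)
  d <- gd$data
  d[c("n_i", "n_h", "n_ii", "n_ih", "n_hi", "n_hh")] <- 0
  fnull <- fit_growth(d, "null")
  fpair <- fit_growth(d, "pair_only")
  fhoi <- fit_growth(d, "hoi")
  expect_true(fpair$degenerate)
  expect_true(fhoi$degenerate)
  expect_equal(coef_named(fpair), coef_named(fnull), tolerance = 1e-12)
  expect_equal(fhoi$aic, fnull$aic, tolerance = 1e-10)
})

test_that("observed-predicted correlations separate the model classes", {
  gd <- make_growth_data(n = 400, seed = 9, noise_sd = 0)
  fits <- list(null = fit_growth(gd$data, "null"),
               pair_only = fit_growth(gd$data, "pair_only"),
               hoi = fit_growth(gd$data, "hoi"))
  r <- predicted_observed_correlation(fits)
  expect_equal(unname(r[["hoi"]]), 1, tolerance = 1e-10)  # perfect fit
  expect_true(r[["hoi"]] >= r[["pair_only"]])
  expect_true(r[["pair_only"]] >= r[["null"]])
  # paired t-tests over a species table point toward the richer class
  set.seed(10)
  rt <- data.frame(species = sprintf("s%d", 1:30),
                   null = runif(30, 0.3, 0.5))
  rt$pair_only <- rt$null + runif(30, 0, 0.1)
  rt$hoi <- rt$pair_only + runif(30, 0, 0.1)
  cmp <- compare_prediction_correlations(rt)
  row <- cmp[cmp$class_a == "hoi" & cmp$class_b == "null", ]
  expect_gt(row$mean_diff, 0)
  expect_lt(row$p_value, 0.01)
})

test_that("plot-level batch fitting filters, fits and classifies", {
  cfg <- sim_config(n_plots = 1, plot_extent = c(110, 110),
                    stems_per_ha = 700, richness_at_equator = 4,
                    min_richness = 4, richness_decay = 0,
                    abundance_model = "uniform", seed = 21)
  p <- simulate_plot(cfg, latitude = 10, seed = 21)
  dyn <- suppressMessages(link_censuses(p$census1, p$census2, p$meta))
  res <- fit_species_models(dyn, p$crowding, "growth", plot_id = "demo",
                            min_trees = 60)
  expect_gt(nrow(res$support), 0)
  expect_true(all(res$support$best %in% c("null", "pair_only", "hoi")))
  expect_true(all(res$support$species %in%
                    apply_species_filters(dyn, "growth", min_trees = 60)))
  expect_true(all(c("alpha_ii", "alpha_ih") %in%
                    res$coefficients$term[res$coefficients$model_class ==
                                            "pair_only"]))
  # the support table's AICs reproduce the classification
  for (i in seq_len(nrow(res$support))) {
    row <- res$support[i, ]
    expect_equal(row$best, classify_support(row$aic_null, row$aic_pair,
                                            row$aic_hoi)$best)
  }
})
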