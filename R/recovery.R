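#' Build a fixed focal-species design for recovery studies
#'
#' Simulates one plot, selects the most abundant species, restricts to its
#' interior stems and returns the fixed part of the generative model: the
#' design (DBH plus the six crowding indices), the species' true
#' coefficients, and the decomposed linear predictors. Recovery and AIC
#' studies then redraw only the stochastic part (growth noise or survival
#' outcomes) on this fixed design, which isolates estimator calibration
#' from sampling of the spatial pattern.
#'
#' Interaction magnitudes default to a strong-interaction configuration
#' (higher-order scales a few-fold above the network defaults) so that
#' relative bias is measurable against Monte Carlo error and
#' likelihood-ratio noncentrality is large.
#'
#' @param n_focal Number of interior focal stems to keep (default 2000).
#' @param latitude Plot latitude (default 5 degrees).
#' @param seed Integer seed for the plot simulation.
#' @param plot_extent,stems_per_ha Plot geometry (defaults sized so the
#'   focal species has at least `n_focal` interior stems).
#' @param coefficient_priors Optional override of [sim_config()] priors.
#' @return List: `data` (design data.frame with `dbh0` and indices),
#'   `truth` (named coefficient vector, canonical names), `size_lp`,
#'   `pair_lp`, `hoi_lp` (per-stem linear-predictor components for
#'   growth), `eta_survival` (full survival linear predictor).
#' @export
recovery_design <- function(n_focal = 2000, latitude = 5, seed = 1,
                            plot_extent = c(300, 300), stems_per_ha = 1000,
                            coefficient_priors = list(
                              beta_iii = list(scale = 2e-3),
                              beta_iih = list(scale = 1e-3),
                              beta_ihi = list(scale = 1e-3),
                              beta_ihh = list(scale = 5e-4))) {
  cfg <- sim_config(n_plots = 1, plot_extent = plot_extent,
                    stems_per_ha = stems_per_ha,
                    richness_at_equator = 3, min_richness = 3,
                    richness_decay = 0, abundance_model = "uniform",
                    spatial_pattern = "poisson",
                    coefficient_priors = coefficient_priors, seed = seed)
  p <- simulate_plot(cfg, latitude, seed = seed)
  cr <- p$crowding
  counts <- table(cr$species[cr$interior])
  sp <- names(counts)[which.max(counts)]
  idx <- which(cr$species == sp & cr$interior)
  if (length(idx) < n_focal)
    stop("only ", length(idx), " interior stems of the focal species; ",
         "enlarge the plot or density")
  idx <- idx[seq_len(n_focal)]
  tr <- p$truth[p$truth$species == sp, ]
  truth <- c(log_G = tr$log_G, gamma = tr$gamma, lambda = tr$lambda,
             gamma1 = tr$gamma1, gamma2 = tr$gamma2, gamma3 = tr$gamma3,
             alpha_ii = tr$alpha_ii, alpha_ih = tr$alpha_ih,
             beta_iii = tr$beta_iii, beta_iih = tr$beta_iih,
             beta_ihi = tr$beta_ihi, beta_ihh = tr$beta_ihh)
  stem_idx <- match(cr$stem_id[idx], p$census1$stem_id)
  data <- data.frame(dbh0 = p$census1$dbh[stem_idx],
                     n_i = cr$n_i[idx], n_h = cr$n_h[idx],
                     n_ii = cr$n_ii[idx], n_ih = cr$n_ih[idx],
                     n_hi = cr$n_hi[idx], n_hh = cr$n_hh[idx])
  pair_lp <- truth[["alpha_ii"]] * data$n_i + truth[["alpha_ih"]] * data$n_h
  hoi_lp <- truth[["beta_iii"]] * data$n_ii + truth[["beta_iih"]] * data$n_ih +
    truth[["beta_ihi"]] * data$n_hi + truth[["beta_ihh"]] * data$n_hh
  size_lp <- truth[["log_G"]] + truth[["gamma"]] * log(data$dbh0)
  eta_surv <- truth[["lambda"]] + truth[["gamma1"]] / data$dbh0 +
    truth[["gamma2"]] * data$dbh0 + truth[["gamma3"]] * data$dbh0^2 +
    pair_lp + hoi_lp
  list(data = data, truth = truth, size_lp = size_lp, pair_lp = pair_lp,
       hoi_lp = hoi_lp, eta_survival = eta_surv)
}

.growth_truth_terms <- c("log_G", "gamma", "alpha_ii", "alpha_ih",
                         "beta_iii", "beta_iih", "beta_ihi", "beta_ihh")
.survival_truth_terms <- c("lambda", "gamma1", "gamma2", "gamma3",
                           "alpha_ii", "alpha_ih", "beta_iii", "beta_iih",
                           "beta_ihi", "beta_ihh")

#' Growth-model parameter recovery study
#'
#' On a fixed [recovery_design()], redraws the lognormal growth noise
#' `n_replicates` times, refits the HOI-inclusive growth model, and
#' records for each true coefficient whether it lies inside the
#' t-based 95% confidence interval, plus the signed relative bias.
#'
#' @param design A [recovery_design()].
#' @param n_replicates Number of noise redraws (default 200).
#' @param noise_sd Lognormal noise SD on the log scale (default 0.5).
#' @param seed Seed for the noise stream.
#' @param level CI level (default 0.95).
#' @return List: `coverage_pct` and `bias_pct` (named by coefficient),
#'   `estimates` (replicate x coefficient matrix), `n` (stems).
#' @export
growth_recovery_study <- function(design, n_replicates = 200,
                                  noise_sd = 0.5, seed = 1, level = 0.95) {
  set.seed(seed)
  mu <- design$size_lp + design$pair_lp + design$hoi_lp
  n <- nrow(design$data)
  terms <- .growth_truth_terms
  truth <- design$truth[terms]
  cover <- est <- matrix(NA_real_, n_replicates, length(terms),
                         dimnames = list(NULL, terms))
  d <- design$data
  for (r in seq_len(n_replicates)) {
    d$growth <- exp(mu + stats::rnorm(n, 0, noise_sd))
    f <- fit_growth(d, "hoi")
    co <- f$coefficients
    tq <- stats::qt(1 - (1 - level) / 2, f$fit$df.residual)
    m <- match(terms, co$term)
    est[r, ] <- co$estimate[m]
    cover[r, ] <- abs(co$estimate[m] - truth) <= tq * co$std_error[m]
  }
  list(coverage_pct = 100 * colMeans(cover),
       bias_pct = 100 * (colMeans(est) - truth) / abs(truth),
       estimates = est, truth = truth, n = n)
}

#' Survival-model parameter recovery study
#'
#' On a fixed [recovery_design()], redraws Bernoulli survival outcomes
#' from the true logistic predictor, refits the HOI-inclusive survival
#' model, and records Wald 95% CI coverage for every coefficient.
#'
#' @inheritParams growth_recovery_study
#' @return List: `coverage_pct`, `bias_pct`, `estimates`, `truth`, `n`.
#' @export
survival_recovery_study <- function(design, n_replicates = 200, seed = 1,
                                    level = 0.95) {
  set.seed(seed)
  p <- stats::plogis(design$eta_survival)
  n <- nrow(design$data)
  terms <- .survival_truth_terms
  truth <- design$truth[terms]
  z <- stats::qnorm(1 - (1 - level) / 2)
  cover <- est <- matrix(NA_real_, n_replicates, length(terms),
                         dimnames = list(NULL, terms))
  d <- design$data
  for (r in seq_len(n_replicates)) {
    d$survived <- stats::rbinom(n, 1, p)
    f <- fit_survival(d, "hoi")
    co <- f$coefficients
    m <- match(terms, co$term)
    est[r, ] <- co$estimate[m]
    cover[r, ] <- abs(co$estimate[m] - truth) <= z * co$std_error[m]
  }
  list(coverage_pct = 100 * colMeans(cover),
       bias_pct = 100 * (colMeans(est) - truth) / abs(truth),
       estimates = est, truth = truth, n = n)
}

#' AIC support-rate study
#'
#' Measures how often the HOI-inclusive class is best supported by the
#' two-unit AIC rule on a fixed design, either when the generative truth
#' contains no higher-order effects (`hoi_truth = FALSE`; the false
#' support rate of the rule) or when it contains the design's strong
#' higher-order effects (`hoi_truth = TRUE`; the power).
#'
#' @param design A [recovery_design()].
#' @param hoi_truth Logical; include the higher-order component in the
#'   generative mean?
#' @inheritParams growth_recovery_study
#' @return List: `hoi_support_pct`, `best` (replicate labels), `n`.
#' @export
aic_support_study <- function(design, hoi_truth = FALSE, n_replicates = 200,
                              noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  mu <- design$size_lp + design$pair_lp +
    if (hoi_truth) design$hoi_lp else 0
  n <- nrow(design$data)
  d <- design$data
  best <- character(n_replicates)
  for (r in seq_len(n_replicates)) {
    d$growth <- exp(mu + stats::rnorm(n, 0, noise_sd))
    aics <- vapply(c("null", "pair_only", "hoi"),
                   function(cl) fit_growth(d, cl)$aic, numeric(1))
    best[r] <- classify_support(aics[1], aics[2], aics[3])$best
  }
  list(hoi_support_pct = 100 * mean(best == "hoi"), best = best, n = n)
}

#' Latitudinal gradient contrast study
#'
#' Repeatedly simulates a plot network whose intraspecific pairwise
#' magnitudes decay with latitude while interspecific magnitudes are
#' flat, fits the HOI-inclusive growth model per species and plot, and
#' runs the exponential latitude regression on the competitive subset of
#' the estimated intraspecific and interspecific coefficients. A
#' replicate succeeds when the intraspecific slope is significantly
#' negative (two-sided p < 0.05) and the interspecific slope is
#' non-significant.
#'
#' By default the regression uses the pairwise coefficients of the
#' pair-only fits (the modified coefficients). In this network every
#' conspecific-linked coefficient type decays at `intra_decay` and every
#' heterospecific-linked type at `inter_decay`, so modified and true
#' pairwise coefficients carry the same latitudinal contrast, and the
#' pair-only estimates are much more precise (the higher-order indices
#' are strongly collinear with `n_i`, which inflates the variance of the
#' pairwise coefficients in the HOI-inclusive fit). Set
#' `model_class = "hoi"` to regress the true coefficients instead.
#'
#' @param n_replicates Number of independent network replicates
#'   (default 50).
#' @param n_plots Plots per network (default 20).
#' @param seed Base seed; replicate k uses `seed + k`.
#' @param intra_decay,inter_decay Generative decay rates per degree
#'   (defaults 0.05 and 0).
#' @param plot_extent,stems_per_ha,n_species Network geometry (defaults
#'   130 m plots, 700 stems/ha, 4 species of equal abundance, all
#'   competitive so the sign subset is well populated).
#' @param model_class Model class whose pairwise coefficients are
#'   regressed (`"pair_only"`, the default, or `"hoi"`).
#' @return List: `success_pct`, per-replicate data.frame `detail`
#'   (intra/inter slopes and p values), `n` (species-plot estimates per
#'   replicate).
#' @export
gradient_contrast_study <- function(n_replicates = 50, n_plots = 20,
                                    seed = 1, intra_decay = 0.05,
                                    inter_decay = 0,
                                    plot_extent = c(130, 130),
                                    stems_per_ha = 700, n_species = 4,
                                    model_class = c("pair_only", "hoi")) {
  model_class <- match.arg(model_class)
  detail <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    cfg <- sim_config(
      n_plots = n_plots, latitude_range = c(2, 61),
      plot_extent = plot_extent, stems_per_ha = stems_per_ha,
      richness_at_equator = n_species, min_richness = n_species,
      richness_decay = 0, abundance_model = "uniform",
      coefficient_priors = list(
        alpha_ii = list(decay = intra_decay, facilitative = 0),
        alpha_ih = list(decay = inter_decay, facilitative = 0),
        beta_iii = list(decay = intra_decay, facilitative = 0),
        beta_iih = list(decay = intra_decay, facilitative = 0),
        beta_ihi = list(decay = intra_decay, facilitative = 0),
        beta_ihh = list(decay = inter_decay, facilitative = 0)),
      seed = (seed + 104729L * k) %% .Machine$integer.max)
    net <- simulate_network(cfg)
    rows <- list()
    for (p in net$plots) {
      dyn <- link_censuses(p$census1, p$census2, p$meta)
      merged <- merge(dyn, p$crowding[, c("stem_id", "n_i", "n_h", "n_ii",
                                          "n_ih", "n_hi", "n_hh",
                                          "interior")], by = "stem_id",
                      sort = FALSE)
      for (sp in unique(merged$species)) {
        d <- merged[merged$species == sp & merged$interior &
                      merged$survived == 1L & !is.na(merged$growth) &
                      merged$growth > 0, , drop = FALSE]
        if (nrow(d) < 30) next
        f <- fit_growth(d, model_class, species = sp,
                        plot_id = p$meta$plot_id)
        co <- stats::setNames(f$coefficients$estimate, f$coefficients$term)
        rows[[paste(p$meta$plot_id, sp)]] <- data.frame(
          lat = abs(p$meta$latitude), alpha_ii = co[["alpha_ii"]],
          alpha_ih = co[["alpha_ih"]])
      }
    }
    est <- do.call(rbind, rows)
    fi <- exponential_latitude_fit(est$alpha_ii, est$lat, "competitive")
    fh <- exponential_latitude_fit(est$alpha_ih, est$lat, "competitive")
    detail[[k]] <- data.frame(
      replicate = k, n_est = nrow(est),
      intra_slope = fi$slope, intra_p = fi$p_value,
      inter_slope = fh$slope, inter_p = fh$p_value,
      success = !is.na(fi$p_value) && !is.na(fh$p_value) &&
        fi$slope < 0 && fi$p_value < 0.05 && fh$p_value >= 0.05)
  }
  detail <- do.call(rbind, detail)
  list(success_pct = 100 * mean(detail$success), detail = detail,
       n = round(mean(detail$n_est)))
}

#' RC abundance-slope recovery study
#'
#' Generates species-level RC records directly from a known four-term
#' linear model of log RC on log abundance, absolute latitude and their
#' interaction, fits the RC abundance-latitude model, and measures the
#' 95% CI coverage of the abundance coefficient over replicates.
#'
#' @param n_replicates Number of replicates (default 200).
#' @param n_species Species per replicate (default 300).
#' @param abundance_slope True log-abundance coefficient for the
#'   higher-order multiplier (default -0.8).
#' @param latitude_slope,interaction True latitude and interaction
#'   coefficients (defaults -0.03 and 0).
#' @param noise_sd Residual SD of log RC (default 0.5).
#' @param seed Seed.
#' @return List: `coverage_pct`, `mean_estimate`, `estimates`, `n`.
#' @export
rc_recovery_study <- function(n_replicates = 200, n_species = 300,
                              abundance_slope = -0.8,
                              latitude_slope = -0.03, interaction = 0,
                              noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  est <- cover <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    log_ab <- stats::rnorm(n_species, log(50), 1)
    lat <- stats::runif(n_species, 2, 50)
    log_rc <- 3.5 + abundance_slope * log_ab + latitude_slope * lat +
      interaction * log_ab * lat + stats::rnorm(n_species, 0, noise_sd)
    rec <- data.frame(rc_pair = exp(stats::rnorm(n_species, 0, 0.1)),
                      rc_hoi = exp(log_rc), abundance = exp(log_ab),
                      latitude_abs = lat)
    m <- rc_abundance_latitude_model(rec, responses = "rc_hoi")
    row <- m$table[m$table$term == "Abundance", ]
    ci <- stats::confint(m$models$rc_hoi, "log_abund", level = 0.95)
    est[r] <- row$estimate
    cover[r] <- ci[1] <= abundance_slope && abundance_slope <= ci[2]
  }
  list(coverage_pct = 100 * mean(cover), mean_estimate = mean(est),
       estimates = est, n = n_species)
}
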