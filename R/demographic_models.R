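#' @keywords internal
.pair_terms <- c("n_i", "n_h")
.hoi_terms <- c("n_ii", "n_ih", "n_hi", "n_hh")

# canonical coefficient names per response
.term_map <- function(response) {
  if (response == "growth")
    c("(Intercept)" = "log_G", "log(dbh0)" = "gamma",
      n_i = "alpha_ii", n_h = "alpha_ih",
      n_ii = "beta_iii", n_ih = "beta_iih", n_hi = "beta_ihi",
      n_hh = "beta_ihh")
  else
    c("(Intercept)" = "lambda", "I(1/dbh0)" = "gamma1", dbh0 = "gamma2",
      "I(dbh0^2)" = "gamma3",
      n_i = "alpha_ii", n_h = "alpha_ih",
      n_ii = "beta_iii", n_ih = "beta_iih", n_hi = "beta_ihi",
      n_hh = "beta_ihh")
}

.model_terms <- function(response, model_class) {
  size <- if (response == "growth") "log(dbh0)"
          else c("I(1/dbh0)", "dbh0", "I(dbh0^2)")
  switch(model_class,
         null = size,
         pair_only = c(size, .pair_terms),
         hoi = c(size, .pair_terms, .hoi_terms),
         stop("unknown model class: ", model_class))
}

# drop crowding columns with no variation so batch fits never abort
.droppable <- function(data, terms) {
  crowd <- intersect(terms, c(.pair_terms, .hoi_terms))
  bad <- crowd[vapply(crowd, function(v) {
    z <- data[[v]]
    !any(is.finite(z)) || stats::sd(z) == 0
  }, logical(1))]
  bad
}

.tidy_fit <- function(fit, response) {
  sm <- summary(fit)$coefficients
  map <- .term_map(response)
  data.frame(term = unname(map[rownames(sm)]),
             raw_term = rownames(sm),
             estimate = sm[, 1], std_error = sm[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

.new_species_fit <- function(species, plot_id, response, model_class, fit,
                             coefficients, aic, n_obs, degenerate, dropped) {
  structure(list(species = species, plot_id = plot_id, response = response,
                 model_class = model_class, fit = fit,
                 coefficients = coefficients, aic = aic, n_obs = n_obs,
                 degenerate = degenerate, dropped = dropped),
            class = "species_fit")
}

#' @export
print.species_fit <- function(x, ...) {
  cat(sprintf("<species_fit> %s / %s / %s / %s: AIC %.2f, n = %d%s\n",
              x$plot_id, x$species, x$response, x$model_class, x$aic,
              x$n_obs, if (x$degenerate) " (degenerate)" else ""))
  print(x$coefficients[, c("term", "estimate", "std_error")])
  invisible(x)
}

#' Fit a growth model for one species
#'
#' Fits the log-linearized power-law growth model by ordinary least
#' squares: `log(growth) ~ log(dbh0)` for the null class, plus the two
#' pairwise crowding indices (`pair_only`) and additionally the four
#' higher-order indices (`hoi`). Under this parameterization the intercept
#' is the log potential growth rate `log_G`, the size slope is `gamma`,
#' and negative crowding coefficients depress growth multiplicatively.
#' AIC uses the Gaussian log-likelihood and counts the residual variance
#' as a free parameter (`stats::AIC`).
#'
#' Crowding columns that are constant across the observations are dropped
#' and the fit is flagged `degenerate` rather than failing, so plot-wide
#' batch runs always complete.
#'
#' @param data Data.frame with columns `growth`, `dbh0` and the crowding
#'   indices `n_i`, `n_h`, `n_ii`, `n_ih`, `n_hi`, `n_hh`; rows should
#'   already be restricted to surviving, interior stems of one species with
#'   positive growth.
#' @param model_class `"null"`, `"pair_only"` or `"hoi"`.
#' @param species,plot_id Labels carried into the result.
#' @return A `species_fit` object: coefficients with standard errors under
#'   canonical names (`log_G`, `gamma`, `alpha_ii`, `alpha_ih`,
#'   `beta_iii`, `beta_iih`, `beta_ihi`, `beta_ihh`), `aic`, `n_obs`,
#'   `degenerate` flag and the underlying `lm` fit.
#' @export
fit_growth <- function(data, model_class = c("hoi", "pair_only", "null"),
                       species = NA_character_, plot_id = NA_character_) {
  model_class <- match.arg(model_class)
  stopifnot(all(data$growth > 0), all(data$dbh0 > 0))
  terms <- .model_terms("growth", model_class)
  dropped <- .droppable(data, terms)
  terms <- setdiff(terms, dropped)
  fml <- stats::reformulate(terms, response = "log(growth)")
  fit <- stats::lm(fml, data = data)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased)) {
    terms <- setdiff(terms, aliased)
    dropped <- c(dropped, aliased)
    fit <- stats::lm(stats::reformulate(terms, response = "log(growth)"),
                     data = data)
  }
  .new_species_fit(species, plot_id, "growth", model_class, fit,
                   .tidy_fit(fit, "growth"), stats::AIC(fit), nrow(data),
                   degenerate = length(dropped) > 0, dropped = dropped)
}

# ridge-penalized logistic fallback for separated designs
.ridge_logistic <- function(X, yv, lambda = 1e-3, maxit = 200L) {
  p <- ncol(X)
  pen <- diag(rep(lambda, p))
  pen[1, 1] <- 0  # intercept unpenalized
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wts <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (yv - mu) / wts
    XtW <- t(X * wts)
    H <- XtW %*% X + 2 * pen
    beta_new <- drop(solve(H, XtW %*% z))
    if (max(abs(beta_new - beta)) < 1e-10) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  loglik <- sum(yv * log(pmax(mu, 1e-300)) +
                  (1 - yv) * log(pmax(1 - mu, 1e-300)))
  wts <- pmax(mu * (1 - mu), 1e-10)
  H <- t(X * wts) %*% X + 2 * pen
  se <- sqrt(diag(solve(H)))
  list(coefficients = beta, se = se, loglik = loglik, fitted = mu)
}

#' Fit a survival model for one species
#'
#' Maximum-likelihood logistic regression of the 0/1 interval survival
#' outcome on `1/dbh0` (rapid decline of mortality with size), `dbh0` and
#' `dbh0^2` (U-shaped senescence), plus the crowding indices of the chosen
#' model class. The linear predictor enters as `logit P(survive) = eta`,
#' so a negative crowding coefficient lowers survival probability (the
#' competitive reading). AIC is the usual binomial AIC.
#'
#' Complete or quasi-complete separation is detected (non-convergence or
#' boundary fitted probabilities) and the fit falls back to a lightly
#' ridge-penalized logistic regression with a warning; the result is
#' flagged `degenerate`.
#'
#' @param data Data.frame with columns `survived` (0/1), `dbh0` and the six
#'   crowding indices; rows restricted to interior stems of one species.
#' @inheritParams fit_growth
#' @return A `species_fit` object with canonical coefficient names
#'   (`lambda`, `gamma1`, `gamma2`, `gamma3`, `alpha_ii`, ..., `beta_ihh`).
#' @export
fit_survival <- function(data, model_class = c("hoi", "pair_only", "null"),
                         species = NA_character_, plot_id = NA_character_) {
  model_class <- match.arg(model_class)
  stopifnot(all(data$survived %in% 0:1))
  if (sum(data$survived) == 0 || sum(data$survived) == nrow(data))
    stop("survival outcome is constant; species fails the survivor/death ",
         "count filter and cannot be fitted")
  terms <- .model_terms("survival", model_class)
  dropped <- .droppable(data, terms)
  terms <- setdiff(terms, dropped)
  fml <- stats::reformulate(terms, response = "survived")

  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased)) {
    terms <- setdiff(terms, aliased)
    dropped <- c(dropped, aliased)
    fit <- suppressWarnings(
      stats::glm(stats::reformulate(terms, response = "survived"),
                 data = data, family = stats::binomial()))
  }

  map <- .term_map("survival")
  if (separated) {
    warning("separation detected for species ", species,
            "; using ridge-penalized logistic fit")
    X <- stats::model.matrix(stats::reformulate(terms), data = data)
    rf <- .ridge_logistic(X, data$survived)
    k <- ncol(X)
    coefs <- data.frame(term = unname(map[colnames(X)]),
                        raw_term = colnames(X),
                        estimate = rf$coefficients, std_error = rf$se,
                        stringsAsFactors = FALSE, row.names = NULL)
    return(.new_species_fit(species, plot_id, "survival", model_class,
                            structure(rf, class = "ridge_logistic"),
                            coefs, -2 * rf$loglik + 2 * k, nrow(data),
                            degenerate = TRUE,
                            dropped = c(dropped, "separation")))
  }
  .new_species_fit(species, plot_id, "survival", model_class, fit,
                   .tidy_fit(fit, "survival"), stats::AIC(fit), nrow(data),
                   degenerate = length(dropped) > 0, dropped = dropped)
}

#' Classify model support by AIC
#'
#' The more complex model class is supported only when its AIC is at least
#' two units below every simpler alternative: the HOI-inclusive class wins
#' iff `aic_hoi <= min(aic_null, aic_pair) - 2`; otherwise the pair-only
#' class wins iff `aic_pair <= aic_null - 2`; otherwise the null class is
#' retained.
#'
#' @param aic_null,aic_pair,aic_hoi Finite AIC values of the three nested
#'   fits.
#' @return A list with `best` (`"null"`, `"pair_only"` or `"hoi"`) and
#'   `delta_aic_to_simpler`, the AIC margin of the winning class below the
#'   best simpler alternative (0 for the null class).
#' @export
classify_support <- function(aic_null, aic_pair, aic_hoi) {
  stopifnot(is.finite(aic_null), is.finite(aic_pair), is.finite(aic_hoi))
  if (aic_hoi <= min(aic_null, aic_pair) - 2)
    list(best = "hoi", delta_aic_to_simpler = min(aic_null, aic_pair) - aic_hoi)
  else if (aic_pair <= aic_null - 2)
    list(best = "pair_only", delta_aic_to_simpler = aic_null - aic_pair)
  else
    list(best = "null", delta_aic_to_simpler = 0)
}

#' Percentages of species best supported by each model class
#'
#' @param support Data.frame with a `best` column of class labels (as in
#'   the `support` element of [fit_species_models()]).
#' @return Data.frame with one row per model class (`null`, `pair_only`,
#'   `hoi`): `n` and `percent` (percentages sum to 100).
#' @export
support_summary <- function(support) {
  stopifnot(nrow(support) >= 1)
  lev <- c("null", "pair_only", "hoi")
  n <- table(factor(support$best, levels = lev))
  data.frame(model_class = lev, n = as.integer(n),
             percent = 100 * as.integer(n) / nrow(support),
             stringsAsFactors = FALSE)
}

#' Observed vs predicted correlation per model class
#'
#' In-sample Pearson correlation between the observed response (log growth
#' for growth fits, the 0/1 outcome for survival fits) and each model
#' class's fitted values.
#'
#' @param fits Named list of `species_fit` objects for the same species
#'   and data, e.g. the output of [fit_species_models()] for one species
#'   (names `null`, `pair_only`, `hoi`).
#' @return Named numeric vector of Pearson r, one per model class.
#' @export
predicted_observed_correlation <- function(fits) {
  vapply(fits, function(f) {
    obs <- if (f$response == "growth") stats::model.frame(f$fit)[[1]]
           else f$fit$y
    stats::cor(obs, stats::fitted(f$fit))
  }, numeric(1))
}

#' Paired comparison of prediction correlations across species
#'
#' Two-sided paired t-tests between model classes on a species-by-class
#' table of observed-predicted correlations.
#'
#' @param r_table Data.frame with columns `species` and one column per
#'   model class holding Pearson r values.
#' @param classes Model class columns to compare (all pairs).
#' @return Data.frame with one row per class pair: mean difference, t,
#'   df and two-sided p value.
#' @export
compare_prediction_correlations <- function(r_table,
                                            classes = c("null", "pair_only",
                                                        "hoi")) {
  classes <- intersect(classes, names(r_table))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    tt <- stats::t.test(r_table[[p[2]]], r_table[[p[1]]], paired = TRUE)
    data.frame(class_a = p[2], class_b = p[1],
               mean_diff = unname(tt$estimate), t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit all three model classes for every eligible species of a plot
#'
#' Applies the species eligibility filters, restricts observations to
#' interior stems (and, for growth, to survivors with positive recorded
#' growth), fits the null, pair-only and HOI-inclusive models for each
#' species, and classifies AIC support.
#'
#' @param dyn Linked stem dynamics from [link_censuses()].
#' @param crowding Crowding table from [compute_crowding_table()] for the
#'   same census-1 stems (matched by `stem_id`).
#' @param response `"growth"` or `"survival"`.
#' @param plot_id Plot label carried into results.
#' @param min_trees,min_survivors,min_dead Passed to
#'   [apply_species_filters()].
#' @return List with elements `fits` (per species, a named list of the
#'   three `species_fit` objects), `support` (data.frame: species, AICs,
#'   best class, margin), and `coefficients` (long data.frame of every
#'   coefficient of every fit).
#' @export
fit_species_models <- function(dyn, crowding, response = c("growth", "survival"),
                               plot_id = "plot", min_trees = 100,
                               min_survivors = 20, min_dead = 20) {
  response <- match.arg(response)
  eligible <- apply_species_filters(dyn, response, min_trees,
                                    min_survivors, min_dead)
  merged <- merge(dyn, crowding[, c("stem_id", .pair_terms, .hoi_terms,
                                    "interior")],
                  by = "stem_id", sort = FALSE)
  fit_fun <- if (response == "growth") fit_growth else fit_survival
  fits <- list()
  support_rows <- list()
  coef_rows <- list()
  for (sp in eligible) {
    d <- merged[merged$species == sp & merged$interior, , drop = FALSE]
    if (response == "growth")
      d <- d[d$survived == 1L & !is.na(d$growth) & d$growth > 0, ,
             drop = FALSE]
    # enough observations (and both outcome classes) to fit the widest model
    if (nrow(d) < 15) next
    if (response == "survival" &&
        (sum(d$survived) < 2 || sum(1 - d$survived) < 2)) next
    triple <- list(
      null = fit_fun(d, "null", species = sp, plot_id = plot_id),
      pair_only = fit_fun(d, "pair_only", species = sp, plot_id = plot_id),
      hoi = fit_fun(d, "hoi", species = sp, plot_id = plot_id)
    )
    cls <- classify_support(triple$null$aic, triple$pair_only$aic,
                            triple$hoi$aic)
    fits[[sp]] <- triple
    support_rows[[sp]] <- data.frame(
      plot_id = plot_id, species = sp, response = response,
      aic_null = triple$null$aic, aic_pair = triple$pair_only$aic,
      aic_hoi = triple$hoi$aic, best = cls$best,
      delta_aic_to_simpler = cls$delta_aic_to_simpler,
      n_obs = nrow(d), stringsAsFactors = FALSE)
    coef_rows[[sp]] <- do.call(rbind, lapply(triple, function(f)
      cbind(data.frame(plot_id = plot_id, species = sp, response = response,
                       model_class = f$model_class, aic = f$aic,
                       n_obs = f$n_obs, degenerate = f$degenerate,
                       stringsAsFactors = FALSE),
            f$coefficients[, c("term", "estimate", "std_error")])))
  }
  list(fits = fits,
       support = if (length(support_rows)) do.call(rbind, c(support_rows,
                                                            make.row.names = FALSE))
                 else NULL,
       coefficients = if (length(coef_rows)) do.call(rbind, c(coef_rows,
                                                              make.row.names = FALSE))
                      else NULL)
}
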