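#' Cumulative neighbourhood effect multipliers for one species
#'
#' For every focal tree of the species, the pairwise linear predictor
#' `Pair = alpha_ii * n_i + alpha_ih * n_h` and the higher-order predictor
#' `HOI = beta_iii * n_ii + beta_iih * n_ih + beta_ihi * n_hi +
#' beta_ihh * n_hh` are evaluated with the coefficients of the
#' HOI-inclusive fit (the true pairwise coefficients, with higher-order
#' effects isolated). The relative change statistics are the species means
#' of the per-tree multipliers: `RC_Pair = mean(exp(Pair))` and
#' `RC_HOI = mean(exp(HOI))`. A species whose trees all have zero crowding
#' gets the neutral value 1 for both.
#'
#' Coefficients dropped from a degenerate design contribute zero to the
#' linear predictor.
#'
#' @param fit HOI-class `species_fit` (growth or survival).
#' @param profiles Crowding profiles of the species' trees (rows of
#'   [compute_crowding_table()]); only interior trees are used.
#' @return One-row data.frame: `species`, `plot_id`, `response`,
#'   `rc_pair`, `rc_hoi`, `n_trees`.
#' @export
compute_rc <- function(fit, profiles) {
  if (is.null(fit) || fit$model_class != "hoi")
    stop("an HOI-class fit is required to compute RC statistics")
  p <- profiles[profiles$interior, , drop = FALSE]
  stopifnot(nrow(p) >= 1)
  cf <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  g <- function(term) if (term %in% names(cf)) cf[[term]] else 0
  pair_lp <- g("alpha_ii") * p$n_i + g("alpha_ih") * p$n_h
  hoi_lp <- g("beta_iii") * p$n_ii + g("beta_iih") * p$n_ih +
    g("beta_ihi") * p$n_hi + g("beta_ihh") * p$n_hh
  data.frame(species = fit$species, plot_id = fit$plot_id,
             response = fit$response,
             rc_pair = mean(exp(pair_lp)), rc_hoi = mean(exp(hoi_lp)),
             n_trees = nrow(p), stringsAsFactors = FALSE)
}

#' RC records for every species of a plot
#'
#' Combines [compute_rc()] over all species with an HOI-class fit
#' (all filter-eligible species, regardless of AIC support class) and
#' attaches species abundance (census-1 main stems per hectare) and the
#' plot's absolute latitude.
#'
#' @param fits The `fits` element of [fit_species_models()].
#' @param crowding Crowding table of the plot.
#' @param dyn Linked stem dynamics of the plot (abundance source).
#' @param meta Plot metadata with `latitude`, `x_extent`, `y_extent`.
#' @return Data.frame of RC records, or `NULL` when no species qualifies.
#' @export
rc_records <- function(fits, crowding, dyn, meta) {
  area_ha <- meta$x_extent * meta$y_extent / 1e4
  n_by_sp <- table(dyn$species)
  rows <- lapply(names(fits), function(sp) {
    f <- fits[[sp]]$hoi
    if (is.null(f)) return(NULL)
    prof <- crowding[crowding$species == sp, , drop = FALSE]
    if (!any(prof$interior)) return(NULL)
    rc <- compute_rc(f, prof)
    rc$abundance <- as.numeric(n_by_sp[[sp]]) / area_ha
    rc$latitude_abs <- abs(meta$latitude)
    rc
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Model RC statistics against abundance and latitude
#'
#' Linear models of log RC on log species abundance, absolute latitude and
#' their interaction, fitted separately for the pairwise and higher-order
#' multipliers. A negative abundance coefficient is the stabilization
#' signature: rare species benefit (RC > 1) while common species are
#' suppressed (RC < 1); a positive abundance-latitude interaction means
#' this stabilizing effect weakens toward higher latitudes.
#'
#' @param records RC records with columns `rc_pair`, `rc_hoi`,
#'   `abundance`, `latitude_abs` (see [rc_records()]).
#' @param responses RC columns to model.
#' @return List with `models` (fitted `lm` objects, named by RC column)
#'   and `table` (one row per response and term: estimate, se, t, p).
#' @export
rc_abundance_latitude_model <- function(records,
                                        responses = c("rc_pair", "rc_hoi")) {
  stopifnot(nrow(records) >= 4)
  models <- list()
  rows <- list()
  labels <- c("(Intercept)" = "Intercept", log_abund = "Abundance",
              lat = "Latitude", "log_abund:lat" = "Abundance:latitude")
  for (resp in responses) {
    d <- data.frame(log_rc = log(records[[resp]]),
                    log_abund = log(records$abundance),
                    lat = records$latitude_abs)
    fit <- stats::lm(log_rc ~ log_abund * lat, data = d)
    models[[resp]] <- fit
    sm <- summary(fit)$coefficients
    rows[[resp]] <- data.frame(
      response = resp, term = unname(labels[rownames(sm)]),
      estimate = sm[, 1], std_error = sm[, 2], t = sm[, 3],
      p_value = sm[, 4], stringsAsFactors = FALSE, row.names = NULL)
  }
  list(models = models, table = do.call(rbind, c(rows,
                                                 make.row.names = FALSE)))
}

#' Predicted RC-abundance relationships by latitudinal zone
#'
#' Evaluates a fitted RC model along an abundance grid at representative
#' zone latitudes (defaults: the middle latitudes of the tropical,
#' subtropical and temperate zones) with pointwise 95% confidence bands.
#'
#' @param model A fitted `lm` from [rc_abundance_latitude_model()].
#' @param abundance_grid Abundances (stems per hectare) at which to
#'   predict.
#' @param zone_latitudes Named vector of zone latitudes in degrees
#'   (defaults 11.75, 29.25, 45).
#' @param level Confidence level (default 0.95).
#' @return Data.frame: `zone`, `latitude`, `abundance`, `log_rc`
#'   (predicted), `lwr`, `upr`.
#' @export
zone_predictions <- function(model, abundance_grid = exp(seq(log(1), log(500),
                                                             length.out = 50)),
                             zone_latitudes = c(tropical = 11.75,
                                                subtropical = 29.25,
                                                temperate = 45),
                             level = 0.95) {
  rows <- lapply(names(zone_latitudes), function(zone) {
    nd <- data.frame(log_abund = log(abundance_grid),
                     lat = zone_latitudes[[zone]])
    pr <- stats::predict(model, newdata = nd, interval = "confidence",
                         level = level)
    data.frame(zone = zone, latitude = zone_latitudes[[zone]],
               abundance = abundance_grid, log_rc = pr[, "fit"],
               lwr = pr[, "lwr"], upr = pr[, "upr"],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
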