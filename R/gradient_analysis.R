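#' Exponential latitude regression for one coefficient type
#'
#' Models the magnitude of species-level interaction coefficients as an
#' exponential function of absolute latitude, fitted as ordinary least
#' squares of `log|value|` on latitude. Competitive (negative) and
#' facilitative (positive) coefficients are analysed separately; zeros are
#' excluded. The slope is tested with a two-sided t-test. A fit is reported
#' only when at least `min_n` values fall in the requested sign subset.
#'
#' @param values Signed species-level coefficient estimates.
#' @param latitudes Absolute latitudes (degrees), one per value.
#' @param sign_subset `"competitive"` (values < 0), `"facilitative"`
#'   (values > 0) or `"all"` (all non-zero values, by magnitude).
#' @param coefficient_type Optional label carried into the result.
#' @param min_n Minimum subset size for a reported fit (default 3).
#' @return One-row data.frame: `coefficient_type`, `sign_subset`,
#'   `log_intercept`, `slope` (per degree), `t_stat`, `p_value`, `n`, and
#'   `reason` (`NA` for a successful fit, otherwise why none was made).
#' @export
exponential_latitude_fit <- function(values, latitudes,
                                     sign_subset = c("competitive",
                                                     "facilitative", "all"),
                                     coefficient_type = NA_character_,
                                     min_n = 3) {
  sign_subset <- match.arg(sign_subset)
  stopifnot(length(values) == length(latitudes))
  keep <- switch(sign_subset,
                 competitive = values < 0,
                 facilitative = values > 0,
                 all = values != 0)
  keep <- keep & !is.na(values) & !is.na(latitudes)
  v <- abs(values[keep])
  lat <- abs(latitudes[keep])
  empty <- data.frame(coefficient_type = coefficient_type,
                      sign_subset = sign_subset,
                      log_intercept = NA_real_, slope = NA_real_,
                      t_stat = NA_real_, p_value = NA_real_,
                      n = sum(keep), reason = "fewer values than min_n",
                      stringsAsFactors = FALSE)
  if (sum(keep) < min_n) return(empty)
  if (stats::sd(log(v)) < 1e-12) {
    # identical magnitudes everywhere: flat gradient by construction
    empty$log_intercept <- mean(log(v))
    empty$slope <- 0
    empty$t_stat <- 0
    empty$p_value <- 1
    empty$reason <- NA_character_
    return(empty)
  }
  fit <- stats::lm(log(v) ~ lat)
  sm <- summary(fit)$coefficients
  if (nrow(sm) < 2) {  # e.g. all latitudes identical
    empty$reason <- "latitude has no variation"
    return(empty)
  }
  data.frame(coefficient_type = coefficient_type, sign_subset = sign_subset,
             log_intercept = sm[1, 1], slope = sm[2, 1],
             t_stat = sm[2, 3], p_value = sm[2, 4], n = sum(keep),
             reason = NA_character_, stringsAsFactors = FALSE)
}

#' Latitudinal gradient table for all coefficient types
#'
#' Runs [exponential_latitude_fit()] for every interaction coefficient
#' type and sign subset over a long coefficient table. Pairwise
#' coefficients are split into `_true` (from HOI-inclusive fits) and
#' `_modified` (from pair-only fits); the four higher-order coefficients
#' come from HOI-inclusive fits. Coefficients from degenerate fits are
#' excluded.
#'
#' @param coefficients Long coefficient table, as the `coefficients`
#'   element of [fit_species_models()] pooled over plots.
#' @param plot_meta Plot metadata table with `plot_id` and `latitude`.
#' @param sign_subsets Character vector of subsets to fit.
#' @return Data.frame with one row per coefficient type and sign subset.
#' @export
gradient_table <- function(coefficients, plot_meta,
                           sign_subsets = c("competitive", "facilitative")) {
  co <- coefficients[!coefficients$degenerate, , drop = FALSE]
  co$lat <- abs(plot_meta$latitude[match(co$plot_id, plot_meta$plot_id)])
  types <- list(
    alpha_ii_true = c("hoi", "alpha_ii"),
    alpha_ii_modified = c("pair_only", "alpha_ii"),
    alpha_ih_true = c("hoi", "alpha_ih"),
    alpha_ih_modified = c("pair_only", "alpha_ih"),
    beta_iii = c("hoi", "beta_iii"),
    beta_iih = c("hoi", "beta_iih"),
    beta_ihi = c("hoi", "beta_ihi"),
    beta_ihh = c("hoi", "beta_ihh")
  )
  rows <- list()
  for (type in names(types)) {
    sel <- co$model_class == types[[type]][1] & co$term == types[[type]][2]
    for (ss in sign_subsets)
      rows[[paste(type, ss)]] <- exponential_latitude_fit(
        co$estimate[sel], co$lat[sel], ss, coefficient_type = type)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Species richness per hectare of a plot
#'
#' Mean number of species over non-overlapping `quadrat` x `quadrat` m
#' cells (default 100 m, i.e. species per hectare). When the plot is too
#' small for a full quadrat, or with `estimator = "total"`, total species
#' count divided by plot area in hectares is returned instead.
#'
#' @param stems Census stem records with `species`, `x`, `y`.
#' @param meta Plot metadata with `x_extent`, `y_extent`.
#' @param quadrat Quadrat side length in metres (default 100).
#' @param estimator `"quadrat"` (default) or `"total"`.
#' @return Single numeric richness value.
#' @export
quadrat_richness <- function(stems, meta, quadrat = 100,
                             estimator = c("quadrat", "total")) {
  estimator <- match.arg(estimator)
  nx <- floor(meta$x_extent / quadrat)
  ny <- floor(meta$y_extent / quadrat)
  if (estimator == "total" || nx < 1 || ny < 1) {
    area_ha <- meta$x_extent * meta$y_extent / 1e4
    return(length(unique(stems$species)) / area_ha)
  }
  cx <- pmin(floor(stems$x / quadrat), nx - 1)
  cy <- pmin(floor(stems$y / quadrat), ny - 1)
  inside <- stems$x < nx * quadrat & stems$y < ny * quadrat
  cell <- paste(cx[inside], cy[inside])
  rich <- tapply(stems$species[inside], cell, function(s) length(unique(s)))
  # empty cells count as zero species
  sum(rich) / (nx * ny)
}

#' Richness-latitude exponential regression
#'
#' OLS of log richness on absolute latitude with a two-sided t-test on the
#' slope (df = n - 2).
#'
#' @param richness Species richness per plot (per hectare).
#' @param latitudes Plot latitudes in degrees (absolute value is taken).
#' @return One-row data.frame: `log_intercept`, `slope`, `t_stat`, `df`,
#'   `p_value`, `n`.
#' @export
richness_gradient <- function(richness, latitudes) {
  stopifnot(length(richness) == length(latitudes), all(richness > 0))
  lat <- abs(latitudes)
  fit <- stats::lm(log(richness) ~ lat)
  sm <- summary(fit)$coefficients
  if (nrow(sm) < 2)
    stop("latitude has no variation; cannot fit richness gradient")
  data.frame(log_intercept = sm[1, 1], slope = sm[2, 1], t_stat = sm[2, 3],
             df = fit$df.residual, p_value = sm[2, 4],
             n = length(richness), stringsAsFactors = FALSE)
}

#' Correlations between true pairwise and higher-order coefficients
#'
#' Pearson correlations across species between `alpha_ii_true` and
#' `beta_iih`, and between `alpha_ih_true` and `beta_ihh` (both taken from
#' HOI-inclusive fits), quantifying how strongly heterospecific initiators
#' modify intraspecific and interspecific pairwise interactions.
#'
#' @param coefficients Long coefficient table (see [gradient_table()]).
#' @return Data.frame with one row per coefficient pair: `r`, `p_value`,
#'   `n`.
#' @export
alpha_beta_correlation <- function(coefficients) {
  co <- coefficients[coefficients$model_class == "hoi" &
                       !coefficients$degenerate, , drop = FALSE]
  key <- paste(co$plot_id, co$species)
  wide <- function(term) {
    v <- co$estimate[co$term == term]
    names(v) <- key[co$term == term]
    v
  }
  pairs <- list(c("alpha_ii", "beta_iih"), c("alpha_ih", "beta_ihh"))
  rows <- lapply(pairs, function(p) {
    a <- wide(p[1]); b <- wide(p[2])
    common <- intersect(names(a), names(b))
    if (length(common) < 3)
      return(data.frame(pair = paste(p, collapse = " ~ "), r = NA_real_,
                        p_value = NA_real_, n = length(common),
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(a[common], b[common])
    data.frame(pair = paste(p, collapse = " ~ "), r = unname(ct$estimate),
               p_value = ct$p.value, n = length(common),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot-level mean and standard error of species coefficients
#'
#' Per plot, coefficient type and sign subset: mean and standard error of
#' the mean of species-level estimates (the display summary used alongside
#' [gradient_table()]). Plots contributing a single species get `sem = NA`
#' and are flagged.
#'
#' @param coefficients Long coefficient table (see [gradient_table()]).
#' @param sign_subsets Sign subsets to summarise.
#' @return Data.frame: `plot_id`, `coefficient_type`, `sign_subset`,
#'   `mean`, `sem`, `n`, `sem_defined`.
#' @export
plot_level_summary <- function(coefficients,
                               sign_subsets = c("competitive",
                                                "facilitative")) {
  co <- coefficients[!coefficients$degenerate, , drop = FALSE]
  types <- list(alpha_ii_true = c("hoi", "alpha_ii"),
               alpha_ii_modified = c("pair_only", "alpha_ii"),
               alpha_ih_true = c("hoi", "alpha_ih"),
               alpha_ih_modified = c("pair_only", "alpha_ih"),
               beta_iii = c("hoi", "beta_iii"),
               beta_iih = c("hoi", "beta_iih"),
               beta_ihi = c("hoi", "beta_ihi"),
               beta_ihh = c("hoi", "beta_ihh"))
  rows <- list()
  for (type in names(types)) {
    sel <- co[co$model_class == types[[type]][1] &
                co$term == types[[type]][2], , drop = FALSE]
    for (ss in sign_subsets) {
      sub <- if (ss == "competitive") sel[sel$estimate < 0, , drop = FALSE]
             else sel[sel$estimate > 0, , drop = FALSE]
      if (!nrow(sub)) next
      agg <- split(sub$estimate, sub$plot_id)
      for (pid in names(agg)) {
        v <- agg[[pid]]
        rows[[paste(type, ss, pid)]] <- data.frame(
          plot_id = pid, coefficient_type = type, sign_subset = ss,
          mean = mean(v),
          sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
          n = length(v), sem_defined = length(v) > 1,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, make.row.names = FALSE))
}
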