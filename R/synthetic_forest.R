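#' Synthetic forest network configuration
#'
#' Defines the generative conditions for multi-plot, two-census forests:
#' plots along a latitudinal gradient, species richness declining
#' exponentially with latitude, log-series (or uniform) species
#' abundances, clustered (Thomas) or homogeneous Poisson stem positions,
#' truncated-lognormal DBH, and growth/survival produced by the same
#' power-law growth and logistic survival models the inference side fits,
#' with interaction coefficient magnitudes decaying exponentially with
#' latitude.
#'
#' @param n_plots Number of plots (default 8).
#' @param latitude_range Absolute latitude range spanned by the plots in
#'   degrees (default `c(2, 61)`).
#' @param plot_extent Plot dimensions in metres (default `c(160, 160)`).
#' @param stems_per_ha Expected stem density (default 700 per hectare;
#'   a deliberately thinned stand so desk-scale runs stay fast).
#' @param richness_at_equator,richness_decay Expected species richness
#'   `S(L) = S0 * exp(-k * |L|)` (defaults 30 and 0.03 per degree).
#' @param min_richness Lower bound on plot richness (default 2).
#' @param abundance_model `"logseries"` (default) or `"uniform"`.
#' @param logseries_x Log-series parameter: rank r has probability
#'   proportional to `x^r / r` (default 0.95).
#' @param spatial_pattern `"thomas"` (default; monospecific clusters) or
#'   `"poisson"`.
#' @param cluster_sd,cluster_size Thomas process offspring dispersion (m)
#'   and mean offspring per parent (defaults 8 and 8).
#' @param dbh_meanlog,dbh_sdlog,dbh_min Truncated lognormal DBH model
#'   (defaults log(3), 0.7, 1 cm).
#' @param census_interval Years between censuses (default 5).
#' @param growth_noise_sd Lognormal growth noise on the log scale
#'   (default 0.5).
#' @param log_G_mean,log_G_sd Species potential growth rate prior
#'   (log cm/yr; defaults log(0.15), 0.3).
#' @param gamma_mean,gamma_sd Growth size-exponent prior (defaults 0.3,
#'   0.1).
#' @param lambda_mean,lambda_sd Baseline survival logit prior (defaults
#'   1.5, 0.3; roughly 80-85% interval survival, i.e. 3-4% annual
#'   mortality).
#' @param gamma1,gamma2,gamma3 Survival size terms on `1/DBH`, `DBH`,
#'   `DBH^2` (defaults -1.2, -0.02, -2e-4).
#' @param coefficient_priors Per coefficient type, a list with `scale`
#'   (magnitude at the equator), `decay` (exponential decline per degree
#'   of latitude), `facilitative` (probability of a positive sign) and
#'   `sdlog` (lognormal spread of species magnitudes). Defaults make
#'   intraspecific pairwise and most higher-order magnitudes decay with
#'   latitude while interspecific ones stay flat, with an even
#'   competitive/facilitative split.
#' @param neighborhood A [crowding_config()] used by the generative model
#'   (inference should use the same one for exact parameter recovery).
#' @param seed Integer seed; all simulation is deterministic given it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_plots = 8,
                       latitude_range = c(2, 61),
                       plot_extent = c(160, 160),
                       stems_per_ha = 700,
                       richness_at_equator = 30,
                       richness_decay = 0.03,
                       min_richness = 2,
                       abundance_model = c("logseries", "uniform"),
                       logseries_x = 0.95,
                       spatial_pattern = c("thomas", "poisson"),
                       cluster_sd = 8,
                       cluster_size = 8,
                       dbh_meanlog = log(3),
                       dbh_sdlog = 0.7,
                       dbh_min = 1,
                       census_interval = 5,
                       growth_noise_sd = 0.5,
                       log_G_mean = log(0.15),
                       log_G_sd = 0.3,
                       gamma_mean = 0.3,
                       gamma_sd = 0.1,
                       lambda_mean = 1.5,
                       lambda_sd = 0.3,
                       gamma1 = -1.2,
                       gamma2 = -0.02,
                       gamma3 = -2e-4,
                       coefficient_priors = NULL,
                       neighborhood = crowding_config(),
                       seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  spatial_pattern <- match.arg(spatial_pattern)
  priors <- default_coefficient_priors()
  if (!is.null(coefficient_priors)) {
    unknown <- setdiff(names(coefficient_priors), names(priors))
    if (length(unknown))
      stop("unknown coefficient prior(s): ", paste(unknown, collapse = ", "))
    for (nm in names(coefficient_priors))
      priors[[nm]][names(coefficient_priors[[nm]])] <- coefficient_priors[[nm]]
  }
  cfg <- list(n_plots = n_plots, latitude_range = latitude_range,
              plot_extent = plot_extent, stems_per_ha = stems_per_ha,
              richness_at_equator = richness_at_equator,
              richness_decay = richness_decay, min_richness = min_richness,
              abundance_model = abundance_model, logseries_x = logseries_x,
              spatial_pattern = spatial_pattern, cluster_sd = cluster_sd,
              cluster_size = cluster_size, dbh_meanlog = dbh_meanlog,
              dbh_sdlog = dbh_sdlog, dbh_min = dbh_min,
              census_interval = census_interval,
              growth_noise_sd = growth_noise_sd,
              log_G_mean = log_G_mean, log_G_sd = log_G_sd,
              gamma_mean = gamma_mean, gamma_sd = gamma_sd,
              lambda_mean = lambda_mean, lambda_sd = lambda_sd,
              gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
              coefficient_priors = priors, neighborhood = neighborhood,
              seed = as.integer(seed))
  stopifnot(cfg$n_plots >= 1, all(cfg$plot_extent > 0),
            cfg$stems_per_ha > 0, cfg$richness_at_equator >= 1,
            cfg$census_interval > 0, cfg$growth_noise_sd >= 0,
            all(vapply(priors, function(p)
              p$scale >= 0 && p$facilitative >= 0 && p$facilitative <= 1,
              logical(1))))
  structure(cfg, class = "sim_config")
}

#' Default interaction coefficient priors
#'
#' Intraspecific pairwise interactions and the conspecific-linked
#' higher-order types decay with latitude; interspecific pairwise and the
#' fully heterospecific higher-order type are flat. Signs split evenly
#' between competitive and facilitative. Higher-order scales are two to
#' three orders of magnitude below pairwise scales because higher-order
#' indices are products of two crowding sums.
#'
#' @return Named list of prior lists (`scale`, `decay`, `facilitative`,
#'   `sdlog`).
#' @export
default_coefficient_priors <- function() {
  list(
    alpha_ii = list(scale = 0.08, decay = 0.05, facilitative = 0.5, sdlog = 0.3),
    alpha_ih = list(scale = 0.04, decay = 0.00, facilitative = 0.5, sdlog = 0.3),
    beta_iii = list(scale = 8e-4, decay = 0.05, facilitative = 0.5, sdlog = 0.3),
    beta_iih = list(scale = 4e-4, decay = 0.05, facilitative = 0.5, sdlog = 0.3),
    beta_ihi = list(scale = 4e-4, decay = 0.05, facilitative = 0.5, sdlog = 0.3),
    beta_ihh = list(scale = 2e-4, decay = 0.00, facilitative = 0.5, sdlog = 0.3)
  )
}

.rtrunc_lnorm <- function(n, meanlog, sdlog, lower) {
  p0 <- stats::plnorm(lower, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, p0, 1), meanlog, sdlog)
}

.species_probs <- function(cfg, S) {
  if (cfg$abundance_model == "uniform") rep(1 / S, S)
  else {
    p <- cfg$logseries_x^seq_len(S) / seq_len(S)
    p / sum(p)
  }
}

.draw_truth <- function(cfg, species, latitude) {
  S <- length(species)
  lat <- abs(latitude)
  draw <- function(prior) {
    mag <- prior$scale * exp(-prior$decay * lat) *
      stats::rlnorm(S, 0, prior$sdlog)
    sign <- ifelse(stats::runif(S) < prior$facilitative, 1, -1)
    sign * mag
  }
  pr <- cfg$coefficient_priors
  data.frame(
    species = species,
    log_G = stats::rnorm(S, cfg$log_G_mean, cfg$log_G_sd),
    gamma = stats::rnorm(S, cfg$gamma_mean, cfg$gamma_sd),
    lambda = stats::rnorm(S, cfg$lambda_mean, cfg$lambda_sd),
    gamma1 = cfg$gamma1, gamma2 = cfg$gamma2, gamma3 = cfg$gamma3,
    alpha_ii = draw(pr$alpha_ii), alpha_ih = draw(pr$alpha_ih),
    beta_iii = draw(pr$beta_iii), beta_iih = draw(pr$beta_iih),
    beta_ihi = draw(pr$beta_ihi), beta_ihh = draw(pr$beta_ihh),
    stringsAsFactors = FALSE
  )
}

.place_stems <- function(cfg, n_expected, probs, species) {
  ex <- cfg$plot_extent[1]
  ey <- cfg$plot_extent[2]
  if (cfg$spatial_pattern == "poisson") {
    n <- n_expected
    data.frame(species = sample(species, n, replace = TRUE, prob = probs),
               x = stats::runif(n, 0, ex), y = stats::runif(n, 0, ey),
               stringsAsFactors = FALSE)
  } else {
    n_par <- max(1L, stats::rpois(1, n_expected / cfg$cluster_size))
    px <- stats::runif(n_par, 0, ex)
    py <- stats::runif(n_par, 0, ey)
    psp <- sample(species, n_par, replace = TRUE, prob = probs)
    n_off <- stats::rpois(n_par, cfg$cluster_size)
    if (sum(n_off) == 0) n_off[1] <- 1L
    parent <- rep.int(seq_len(n_par), n_off)
    # toroidal wrap keeps intensity homogeneous at the edges
    data.frame(
      species = psp[parent],
      x = (px[parent] + stats::rnorm(sum(n_off), 0, cfg$cluster_sd)) %% ex,
      y = (py[parent] + stats::rnorm(sum(n_off), 0, cfg$cluster_sd)) %% ey,
      stringsAsFactors = FALSE)
  }
}

#' Simulate one two-census forest plot
#'
#' Draws census-1 positions, species and DBH from the configured spatial
#' and abundance models, computes crowding indices with the configured
#' neighbourhood kernel, then generates annual growth as
#' `G * DBH^gamma * exp(Pair) * exp(HOI)` with multiplicative lognormal
#' noise and interval survival as a single Bernoulli draw from
#' `logit P(survive) = lambda + gamma1/DBH + gamma2*DBH + gamma3*DBH^2 +
#' Pair + HOI`. Census 2 contains survivors with updated DBH and the dead
#' stems flagged dead; no recruits are generated. Fully deterministic
#' given `seed`.
#'
#' @param cfg A [sim_config()].
#' @param latitude Signed plot latitude in degrees.
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @param plot_id Plot label.
#' @return List with `census1`, `census2` (stem record data.frames),
#'   `meta` (one-row metadata data.frame), `truth` (per-species generative
#'   coefficients), and `crowding` (the census-1 crowding table).
#' @export
simulate_plot <- function(cfg, latitude, seed = cfg$seed, plot_id = "plot1") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  area_ha <- prod(cfg$plot_extent) / 1e4
  S <- max(cfg$min_richness,
           round(cfg$richness_at_equator *
                   exp(-cfg$richness_decay * abs(latitude))))
  species <- sprintf("sp%03d", seq_len(S))
  probs <- .species_probs(cfg, S)
  n_expected <- max(2L, round(cfg$stems_per_ha * area_ha))
  stems <- .place_stems(cfg, n_expected, probs, species)
  n <- nrow(stems)
  if (n < 2) stop("configuration yields an (almost) empty plot")
  stems$dbh <- .rtrunc_lnorm(n, cfg$dbh_meanlog, cfg$dbh_sdlog, cfg$dbh_min)
  stems$tree_id <- sprintf("t%06d", seq_len(n))
  stems$stem_id <- stems$tree_id
  stems$status <- "alive"
  census1 <- stems[, c("tree_id", "stem_id", "species", "x", "y", "dbh",
                       "status")]
  meta <- data.frame(plot_id = plot_id, latitude = latitude,
                     x_extent = cfg$plot_extent[1],
                     y_extent = cfg$plot_extent[2],
                     date1 = 2005, date2 = 2005 + cfg$census_interval,
                     stringsAsFactors = FALSE)

  truth <- .draw_truth(cfg, species, latitude)
  crowding <- compute_crowding_table(census1, meta, cfg$neighborhood)

  ti <- match(census1$species, truth$species)
  pair_lp <- truth$alpha_ii[ti] * crowding$n_i +
    truth$alpha_ih[ti] * crowding$n_h
  hoi_lp <- truth$beta_iii[ti] * crowding$n_ii +
    truth$beta_iih[ti] * crowding$n_ih +
    truth$beta_ihi[ti] * crowding$n_hi +
    truth$beta_ihh[ti] * crowding$n_hh

  growth <- exp(truth$log_G[ti]) * census1$dbh^truth$gamma[ti] *
    exp(pair_lp + hoi_lp) *
    exp(stats::rnorm(n, 0, cfg$growth_noise_sd))
  eta <- truth$lambda[ti] + truth$gamma1[ti] / census1$dbh +
    truth$gamma2[ti] * census1$dbh + truth$gamma3[ti] * census1$dbh^2 +
    pair_lp + hoi_lp
  survived <- stats::rbinom(n, 1, stats::plogis(eta))

  census2 <- census1
  census2$status <- ifelse(survived == 1L, "alive", "dead")
  census2$dbh <- ifelse(survived == 1L,
                        census1$dbh + growth * cfg$census_interval,
                        census1$dbh)
  list(census1 = census1, census2 = census2, meta = meta, truth = truth,
       crowding = crowding)
}

#' Simulate a multi-plot forest network
#'
#' Plots are placed at evenly spaced absolute latitudes across
#' `cfg$latitude_range` (or at `latitudes` when given), each simulated by
#' [simulate_plot()] with a seed derived from `cfg$seed` so the whole
#' network is reproducible.
#'
#' @param cfg A [sim_config()] with `n_plots >= 2`.
#' @param latitudes Optional explicit plot latitudes.
#' @return List with `plots` (list of [simulate_plot()] results, named by
#'   plot id), `meta` (combined metadata table) and `truth` (combined
#'   per-plot species truth with `plot_id` and `latitude`).
#' @export
simulate_network <- function(cfg, latitudes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(latitudes))
    latitudes <- seq(cfg$latitude_range[1], cfg$latitude_range[2],
                     length.out = cfg$n_plots)
  stopifnot(length(latitudes) >= 2)
  ids <- sprintf("plot%02d", seq_along(latitudes))
  plots <- lapply(seq_along(latitudes), function(i)
    simulate_plot(cfg, latitudes[i],
                  seed = (cfg$seed + 7919L * i) %% .Machine$integer.max,
                  plot_id = ids[i]))
  names(plots) <- ids
  meta <- do.call(rbind, lapply(plots, `[[`, "meta"))
  rownames(meta) <- NULL
  truth <- do.call(rbind, lapply(plots, function(p)
    cbind(plot_id = p$meta$plot_id, latitude = p$meta$latitude, p$truth,
          stringsAsFactors = FALSE)))
  rownames(truth) <- NULL
  list(plots = plots, meta = meta, truth = truth)
}

#' Write a simulated network as plain-text fixture files
#'
#' Produces the file layout consumed by the reading side: per plot,
#' `<plot_id>_census1.csv` and `<plot_id>_census2.csv` in the canonical
#' census dialect; `plots.csv` with the metadata; `truth.csv` with the
#' generative coefficients; and `manifest.json` recording the seed and
#' per-file checksums.
#'
#' @param network Output of [simulate_network()].
#' @param dir Output directory (created if needed).
#' @param cfg The [sim_config()] used (recorded in the manifest).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(network, dir, cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (p in network$plots) {
    f1 <- file.path(dir, paste0(p$meta$plot_id, "_census1.csv"))
    f2 <- file.path(dir, paste0(p$meta$plot_id, "_census2.csv"))
    write_census_table(p$census1, f1)
    write_census_table(p$census2, f2)
    files <- c(files, f1, f2)
  }
  fm <- file.path(dir, "plots.csv")
  utils::write.table(network$meta, fm, sep = ",", row.names = FALSE,
                     quote = FALSE)
  ft <- file.path(dir, "truth.csv")
  utils::write.table(network$truth, ft, sep = ",", row.names = FALSE,
                     quote = FALSE)
  files <- c(files, fm, ft)
  manifest <- list(
    seed = if (!is.null(cfg)) cfg$seed else NA,
    n_plots = length(network$plots),
    files = as.list(tools::md5sum(files)),
    config = if (!is.null(cfg)) unclass(cfg)[setdiff(names(cfg),
                                                     "neighborhood")]
             else NULL,
    neighborhood = if (!is.null(cfg)) unclass(cfg$neighborhood) else NULL
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture directory back into censuses and metadata
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `meta` (plot metadata), `censuses` (per plot, a list
#'   with `census1` and `census2`), and `truth` (when present).
#' @export
read_fixture <- function(dir) {
  meta <- read_plot_meta(file.path(dir, "plots.csv"))
  censuses <- lapply(seq_len(nrow(meta)), function(i) {
    pid <- meta$plot_id[i]
    m <- meta[i, ]
    list(census1 = read_census_table(file.path(dir, paste0(pid, "_census1.csv")),
                                     meta = m),
         census2 = read_census_table(file.path(dir, paste0(pid, "_census2.csv")),
                                     meta = m))
  })
  names(censuses) <- meta$plot_id
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.table(truth_path, header = TRUE, sep = ",",
                      stringsAsFactors = FALSE)
  else NULL
  list(meta = meta, censuses = censuses, truth = truth)
}
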