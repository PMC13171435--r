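.default_config <- function() {
  list(
    simulate = list(enabled = TRUE, n_plots = 4, seed = 1,
                    latitude_range = c(5, 50), plot_extent = c(140, 140),
                    stems_per_ha = 700, richness_at_equator = 12,
                    richness_decay = 0.03),
    io = list(fixture_dir = NULL, schema = NULL),
    neighborhood = list(radius = 10, size_exponent = 1, distance_exponent = 1,
                        min_distance = 0.1, exclude_focal = TRUE,
                        standardize = FALSE),
    models = list(growth_floor = 0.01, nonpositive = "floor",
                  min_trees = 100, min_survivors = 20, min_dead = 20,
                  responses = "growth"),
    gradients = list(quadrat = 100, estimator = "quadrat"),
    rc = list(zone_latitudes = list(tropical = 11.75, subtropical = 29.25,
                                    temperate = 45))
  )
}

.merge_block <- function(defaults, user, block, allowed = names(defaults)) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), allowed)
  if (length(unknown)) {
    hints <- vapply(unknown, function(k) {
      d <- utils::adist(k, allowed)
      allowed[which.min(d)]
    }, character(1))
    warning("unknown key(s) in '", block, "': ",
            paste(sprintf("%s (did you mean '%s'?)", unknown, hints),
                  collapse = ", "))
    user <- user[setdiff(names(user), unknown)]
  }
  defaults[names(user)] <- user
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), fills every
#' omitted key with its default, warns about unknown keys (suggesting the
#' nearest valid one), and checks cross-block consistency: the
#' neighbourhood radius must not exceed half the smaller plot dimension,
#' otherwise no stem can be interior.
#'
#' Blocks: `simulate` ([sim_config()] fields plus `enabled`), `io`
#' (`fixture_dir`, `schema`), `neighborhood` ([crowding_config()] fields),
#' `models` (filters, growth floor, `responses`), `gradients`, `rc`.
#'
#' @param config Path to a YAML file, or a named list of blocks.
#' @return Normalized configuration list of class `"hoiforest_config"`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    warning("unknown config block(s): ", paste(unknown, collapse = ", "))
  cfg <- lapply(names(defaults), function(b) {
    allowed <- names(defaults[[b]])
    if (b == "simulate")  # any generator argument is a valid key here
      allowed <- union(allowed,
                       setdiff(names(formals(sim_config)), "neighborhood"))
    .merge_block(defaults[[b]], config[[b]], b, allowed = allowed)
  })
  names(cfg) <- names(defaults)

  if (!is.null(cfg$io$fixture_dir)) cfg$simulate$enabled <- FALSE
  if (isTRUE(cfg$simulate$enabled)) {
    extent <- unlist(cfg$simulate$plot_extent)
    if (cfg$neighborhood$radius > min(extent) / 2)
      stop("neighbourhood radius (", cfg$neighborhood$radius,
           " m) exceeds half the plot extent (", min(extent), " m plot); ",
           "no stem can be interior")
  }
  cfg$models$responses <- match.arg(cfg$models$responses,
                                    c("growth", "survival"),
                                    several.ok = TRUE)
  structure(cfg, class = "hoiforest_config")
}

.crowding_from_config <- function(cfg) {
  nb <- cfg$neighborhood
  crowding_config(radius = nb$radius, size_exponent = nb$size_exponent,
                  distance_exponent = nb$distance_exponent,
                  min_distance = nb$min_distance,
                  exclude_focal = nb$exclude_focal,
                  standardize = nb$standardize)
}

.hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(x), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Orchestrates one reproducible run: obtain censuses (from a fixture
#' directory or by simulation), link censuses, compute crowding indices,
#' fit the three demographic model classes per eligible species, classify
#' AIC support, fit the latitudinal gradient regressions (coefficients and
#' richness), and compute the RC statistics with their
#' abundance-latitude model and zone predictions. All stages are pure
#' functions of the configuration, so re-running with the same
#' configuration reproduces the report exactly.
#'
#' @param config Path to a YAML configuration or a configuration list
#'   (see [validate_config()]).
#' @param out_dir Optional output directory; when given, the summary
#'   tables are written as CSV and the report (with manifest) as JSON.
#' @return List: `support_summary` (per response), `support`,
#'   `coefficients`, `gradients`, `richness_gradient`, `rc` (records,
#'   model table, zone predictions), and `manifest`.
#' @export
run_all <- function(config = list(), out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  cfg <- if (inherits(config, "hoiforest_config")) config
         else validate_config(config)
  ncfg <- .crowding_from_config(cfg)
  timings <- list()

  tick <- function() proc.time()[["elapsed"]]
  t_stage <- tick()
  if (!is.null(cfg$io$fixture_dir)) {
    fx <- read_fixture(cfg$io$fixture_dir)
    meta <- fx$meta
    plots <- lapply(seq_len(nrow(meta)), function(i)
      list(census1 = fx$censuses[[i]]$census1,
           census2 = fx$censuses[[i]]$census2, meta = meta[i, ]))
    sim_seed <- NA
  } else {
    sim_args <- cfg$simulate[setdiff(names(cfg$simulate), "enabled")]
    sim_args$neighborhood <- ncfg
    scfg <- do.call(sim_config, sim_args)
    net <- simulate_network(scfg)
    meta <- net$meta
    plots <- net$plots
    sim_seed <- scfg$seed
  }
  timings$data <- tick() - t_stage

  t_stage <- tick()
  all_support <- list()
  all_coefs <- list()
  all_rc <- list()
  richness <- numeric(nrow(meta))
  dropped_log <- list()
  for (i in seq_len(nrow(meta))) {
    p <- plots[[i]]
    m <- meta[i, ]
    dyn <- link_censuses(p$census1, p$census2, m,
                         growth_floor = cfg$models$growth_floor,
                         nonpositive = cfg$models$nonpositive)
    crowding <- compute_crowding_table(p$census1, m, ncfg)
    richness[i] <- quadrat_richness(p$census1, m,
                                    quadrat = cfg$gradients$quadrat,
                                    estimator = cfg$gradients$estimator)
    dropped_log[[m$plot_id]] <- list(
      n_stems = nrow(p$census1),
      n_edge = sum(!crowding$interior),
      n_floored = attr(dyn, "n_floored"))
    for (resp in cfg$models$responses) {
      res <- fit_species_models(dyn, crowding, resp, plot_id = m$plot_id,
                                min_trees = cfg$models$min_trees,
                                min_survivors = cfg$models$min_survivors,
                                min_dead = cfg$models$min_dead)
      if (is.null(res$support)) next
      all_support[[paste(m$plot_id, resp)]] <- res$support
      all_coefs[[paste(m$plot_id, resp)]] <- res$coefficients
      if (resp == "growth") {
        rc <- rc_records(res$fits, crowding, dyn, m)
        if (!is.null(rc)) all_rc[[m$plot_id]] <- rc
      }
    }
  }
  support <- if (length(all_support))
    do.call(rbind, c(all_support, make.row.names = FALSE)) else NULL
  coefs <- if (length(all_coefs))
    do.call(rbind, c(all_coefs, make.row.names = FALSE)) else NULL
  timings$models <- tick() - t_stage

  t_stage <- tick()
  sup_sum <- if (!is.null(support))
    lapply(split(support, support$response), support_summary) else NULL
  gradients <- if (!is.null(coefs) &&
                     any(coefs$response == "growth"))
    gradient_table(coefs[coefs$response == "growth", ], meta) else NULL
  rich_fit <- if (nrow(meta) >= 3)
    richness_gradient(richness, meta$latitude) else NULL

  rc_out <- NULL
  rc_all <- if (length(all_rc))
    do.call(rbind, c(all_rc, make.row.names = FALSE)) else NULL
  if (!is.null(rc_all) && nrow(rc_all) >= 4) {
    rc_model <- rc_abundance_latitude_model(rc_all)
    zones <- unlist(cfg$rc$zone_latitudes)
    rc_out <- list(records = rc_all, table = rc_model$table,
                   zone_predictions = zone_predictions(
                     rc_model$models$rc_hoi,
                     zone_latitudes = zones))
  } else if (!is.null(rc_all)) {
    rc_out <- list(records = rc_all, table = NULL, zone_predictions = NULL)
  }
  timings$summaries <- tick() - t_stage

  manifest <- list(
    config_hash = .hash_object(unclass(cfg)),
    seed = sim_seed,
    n_plots = nrow(meta),
    filter_log = dropped_log,
    timings = timings,
    r_version = as.character(getRversion()),
    total_elapsed = tick() - t0
  )
  report <- list(support_summary = sup_sum, support = support,
                 coefficients = coefs, gradients = gradients,
                 richness = data.frame(plot_id = meta$plot_id,
                                       latitude = meta$latitude,
                                       richness = richness),
                 richness_gradient = rich_fit, rc = rc_out,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, name) if (!is.null(x))
      utils::write.table(x, file.path(out_dir, name), sep = ",",
                         row.names = FALSE, quote = FALSE)
    wt(support, "support.csv")
    wt(coefs, "coefficients.csv")
    wt(gradients, "gradients.csv")
    wt(report$richness, "richness.csv")
    if (!is.null(rc_out)) {
      wt(rc_out$records, "rc_records.csv")
      wt(rc_out$table, "rc_model.csv")
      wt(rc_out$zone_predictions, "rc_zone_predictions.csv")
    }
    jsonlite::write_json(
      list(support_summary = sup_sum, richness_gradient = rich_fit,
           manifest = manifest),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, force = TRUE)
  }
  report
}
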