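# shared test fixtures and independent oracles, built in code

random_stems <- function(n, n_species = 2, extent = 50, seed = 1,
                         dbh_range = c(1, 30)) {
  set.seed(seed)
  data.frame(
    species = sample(sprintf("sp%02d", seq_len(n_species)), n,
                     replace = TRUE),
    x = runif(n, 0, extent), y = runif(n, 0, extent),
    dbh = runif(n, dbh_range[1], dbh_range[2]),
    stem_id = sprintf("s%04d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

# fully independent crowding oracle: plain nested loops over all stems
# (focal -> transmitter -> initiator), no shared code with the package
oracle_crowding <- function(stems, radius = 10, min_distance = 0.1,
                            size_exp = 1, dist_exp = 1,
                            exclude_focal = TRUE) {
  n <- nrow(stems)
  contrib <- function(dbh_j, d)
    dbh_j^size_exp / max(d, min_distance)^dist_exp
  dist_ij <- function(i, j)
    sqrt((stems$x[i] - stems$x[j])^2 + (stems$y[i] - stems$y[j])^2)
  out <- matrix(0, n, 6,
                dimnames = list(NULL, c("n_i", "n_h", "n_ii", "n_ih",
                                        "n_hi", "n_hh")))
  for (f in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == f) next
      dfj <- dist_ij(f, j)
      if (dfj > radius) next
      cfj <- contrib(stems$dbh[j], dfj)
      consp_j <- stems$species[j] == stems$species[f]
      if (consp_j) out[f, "n_i"] <- out[f, "n_i"] + cfj
      else out[f, "n_h"] <- out[f, "n_h"] + cfj
      inner_i <- inner_h <- 0
      for (k in seq_len(n)) {
        if (k == j) next
        if (exclude_focal && k == f) next
        djk <- dist_ij(j, k)
        if (djk > radius) next
        cjk <- contrib(stems$dbh[k], djk)
        if (stems$species[k] == stems$species[f]) inner_i <- inner_i + cjk
        else inner_h <- inner_h + cjk
      }
      if (consp_j) {
        out[f, "n_ii"] <- out[f, "n_ii"] + cfj * inner_i
        out[f, "n_ih"] <- out[f, "n_ih"] + cfj * inner_h
      } else {
        out[f, "n_hi"] <- out[f, "n_hi"] + cfj * inner_i
        out[f, "n_hh"] <- out[f, "n_hh"] + cfj * inner_h
      }
    }
  }
  out
}

# growth observations generated exactly from the power-law growth model
make_growth_data <- function(n = 300, seed = 1, noise_sd = 0,
                             truth = c(log_G = log(0.2), gamma = 0.4,
                                       alpha_ii = -0.03, alpha_ih = 0.015,
                                       beta_iii = -4e-4, beta_iih = 2e-4,
                                       beta_ihi = -1e-4, beta_ihh = 5e-5),
                             extent = 80) {
  st <- random_stems(n, n_species = 3, extent = extent, seed = seed)
  cfg <- crowding_config(radius = 10)
  cr <- compute_crowding_table(st, list(x_extent = extent, y_extent = extent),
                               cfg)
  set.seed(seed + 1)
  d <- data.frame(dbh0 = st$dbh, n_i = cr$n_i, n_h = cr$n_h,
                  n_ii = cr$n_ii, n_ih = cr$n_ih, n_hi = cr$n_hi,
                  n_hh = cr$n_hh)
  mu <- truth[["log_G"]] + truth[["gamma"]] * log(d$dbh0) +
    truth[["alpha_ii"]] * d$n_i + truth[["alpha_ih"]] * d$n_h +
    truth[["beta_iii"]] * d$n_ii + truth[["beta_iih"]] * d$n_ih +
    truth[["beta_ihi"]] * d$n_hi + truth[["beta_ihh"]] * d$n_hh
  d$growth <- exp(mu + rnorm(n, 0, noise_sd))
  list(data = d, truth = truth, mu = mu)
}

coef_named <- function(fit) {
  stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
}
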