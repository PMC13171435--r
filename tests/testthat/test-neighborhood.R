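test_that("neighbour contribution follows the size/distance kernel", {
  cfg <- crowding_config()
  expect_equal(neighbor_contribution(10, 2, cfg), 5)
  # clamp: distances below min_distance never blow up
  expect_equal(neighbor_contribution(10, 0.01, cfg), 100)
  expect_equal(neighbor_contribution(10, 0, cfg), 100)
  cfg2 <- crowding_config(size_exponent = 2, distance_exponent = 2)
  expect_equal(neighbor_contribution(10, 2, cfg2), 25)
})

test_that("pairwise indices sum con- and heterospecific contributions", {
  st <- data.frame(species = c("i", "i", "h"),
                   x = c(0, 2, 4), y = 0, dbh = c(5, 10, 20))
  cfg <- crowding_config(radius = 10)
  expect_equal(pairwise_indices(st, 1, cfg), c(n_i = 5, n_h = 5))
  # isolated focal
  st2 <- data.frame(species = c("i", "h"), x = c(0, 50), y = 0,
                    dbh = c(5, 10))
  expect_equal(pairwise_indices(st2, 1, cfg), c(n_i = 0, n_h = 0))
})

test_that("higher-order chain example matches the hand-computed value", {
  # focal at origin; conspecific transmitter j (dbh 10, 2 m away);
  # conspecific initiator k (dbh 20) 2 m beyond j, outside the focal radius 3
  st <- data.frame(species = c("i", "i", "i"),
                   x = c(0, 2, 4), y = 0, dbh = c(5, 10, 20))
  cfg <- crowding_config(radius = 3)
  expect_equal(pairwise_indices(st, 1, cfg), c(n_i = 5, n_h = 0))
  ho <- higher_order_indices(st, 1, cfg)
  expect_equal(ho, c(n_ii = 5 * (20 / 2), n_ih = 0, n_hi = 0, n_hh = 0))
  # a transmitter with no neighbours of its own transmits nothing
  st3 <- data.frame(species = c("i", "i"), x = c(0, 2), y = 0,
                    dbh = c(5, 10))
  expect_equal(higher_order_indices(st3, 1, cfg),
               c(n_ii = 0, n_ih = 0, n_hi = 0, n_hh = 0))
})

test_that("batch, per-focal and exhaustive-loop computations agree", {
  for (seed in 1:3) {
    st <- random_stems(50, n_species = 2, extent = 40, seed = seed)
    cfg <- crowding_config(radius = 10)
    meta <- list(x_extent = 40, y_extent = 40)
    batch <- as.matrix(compute_crowding_table(st, meta, cfg)[, 3:8])
    oracle <- oracle_crowding(st)
    perfocal <- t(vapply(seq_len(nrow(st)), function(i)
      c(pairwise_indices(st, i, cfg), higher_order_indices(st, i, cfg)),
      numeric(6)))
    expect_lt(max(abs(batch - oracle) / pmax(abs(oracle), 1e-8)), 1e-10)
    expect_lt(max(abs(perfocal - oracle) / pmax(abs(oracle), 1e-8)), 1e-10)
  }
  # including the focal as an initiator is honoured in both routes
  st <- random_stems(40, n_species = 2, extent = 30, seed = 7)
  cfg <- crowding_config(radius = 10, exclude_focal = FALSE)
  batch <- as.matrix(compute_crowding_table(
    st, list(x_extent = 30, y_extent = 30), cfg)[, 3:8])
  oracle <- oracle_crowding(st, exclude_focal = FALSE)
  expect_lt(max(abs(batch - oracle) / pmax(abs(oracle), 1e-8)), 1e-10)
})

test_that("block size does not affect results", {
  st <- random_stems(120, n_species = 3, extent = 60, seed = 4)
  meta <- list(x_extent = 60, y_extent = 60)
  cfg <- crowding_config()
  a <- compute_crowding_table(st, meta, cfg, block_size = 7L)
  b <- compute_crowding_table(st, meta, cfg, block_size = 512L)
  expect_equal(a, b, tolerance = 1e-14)
})

test_that("indices are invariant to translation and rotation", {
  st <- random_stems(80, n_species = 2, extent = 50, seed = 2)
  meta <- list(x_extent = 70, y_extent = 70)
  cfg <- crowding_config()
  base <- compute_crowding_table(st, meta, cfg)[, 3:8]
  tr <- st
  tr$x <- st$x + 3
  tr$y <- st$y + 7
  expect_equal(compute_crowding_table(tr, meta, cfg)[, 3:8], base,
               tolerance = 1e-10)
  th <- 0.73
  rot <- st
  cx <- st$x - 25
  cy <- st$y - 25
  rot$x <- 35 + cos(th) * cx - sin(th) * cy
  rot$y <- 35 + sin(th) * cx + cos(th) * cy
  expect_equal(compute_crowding_table(rot, meta, cfg)[, 3:8], base,
               tolerance = 1e-9)
})

test_that("DBH rescaling scales pairwise and higher-order indices correctly", {
  st <- random_stems(60, n_species = 2, extent = 40, seed = 6)
  meta <- list(x_extent = 40, y_extent = 40)
  cfg <- crowding_config(size_exponent = 1.5)
  base <- compute_crowding_table(st, meta, cfg)
  sc <- st
  s <- 2.5
  sc$dbh <- st$dbh * s
  scaled <- compute_crowding_table(sc, meta, cfg)
  a <- cfg$size_exponent
  expect_equal(scaled$n_i, base$n_i * s^a, tolerance = 1e-12)
  expect_equal(scaled$n_h, base$n_h * s^a, tolerance = 1e-12)
  for (col in c("n_ii", "n_ih", "n_hi", "n_hh"))
    expect_equal(scaled[[col]], base[[col]] * s^(2 * a), tolerance = 1e-12)
})

test_that("adding a stem never decreases any index and all stay non-negative", {
  st <- random_stems(70, n_species = 2, extent = 40, seed = 8)
  meta <- list(x_extent = 40, y_extent = 40)
  cfg <- crowding_config()
  base <- compute_crowding_table(st, meta, cfg)
  expect_true(all(as.matrix(base[, 3:8]) >= 0))
  extra <- rbind(st, data.frame(species = "sp01", x = 20, y = 20, dbh = 15,
                                stem_id = "extra"))
  grown <- compute_crowding_table(extra, meta, cfg)
  for (col in c("n_i", "n_h", "n_ii", "n_ih", "n_hi", "n_hh"))
    expect_true(all(grown[[col]][1:70] >= base[[col]] - 1e-12))
})

test_that("interior flag marks stems at least twice the radius from edges", {
  st <- data.frame(species = "a", x = c(19.9, 20, 50, 80.1),
                   y = c(50, 50, 50, 50), dbh = 10,
                   stem_id = as.character(1:4))
  tab <- compute_crowding_table(st, list(x_extent = 100, y_extent = 100),
                                crowding_config(radius = 10))
  expect_equal(tab$interior, c(FALSE, TRUE, TRUE, FALSE))
  # single isolated stem: all indices zero
  one <- compute_crowding_table(st[3, ], list(x_extent = 100, y_extent = 100),
                                crowding_config(radius = 10))
  expect_equal(unlist(one[, 3:8]), setNames(rep(0, 6),
                                            c("n_i", "n_h", "n_ii", "n_ih",
                                              "n_hi", "n_hh")))
})

test_that("per-species standardization divides by the within-species sd", {
  st <- random_stems(100, n_species = 2, extent = 50, seed = 11)
  meta <- list(x_extent = 50, y_extent = 50)
  raw <- compute_crowding_table(st, meta, crowding_config())
  std <- compute_crowding_table(st, meta,
                                crowding_config(standardize = TRUE))
  for (sp in unique(raw$species)) {
    sel <- raw$species == sp
    s <- sd(raw$n_i[sel])
    expect_equal(std$n_i[sel], raw$n_i[sel] / s, tolerance = 1e-12)
  }
})
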