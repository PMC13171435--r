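#' Neighbourhood crowding configuration
#'
#' Parameters of the crowding kernel and of the batch computation. A
#' neighbour's contribution to a focal stem is
#' `dbh^size_exponent / distance^distance_exponent`, summed over all
#' neighbours within `radius` metres. Distances below `min_distance` are
#' clamped so co-located stems never contribute infinitely.
#'
#' @param radius Neighbourhood radius in metres (default 10).
#' @param size_exponent Exponent on neighbour DBH (default 1).
#' @param distance_exponent Exponent on distance (default 1).
#' @param min_distance Distance clamp in metres (default 0.1).
#' @param exclude_focal Logical; when `TRUE` (default) the focal stem is
#'   excluded from its neighbours' own crowding, so it never acts as the
#'   initiator of a higher-order effect on itself.
#' @param standardize Logical; when `TRUE`, divide each index by its
#'   within-species standard deviation after computation (default `FALSE`;
#'   raw indices keep generative-model parameter recovery exact).
#' @return A list of class `"crowding_config"`.
#' @export
crowding_config <- function(radius = 10, size_exponent = 1,
                            distance_exponent = 1, min_distance = 0.1,
                            exclude_focal = TRUE, standardize = FALSE) {
  stopifnot(radius > 0, min_distance > 0,
            is.finite(size_exponent), is.finite(distance_exponent))
  structure(list(radius = radius, size_exponent = size_exponent,
                 distance_exponent = distance_exponent,
                 min_distance = min_distance,
                 exclude_focal = isTRUE(exclude_focal),
                 standardize = isTRUE(standardize)),
            class = "crowding_config")
}

#' Crowding contribution of a single neighbour
#'
#' Directly proportional to the neighbour's size and inversely proportional
#' to its distance from the focal stem:
#' `dbh^size_exponent / max(distance, min_distance)^distance_exponent`.
#'
#' @param dbh Neighbour DBH in cm (vectorised).
#' @param distance Distance to the focal stem in metres (vectorised).
#' @param cfg A [crowding_config()].
#' @return Numeric crowding contribution(s), always finite.
#' @export
neighbor_contribution <- function(dbh, distance, cfg = crowding_config()) {
  d <- pmax(distance, cfg$min_distance)
  dbh^cfg$size_exponent / d^cfg$distance_exponent
}

.drop_dust <- function(diff, total) {
  ifelse(diff > 1e-9 * total, diff, 0)
}

.stem_distances <- function(stems, focal) {
  sqrt((stems$x - stems$x[focal])^2 + (stems$y - stems$y[focal])^2)
}

#' Pairwise crowding indices for one focal stem
#'
#' Sums the crowding contributions of all conspecific (`n_i`) and
#' heterospecific (`n_h`) neighbours within the radius. Written as a
#' direct, definitional loop over stems; use [compute_crowding_table()]
#' for whole-plot computation.
#'
#' @param stems Data.frame with columns `species`, `x`, `y`, `dbh`.
#' @param focal Integer row index of the focal stem in `stems`.
#' @param cfg A [crowding_config()].
#' @return Named numeric vector `c(n_i = , n_h = )`.
#' @export
pairwise_indices <- function(stems, focal, cfg = crowding_config()) {
  d <- .stem_distances(stems, focal)
  nb <- which(d <= cfg$radius)
  nb <- nb[nb != focal]
  if (!length(nb)) return(c(n_i = 0, n_h = 0))
  contrib <- neighbor_contribution(stems$dbh[nb], d[nb], cfg)
  consp <- stems$species[nb] == stems$species[focal]
  c(n_i = sum(contrib[consp]), n_h = sum(contrib[!consp]))
}

#' Higher-order crowding indices for one focal stem
#'
#' Each neighbour `j` (the transmitter) contributes its own pairwise
#' crowding, split by the identity of the stems crowding it (the
#' initiators) *relative to the focal species*: `n_ii` and `n_ih` sum, over
#' conspecific transmitters, the focal's contribution from `j` multiplied
#' by `j`'s crowding from focal-species stems and from other stems
#' respectively; `n_hi` and `n_hh` do the same over heterospecific
#' transmitters. When `cfg$exclude_focal` is `TRUE`, the focal stem is left
#' out of every transmitter's crowding.
#'
#' @inheritParams pairwise_indices
#' @return Named numeric vector `c(n_ii = , n_ih = , n_hi = , n_hh = )`.
#' @export
higher_order_indices <- function(stems, focal, cfg = crowding_config()) {
  d <- .stem_distances(stems, focal)
  nb <- which(d <= cfg$radius)
  nb <- nb[nb != focal]
  out <- c(n_ii = 0, n_ih = 0, n_hi = 0, n_hh = 0)
  if (!length(nb)) return(out)
  sp_f <- stems$species[focal]
  for (j in nb) {
    cj <- neighbor_contribution(stems$dbh[j], d[j], cfg)
    dj <- .stem_distances(stems, j)
    inner <- which(dj <= cfg$radius)
    inner <- inner[inner != j]
    if (cfg$exclude_focal) inner <- inner[inner != focal]
    if (length(inner)) {
      w <- neighbor_contribution(stems$dbh[inner], dj[inner], cfg)
      from_i <- stems$species[inner] == sp_f
      inner_i <- sum(w[from_i])
      inner_h <- sum(w[!from_i])
    } else {
      inner_i <- inner_h <- 0
    }
    if (stems$species[j] == sp_f) {
      out["n_ii"] <- out["n_ii"] + cj * inner_i
      out["n_ih"] <- out["n_ih"] + cj * inner_h
    } else {
      out["n_hi"] <- out["n_hi"] + cj * inner_i
      out["n_hh"] <- out["n_hh"] + cj * inner_h
    }
  }
  out
}

#' Crowding indices for every stem of a plot
#'
#' Computes the two pairwise (`n_i`, `n_h`) and four higher-order (`n_ii`,
#' `n_ih`, `n_hi`, `n_hh`) crowding indices for every stem, plus an
#' `interior` flag marking stems at least `2 * radius` from every plot
#' edge (stems nearer the edge have truncated transmitter neighbourhoods
#' and are excluded from model fitting; they still act as neighbours).
#'
#' The computation is a blocked matrix formulation of the same sums as
#' [pairwise_indices()] and [higher_order_indices()] and is exactly
#' equivalent to them.
#'
#' @param stems Data.frame with columns `species`, `x`, `y`, `dbh` and
#'   optionally `stem_id` (carried through).
#' @param meta Plot metadata (list or one-row data.frame) with `x_extent`
#'   and `y_extent` in metres.
#' @param cfg A [crowding_config()].
#' @param block_size Number of focal stems processed per block (memory /
#'   speed trade-off; results are independent of it).
#' @return Data.frame with columns `stem_id`, `species`, `n_i`, `n_h`,
#'   `n_ii`, `n_ih`, `n_hi`, `n_hh`, `interior`.
#' @export
compute_crowding_table <- function(stems, meta, cfg = crowding_config(),
                                   block_size = 512L) {
  n <- nrow(stems)
  stopifnot(n >= 1)
  sp <- factor(stems$species)
  spi <- as.integer(sp)
  S <- nlevels(sp)
  a <- cfg$size_exponent
  b <- cfg$distance_exponent
  dbh_a <- stems$dbh^a
  x <- stems$x
  y <- stems$y
  Z <- matrix(0, n, S)
  Z[cbind(seq_len(n), spi)] <- 1

  blocks <- split(seq_len(n), ceiling(seq_len(n) / block_size))
  # pass 1: M[j, s] = crowding of stem j by stems of species s (self excluded)
  M <- matrix(0, n, S)
  Stot <- numeric(n)
  for (idx in blocks) {
    D <- sqrt(outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2)
    W <- (D <= cfg$radius) / pmax(D, cfg$min_distance)^b
    W <- sweep(W, 2, dbh_a, "*")
    W[cbind(seq_along(idx), idx)] <- 0
    M[idx, ] <- W %*% Z
    Stot[idx] <- rowSums(W)
  }
  n_i <- M[cbind(seq_len(n), spi)]
  # differences of accumulated sums leave O(eps)*total dust where the true
  # value is zero; real contributions are >> 1e-9 of the total, so zero them
  n_h <- .drop_dust(Stot - n_i, Stot)

  # pass 2: higher-order sums over transmitters j within radius of each focal
  n_ii <- n_ih <- n_hi <- n_hh <- numeric(n)
  for (idx in blocks) {
    D <- sqrt(outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2)
    inr <- D <= cfg$radius
    Db <- pmax(D, cfg$min_distance)^b
    for (r in seq_along(idx)) {
      f <- idx[r]
      m <- inr[r, ]
      m[f] <- FALSE
      if (!any(m)) next
      w <- which(m)
      invd <- 1 / Db[r, w]
      v <- dbh_a[w] * invd       # contribution of transmitter j to focal
      cback <- dbh_a[f] * invd   # contribution of focal to transmitter j
      mi <- M[w, spi[f]]
      inner_i <- if (cfg$exclude_focal) .drop_dust(mi - cback, mi) else mi
      inner_h <- .drop_dust(Stot[w] - mi, Stot[w])
      consp <- spi[w] == spi[f]
      n_ii[f] <- sum(v[consp] * inner_i[consp])
      n_ih[f] <- sum(v[consp] * inner_h[consp])
      n_hi[f] <- sum(v[!consp] * inner_i[!consp])
      n_hh[f] <- sum(v[!consp] * inner_h[!consp])
    }
  }

  interior <- x >= 2 * cfg$radius & x <= meta$x_extent - 2 * cfg$radius &
    y >= 2 * cfg$radius & y <= meta$y_extent - 2 * cfg$radius

  out <- data.frame(
    stem_id = if ("stem_id" %in% names(stems)) stems$stem_id
              else as.character(seq_len(n)),
    species = as.character(stems$species),
    n_i = n_i, n_h = n_h, n_ii = n_ii, n_ih = n_ih, n_hi = n_hi, n_hh = n_hh,
    interior = interior, stringsAsFactors = FALSE
  )
  if (cfg$standardize) out <- .standardize_indices(out)
  out
}

.standardize_indices <- function(crowding) {
  idx_cols <- c("n_i", "n_h", "n_ii", "n_ih", "n_hi", "n_hh")
  for (col in idx_cols) {
    s <- stats::ave(crowding[[col]], crowding$species,
                    FUN = function(v) stats::sd(v))
    ok <- !is.na(s) & s > 0
    crowding[[col]][ok] <- crowding[[col]][ok] / s[ok]
  }
  crowding
}

#' Write a crowding table to delimited text
#'
#' @param crowding Output of [compute_crowding_table()].
#' @param path Output path (`.tsv` for tab separation, else comma).
#' @return `path`, invisibly.
#' @export
write_crowding_table <- function(crowding, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(crowding, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
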