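#' Canonical census column names
#'
#' The tabular census dialect understood by [read_census_table()]. A schema
#' map can rename any of these to match the columns of a particular file.
#'
#' @return Named character vector mapping internal field names to the
#'   canonical column names (`treeID`, `stemID`, `sp`, `gx`, `gy`, `dbh`,
#'   `status`, `date`).
#' @export
census_schema <- function() {
  c(tree_id = "treeID", stem_id = "stemID", species = "sp",
    x = "gx", y = "gy", dbh = "dbh", status = "status", date = "date")
}

.normalize_status <- function(status) {
  s <- tolower(trimws(as.character(status)))
  map <- c(a = "alive", alive = "alive", live = "alive",
           d = "dead", dead = "dead",
           r = "recruit", recruit = "recruit")
  out <- unname(map[s])
  if (anyNA(out)) {
    bad <- unique(s[is.na(out)])
    stop("unrecognised stem status value(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Read a mapped stem census table
#'
#' Reads one census of a mapped forest plot from delimited text (comma or
#' tab, auto-detected), applies the column schema, and enforces the census
#' protocol invariants: every alive stem must have DBH of at least 1 cm
#' (the census minimum), and, when plot metadata are supplied, coordinates
#' must lie inside `[0, x_extent] x [0, y_extent]`.
#'
#' Rows violating the DBH minimum are rejected (not an error): they are
#' dropped with a logged reason, retrievable via `attr(x, "rejected")`.
#' Out-of-bounds coordinates are treated as a data integrity failure and
#' raise an error naming the offending row(s).
#'
#' @param path Path to a delimited census file with a header row.
#' @param schema Optional named character vector overriding entries of
#'   [census_schema()], e.g. `c(species = "Latin", x = "X")`.
#' @param meta Optional one-row plot metadata (a list or data.frame with
#'   `x_extent` and `y_extent` in metres) used for coordinate validation.
#' @param dbh_min Census minimum DBH in cm for alive stems (default 1).
#' @return A data.frame of stem records with columns `tree_id`, `stem_id`,
#'   `species`, `x`, `y`, `dbh`, `status` (one of `"alive"`, `"dead"`,
#'   `"recruit"`) and, when present in the file, `date` (decimal years).
#'   Attribute `"rejected"` holds dropped rows with a `reason` column.
#' @export
read_census_table <- function(path, schema = NULL, meta = NULL, dbh_min = 1) {
  if (!file.exists(path)) stop("census file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  cols <- census_schema()
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), names(cols))
    if (length(unknown))
      stop("schema refers to unknown field(s): ", paste(unknown, collapse = ", "))
    cols[names(schema)] <- unlist(schema)
  }
  required <- cols[setdiff(names(cols), "date")]
  missing <- required[!required %in% names(raw)]
  if (length(missing))
    stop("census table is missing required column(s): ",
         paste(missing, collapse = ", "))

  out <- data.frame(
    tree_id = as.character(raw[[cols[["tree_id"]]]]),
    stem_id = as.character(raw[[cols[["stem_id"]]]]),
    species = as.character(raw[[cols[["species"]]]]),
    x = as.numeric(raw[[cols[["x"]]]]),
    y = as.numeric(raw[[cols[["y"]]]]),
    dbh = as.numeric(raw[[cols[["dbh"]]]]),
    status = .normalize_status(raw[[cols[["status"]]]]),
    stringsAsFactors = FALSE
  )
  if (cols[["date"]] %in% names(raw))
    out$date <- as.numeric(raw[[cols[["date"]]]])

  if (!is.null(meta)) {
    bad <- which(is.na(out$x) | is.na(out$y) |
                   out$x < 0 | out$x > meta$x_extent |
                   out$y < 0 | out$y > meta$y_extent)
    if (length(bad))
      stop("coordinates outside plot bounds at row(s): ",
           paste(utils::head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "")
  }

  drop <- which(out$status == "alive" & (is.na(out$dbh) | out$dbh < dbh_min))
  rejected <- out[drop, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- "dbh below census minimum"
    out <- out[-drop, , drop = FALSE]
    message(nrow(rejected), " row(s) rejected: dbh below census minimum")
  }
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a census table
#'
#' Inverse of [read_census_table()]: writes stem records under the canonical
#' column names so that a write/read round trip reproduces the records.
#'
#' @param stems Data.frame of stem records as returned by
#'   [read_census_table()] or [simulate_plot()].
#' @param path Output path; extension `.tsv` selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_census_table <- function(stems, path) {
  cols <- census_schema()
  keep <- intersect(names(cols), names(stems))
  out <- stems[, keep, drop = FALSE]
  names(out) <- cols[keep]
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plot metadata table
#'
#' One row per plot: `plot_id`, `latitude` (signed degrees), `x_extent`,
#' `y_extent` (metres) and the two census dates `date1`, `date2` in decimal
#' years. An optional `longitude` column is carried through.
#'
#' @param path Path to a delimited file (comma or tab, auto-detected).
#' @return Data.frame of validated plot metadata.
#' @export
read_plot_meta <- function(path) {
  if (!file.exists(path)) stop("plot metadata file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("plot_id", "latitude", "x_extent", "y_extent", "date1", "date2")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("plot metadata missing column(s): ", paste(missing, collapse = ", "))
  validate_plot_meta(meta)
  meta
}

validate_plot_meta <- function(meta) {
  stopifnot(all(meta$x_extent > 0), all(meta$y_extent > 0),
            all(abs(meta$latitude) <= 90),
            all(meta$date2 - meta$date1 > 0))
  invisible(meta)
}

#' Link two censuses into stem-level demographic outcomes
#'
#' Reduces multi-stem trees to their main stem (largest census-1 DBH), links
#' stems across censuses by `tree_id` + `stem_id`, and derives the two
#' demographic responses: annualized DBH growth (cm/yr) for survivors, and
#' a 0/1 survival outcome over the census interval. Every census-1 main stem
#' yields exactly one record. Stems absent from census 2, or present but
#' dead, have `survived = 0` and undefined growth. Recruits (new stems in
#' census 2) are not focal observations and are skipped; a census-2 stem
#' that is neither in census 1 nor flagged recruit raises a consistency
#' error.
#'
#' The log-linear growth model requires strictly positive growth, so
#' non-positive annualized increments are replaced by `growth_floor`
#' (default 0.01 cm/yr) when `nonpositive = "floor"`, or set to `NA`
#' (excluded from growth fits) when `nonpositive = "drop"`. The number of
#' affected stems is reported via attribute `"n_floored"`.
#'
#' @param census1,census2 Stem record data.frames (see
#'   [read_census_table()]).
#' @param meta One-row plot metadata with `date1`, `date2` (decimal years).
#' @param growth_floor Replacement annual increment in cm/yr for
#'   non-positive growth (default 0.01).
#' @param nonpositive Policy for non-positive increments: `"floor"`
#'   (default) or `"drop"`.
#' @return Data.frame with one row per census-1 main stem: `tree_id`,
#'   `stem_id`, `species`, `x`, `y`, `dbh0`, `dbh1`, `growth`, `survived`,
#'   `dt`.
#' @export
link_censuses <- function(census1, census2, meta, growth_floor = 0.01,
                          nonpositive = c("floor", "drop")) {
  nonpositive <- match.arg(nonpositive)
  dt <- meta$date2 - meta$date1
  stopifnot(dt > 0)

  c1 <- census1[census1$status != "dead", , drop = FALSE]
  # main stem: largest census-1 DBH per tree, ties broken by stem_id order
  ord <- order(c1$tree_id, -c1$dbh, c1$stem_id)
  c1 <- c1[ord, , drop = FALSE]
  main <- c1[!duplicated(c1$tree_id), , drop = FALSE]

  key1_all <- paste(census1$tree_id, census1$stem_id, sep = "\r")
  key2 <- paste(census2$tree_id, census2$stem_id, sep = "\r")
  orphan <- !(key2 %in% key1_all) & census2$status != "recruit"
  if (any(orphan))
    stop("census 2 contains ", sum(orphan),
         " stem(s) absent from census 1 and not flagged as recruits, e.g. ",
         paste(utils::head(census2$stem_id[orphan], 5), collapse = ", "))

  keym <- paste(main$tree_id, main$stem_id, sep = "\r")
  idx2 <- match(keym, key2)
  status2 <- ifelse(is.na(idx2), "dead", census2$status[idx2])
  survived <- as.integer(status2 == "alive")
  dbh1 <- ifelse(survived == 1L, census2$dbh[idx2], NA_real_)

  growth <- rep(NA_real_, nrow(main))
  live <- survived == 1L
  growth[live] <- (dbh1[live] - main$dbh[live]) / dt
  nonpos <- which(live & growth <= 0)
  if (length(nonpos)) {
    if (nonpositive == "floor") growth[nonpos] <- growth_floor
    else growth[nonpos] <- NA_real_
    message(length(nonpos), " non-positive increment(s) ",
            if (nonpositive == "floor") paste0("floored at ", growth_floor, " cm/yr")
            else "dropped")
  }

  out <- data.frame(
    tree_id = main$tree_id, stem_id = main$stem_id, species = main$species,
    x = main$x, y = main$y, dbh0 = main$dbh, dbh1 = dbh1,
    growth = growth, survived = survived, dt = dt,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_floored") <- length(nonpos)
  out
}

#' Species eligibility filters for demographic model fitting
#'
#' A species enters the growth analysis only when it has more than
#' `min_trees` linked trees in the plot (strictly greater than 100 by
#' default); for survival it must additionally have at least `min_survivors`
#' surviving and `min_dead` dead trees, so that the logistic fit has
#' information in both outcome classes.
#'
#' @param dyn Linked stem dynamics from [link_censuses()].
#' @param response `"growth"` or `"survival"`.
#' @param min_trees Minimum tree count; a species qualifies with
#'   `n > min_trees`.
#' @param min_survivors,min_dead Additional survival-model minima
#'   (`n >= 20` each by default).
#' @return Character vector of eligible species codes (possibly empty).
#' @export
apply_species_filters <- function(dyn, response = c("growth", "survival"),
                                  min_trees = 100, min_survivors = 20,
                                  min_dead = 20) {
  response <- match.arg(response)
  if (nrow(dyn) == 0) return(character(0))
  n <- table(dyn$species)
  ok <- names(n)[n > min_trees]
  if (response == "survival") {
    surv <- tapply(dyn$survived, dyn$species, sum)
    dead <- tapply(1L - dyn$survived, dyn$species, sum)
    ok <- ok[surv[ok] >= min_survivors & dead[ok] >= min_dead]
  }
  sort(unname(ok))
}
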