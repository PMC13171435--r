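make_census_file <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

basic_census <- function() {
  data.frame(treeID = c("t1", "t2", "t3"), stemID = c("s1", "s2", "s3"),
             sp = c("a", "a", "b"), gx = c(1, 2, 3), gy = c(4, 5, 6),
             dbh = c(10, 12, 5), status = c("alive", "alive", "alive"))
}

test_that("well-formed tables parse to one record per row", {
  path <- make_census_file(basic_census())
  rec <- read_census_table(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$species, c("a", "a", "b"))
  expect_equal(rec$dbh, c(10, 12, 5))
  expect_equal(rec$status, rep("alive", 3))
})

test_that("schema remapping and missing columns are handled", {
  df <- basic_census()
  names(df)[names(df) == "sp"] <- "Latin"
  path <- make_census_file(df)
  expect_error(read_census_table(path), "missing required column")
  rec <- read_census_table(path, schema = c(species = "Latin"))
  expect_equal(rec$species, c("a", "a", "b"))
})

test_that("alive stems below the 1 cm census minimum are rejected with a reason", {
  df <- basic_census()
  df$dbh[2] <- 0.5
  path <- make_census_file(df)
  expect_message(rec <- read_census_table(path), "dbh below census minimum")
  expect_equal(nrow(rec), 2)
  rej <- attr(rec, "rejected")
  expect_equal(rej$tree_id, "t2")
  expect_equal(rej$reason, "dbh below census minimum")
  # dead stems are exempt from the alive-stem minimum
  df2 <- basic_census()
  df2$status[2] <- "dead"
  df2$dbh[2] <- 0.5
  rec2 <- read_census_table(make_census_file(df2))
  expect_equal(nrow(rec2), 3)
})

test_that("out-of-bounds coordinates raise an error naming the row", {
  df <- basic_census()
  df$gx[3] <- 101
  path <- make_census_file(df)
  meta <- list(x_extent = 100, y_extent = 100)
  expect_error(read_census_table(path, meta = meta), "row\\(s\\): 3")
  expect_silent(read_census_table(make_census_file(basic_census()),
                                  meta = meta))
})

test_that("write/read round trip preserves all declared columns", {
  st <- random_stems(40, n_species = 3, seed = 5)
  st$status <- sample(c("alive", "dead"), 40, replace = TRUE)
  st$tree_id <- sprintf("t%03d", 1:40)
  path <- tempfile(fileext = ".csv")
  write_census_table(st, path)
  back <- read_census_table(path)
  for (col in c("tree_id", "stem_id", "species", "status"))
    expect_identical(back[[col]], st[[col]])
  for (col in c("x", "y", "dbh"))
    expect_equal(back[[col]], st[[col]], tolerance = 1e-12)
})

meta1 <- data.frame(plot_id = "p", latitude = 10, x_extent = 100,
                    y_extent = 100, date1 = 2000, date2 = 2005)

test_that("census linking computes annualized growth and survival", {
  c1 <- data.frame(tree_id = c("t1", "t2", "t3"), stem_id = c("s1", "s2", "s3"),
                   species = "a", x = 1:3, y = 1:3, dbh = c(10, 10, 10),
                   status = "alive", stringsAsFactors = FALSE)
  c2 <- c1
  c2$dbh <- c(15, 10, 9)
  c2$status <- c("alive", "dead", "alive")
  dyn <- link_censuses(c1, c2, meta1)
  expect_equal(dyn$growth[1], 1.0)            # (15-10)/5
  expect_equal(dyn$survived, c(1L, 0L, 1L))
  expect_true(is.na(dyn$growth[2]))           # dead: growth undefined
  expect_equal(dyn$growth[3], 0.01)           # shrinkage floored
  expect_equal(dyn$dt, rep(5, 3))
  # drop policy instead of floor
  dyn2 <- suppressMessages(link_censuses(c1, c2, meta1, nonpositive = "drop"))
  expect_true(is.na(dyn2$growth[3]))
  expect_equal(dyn2$survived[3], 1L)
})

test_that("stems absent from census 2 count as dead", {
  c1 <- data.frame(tree_id = c("t1", "t2"), stem_id = c("s1", "s2"),
                   species = "a", x = 1:2, y = 1:2, dbh = 10,
                   status = "alive", stringsAsFactors = FALSE)
  c2 <- c1[1, ]
  c2$dbh <- 12
  dyn <- link_censuses(c1, c2, meta1)
  expect_equal(dyn$survived, c(1L, 0L))
})

test_that("multi-stem trees reduce to the largest census-1 stem", {
  c1 <- data.frame(tree_id = c("t1", "t1", "t2"), stem_id = c("s1", "s2", "s3"),
                   species = "a", x = 1:3, y = 1:3, dbh = c(8, 20, 5),
                   status = "alive", stringsAsFactors = FALSE)
  c2 <- c1
  c2$dbh <- c(9, 25, 6)
  dyn <- link_censuses(c1, c2, meta1)
  expect_equal(nrow(dyn), 2)              # one record per tree
  expect_equal(dyn$dbh0[dyn$tree_id == "t1"], 20)
  expect_equal(dyn$growth[dyn$tree_id == "t1"], 1.0)
})

test_that("linking partitions census-1 main stems and flags orphans", {
  st <- random_stems(60, n_species = 3, seed = 9, extent = 100)
  c1 <- data.frame(tree_id = st$stem_id, stem_id = st$stem_id,
                   species = st$species, x = st$x, y = st$y, dbh = st$dbh,
                   status = "alive", stringsAsFactors = FALSE)
  set.seed(10)
  keep <- runif(60) < 0.8
  c2 <- c1[keep, ]
  c2$status <- ifelse(runif(nrow(c2)) < 0.9, "alive", "dead")
  c2$dbh <- c2$dbh + 2
  dyn <- suppressMessages(link_censuses(c1, c2, meta1))
  expect_equal(sort(dyn$tree_id), sort(c1$tree_id))  # exact partition
  expect_equal(anyDuplicated(dyn$tree_id), 0)
  # recruits are tolerated, unflagged newcomers are not
  recruit <- data.frame(tree_id = "new1", stem_id = "new1", species = "a",
                        x = 1, y = 1, dbh = 2, status = "recruit",
                        stringsAsFactors = FALSE)
  expect_silent(suppressMessages(link_censuses(c1, rbind(c2, recruit), meta1)))
  orphan <- recruit
  orphan$status <- "alive"
  expect_error(link_censuses(c1, rbind(c2, orphan), meta1),
               "not flagged as recruits")
})

test_that("species filters apply the >100 trees and 20/20 outcome rules", {
  mk <- function(sp, n, n_dead) data.frame(
    species = sp, survived = rep(c(0L, 1L), c(n_dead, n - n_dead)))
  dyn <- rbind(mk("a", 100, 30), mk("b", 101, 30), mk("c", 150, 15),
               mk("d", 200, 185))
  expect_equal(apply_species_filters(dyn, "growth"), c("b", "c", "d"))
  # c: only 15 dead; d: only 15 survivors -> both fail the survival filter
  expect_equal(apply_species_filters(dyn, "survival"), "b")
  expect_equal(apply_species_filters(dyn[0, ], "growth"), character(0))
})

test_that("adding trees never removes a species from the growth-eligible set", {
  set.seed(3)
  dyn <- data.frame(species = sample(letters[1:4], 500, replace = TRUE),
                    survived = rbinom(500, 1, 0.8))
  before <- apply_species_filters(dyn, "growth")
  extra <- data.frame(species = sample(letters[1:6], 200, replace = TRUE),
                      survived = rbinom(200, 1, 0.8))
  after <- apply_species_filters(rbind(dyn, extra), "growth")
  expect_true(all(before %in% after))
})
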