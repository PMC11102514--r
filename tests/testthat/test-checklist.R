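# Checklist pool: validation, CSV I/O, synthetic generation, calibration.

test_that("pool validation enforces the score invariants", {
  p <- dbi_pool("Aeshna alpha", dbi = 9, dbi_d = 3, dbi_t = 3, dbi_s = 3)
  expect_s3_class(p, "dbi_pool")
  expect_true(has_subindices(p))

  # total must equal the subindex sum, naming the offender
  expect_error(
    dbi_pool(c("good sp", "bad sp"), dbi = c(6, 9),
             dbi_d = c(2, 3), dbi_t = c(2, 3), dbi_s = c(2, 2)),
    "bad sp"
  )
  expect_error(dbi_pool("x", dbi = 10), "0\\.\\.9")
  expect_error(dbi_pool("x", dbi = 5, dbi_d = 4, dbi_t = 1, dbi_s = 0), "0\\.\\.3")
  # duplicates are detected case/whitespace-insensitively
  expect_error(dbi_pool(c("Aeshna  alpha", "aeshna alpha"), dbi = c(1, 1)),
               "duplicate")
  expect_error(dbi_pool(character(0), dbi = integer(0)), "at least one")
  # a total-only pool is fine
  expect_false(has_subindices(make_pool(c(0, 9))))
})

test_that("read_checklist excludes unscored rows and reports them", {
  # 73 rows, 5 with blank scores -> pool of 68 with 5 exclusions
  df <- data.frame(
    species = sprintf("species %02d", 1:73),
    dbi = c(rep(0:9, length.out = 68), rep(NA, 5))
  )
  path <- write_checklist_csv(df)
  expect_message(pool <- read_checklist(path), "5 species without")
  expect_equal(nrow(pool), 68)
  expect_equal(attr(pool, "n_excluded"), 5)
  expect_equal(attr(pool, "excluded"), sprintf("species %02d", 69:73))

  # single minimal species
  p1 <- read_checklist(write_checklist_csv(
    data.frame(species = "only sp", dbi_d = 0, dbi_t = 0, dbi_s = 0, dbi = 0)))
  expect_equal(nrow(p1), 1)
  expect_equal(p1$dbi, 0L)

  # inconsistent total vs subindices names the species
  bad <- write_checklist_csv(data.frame(
    species = c("ok sp", "liar sp"),
    dbi_d = c(1, 3), dbi_t = c(1, 3), dbi_s = c(1, 2), dbi = c(3, 9)))
  expect_error(read_checklist(bad), "liar sp")

  # duplicate names rejected
  dup <- write_checklist_csv(data.frame(species = c("a sp", "A  sp"), dbi = c(1, 2)))
  expect_error(read_checklist(dup), "duplicate")

  expect_error(suppressWarnings(read_checklist(tempfile(fileext = ".csv"))),
               "malformed|cannot")
})

test_that("checklists round-trip through CSV", {
  pool <- synthetic_pool(25, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_checklist(pool, path)
  back <- read_checklist(path, region_label = attr(pool, "region_label"))
  expect_equal(as.data.frame(back), as.data.frame(pool), ignore_attr = TRUE)
  expect_identical(back$species, pool$species)
  expect_identical(attr(back, "region_label"), attr(pool, "region_label"))

  # totals-only pools round-trip too
  p2 <- make_pool(c(3, 7, 0))
  write_checklist(p2, path)
  expect_equal(read_checklist(path)$dbi, p2$dbi)
})

test_that("synthetic pools cover all scores with geometrically decaying counts", {
  pool <- synthetic_pool(68, seed = 1)
  expect_equal(nrow(pool), 68)
  counts <- table(factor(pool$dbi, levels = 0:9))
  expect_true(all(counts >= 1))
  expect_gt(counts[["0"]], counts[["9"]])
  # counts per value non-increasing for decay > 1
  expect_true(all(diff(as.integer(counts)) <= 0))
  # subindices are a valid composition of the total
  expect_true(all(pool$dbi_d + pool$dbi_t + pool$dbi_s == pool$dbi))

  # n = 10: pigeonhole forces exactly one species per value
  p10 <- synthetic_pool(10, seed = 4)
  expect_equal(sort(p10$dbi), 0:9)

  # determinism
  expect_identical(synthetic_pool(40, seed = 2, decay = 3),
                   synthetic_pool(40, seed = 2, decay = 3))
  expect_error(synthetic_pool(9, seed = 1), ">= 10")

  # target proportions are exactly geometric, monotone for decay > 1
  pr <- synthetic_pool_proportions(2)
  expect_equal(unname(pr / pr[1]), 2^-(0:9))
  expect_true(all(diff(pr) < 0))
})

test_that("occupancy calibration recovers the weight base", {
  # class means near a halving per step recommend x = 2
  cal <- calibrate_weight_base(c(0.80, 0.38, 0.18))
  expect_equal(cal$x, 2L)
  expect_equal(unname(cal$ratios), c(0.38 / 0.80, 0.18 / 0.38))

  # exact quartering recommends x = 4
  cal4 <- calibrate_weight_base(c(1, 0.25, 0.0625))
  expect_equal(cal4$x, 4L)
  expect_equal(cal4$x_raw, 4)

  # uniform occupancy -> all ratios 1, x = 1
  occ <- data.frame(species = sprintf("s%d", 1:8),
                    quadrats = rep(50L, 8),
                    dbi_d = rep(0:3, 2))
  cal1 <- calibrate_weight_base(occ)
  expect_equal(unname(cal1$class_means), c(1, 1, 1))
  expect_equal(cal1$x, 1L)

  # from a full table: rates are relative to the most common species,
  # class 3 never enters the means
  occ2 <- data.frame(
    species = sprintf("s%d", 1:6),
    quadrats = c(100L, 60L, 38L, 38L, 18L, 90L),
    dbi_d = c(0L, 0L, 1L, 1L, 2L, 3L))
  cal2 <- calibrate_weight_base(occ2)
  expect_equal(unname(cal2$class_means), c(0.80, 0.38, 0.18))
  expect_equal(cal2$x, 2L)

  # errors: missing class, all-zero counts
  expect_error(calibrate_weight_base(
    data.frame(species = c("a", "b"), quadrats = c(5L, 3L), dbi_d = c(0L, 1L))),
    "class 2")
  expect_error(calibrate_weight_base(
    data.frame(species = c("a", "b", "c"), quadrats = c(0L, 0L, 0L),
               dbi_d = c(0L, 1L, 2L))),
    "positive")
})

test_that("occupancy CSV reader validates its columns", {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(species = c("a", "b", "c"),
                              quadrats = c(10L, 5L, 2L),
                              dbi_d = c(0L, 1L, 2L)),
                   path, row.names = FALSE)
  occ <- read_occupancy(path)
  expect_equal(names(occ), c("species", "quadrats", "dbi_d"))
  expect_equal(calibrate_weight_base(occ)$class_means,
               c(`0` = 1, `1` = 0.5, `2` = 0.2))
  utils::write.csv(data.frame(species = "a", n = 1), path, row.names = FALSE)
  expect_error(read_occupancy(path), "columns")
})
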