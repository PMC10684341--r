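test_that("record filter applies year and decimal-precision rules inclusively", {
  recs <- data.frame(
    species = "a",
    lat = c(40.123, 40.1, 40.10, 40.12),
    lon = c(-75.10, -75.123, -75.10, -75.12),
    year = c(1989, 2000, 1990, 2022),
    lat_text = c("40.123", "40.1", "40.10", "40.12"),
    lon_text = c("-75.10", "-75.123", "-75.10", "-75.12")
  )
  kept <- filter_records(recs)
  expect_equal(nrow(kept), 2)                 # 1989 dropped; 1-decimal lat dropped
  expect_equal(kept$year, c(1990, 2022))      # inclusive bounds
  cnt <- attr(kept, "filter_counts")
  expect_equal(unname(cnt["input"]), 4)
  expect_equal(unname(cnt["retained"]), 2)
})

test_that("decimal precision falls back to numeric rendering without coord text", {
  recs <- data.frame(species = "a", lat = c(40.12, 40.1), lon = c(-75.25, -75.25),
                     year = c(2000, 2000))
  expect_equal(nrow(filter_records(recs)), 1)   # 40.1 renders with one decimal
  expect_error(filter_records(data.frame(species = "a", lat = 95, lon = 0,
                                         year = 2000)), "latitude")
})

test_that("minimum-record filter is inclusive at the threshold", {
  m <- rbind(a = c(10, 20, 19), b = c(25, 25, 0), c = c(1, 1, 1))
  colnames(m) <- c("natural", "agricultural", "urban")
  out <- apply_min_records(m, 50)
  expect_equal(rownames(out), "b")              # 49 dropped, 50 kept
  expect_error(apply_min_records(m, 1000), "no species")
})

test_that("habitat assignment uses closed-lower open-upper cells", {
  g <- toy_grid()
  recs <- data.frame(species = "a",
                     lat = c(0.5, 0.5, 1.0, 0.5, 3.0),
                     lon = c(0.5, 2.5, 1.0, 1.0, 1.0),   # last is on the open top edge
                     year = 2000)
  lab <- assign_habitat(recs, g)
  expect_equal(nrow(lab), 4)
  expect_equal(attr(lab, "dropped_outside"), 1)
  expect_equal(lab$habitat, c("natural", "urban", "agricultural", "agricultural"))
  # boundary points resolve identically across runs
  expect_equal(assign_habitat(recs, g)$habitat, lab$habitat)
  expect_error(assign_habitat(recs, g, strict = TRUE), "outside")

  all_nat <- habitat_grid(matrix("natural", 2, 2), bbox = c(0, 2, 0, 2))
  recs2 <- data.frame(species = "a", lat = runif(20, 0, 2), lon = runif(20, 0, 2),
                      year = 2000)
  expect_true(all(assign_habitat(recs2, all_nat)$habitat == "natural"))
})

test_that("occurrence matrix counts records per species and habitat", {
  recs <- data.frame(species = c("A", "A", "A", "B"),
                     habitat = c("urban", "urban", "urban", "natural"))
  m <- build_matrix(recs)
  expect_equal(unname(m["A", ]), c(0, 0, 3))
  expect_equal(colnames(m), c("natural", "agricultural", "urban"))
  expect_equal(build_matrix(recs[sample(4), ]), m)   # order invariance
})

test_that("Patefield draws preserve margins exactly, degenerate margins are unique", {
  one <- patefield_sample(3, c(1, 2), n = 10, seed = 1)
  for (tab in one) expect_equal(unname(tab), matrix(c(1, 2), 1))

  expect_error(patefield_sample(c(2, 2), c(1, 1), seed = 1), "differ")
  expect_error(patefield_sample(c(-1, 2), c(1, 0), seed = 1), "negative")

  set.seed(123)
  for (k in 1:50) {
    mg <- random_margins(sample(2:6, 1), sample(2:4, 1), sample(10:200, 1))
    draws <- patefield_sample(mg$r, mg$c, n = 20)
    for (tab in draws) {
      expect_equal(rowSums(tab), mg$r)
      expect_equal(colSums(tab), mg$c)
    }
  }
})

test_that("percentiles: degenerate null, reproducibility, bounds, tie policy", {
  m1 <- matrix(c(3, 5, 2), 1, dimnames = list("only", c("natural", "agricultural", "urban")))
  r <- occupancy_percentiles(m1, n_sim = 200, seed = 9)
  expect_true(all(r$percentile == 0))          # every simulated matrix is the observed one
  expect_true(all(r$class == "low"))
  # with half-tie credit the degenerate cells sit at 50
  rh <- occupancy_percentiles(m1, n_sim = 200, seed = 9, ties = "half")
  expect_true(all(rh$percentile == 50))

  m <- rbind(a = c(30, 10, 60), b = c(50, 40, 10), c = c(20, 50, 30))
  colnames(m) <- c("natural", "agricultural", "urban")
  r1 <- occupancy_percentiles(m, n_sim = 500, seed = 4)
  r2 <- occupancy_percentiles(m, n_sim = 500, seed = 4)
  expect_identical(r1, r2)
  expect_true(all(r1$percentile >= 0 & r1$percentile <= 100))
  expect_true(all(table(r1$species) == 3))      # one class per cell
})

test_that("permuting habitat columns permutes percentiles identically", {
  m <- rbind(a = c(30, 10, 60), b = c(50, 40, 10), c = c(20, 50, 30))
  colnames(m) <- c("natural", "agricultural", "urban")
  perm <- c(3, 1, 2)
  r <- occupancy_percentiles(m, n_sim = 400, seed = 6)
  rp <- occupancy_percentiles(m[, perm], n_sim = 400, seed = 6)
  for (h in colnames(m)) {
    expect_equal(rp$percentile[rp$habitat == h][order(rp$species[rp$habitat == h])],
                 r$percentile[r$habitat == h][order(r$species[r$habitat == h])])
  }
})

test_that("classification thresholds are strict at both boundaries", {
  expect_equal(classify_occupancy(85), "high")
  expect_equal(classify_occupancy(80), "intermediate")
  expect_equal(classify_occupancy(20), "intermediate")
  expect_equal(classify_occupancy(19.9), "low")
  expect_equal(classify_occupancy(c(0, 100)), c("low", "high"))
  expect_error(classify_occupancy(50, high = 20, low = 80), "thresholds")
})

test_that("grid and records round-trip through their plain-text formats", {
  g <- toy_grid()
  dir <- withr::local_tempdir()
  write_grid(g, file.path(dir, "grid.txt"), file.path(dir, "reclass.csv"))
  g2 <- read_grid(file.path(dir, "grid.txt"), file.path(dir, "reclass.csv"))
  expect_equal(g2$classes, g$classes)
  expect_equal(g2$bbox, g$bbox)

  writeLines(c("species,decimalLatitude,decimalLongitude,year",
               "Apis mellifera,40.10,-75.25,2001"),
             file.path(dir, "recs.csv"))
  recs <- read_records_csv(file.path(dir, "recs.csv"))
  expect_equal(recs$lat, 40.10)
  expect_equal(recs$lat_text, "40.10")
  expect_equal(nrow(filter_records(recs)), 1)   # trailing zero visible in text
})
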