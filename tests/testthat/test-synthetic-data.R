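test_that("tree simulation is ultrametric and deterministic per seed", {
  t2 <- simulate_tree(2, seed = 1)
  V2 <- phylo_covariance(t2)
  expect_equal(V2[1, 1], V2[2, 2])             # cherry: equal root-to-tip depths

  expect_identical(write_newick(simulate_tree(20, seed = 5)),
                   write_newick(simulate_tree(20, seed = 5)))
  expect_false(identical(write_newick(simulate_tree(20, seed = 5)),
                         write_newick(simulate_tree(20, seed = 6))))

  depths <- replicate(50, max(diag(phylo_covariance(
    simulate_tree(20, seed = sample.int(1e6, 1))))))
  expect_true(all(is.finite(depths)) && all(depths > 0))
  expect_error(simulate_tree(10, birth = 1, death = 2, seed = 1), "rates")
})

test_that("noise-free allometric traits sit exactly on the line", {
  tr <- simulate_tree(30, seed = 3)
  cfg <- scenario_config(n_species = 30, sigma_resid = 0, seed = 3)
  sp <- simulate_allometric_traits(tr, cfg, seed = 3)
  tru <- attr(sp, "truth")
  expect_equal(tru$residual, rep(0, 30))
  fit <- pgls_fit(log_brain ~ log_body, species_means(sp), phylo_covariance(tr))
  expect_equal(unname(residuals(fit)), rep(0, 30), tolerance = 1e-8)
  expect_equal(unname(coef(fit)), c(cfg$intercept, cfg$slope), tolerance = 1e-8)
})

test_that("distinct lambda_true regimes are discriminable from the residuals", {
  lam_hat <- function(lambda_true, seed) {
    tr <- simulate_tree(100, seed = seed)
    cfg <- scenario_config(n_species = 100, lambda_true = lambda_true, seed = seed)
    sp <- simulate_allometric_traits(tr, cfg, seed = seed)
    fit <- pgls_fit(log_brain ~ log_body, species_means(sp), phylo_covariance(tr))
    fit$lambda
  }
  seeds <- 1:15
  hi <- vapply(seeds, function(s) lam_hat(1, s), 0)
  lo <- vapply(seeds, function(s) lam_hat(0, s), 0)
  expect_gte(mean(hi) - mean(lo), 0.6)
})

test_that("occurrence simulation honours the habitat mixture when uncoupled", {
  tr <- simulate_tree(40, seed = 12)
  cfg <- scenario_config(n_species = 40, gamma = 0, affinity_sd = 0,
                         records_mean = 2500, seed = 12)
  g <- simulate_grid(cfg, seed = 12)
  recs <- simulate_occurrence_records(tr$tip.label, rep(0, 40), g, cfg, seed = 12)
  shares <- prop.table(table(factor(recs$habitat_true,
                                    c("natural", "agricultural", "urban"))))
  expect_gt(nrow(recs), 1e5 * 0.9)
  expect_true(all(abs(shares - cfg$class_mixture) < 0.01))
})

test_that("a huge urban coupling saturates the urban share", {
  tr <- simulate_tree(10, seed = 13)
  cfg <- scenario_config(n_species = 10, gamma = 10, affinity_sd = 0, seed = 13)
  g <- simulate_grid(cfg, seed = 13)
  res <- rep(1, 10)     # strongly positive residuals
  recs <- simulate_occurrence_records(tr$tip.label, res, g, cfg, seed = 13)
  expect_gt(mean(recs$habitat_true == "urban"), 0.95)
})

test_that("record simulation is byte-identical per seed and filter-clean", {
  cfg <- scenario_config(n_species = 25, seed = 77)
  b1 <- make_scenario(cfg)
  b2 <- make_scenario(cfg)
  expect_identical(b1$records, b2$records)
  expect_false(identical(b1$records,
                         make_scenario(scenario_config(n_species = 25, seed = 78))$records))

  # generated records pass the year/decimal filters by construction
  kept <- filter_records(b1$records)
  expect_equal(nrow(kept), nrow(b1$records))
  # every record's species is a tree tip, min-records clamp holds
  expect_true(all(b1$records$species %in% b1$tree$tip.label))
  expect_true(all(table(b1$records$species) >= cfg$min_records))
})

test_that("scenario bundle and truth round-trip through disk", {
  dir <- withr::local_tempdir()
  cfg <- scenario_config(n_species = 12, seed = 5)
  b <- make_scenario(cfg, dir = dir)
  expect_true(all(file.exists(file.path(dir, readLines(file.path(dir, "MANIFEST"))))))

  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(unlist(truth$residuals), unlist(b$truth$residuals), tolerance = 1e-12)
  expect_equal(truth$config$gamma, b$config$gamma)

  tr2 <- read_newick(file = file.path(dir, "tree.nwk"))
  expect_setequal(tr2$tip.label, b$tree$tip.label)
  recs2 <- read_records_csv(file.path(dir, "records.csv"))
  expect_equal(nrow(recs2), nrow(b$records))
})
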