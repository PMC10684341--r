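test_that("species means average on the natural-log scale", {
  sp <- data.frame(species = c("a", "a", "b", "c", "c"),
                   brain_mg = c(exp(1), exp(1), 5, 1, exp(2)),
                   itd_mm = c(2, 4, 3, 1, 1))
  m <- species_means(sp)
  expect_equal(m$log_brain[m$species == "a"], 1)            # ln e = 1
  expect_equal(m$log_brain[m$species == "b"], log(5))       # single specimen
  expect_equal(m$log_brain[m$species == "c"], 1)            # mean of 0 and 2
  expect_equal(m$n_specimens, c(2L, 1L, 2L))
  expect_error(species_means(transform(sp, brain_mg = c(1, -1, 1, 1, 1))),
               "nonpositive")
})

test_that("species means carry region, 'both' when regions mix", {
  sp <- data.frame(species = c("a", "a", "b"), brain_mg = 1:3, itd_mm = 1:3,
                   region = c("US", "EU", "US"))
  m <- species_means(sp)
  expect_equal(m$region, c("both", "US"))
})

make_traits <- function(tree, slope = 2.5, intercept = -2, sd = 0.3, seed = 1) {
  set.seed(seed)
  d <- data.frame(species = tree$tip.label, log_body = rnorm(length(tree$tip.label)))
  d$log_brain <- intercept + slope * d$log_body + rnorm(nrow(d), sd = sd)
  d
}

test_that("PGLS on a star tree reproduces closed-form OLS", {
  star <- ape::stree(40, "star")
  star$edge.length <- rep(1, 40)
  star$tip.label <- sprintf("s%02d", 1:40)
  d <- make_traits(star, seed = 11)
  fit <- pgls_fit(log_brain ~ log_body, d, phylo_covariance(star))
  ols <- ols_oracle(d$log_brain, d$log_body)
  expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-8)
  expect_equal(unname(residuals(fit)),
               d$log_brain - ols[1] - ols[2] * d$log_body, tolerance = 1e-8)
})

test_that("PGLS with identity covariance reproduces OLS, and GLS normal equations hold", {
  set.seed(3)
  n <- 30
  V <- diag(n)
  dimnames(V) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  d <- data.frame(species = rownames(V), log_body = rnorm(n))
  d$log_brain <- 1 + 0.8 * d$log_body + rnorm(n, sd = 0.2)
  fit <- pgls_fit(log_brain ~ log_body, d, V)
  lmfit <- lm(log_brain ~ log_body, d)
  expect_equal(unname(coef(fit)), unname(coef(lmfit)), tolerance = 1e-8)

  # orthogonality of transformed residuals to the transformed design
  tr <- simulate_tree(40, seed = 4)
  d2 <- make_traits(tr, seed = 5)
  V2 <- phylo_covariance(tr)
  f2 <- pgls_fit(log_brain ~ log_body, d2, V2)
  W <- lambda_transform(V2, f2$lambda)
  e <- residuals(f2)[rownames(W)]
  Winv_e <- solve(W, e)
  x <- d2$log_body[match(rownames(W), d2$species)]
  expect_lt(abs(sum(Winv_e)), 1e-6)
  expect_lt(abs(sum(x * Winv_e)), 1e-6)
})

test_that("profiled lambda beats a fine grid and r2 behaves", {
  tr <- simulate_tree(60, seed = 9)
  cfg <- scenario_config(n_species = 60, lambda_true = 0.7, seed = 9)
  sp <- simulate_allometric_traits(tr, cfg, seed = 9)
  d <- species_means(sp)
  V <- phylo_covariance(tr)
  fit <- pgls_fit(log_brain ~ log_body, d, V)

  X <- cbind(1, d$log_body[match(rownames(V), d$species)])
  y <- d$log_brain[match(rownames(V), d$species)]
  grid_ll <- vapply(seq(0, 1, length.out = 101),
                    function(l) beehab:::gls_profile(y, X, V, l)$loglik, 0)
  expect_gte(fit$loglik, max(grid_ll) - 1e-6)

  expect_gte(fit$loglik, beehab:::gls_profile(y, X, V, 0)$loglik)
  expect_gte(fit$loglik, beehab:::gls_profile(y, X, V, 1)$loglik)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1)

  # noise-free data sit exactly on the line: residuals 0, r2 = 1
  d0 <- d
  d0$log_brain <- -2.75 + 2.5 * d0$log_body
  f0 <- pgls_fit(log_brain ~ log_body, d0, V)
  expect_equal(unname(residuals(f0)), rep(0, nrow(d0)), tolerance = 1e-8)
  expect_equal(f0$r2, 1, tolerance = 1e-8)
})

test_that("relative brain size scores are regression residuals with stable ranks", {
  tr <- simulate_tree(30, seed = 2)
  d <- make_traits(tr, seed = 2)
  V <- phylo_covariance(tr)
  fit <- pgls_fit(log_brain ~ log_body, d, V)
  rbs <- relative_brain_size(fit)
  expect_equal(rbs$residual, unname(residuals(fit)))
  expect_equal(rbs$species[rbs$rank == 1],
               names(which.max(residuals(fit))))

  # shifting every log_brain by a constant moves only the intercept
  d2 <- d
  d2$log_brain <- d$log_brain + 3
  fit2 <- pgls_fit(log_brain ~ log_body, d2, V)
  expect_equal(residuals(fit2), residuals(fit), tolerance = 1e-8)
  expect_equal(unname(coef(fit2)[1] - coef(fit)[1]), 3, tolerance = 1e-8)

  # permuting row order leaves per-species scores unchanged
  perm <- sample(nrow(d))
  fit3 <- pgls_fit(log_brain ~ log_body, d[perm, ], V)
  expect_equal(residuals(fit3)[names(residuals(fit))], residuals(fit),
               tolerance = 1e-8)
})

test_that("PGLS rejects degenerate inputs", {
  tr <- simulate_tree(10, seed = 1)
  V <- phylo_covariance(tr)
  d <- data.frame(species = tr$tip.label, log_body = rep(1, 10),
                  log_brain = rnorm(10))
  expect_error(pgls_fit(log_brain ~ log_body, d, V), "singular")
  expect_error(pgls_fit(log_brain ~ log_body,
                        data.frame(species = c("w", "x", "y", "z"),
                                   log_body = 1:4, log_brain = 1:4), V),
               "absent")
})
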