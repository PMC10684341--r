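#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator with defaults chosen to emulate the
#' structure of a bee comparative dataset: a birth-death phylogeny,
#' log-log brain-body allometry with phylogenetically structured residuals,
#' overdispersed (negative-binomial) occurrence counts per species, and a
#' habitat grid dominated by natural cover with a smaller urban fraction.
#'
#' @param n_species number of species (>= 4).
#' @param birth,death birth-death rates of the tree simulation (death = 0
#'   gives a Yule tree).
#' @param intercept,slope allometric intercept and exponent on the natural-log
#'   scale (brain mass mg vs intertegular span mm).
#' @param lambda_true Pagel's lambda of the allometric residuals.
#' @param sigma_resid marginal SD of the residuals (log scale).
#' @param mean_log_body,sigma_body Brownian root value and marginal SD of log
#'   body size.
#' @param gamma coupling of the allometric residual to the *urban* log-odds of
#'   an occurrence (0 = no brain-habitat association).
#' @param affinity_sd SD of the species-specific latent habitat affinities:
#'   each species x habitat log-odds gets an independent normal deviation, so
#'   occupancy varies across species for reasons unrelated to brain size (as
#'   it does in real occurrence data) and the residual coupling is a
#'   weak-to-moderate effect rather than a deterministic rule.
#' @param records_mean,records_dispersion negative-binomial mean and size of
#'   the per-species record count.
#' @param enforce_min_records logical; clamp counts up to `min_records` so the
#'   downstream filter keeps every species.
#' @param min_records the clamp (and downstream filter) threshold.
#' @param grid_rows,grid_cols,class_mixture habitat-grid dimensions and the
#'   natural/agricultural/urban cell-class proportions (sum to 1).
#' @param bbox grid bounding box `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param year_range inclusive year range of simulated records.
#' @param coord_decimals decimals printed on simulated coordinates.
#' @param seed master seed (mandatory; all stages derive sub-streams from it).
#' @return a list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_species = 150, birth = 1, death = 0,
                            intercept = -2.75, slope = 2.5,
                            lambda_true = 0.6, sigma_resid = 0.25,
                            mean_log_body = log(2.5), sigma_body = 0.35,
                            gamma = 1.5, affinity_sd = 1,
                            records_mean = 200, records_dispersion = 5,
                            enforce_min_records = TRUE, min_records = 50,
                            grid_rows = 20, grid_cols = 20,
                            class_mixture = c(natural = 0.5,
                                              agricultural = 0.3,
                                              urban = 0.2),
                            bbox = c(38, 43, -78, -70),
                            year_range = c(1990, 2022),
                            coord_decimals = 4, seed = 1) {
  stopifnot(n_species >= 4, birth > 0, death >= 0,
            sigma_resid >= 0, sigma_body > 0,
            records_mean > 0, records_dispersion > 0, affinity_sd >= 0,
            abs(sum(class_mixture) - 1) < 1e-8,
            length(seed) == 1, is.finite(seed))
  if (lambda_true < 0 || lambda_true > 1) stop("lambda_true must be in [0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

#' Simulate an ultrametric birth-death phylogeny
#'
#' @param n_species number of extant tips.
#' @param birth,death speciation and extinction rates.
#' @param seed integer seed (deterministic per seed).
#' @return a `"phylo"` tree with tips `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n_species, birth = 1, death = 0, seed = 1) {
  if (n_species < 2) stop("need at least 2 species")
  if (birth <= 0 || death < 0 || death >= birth) {
    stop("rates must satisfy birth > 0 and 0 <= death < birth")
  }
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = birth, death = death)
  tr$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tr
}

#' Simulate allometric brain-body traits on a tree
#'
#' Log body size evolves as Brownian motion; log brain mass is
#' `intercept + slope * log_body + eps` with `cov(eps) = sigma_resid^2 *
#' V(lambda_true)`, `V` scaled to unit mean diagonal so `sigma_resid` is the
#' marginal residual SD. One specimen per species is exported, with masses and
#' spans as exp of the logs.
#'
#' @param tree a `"phylo"` tree.
#' @param cfg a [scenario_config()] (only the allometry fields are used).
#' @param seed integer seed.
#' @return a specimen data frame (`species`, `brain_mg`, `itd_mm`) with the
#'   generating residuals attached as attribute `"truth"`.
#' @export
simulate_allometric_traits <- function(tree, cfg = scenario_config(), seed = 1) {
  V <- phylo_covariance(tree)
  Vn <- V / mean(diag(V))
  n <- nrow(Vn)
  set.seed(seed)
  log_body <- cfg$mean_log_body +
    drop(MASS::mvrnorm(1, rep(0, n), cfg$sigma_body^2 * Vn))
  eps <- if (cfg$sigma_resid > 0) {
    drop(MASS::mvrnorm(1, rep(0, n),
                       cfg$sigma_resid^2 * lambda_transform(Vn, cfg$lambda_true)))
  } else rep(0, n)
  log_brain <- cfg$intercept + cfg$slope * log_body + eps
  out <- data.frame(species = tree$tip.label,
                    brain_mg = exp(log_brain), itd_mm = exp(log_body),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(species = tree$tip.label,
                                   log_body = log_body, log_brain = log_brain,
                                   residual = eps, stringsAsFactors = FALSE)
  out
}

#' Simulate a random habitat grid
#'
#' @param cfg a [scenario_config()].
#' @param seed integer seed.
#' @return a `"habitat_grid"` whose cell classes are i.i.d. draws from the
#'   configured mixture (each class guaranteed present).
#' @export
simulate_grid <- function(cfg = scenario_config(), seed = 1) {
  set.seed(seed)
  n_cell <- cfg$grid_rows * cfg$grid_cols
  if (n_cell < 3) stop("grid too small to hold all three classes")
  cls <- sample(HABITATS, n_cell, replace = TRUE, prob = cfg$class_mixture)
  cls[sample.int(n_cell, 3)] <- HABITATS    # every class must exist somewhere
  habitat_grid(matrix(cls, cfg$grid_rows, cfg$grid_cols), bbox = cfg$bbox)
}

#' Simulate georeferenced occurrence records
#'
#' Per species the habitat-class probabilities are
#' `softmax(log(class_mixture) + a + gamma * residual on the urban entry)`,
#' where `a` is the species' latent affinity vector (iid
#' `N(0, affinity_sd^2)` per habitat); the
#' record count is negative-binomial (optionally clamped up to
#' `min_records`); each record lands uniformly inside a random cell of its
#' class, with a uniform year in `year_range` and coordinates printed at
#' `coord_decimals` decimals.
#'
#' @param species character vector of species labels.
#' @param residuals numeric relative-brain-size scores, aligned with
#'   `species` (all zero for a null scenario).
#' @param grid a `"habitat_grid"`.
#' @param cfg a [scenario_config()].
#' @param seed integer seed.
#' @return records data frame (`species`, `lat`, `lon`, `year`, `lat_text`,
#'   `lon_text`, `habitat_true`) with per-species class probabilities attached
#'   as attribute `"affinities"`.
#' @export
simulate_occurrence_records <- function(species, residuals, grid,
                                        cfg = scenario_config(), seed = 1) {
  stopifnot(length(species) == length(residuals))
  base <- log(cfg$class_mixture)
  cells_by_class <- lapply(HABITATS, function(h) which(grid$classes == h))
  names(cells_by_class) <- HABITATS
  if (any(vapply(cells_by_class, length, 0L) == 0 & cfg$class_mixture > 0)) {
    stop("grid lacks a habitat class that has positive probability")
  }
  set.seed(seed)
  affinity <- matrix(stats::rnorm(length(species) * 3, sd = cfg$affinity_sd),
                     length(species), 3)
  probs <- t(vapply(seq_along(species), function(i) {
    lo <- base + affinity[i, ] + c(0, 0, cfg$gamma * residuals[i])
    p <- exp(lo - max(lo)); p / sum(p)
  }, numeric(3)))
  colnames(probs) <- HABITATS
  rownames(probs) <- species
  counts <- stats::rnbinom(length(species), mu = cfg$records_mean,
                           size = cfg$records_dispersion)
  if (cfg$enforce_min_records) counts <- pmax(counts, cfg$min_records)

  dy <- (grid$bbox[2] - grid$bbox[1]) / grid$n_rows
  dx <- (grid$bbox[4] - grid$bbox[3]) / grid$n_cols
  recs <- vector("list", length(species))
  for (i in seq_along(species)) {
    n_i <- counts[i]
    if (n_i == 0) next
    hab <- sample(HABITATS, n_i, replace = TRUE, prob = probs[i, ])
    cell <- vapply(hab, function(h) {
      cs <- cells_by_class[[h]]
      cs[sample.int(length(cs), 1)]
    }, 0L)
    row <- (cell - 1) %% grid$n_rows + 1
    col <- (cell - 1) %/% grid$n_rows + 1
    lat <- grid$bbox[1] + (row - 1 + stats::runif(n_i)) * dy
    lon <- grid$bbox[3] + (col - 1 + stats::runif(n_i)) * dx
    fmt <- paste0("%.", cfg$coord_decimals, "f")
    recs[[i]] <- data.frame(
      species = species[i],
      lat = round(lat, cfg$coord_decimals),
      lon = round(lon, cfg$coord_decimals),
      year = sample(seq(cfg$year_range[1], cfg$year_range[2]), n_i, replace = TRUE),
      lat_text = sprintf(fmt, lat), lon_text = sprintf(fmt, lon),
      habitat_true = hab, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "affinities") <- probs
  out
}

#' Generate a full synthetic scenario
#'
#' Composes the tree, trait, grid and occurrence simulators under one master
#' seed (each stage on its own deterministic sub-stream), returning the bundle
#' the pipeline consumes plus the complete generating truth.
#'
#' @param cfg a [scenario_config()].
#' @param dir optional directory; when given, the bundle is written to disk
#'   via [write_scenario()].
#' @return a list of class `"scenario_bundle"`: `tree`, `specimens`,
#'   `records`, `grid`, `truth` (generating parameters, per-species residuals
#'   and habitat affinities), `config`.
#' @export
make_scenario <- function(cfg = scenario_config(), dir = NULL) {
  tree <- simulate_tree(cfg$n_species, cfg$birth, cfg$death,
                        seed = sub_seed(cfg$seed, 1))
  specimens <- simulate_allometric_traits(tree, cfg, seed = sub_seed(cfg$seed, 2))
  grid <- simulate_grid(cfg, seed = sub_seed(cfg$seed, 3))
  tru <- attr(specimens, "truth")
  records <- simulate_occurrence_records(tree$tip.label, tru$residual, grid,
                                         cfg, seed = sub_seed(cfg$seed, 4))
  truth <- list(
    config = unclass(cfg)[setdiff(names(cfg), "class_mixture")],
    class_mixture = as.list(cfg$class_mixture),
    residuals = stats::setNames(as.list(tru$residual), tru$species),
    affinities = apply(attr(records, "affinities"), 1, as.list)
  )
  names(truth$affinities) <- tree$tip.label
  bundle <- structure(list(tree = tree, specimens = specimens,
                           records = records, grid = grid, truth = truth,
                           config = cfg),
                      class = "scenario_bundle")
  if (!is.null(dir)) write_scenario(bundle, dir)
  bundle
}

#' Write a scenario bundle to disk
#'
#' Writes Newick + specimens CSV + records CSV + grid files + truth JSON and a
#' manifest into one directory, all as plain text.
#'
#' @param bundle a `"scenario_bundle"`.
#' @param dir output directory (created if absent).
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(bundle$specimens, file.path(dir, "specimens.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  write_grid(bundle$grid, file.path(dir, "grid.txt"),
             file.path(dir, "reclass.csv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- c("tree.nwk", "specimens.csv", "records.csv", "grid.txt",
                "grid.txt.json", "reclass.csv", "truth.json")
  writeLines(manifest, file.path(dir, "MANIFEST"))
  invisible(dir)
}
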