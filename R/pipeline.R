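#' Pipeline configuration
#'
#' Either a synthetic scenario (`scenario =` a [scenario_config()]) or paths
#' to on-disk inputs (`tree_file`, `specimens_file`, `records_file`,
#' `grid_file`, `reclass_file`), plus the filter, null-model and model
#' settings of the analysis.
#'
#' @param scenario optional [scenario_config()]; when given, inputs are
#'   simulated rather than read.
#' @param tree_file,specimens_file,records_file,grid_file,reclass_file input
#'   paths (ignored when `scenario` is given).
#' @param min_year,max_year,min_decimals record filters.
#' @param min_records minimum records per retained species.
#' @param n_sim number of null-model randomizations.
#' @param high,low percentile classification thresholds.
#' @param ties null-model tie policy, `"strict"` or `"half"`.
#' @param predictors which predictors to regress occupancy on; any of
#'   `"residual"` (relative brain size), `"log_brain"`, `"log_body"`.
#' @param signal logical; estimate phylogenetic signal of relative brain size
#'   and of each habitat's occupancy degree.
#' @param exclude_species optional species to drop before analysis (e.g. a
#'   user-supplied edge-of-range exclusion list).
#' @param seed master seed for all stochastic stages.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(scenario = NULL, tree_file = NULL,
                            specimens_file = NULL, records_file = NULL,
                            grid_file = NULL, reclass_file = NULL,
                            min_year = 1990, max_year = 2022,
                            min_decimals = 2, min_records = 50,
                            n_sim = 10000, high = 80, low = 20,
                            ties = "strict",
                            predictors = c("residual", "log_brain", "log_body"),
                            signal = TRUE, exclude_species = NULL, seed = 1) {
  stopifnot(n_sim >= 1, low >= 0, high <= 100, low < high)
  predictors <- match.arg(predictors, several.ok = TRUE)
  if (is.null(scenario) &&
      (is.null(tree_file) || is.null(specimens_file) || is.null(records_file) ||
       is.null(grid_file) || is.null(reclass_file))) {
    stop("either a scenario or all five input paths must be given")
  }
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

load_inputs <- function(config) {
  if (!is.null(config$scenario)) {
    make_scenario(config$scenario)
  } else {
    structure(list(
      tree = read_newick(file = config$tree_file),
      specimens = utils::read.csv(config$specimens_file, stringsAsFactors = FALSE),
      records = read_records_csv(config$records_file),
      grid = read_grid(config$grid_file, config$reclass_file),
      truth = NULL, config = NULL
    ), class = "scenario_bundle")
  }
}

#' Restrict a scenario bundle to one region
#'
#' Keeps specimens whose `region` is the requested one (or `"both"`),
#' restricts records to the retained species and prunes the tree through
#' [match_tips()].
#'
#' @param bundle a `"scenario_bundle"` (or compatible list).
#' @param region region label, e.g. `"US"` or `"EU"`.
#' @return the restricted bundle.
#' @export
subset_by_region <- function(bundle, region) {
  if (!"region" %in% names(bundle$specimens)) {
    stop("specimens carry no `region` column")
  }
  keep <- bundle$specimens$region %in% c(region, "both")
  if (!any(keep)) stop("no specimens in region: ", region)
  bundle$specimens <- bundle$specimens[keep, , drop = FALSE]
  sp <- unique(bundle$specimens$species)
  bundle$records <- bundle$records[bundle$records$species %in% sp, , drop = FALSE]
  bundle$tree <- match_tips(bundle$tree, sp)$tree
  bundle
}

#' Run the full brain-size / habitat-occupancy analysis
#'
#' Executes the pipeline: record filtering, habitat assignment, occurrence
#' matrix, minimum-record filter, fixed-margin null-model percentiles and
#' 80/20 classification, allometric PGLS and relative brain size,
#' phylogenetic signal, and one phylogenetic logistic regression of high (1)
#' versus low (0) occupancy per habitat and per predictor (intermediate
#' species excluded, mirroring the extremes-only analysis). Identical
#' config and seed give an identical report (apart from the timestamp).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for the JSON report and per-stage CSVs.
#' @return a list of class `"pipeline_report"`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- tryCatch(load_inputs(config), error = function(e)
    stop_stage("load_inputs", conditionMessage(e)))
  counts <- list(records_input = nrow(bundle$records))

  if (!is.null(config$exclude_species)) {
    bundle$records <- bundle$records[
      !bundle$records$species %in% config$exclude_species, , drop = FALSE]
    bundle$specimens <- bundle$specimens[
      !bundle$specimens$species %in% config$exclude_species, , drop = FALSE]
  }
  counts$records_after_exclusions <- nrow(bundle$records)

  recs <- tryCatch(
    filter_records(bundle$records, config$min_year, config$max_year,
                   config$min_decimals),
    error = function(e) stop_stage("filter_records", conditionMessage(e)))
  counts$records_after_filters <- nrow(recs)

  recs <- tryCatch(assign_habitat(recs, bundle$grid),
                   error = function(e) stop_stage("assign_habitat",
                                                  conditionMessage(e)))
  counts$records_in_grid <- nrow(recs)

  mat <- build_matrix(recs)
  counts$species_with_records <- nrow(mat)
  mat <- tryCatch(apply_min_records(mat, config$min_records),
                  error = function(e) stop_stage("apply_min_records",
                                                 conditionMessage(e)))
  counts$species_min_records <- nrow(mat)

  traits <- tryCatch(species_means(bundle$specimens),
                     error = function(e) stop_stage("species_means",
                                                    conditionMessage(e)))
  shared <- intersect(rownames(mat), traits$species)
  mt <- tryCatch(match_tips(bundle$tree, shared),
                 error = function(e) stop_stage("match_tips",
                                                conditionMessage(e)))
  shared <- mt$tree$tip.label
  counts$species_analysed <- length(shared)
  mat <- mat[shared, , drop = FALSE]
  traits <- traits[match(shared, traits$species), , drop = FALSE]

  V <- phylo_covariance(mt$tree)
  allom <- tryCatch(pgls_fit(log_brain ~ log_body, traits, V),
                    error = function(e) stop_stage("pgls_fit",
                                                   conditionMessage(e)))
  rbs <- relative_brain_size(allom)

  occ <- tryCatch(
    occupancy_percentiles(mat, n_sim = config$n_sim,
                          seed = sub_seed(config$seed, 10),
                          ties = config$ties,
                          high = config$high, low = config$low),
    error = function(e) stop_stage("occupancy_percentiles",
                                   conditionMessage(e)))
  class_counts <- table(factor(occ$habitat, HABITATS),
                        factor(occ$class, c("low", "intermediate", "high")))

  signal <- NULL
  if (isTRUE(config$signal)) {
    resid <- stats::setNames(rbs$residual, rbs$species)
    signal <- list(relative_brain = unclass(phylo_signal(resid, V)))
    for (h in HABITATS) {
      deg <- occ$percentile[occ$habitat == h] / 100
      names(deg) <- occ$species[occ$habitat == h]
      signal[[paste0("occupancy_", h)]] <- tryCatch(
        unclass(phylo_signal(deg, V)), error = function(e) conditionMessage(e))
    }
  }

  predictors <- list(residual = stats::setNames(rbs$residual, rbs$species),
                     log_brain = stats::setNames(traits$log_brain, traits$species),
                     log_body = stats::setNames(traits$log_body, traits$species))
  models <- list()
  for (h in HABITATS) {
    cell <- occ[occ$habitat == h, ]
    keep <- cell$class != "intermediate"
    y <- stats::setNames(as.numeric(cell$class[keep] == "high"),
                         cell$species[keep])
    for (pr in config$predictors) {
      x <- predictors[[pr]][names(y)]
      fit <- tryCatch(phylo_logit(y, x, V[names(y), names(y), drop = FALSE]),
                      error = function(e) stop_stage(
                        paste0("phylo_logit[", h, ", ", pr, "]"),
                        conditionMessage(e)))
      models[[h]][[pr]] <- list(
        beta0 = unname(fit$coefficients[1]), beta1 = unname(fit$coefficients[2]),
        se_beta1 = unname(fit$se[2]), sigma2 = fit$sigma2,
        r2_analogue = fit$r2_analogue, n_used = fit$n_used,
        n_high = sum(y == 1), n_low = sum(y == 0))
    }
  }

  report <- structure(list(
    stage_counts = counts,
    allometry = list(intercept = unname(allom$coefficients[1]),
                     slope = unname(allom$coefficients[2]),
                     lambda = allom$lambda, sigma2 = allom$sigma2,
                     r2 = allom$r2, loglik = allom$loglik, n = allom$n),
    relative_brain_size = rbs,
    occupancy = occ,
    class_counts = class_counts,
    signal = signal,
    models = models,
    provenance = list(seed = config$seed, n_sim = config$n_sim,
                      thresholds = c(high = config$high, low = config$low),
                      ties = config$ties,
                      package_version = as.character(utils::packageVersion("beehab")),
                      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "pipeline_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("beehab pipeline report\n")
  cat("  species analysed:", x$stage_counts$species_analysed, "\n")
  cat("  allometry: slope =", format(x$allometry$slope, digits = 4),
      " lambda =", format(x$allometry$lambda, digits = 3),
      " R2 =", format(x$allometry$r2, digits = 3), "\n")
  cat("  occupancy classes (species per habitat):\n")
  print(x$class_counts)
  cat("  occupancy ~ relative brain size (beta1 per habitat):\n")
  for (h in names(x$models)) {
    m <- x$models[[h]][["residual"]]
    if (!is.null(m)) {
      cat(sprintf("    %-13s beta1 = %8.3f (se %.3f, sigma2 %.3f)\n",
                  h, m$beta1, m$se_beta1, m$sigma2))
    }
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Serializes the report as JSON plus per-stage CSVs (occupancy table and
#' relative brain size scores).
#'
#' @param report a `"pipeline_report"`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- report
  json$occupancy <- as.data.frame(json$occupancy)
  json$class_counts <- as.data.frame.matrix(json$class_counts)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_occupancy_csv(report$occupancy, file.path(dir, "occupancy.csv"))
  utils::write.csv(report$relative_brain_size,
                   file.path(dir, "relative_brain_size.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file's top-level keys mirror the arguments of [pipeline_config()]; a
#' `scenario` block, when present, mirrors [scenario_config()].
#'
#' @param file path to a `.yaml`/`.yml` or `.json` config file.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(file) {
  vals <- if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
  else jsonlite::read_json(file, simplifyVector = TRUE)
  if (!is.null(vals$scenario)) {
    sc <- vals$scenario
    if (!is.null(sc$class_mixture)) sc$class_mixture <- unlist(sc$class_mixture)
    if (!is.null(sc$bbox)) sc$bbox <- unlist(sc$bbox)
    if (!is.null(sc$year_range)) sc$year_range <- unlist(sc$year_range)
    vals$scenario <- do.call(scenario_config, sc)
  }
  do.call(pipeline_config, vals)
}
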