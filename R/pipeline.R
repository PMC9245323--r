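#' Load and validate a pipeline run configuration
#'
#' The YAML configuration must name either a `synthetic` block (passed to
#' [sim_config()]) or an `inputs` block (paths to a Newick tree and a trait
#' CSV), never both, and must carry an explicit integer `seed` (wall-clock
#' seeding is deliberately impossible). Unknown keys anywhere in the file
#' are rejected, and every violation is reported at once.
#'
#' @param path YAML file path.
#' @return Validated list of class `run_config`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  problems <- character(0)
  known <- c("seed", "synthetic", "inputs", "stages", "threshold_rules",
             "hisse_models", "n_fisse_sim", "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  if (is.null(cfg$seed))
    problems <- c(problems, "'seed' is required (reproducibility contract)")
  has_syn <- !is.null(cfg$synthetic)
  has_inp <- !is.null(cfg$inputs)
  if (has_syn && has_inp)
    problems <- c(problems, "give either 'synthetic' or 'inputs', not both")
  if (!has_syn && !has_inp)
    problems <- c(problems, "one of 'synthetic' or 'inputs' is required")
  if (has_syn) {
    syn_known <- names(formals(sim_config))
    bad <- setdiff(names(cfg$synthetic), syn_known)
    if (length(bad))
      problems <- c(problems, paste0("unknown synthetic key(s): ",
                                     paste(bad, collapse = ", ")))
  }
  if (has_inp) {
    inp_known <- c("tree", "traits", "coords", "polygons")
    bad <- setdiff(names(cfg$inputs), inp_known)
    if (length(bad))
      problems <- c(problems, paste0("unknown inputs key(s): ",
                                     paste(bad, collapse = ", ")))
    if (is.null(cfg$inputs$tree) || is.null(cfg$inputs$traits))
      problems <- c(problems, "'inputs' needs at least 'tree' and 'traits'")
  }
  all_stages <- c("metrics", "dr", "pgls", "path", "fisse", "hisse", "spatial")
  cfg$stages <- cfg$stages %||% all_stages
  bad <- setdiff(cfg$stages, all_stages)
  if (length(bad))
    problems <- c(problems, paste0("unknown stage(s): ",
                                   paste(bad, collapse = ", ")))
  cfg$threshold_rules <- cfg$threshold_rules %||%
    c("median", "q25", "q75", "quartile-grouping")
  cfg$hisse_models <- cfg$hisse_models %||% "reduced"
  if (!cfg$hisse_models %in% c("reduced", "full"))
    problems <- c(problems, "hisse_models must be 'reduced' or 'full'")
  cfg$n_fisse_sim <- cfg$n_fisse_sim %||% 100
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on either a synthetic
#' clade or user-supplied inputs: trait/model-frame preparation, tip DR
#' rates, the PGLS battery (interaction plus island/continent splits), the
#' path model (all species and per setting), FiSSE tests across threshold
#' rules, the state-dependent (HiSSE/CID) model table, and the
#' spatial-phylogenetic mixed model. One CSV per result table, a JSON
#' manifest (seed, stages, config hash, estimator notes) and the returned
#' manifest list. Reruns with the same configuration and seed are
#' bit-identical. A stage that fails aborts its dependents but independent
#' stages still run; the error is recorded in the manifest.
#'
#' @param config A `run_config` from [load_config()] (or a path to one).
#' @param output_dir Overrides the configured output directory.
#' @return Invisibly, a list with `results` (per-stage objects) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- output_dir %||% config$output_dir %||% stop("no output directory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  if (!is.null(config$synthetic)) {
    sc <- do.call(sim_config, c(config$synthetic,
                                if (is.null(config$synthetic$seed))
                                  list(seed = config$seed)))
    sim <- generate_clade_dataset(sc)
    tree <- sim$tree
    data <- sim$data
  } else {
    tree <- parse_newick(paste(readLines(config$inputs$tree), collapse = ""))
    data <- utils::read.csv(config$inputs$traits, stringsAsFactors = FALSE)
    rownames(data) <- data$tip
  }
  frame <- prepare_model_frame(data)
  results <- list()
  errors <- list()
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      message("stage '", name, "' failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      results[[name]] <<- res
      message(sprintf("stage '%s' done in %.1fs", name,
                      proc.time()[["elapsed"]] - t0))
    }
    invisible(res)
  }

  run_stage("metrics", function() {
    poly_path <- config$inputs$polygons
    if (is.null(poly_path)) {
      message("stage 'metrics' skipped: no range polygons supplied")
      return(NULL)
    }
    ranges <- read_ranges_geojson(poly_path)
    rows <- lapply(names(ranges), function(sp) {
      pm <- polygon_metrics(ranges[[sp]], species = sp)
      em <- extent_metrics(ranges[[sp]], species = sp)
      data.frame(tip = sp, area = pm$area, perimeter = pm$perimeter,
                 shape_index = pm$shape_index, length = em$length,
                 width = em$width, lon_midpoint = em$lon_midpoint,
                 lat_midpoint = em$lat_midpoint,
                 centroid_x = em$centroid[["x"]],
                 centroid_y = em$centroid[["y"]])
    })
    do.call(rbind, rows)
  })
  run_stage("dr", function() dr_statistic(tree))

  predictors <- c("log_range_size", "log_shape_index", "log_hwi",
                  "log_body_mass", "abs_lat", "abs_lon")
  run_stage("pgls", function() {
    rate <- fit_interaction_and_splits("log_dr", predictors, frame, tree)
    size <- fit_pgls(log_range_size ~ log_hwi + log_body_mass + abs_lat +
                       abs_lon + island, frame, tree)
    list(rate = rate, range_size = size)
  })
  run_stage("path", function() {
    dag <- default_path_dag()
    dag_sub <- default_path_dag(include_island = FALSE)
    list(all = fit_path_model(dag, frame, tree),
         island = fit_path_model(dag_sub, frame, tree, subgroup = "island"),
         continental = fit_path_model(dag_sub, frame, tree,
                                      subgroup = "continental"))
  })
  run_stage("fisse", function() {
    seeds <- config$seed + seq_along(config$threshold_rules)
    rows <- list()
    for (i in seq_along(config$threshold_rules)) {
      rule <- config$threshold_rules[[i]]
      bin <- binarize_by_threshold(
        stats::setNames(data$range_size, rownames(data)), rule)
      ft <- fisse_test(tree, bin$states, n_sim = config$n_fisse_sim,
                       seed = seeds[i])
      rows[[paste0("range_size_", bin$rule)]] <- ft
    }
    if ("setting" %in% names(data) &&
        length(unique(data$setting)) == 2) {
      st <- stats::setNames(as.integer(data$setting == "island"),
                            rownames(data))
      rows[["island_vs_continental"]] <- fisse_test(
        tree, st, n_sim = config$n_fisse_sim,
        seed = config$seed + 1000L)
    }
    rows
  })
  run_stage("hisse", function() {
    specs <- make_model_set("hisse_binary")
    if (config$hisse_models == "reduced")
      specs <- specs[c("hisse_lam.full_mu.equal_q.two",
                       "hisse_lam.hid1_mu.equal_q.equal",
                       "cid2_a", "cid2_b", "cid4_b")]
    st <- stats::setNames(as.integer(data$setting == "island"),
                          rownames(data))
    n_starts <- if (config$hisse_models == "reduced") 2 else 5
    fits <- lapply(specs, function(sp)
      fit_sse_model(tree, st, sp, n_starts = n_starts,
                    seed = config$seed))
    list(fits = fits, table = akaike_weights(fits))
  })
  run_stage("spatial", function() {
    # planar km coordinates from the midpoints (equirectangular at -20 deg)
    coords <- cbind(x = data$lon_midpoint * 111.32 * cos(-20 * pi / 180),
                    y = data$lat_midpoint * 110.57)
    rownames(coords) <- rownames(data)
    fit_spatiophylo(log_dr ~ log_range_size + abs_lat + abs_lon + log_hwi +
                      log_body_mass, frame, tree, coords)
  })

  files <- write_results_tables(results, out_dir)
  tree_file <- file.path(out_dir, "tree.nwk")
  writeLines(write_newick(tree), tree_file)
  utils::write.csv(data, file.path(out_dir, "species_data.csv"),
                   row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rangediv")),
    seed = config$seed,
    stages_run = names(results),
    stages_failed = errors,
    config_hash = config_hash(config),
    estimator_notes = c(
      path = "per-equation ML lambda-PGLS (not a joint Bayesian system)",
      spatial = "Matern kernel at one coordinate per species; ML + Wald"),
    files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, manifest = manifest,
                 tree = tree, data = data, frame = frame))
}

# deterministic hash of the configuration (md5 of its canonical JSON)
config_hash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)),
             tf)
  unname(tools::md5sum(tf))
}

#' Write pipeline results as tidy CSV tables
#'
#' One file per analysis table, with fixed column orders and floats at six
#' significant digits: the PGLS battery, the path-model edge tables, the
#' FiSSE rows (one per threshold rule), the state-dependent model table and
#' the spatial model's fixed effects and variance components.
#'
#' @param results Named list of stage results from [run_pipeline()].
#' @param dir Output directory.
#' @return Character vector of files written (named by table).
#' @export
write_results_tables <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(tab, name) {
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], signif, digits = 6)
    f <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(tab, f, row.names = FALSE)
    files[[name]] <<- f
  }
  if (!is.null(results$metrics)) put(results$metrics, "range_metrics")
  if (!is.null(results$dr)) put(results$dr, "tip_rates")
  if (!is.null(results$pgls)) {
    tidy_one <- function(fit, id) {
      if (is.null(fit)) return(NULL)
      cbind(model = id, fit$coefficients, lambda = fit$lambda, n = fit$n)
    }
    tab <- rbind(tidy_one(results$pgls$rate$interaction, "rate_interaction"),
                 tidy_one(results$pgls$rate$island, "rate_island"),
                 tidy_one(results$pgls$rate$continental, "rate_continental"),
                 tidy_one(results$pgls$range_size, "range_size"))
    put(tab, "pgls")
  }
  if (!is.null(results$path)) {
    tab <- do.call(rbind, Filter(Negate(is.null), results$path))
    put(as.data.frame(tab), "path_model")
  }
  if (!is.null(results$fisse)) {
    tab <- do.call(rbind, lapply(names(results$fisse), function(nm) {
      f <- results$fisse[[nm]]
      data.frame(grouping = nm, lambda0 = f$lambda0, lambda1 = f$lambda1,
                 statistic = f$statistic, p = f$p, n_sim = f$n_sim)
    }))
    put(tab, "fisse")
  }
  if (!is.null(results$hisse)) put(results$hisse$table, "hisse_models")
  if (!is.null(results$spatial)) {
    put(results$spatial$coefficients, "spatial_fixed_effects")
    vc <- results$spatial$varcomp
    put(data.frame(component = names(vc), variance = as.numeric(vc),
                   rho_km = results$spatial$rho), "spatial_varcomp")
  }
  files
}
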