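#' Configuration for the synthetic clade generator
#'
#' Bundles and validates every knob of [generate_clade_dataset()]. Defaults
#' emulate a honeyeater-sized radiation: 192 tips of which 68/192 are island
#' species, right-skewed range sizes spanning roughly 10^2 to 10^7 km^2 with
#' island ranges systematically smaller, and trait covariances induced by a
#' linear structural simulation (position and setting act on body size and
#' dispersal; body size acts on dispersal; position, setting, body size and
#' dispersal act on range size and shape).
#'
#' @param n_tips Number of species.
#' @param birth,death Birth-death rates for the tree simulation (tree depth
#'   is rescaled to 1).
#' @param island_fraction Expected proportion of island species.
#' @param island_mode `"iid"` draws the island flag independently per
#'   species; `"mk"` evolves it on the tree under a symmetric Mk process
#'   calibrated to the same expected frequency.
#' @param range_meanlog Named vector `c(island=, continental=)`: log-scale
#'   location of range size (km^2) per setting.
#' @param range_sdlog Named vector of log-scale spreads per setting.
#' @param path_coefficients Named list of structural coefficients on the
#'   standardized scale; see Details. Set them to 0 for a null dataset.
#' @param trait_lambda Pagel's lambda of the phylogenetic noise added to
#'   each structural equation.
#' @param trait_sigma2 Brownian rate of that noise.
#' @param missing_fraction Fraction of `hwi` and `body_mass` values set to
#'   `NA`, to exercise imputation.
#' @param seed Integer seed.
#' @details Structural coefficients (defaults in parentheses, signs follow
#' the hypothesized causal diagram): `lat_to_mass` (0.3: body size grows
#' away from the tropics), `lon_to_mass` (0.15), `mass_to_hwi` (0.25),
#' `island_to_hwi` (0.3: island colonists are better dispersers),
#' `hwi_to_range` (0.3), `mass_to_range` (-0.2), `lat_to_range` (0.25),
#' `lon_to_range` (-0.15), `hwi_to_shape` (0.2).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 192, birth = 1, death = 0,
                       island_fraction = 68 / 192,
                       island_mode = c("iid", "mk"),
                       range_meanlog = c(island = log(2e4),
                                         continental = log(3e5)),
                       range_sdlog = c(island = 1.2, continental = 1.6),
                       path_coefficients = list(),
                       trait_lambda = 0.7, trait_sigma2 = 1,
                       missing_fraction = 0, seed = 1) {
  island_mode <- match.arg(island_mode)
  stopifnot(n_tips >= 2, birth > 0, death >= 0,
            island_fraction >= 0, island_fraction <= 1,
            trait_lambda >= 0, trait_lambda <= 1, trait_sigma2 > 0,
            missing_fraction >= 0, missing_fraction < 0.5)
  defaults <- list(lat_to_mass = 0.3, lon_to_mass = 0.15, mass_to_hwi = 0.25,
                   island_to_hwi = 0.3, hwi_to_range = 0.3,
                   mass_to_range = -0.2, lat_to_range = 0.25,
                   lon_to_range = -0.15, hwi_to_shape = 0.2)
  unknown <- setdiff(names(path_coefficients), names(defaults))
  if (length(unknown))
    stop("unknown path coefficient(s): ", paste(unknown, collapse = ", "))
  defaults[names(path_coefficients)] <- path_coefficients
  cfg <- list(n_tips = n_tips, birth = birth, death = death,
              island_fraction = island_fraction, island_mode = island_mode,
              range_meanlog = range_meanlog, range_sdlog = range_sdlog,
              path_coefficients = defaults, trait_lambda = trait_lambda,
              trait_sigma2 = trait_sigma2,
              missing_fraction = missing_fraction, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic clade: tree plus species trait table
#'
#' Simulates a birth-death tree (depth 1), assigns island/continental
#' settings, and builds a species table whose covariance structure follows
#' the configured structural coefficients, with phylogenetically correlated
#' residuals. Range sizes are log-normal per setting; body mass (g) and
#' hand-wing index are positive and realistically scaled. Tip DR values are
#' computed from the simulated tree.
#'
#' @param config A [sim_config()] object.
#' @return List with `tree` (`phylo`) and `data` (data.frame with columns
#'   `tip`, `setting`, `genus`, `lat_midpoint`, `lon_midpoint`, `body_mass`,
#'   `hwi`, `range_size`, `shape_index`, `dr`, `log_dr`; row names = tips).
#' @export
generate_clade_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_tips
  tree <- simulate_bd_tree(n, config$birth, config$death)
  tips <- tree$tip.label
  b <- config$path_coefficients

  # geographic setting
  setting <- if (config$island_mode == "iid") {
    ifelse(stats::runif(n) < config$island_fraction, "island", "continental")
  } else {
    q <- 2 # symmetric flips on the depth-1 tree
    st <- simulate_mk_character(tree, q01 = q * config$island_fraction,
                                q10 = q * (1 - config$island_fraction),
                                root_freq = config$island_fraction)
    ifelse(st[tips] == 1L, "island", "continental")
  }
  names(setting) <- tips
  if (length(unique(setting)) < 2L && config$island_fraction > 0 &&
      config$island_fraction < 1)
    warning("all species fell in one geographic setting at n = ", n)

  phylo_noise <- function() {
    z <- simulate_bm_trait(tree, sigma2 = config$trait_sigma2,
                           lambda = config$trait_lambda)
    as.numeric(scale(z[tips]))
  }
  zscore <- function(x) as.numeric(scale(x))
  island <- as.numeric(setting == "island")

  # position: islands concentrated nearer the tropics, wider longitude spread
  lat <- ifelse(island == 1, stats::rnorm(n, -12, 6), stats::rnorm(n, -22, 8))
  lon <- ifelse(island == 1, stats::rnorm(n, 160, 15), stats::rnorm(n, 140, 8))

  # structural equations on standardized scales
  z_mass <- b$lat_to_mass * zscore(abs(lat)) + b$lon_to_mass * zscore(abs(lon)) +
    sqrt(0.8) * phylo_noise()
  body_mass <- exp(log(30) + 0.6 * z_mass) # grams, ~10-100 g
  z_hwi <- b$mass_to_hwi * zscore(z_mass) + b$island_to_hwi * island +
    sqrt(0.8) * phylo_noise()
  hwi <- pmax(1, 25 + 6 * z_hwi)

  log_range <- config$range_meanlog[setting] +
    config$range_sdlog[setting] *
      (b$hwi_to_range * zscore(z_hwi) + b$mass_to_range * zscore(z_mass) +
       b$lat_to_range * zscore(abs(lat)) + b$lon_to_range * zscore(abs(lon)) +
       sqrt(0.7) * phylo_noise())
  range_size <- as.numeric(exp(log_range))

  # geometric baseline: a square of area A has shape index sqrt(A)/4
  shape_index <- sqrt(range_size) / 4 *
    exp(b$hwi_to_shape * zscore(z_hwi) + 0.4 * phylo_noise())

  drtab <- dr_statistic(tree)
  dr <- drtab$dr[match(tips, drtab$tip)]

  genus <- assign_genera(tree)

  data <- data.frame(tip = tips, setting = unname(setting),
                     genus = genus[tips],
                     lat_midpoint = lat, lon_midpoint = lon,
                     body_mass = body_mass, hwi = hwi,
                     range_size = range_size, shape_index = shape_index,
                     dr = dr, log_dr = log(dr),
                     row.names = tips, stringsAsFactors = FALSE)

  if (config$missing_fraction > 0) {
    nmiss <- floor(config$missing_fraction * n)
    data$hwi[sample.int(n, nmiss)] <- NA
    data$body_mass[sample.int(n, nmiss)] <- NA
  }
  list(tree = tree, data = data)
}

# carve the tree into genus-like groups by slicing at 30% of tree depth
assign_genera <- function(tree, frac = 0.3) {
  ntip <- ape::Ntip(tree)
  depth <- node_depths(tree)
  cut <- frac * max(depth)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  grp <- vapply(seq_len(ntip), function(tip) {
    node <- tip
    while (parent[node] != 0L && depth[parent[node]] > cut) node <- parent[node]
    node
  }, integer(1))
  g <- paste0("g", as.integer(factor(grp, levels = unique(grp))))
  names(g) <- tree$tip.label
  g
}
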