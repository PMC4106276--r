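# Synthetic meadow generator: spatially autocorrelated environmental
# surfaces, habitat-driven plant placement, spatially clustered inbred
# lines, and plant traits produced by a known directed causal structure.
# The generator's defaults emulate the study design: a 40 x 50 m meadow,
# 234 plants, 71 environmental sample points.

#' Rectangular study domain
#'
#' @param width,height Extent in meters; both positive. Defaults give the
#'   40 x 50 m meadow of the study design.
#' @return A `domain` object.
#' @export
domain <- function(width = 40, height = 50) {
  stopifnot(is.finite(width), is.finite(height))
  if (width <= 0 || height <= 0) stop("domain sides must be positive")
  structure(list(width = width, height = height), class = "domain")
}

#' Simulate a Gaussian random field at point locations
#'
#' Draws one realization of the stationary Gaussian process: a multivariate
#' normal with constant mean `beta` and covariance
#' `sigma2 * exp(-h / phi)` plus the nugget `sigma2 * tau2_rel` on the
#' diagonal.
#'
#' @param locations Two-column coordinate matrix (meters).
#' @param params A [gp_params()].
#' @param seed Integer seed; the same seed reproduces identical values.
#' @return A [spatial_field()].
#' @param name Variable label for the returned field.
#' @export
simulate_grf <- function(locations, params, seed = NULL, name = "grf") {
  stopifnot(inherits(params, "gp_params"))
  locations <- as_points(locations)
  if (!nrow(locations)) stop("need at least one location")
  sig <- covariance_matrix(locations, params)
  r <- chol_jitter(sig)
  z <- with_seed(seed, rnorm(nrow(locations)))
  spatial_field(locations, params$beta + drop(crossprod(r, z)), name = name)
}

# --- rasters -----------------------------------------------------------

# Regular-grid surface: values[i, j] is the value at (x[i], y[j]).
surface_raster <- function(x, y, values) {
  values <- as.matrix(values)
  stopifnot(length(x) == nrow(values), length(y) == ncol(values),
            !is.unsorted(x, strictly = TRUE), !is.unsorted(y, strictly = TRUE))
  structure(list(x = as.numeric(x), y = as.numeric(y), values = values),
            class = "surface_raster")
}

# Bilinear interpolation of a raster at arbitrary points. Coordinates are
# clamped to the node hull; points farther than `tol_cells` grid cells
# outside it are an error.
bilinear_interp <- function(raster, points, tol_cells = 1) {
  stopifnot(inherits(raster, "surface_raster"))
  pts <- as_points(points)
  gx <- raster$x; gy <- raster$y
  dx <- if (length(gx) > 1) min(diff(gx)) else 1
  dy <- if (length(gy) > 1) min(diff(gy)) else 1
  bad <- pts[, 1] < gx[1] - tol_cells * dx | pts[, 1] > gx[length(gx)] + tol_cells * dx |
         pts[, 2] < gy[1] - tol_cells * dy | pts[, 2] > gy[length(gy)] + tol_cells * dy
  if (any(bad))
    stop(sprintf("points outside raster bounds: rows %s",
                 paste(utils::head(which(bad), 5), collapse = ", ")))
  px <- pmin(pmax(pts[, 1], gx[1]), gx[length(gx)])
  py <- pmin(pmax(pts[, 2], gy[1]), gy[length(gy)])
  ix <- pmin(pmax(findInterval(px, gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(py, gy), 1L), length(gy) - 1L)
  if (length(gx) == 1L) ix <- rep(1L, length(px))
  if (length(gy) == 1L) iy <- rep(1L, length(py))
  fx <- (px - gx[ix]) / (gx[ix + 1L] - gx[ix])
  fy <- (py - gy[iy]) / (gy[iy + 1L] - gy[iy])
  v <- raster$values
  v00 <- v[cbind(ix, iy)]; v10 <- v[cbind(ix + 1L, iy)]
  v01 <- v[cbind(ix, iy + 1L)]; v11 <- v[cbind(ix + 1L, iy + 1L)]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

# --- plant placement ----------------------------------------------------

#' Place plants by rejection sampling from an intensity surface
#'
#' Grid cells are drawn with probability proportional to the (non-negative)
#' intensity raster and each point is placed uniformly within its cell, so
#' the realized pattern follows the gridded inhomogeneous intensity.
#'
#' @param dom A [domain()].
#' @param intensity A `surface_raster` of non-negative intensities on a grid
#'   covering the domain.
#' @param n_target Exact number of points to place.
#' @param seed Integer seed.
#' @return `n_target x 2` coordinate matrix.
#' @export
simulate_plant_locations <- function(dom, intensity, n_target, seed = NULL) {
  stopifnot(inherits(dom, "domain"), inherits(intensity, "surface_raster"))
  if (n_target == 0) return(matrix(numeric(0), 0, 2))
  v <- intensity$values
  if (any(v < 0)) stop("intensity surface must be non-negative")
  if (all(v == 0)) stop("intensity surface is zero everywhere")
  nx <- length(intensity$x); ny <- length(intensity$y)
  dx <- if (nx > 1) diff(intensity$x)[1] else dom$width
  dy <- if (ny > 1) diff(intensity$y)[1] else dom$height
  with_seed(seed, {
    cell <- sample.int(nx * ny, n_target, replace = TRUE, prob = as.vector(v))
    ix <- (cell - 1L) %% nx + 1L
    iy <- (cell - 1L) %/% nx + 1L
    x <- intensity$x[ix] + runif(n_target, -dx / 2, dx / 2)
    y <- intensity$y[iy] + runif(n_target, -dy / 2, dy / 2)
    cbind(x = pmin(pmax(x, 0), dom$width), y = pmin(pmax(y, 0), dom$height))
  })
}

# --- inbred lines -------------------------------------------------------

#' Assign spatially clustered inbred-line labels
#'
#' `n_lines` founder plants are chosen at random; every plant takes the line
#' of its nearest founder with probability `exp(-d / dispersal_scale)`
#' (where `d` is the distance to that founder) and a uniformly random line
#' otherwise. Founders always take their own line, so each line occurs at
#' least once; as `dispersal_scale` grows the labels approach a pure
#' nearest-founder (Voronoi) tessellation.
#'
#' @param locations Plant coordinate matrix.
#' @param n_lines Number of lines (1 <= n_lines <= n plants).
#' @param dispersal_scale Distance-decay scale in meters (`Inf` allowed).
#' @param seed Integer seed.
#' @return Integer label vector in `1..n_lines`.
#' @export
assign_lines <- function(locations, n_lines, dispersal_scale, seed = NULL) {
  locations <- as_points(locations)
  n <- nrow(locations)
  if (n_lines < 1) stop("n_lines must be >= 1")
  if (n_lines > n) stop("n_lines cannot exceed the number of plants")
  if (dispersal_scale <= 0) stop("dispersal_scale must be > 0")
  with_seed(seed, {
    founders <- sample.int(n, n_lines)
    d <- cross_dist(locations, locations[founders, , drop = FALSE])
    nearest <- max.col(-d, ties.method = "first")
    dmin <- d[cbind(seq_len(n), nearest)]
    keep <- runif(n) < exp(-dmin / dispersal_scale)
    labels <- ifelse(keep, nearest, sample.int(n_lines, n, replace = TRUE))
    labels[founders] <- seq_len(n_lines)
    as.integer(labels)
  })
}

# --- neighbors ----------------------------------------------------------

#' Count neighbor plants within a radius
#'
#' Closed-ball count: a neighbor exactly at `radius` is included. The study
#' protocol used a 15 cm radius around each focal plant.
#'
#' @param focal Focal coordinate matrix.
#' @param neighbors Neighbor coordinate matrix (may be empty).
#' @param radius Radius in meters, positive.
#' @return Integer count per focal point.
#' @export
neighbor_counts <- function(focal, neighbors, radius = 0.15) {
  focal <- as_points(focal)
  if (radius <= 0) stop("radius must be > 0")
  if (is.null(neighbors) || !length(neighbors)) return(integer(nrow(focal)))
  neighbors <- as_points(neighbors)
  d <- cross_dist(focal, neighbors)
  as.integer(rowSums(d <= radius))
}

# --- causal trait structure --------------------------------------------

default_edge_list <- function() {
  data.frame(
    source = c("elevation", "elevation", "soil_moisture", "rosette_diameter",
               "rosette_diameter", "stalk_number", "stalk_herbivory",
               "dandelion_density", "rosette_herbivory"),
    target = c("soil_moisture", "rosette_diameter", "rosette_diameter",
               "stalk_number", "stalk_diameter", "fruit_number",
               "fruit_number", "rosette_herbivory", "stalk_herbivory"),
    sign = c("-", "-", "+", "+", "+", "+", "-", "+", "+"),
    effect = c(0.7, 0.5, 0.3, 0.8, 0.6, 0.6, 0.6, 0.8, 0.7),
    directed = TRUE,
    stringsAsFactors = FALSE)
}

default_var_specs <- function() {
  data.frame(
    name = c("rosette_diameter", "stalk_number", "stalk_diameter",
             "fruit_number", "rosette_herbivory", "stalk_herbivory",
             "goldenrod_density", "dandelion_density"),
    type = c("continuous", "count", "continuous", "count", "count", "count",
             "count", "count"),
    mean = c(6, 4, 3, 25, 8, 6, 2.5, 2.5),
    scale = c(1.5, 1.6, 0.8, 8, 3, 2.5, 1.4, 1.4),
    stringsAsFactors = FALSE)
}

#' Ground-truth configuration for the synthetic meadow
#'
#' Bundles everything the generator needs: Gaussian-process parameters for
#' the environmental surfaces, the habitat link driving plant placement, the
#' signed causal edge list for plant traits, per-variable noise levels, and
#' the study shape (234 plants, 71 environmental sites, 40 x 50 m domain by
#' default). Values not fixed by the study design (effect sizes, noise
#' magnitudes) carry defaults chosen for statistical test power.
#'
#' @param n_plants,n_env_sites,n_lines Study shape.
#' @param dispersal_scale Line dispersal decay, meters.
#' @param surface_params Named list of [gp_params()] for `elevation`, the
#'   `soil_moisture` residual surface, and `vpd`.
#' @param intensity_link Named coefficients on standardized (elevation,
#'   soil_moisture) in the log-intensity of plant placement.
#' @param edge_list Data frame (`source`, `target`, `sign`, `effect`,
#'   `directed`) describing the generative causal structure.
#' @param noise_sd Named per-variable structural noise (latent scale).
#' @param spatial_latents Named list `variable -> list(phi, sd)` of extra
#'   spatially structured noise components.
#' @param obs_noise Named measurement-error SD added to environmental
#'   observations at sample sites (observed units).
#' @param var_specs Observed-scale transforms (type, mean, scale) per trait.
#' @param env_means,env_scales Observed-scale affine transform of the
#'   latent `soil_moisture` and `vpd` surfaces.
#' @param grid_res,placement_res Simulation / placement grid resolutions, m.
#' @param seed Master seed.
#' @return A `truth_config` object.
#' @export
truth_config <- function(n_plants = 234, n_env_sites = 71, n_lines = 10,
                         dispersal_scale = 3,
                         surface_params = list(
                           elevation = gp_params(beta = 1365, sigma2 = 4, phi = 8),
                           soil_moisture = gp_params(beta = 0, sigma2 = 1, phi = 5),
                           vpd = gp_params(beta = 0, sigma2 = 1, phi = 4.2)),
                         intensity_link = c(elevation = -0.8, soil_moisture = 0.8),
                         edge_list = default_edge_list(),
                         noise_sd = c(soil_moisture = 0.7, rosette_diameter = 0.6,
                                      stalk_number = 0.5, stalk_diameter = 0.7,
                                      fruit_number = 0.5, rosette_herbivory = 0.5,
                                      stalk_herbivory = 0.5, goldenrod_density = 0.45,
                                      dandelion_density = 0.45),
                         spatial_latents = list(
                           goldenrod_density = list(phi = 4.2, sd = 0.9),
                           dandelion_density = list(phi = 4.2, sd = 0.9),
                           rosette_herbivory = list(phi = 4.2, sd = 0.3)),
                         obs_noise = c(elevation = 0.15, soil_moisture = 1.0,
                                       vpd = 0.06),
                         var_specs = default_var_specs(),
                         env_means = c(soil_moisture = 25, vpd = 1.2),
                         env_scales = c(soil_moisture = 5, vpd = 0.3),
                         grid_res = 2, placement_res = 0.5,
                         seed = 1L) {
  if (n_plants < 10) stop("n_plants must be >= 10")
  if (dispersal_scale <= 0) stop("dispersal_scale must be > 0")
  stopifnot(all(c("source", "target", "sign", "effect", "directed") %in%
                  names(edge_list)))
  if (any(!is.finite(edge_list$effect))) stop("effect sizes must be finite")
  known <- c(names(surface_params), var_specs$name)
  unknown <- setdiff(unique(c(edge_list$source, edge_list$target)), known)
  if (length(unknown))
    stop(sprintf("edge list names unknown variables: %s",
                 paste(unknown, collapse = ", ")))
  structure(list(n_plants = n_plants, n_env_sites = n_env_sites,
                 n_lines = n_lines, dispersal_scale = dispersal_scale,
                 surface_params = surface_params,
                 intensity_link = intensity_link, edge_list = edge_list,
                 noise_sd = noise_sd, spatial_latents = spatial_latents,
                 obs_noise = obs_noise, var_specs = var_specs,
                 env_means = env_means, env_scales = env_scales,
                 grid_res = grid_res, placement_res = placement_res,
                 seed = as.integer(seed)),
            class = "truth_config")
}

# Topological order of the directed edges; errors naming a cycle.
topo_order <- function(nodes, edges) {
  edges <- edges[edges$directed, , drop = FALSE]
  order <- character(0)
  remaining <- nodes
  while (length(remaining)) {
    free <- remaining[!remaining %in% edges$target[edges$source %in% remaining]]
    if (!length(free))
      stop(sprintf("cyclic directed edges among: %s",
                   paste(remaining, collapse = " -> ")))
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
  }
  order
}

signed_effect <- function(edges) ifelse(edges$sign == "-", -1, 1) * edges$effect

#' Simulate plant traits from the causal structure
#'
#' Variables are generated in topological order of the directed edge list:
#' each latent trait is a linear combination of its parents' standardized
#' latents plus optional spatially structured noise (a Gaussian random field
#' at the plant locations) plus independent Gaussian noise. Bidirectional
#' edges contribute a shared standard-normal latent to both endpoints.
#' Observed traits are affine transforms of the latents; count traits are
#' rounded and floored at zero. Variables supplied in `fields` (the
#' environmental surfaces sampled at plant locations) are taken as given and
#' their incoming edges are assumed already applied by the surface stage.
#'
#' @param locations Plant coordinate matrix.
#' @param fields Named list of numeric vectors: environmental values at the
#'   plant locations (exogenous to the trait equations).
#' @param truth A [truth_config()].
#' @param seed Integer seed.
#' @return List with `traits` (data frame of observed traits), `latents`
#'   (data frame of the underlying continuous latents).
#' @export
simulate_traits <- function(locations, fields, truth, seed = NULL) {
  stopifnot(inherits(truth, "truth_config"))
  locations <- as_points(locations)
  n <- nrow(locations)
  specs <- truth$var_specs
  edges <- truth$edge_list
  nodes <- specs$name
  ord <- topo_order(unique(c(names(fields), nodes)), edges)
  ord <- ord[ord %in% nodes]
  with_seed(seed, {
    latents <- lapply(fields, function(v) standardize(as.numeric(v), "field"))
    # shared latents for bidirectional relations
    undirected <- edges[!edges$directed, , drop = FALSE]
    shared <- lapply(seq_len(nrow(undirected)), function(i) rnorm(n))
    for (nm in ord) {
      nsd <- if (nm %in% names(truth$noise_sd)) truth$noise_sd[[nm]] else 0.5
      val <- rnorm(n, sd = nsd)
      sl <- truth$spatial_latents[[nm]]
      if (!is.null(sl)) {
        f <- simulate_grf(locations,
                          gp_params(beta = 0, sigma2 = sl$sd^2, phi = sl$phi),
                          seed = NULL, name = nm)
        val <- val + f$values
      }
      din <- edges[edges$directed & edges$target == nm, , drop = FALSE]
      if (nrow(din)) {
        eff <- signed_effect(din)
        for (i in seq_len(nrow(din))) {
          parent <- latents[[din$source[i]]]
          if (is.null(parent))
            stop(sprintf("parent '%s' not yet generated", din$source[i]))
          if (sd(parent) > 0) parent <- (parent - mean(parent)) / sd(parent)
          val <- val + eff[i] * parent
        }
      }
      if (nrow(undirected)) {
        for (i in seq_len(nrow(undirected))) {
          if (nm %in% c(undirected$source[i], undirected$target[i]))
            val <- val + signed_effect(undirected[i, ]) * shared[[i]]
        }
      }
      latents[[nm]] <- val
    }
    traits <- lapply(nodes, function(nm) {
      sp <- specs[specs$name == nm, ]
      obs <- sp$mean + sp$scale * latents[[nm]]
      if (sp$type == "count") pmax(0, round(obs)) else obs
    })
    names(traits) <- nodes
    list(traits = as.data.frame(traits), latents = as.data.frame(latents))
  })
}

# --- end-to-end study ---------------------------------------------------

#' Generate a complete synthetic study
#'
#' Runs the full generative pipeline: Gaussian-random-field environmental
#' surfaces on a simulation grid (soil moisture structurally tied to
#' elevation), habitat-driven plant placement, environmental sampling at
#' random sites with measurement noise, causal trait generation, and
#' spatially clustered line labels. Deterministic under the config seed.
#'
#' @param config A [truth_config()].
#' @param dom A [domain()]; default 40 x 50 m.
#' @return A `synthetic_study` list: `plants` (data frame matching the field
#'   protocol columns), `env_sites` (x, y, elevation, soil_moisture, vpd),
#'   `plant_env` (true environmental values at plant locations),
#'   `surfaces` (observed-scale rasters), `latent_rasters`, `truth` (config
#'   echo with realized sub-seeds), `domain`.
#' @export
generate_study <- function(config = truth_config(), dom = domain()) {
  stopifnot(inherits(config, "truth_config"), inherits(dom, "domain"))
  seeds <- list(
    elevation = derive_seed(config$seed, "surface:elevation"),
    soil_moisture = derive_seed(config$seed, "surface:soil_moisture"),
    vpd = derive_seed(config$seed, "surface:vpd"),
    placement = derive_seed(config$seed, "placement"),
    env_sites = derive_seed(config$seed, "env_sites"),
    env_noise = derive_seed(config$seed, "env_noise"),
    traits = derive_seed(config$seed, "traits"),
    lines = derive_seed(config$seed, "lines"))
  res <- config$grid_res
  gx <- seq(res / 2, dom$width - res / 2, by = res)
  gy <- seq(res / 2, dom$height - res / 2, by = res)
  grid <- as.matrix(expand.grid(x = gx, y = gy))

  elev <- simulate_grf(grid, config$surface_params$elevation,
                       seed = seeds$elevation, name = "elevation")
  elev_std <- standardize(elev$values, "elevation")
  moist_resid <- simulate_grf(grid, config$surface_params$soil_moisture,
                              seed = seeds$soil_moisture, name = "soil_moisture")
  em_edge <- config$edge_list[config$edge_list$source == "elevation" &
                                config$edge_list$target == "soil_moisture", ]
  em_eff <- if (nrow(em_edge)) signed_effect(em_edge)[1] else 0
  moist_latent <- em_eff * elev_std +
    config$noise_sd[["soil_moisture"]] * standardize(moist_resid$values, "sm")
  vpd <- simulate_grf(grid, config$surface_params$vpd, seed = seeds$vpd,
                      name = "vpd")
  vpd_latent <- standardize(vpd$values, "vpd")

  rast <- function(v) surface_raster(gx, gy, matrix(v, length(gx), length(gy)))
  lat_rasters <- list(elevation = rast(elev$values),
                      soil_moisture = rast(moist_latent),
                      vpd = rast(vpd_latent))

  # placement intensity on a fine grid
  px <- seq(config$placement_res / 2, dom$width - config$placement_res / 2,
            by = config$placement_res)
  py <- seq(config$placement_res / 2, dom$height - config$placement_res / 2,
            by = config$placement_res)
  pgrid <- as.matrix(expand.grid(x = px, y = py))
  le <- standardize(bilinear_interp(lat_rasters$elevation, pgrid), "elev")
  lm_ <- standardize(bilinear_interp(lat_rasters$soil_moisture, pgrid), "moist")
  log_int <- config$intensity_link[["elevation"]] * le +
    config$intensity_link[["soil_moisture"]] * lm_
  intensity <- surface_raster(px, py,
                              matrix(exp(log_int), length(px), length(py)))
  plant_xy <- simulate_plant_locations(dom, intensity, config$n_plants,
                                       seed = seeds$placement)

  env_xy <- with_seed(seeds$env_sites, cbind(
    x = runif(config$n_env_sites, 0, dom$width),
    y = runif(config$n_env_sites, 0, dom$height)))

  to_obs <- function(var, latent) {
    if (var == "elevation") return(latent)
    config$env_means[[var]] + config$env_scales[[var]] * latent
  }
  env_true <- lapply(names(lat_rasters), function(v)
    to_obs(v, bilinear_interp(lat_rasters[[v]], env_xy)))
  names(env_true) <- names(lat_rasters)
  env_obs <- with_seed(seeds$env_noise, {
    lapply(names(env_true), function(v)
      env_true[[v]] + rnorm(config$n_env_sites, sd = config$obs_noise[[v]]))
  })
  names(env_obs) <- names(env_true)
  env_sites <- data.frame(x = env_xy[, 1], y = env_xy[, 2],
                          elevation = env_obs$elevation,
                          soil_moisture = env_obs$soil_moisture,
                          vpd = env_obs$vpd)

  plant_fields <- lapply(names(lat_rasters), function(v)
    bilinear_interp(lat_rasters[[v]], plant_xy))
  names(plant_fields) <- names(lat_rasters)
  tr <- simulate_traits(plant_xy, plant_fields, config, seed = seeds$traits)
  line <- assign_lines(plant_xy, config$n_lines, config$dispersal_scale,
                       seed = seeds$lines)

  plants <- data.frame(x = plant_xy[, 1], y = plant_xy[, 2],
                       rosette_diameter = tr$traits$rosette_diameter,
                       stalk_number = tr$traits$stalk_number,
                       stalk_diameter = tr$traits$stalk_diameter,
                       fruit_number = tr$traits$fruit_number,
                       line = line,
                       rosette_herbivory = tr$traits$rosette_herbivory,
                       stalk_herbivory = tr$traits$stalk_herbivory,
                       goldenrod_density = tr$traits$goldenrod_density,
                       dandelion_density = tr$traits$dandelion_density)
  plant_env <- data.frame(x = plant_xy[, 1], y = plant_xy[, 2],
                          elevation = plant_fields$elevation,
                          soil_moisture = to_obs("soil_moisture", plant_fields$soil_moisture),
                          vpd = to_obs("vpd", plant_fields$vpd))
  obs_rasters <- list(
    elevation = lat_rasters$elevation,
    soil_moisture = surface_raster(gx, gy, matrix(
      to_obs("soil_moisture", moist_latent), length(gx), length(gy))),
    vpd = surface_raster(gx, gy, matrix(
      to_obs("vpd", vpd_latent), length(gx), length(gy))))
  truth <- config
  truth$realized_seeds <- seeds
  structure(list(plants = plants, env_sites = env_sites,
                 plant_env = plant_env, surfaces = obs_rasters,
                 latent_rasters = lat_rasters, truth = truth, domain = dom),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d plants, %d env sites on a %g x %g m domain (seed %d)\n",
              nrow(x$plants), nrow(x$env_sites), x$domain$width,
              x$domain$height, x$truth$seed))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Produces `plants.csv`, `env_sites.csv` and `truth.json` (the full config
#' echo including realized sub-seeds and the edge list) in `dir`.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(plants = file.path(dir, "plants.csv"),
             env_sites = file.path(dir, "env_sites.csv"),
             truth = file.path(dir, "truth.json"))
  write.csv(study$plants, paths["plants"], row.names = FALSE)
  write.csv(study$env_sites, paths["env_sites"], row.names = FALSE)
  truth <- study$truth
  truth$surface_params <- lapply(truth$surface_params, unclass)
  truth$var_specs <- as.list(truth$var_specs)
  cfg <- unclass(truth)
  jsonlite::write_json(cfg, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
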