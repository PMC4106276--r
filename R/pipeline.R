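# Pipeline orchestration: simulate -> krige -> sample surfaces at plant
# locations -> correlograms -> pairwise Mantel -> path network, with a
# manifest recording seeds, settings and file digests.

#' Pipeline run configuration
#'
#' Defaults follow the study's stated settings: 2.5-m lag classes, 10,000
#' permutations, 100,000 posterior draws, 90% confidence intervals, P = 0.05
#' significance, a 0.5-m prediction raster. Every randomized stage receives
#' a sub-seed derived from the master seed and recorded in the manifest.
#'
#' @param seed Master seed.
#' @param out_dir Output directory for all stage files.
#' @param n_perm Mantel permutations.
#' @param n_draws Posterior draws for kriging.
#' @param n_boot Bootstrap resamples for edge confidence intervals.
#' @param lag_width Correlogram lag width, meters.
#' @param ci_level Confidence level for intervals.
#' @param alpha Significance level.
#' @param raster_res Prediction raster resolution, meters.
#' @param grid Kriging [parameter_grid()].
#' @param truth [truth_config()] for the simulate stage (its seed is
#'   overridden by the derived stage seed).
#' @param dom Study [domain()].
#' @param env_vars Environmental variables to krige.
#' @param plant_vars Plant variables entering correlograms and the network.
#' @param hypotheses Edge-spec data frame (default [default_hypotheses()]).
#' @param surface_sampling `"bilinear"` or `"nearest"` extraction of kriged
#'   maps at plant locations.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("meadowpath_run_"),
                       n_perm = 10000, n_draws = 100000, n_boot = 1000,
                       lag_width = 2.5, ci_level = 0.90, alpha = 0.05,
                       raster_res = 0.5, grid = parameter_grid(),
                       truth = truth_config(), dom = domain(),
                       env_vars = c("elevation", "soil_moisture", "vpd"),
                       plant_vars = c("rosette_diameter", "stalk_number",
                                      "stalk_diameter", "fruit_number", "line",
                                      "rosette_herbivory", "stalk_herbivory",
                                      "goldenrod_density", "dandelion_density"),
                       hypotheses = default_hypotheses(),
                       surface_sampling = c("bilinear", "nearest")) {
  surface_sampling <- match.arg(surface_sampling)
  structure(list(seed = as.integer(seed), out_dir = out_dir, n_perm = n_perm,
                 n_draws = n_draws, n_boot = n_boot, lag_width = lag_width,
                 ci_level = ci_level, alpha = alpha, raster_res = raster_res,
                 grid = grid, truth = truth, dom = dom, env_vars = env_vars,
                 plant_vars = plant_vars, hypotheses = hypotheses,
                 surface_sampling = surface_sampling),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Only keys present in the file override [run_config()] defaults; nested
#' keys `grid.phi_support`, `grid.tau2rel_support`, `domain.width`,
#' `domain.height` and scalar truth fields (`n_plants`, `n_env_sites`,
#' `n_lines`, `dispersal_scale`) are honored.
#'
#' @param path YAML file path.
#' @param ... Overrides passed straight to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  args <- list(...)
  for (k in c("seed", "out_dir", "n_perm", "n_draws", "n_boot", "lag_width",
              "ci_level", "alpha", "raster_res", "surface_sampling"))
    if (!is.null(y[[k]]) && is.null(args[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$grid))
    args$grid <- parameter_grid(
      phi_support = y$grid$phi_support %||% parameter_grid()$phi_support,
      tau2rel_support = y$grid$tau2rel_support %||% parameter_grid()$tau2rel_support)
  if (!is.null(y$domain))
    args$dom <- domain(y$domain$width %||% 40, y$domain$height %||% 50)
  if (!is.null(y$truth)) {
    targs <- y$truth[intersect(names(y$truth),
                               c("n_plants", "n_env_sites", "n_lines",
                                 "dispersal_scale", "seed"))]
    args$truth <- do.call(truth_config, targs)
  }
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a kriged surface at point locations
#'
#' Bilinear (default) or nearest-node interpolation of the predictive mean
#' raster produced by [krige_predict()] on a regular grid. Points more than
#' one grid cell outside the raster are an error.
#'
#' @param points Two-column coordinate matrix.
#' @param surface Either a `surface_raster` or a [krige_predict()] data
#'   frame on a regular grid.
#' @param mode `"bilinear"` or `"nearest"`.
#' @return Numeric vector of interpolated predictive means.
#' @export
sample_surface_at <- function(points, surface, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  if (!inherits(surface, "surface_raster")) {
    stopifnot(all(c("x", "y", "pred_mean") %in% names(surface)))
    gx <- sort(unique(surface$x)); gy <- sort(unique(surface$y))
    if (nrow(surface) != length(gx) * length(gy))
      stop("surface is not on a regular grid")
    v <- matrix(NA_real_, length(gx), length(gy))
    v[cbind(match(surface$x, gx), match(surface$y, gy))] <- surface$pred_mean
    surface <- surface_raster(gx, gy, v)
  }
  if (mode == "bilinear") return(bilinear_interp(surface, points))
  pts <- as_points(points)
  ix <- vapply(pts[, 1], function(p) which.min(abs(surface$x - p)), 0L)
  iy <- vapply(pts[, 2], function(p) which.min(abs(surface$y - p)), 0L)
  surface$values[cbind(ix, iy)]
}

#' Krige one environmental variable from sampled sites
#'
#' Fits the discrete posterior, draws parameters, and predicts the surface
#' on a regular raster over the domain.
#'
#' @param env_sites Data frame with `x`, `y` and the variable column.
#' @param variable Column name to interpolate.
#' @param dom A [domain()].
#' @param grid A [parameter_grid()].
#' @param n_draws Posterior draws.
#' @param raster_res Raster resolution in meters.
#' @param seed Integer seed.
#' @param loo Run leave-one-out validation as well.
#' @return List with `posterior` (table), `draws`, `surface` (prediction
#'   data frame), `loo` (leave-one-out table or `NULL`).
#' @export
krige_surface <- function(env_sites, variable, dom = domain(),
                          grid = parameter_grid(), n_draws = 100000,
                          raster_res = 0.5, seed = NULL, loo = TRUE) {
  field <- spatial_field(env_sites[, c("x", "y")], env_sites[[variable]],
                         name = variable)
  post <- log_marginal_posterior(field, grid)
  draws <- sample_posterior(post, n_draws = n_draws, seed = seed)
  rx <- seq(0, dom$width, by = raster_res)
  ry <- seq(0, dom$height, by = raster_res)
  nodes <- as.matrix(expand.grid(x = rx, y = ry))
  surface <- krige_predict(field, draws, nodes)
  list(posterior = post, draws = draws, surface = surface,
       loo = if (loo) loo_validate(field, grid) else NULL)
}

write_stage_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-study generation, Bayesian kriging of each
#' environmental variable (with leave-one-out validation), extraction of the
#' kriged maps at the plant locations, per-variable Mantel correlograms,
#' pairwise simple Mantel tests, and the path-network evaluation. All stage
#' outputs land in `config$out_dir`; `manifest.json` records settings,
#' derived stage seeds and an MD5 digest of every output file. Two runs
#' with the same master seed produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # simulate
  truth <- config$truth
  truth$seed <- derive_seed(config$seed, "simulate")
  study <- stage("simulate", generate_study(truth, config$dom))
  files <- c(files, write_study(study, config$out_dir))

  # krige environmental surfaces
  plant_env <- study$plants[, c("x", "y")]
  kriged <- list()
  for (v in config$env_vars) {
    k <- stage(paste0("krige:", v), krige_surface(
      study$env_sites, v, dom = config$dom, grid = config$grid,
      n_draws = config$n_draws, raster_res = config$raster_res,
      seed = derive_seed(config$seed, paste0("krige:", v))))
    kriged[[v]] <- k
    files <- c(files,
               write_stage_csv(k$surface, out(sprintf("surface_%s.csv", v))),
               write_stage_csv(k$posterior[, c("phi", "tau2_rel", "mass")],
                               out(sprintf("posterior_%s.csv", v))),
               write_stage_csv(k$loo, out(sprintf("loo_%s.csv", v))))
    plant_env[[v]] <- stage(paste0("sample:", v), sample_surface_at(
      as.matrix(study$plants[, c("x", "y")]), k$surface,
      mode = config$surface_sampling))
  }
  analysis <- cbind(plant_env,
                    study$plants[, setdiff(names(study$plants), c("x", "y"))])
  files <- c(files, write_stage_csv(analysis, out("plants_env.csv")))

  # correlograms
  all_vars <- c(config$env_vars, config$plant_vars)
  cg <- stage("correlogram", variable_correlograms(
    analysis, all_vars, lag_width = config$lag_width,
    n_perm = config$n_perm, alpha = config$alpha,
    seed = derive_seed(config$seed, "correlogram")))
  for (v in all_vars)
    files <- c(files, write_stage_csv(
      cg$correlograms[[v]], out(sprintf("correlogram_%s.csv", v))))

  # pairwise simple Mantel tests
  pairs <- combn(all_vars, 2)
  mp_seed <- derive_seed(config$seed, "mantel_pairs")
  dmats <- lapply(setNames(all_vars, all_vars),
                  function(v) variable_dmat(analysis, v))
  mantel_pairs <- stage("mantel", do.call(rbind, lapply(
    seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      res <- mantel(dmats[[a]], dmats[[b]], n_perm = config$n_perm,
                    seed = derive_seed(mp_seed, paste(a, b)),
                    alternative = "two.sided")
      data.frame(varA = a, varB = b, r = res$r, p_value = res$p_value,
                 stringsAsFactors = FALSE)
    })))
  files <- c(files, write_stage_csv(mantel_pairs, out("mantel_pairs.csv")))

  # path network
  hyp <- stage("path", build_hypotheses(all_vars, config$hypotheses))
  net <- stage("path", evaluate_network(
    analysis, hyp, ranges = cg$ranges, n_perm = config$n_perm,
    n_boot = config$n_boot, ci_level = config$ci_level, alpha = config$alpha,
    seed = derive_seed(config$seed, "path")))
  export_network(net, out("network.json"), out("network_edges.csv"))
  files <- c(files, out("network.json"), out("network_edges.csv"))

  manifest <- list(
    package = "meadowpath",
    version = as.character(utils::packageVersion("meadowpath")),
    master_seed = config$seed,
    stage_seeds = list(
      simulate = derive_seed(config$seed, "simulate"),
      krige = setNames(lapply(config$env_vars, function(v)
        derive_seed(config$seed, paste0("krige:", v))), config$env_vars),
      correlogram = derive_seed(config$seed, "correlogram"),
      mantel_pairs = mp_seed,
      path = derive_seed(config$seed, "path")),
    settings = config[c("n_perm", "n_draws", "n_boot", "lag_width",
                        "ci_level", "alpha", "raster_res", "surface_sampling")],
    files = {
      sums <- tools::md5sum(unname(files))
      names(sums) <- basename(unname(files))
      as.list(sums)
    })
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(study = study, kriged = kriged, analysis = analysis,
                 correlograms = cg, mantel_pairs = mantel_pairs, network = net,
                 manifest = manifest, out_dir = config$out_dir))
}

#' Verify a pipeline manifest
#'
#' Recomputes the MD5 digest of every file listed in a run's manifest and
#' reports mismatches (tampered or missing outputs).
#'
#' @param out_dir A pipeline output directory containing `manifest.json`.
#' @return Logical: `TRUE` when all digests match; attribute `mismatches`
#'   lists offending files.
#' @export
verify_manifest <- function(out_dir) {
  man <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect <- unlist(man$files)
  got <- tools::md5sum(file.path(out_dir, names(expect)))
  bad <- names(expect)[is.na(got) | got != expect]
  structure(length(bad) == 0L, mismatches = bad)
}
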