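test_that("neighbor counts use a closed ball", {
  focal <- rbind(c(0, 0))
  nb <- rbind(c(0.1, 0), c(0.2, 0))
  expect_equal(neighbor_counts(focal, nb, 0.15), 1L)
  # boundary neighbor at exactly the radius is counted
  expect_equal(neighbor_counts(focal, rbind(c(0.15, 0)), 0.15), 1L)
  expect_equal(neighbor_counts(rbind(c(0, 0), c(5, 5)), NULL, 0.15), c(0L, 0L))
  expect_error(neighbor_counts(focal, nb, 0), "radius")
})

test_that("plant placement follows the intensity surface", {
  dom <- domain(40, 50)
  gx <- seq(0.25, 39.75, by = 0.5); gy <- seq(0.25, 49.75, by = 0.5)
  # left-half-only intensity confines every plant to the left half
  v <- matrix(0, length(gx), length(gy)); v[gx < 20, ] <- 1
  left <- simulate_plant_locations(dom, meadowpath:::surface_raster(gx, gy, v),
                                   200, seed = 3)
  expect_equal(nrow(left), 200)
  expect_true(all(left[, 1] <= 20))
  expect_equal(nrow(simulate_plant_locations(
    dom, meadowpath:::surface_raster(gx, gy, v), 0, seed = 1)), 0)
  expect_error(simulate_plant_locations(
    dom, meadowpath:::surface_raster(gx, gy, v * 0), 10, seed = 1), "zero")
  # uniform intensity: quadrat-count chi-square rarely rejects at alpha = 0.01
  u <- meadowpath:::surface_raster(gx, gy, matrix(1, length(gx), length(gy)))
  keeps <- vapply(1:20, function(s) {
    pts <- simulate_plant_locations(dom, u, 234, seed = 100 + s)
    qx <- cut(pts[, 1], seq(0, 40, by = 10)); qy <- cut(pts[, 2], seq(0, 50, by = 10))
    suppressWarnings(stats::chisq.test(as.vector(table(qx, qy)),
                                       p = rep(1 / 20, 20))$p.value) > 0.01
  }, TRUE)
  expect_gte(sum(keeps), 18)
})

test_that("line labels are spatially clustered and respect their limits", {
  locs <- random_points(120, seed = 11)
  expect_error(assign_lines(locs, 0, 3), "n_lines")
  expect_equal(unique(assign_lines(locs, 1, 3, seed = 1)), 1L)
  # n_lines = n: every plant is its own founder
  expect_equal(sort(assign_lines(locs, 120, 3, seed = 2)), 1:120)
  # infinite dispersal scale: deterministic nearest-founder labels
  v1 <- assign_lines(locs, 8, Inf, seed = 5)
  v2 <- assign_lines(locs, 8, Inf, seed = 5)
  expect_identical(v1, v2)
  expect_equal(sort(unique(v1)), 1:8)
  # join-count: like-labeled nearest neighbors exceed the permutation null
  lab <- assign_lines(locs, 8, 3, seed = 7)
  d <- meadowpath:::cross_dist(locs, locs); diag(d) <- Inf
  nn <- max.col(-d, ties.method = "first")
  observed <- mean(lab == lab[nn])
  null <- vapply(1:200, function(s) {
    p <- meadowpath:::with_seed(1000 + s, sample(lab))
    mean(p == p[nn])
  }, 0)
  expect_gt(observed, mean(null))
})

test_that("trait generation follows the declared causal structure", {
  locs <- random_points(150, seed = 12)
  # large single effect with no noise: child is a deterministic parent image
  cfg <- truth_config(
    edge_list = data.frame(source = "rosette_diameter", target = "stalk_number",
                           sign = "+", effect = 0.9, directed = TRUE),
    noise_sd = c(rosette_diameter = 1, stalk_number = 0),
    spatial_latents = list(), seed = 3)
  fields <- list(elevation = rnorm(150), soil_moisture = rnorm(150),
                 vpd = rnorm(150))
  tr <- simulate_traits(locs, fields, cfg, seed = 5)
  expect_equal(cor(tr$latents$rosette_diameter, tr$latents$stalk_number), 1)
  expect_gt(cor(tr$traits$rosette_diameter, tr$traits$stalk_number), 0.9)
  # all-zero effects: traits uncorrelated within null bounds
  cfg0 <- truth_config(
    edge_list = within(default_edge_list(), effect <- 0),
    spatial_latents = list(), seed = 4)
  tr0 <- simulate_traits(locs, fields, cfg0, seed = 6)
  cm <- cor(tr0$latents)
  off <- abs(cm[upper.tri(cm)])
  expect_lt(max(off), 4 / sqrt(150))
  # cyclic edges are refused with the cycle named
  bad <- truth_config(edge_list = data.frame(
    source = c("rosette_diameter", "stalk_number"),
    target = c("stalk_number", "rosette_diameter"),
    sign = "+", effect = 0.5, directed = TRUE), seed = 1)
  expect_error(simulate_traits(locs, fields, bad, seed = 1), "cyclic")
})

test_that("negative edges and count links preserve sign structure and integrality", {
  locs <- random_points(200, seed = 13)
  st <- generate_study(truth_config(seed = 21))
  p <- st$plants
  counts <- c("stalk_number", "fruit_number", "rosette_herbivory",
              "stalk_herbivory", "goldenrod_density", "dandelion_density")
  for (v in counts) {
    expect_true(all(p[[v]] >= 0), info = v)
    expect_true(all(p[[v]] == round(p[[v]])), info = v)
  }
  expect_lt(cor(st$plant_env$elevation, st$plant_env$soil_moisture), -0.3)
  expect_lt(cor(p$stalk_herbivory, p$fruit_number), 0)
  expect_gt(cor(p$dandelion_density, p$rosette_herbivory), 0.3)
})

test_that("study generation is deterministic, respects the domain, and writes stable files", {
  cfg <- small_truth(seed = 31)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$plants, s2$plants)
  expect_identical(s1$env_sites, s2$env_sites)
  s3 <- generate_study(small_truth(seed = 32))
  expect_false(isTRUE(all.equal(s1$plants$x, s3$plants$x)))
  expect_equal(nrow(s1$plants), 80)
  expect_equal(nrow(s1$env_sites), 40)
  expect_true(all(s1$plants$x >= 0 & s1$plants$x <= 40))
  expect_true(all(s1$plants$y >= 0 & s1$plants$y <= 50))
  expect_true(all(s1$plants$line %in% 1:5))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  for (f in c("plants.csv", "env_sites.csv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("the default study reproduces the field campaign's shape", {
  st <- generate_study(truth_config(seed = 1))
  expect_equal(nrow(st$plants), 234)
  expect_equal(nrow(st$env_sites), 71)
  expect_equal(st$domain$width, 40)
  expect_equal(st$domain$height, 50)
  expect_named(st$plants, c("x", "y", "rosette_diameter", "stalk_number",
                            "stalk_diameter", "fruit_number", "line",
                            "rosette_herbivory", "stalk_herbivory",
                            "goldenrod_density", "dandelion_density"))
})
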