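test_that("hypothesis compilation builds conditioning sets and rejects malformed specs", {
  vars <- c("A", "B", "C", "D")
  expect_identical(build_hypotheses(vars, data.frame()), list())
  chain <- data.frame(source = c("A", "B", "A"), target = c("B", "C", "C"),
                      sign = "+", directed = TRUE)
  hyp <- build_hypotheses(vars, chain)
  ac <- hyp[[3]]
  expect_equal(ac$source, "A"); expect_equal(ac$target, "C")
  expect_equal(ac$conditioning, "B")   # the mediator is held constant
  allmode <- build_hypotheses(vars, chain, conditioning = "all")
  expect_setequal(allmode[[3]]$conditioning, c("B", "D"))
  expect_error(build_hypotheses(vars, data.frame(source = "A", target = "A",
                                                 sign = "+", directed = TRUE)),
               "self")
  expect_error(build_hypotheses(vars, data.frame(source = c("A", "A"),
                                                 target = c("B", "B"),
                                                 sign = "+", directed = TRUE)),
               "duplicate")
  expect_error(build_hypotheses(vars, data.frame(source = "A", target = "Z",
                                                 sign = "+", directed = TRUE)),
               "unknown")
  expect_error(build_hypotheses(vars, data.frame(source = "A", target = "B",
                                                 sign = "", directed = TRUE)),
               "sign")
})

test_that("an irrelevant conditioning variable leaves the partial r near the simple r", {
  set.seed(41)
  n <- 120
  dat <- data.frame(x = runif(n, 0, 40), y = runif(n, 0, 50))
  dat$A <- rnorm(n); dat$B <- dat$A + rnorm(n, sd = 0.4); dat$C <- rnorm(n)
  hyp <- build_hypotheses(c("A", "B", "C"),
                          data.frame(source = c("A", "C"), target = c("B", "B"),
                                     sign = "+", directed = TRUE))
  ranges <- c(A = NA_real_, B = NA_real_, C = NA_real_)
  net <- evaluate_network(dat, hyp, ranges, n_perm = 499, n_boot = 100, seed = 3)
  simple <- mantel(euclidean_dmat(standardize(dat$A)),
                   euclidean_dmat(standardize(dat$B)), n_perm = 9, seed = 1)$r
  eAB <- net$edges[net$edges$source == "A", ]
  expect_equal(eAB$r, simple, tolerance = 0.05)
  expect_true(eAB$retained)
  expect_equal(eAB$sign, "+")
  # nothing autocorrelated: space never enters
  expect_true(all(!net$edges$space_included))
  expect_true(all(is.na(net$nodes$range_m)))
})

test_that("space conditioning is governed by the correlogram ranges", {
  set.seed(43)
  n <- 60
  dat <- data.frame(x = runif(n, 0, 40), y = runif(n, 0, 50),
                    A = rnorm(n), B = rnorm(n))
  hyp <- build_hypotheses(c("A", "B"),
                          data.frame(source = "A", target = "B", sign = "+",
                                     directed = TRUE))
  with_r <- evaluate_network(dat, hyp, c(A = 5, B = NA_real_), n_perm = 99,
                             n_boot = 100, seed = 2)
  without_r <- evaluate_network(dat, hyp, c(A = NA_real_, B = NA_real_),
                                n_perm = 99, n_boot = 100, seed = 2)
  expect_true(with_r$edges$space_included)
  expect_false(without_r$edges$space_included)
})

test_that("signed arrows recover the direction of negative relations", {
  set.seed(47)
  n <- 150
  dat <- data.frame(x = runif(n, 0, 40), y = runif(n, 0, 50))
  dat$elev <- rnorm(n); dat$moist <- -0.9 * dat$elev + rnorm(n, sd = 0.4)
  hyp <- build_hypotheses(c("elev", "moist"),
                          data.frame(source = "elev", target = "moist",
                                     sign = "-", directed = TRUE))
  net <- evaluate_network(dat, hyp, c(elev = NA_real_, moist = NA_real_),
                          n_perm = 499, n_boot = 100, seed = 5)
  e <- net$edges[1, ]
  expect_true(e$retained)      # association detected on the distance scale
  expect_gt(e$r, 0)            # distances cannot carry the sign ...
  expect_equal(e$sign, "-")    # ... the value-scale partial correlation does
})

test_that("zero-variance variables are dropped with a warning, not an error", {
  set.seed(51)
  n <- 40
  dat <- data.frame(x = runif(n, 0, 40), y = runif(n, 0, 50),
                    A = rnorm(n), B = rnorm(n), Z = 1)
  hyp <- build_hypotheses(c("A", "B", "Z"),
                          data.frame(source = c("A", "Z"), target = c("B", "B"),
                                     sign = "+", directed = TRUE))
  expect_warning(net <- evaluate_network(dat, hyp,
                                         c(A = NA_real_, B = NA_real_, Z = NA_real_),
                                         n_perm = 49, n_boot = 100, seed = 1),
                 "zero-variance")
  expect_equal(nrow(net$edges), 1)   # the Z edge is skipped
})

test_that("networks are deterministic under a fixed seed and round-trip through JSON", {
  set.seed(53)
  n <- 50
  dat <- data.frame(x = runif(n, 0, 40), y = runif(n, 0, 50),
                    A = rnorm(n), B = rnorm(n))
  dat$B <- dat$B + 0.8 * dat$A
  hyp <- build_hypotheses(c("A", "B"),
                          data.frame(source = "A", target = "B", sign = "+",
                                     directed = TRUE))
  rg <- c(A = NA_real_, B = NA_real_)
  n1 <- evaluate_network(dat, hyp, rg, n_perm = 199, n_boot = 120, seed = 9)
  n2 <- evaluate_network(dat, hyp, rg, n_perm = 199, n_boot = 120, seed = 9)
  expect_identical(n1$edges, n2$edges)
  path <- withr::local_tempfile(fileext = ".json")
  export_network(n1, path)
  back <- read_network(path)
  expect_equal(back$edges, n1$edges, tolerance = 1e-12)
  expect_equal(back$nodes$variable, n1$nodes$variable)
  # empty network round-trips too
  empty <- evaluate_network(dat, list(), rg, n_perm = 9, n_boot = 100, seed = 1)
  expect_equal(nrow(empty$edges), 0)
  p2 <- withr::local_tempfile(fileext = ".json")
  export_network(empty, p2)
  expect_equal(nrow(read_network(p2)$edges), 0)
})
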