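# Model-based Bayesian kriging under the hierarchical Gaussian process
#
#   level 1:  Y_i | S ~ N(beta + S(x_i), tau^2)
#   level 2:  S(x)    ~ stationary GP, mean 0, variance sigma^2,
#                       correlation R(h; phi) = exp(-h / phi)
#   level 3:  flat priors on beta, phi and tau2_rel = tau^2 / sigma^2,
#             reciprocal prior on sigma^2
#
# beta and sigma^2 are marginalized analytically; (phi, tau2_rel) live on a
# discrete grid whose normalized masses form the posterior sampled by
# sample_posterior().

#' Parameters of the hierarchical Gaussian spatial process
#'
#' @param beta Constant trend mean, in the units of the variable.
#' @param sigma2 Partial sill (variance of the spatially structured
#'   component); must be positive.
#' @param phi Correlation scale in meters; the effective range of spatial
#'   autocorrelation is `3 * phi` (correlation has decayed to about 5%).
#' @param tau2_rel Relative nugget `tau^2 / sigma^2`, dimensionless,
#'   non-negative. The nugget absorbs measurement error and variation below
#'   the sampling grain.
#' @return An object of class `gp_params`.
#' @examples
#' gp_params(beta = 0, sigma2 = 1, phi = 5, tau2_rel = 0.25)
#' @export
gp_params <- function(beta = 0, sigma2 = 1, phi = 1, tau2_rel = 0) {
  stopifnot(is.finite(beta), is.finite(sigma2), is.finite(phi), is.finite(tau2_rel))
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (phi <= 0) stop("phi must be > 0")
  if (tau2_rel < 0) stop("tau2_rel must be >= 0")
  structure(list(beta = beta, sigma2 = sigma2, phi = phi, tau2_rel = tau2_rel),
            class = "gp_params")
}

#' @export
print.gp_params <- function(x, ...) {
  cat(sprintf("Gaussian process: beta = %g, sigma2 = %g, phi = %g m (range %g m), tau2_rel = %g\n",
              x$beta, x$sigma2, x$phi, 3 * x$phi, x$tau2_rel))
  invisible(x)
}

#' Point observations of one spatial variable
#'
#' @param locations Two-column matrix or data frame of (x, y) coordinates in
#'   meters.
#' @param values Numeric vector, one observation per location.
#' @param name Variable label.
#' @return An object of class `spatial_field`.
#' @export
spatial_field <- function(locations, values, name = "value") {
  locations <- as_points(locations)
  values <- as.numeric(values)
  if (nrow(locations) != length(values))
    stop("locations and values must have equal length")
  if (anyNA(values)) stop("values must not contain NA")
  structure(list(locations = locations, values = values, name = name),
            class = "spatial_field")
}

#' @export
print.spatial_field <- function(x, ...) {
  cat(sprintf("spatial_field '%s': %d locations, value range [%g, %g]\n",
              x$name, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Exponential correlation function
#'
#' `R(h; phi) = exp(-h / phi)`: correlation 1 at distance 0, `exp(-1)` at
#' `h = phi`, and about 0.05 at the effective range `h = 3 * phi`.
#'
#' @param h Non-negative lag distance(s), meters.
#' @param phi Correlation scale, meters, positive.
#' @return Correlation value(s) in (0, 1].
#' @examples
#' exp_correlation(0, 5)       # 1
#' exp_correlation(15, 5)      # exp(-3), ~0.05 at the effective range
#' @export
exp_correlation <- function(h, phi) {
  if (any(!is.finite(phi)) || any(phi <= 0)) stop("phi must be > 0")
  if (any(!is.finite(h)) || any(h < 0)) stop("h must be >= 0")
  exp(-h / phi)
}

#' Covariance matrix of the observation vector
#'
#' Entry (i, j) is `sigma2 * exp(-h_ij / phi)` off the diagonal and
#' `sigma2 * (1 + tau2_rel)` on it (the nugget enters the diagonal only).
#'
#' @param locations Two-column coordinate matrix.
#' @param params A [gp_params()] object.
#' @return Symmetric covariance matrix.
#' @export
covariance_matrix <- function(locations, params) {
  stopifnot(inherits(params, "gp_params"))
  locations <- as_points(locations)
  h <- cross_dist(locations, locations)
  m <- params$sigma2 * exp(-h / params$phi)
  diag(m) <- params$sigma2 * (1 + params$tau2_rel)
  m
}

# Cholesky with escalating diagonal jitter: start at 1e-10 * scale,
# escalate x10 up to 1e-6 * scale, then fail with a condition diagnostic.
chol_jitter <- function(m, scale = mean(diag(m))) {
  r <- tryCatch(chol(m), error = function(e) NULL)
  if (!is.null(r)) return(r)
  jit <- 1e-10 * scale
  while (jit <= 1e-6 * scale) {
    r <- tryCatch(chol(m + diag(jit, nrow(m))), error = function(e) NULL)
    if (!is.null(r)) return(r)
    jit <- jit * 10
  }
  stop(sprintf(
    "covariance matrix not positive definite after jitter up to %.1e (reciprocal condition %.3e)",
    1e-6 * scale, rcond(m)))
}

#' Discrete support for the correlation-scale and relative-nugget posterior
#'
#' Defaults: 20 log-spaced phi values on [0.5, 25] m and tau2_rel on
#' 0, 0.05, ..., 1. Flat priors are uniform over the supplied support.
#'
#' @param phi_support Strictly increasing positive phi candidates, meters.
#' @param tau2rel_support Strictly increasing non-negative relative-nugget
#'   candidates.
#' @return An object of class `parameter_grid`.
#' @export
parameter_grid <- function(phi_support = exp(seq(log(0.5), log(25), length.out = 20)),
                           tau2rel_support = seq(0, 1, by = 0.05)) {
  phi_support <- as.numeric(phi_support)
  tau2rel_support <- as.numeric(tau2rel_support)
  if (!length(phi_support) || any(phi_support <= 0) || is.unsorted(phi_support, strictly = TRUE))
    stop("phi_support must be nonempty, positive and strictly increasing")
  if (!length(tau2rel_support) || any(tau2rel_support < 0) ||
      is.unsorted(tau2rel_support, strictly = TRUE))
    stop("tau2rel_support must be nonempty, non-negative and strictly increasing")
  structure(list(phi_support = phi_support, tau2rel_support = tau2rel_support),
            class = "parameter_grid")
}

# Per-grid-point sufficient statistics with beta and sigma^2 marginalized.
# Returns logdet(V), S11 = 1'V^-1 1, S1y, Syy, beta_hat, Qhat, where V is the
# correlation-scale covariance R + tau2_rel * I.
grid_point_stats <- function(h, y, phi, tau2_rel) {
  v <- exp(-h / phi)
  diag(v) <- 1 + tau2_rel
  r <- chol_jitter(v, scale = 1 + tau2_rel)
  one <- rep(1, length(y))
  u <- backsolve(r, forwardsolve(t(r), cbind(one, y)))
  s11 <- sum(u[, 1]); s1y <- sum(u[, 2]); syy <- sum(y * u[, 2])
  beta_hat <- s1y / s11
  qhat <- syy - s1y^2 / s11
  list(logdet = 2 * sum(log(diag(r))), s11 = s11, beta_hat = beta_hat,
       qhat = max(qhat, .Machine$double.eps))
}

#' Discrete posterior over (phi, tau2_rel) with analytic marginalization
#'
#' For every grid point the trend mean (flat prior) and partial sill
#' (reciprocal prior) are integrated out in closed form, giving the exact
#' log marginal density
#' `-(n-1)/2 log(2 pi) - 1/2 log|V| - 1/2 log(1'V^-1 1) + lgamma((n-1)/2)
#'  - (n-1)/2 log(Qhat/2)`,
#' where `V` is the correlation-scale covariance and `Qhat` the generalized
#' residual sum of squares at the GLS trend estimate. Masses are the
#' normalized exponentials over the grid.
#'
#' @param field A [spatial_field()] with at least 3 distinct locations.
#' @param grid A [parameter_grid()].
#' @return A data frame of class `posterior_table` with columns `phi`,
#'   `tau2_rel`, `log_density` (full log marginal, constants included),
#'   `mass`, and the conditional summaries `beta_hat`, `s11`, `qhat`;
#'   attributes carry `n` and the field.
#' @export
log_marginal_posterior <- function(field, grid = parameter_grid()) {
  stopifnot(inherits(field, "spatial_field"), inherits(grid, "parameter_grid"))
  n <- length(field$values)
  if (n < 3) stop("need at least 3 observations")
  h <- cross_dist(field$locations, field$locations)
  if (max(h) == 0) stop("degenerate design: all locations coincident")
  y <- field$values
  pts <- expand.grid(phi = grid$phi_support, tau2_rel = grid$tau2rel_support,
                     KEEP.OUT.ATTRS = FALSE)
  const <- -(n - 1) / 2 * log(2 * pi) + lgamma((n - 1) / 2)
  stats <- lapply(seq_len(nrow(pts)), function(k) {
    s <- grid_point_stats(h, y, pts$phi[k], pts$tau2_rel[k])
    c(log_density = const - 0.5 * s$logdet - 0.5 * log(s$s11) -
        (n - 1) / 2 * log(s$qhat / 2),
      beta_hat = s$beta_hat, s11 = s$s11, qhat = s$qhat)
  })
  stats <- do.call(rbind, stats)
  tab <- cbind(pts, as.data.frame(stats))
  ld <- tab$log_density
  tab$mass <- exp(ld - max(ld)) / sum(exp(ld - max(ld)))
  class(tab) <- c("posterior_table", "data.frame")
  attr(tab, "n") <- n
  attr(tab, "field") <- field
  tab
}

#' @export
print.posterior_table <- function(x, ...) {
  i <- which.max(x$mass)
  cat(sprintf("posterior_table: %d grid points over (phi, tau2_rel); mode phi = %.3g m, tau2_rel = %.3g (mass %.3f)\n",
              nrow(x), x$phi[i], x$tau2_rel[i], x$mass[i]))
  invisible(x)
}

#' Draw parameters from the discrete posterior
#'
#' Samples `(phi, tau2_rel)` from the normalized grid masses, then for each
#' draw `sigma^2` from its scaled inverse-chi-square conditional
#' (`Qhat / sigma^2 ~ chi^2_{n-1}`) and `beta` from its Gaussian conditional
#' `N(beta_hat, sigma^2 / (1'V^-1 1))`.
#'
#' @param table A `posterior_table`.
#' @param n_draws Number of posterior draws (the study default is 100000).
#' @param seed Integer seed.
#' @return Data frame with columns `phi`, `tau2_rel`, `sigma2`, `beta`.
#' @export
sample_posterior <- function(table, n_draws = 100000, seed = NULL) {
  stopifnot(inherits(table, "posterior_table"))
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (abs(sum(table$mass) - 1) > 1e-10) stop("posterior table is not normalized")
  n <- attr(table, "n")
  with_seed(seed, {
    idx <- sample.int(nrow(table), n_draws, replace = TRUE, prob = table$mass)
    sigma2 <- table$qhat[idx] / rchisq(n_draws, df = n - 1)
    beta <- rnorm(n_draws, mean = table$beta_hat[idx],
                  sd = sqrt(sigma2 / table$s11[idx]))
    data.frame(phi = table$phi[idx], tau2_rel = table$tau2_rel[idx],
               sigma2 = sigma2, beta = beta, grid_index = idx)
  })
}

#' Kriging prediction from posterior draws
#'
#' For each draw the conditional Gaussian predictive mean and variance of the
#' observable (signal plus nugget) are computed at every new location; the
#' returned mean is the average of draw means and the returned variance
#' combines within-draw variance and between-draw spread (law of total
#' variance). Draws sharing a `(phi, tau2_rel)` grid point share their
#' kriging weights, so large draw counts cost little.
#'
#' @param field The observed [spatial_field()].
#' @param draws Data frame from [sample_posterior()].
#' @param new_locations Two-column coordinate matrix of prediction points.
#' @return Data frame with `x`, `y`, `pred_mean`, `pred_var` and an
#'   `n_draws` attribute.
#' @export
krige_predict <- function(field, draws, new_locations) {
  stopifnot(inherits(field, "spatial_field"))
  new_locations <- as_points(new_locations)
  if (!nrow(draws)) stop("no posterior draws supplied")
  if (!nrow(new_locations)) stop("no prediction locations supplied")
  if (!length(field$values)) stop("cannot predict from an empty field")
  y <- field$values
  h <- cross_dist(field$locations, field$locations)
  h0 <- cross_dist(new_locations, field$locations)
  m <- nrow(new_locations)
  key <- paste(draws$phi, draws$tau2_rel)
  sum_mean <- numeric(m); sum_mean2 <- numeric(m); sum_var <- numeric(m)
  for (k in unique(key)) {
    sel <- key == k
    phi <- draws$phi[sel][1]; tau <- draws$tau2_rel[sel][1]
    nd <- sum(sel)
    sb <- sum(draws$beta[sel]); sb2 <- sum(draws$beta[sel]^2)
    ss <- sum(draws$sigma2[sel])
    v <- exp(-h / phi); diag(v) <- 1 + tau
    r <- chol_jitter(v, scale = 1 + tau)
    a <- backsolve(r, forwardsolve(t(r), cbind(1, y)))
    r0 <- exp(-h0 / phi)                       # m x n cross-correlations
    w1 <- drop(r0 %*% a[, 1])                  # r0' V^-1 1
    wy <- drop(r0 %*% a[, 2])                  # r0' V^-1 y
    c0 <- rowSums((r0 %*% chol2inv(r)) * r0)   # r0' V^-1 r0
    u <- 1 - w1
    # draw d mean = wy + beta_d * u; accumulate its first two moments
    sum_mean  <- sum_mean  + nd * wy + sb * u
    sum_mean2 <- sum_mean2 + nd * wy^2 + 2 * wy * u * sb + u^2 * sb2
    sum_var   <- sum_var   + ss * pmax(1 + tau - c0, 0)
  }
  nd_tot <- nrow(draws)
  pred_mean <- sum_mean / nd_tot
  pred_var <- sum_var / nd_tot + pmax(sum_mean2 / nd_tot - pred_mean^2, 0)
  out <- data.frame(x = new_locations[, 1], y = new_locations[, 2],
                    pred_mean = pred_mean, pred_var = pmax(pred_var, 0))
  attr(out, "n_draws") <- nd_tot
  out
}

#' Leave-one-out cross-validation of the kriging model
#'
#' Each observation is predicted from the remaining `n - 1`. With
#' `method = "refit"` (default) the discrete posterior is re-derived for
#' every fold; the refit is computed exactly through rank-one downdates of
#' the full-data per-grid-point quantities, so it matches literally refitting
#' on `n - 1` points while costing a single Cholesky per grid point. The
#' predictive mean and variance are the exact posterior mixture over the
#' grid (beta and sigma^2 marginalized), making the output deterministic.
#' `method = "shared"` reuses the full-data posterior masses for every fold.
#'
#' @param field A [spatial_field()] with `n >= 4`.
#' @param grid A [parameter_grid()].
#' @param method `"refit"` or `"shared"`.
#' @return Data frame with `observed`, `pred_mean`, `pred_var`,
#'   `std_resid = (observed - pred_mean) / sqrt(pred_var)`; the method is
#'   recorded as an attribute.
#' @export
loo_validate <- function(field, grid = parameter_grid(),
                         method = c("refit", "shared")) {
  stopifnot(inherits(field, "spatial_field"))
  method <- match.arg(method)
  n <- length(field$values)
  if (n < 4) stop("need at least 4 observations for leave-one-out validation")
  y <- field$values
  one <- rep(1, n)
  h <- cross_dist(field$locations, field$locations)
  pts <- expand.grid(phi = grid$phi_support, tau2_rel = grid$tau2rel_support,
                     KEEP.OUT.ATTRS = FALSE)
  g <- nrow(pts)
  ld <- matrix(0, n, g)    # per-fold log marginal density of each grid point
  pm <- matrix(0, n, g)    # per-fold predictive mean given the grid point
  pv <- matrix(0, n, g)    # per-fold predictive variance given the grid point
  ld_full <- numeric(g)
  n1 <- n - 1
  for (k in seq_len(g)) {
    v <- exp(-h / pts$phi[k]); diag(v) <- 1 + pts$tau2_rel[k]
    r <- chol_jitter(v, scale = 1 + pts$tau2_rel[k])
    p <- chol2inv(r)
    logdet <- 2 * sum(log(diag(r)))
    p1 <- drop(p %*% one); py <- drop(p %*% y); pii <- diag(p)
    s11f <- sum(p1); s1yf <- sum(py); syyf <- sum(y * py)
    # drop-one quantities a'_{-i} V_{-i}^{-1} b_{-i} by block-inverse downdate
    c1 <- p1 - pii; cy <- py - y * pii
    s11 <- (s11f - 2 * p1 + pii) - c1^2 / pii
    s1y <- (s1yf - py - y * p1 + y * pii) - c1 * cy / pii
    syy <- (syyf - 2 * y * py + y^2 * pii) - cy^2 / pii
    beta <- s1y / s11
    qhat <- pmax(syy - s1y^2 / s11, .Machine$double.eps)
    ld[, k] <- -0.5 * (logdet + log(pii)) - 0.5 * log(s11) -
      (n1 - 1) / 2 * log(qhat / 2)
    pm[, k] <- y - (py - beta * p1) / pii
    s2 <- qhat / max(n1 - 3, 1)            # posterior mean of sigma^2
    pv[, k] <- s2 * (1 / pii + (p1 / pii)^2 / s11)
    qf <- max(syyf - s1yf^2 / s11f, .Machine$double.eps)
    ld_full[k] <- -0.5 * logdet - 0.5 * log(s11f) - (n - 1) / 2 * log(qf / 2)
  }
  if (method == "shared") ld <- matrix(ld_full, n, g, byrow = TRUE)
  w <- exp(ld - apply(ld, 1, max))
  w <- w / rowSums(w)
  pred_mean <- rowSums(w * pm)
  pred_var <- pmax(rowSums(w * (pv + pm^2)) - pred_mean^2, 0)
  out <- data.frame(observed = y, pred_mean = pred_mean, pred_var = pred_var,
                    std_resid = (y - pred_mean) / sqrt(pred_var))
  attr(out, "method") <- method
  out
}
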