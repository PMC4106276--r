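# Distance-matrix inference: standardization, Euclidean dissimilarities,
# simple and partial Mantel permutation tests, bootstrap confidence
# intervals. Permutation p-values follow the (exceedances + 1)/(n_perm + 1)
# convention, so p is never exactly zero.

#' Standardize a variable to mean 0 and unit sample standard deviation
#'
#' Applied to every variable before Euclidean dissimilarities are formed, so
#' that all distance matrices live on a comparable scale.
#'
#' @param values Numeric vector of length >= 2 with nonzero spread.
#' @param name Variable name used in error messages.
#' @return Standardized vector.
#' @export
standardize <- function(values, name = deparse(substitute(values))) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values to standardize")
  s <- sd(values)
  if (!is.finite(s) || s == 0)
    stop(sprintf("variable '%s' has zero spread and cannot be standardized", name))
  (values - mean(values)) / s
}

#' Euclidean distance matrix over one or more columns
#'
#' For plant/environment variables the columns should already be
#' standardized (see [standardize()]); for geographic coordinates pass the
#' raw (x, y) columns to obtain distances in meters. A single categorical
#' (factor or character) column yields the 0/1 mismatch matrix used for
#' inbred-line labels.
#'
#' @param columns Vector, matrix or data frame; rows are sample units.
#' @param label Label stored on the result.
#' @return A symmetric `dist_matrix` (plain matrix with zero diagonal and a
#'   `label` attribute).
#' @export
euclidean_dmat <- function(columns, label = NULL) {
  if (is.factor(columns) || is.character(columns)) {
    d <- outer(columns, columns, FUN = "!=") * 1
    dimnames(d) <- NULL
  } else {
    m <- as.matrix(columns)
    storage.mode(m) <- "double"
    if (anyNA(m)) stop("distance input contains NA")
    d <- as.matrix(dist(m))
    dimnames(d) <- NULL
  }
  if (nrow(d) < 3) stop("need at least 3 sample units")
  attr(d, "label") <- label
  class(d) <- c("dist_matrix", class(d))
  d
}

check_dmat <- function(d, what = "distance matrix") {
  d <- unclass(as.matrix(d))
  if (nrow(d) != ncol(d)) stop(sprintf("%s must be square", what))
  if (any(!is.finite(d))) stop(sprintf("%s has non-finite entries", what))
  if (max(abs(d - t(d))) > 1e-8) stop(sprintf("%s must be symmetric", what))
  d
}

# Generate n_perm random relabelings as a 0-based integer matrix (n x n_perm).
perm_matrix <- function(n, n_perm) {
  vapply(seq_len(n_perm), function(i) sample.int(n) - 1L, integer(n))
}

# All n! permutations of 1..n (n small), one per column.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (j in seq_len(ncol(sub))) {
    for (pos in seq_len(n)) {
      col <- col + 1L
      out[, col] <- append(sub[, j], n, after = pos - 1L)
    }
  }
  out
}

mantel_r <- function(a_ut, b_ut) cor(a_ut, b_ut)

#' Simple Mantel test
#'
#' `r` is the Pearson correlation between the unfolded upper triangles of
#' two distance matrices; significance comes from joint row/column
#' relabelings of the second matrix. For `n <= 7`, `exact = TRUE` enumerates
#' all `n!` relabelings and reports the exact tail proportion.
#'
#' @param dA,dB Distance matrices from [euclidean_dmat()] (or any symmetric
#'   matrices with zero diagonal) on the same `n` units.
#' @param n_perm Number of permutations (study default 10000).
#' @param seed Integer seed for the permutation stream.
#' @param alternative `"greater"` (one-tailed, default), `"less"`, or
#'   `"two.sided"`.
#' @param exact Enumerate all relabelings instead of sampling (`n <= 7`).
#' @return A `mantel_result` with elements `r`, `p_value`, `n_perm`,
#'   `alternative`, `ci90` (`NULL` unless added by [bootstrap_ci()]).
#' @examples
#' dA <- euclidean_dmat(c(0, 1, 2))
#' dB <- euclidean_dmat(c(0, 2, 1))
#' mantel(dA, dB, exact = TRUE)$r   # -0.5
#' @export
mantel <- function(dA, dB, n_perm = 10000, seed = NULL,
                   alternative = c("greater", "less", "two.sided"),
                   exact = FALSE) {
  alternative <- match.arg(alternative)
  a <- check_dmat(dA, "dA"); b <- check_dmat(dB, "dB")
  if (nrow(a) != nrow(b)) stop("dA and dB must have matching n")
  n <- nrow(a)
  a_ut <- ut(a); b_ut <- ut(b)
  if (sd(a_ut) == 0 || sd(b_ut) == 0) stop("distance matrix has zero variance")
  r_obs <- mantel_r(a_ut, b_ut)
  if (exact) {
    if (n > 7) stop("exact enumeration supported only for n <= 7")
    perms <- all_perms(n) - 1L
    r_perm <- mantel_perm_cor(a_ut, b, perms)
    p <- perm_pvalue(r_obs, r_perm, alternative, exact = TRUE)
    n_used <- ncol(perms)
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1")
    r_perm <- with_seed(seed, mantel_perm_cor(a_ut, b, perm_matrix(n, n_perm)))
    p <- perm_pvalue(r_obs, r_perm, alternative, exact = FALSE)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p_value = p, n_perm = n_used,
                 alternative = alternative, exact = exact, ci90 = NULL,
                 partials = character(0)),
            class = "mantel_result")
}

perm_pvalue <- function(r_obs, r_perm, alternative, exact) {
  tol <- 1e-12
  count <- switch(alternative,
    greater   = sum(r_perm >= r_obs - tol),
    less      = sum(r_perm <= r_obs + tol),
    two.sided = sum(abs(r_perm) >= abs(r_obs) - tol))
  if (exact) count / length(r_perm) else (count + 1) / (length(r_perm) + 1)
}

#' @export
print.mantel_result <- function(x, ...) {
  kind <- if (length(x$partials)) sprintf("partial Mantel (| %s)", paste(x$partials, collapse = " + "))
          else "Mantel"
  cat(sprintf("%s: r = %.4f, p = %.4g (%s, %d %s)\n", kind, x$r, x$p_value,
              x$alternative, x$n_perm, if (isTRUE(x$exact)) "exact relabelings" else "permutations"))
  if (!is.null(x$ci90))
    cat(sprintf("  90%% bootstrap CI: [%.4f, %.4f]\n", x$ci90[1], x$ci90[2]))
  invisible(x)
}

# Residualize the unfolded upper triangles of `mats` on the partial
# matrices' upper triangles (intercept included). Constant-pattern partials
# carry no information beyond the intercept and are dropped; genuinely
# collinear partials are an error. Returns residual vectors.
residualize_ut <- function(uts, partials) {
  cols <- lapply(partials, ut)
  keep <- vapply(cols, function(u) sd(u) > 0, TRUE)
  x <- cbind(rep(1, length(uts[[1]])), do.call(cbind, cols[keep]))
  q <- qr(x)
  if (q$rank < ncol(x))
    stop(sprintf("collinear partial matrices (design rank %d < %d columns)",
                 q$rank, ncol(x)))
  lapply(uts, function(u) qr.resid(q, u))
}

# Fast residualization via normal equations for tight resampling loops;
# falls back to the QR route on (near-)singular designs.
resid_fast <- function(uts, partial_uts) {
  keep <- vapply(partial_uts, function(u) sd(u) > 0, TRUE)
  x <- cbind(1, do.call(cbind, partial_uts[keep]))
  xtx <- crossprod(x)
  b <- tryCatch(solve(xtx, crossprod(x, do.call(cbind, uts))),
                error = function(e) NULL)
  if (is.null(b)) return(NULL)
  fitted <- x %*% b
  lapply(seq_along(uts), function(i) uts[[i]] - fitted[, i])
}

# Rebuild a symmetric zero-diagonal matrix from its unfolded upper triangle.
from_ut <- function(u, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- u
  m + t(m)
}

#' Partial Mantel test
#'
#' Both focal matrices are residualized by least squares on the unfolded
#' upper triangles of the conditioning matrices (intercept included); `r` is
#' the Pearson correlation of the residuals. Permutations jointly relabel
#' the rows/columns of the second residual matrix and the statistic is
#' recomputed per relabeling. With `permute_raw = TRUE` the raw second
#' matrix is relabeled and re-residualized each time instead.
#'
#' @inheritParams mantel
#' @param partials List of conditioning distance matrices (may include the
#'   geographic "space" matrix); an empty list reduces to [mantel()].
#' @param permute_raw Permute the raw matrix and re-residualize per
#'   permutation (slower alternative scheme).
#' @return A `mantel_result`.
#' @export
partial_mantel <- function(dA, dB, partials = list(), n_perm = 10000,
                           seed = NULL,
                           alternative = c("greater", "less", "two.sided"),
                           permute_raw = FALSE) {
  alternative <- match.arg(alternative)
  if (!length(partials))
    return(mantel(dA, dB, n_perm = n_perm, seed = seed, alternative = alternative))
  a <- check_dmat(dA, "dA"); b <- check_dmat(dB, "dB")
  n <- nrow(a)
  partials <- lapply(partials, check_dmat, what = "partial matrix")
  if (any(vapply(partials, nrow, 0L) != n) || nrow(b) != n)
    stop("all matrices must share the same n")
  res <- residualize_ut(list(ut(a), ut(b)), partials)
  ra <- res[[1]]; rb <- res[[2]]
  if (sd(ra) == 0 || sd(rb) == 0) stop("zero residual variance after conditioning")
  r_obs <- mantel_r(ra, rb)
  perms <- with_seed(seed, perm_matrix(n, n_perm))
  if (permute_raw) {
    r_perm <- vapply(seq_len(n_perm), function(t) {
      p <- perms[, t] + 1L
      resp <- residualize_ut(list(ut(a), ut(b[p, p])), partials)
      mantel_r(resp[[1]], resp[[2]])
    }, 0)
  } else {
    r_perm <- mantel_perm_cor(ra, from_ut(rb, n), perms)
  }
  structure(list(r = r_obs, p_value = perm_pvalue(r_obs, r_perm, alternative, FALSE),
                 n_perm = n_perm, alternative = alternative, exact = FALSE,
                 ci90 = NULL,
                 partials = vapply(seq_along(partials), function(i) {
                   lb <- attr(partials[[i]], "label")
                   if (is.null(lb)) sprintf("partial%d", i) else lb
                 }, "")),
            class = "mantel_result")
}

#' Bootstrap confidence interval for a (partial) Mantel correlation
#'
#' Nonparametric bootstrap over sample units: unit indices are resampled
#' with replacement, all matrices are subset accordingly (equivalent to
#' rebuilding Euclidean distances from resampled rows), and the (partial)
#' Mantel `r` is recomputed; the percentile interval at `level` is returned.
#' Degenerate resamples (zero distance variance) are redrawn, up to a cap of
#' `10 * n_boot` attempts.
#'
#' @inheritParams partial_mantel
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param level Interval level, default 0.90 as used for network edges.
#' @return Numeric `c(lower, upper)` with attribute `level`.
#' @export
bootstrap_ci <- function(dA, dB, partials = list(), n_boot = 1000,
                         level = 0.90, seed = NULL) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  a <- check_dmat(dA, "dA"); b <- check_dmat(dB, "dB")
  partials <- lapply(partials, check_dmat, what = "partial matrix")
  n <- nrow(a)
  with_seed(seed, {
    rs <- numeric(n_boot)
    got <- 0L; tries <- 0L
    while (got < n_boot && tries < 10L * n_boot) {
      tries <- tries + 1L
      idx <- sample.int(n, replace = TRUE)
      ab <- a[idx, idx]; bb <- b[idx, idx]
      au <- ut(ab); bu <- ut(bb)
      if (sd(au) == 0 || sd(bu) == 0) next
      r <- if (length(partials)) {
        res <- resid_fast(list(au, bu),
                          lapply(partials, function(p) ut(p[idx, idx])))
        if (is.null(res) || sd(res[[1]]) == 0 || sd(res[[2]]) == 0) NA_real_
        else mantel_r(res[[1]], res[[2]])
      } else mantel_r(au, bu)
      if (is.na(r)) next
      got <- got + 1L
      rs[got] <- r
    }
    if (got < n_boot)
      stop("too many degenerate bootstrap resamples")
    ci <- unname(quantile(rs, c((1 - level) / 2, 1 - (1 - level) / 2)))
    attr(ci, "level") <- level
    ci
  })
}
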