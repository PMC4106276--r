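# Piecewise Mantel correlogram: Mantel statistics between a data
# dissimilarity matrix and indicator matrices of geographic lag classes,
# read as an autocorrelation-vs-distance profile.

#' Piecewise Mantel correlogram
#'
#' Distance pairs are binned into contiguous half-open lag classes
#' `[k w, (k+1) w)` of width `lag_width` (study default 2.5 m). For each
#' class the statistic is the negated Mantel correlation between the data
#' dissimilarity matrix and the 0/1 indicator matrix of pairs falling in the
#' class, so positive values read as positive spatial autocorrelation
#' (nearby units more similar than average). Per-class one-tailed
#' permutation p-values test for positive autocorrelation. Classes with
#' fewer than `min_pairs` pairs are flagged unusable and ignored by
#' [autocorr_range()].
#'
#' @param dData Data dissimilarity matrix ([euclidean_dmat()] of the
#'   standardized variable).
#' @param dGeo Geographic distance matrix in meters.
#' @param lag_width Lag class width in meters (default 2.5).
#' @param max_lag Largest lag considered; defaults to half the maximum
#'   pairwise distance (rounded up to a whole class).
#' @param n_perm Permutations per class.
#' @param seed Integer seed.
#' @param min_pairs Minimum pair count for a class to enter range detection.
#' @return A `correlogram` data frame with columns `lower`, `upper`,
#'   `midpoint`, `n_pairs`, `mantel_r`, `p_value`, `usable`, `significant`
#'   (at `alpha = 0.05`).
#' @export
correlogram <- function(dData, dGeo, lag_width = 2.5, max_lag = NULL,
                        n_perm = 10000, seed = NULL, min_pairs = 20) {
  d <- check_dmat(dData, "dData")
  g <- check_dmat(dGeo, "dGeo")
  if (nrow(d) != nrow(g)) stop("dData and dGeo must share n")
  if (lag_width <= 0) stop("lag_width must be > 0")
  n <- nrow(d)
  g_ut <- ut(g)
  if (is.null(max_lag)) max_lag <- ceiling(max(g_ut) / 2 / lag_width) * lag_width
  if (max_lag < lag_width) stop("max_lag must be at least one lag_width")
  n_bins <- floor(max_lag / lag_width + 1e-9)
  a_ut <- ut(d)
  if (sd(a_ut) == 0) stop("data dissimilarity matrix has zero variance")
  perms <- with_seed(seed, perm_matrix(n, n_perm))
  rows <- lapply(seq_len(n_bins), function(k) {
    lo <- (k - 1) * lag_width; hi <- k * lag_width
    in_bin <- g_ut >= lo & g_ut < hi
    npairs <- sum(in_bin)
    if (npairs == 0 || npairs == length(in_bin)) {
      return(data.frame(lower = lo, upper = hi, midpoint = (lo + hi) / 2,
                        n_pairs = npairs, mantel_r = NA_real_,
                        p_value = NA_real_, usable = FALSE))
    }
    ind <- from_ut(as.numeric(in_bin), n)
    r_obs <- -mantel_r(a_ut, ut(ind))
    r_perm <- -mantel_perm_cor(a_ut, ind, perms)
    p <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1)
    data.frame(lower = lo, upper = hi, midpoint = (lo + hi) / 2,
               n_pairs = npairs, mantel_r = r_obs, p_value = p,
               usable = npairs >= min_pairs)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value <= 0.05 & out$mantel_r > 0
  class(out) <- c("correlogram", "data.frame")
  attr(out, "lag_width") <- lag_width
  attr(out, "n_perm") <- n_perm
  out
}

#' Spatial autocorrelation range from a correlogram
#'
#' Scans usable lag classes from lag zero outward and returns the midpoint
#' of the last class in the initial consecutive run of significant
#' (`p <= alpha`), positive-statistic classes. Returns `NA` when the first
#' usable class is not significant. If every usable class is significant the
#' last midpoint is returned with attribute `truncated = TRUE` (the true
#' range may exceed the examined lags).
#'
#' @param result A [correlogram()] result.
#' @param alpha Per-class significance level (study convention 0.05).
#' @return Range in meters, or `NA_real_`.
#' @export
autocorr_range <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "correlogram"))
  use <- result[result$usable, , drop = FALSE]
  if (!nrow(use)) stop("no usable lag classes")
  sig <- use$p_value <= alpha & use$mantel_r > 0
  if (!sig[1]) return(NA_real_)
  last <- if (all(sig)) nrow(use) else min(which(!sig)) - 1L
  out <- use$midpoint[last]
  if (all(sig)) attr(out, "truncated") <- TRUE
  out
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("Mantel correlogram: %d lag classes of %g m, %d permutations each\n",
              nrow(x), attr(x, "lag_width"), attr(x, "n_perm")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
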