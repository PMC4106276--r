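# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for a named pipeline stage; stays below 2^31.
derive_seed <- function(master, label) {
  codes <- utf8ToInt(label)
  h <- as.double(master %% 2147483647)
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Cross-distance matrix between two sets of points (n x 2 matrices), meters.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

as_points <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("point list must have two columns (x, y)")
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) stop("point coordinates must be finite")
  unname(x)
}

# Upper-triangle (i < j) unfold of a symmetric matrix, column-major order.
ut <- function(m) m[upper.tri(m)]
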