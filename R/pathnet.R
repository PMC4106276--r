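# Mantel path analysis: a pre-declared hypothesis network of directed and
# bidirectional relations among variables, each edge evaluated by a partial
# Mantel test conditioned on the other linked variables and on geographic
# space whenever either endpoint is spatially autocorrelated.

#' Compile a hypothesis network
#'
#' Edge directions and expected signs are declarative metadata fixed a
#' priori from ecological knowledge (e.g., relief influences soil moisture
#' and not the other way); the Mantel statistics themselves are symmetric.
#' Each edge's conditioning set defaults to the other variables adjacent to
#' either endpoint in the hypothesis graph; `conditioning = "all"` uses
#' every other declared variable instead.
#'
#' @param variables Character vector of known variable names.
#' @param edge_spec Data frame with columns `source`, `target`, optional
#'   `directed` (default `TRUE`) and `sign` (`"+"`, `"-"`, or `""`;
#'   required for directed edges).
#' @param conditioning `"adjacent"` or `"all"`.
#' @return List of `path_hypothesis` objects.
#' @export
build_hypotheses <- function(variables, edge_spec,
                             conditioning = c("adjacent", "all")) {
  conditioning <- match.arg(conditioning)
  if (is.null(edge_spec) || !nrow(edge_spec)) return(list())
  if (is.null(edge_spec$directed)) edge_spec$directed <- TRUE
  if (is.null(edge_spec$sign)) edge_spec$sign <- ""
  unknown <- setdiff(c(edge_spec$source, edge_spec$target), variables)
  if (length(unknown))
    stop(sprintf("unknown variables in edge spec: %s",
                 paste(unique(unknown), collapse = ", ")))
  if (any(edge_spec$source == edge_spec$target))
    stop("self-edges are not allowed")
  key <- paste(pmin(edge_spec$source, edge_spec$target),
               pmax(edge_spec$source, edge_spec$target))
  if (anyDuplicated(key))
    stop(sprintf("duplicate edge: %s", key[duplicated(key)][1]))
  if (any(edge_spec$directed & !edge_spec$sign %in% c("+", "-")))
    stop("directed edges require an expected sign ('+' or '-')")
  lapply(seq_len(nrow(edge_spec)), function(i) {
    s <- edge_spec$source[i]; t <- edge_spec$target[i]
    cond <- if (conditioning == "all") {
      setdiff(variables, c(s, t))
    } else {
      adj <- unique(c(edge_spec$target[edge_spec$source %in% c(s, t)],
                      edge_spec$source[edge_spec$target %in% c(s, t)]))
      setdiff(adj, c(s, t))
    }
    structure(list(source = s, target = t,
                   directed = isTRUE(edge_spec$directed[i]),
                   expected_sign = edge_spec$sign[i],
                   conditioning = cond),
              class = "path_hypothesis")
  })
}

# Sign of the relation between two variables after partialling out the
# numeric conditioning variables on the raw (standardized value) scale.
# Distances discard the direction of a monotone relation — a strong negative
# correlation still yields a positive Mantel r — so signed network arrows
# must be read off the value scale. Returns NA for categorical variables.
partial_value_sign <- function(data, source, target, conditioning) {
  num <- function(v) !(is.factor(data[[v]]) || is.character(data[[v]]) || v == "line")
  if (!num(source) || !num(target)) return(NA_character_)
  s <- standardize(data[[source]], source)
  t <- standardize(data[[target]], target)
  cond <- Filter(num, conditioning)
  if (length(cond)) {
    x <- cbind(1, vapply(cond, function(v) standardize(data[[v]], v),
                         numeric(nrow(data))))
    q <- qr(x)
    s <- qr.resid(q, s); t <- qr.resid(q, t)
  }
  if (cor(s, t) >= 0) "+" else "-"
}

# Distance matrix for one variable column: 0/1 mismatch for categorical
# line labels, standardized Euclidean otherwise.
variable_dmat <- function(data, var) {
  v <- data[[var]]
  if (is.factor(v) || is.character(v) || var == "line")
    euclidean_dmat(as.character(v), label = var)
  else
    euclidean_dmat(standardize(v, var), label = var)
}

#' Evaluate a hypothesis network with partial Mantel tests
#'
#' For each hypothesis the standardized Euclidean distance matrices of
#' source, target, and conditioning variables are built; the geographic
#' distance matrix is appended to the partials iff either endpoint shows
#' significant spatial autocorrelation (a non-missing range in its
#' correlogram). Each edge gets a one-tailed ("greater") partial Mantel
#' test — on the distance scale any monotone relation, whatever its sign,
#' raises the statistic — and a bootstrap confidence interval; edges with
#' `p <= alpha` are retained. The reported edge sign comes from the raw
#' (standardized value) scale partial correlation, because distances cannot
#' carry the direction of a relation; for categorical variables the Mantel
#' statistic's own sign is used.
#'
#' @param data Data frame with coordinate columns `x`, `y` and every
#'   hypothesis variable. Zero-variance variables are dropped with a
#'   warning (their edges are skipped).
#' @param hypotheses From [build_hypotheses()].
#' @param ranges Named numeric vector (or list) of autocorrelation ranges in
#'   meters per variable, `NA` when absent — typically
#'   [autocorr_range()] applied per variable, see [variable_correlograms()].
#' @param n_perm Permutations per test (study default 10000).
#' @param n_boot Bootstrap resamples for the confidence intervals.
#' @param ci_level Confidence level (study convention 0.90).
#' @param alpha Retention threshold (study convention 0.05).
#' @param seed Integer seed.
#' @return A `path_network`: list with `nodes` (variable, range) and
#'   `edges` (source, target, directed, expected_sign, r, p_value, ci_lo,
#'   ci_hi, sign, space_included, conditioning, retained).
#' @export
evaluate_network <- function(data, hypotheses, ranges, n_perm = 10000,
                             n_boot = 1000, ci_level = 0.90, alpha = 0.05,
                             seed = NULL) {
  stopifnot(all(c("x", "y") %in% names(data)))
  vars <- as.character(unique(unlist(lapply(hypotheses, function(h)
    c(h$source, h$target, h$conditioning)))))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop(sprintf("variables absent from data: %s",
                 paste(missing_vars, collapse = ", ")))
  degenerate <- vars[vapply(vars, function(v) {
    col <- data[[v]]
    !(is.factor(col) || is.character(col) || v == "line") && sd(col) == 0
  }, TRUE)]
  if (length(degenerate)) {
    warning(sprintf("dropping zero-variance variables: %s",
                    paste(degenerate, collapse = ", ")))
    vars <- setdiff(vars, degenerate)
  }
  dmats <- lapply(setNames(vars, vars), function(v) variable_dmat(data, v))
  dgeo <- euclidean_dmat(as.matrix(data[, c("x", "y")]), label = "space")
  ranges <- unlist(ranges)[vars]
  names(ranges) <- vars
  rows <- list()
  for (i in seq_along(hypotheses)) {
    h <- hypotheses[[i]]
    if (h$source %in% degenerate || h$target %in% degenerate) next
    cond <- setdiff(h$conditioning, degenerate)
    partials <- dmats[cond]
    space_in <- isTRUE(!is.na(ranges[[h$source]])) ||
      isTRUE(!is.na(ranges[[h$target]]))
    if (space_in) partials <- c(partials, list(dgeo))
    # distance-scale association is one-tailed "greater": any monotone
    # relation, of either sign, raises the Mantel statistic
    sub_seed <- if (is.null(seed)) NULL else
      derive_seed(seed, paste("edge", h$source, h$target))
    res <- partial_mantel(dmats[[h$source]], dmats[[h$target]],
                          partials = unname(partials), n_perm = n_perm,
                          seed = sub_seed, alternative = "greater")
    ci <- bootstrap_ci(dmats[[h$source]], dmats[[h$target]],
                       partials = unname(partials), n_boot = n_boot,
                       level = ci_level,
                       seed = if (is.null(sub_seed)) NULL else sub_seed + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      source = h$source, target = h$target, directed = h$directed,
      expected_sign = h$expected_sign, r = res$r, p_value = res$p_value,
      ci_lo = ci[1], ci_hi = ci[2],
      sign = {
        vs <- partial_value_sign(data, h$source, h$target, cond)
        if (is.na(vs)) (if (res$r >= 0) "+" else "-") else vs
      },
      space_included = space_in,
      conditioning = paste(cond, collapse = ";"),
      retained = res$p_value <= alpha,
      stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else data.frame(
    source = character(0), target = character(0), directed = logical(0),
    expected_sign = character(0), r = numeric(0), p_value = numeric(0),
    ci_lo = numeric(0), ci_hi = numeric(0), sign = character(0),
    space_included = logical(0), conditioning = character(0),
    retained = logical(0), stringsAsFactors = FALSE)
  structure(list(
    nodes = data.frame(variable = vars, range_m = as.numeric(ranges),
                       stringsAsFactors = FALSE),
    edges = edges,
    settings = list(n_perm = n_perm, n_boot = n_boot, ci_level = ci_level,
                    alpha = alpha, seed = seed)),
    class = "path_network")
}

#' Correlograms and autocorrelation ranges for a set of variables
#'
#' Convenience wrapper running [correlogram()] and [autocorr_range()] per
#' variable; the range vector feeds the space-inclusion rule of
#' [evaluate_network()].
#'
#' @inheritParams evaluate_network
#' @param variables Variables to profile.
#' @inheritParams correlogram
#' @return List with `correlograms` (named list) and `ranges` (named
#'   numeric vector, `NA` where no initial significant lag class).
#' @export
variable_correlograms <- function(data, variables, lag_width = 2.5,
                                  max_lag = NULL, n_perm = 1000,
                                  alpha = 0.05, seed = NULL) {
  dgeo <- euclidean_dmat(as.matrix(data[, c("x", "y")]), label = "space")
  cgs <- lapply(setNames(variables, variables), function(v) {
    correlogram(variable_dmat(data, v), dgeo, lag_width = lag_width,
                max_lag = max_lag, n_perm = n_perm,
                seed = if (is.null(seed)) NULL else derive_seed(seed, paste("cg", v)))
  })
  ranges <- vapply(cgs, function(cg) as.numeric(autocorr_range(cg, alpha)), 0)
  list(correlograms = cgs, ranges = ranges)
}

#' @export
print.path_network <- function(x, ...) {
  cat(sprintf("path_network: %d nodes, %d edges tested, %d retained (p <= %g)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$retained),
              x$settings$alpha))
  if (nrow(x$edges)) {
    e <- x$edges
    arrow <- ifelse(e$directed, "->", "<->")
    for (i in seq_len(nrow(e)))
      cat(sprintf("  %s %s %s: r = %+.3f (%.3f, %.3f), p = %.4g%s\n",
                  e$source[i], arrow[i], e$target[i], e$r[i], e$ci_lo[i],
                  e$ci_hi[i], e$p_value[i],
                  if (e$retained[i]) "" else "  [not retained]"))
  }
  invisible(x)
}

#' Serialize / restore a path network
#'
#' `export_network()` writes nodes, edges, coefficients, intervals and
#' settings as JSON (plus an optional flat edges CSV); `read_network()`
#' restores an identical object, so `read_network(export_network(net))`
#' round-trips.
#'
#' @param net A `path_network`.
#' @param path Output JSON path.
#' @param csv_path Optional CSV path for the edge table.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, csv_path = NULL) {
  stopifnot(inherits(net, "path_network"))
  jsonlite::write_json(
    list(nodes = net$nodes, edges = net$edges, settings = net$settings),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  if (!is.null(csv_path)) write.csv(net$edges, csv_path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(j$nodes, stringsAsFactors = FALSE)
  nodes$range_m <- if (is.null(nodes$range_m)) rep(NA_real_, nrow(nodes))
                   else as.numeric(nodes$range_m)
  edges <- as.data.frame(j$edges, stringsAsFactors = FALSE)
  if (!nrow(edges)) edges <- data.frame(
    source = character(0), target = character(0), directed = logical(0),
    expected_sign = character(0), r = numeric(0), p_value = numeric(0),
    ci_lo = numeric(0), ci_hi = numeric(0), sign = character(0),
    space_included = logical(0), conditioning = character(0),
    retained = logical(0), stringsAsFactors = FALSE)
  settings <- j$settings
  structure(list(nodes = nodes, edges = edges, settings = settings),
            class = "path_network")
}

#' Default hypothesis network for the meadow study
#'
#' A reconstruction of the study's a-priori hypothesis list from its
#' reported relationships: topography drives soil moisture, environment
#' drives rockcress growth, growth drives reproduction, neighbor density
#' drives herbivory, and herbivory reduces fecundity. Also includes
#' declared-null control edges (vapor pressure deficit and goldenrod
#' density against rockcress fitness) used by recovery experiments.
#'
#' @param include_nulls Include the declared-null control edges.
#' @return Edge-spec data frame for [build_hypotheses()].
#' @export
default_hypotheses <- function(include_nulls = TRUE) {
  core <- data.frame(
    source = c("elevation", "elevation", "soil_moisture", "rosette_diameter",
               "rosette_diameter", "stalk_number", "stalk_herbivory",
               "dandelion_density", "rosette_herbivory"),
    target = c("soil_moisture", "rosette_diameter", "rosette_diameter",
               "stalk_number", "stalk_diameter", "fruit_number",
               "fruit_number", "rosette_herbivory", "stalk_herbivory"),
    sign = c("-", "-", "+", "+", "+", "+", "-", "+", "+"),
    directed = TRUE, truth = TRUE, stringsAsFactors = FALSE)
  if (!include_nulls) return(core)
  nulls <- data.frame(
    source = c("vpd", "vpd", "vpd", "vpd", "goldenrod_density",
               "goldenrod_density", "goldenrod_density", "goldenrod_density",
               "soil_moisture", "elevation"),
    target = c("rosette_diameter", "stalk_number", "fruit_number",
               "stalk_diameter", "rosette_diameter", "stalk_number",
               "fruit_number", "rosette_herbivory", "rosette_herbivory",
               "stalk_herbivory"),
    sign = c("+", "+", "-", "+", "-", "-", "-", "+", "+", "-"),
    directed = TRUE, truth = FALSE, stringsAsFactors = FALSE)
  rbind(core, nulls)
}
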