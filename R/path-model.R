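#' Build and validate a directed acyclic path diagram
#'
#' Edges are given as `"parent -> child"` strings (or a two-column data
#' frame). The graph must be acyclic and the speciation-rate variable, if
#' present, must be a sink (no outgoing edges). A topological order is
#' computed and stored.
#'
#' @param edges Character vector of `"parent -> child"` strings, or a data
#'   frame/matrix with columns `parent`, `child`.
#' @param sink Name of the variable required to have no outgoing edges
#'   (default `"log_dr"`; set `NULL` to skip the check).
#' @return Object of class `path_dag`: list with `edges` (data frame),
#'   `variables`, `order` (topological, exogenous first).
#' @examples
#' build_path_dag(c("a -> b", "b -> c"))
#' @export
build_path_dag <- function(edges, sink = "log_dr") {
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) stop("malformed edge(s): ", paste(edges[bad], collapse = ", "))
    ed <- data.frame(parent = trimws(vapply(parts, `[`, "", 1)),
                     child = trimws(vapply(parts, `[`, "", 2)),
                     stringsAsFactors = FALSE)
  } else {
    ed <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(ed) <- c("parent", "child")
  }
  vars <- unique(c(ed$parent, ed$child))
  if (!is.null(sink) && sink %in% vars && sink %in% ed$parent)
    stop("'", sink, "' must be a sink (it has outgoing edges)")
  # Kahn's algorithm; report a cycle if it stalls
  order <- character(0)
  remaining <- ed
  pending <- vars
  while (length(pending)) {
    free <- setdiff(pending, remaining$child)
    if (!length(free)) {
      cyc <- unique(c(remaining$parent, remaining$child))
      stop("cycle detected among: ", paste(cyc, collapse = " -> "))
    }
    order <- c(order, free)
    pending <- setdiff(pending, free)
    remaining <- remaining[!(remaining$parent %in% free), , drop = FALSE]
  }
  structure(list(edges = ed, variables = vars, order = order),
            class = "path_dag")
}

#' Default path diagram for the range-size / speciation system
#'
#' Position (absolute latitudinal and longitudinal midpoints) and the island
#' flag act on body size, dispersal and range size; body size acts on
#' dispersal; body size and dispersal act on range size and range shape; and
#' range size, shape, dispersal, body size and position all act on the tip
#' speciation rate, which is the sink. Variable names match the columns
#' produced by [prepare_model_frame()] on a [generate_clade_dataset()] table.
#'
#' @param include_island Include island-flag edges (drop for single-setting
#'   subgroup fits).
#' @return A `path_dag`.
#' @export
default_path_dag <- function(include_island = TRUE) {
  e <- c(
    "abs_lat -> log_body_mass", "abs_lon -> log_body_mass",
    "log_body_mass -> log_hwi",
    "abs_lat -> log_range_size", "abs_lon -> log_range_size",
    "log_body_mass -> log_range_size", "log_hwi -> log_range_size",
    "log_body_mass -> log_shape_index", "log_hwi -> log_shape_index",
    "log_range_size -> log_dr", "log_shape_index -> log_dr",
    "log_hwi -> log_dr", "log_body_mass -> log_dr",
    "abs_lat -> log_dr", "abs_lon -> log_dr")
  if (include_island)
    e <- c(e, "island -> log_hwi", "island -> log_range_size",
           "island -> log_dr")
  build_path_dag(e)
}

#' Fit a phylogenetic path model equation by equation
#'
#' Each endogenous variable (every DAG child) is regressed on its parents by
#' lambda-PGLS ([fit_pgls()]), giving one structural equation per child.
#' Intervals are t-based at the requested level; an edge is flagged
#' significant when its interval excludes zero (the red/blue/grey
#' convention). Optionally a parametric bootstrap (resimulating each
#' equation's phylogenetic residuals at the fitted lambda) replaces the
#' analytic intervals. The estimator is single-equation ML lambda-PGLS, not
#' a joint Bayesian system; this is recorded in the result.
#'
#' @param dag A `path_dag`.
#' @param data Data frame (row names or `tip` column matching tips); must
#'   contain every DAG variable.
#' @param tree Ultrametric `phylo`.
#' @param subgroup Optional: value of `setting_column` to restrict to (tree
#'   pruned accordingly).
#' @param setting_column Column used by `subgroup`.
#' @param level Interval level (default 0.95).
#' @param bootstrap Number of parametric-bootstrap draws (0 = analytic
#'   intervals).
#' @return Object of class `path_fit`: data frame with one row per edge
#'   (`parent`, `child`, `estimate`, `lower`, `upper`, `significant`,
#'   `lambda`, `subgroup`) plus attributes `estimator` and `level`.
#' @export
fit_path_model <- function(dag, data, tree, subgroup = NULL,
                           setting_column = "setting", level = 0.95,
                           bootstrap = 0) {
  stopifnot(inherits(dag, "path_dag"))
  if (!is.null(subgroup)) {
    if (!setting_column %in% names(data))
      stop("no '", setting_column, "' column to subgroup on")
    keep <- rownames(data)[data[[setting_column]] == subgroup]
    if (length(keep) < 8) {
      warning("subgroup '", subgroup, "' too small (", length(keep),
              " species); skipped")
      return(NULL)
    }
    tree <- ape::keep.tip(tree, intersect(tree$tip.label, keep))
    data <- data[tree$tip.label, , drop = FALSE]
  }
  miss <- setdiff(dag$variables, names(data))
  if (length(miss))
    stop("data lacks DAG variable(s): ", paste(miss, collapse = ", "))

  children <- unique(dag$edges$child)
  rows <- list()
  for (ch in children) {
    parents <- dag$edges$parent[dag$edges$child == ch]
    # a constant parent (e.g. island flag inside a subgroup) is dropped
    keepp <- parents[vapply(parents, function(p)
      length(unique(data[[p]])) > 1, logical(1))]
    if (!length(keepp)) next
    fml <- stats::as.formula(paste(ch, "~", paste(keepp, collapse = " + ")))
    fit <- fit_pgls(fml, data, tree, lambda = "ML")
    ci <- if (bootstrap > 0)
      path_bootstrap_ci(fit, fml, data, tree, bootstrap, level)
    else confint(fit, level = level)
    co <- fit$coefficients
    for (p in keepp) {
      i <- match(p, co$term)
      rows[[length(rows) + 1]] <- data.frame(
        parent = p, child = ch, estimate = co$estimate[i],
        lower = ci[p, "lower"], upper = ci[p, "upper"],
        significant = ci[p, "lower"] > 0 | ci[p, "upper"] < 0,
        lambda = fit$lambda,
        subgroup = if (is.null(subgroup)) "all" else subgroup,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "estimator") <- "per-equation ML lambda-PGLS"
  attr(out, "level") <- level
  class(out) <- c("path_fit", "data.frame")
  out
}

# parametric bootstrap: resimulate the response from the fitted equation
path_bootstrap_ci <- function(fit, fml, data, tree, B, level) {
  C <- transform_vcv(phylo_vcv(tree), lambda = fit$lambda)
  L <- t(chol(fit$sigma2 * C[rownames(data), rownames(data)]))
  est <- matrix(NA_real_, B, nrow(fit$coefficients))
  resp <- all.vars(fml)[1]
  for (b in seq_len(B)) {
    sim <- data
    sim[[resp]] <- fit$fitted + as.numeric(L %*% stats::rnorm(nrow(data)))
    est[b, ] <- fit_pgls(fml, sim, tree, lambda = fit$lambda)$coefficients$estimate
  }
  a <- (1 - level) / 2
  out <- t(apply(est, 2, stats::quantile, probs = c(a, 1 - a)))
  dimnames(out) <- list(fit$coefficients$term, c("lower", "upper"))
  out
}
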