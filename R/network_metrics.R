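# Descriptive network statistics for a patient-sharing network.
#
# Conventions (all on the unweighted, undirected simple graph):
#   density        = 2E / (N(N-1))
#   mean_distance  = mean geodesic over reachable ordered pairs only;
#                    the number of unreachable pairs is reported alongside
#   transitivity   = global clustering: 3 * triangles / connected triples
#   betweenness    = unnormalized shortest-path betweenness (each unordered
#                    pair counted once), averaged over nodes
# Relative group metrics divide the in-group mean by the out-group mean, so
# they are invariant to any common normalization of the underlying metric.

#' Summary statistics for a sharing network
#'
#' @param net a sharing network (`igraph`).
#' @param relative_attribute vertex attribute for the relative degree /
#'   betweenness ratios (default `"occupation"` when present; `NULL`
#'   disables).
#' @return an object of class `network_stats`: a list with `n_nodes`,
#'   `n_edges`, `mean_degree`, `density`, `mean_distance`,
#'   `n_unreachable_pairs`, `transitivity`, `mean_betweenness`, and (when
#'   the attribute is available with >= 2 levels) `relative_degree` and
#'   `relative_betweenness` tables.  Undefined quantities (empty or
#'   single-node networks, zero denominators) are `NA` rather than errors.
#' @export
network_summary <- function(net, relative_attribute = "occupation") {
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  out <- list(n_nodes = n, n_edges = m,
              mean_degree = NA_real_, density = NA_real_,
              mean_distance = NA_real_, n_unreachable_pairs = NA_real_,
              transitivity = NA_real_, mean_betweenness = NA_real_,
              relative_degree = NULL, relative_betweenness = NULL)
  class(out) <- "network_stats"
  if (n == 0L) return(out)
  out$mean_degree <- 2 * m / n
  out$mean_betweenness <- mean(igraph::betweenness(net, directed = FALSE,
                                                   weights = NA, normalized = FALSE))
  if (n >= 2L) {
    out$density <- 2 * m / (n * (n - 1))
    d <- igraph::distances(net, weights = NA)
    finite <- is.finite(d) & d > 0
    out$mean_distance <- if (any(finite)) mean(d[finite]) else NA_real_
    out$n_unreachable_pairs <- sum(!is.finite(d)) / 2
  }
  tr <- igraph::transitivity(net, type = "global")
  out$transitivity <- if (is.nan(tr)) NA_real_ else tr
  attrs <- igraph::vertex_attr_names(net)
  if (!is.null(relative_attribute) && relative_attribute %in% attrs &&
      length(unique(igraph::vertex_attr(net, relative_attribute))) >= 2L) {
    out$relative_degree <- relative_group_metric(net, relative_attribute, "degree")
    out$relative_betweenness <- relative_group_metric(net, relative_attribute, "betweenness")
  }
  out
}

#' @export
print.network_stats <- function(x, ...) {
  cat("Patient-sharing network statistics\n")
  cat(sprintf("  nodes: %d  edges: %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("  mean degree: %.2f  density: %.4f\n", x$mean_degree, x$density))
  cat(sprintf("  mean distance: %.2f (unreachable pairs: %s)\n",
              x$mean_distance, format(x$n_unreachable_pairs)))
  cat(sprintf("  transitivity: %.3f  mean betweenness: %.2f\n",
              x$transitivity, x$mean_betweenness))
  if (!is.null(x$relative_degree)) {
    cat("  relative degree by group:\n")
    print(x$relative_degree, row.names = FALSE)
  }
  if (!is.null(x$relative_betweenness)) {
    cat("  relative betweenness by group:\n")
    print(x$relative_betweenness, row.names = FALSE)
  }
  invisible(x)
}

# Flatten a network_stats object to a named numeric vector (relative
# metrics become e.g. "relative_degree.physician").
stats_vector <- function(x) {
  out <- c(n_nodes = x$n_nodes, n_edges = x$n_edges,
           mean_degree = x$mean_degree, density = x$density,
           mean_distance = x$mean_distance, transitivity = x$transitivity,
           mean_betweenness = x$mean_betweenness)
  for (f in c("relative_degree", "relative_betweenness")) {
    tab <- x[[f]]
    if (!is.null(tab)) {
      v <- stats::setNames(tab$ratio, paste0(f, ".", tab$level))
      out <- c(out, v)
    }
  }
  out
}

#' Relative in-group versus out-group centrality
#'
#' For each level g of a node attribute: mean(metric | node in g) /
#' mean(metric | node not in g).  A zero denominator yields `NA` (the
#' convention behind dashes in published tables).
#'
#' @param net a sharing network (`igraph`).
#' @param attribute vertex attribute name with >= 2 observed levels.
#' @param metric `"degree"` or `"betweenness"`.
#' @return data.frame `level, n, in_mean, out_mean, ratio`.
#' @export
relative_group_metric <- function(net, attribute = "occupation",
                                  metric = c("degree", "betweenness")) {
  metric <- match.arg(metric)
  vals <- switch(metric,
                 degree = igraph::degree(net),
                 betweenness = igraph::betweenness(net, directed = FALSE,
                                                   weights = NA, normalized = FALSE))
  grp <- igraph::vertex_attr(net, attribute)
  if (is.null(grp)) stop("data error: attribute '", attribute, "' not present", call. = FALSE)
  levels <- sort(unique(grp))
  if (length(levels) < 2L) {
    stop("specification error: attribute '", attribute, "' has a single level", call. = FALSE)
  }
  res <- lapply(levels, function(g) {
    in_mean <- mean(vals[grp == g])
    out_mean <- mean(vals[grp != g])
    data.frame(level = g, n = sum(grp == g), in_mean = in_mean, out_mean = out_mean,
               ratio = if (out_mean == 0) NA_real_ else in_mean / out_mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
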