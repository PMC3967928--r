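# Graph-theoretic characterization of the regulatory network.  Topology
# metrics are sign-blind; edge signs are carried only for export.  Built on
# igraph primitives; the test suite checks them against brute-force
# breadth-first-search oracles on small graphs.

#' Build the analysis view of a regulatory network
#'
#' Drops genes with no connections (isolated nodes are excluded from all
#' topology metrics) and records which were dropped.
#'
#' @param network a \linkS4class{RegulatoryNetwork} or an igraph graph.
#' @return list with \code{graph} (igraph, directed), \code{nodes},
#'   \code{dropped}.
#' @export
buildGraphView <- function(network) {
  g <- if (is(network, "RegulatoryNetwork")) asIgraph(network) else network
  if (any(igraph::which_loop(g)))
    stop("self-loops are not allowed in the analysis view", call. = FALSE)
  deg <- igraph::degree(g, mode = "all")
  dropped <- names(deg)[deg == 0]
  g <- igraph::delete_vertices(g, dropped)
  list(graph = g, nodes = igraph::V(g)$name, dropped = dropped)
}

#' Characteristic path length
#'
#' Mean shortest-path edge count over connected node pairs.  On a directed
#' graph that is not strongly connected some ordered pairs are unreachable;
#' they are excluded from the mean (the only way to obtain a finite value).
#' \code{mode = "directed_reachable"} averages over reachable ordered
#' pairs; \code{mode = "undirected"} first projects to an undirected
#' graph.
#'
#' @param view from \code{\link{buildGraphView}} (or an igraph graph).
#' @param mode \code{"directed_reachable"} or \code{"undirected"}.
#' @return mean shortest-path length (numeric scalar).
#' @examples
#' g <- igraph::make_ring(3, directed = TRUE)
#' characteristicPathLength(g)  # 1.5
#' @export
characteristicPathLength <- function(view,
                                     mode = c("directed_reachable",
                                              "undirected")) {
  mode <- match.arg(mode)
  g <- if (is.list(view) && !is.null(view$graph)) view$graph else view
  if (mode == "undirected") g <- igraph::as_undirected(g, mode = "collapse")
  d <- igraph::distances(g, mode = "out")
  diag(d) <- NA
  d[!is.finite(d)] <- NA
  if (all(is.na(d)))
    stop("no connected pairs: path length undefined", call. = FALSE)
  mean(d, na.rm = TRUE)
}

#' Clustering coefficients and transitivity
#'
#' Watts-Strogatz local clustering on the undirected projection: for each
#' node, the density of edges among its neighbours (0 for degree < 2);
#' the average coefficient C is the mean over all nodes.  Transitivity T
#' is 3 x triangles / connected triples, also on the projection.
#'
#' @param view from \code{\link{buildGraphView}} (or an igraph graph).
#' @return list with \code{local} (named per-node coefficients),
#'   \code{average} and \code{transitivity}.
#' @export
clusteringCoefficients <- function(view) {
  g <- if (is.list(view) && !is.null(view$graph)) view$graph else view
  gu <- igraph::as_undirected(g, mode = "collapse")
  loc <- igraph::transitivity(gu, type = "local", isolates = "zero")
  names(loc) <- igraph::V(gu)$name
  trans <- igraph::transitivity(gu, type = "global")
  if (is.nan(trans)) trans <- 0
  list(local = loc, average = mean(loc), transitivity = trans)
}

#' Node centralities of the directed network
#'
#' In/out degree, betweenness (shortest-path counting on the directed
#' graph) and closeness (on each node's reachable set), plus the
#' undirected local clustering coefficient.
#'
#' @param view from \code{\link{buildGraphView}} (or an igraph graph).
#' @param normalized normalize betweenness/closeness to [0, 1].
#' @return data.frame, one row per node: \code{node}, \code{in_degree},
#'   \code{out_degree}, \code{betweenness}, \code{closeness},
#'   \code{clustering}.
#' @export
nodeCentralities <- function(view, normalized = TRUE) {
  g <- if (is.list(view) && !is.null(view$graph)) view$graph else view
  btw <- igraph::betweenness(g, directed = TRUE, normalized = normalized)
  cls <- suppressWarnings(
    igraph::closeness(g, mode = "out", normalized = normalized))
  cls[is.nan(cls)] <- 0     # nodes with empty reachable set
  data.frame(node = igraph::V(g)$name,
             in_degree = igraph::degree(g, mode = "in"),
             out_degree = igraph::degree(g, mode = "out"),
             betweenness = unname(btw),
             closeness = unname(cls),
             clustering = unname(clusteringCoefficients(g)$local),
             stringsAsFactors = FALSE, row.names = NULL)
}

# One uniform random simple directed graph with the same node and edge
# counts (no self-loops), the null family for small-worldness.
randomSameSizeGraph <- function(n, m) {
  igraph::sample_gnm(n, m, directed = TRUE)
}

#' Humphries small-worldness with a random-graph bootstrap
#'
#' S = (C / <C_rand>) / (L / <L_rand>), where C is the average clustering
#' coefficient (or transitivity, \code{variant = "transitivity"}), L the
#' characteristic path length over reachable ordered pairs, and the
#' baselines are means over uniform random directed graphs with identical
#' node and edge counts.  The percentile of the observed S within the null
#' S distribution is reported alongside.
#'
#' @param view from \code{\link{buildGraphView}} (or an igraph graph).
#' @param n_null number of random null graphs (>= 100).
#' @param seed integer seed for the null sample.
#' @param variant \code{"clustering"} or \code{"transitivity"}.
#' @return list with \code{S}, \code{L}, \code{C}, \code{L_rand},
#'   \code{C_rand}, \code{null_S} (vector), \code{percentile},
#'   \code{variant}, \code{n_null}, \code{seed}.
#' @export
smallWorldness <- function(view, n_null = 100L, seed = 1L,
                           variant = c("clustering", "transitivity")) {
  variant <- match.arg(variant)
  if (n_null < 100L) stop("n_null must be >= 100", call. = FALSE)
  g <- if (is.list(view) && !is.null(view$graph)) view$graph else view
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  cstat <- function(gr) {
    cc <- clusteringCoefficients(gr)
    if (variant == "clustering") cc$average else cc$transitivity
  }
  L <- characteristicPathLength(g)
  C <- cstat(g)
  nulls <- withSeed(deriveSeed(seed, "small_world_null"), {
    lapply(seq_len(n_null), function(i) {
      gr <- randomSameSizeGraph(n, m)
      c(L = characteristicPathLength(gr), C = cstat(gr))
    })
  })
  nl <- vapply(nulls, `[[`, 0, "L")
  nc <- vapply(nulls, `[[`, 0, "C")
  Lr <- mean(nl); Cr <- mean(nc)
  S <- (C / Cr) / (L / Lr)
  null_S <- (nc / Cr) / (nl / Lr)
  list(S = S, L = L, C = C, L_rand = Lr, C_rand = Cr, null_S = null_S,
       percentile = 100 * mean(null_S < S), variant = variant,
       n_null = n_null, seed = seed)
}

perturbEdges <- function(g, mode, k) {
  if (k == 0L) return(g)
  if (mode == "remove") {
    igraph::delete_edges(g, sample(igraph::E(g), k))
  } else {
    n <- igraph::vcount(g)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    absent <- which(adj == 0 & diag(n) == 0, arr.ind = TRUE)
    pick <- absent[sample(nrow(absent), min(k, nrow(absent))), ,
                   drop = FALSE]
    igraph::add_edges(g, as.vector(t(pick)))
  }
}

#' Rank robustness of node metrics under edge perturbation
#'
#' Repeatedly adds (uniformly among absent ordered pairs) or removes
#' (uniformly among present edges) \code{round(fraction * m)} edges,
#' recomputes the chosen node metric, and records each original node's
#' rank (1 = highest, ties broken by average rank).
#'
#' @param view from \code{\link{buildGraphView}} (or an igraph graph).
#' @param metric one of \code{"degree"}, \code{"betweenness"},
#'   \code{"closeness"}, \code{"clustering"}.
#' @param mode \code{"add"} or \code{"remove"}.
#' @param fraction fraction of the edge count perturbed per iteration
#'   (default 0.25).
#' @param n_iter number of perturbation iterations.
#' @param seed integer seed.
#' @return data.frame per node: \code{node}, \code{base_rank},
#'   \code{mean_rank}, \code{sd_rank}; perturbation settings as
#'   attributes.
#' @export
rankRobustness <- function(view, metric = c("degree", "betweenness",
                                            "closeness", "clustering"),
                           mode = c("remove", "add"), fraction = 0.25,
                           n_iter = 100L, seed = 1L) {
  metric <- match.arg(metric); mode <- match.arg(mode)
  g <- if (is.list(view) && !is.null(view$graph)) view$graph else view
  metricValues <- function(gr) {
    switch(metric,
      degree = igraph::degree(gr, mode = "all"),
      betweenness = igraph::betweenness(gr, directed = TRUE),
      closeness = {
        x <- suppressWarnings(igraph::closeness(gr, mode = "out"))
        x[is.nan(x)] <- 0
        x
      },
      clustering = clusteringCoefficients(gr)$local)
  }
  m <- igraph::ecount(g)
  k <- round(fraction * m)
  base <- rankDesc(metricValues(g))
  ranks <- withSeed(deriveSeed(seed, "rank_robustness"), {
    vapply(seq_len(n_iter), function(i) {
      rankDesc(metricValues(perturbEdges(g, mode, k)))
    }, numeric(igraph::vcount(g)))
  })
  out <- data.frame(node = igraph::V(g)$name, base_rank = unname(base),
                    mean_rank = unname(rowMeans(ranks)),
                    sd_rank = unname(apply(ranks, 1L, sd)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "settings") <- list(metric = metric, mode = mode,
                                fraction = fraction, n_iter = n_iter,
                                seed = seed)
  out
}

#' Pearson correlation of a node metric with pleiotropy
#'
#' @param metric_values numeric vector (e.g. betweenness per ILP).
#' @param pleiotropy_values matching pleiotropy percentages.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
correlateWithPleiotropy <- function(metric_values, pleiotropy_values) {
  stopifnot(length(metric_values) == length(pleiotropy_values))
  ct <- cor.test(metric_values, pleiotropy_values, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       n = sum(complete.cases(metric_values, pleiotropy_values)))
}
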