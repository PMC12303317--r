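# Thresholded Pearson correlation network over the feature matrix:
# |r| >= 0.5 edges, normalized degree and betweenness centrality, and
# within/between-group edge densities.

#' Pairwise Pearson correlation matrix with sample counts and p-values
#'
#' Correlations are computed on pairwise-complete observations. Pairs with
#' fewer than 3 complete observations, or with zero variance on either
#' side, are flagged undefined (`NA`) and never become edges. Two-sided
#' p-values come from the t transform `t = r * sqrt((n-2) / (1-r^2))` with
#' `n - 2` degrees of freedom; they are reported only and play no role in
#' edge selection.
#'
#' @param fm A `feature_matrix` (or plain numeric matrix, columns =
#'   features).
#' @return Object of class `correlation_matrix`: list with `r`, `n_obs`,
#'   `p` (all features x features).
#' @export
correlation_matrix <- function(fm) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  p <- ncol(X)
  obs <- !is.na(X)
  n_obs <- crossprod(obs)
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  r[n_obs < 3] <- NA_real_
  diag(r) <- 1
  tt <- r * sqrt((n_obs - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tt), df = pmax(n_obs - 2, 1))
  pv[is.na(r)] <- NA_real_
  diag(pv) <- 0
  structure(list(r = r, n_obs = n_obs, p = pv), class = "correlation_matrix")
}

#' Build the thresholded correlation graph
#'
#' Undirected graph on all features, with an edge between i and j iff
#' `|r_ij| >= threshold` (inclusive rule) and `r_ij` is defined. Each edge
#' carries its signed correlation as attribute `r`. No self loops.
#'
#' @param cm A [correlation_matrix()].
#' @param threshold Correlation magnitude cut-off (default 0.5).
#' @param groups Optional named group vector (feature -> group) attached
#'   as a node attribute.
#' @return An `igraph` graph with vertex attributes `name`, `group` and
#'   edge attribute `r`.
#' @export
build_graph <- function(cm, threshold = 0.5, groups = NULL) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (threshold <= 0 || threshold > 1) stop_invalid("threshold must be in (0, 1]")
  r <- cm$r
  feats <- colnames(r)
  idx <- which(abs(r) >= threshold & upper.tri(r) & !is.na(r), arr.ind = TRUE)
  edges <- data.frame(from = feats[idx[, 1]], to = feats[idx[, 2]],
                      r = r[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = feats))
  if (!is.null(groups)) {
    igraph::V(g)$group <- unname(groups[igraph::V(g)$name])
  }
  g
}

#' Normalized degree and betweenness centrality
#'
#' Degree is normalized by `n - 1` (the maximum possible number of
#' neighbours); betweenness by `(n-1)(n-2)/2` (the number of node pairs a
#' node could mediate). Betweenness uses unweighted shortest paths with
#' full shortest-path multiplicity accounting; pairs in different
#' components contribute zero. Set `weighted = TRUE` to use `1/|r|` edge
#' lengths instead.
#'
#' @param g Graph from [build_graph()].
#' @param weighted Use `1/|r|` as shortest-path edge length.
#' @return Data frame `feature, degree, degree_norm, betweenness,
#'   betweenness_norm`.
#' @export
centralities <- function(g, weighted = FALSE) {
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  w <- if (weighted) 1 / abs(igraph::E(g)$r) else NA
  btw <- igraph::betweenness(g, directed = FALSE, weights = w)
  data.frame(
    feature = igraph::V(g)$name,
    degree = as.integer(deg),
    degree_norm = deg / (n - 1),
    betweenness = btw,
    betweenness_norm = btw / ((n - 1) * (n - 2) / 2),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Within- and between-group edge densities
#'
#' Density of realized edges among possible pairs: `m*(m-1)/2` within a
#' group of size `m`, `m_a * m_b` between two groups. A group of size < 2
#' has undefined (NA) within-group density.
#'
#' @param g Graph from [build_graph()].
#' @param schema Feature schema data frame (`feature`, `group`).
#' @return Symmetric group x group matrix of densities.
#' @export
group_densities <- function(g, schema) {
  groups <- unique(schema$group)
  member <- stats::setNames(schema$group, schema$feature)
  ends <- igraph::as_edgelist(g)
  eg <- cbind(member[ends[, 1]], member[ends[, 2]])
  sizes <- table(factor(schema$group, levels = groups))
  D <- matrix(NA_real_, length(groups), length(groups), dimnames = list(groups, groups))
  for (a in seq_along(groups)) {
    for (b in a:length(groups)) {
      ga <- groups[a]; gb <- groups[b]
      if (a == b) {
        possible <- sizes[[ga]] * (sizes[[ga]] - 1) / 2
        realized <- sum(eg[, 1] == ga & eg[, 2] == ga)
      } else {
        possible <- sizes[[ga]] * sizes[[gb]]
        realized <- sum((eg[, 1] == ga & eg[, 2] == gb) | (eg[, 1] == gb & eg[, 2] == ga))
      }
      D[a, b] <- D[b, a] <- if (possible > 0) realized / possible else NA_real_
    }
  }
  D
}

#' Fit the feature correlation network
#'
#' The one-call network stage: computes the Pearson correlation matrix of
#' the feature table, thresholds it at `|r| >= threshold` to build the
#' graph, and derives normalized centralities and group densities.
#'
#' @param fm A `feature_matrix` (see [assemble_features()]).
#' @param threshold Correlation magnitude cut-off (default 0.5).
#' @param weighted Use `1/|r|` shortest-path lengths for betweenness.
#' @return Object of class `feature_network`: list with `correlation`
#'   ([correlation_matrix()]), `graph` (igraph), `centrality` (data
#'   frame), `density` (group matrix), `threshold`, `schema`.
#' @export
feature_network <- function(fm, threshold = 0.5, weighted = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  cm <- correlation_matrix(fm)
  groups <- stats::setNames(fm$schema$group, fm$schema$feature)
  g <- build_graph(cm, threshold = threshold, groups = groups)
  structure(list(
    correlation = cm,
    graph = g,
    centrality = centralities(g, weighted = weighted),
    density = group_densities(g, fm$schema),
    threshold = threshold,
    schema = fm$schema
  ), class = "feature_network")
}

#' @export
print.feature_network <- function(x, ...) {
  cat("Feature correlation network (|r| >=", x$threshold, ")\n")
  cat("  nodes:", igraph::vcount(x$graph), " edges:", igraph::ecount(x$graph), "\n")
  top <- x$centrality[order(-x$centrality$degree_norm), ][1:min(5, nrow(x$centrality)), ]
  cat("  highest normalized degree:\n")
  print(top[, c("feature", "degree_norm", "betweenness_norm")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.feature_network <- function(object, ...) {
  cat("Edges:", igraph::ecount(object$graph), "of",
      choose(igraph::vcount(object$graph), 2), "possible\n")
  cat("Group densities:\n")
  print(round(object$density, 3))
  invisible(object)
}

#' @export
plot.feature_network <- function(x, ...) {
  groups <- factor(igraph::V(x$graph)$group)
  pal <- grDevices::hcl.colors(nlevels(groups), "Dark 3")
  set.seed(1L)  # deterministic layout
  igraph::plot.igraph(x$graph, vertex.color = pal[as.integer(groups)],
                      vertex.size = 6, vertex.label.cex = 0.5,
                      edge.width = abs(igraph::E(x$graph)$r) * 2, ...)
  graphics::legend("topleft", legend = levels(groups), col = pal, pch = 19, bty = "n")
  invisible(x)
}

#' Write network artifacts
#'
#' Writes `correlation_matrix.csv`, `edges.csv` (`source, target, r`),
#' `centrality.csv`, `group_density.csv` and `network.graphml` (node
#' attributes `group`, `degree_norm`, `betweenness_norm`; edge attribute
#' `r`).
#'
#' @param net A `feature_network`.
#' @param dir Output directory.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- net$correlation$r
  utils::write.csv(data.frame(feature = rownames(r), r, check.names = FALSE),
                   file.path(dir, "correlation_matrix.csv"), row.names = FALSE)
  ends <- igraph::as_edgelist(net$graph)
  utils::write.csv(data.frame(source = ends[, 1], target = ends[, 2],
                              r = igraph::E(net$graph)$r),
                   file.path(dir, "edges.csv"), row.names = FALSE)
  utils::write.csv(net$centrality, file.path(dir, "centrality.csv"), row.names = FALSE)
  utils::write.csv(data.frame(group = rownames(net$density), net$density,
                              check.names = FALSE),
                   file.path(dir, "group_density.csv"), row.names = FALSE)
  g <- net$graph
  cent <- net$centrality
  igraph::V(g)$degree_norm <- cent$degree_norm[match(igraph::V(g)$name, cent$feature)]
  igraph::V(g)$betweenness_norm <- cent$betweenness_norm[match(igraph::V(g)$name, cent$feature)]
  igraph::write_graph(g, file.path(dir, "network.graphml"), format = "graphml")
  invisible(dir)
}
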