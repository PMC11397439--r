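#' Sub-networks of a displayed partial-correlation graph
#'
#' Sub-networks are operationalized as the connected components of the
#' post-threshold displayed edge list; nodes without displayed edges are
#' singleton components.
#'
#' @param edges Displayed edge data frame with `from`/`to` columns (as from
#'   [network_edges()]).
#' @param nodes Character vector of all node labels.
#' @return List with `components` (list of node-label vectors, largest
#'   first) and `singleton_count`.
#' @export
connected_components <- function(edges, nodes) {
  dangling <- setdiff(unique(c(edges$from, edges$to)), nodes)
  if (length(dangling)) {
    stop_mhonet("edge endpoint(s) not in node set: ",
                paste(dangling, collapse = ", "))
  }
  if (length(nodes) == 0) {
    return(list(components = list(), singleton_count = 0L))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  groups <- split(nodes, comp$membership)
  groups <- groups[order(-lengths(groups))]
  names(groups) <- NULL
  list(components = groups,
       singleton_count = sum(lengths(groups) == 1L))
}

#' Deterministic Fruchterman-Reingold layout
#'
#' Force-directed placement in which displayed edges attract their
#' endpoints with strength proportional to `|rho|` and all node pairs
#' repel; strongly connected variables therefore land close together.
#' The layout is centred on its centroid and is deterministic for a fixed
#' seed and graph.
#'
#' @param edges Displayed edge data frame (`from`, `to`, `weight`).
#' @param nodes Character vector of node labels (nonempty).
#' @param seed Layout seed, default 0.
#' @param iterations Annealing iterations, default 200.
#' @return Data frame `node`, `x`, `y`, with `seed` and `iterations`
#'   attributes.
#' @export
layout_fruchterman_reingold <- function(edges, nodes, seed = 0,
                                        iterations = 200) {
  if (length(nodes) == 0) stop_mhonet("node set must be nonempty")
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = nodes))
  local_seed(seed)
  w <- if (nrow(edges)) edges$weight else NULL
  xy <- igraph::layout_with_fr(g, niter = iterations, weights = w)
  xy <- sweep(xy, 2, colMeans(xy))  # centre on the centroid
  out <- data.frame(node = nodes, x = xy[, 1], y = xy[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "iterations") <- iterations
  out
}

# Presentational width map: |rho| = 0.1 -> 0.5 pt up to |rho| = 1 -> 6 pt.
edge_widths <- function(weight, w_min = 0.5, w_max = 6, rho_min = 0.1) {
  pmax(w_min, w_min + (weight - rho_min) * (w_max - w_min) / (1 - rho_min))
}

#' Render a partial-correlation network
#'
#' Draws the displayed graph with the usual conventions: green edges for
#' positive partial correlations, red for negative, line width increasing
#' with `|rho|`, node labels printed at their layout positions.  Edges
#' below the display threshold are absent.  The format follows the file
#' extension: `.png` or `.svg`.
#'
#' @param network A `pcor_network`.
#' @param layout Layout data frame covering all network nodes (as from
#'   [layout_fruchterman_reingold()]).
#' @param path Output file ending in `.png` or `.svg`.
#' @param title Optional plot title.
#' @return The path, invisibly.
#' @export
render_network <- function(network, layout, path, title = NULL) {
  if (!all(network$labels %in% layout$node)) {
    stop_mhonet("layout does not cover all network nodes")
  }
  edges <- network_edges(network)
  ext <- tolower(tools::file_ext(path))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  switch(ext,
         png = grDevices::png(path, width = 1200, height = 1200, res = 150),
         svg = grDevices::svg(path, width = 8, height = 8),
         stop_mhonet("unsupported image format: .", ext))
  on.exit(grDevices::dev.off(), add = TRUE)

  pos <- layout[match(network$labels, layout$node), ]
  pad <- 0.15 * max(diff(range(pos$x)), diff(range(pos$y)), 1)
  graphics::plot(pos$x, pos$y, type = "n", axes = FALSE, asp = 1,
                 xlab = "", ylab = "", main = title,
                 xlim = range(pos$x) + c(-pad, pad),
                 ylim = range(pos$y) + c(-pad, pad))
  if (nrow(edges)) {
    i <- match(edges$from, pos$node)
    j <- match(edges$to, pos$node)
    graphics::segments(pos$x[i], pos$y[i], pos$x[j], pos$y[j],
                       col = ifelse(edges$rho > 0, "forestgreen",
                                    "firebrick"),
                       lwd = edge_widths(edges$weight))
  }
  graphics::points(pos$x, pos$y, pch = 21, bg = "grey90", cex = 2.2)
  graphics::text(pos$x, pos$y, labels = pos$node, cex = 0.55, pos = 3,
                 offset = 0.6)
  invisible(path)
}
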