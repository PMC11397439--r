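#' Build a random sparse ground-truth conditional-dependence graph
#'
#' Draws a sparse symmetric precision matrix with a known edge support, used
#' by [simulate_cohort()] as the true conditional-dependence structure that
#' the graphical-lasso stage is later asked to recover.  Edges are sampled
#' uniformly among the `p(p-1)/2` variable pairs; off-diagonal magnitudes are
#' drawn uniformly from `value_range` with random sign, and each diagonal
#' entry is set to the absolute row sum of its off-diagonal entries plus one,
#' which makes the matrix strictly diagonally dominant and hence positive
#' definite.
#'
#' @param p Number of variables (at least 2).
#' @param density Fraction of the possible `p(p-1)/2` edges to include,
#'   in `[0, 1]`.  The realized edge count is `round(density * p*(p-1)/2)`.
#' @param seed Integer seed; the graph is reproducible from `(p, density,
#'   seed)` and the draw does not disturb the caller's RNG stream.
#' @param value_range Magnitude range for nonzero off-diagonal precision
#'   entries.
#' @return An object of class `ground_truth_graph`: a list with `p`,
#'   `precision` (the p x p matrix), `adjacency` (binary off-diagonal
#'   support), `n_edges` and `seed`.
#' @examples
#' g <- make_ground_truth_graph(15, density = 0.1, seed = 42)
#' g$n_edges
#' min(eigen(g$precision, symmetric = TRUE, only.values = TRUE)$values) > 0
#' @export
make_ground_truth_graph <- function(p, density, seed = 1,
                                    value_range = c(0.4, 0.8)) {
  if (length(p) != 1L || !is.finite(p) || p < 2 || p != round(p)) {
    stop_mhonet("`p` must be a single integer >= 2")
  }
  if (density < 0 || density > 1) {
    stop_mhonet("`density` must lie in [0, 1]")
  }
  p <- as.integer(p)
  local_seed(seed)

  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  n_pairs <- nrow(pairs)
  m <- round(density * n_pairs)
  chosen <- if (m > 0) sample.int(n_pairs, m) else integer(0)

  precision <- matrix(0, p, p)
  if (m > 0) {
    vals <- runif(m, value_range[1], value_range[2]) *
      sample(c(-1, 1), m, replace = TRUE)
    precision[pairs[chosen, , drop = FALSE]] <- vals
    precision <- precision + t(precision)
  }
  diag(precision) <- rowSums(abs(precision)) + 1

  adjacency <- (precision != 0) * 1L
  diag(adjacency) <- 0L

  ev_min <- min(eigen(precision, symmetric = TRUE, only.values = TRUE)$values)
  stopifnot(ev_min > 0)  # guaranteed by diagonal dominance

  structure(
    list(p = p, precision = precision, adjacency = adjacency,
         n_edges = m, seed = seed),
    class = "ground_truth_graph"
  )
}

#' @export
print.ground_truth_graph <- function(x, ...) {
  cat(sprintf("Ground-truth graph: p = %d, %d edge(s), seed = %s\n",
              x$p, x$n_edges, format(x$seed)))
  invisible(x)
}

# Edge support of a symmetric matrix as a two-column index matrix (i < j).
support_pairs <- function(mat, tol = 0) {
  idx <- which(upper.tri(mat) & abs(mat) > tol, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Compare an estimated edge set with a reference adjacency
#'
#' Computes precision, recall and F1 of an estimated graph's edge support
#' against a reference adjacency matrix.  Degenerate cases follow the usual
#' convention: with no predicted edges precision is 1, with no true edges
#' recall is 1, so two empty graphs score F1 = 1.
#'
#' @param estimated,truth Symmetric adjacency (or weighted) matrices; any
#'   nonzero off-diagonal entry counts as an edge.
#' @return A list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
edge_support_metrics <- function(estimated, truth) {
  stopifnot(all(dim(estimated) == dim(truth)))
  est <- abs(estimated[upper.tri(estimated)]) > 0
  tru <- abs(truth[upper.tri(truth)]) > 0
  tp <- sum(est & tru)
  fp <- sum(est & !tru)
  fn <- sum(!est & tru)
  prec <- if (tp + fp == 0) 1 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}
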