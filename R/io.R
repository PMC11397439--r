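#' Write a synthetic cohort to plain-text files
#'
#' Emits `cohort.csv` (one row per participant, including the label
#' column), `dass_items.csv` (21 item columns), `ffq_records.csv`
#' (long format: participant, food_id, frequency_unit, times, portion_g),
#' `food_composition.csv`, `ground_truth_edges.tsv` (i, j, precision
#' value) and `precision.csv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  tab <- cbind(cohort$table, label = cohort$true_labels)
  f <- file.path(dir, "cohort.csv")
  utils::write.csv(tab, f, row.names = FALSE)
  files["cohort"] <- f
  if (!is.null(cohort$dass_items)) {
    f <- file.path(dir, "dass_items.csv")
    utils::write.csv(as.data.frame(cohort$dass_items), f,
                     row.names = FALSE)
    files["dass_items"] <- f
  }
  if (!is.null(cohort$ffq_records)) {
    f <- file.path(dir, "ffq_records.csv")
    utils::write.csv(cohort$ffq_records, f, row.names = FALSE)
    files["ffq_records"] <- f
    f <- file.path(dir, "food_composition.csv")
    utils::write.csv(cohort$food_composition, f, row.names = FALSE)
    files["food_composition"] <- f
  }
  g <- cohort$spec$graph
  labels <- cohort$spec$marginals$name
  idx <- support_pairs(g$precision * upper.tri(g$precision))
  edges <- data.frame(node_i = labels[idx[, 1]], node_j = labels[idx[, 2]],
                      value = g$precision[idx])
  f <- file.path(dir, "ground_truth_edges.tsv")
  utils::write.table(edges, f, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  files["ground_truth_edges"] <- f
  prec <- as.data.frame(g$precision)
  names(prec) <- labels
  f <- file.path(dir, "precision.csv")
  utils::write.csv(prec, f, row.names = FALSE)
  files["precision"] <- f
  invisible(files)
}

#' Serialize a cohort spec to YAML
#'
#' @param spec A `cohort_spec`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  obj <- list(
    n = spec$n, seed = spec$seed, muo_fraction = spec$muo_fraction,
    group_effect = spec$group_effect,
    marginals = lapply(seq_len(nrow(spec$marginals)), function(i) {
      as.list(spec$marginals[i, ])
    }),
    graph = list(p = spec$graph$p, seed = spec$graph$seed,
                 n_edges = spec$graph$n_edges,
                 precision = apply(spec$graph$precision, 1, as.numeric,
                                   simplify = FALSE)))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read a cohort spec back from YAML
#'
#' @param path YAML file written by [write_cohort_spec()].
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  marg <- do.call(rbind, lapply(obj$marginals, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  precision <- do.call(rbind, lapply(obj$graph$precision, as.numeric))
  adjacency <- (precision != 0) * 1L
  diag(adjacency) <- 0L
  graph <- structure(
    list(p = obj$graph$p, precision = precision, adjacency = adjacency,
         n_edges = obj$graph$n_edges, seed = obj$graph$seed),
    class = "ground_truth_graph")
  cohort_spec(n = obj$n, marginals = marg, graph = graph,
              group_effect = obj$group_effect,
              muo_fraction = obj$muo_fraction, seed = obj$seed)
}

write_edge_tsv <- function(edges, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    edges[, c("from", "to", "rho", "sign"), drop = FALSE], path,
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
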