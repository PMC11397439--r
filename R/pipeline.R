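#' Configuration for the end-to-end analysis pipeline
#'
#' @param out_dir Output directory for all artifacts.
#' @param n Cohort size for the bundled simulation, default 230.
#' @param seed Master seed, default 1.
#' @param cohort_csv Optional path to an existing participant CSV (with the
#'   classification variable columns); when given, simulation is skipped.
#' @param label_method `"idf"` (default) or `"idf_homa"`: which
#'   classification defines the MHO/MUO grouping.
#' @param gamma EBIC gamma, default 0.5.
#' @param n_lambda Penalty-grid size, default 100.
#' @param display_threshold Partial-correlation display cutoff, default
#'   0.1.
#' @param bands Named list of Rho bands; default the full network plus the
#'   three conventional bands.
#' @param image_format `"png"` (default) or `"svg"`.
#' @param layout_seed Layout seed, default 0.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n = 230, seed = 1, cohort_csv = NULL,
                            label_method = c("idf", "idf_homa"),
                            gamma = 0.5, n_lambda = 100,
                            display_threshold = 0.1,
                            bands = list(all = NULL,
                                         rho_0.400_0.599 = c(0.400, 0.599),
                                         rho_0.600_0.799 = c(0.600, 0.799),
                                         rho_0.800_0.999 = c(0.800, 0.999)),
                            image_format = c("png", "svg"),
                            layout_seed = 0) {
  structure(list(out_dir = out_dir, n = n, seed = seed,
                 cohort_csv = cohort_csv,
                 label_method = match.arg(label_method), gamma = gamma,
                 n_lambda = n_lambda,
                 display_threshold = display_threshold, bands = bands,
                 image_format = match.arg(image_format),
                 layout_seed = layout_seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys match the arguments of [pipeline_config()]; bands are
#' given as named two-element lists.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_mhonet("config file not found: ", path)
  obj <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
  names(obj)[names(obj) %in% c("FALSE", "false")] <- "n"
  if (!is.null(obj$bands)) {
    obj$bands <- lapply(obj$bands, function(b) {
      if (is.null(b) || length(b) == 0) NULL else as.numeric(b)
    })
  }
  do.call(pipeline_config, obj)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_mhonet("pipeline stage '", stage, "' failed: ",
                conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Chains every stage on one seeded configuration: simulate (or load) the
#' cohort, re-score the instruments (FFQ to nutrient totals, DASS-21 items
#' to subscales) and verify they reproduce the table, classify metabolic
#' health, describe all variables, compare MHO vs MUO, and estimate a
#' partial-correlation network per group (all participants, MHO, MUO)
#' crossed with each Rho band, including connected components, a
#' deterministic layout, a rendered figure, and an edge-list TSV.  A JSON
#' manifest of every artifact is written last.
#'
#' @param config A `pipeline_config`, a YAML path, or a list of
#'   [pipeline_config()] arguments.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config)[setdiff(names(config),
                                                    "bands")],
                   files = list(), networks = list())

  # --- cohort -------------------------------------------------------------
  cohort <- NULL
  if (is.null(config$cohort_csv)) {
    spec <- pipeline_stage("simulate",
                           cohort_spec(n = config$n, seed = config$seed))
    cohort <- pipeline_stage("simulate", simulate_cohort(spec))
    table <- cohort$table
    files <- pipeline_stage("simulate",
                            write_cohort(cohort, config$out_dir))
    manifest$files <- as.list(files)
    manifest$mismatch_rate <- cohort$mismatch_rate

    # instrument round-trip: re-score the generated raw instruments and
    # check they reproduce the simulated columns
    checks <- pipeline_stage("instruments", {
      psych <- score_dass(cohort$dass_items)
      d_psych <- max(abs(as.matrix(psych) -
                           as.matrix(table[, names(psych)])))
      intake <- cohort$spec$marginals$name[
        cohort$spec$marginals$block == "intake"]
      d_intake <- 0
      for (pid in unique(cohort$ffq_records$participant)) {
        rec <- cohort$ffq_records[cohort$ffq_records$participant == pid, ]
        grams <- stats::setNames(
          ffq_to_daily_grams(rec$frequency_unit, rec$times, rec$portion_g),
          rec$food_id)
        tot <- nutrient_totals(grams, cohort$food_composition)
        d_intake <- max(d_intake,
                        max(abs(tot[intake] -
                                  unlist(table[pid, intake]))))
      }
      list(dass = d_psych, ffq = d_intake)
    })
    manifest$instrument_roundtrip <- checks
  } else {
    if (!file.exists(config$cohort_csv)) {
      stop_mhonet("pipeline stage 'load' failed: file not found: ",
                  config$cohort_csv)
    }
    table <- utils::read.csv(config$cohort_csv)
  }

  # --- classification -----------------------------------------------------
  classified <- pipeline_stage("classify", classify_cohort(table))
  label_col <- paste0("label_", config$label_method)
  f <- file.path(config$out_dir, "classified.csv")
  utils::write.csv(classified, f, row.names = FALSE)
  manifest$files$classified <- f
  manifest$muo_fraction <- mean(classified[[label_col]] == "MUO")

  # --- descriptives and group comparison ----------------------------------
  raw_vars <- setdiff(names(table),
                      c("bmi", "bmi_category", "homa_ir",
                        "risk_factor_count", "label_idf",
                        "label_idf_homa"))
  desc <- pipeline_stage("describe",
                         describe_cohort(classified[, c(raw_vars,
                                                        "bmi", "homa_ir")]))
  f <- file.path(config$out_dir, "descriptives.csv")
  utils::write.csv(desc, f, row.names = FALSE)
  manifest$files$descriptives <- f

  comp <- pipeline_stage("compare", {
    cols <- c(raw_vars, "bmi", "homa_ir", label_col)
    compare_groups(classified[, cols], label_col)
  })
  f <- file.path(config$out_dir, "group_comparison.csv")
  utils::write.csv(comp, f, row.names = FALSE)
  manifest$files$group_comparison <- f

  # --- networks: group x band ---------------------------------------------
  groups <- list(all = rep(TRUE, nrow(classified)),
                 MHO = classified[[label_col]] == "MHO",
                 MUO = classified[[label_col]] == "MUO")
  num_vars <- raw_vars[vapply(table[raw_vars], is.numeric, logical(1))]

  for (gname in names(groups)) {
    sub <- classified[groups[[gname]], num_vars, drop = FALSE]
    S_full <- pipeline_stage(paste0("spearman:", gname),
                             spearman_matrix(sub))
    for (bname in names(config$bands)) {
      band <- config$bands[[bname]]
      S <- if (is.null(band)) S_full else band_filter(S_full, band)
      key <- paste(gname, bname, sep = ".")
      entry <- list(group = gname, band = bname, n = S$n, p = S$p)
      if (S$p < 2) {
        entry$empty <- TRUE
        entry$edges <- 0L
        manifest$networks[[key]] <- entry
        next
      }
      sel <- pipeline_stage(
        paste0("ggm:", key),
        select_lambda_ebic(S, lambdas = lambda_grid(S, config$n_lambda),
                           gamma = config$gamma))
      net <- partial_correlations(
        sel$fit, display_threshold = config$display_threshold)
      edges <- network_edges(net)
      comp_parts <- connected_components(edges, net$labels)
      lay <- layout_fruchterman_reingold(edges, net$labels,
                                         seed = config$layout_seed)
      f_edges <- file.path(config$out_dir,
                           paste0("edges_", key, ".tsv"))
      write_edge_tsv(edges, f_edges)
      f_img <- file.path(config$out_dir,
                         paste0("network_", key, ".",
                                config$image_format))
      render_network(net, lay, f_img,
                     title = paste0(gname, " / ", bname))
      entry$lambda <- sel$lambda
      entry$edges <- nrow(edges)
      entry$components <- length(comp_parts$components)
      entry$singletons <- comp_parts$singleton_count
      entry$edge_list <- f_edges
      entry$image <- f_img
      manifest$networks[[key]] <- entry
    }
  }

  f <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest$files$manifest <- f
  invisible(manifest)
}
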