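#' Specify a synthetic cohort
#'
#' Bundles everything the simulator needs: the sample size, the marginal
#' anchor table, the ground-truth conditional-dependence graph, the
#' per-variable latent group-effect shifts, the target fraction of
#' metabolically unhealthy (MUO) participants, and the seed.
#'
#' @param n Number of participants (>= 0).
#' @param marginals Marginal data frame as from [cohort_anchors()] or
#'   [generic_marginals()]; one row per variable.
#' @param graph A `ground_truth_graph` with `p == nrow(marginals)`; by
#'   default one is drawn with [make_ground_truth_graph()] at `density`.
#' @param density Edge density for the default graph.
#' @param group_effect Optional numeric vector of latent shifts (SD units)
#'   applied to MUO-assigned rows; defaults to the `group_effect` column of
#'   `marginals` (zero if absent).
#' @param muo_fraction Target MUO fraction in (0, 1); default 164/230.
#' @param seed Integer seed controlling every random draw.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, marginals = cohort_anchors(), graph = NULL,
                        density = 0.03, group_effect = NULL,
                        muo_fraction = 164 / 230, seed = 1) {
  if (n < 0 || n != round(n)) stop_mhonet("`n` must be a nonnegative integer")
  if (muo_fraction <= 0 || muo_fraction >= 1) {
    stop_mhonet("`muo_fraction` must lie strictly in (0, 1)")
  }
  needed <- c("name", "family", "median", "sd", "min", "max")
  if (!all(needed %in% names(marginals))) {
    stop_mhonet("`marginals` needs columns ",
                paste(needed, collapse = ", "))
  }
  if (any(marginals$sd <= 0)) stop_mhonet("anchor SDs must be positive")
  if (any(marginals$min > marginals$median |
            marginals$median > marginals$max)) {
    stop_mhonet("anchors must satisfy min <= median <= max")
  }
  # default ground truth: sparse with partial correlations around 0.2-0.45,
  # the strength range typical of reported cohort-scale networks, so the
  # structure is detectable at a few hundred participants
  graph <- graph %||%
    make_ground_truth_graph(nrow(marginals), density, seed = seed,
                            value_range = c(0.6, 0.9))
  if (graph$p != nrow(marginals)) {
    stop_mhonet("graph dimension (", graph$p,
                ") must match the number of marginals (", nrow(marginals),
                ")")
  }
  group_effect <- group_effect %||% marginals$group_effect %||%
    numeric(nrow(marginals))
  if (length(group_effect) != nrow(marginals)) {
    stop_mhonet("`group_effect` must have one entry per variable")
  }
  structure(list(n = as.integer(n), marginals = marginals, graph = graph,
                 group_effect = as.numeric(group_effect),
                 muo_fraction = muo_fraction, seed = seed),
            class = "cohort_spec")
}

# Quantile function (on (0,1)) for one marginal anchor row.  Lognormal
# matches the median exactly and solves sigma from the anchor SD;
# truncated-normal solves its location so the truncated median matches;
# discrete-ordinal rounds a truncated normal to integers.
marginal_quantile_fun <- function(m) {
  family <- m$family
  if (family == "lognormal") {
    mu <- log(m$median)
    target <- m$sd
    f <- function(s) sqrt(exp(s^2) - 1) * exp(mu + s^2 / 2) - target
    sigma <- tryCatch(
      stats::uniroot(f, c(1e-6, 10), tol = 1e-10)$root,
      error = function(e) min(10, max(1e-6, target / m$median)))
    return(function(u) stats::qlnorm(u, meanlog = mu, sdlog = sigma))
  }
  if (family %in% c("truncated-normal", "discrete-ordinal")) {
    s <- m$sd
    a <- m$min; b <- m$max
    tmed <- function(loc) {
      pa <- stats::pnorm(a, loc, s); pb <- stats::pnorm(b, loc, s)
      stats::qnorm(pa + 0.5 * (pb - pa), loc, s)
    }
    g <- function(loc) tmed(loc) - m$median
    # bracket around the target median keeps pnorm/qnorm well conditioned
    lo <- m$median - 6 * s; hi <- m$median + 6 * s
    glo <- g(lo); ghi <- g(hi)
    loc <- if (is.finite(glo) && is.finite(ghi) && glo * ghi < 0) {
      stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
    } else if (isTRUE(abs(glo) < abs(ghi))) lo else hi
    q <- function(u) {
      pa <- stats::pnorm(a, loc, s); pb <- stats::pnorm(b, loc, s)
      stats::qnorm(pa + u * (pb - pa), loc, s)
    }
    if (family == "discrete-ordinal") {
      return(function(u) pmin(m$max, pmax(m$min, round(q(u)))))
    }
    return(q)
  }
  if (family == "normal") {
    return(function(u) stats::qnorm(u, m$median, m$sd))
  }
  stop_mhonet("unknown marginal family: ", family)
}

# Split a DASS subscale total (0..21) into 7 item responses 0..3 that sum
# to it: floor(total/7) everywhere plus one on `total %% 7` positions.
decompose_subscale_total <- function(total) {
  base <- total %/% 7L
  rem <- total %% 7L
  base + as.integer(seq_len(7L) <= rem)
}

#' Synthetic single-nutrient food-composition table
#'
#' One carrier food per nutrient, holding only that nutrient at a density
#' of one third of its anchored median per 100 g (so typical daily amounts
#' come to a few hundred grams).  This diagonal design is deliberately
#' synthetic: it lets the simulator emit FFQ records whose scoring exactly
#' reproduces any target nutrient totals.
#'
#' @param nutrient_medians Named numeric vector of anchored daily medians.
#' @return Data frame with `food_id` plus one density column per nutrient.
#' @export
synthetic_food_composition <- function(nutrient_medians) {
  nutrients <- names(nutrient_medians)
  dens <- diag(pmax(nutrient_medians / 3, 1e-6), nrow = length(nutrients))
  colnames(dens) <- nutrients
  out <- data.frame(food_id = paste0("syn_", nutrients),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(dens))
}

#' Simulate a cohort with known conditional-dependence structure
#'
#' Draws a latent Gaussian sample whose correlation is the (unit-variance
#' rescaled) inverse of the ground-truth precision matrix, maps each column
#' through a monotone quantile (copula) transform to its anchored marginal,
#' and assembles the companion instrument data.  Group structure: each row
#' has a latent severity score; rows above a threshold receive the
#' spec's group-effect shifts on the latent scale before transformation.
#' When the marginal set contains the cardiometabolic classification
#' variables, the threshold is calibrated by bisection so that the fraction
#' classified MUO by [classify_cohort()] matches the spec's target, labels
#' are taken from the classifier (the single source of truth), and the
#' latent-assignment mismatch rate is reported.  Otherwise labels are the
#' latent assignment itself.
#'
#' DASS-21 item responses are decomposed from the psychological subscale
#' columns so that [score_dass()] reproduces them exactly, and FFQ records
#' are built against [synthetic_food_composition()] so that
#' [nutrient_totals()] reproduces the intake columns.
#'
#' @param spec A [cohort_spec()].
#' @param calibrate Calibrate the severity threshold against the metabolic
#'   classifier (default TRUE; ignored when classification variables are
#'   absent).
#' @return Object of class `synthetic_cohort`: `table` (n x p data frame in
#'   natural units), `dass_items`, `ffq_records`, `food_composition`,
#'   `true_labels`, `latent`, `latent_assignment`, `mismatch_rate`,
#'   `threshold`, `spec`.
#' @export
simulate_cohort <- function(spec, calibrate = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  p <- spec$graph$p
  marg <- spec$marginals

  sigma <- solve(spec$graph$precision)
  ev <- eigen(spec$graph$precision, symmetric = TRUE, only.values = TRUE)
  if (min(ev$values) <= 0) {
    stop_mhonet("precision matrix is not positive definite; ",
                "smallest eigenvalue = ", format(min(ev$values)))
  }
  sigma <- stats::cov2cor(sigma)

  local_seed(spec$seed)
  z <- matrix(stats::rnorm(n * p), n, p) %*% chol(sigma)
  severity <- stats::rnorm(n)

  qfuns <- lapply(seq_len(p), function(j) marginal_quantile_fun(marg[j, ]))
  transform <- function(zm) {
    cols <- lapply(seq_len(p), function(j) qfuns[[j]](stats::pnorm(zm[, j])))
    names(cols) <- marg$name
    as.data.frame(cols, optional = TRUE)
  }
  build <- function(threshold) {
    assign_muo <- severity > threshold
    zs <- z
    if (any(assign_muo)) {
      zs[assign_muo, ] <- zs[assign_muo, ] +
        matrix(spec$group_effect, sum(assign_muo), p, byrow = TRUE)
    }
    list(table = transform(zs), assign = assign_muo, latent = zs)
  }

  class_vars <- c("weight", "height", "triglycerides", "glucose", "hdl",
                  "sbp", "dbp", "insulin")
  can_classify <- all(class_vars %in% marg$name)

  if (calibrate && can_classify && n > 0) {
    frac_at <- function(t) {
      mean(classify_cohort(build(t)$table)$label_idf == "MUO")
    }
    lo <- -4; hi <- 4
    if (frac_at(hi) >= spec$muo_fraction) {
      threshold <- hi
    } else if (frac_at(lo) <= spec$muo_fraction) {
      threshold <- lo
    } else {
      for (i in 1:30) {
        mid <- (lo + hi) / 2
        if (frac_at(mid) > spec$muo_fraction) lo <- mid else hi <- mid
      }
      threshold <- (lo + hi) / 2
    }
  } else {
    threshold <- stats::qnorm(1 - spec$muo_fraction)
  }

  final <- build(threshold)
  table <- final$table

  if (can_classify && n > 0) {
    true_labels <- classify_cohort(table)$label_idf
    mismatch_rate <- mean((true_labels == "MUO") != final$assign)
  } else {
    true_labels <- ifelse(final$assign, "MUO", "MHO")
    mismatch_rate <- NA_real_
  }

  # DASS items consistent with the psychological subscale columns
  mapping <- dass21_mapping()
  psych <- c("depression", "anxiety", "stress")
  dass_items <- NULL
  if (all(psych %in% marg$name)) {
    dass_items <- matrix(0L, n, 21L)
    for (i in seq_len(n)) {
      for (sub in psych) {
        vals <- decompose_subscale_total(as.integer(table[[sub]][i]))
        dass_items[i, sample(mapping[[sub]])] <- vals
      }
    }
    colnames(dass_items) <- paste0("item_", 1:21)
  }

  # FFQ records reproducing the intake columns under the synthetic
  # composition table
  ffq_records <- NULL
  food_composition <- NULL
  intake_vars <- marg$name[marg$block == "intake"]
  if (!is.null(marg$block) && length(intake_vars) > 0) {
    medians <- stats::setNames(
      marg$median[match(intake_vars, marg$name)], intake_vars)
    food_composition <- synthetic_food_composition(medians)
    dens <- diag(as.matrix(food_composition[, intake_vars, drop = FALSE]))
    grams <- if (n > 0) {
      t(t(as.matrix(table[, intake_vars, drop = FALSE]) * 100) / dens)
    } else {
      matrix(numeric(0), 0, length(intake_vars))
    }
    n_rec <- n * length(intake_vars)
    ffq_records <- data.frame(
      participant = rep(seq_len(n), each = length(intake_vars)),
      food_id = rep(food_composition$food_id, times = n),
      frequency_unit = rep("daily", n_rec),
      times = rep(1, n_rec),
      portion_g = as.numeric(t(grams)),
      stringsAsFactors = FALSE)
  }

  structure(
    list(table = table, dass_items = dass_items, ffq_records = ffq_records,
         food_composition = food_composition, true_labels = true_labels,
         latent = final$latent, latent_assignment = final$assign,
         mismatch_rate = mismatch_rate, threshold = threshold, spec = spec),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: n = %d, p = %d, MUO fraction %.3f (target %.3f)\n",
    nrow(x$table), ncol(x$table),
    if (nrow(x$table)) mean(x$true_labels == "MUO") else NA,
    x$spec$muo_fraction))
  invisible(x)
}

#' Edge-support recovery benchmark
#'
#' Runs the full inference chain on a simulated cohort — rank correlation,
#' graphical lasso over an EBIC-selected penalty grid — and scores the
#' estimated edge support against the generating graph.
#'
#' @param spec A [cohort_spec()]; `n >= 10 * p` is recommended for stable
#'   recovery.
#' @param gamma EBIC gamma, default 0.5.
#' @param n_lambda Penalty-grid size, default 100.
#' @return List with `precision`, `recall`, `f1`, `lambda` (selected
#'   penalty), `edges_true`, `edges_estimated`, `selection` (the
#'   [select_lambda_ebic()] result) and `cohort`.
#' @export
recovery_experiment <- function(spec, gamma = 0.5, n_lambda = 100) {
  cohort <- simulate_cohort(spec)
  S <- spearman_matrix(cohort$table)
  sel <- select_lambda_ebic(S, lambdas = lambda_grid(S, n_lambda),
                            gamma = gamma)
  est <- sel$fit$theta
  diag(est) <- 0
  m <- edge_support_metrics(est, spec$graph$adjacency)
  list(precision = m$precision, recall = m$recall, f1 = m$f1,
       lambda = sel$lambda, edges_true = spec$graph$n_edges,
       edges_estimated = sel$fit$edge_count, selection = sel,
       cohort = cohort)
}
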