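#' Rank-based correlation matrix for network estimation
#'
#' Computes the Spearman (default) or Pearson correlation matrix of a
#' participant table.  Spearman is the rank transform followed by Pearson
#' correlation of average ranks, matching the nonparametric footing of the
#' rest of the pipeline.  Rank-based matrices need not be positive
#' semidefinite; when the smallest eigenvalue falls below `1e-8` the matrix
#' is repaired by clipping eigenvalues at that floor and rescaling to unit
#' diagonal, and the repair is flagged.
#'
#' @param table n x p numeric matrix or data frame, n >= 3, no missing
#'   values.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return An object of class `corr_matrix`: list with `S`, `labels`, `n`,
#'   `p`, `method`, `repaired`.
#' @export
spearman_matrix <- function(table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- as.matrix(table)
  if (!is.numeric(x)) stop_mhonet("table must be numeric")
  if (anyNA(x)) stop_mhonet("missing values are not supported")
  if (nrow(x) < 3) stop_mhonet("need at least 3 rows")
  constant <- apply(x, 2, function(col) diff(range(col)) == 0)
  if (any(constant)) {
    stop_mhonet("constant column(s): ",
                paste(colnames(x)[constant], collapse = ", "))
  }
  S <- stats::cor(x, method = method)
  repaired <- FALSE
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-8)
    S <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    S <- stats::cov2cor(S)
    S <- (S + t(S)) / 2
    repaired <- TRUE
    message("correlation matrix repaired to positive definite ",
            "(eigenvalue clipping at 1e-8)")
  }
  dimnames(S) <- list(colnames(x), colnames(x))
  structure(list(S = S, labels = colnames(x), n = nrow(x), p = ncol(x),
                 method = method, repaired = repaired),
            class = "corr_matrix")
}

as_corr_input <- function(S) {
  if (inherits(S, "corr_matrix")) return(S)
  S <- as.matrix(S)
  stopifnot(nrow(S) == ncol(S), isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
  structure(list(S = S, labels = colnames(S) %||% paste0("V", seq_len(ncol(S))),
                 n = NA_integer_, p = ncol(S), method = "unknown",
                 repaired = FALSE),
            class = "corr_matrix")
}

#' Graphical lasso with unpenalized diagonal
#'
#' Estimates a sparse precision matrix by maximizing the L1-penalized
#' Gaussian log-likelihood
#' `log det(Theta) - tr(S Theta) - lambda * sum_(i != j) |Theta_ij|`
#' by block coordinate descent over columns with a coordinate-descent lasso
#' inner solver.  The diagonal is not penalized, so the working covariance
#' keeps `W_ii = S_ii`.  Convergence is declared when the largest element
#' change of W in a sweep drops below `tol`; the dual objective
#' `log det W`, which block updates never decrease, is recorded per sweep.
#' Karush-Kuhn-Tucker residuals of the fitted solution are reported.
#'
#' @param S A `corr_matrix` or a plain symmetric correlation/covariance
#'   matrix.
#' @param lambda Penalty, >= 0.
#' @param tol Convergence tolerance on W (default 1e-4).
#' @param max_iter Maximum outer sweeps (default 500).
#' @param warm Optional previous `glasso_fit` on the same S, used as a warm
#'   start (for penalty paths).
#' @return Object of class `glasso_fit`: `lambda`, `theta` (precision),
#'   `sigma` (estimated covariance W), `edge_count`, `iterations`,
#'   `converged`, `dual_trace`, `max_kkt_residual`, `labels`.
#' @examples
#' fit <- glasso_fit(matrix(c(1, .5, .5, 1), 2), lambda = 0)
#' fit$theta  # the 2x2 inverse: 4/3, -2/3
#' @export
glasso_fit <- function(S, lambda, tol = 1e-4, max_iter = 500, warm = NULL) {
  sc <- as_corr_input(S)
  if (lambda < 0) stop_mhonet("`lambda` must be >= 0")
  W0 <- if (!is.null(warm)) warm$sigma else NULL
  B0 <- if (!is.null(warm)) warm$beta else NULL
  res <- .glasso_cd(sc$S, lambda, tol, as.integer(max_iter), tol / 10,
                    1000L, W0, B0)
  theta <- res$theta
  dimnames(theta) <- dimnames(res$w) <- list(sc$labels, sc$labels)
  if (!res$converged) {
    warning("glasso did not converge in ", max_iter, " sweeps",
            call. = FALSE)
  }
  fit <- structure(
    list(lambda = lambda, theta = theta, sigma = res$w, beta = res$beta,
         edge_count = nrow(support_pairs(theta, tol = 0)),
         iterations = res$iterations, converged = res$converged,
         dual_trace = res$dual_trace, labels = sc$labels),
    class = "glasso_fit")
  fit$max_kkt_residual <- glasso_kkt_residual(sc$S, fit)
  fit
}

# Stationarity residuals of the glasso solution: S - W + lambda*Gamma = 0
# with Gamma = sign(Theta_ij) on the active set and |Gamma| <= 1 elsewhere.
glasso_kkt_residual <- function(S, fit) {
  if (inherits(S, "corr_matrix")) S <- S$S
  diffm <- S - fit$sigma
  active <- fit$theta != 0 & upper.tri(S)
  inactive <- fit$theta == 0 & upper.tri(S)
  r_active <- if (any(active)) {
    max(abs(diffm[active] + fit$lambda * sign(fit$theta[active])))
  } else 0
  r_inactive <- if (any(inactive)) {
    max(0, max(abs(diffm[inactive])) - fit$lambda)
  } else 0
  max(r_active, r_inactive)
}

#' @export
print.glasso_fit <- function(x, ...) {
  cat(sprintf(
    "glasso fit: p = %d, lambda = %.4g, %d edge(s), %s in %d sweep(s)\n",
    length(x$labels), x$lambda, x$edge_count,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Extended Bayesian information criterion for a glasso fit
#'
#' The Gaussian profile log-likelihood is
#' `l(Theta) = (n/2) * (log det Theta - tr(S Theta))` and the criterion is
#' `EBIC = -2 l + E log n + 4 E gamma log p`, with `E` the number of
#' off-diagonal nonzero pairs.  `gamma = 0` recovers the classical BIC;
#' larger `gamma` favours sparser graphs.
#'
#' @param fit A converged `glasso_fit`.
#' @param S The correlation input used for the fit.
#' @param n Sample size (taken from `S` when it is a `corr_matrix`).
#' @param gamma EBIC weight in `[0, 1]`, default 0.5.
#' @return List with `loglik`, `edge_count`, `gamma`, `n`, `p`, `score`.
#' @export
ebic_score <- function(fit, S, n = NULL, gamma = 0.5) {
  sc <- as_corr_input(S)
  n <- n %||% sc$n
  if (is.null(n) || is.na(n)) stop_mhonet("sample size `n` is required")
  if (gamma < 0 || gamma > 1) stop_mhonet("`gamma` must be in [0, 1]")
  ev <- eigen(fit$theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop_mhonet("precision matrix is not positive definite")
  p <- length(fit$labels)
  loglik <- n / 2 * (sum(log(ev)) - sum(sc$S * fit$theta))
  e <- fit$edge_count
  list(loglik = loglik, edge_count = e, gamma = gamma, n = n, p = p,
       score = -2 * loglik + e * log(n) + 4 * e * gamma * log(p))
}

#' Logarithmic penalty grid for the graphical lasso
#'
#' Log-spaced from just above `lambda_max` (the largest absolute
#' off-diagonal entry of S, beyond which the estimated graph is empty)
#' down to `ratio * lambda_max`, so the null model is always a candidate.
#'
#' @param S Correlation input.
#' @param n_lambda Grid size, default 100.
#' @param ratio Smallest/largest penalty ratio, default 0.01.
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_grid <- function(S, n_lambda = 100, ratio = 0.01) {
  sc <- as_corr_input(S)
  lmax <- max(abs(sc$S[upper.tri(sc$S)]))
  if (lmax <= 0) lmax <- 1e-4
  # start marginally above lambda_max so the empty (null) model is always
  # among the candidates despite floating-point drift at the boundary
  lmax <- lmax * 1.001
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

#' Select the graphical-lasso penalty by EBIC
#'
#' Fits the glasso at every grid point (warm-starting each fit from the
#' previous, sparser solution) and returns the fit minimizing the EBIC.
#' Ties are broken toward the larger penalty, i.e. the sparser model.
#'
#' @param S Correlation input (a `corr_matrix` carries its own `n`).
#' @param n Sample size if `S` is a plain matrix.
#' @param lambdas Penalty grid; default [lambda_grid()] with 100 points.
#' @param gamma EBIC gamma, default 0.5.
#' @param tol,max_iter Passed to [glasso_fit()].
#' @return List with `fit` (the selected `glasso_fit`), `lambda`, `gamma`,
#'   and `path`, a data frame (`lambda`, `edge_count`, `score`,
#'   `converged`) over the grid.
#' @export
select_lambda_ebic <- function(S, n = NULL, lambdas = NULL, gamma = 0.5,
                               tol = 1e-4, max_iter = 500) {
  sc <- as_corr_input(S)
  n <- n %||% sc$n
  if (is.null(n) || is.na(n)) stop_mhonet("sample size `n` is required")
  lambdas <- lambdas %||% lambda_grid(sc)
  if (length(lambdas) == 0 || any(lambdas < 0)) {
    stop_mhonet("penalty grid must be nonempty and nonnegative")
  }
  lambdas <- sort(lambdas, decreasing = TRUE)
  best <- NULL
  best_score <- Inf
  warm <- NULL
  path <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    fit <- suppressWarnings(
      glasso_fit(sc, lambdas[i], tol = tol, max_iter = max_iter,
                 warm = warm))
    warm <- fit
    score <- if (fit$converged) {
      ebic_score(fit, sc, n = n, gamma = gamma)$score
    } else NA_real_
    path[[i]] <- data.frame(lambda = lambdas[i],
                            edge_count = fit$edge_count,
                            score = score, converged = fit$converged)
    if (fit$converged && score < best_score) {
      best <- fit
      best_score <- score
    }
  }
  if (is.null(best)) stop_mhonet("no penalty produced a converged fit")
  list(fit = best, lambda = best$lambda, gamma = gamma,
       path = do.call(rbind, path))
}

#' Partial correlations from a precision matrix
#'
#' `rho_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)` for `i != j`, zero on
#' the diagonal by convention.  Equals the correlation between the
#' residuals of `i` and `j` after regressing both on all remaining
#' variables.
#'
#' @param fit A `glasso_fit` (or any list with a positive-definite `theta`
#'   and `labels`).
#' @param display_threshold Default absolute display cutoff for edges,
#'   0.1.
#' @return Object of class `pcor_network`: `labels`, `rho`,
#'   `display_threshold`.
#' @export
partial_correlations <- function(fit, display_threshold = 0.1) {
  theta <- fit$theta
  d <- sqrt(diag(theta))
  rho <- -theta / tcrossprod(d)
  diag(rho) <- 0
  rho <- (rho + t(rho)) / 2
  dimnames(rho) <- list(fit$labels, fit$labels)
  structure(list(labels = fit$labels, rho = rho,
                 display_threshold = display_threshold),
            class = "pcor_network")
}

#' Displayed edge list of a partial-correlation network
#'
#' Edges whose absolute partial correlation is below the display threshold
#' are omitted (strictly: `|rho| < threshold` is hidden, `|rho| =
#' threshold` is shown).  The underlying `rho` matrix is untouched.
#'
#' @param network A `pcor_network`.
#' @param threshold Absolute cutoff; defaults to the network's own display
#'   threshold.
#' @return Data frame with columns `from`, `to`, `rho`, `weight` (absolute
#'   value) and `sign` (`"positive"`/`"negative"`).
#' @export
network_edges <- function(network, threshold = network$display_threshold) {
  if (threshold < 0) stop_mhonet("`threshold` must be >= 0")
  idx <- which(upper.tri(network$rho) & abs(network$rho) >= threshold &
                 network$rho != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  rho <- network$rho[idx]
  data.frame(from = network$labels[idx[, 1]],
             to = network$labels[idx[, 2]],
             rho = rho, weight = abs(rho),
             sign = ifelse(rho > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' @export
print.pcor_network <- function(x, ...) {
  cat(sprintf(
    "Partial-correlation network: %d node(s), %d displayed edge(s) at |rho| >= %.2g\n",
    length(x$labels), nrow(network_edges(x)), x$display_threshold))
  invisible(x)
}

#' Restrict a correlation matrix to a Rho band
#'
#' Keeps every variable participating in at least one off-diagonal pair
#' whose absolute marginal correlation falls inside the closed interval
#' `[lo, hi]`, and returns the corresponding sub-matrix for network
#' re-estimation.  The conventional bands are 0.400-0.599, 0.600-0.799 and
#' 0.800-0.999.  An empty selection is returned as a zero-variable
#' `corr_matrix`, not an error.
#'
#' @param S A `corr_matrix`.
#' @param band Numeric `c(lo, hi)` with `0 <= lo < hi <= 1`.
#' @return A `corr_matrix` restricted to the retained variables, with a
#'   `band` attribute.
#' @export
band_filter <- function(S, band) {
  sc <- as_corr_input(S)
  if (length(band) != 2 || band[1] < 0 || band[2] > 1 ||
      band[1] >= band[2]) {
    stop_mhonet("`band` must be c(lo, hi) with 0 <= lo < hi <= 1")
  }
  a <- abs(sc$S)
  diag(a) <- NA
  keep <- apply(a, 1, function(row) {
    any(row >= band[1] & row <= band[2], na.rm = TRUE)
  })
  out <- sc
  out$S <- sc$S[keep, keep, drop = FALSE]
  out$labels <- sc$labels[keep]
  out$p <- sum(keep)
  attr(out, "band") <- band
  out
}
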