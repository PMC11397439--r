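# Independent oracles used across the suite.  Each deliberately takes a
# different algorithmic route than the package implementation it checks.

# ADMM solver for the penalized covariance-selection program
#   max log det Theta - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|
# (diagonal unpenalized).  Generic first-order convex method; independent
# of the coordinate-descent path in the package.
glasso_admm_oracle <- function(S, lambda, rho = 1, max_iter = 20000,
                               tol = 1e-9) {
  p <- nrow(S)
  Z <- diag(1 / diag(S), p)
  U <- matrix(0, p, p)
  for (k in seq_len(max_iter)) {
    A <- rho * (Z - U) - S
    e <- eigen(A, symmetric = TRUE)
    d <- (e$values + sqrt(e$values^2 + 4 * rho)) / (2 * rho)
    theta <- e$vectors %*% (d * t(e$vectors))
    z_old <- Z
    M <- theta + U
    Z <- sign(M) * pmax(abs(M) - lambda / rho, 0)
    diag(Z) <- diag(M)
    U <- U + theta - Z
    if (max(abs(theta - Z)) < tol && rho * max(abs(Z - z_old)) < tol) break
  }
  (Z + t(Z)) / 2
}

# Value of the (maximized) glasso objective at Theta.
glasso_objective <- function(theta, S, lambda) {
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  sum(log(ev)) - sum(S * theta) -
    2 * lambda * sum(abs(theta[upper.tri(theta)]))
}

# Population partial correlation of variables i and j given the rest,
# via conditional covariance of the implied Gaussian (regression route).
partial_cor_regression <- function(theta, i, j) {
  sigma <- solve(theta)
  rest <- setdiff(seq_len(nrow(sigma)), c(i, j))
  if (length(rest) == 0) {
    return(stats::cov2cor(sigma)[i, j])
  }
  cond <- sigma[c(i, j), c(i, j)] -
    sigma[c(i, j), rest, drop = FALSE] %*%
    solve(sigma[rest, rest, drop = FALSE],
          sigma[rest, c(i, j), drop = FALSE])
  cond[1, 2] / sqrt(cond[1, 1] * cond[2, 2])
}

# Exact two-sided Mann-Whitney p by complete enumeration over all
# C(n1+n2, n1) assignments of the pooled values to the first group.
mwu_brute_force <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_of <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  all_u <- combn(length(pooled), n1, u_of)
  p_low <- mean(all_u <= u_obs)
  p_high <- mean(all_u >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Independent restatement of the tie-corrected normal approximation,
# computed from the second sample's rank sum.
mwu_normal_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); nn <- n1 + n2
  r <- rank(c(x, y))
  u2 <- sum(r[(n1 + 1):nn]) - n2 * (n2 + 1) / 2
  u1 <- n1 * n2 - u2
  mu <- n1 * n2 / 2
  tab <- table(c(x, y))
  v <- n1 * n2 / 12 * ((nn + 1) - sum(tab^3 - tab) / (nn * (nn - 1)))
  if (u1 == mu) return(1)
  z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(v)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Step-up BH restated from scratch.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, q_sorted)[order(o)]
}

# Union-find connected components over an edge list.
components_union_find <- function(edges, nodes) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(a) {
    while (parent[[a]] != a) {
      parent[[a]] <<- parent[[parent[[a]]]]
      a <- parent[[a]]
    }
    a
  }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges$from[k]); rb <- find(edges$to[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  unname(split(nodes, roots))
}

# Random correlation matrix from a small Gaussian sample.
random_corr <- function(p, n = 60, seed = 1) {
  set.seed(seed)
  stats::cor(matrix(stats::rnorm(n * p), n, p))
}

# Small anchored marginal table for fast cohort tests.
mini_marginals <- function() {
  a <- cohort_anchors()
  a[a$name %in% c("weight", "height", "triglycerides", "glucose", "hdl",
                  "sbp", "dbp", "insulin", "depression", "anxiety",
                  "stress", "protein", "fiber"), ]
}
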