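test_that("rank correlation is invariant to monotone transforms", {
  set.seed(1)
  x <- rnorm(30)
  tab <- cbind(x = x, y = exp(x), z = -x)
  S <- spearman_matrix(tab)
  expect_equal(S$S["x", "y"], 1)
  expect_equal(S$S["x", "z"], -1)
  expect_equal(diag(S$S), c(x = 1, y = 1, z = 1))
  expect_equal(S$n, 30)
})

test_that("rank correlation equals Pearson on average ranks under ties", {
  x <- c(1, 2, 2, 4)
  y <- c(3, 1, 4, 4)
  S <- spearman_matrix(cbind(x, y))
  expect_equal(S$S[1, 2], stats::cor(rank(x), rank(y)))
})

test_that("constant columns are refused by name", {
  tab <- data.frame(good = rnorm(10), flat = rep(2, 10))
  expect_error(spearman_matrix(tab), "flat")
})

test_that("rank-deficient correlation matrices are repaired to PD", {
  set.seed(5)
  tab <- matrix(rnorm(3 * 5), 3, 5)  # p > n forces a zero eigenvalue
  expect_message(S <- spearman_matrix(tab), "repaired")
  expect_true(S$repaired)
  expect_gte(min(eigen(S$S, symmetric = TRUE, only.values = TRUE)$values),
             1e-9)
  expect_equal(diag(S$S), rep(1, 5))
})

test_that("glasso reduces to the matrix inverse at lambda 0", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  fit <- glasso_fit(S, lambda = 0)
  expect_equal(unname(fit$theta),
               matrix(c(4 / 3, -2 / 3, -2 / 3, 4 / 3), 2),
               tolerance = 1e-6)
  S4 <- random_corr(4, seed = 8)
  expect_equal(unname(glasso_fit(S4, 0)$theta), solve(S4),
               tolerance = 1e-5)
})

test_that("large penalties saturate to a diagonal precision", {
  S <- random_corr(5, seed = 2)
  lam <- max(abs(S[upper.tri(S)]))
  fit <- glasso_fit(S, lam + 0.01)
  expect_equal(fit$edge_count, 0)
  expect_equal(unname(diag(fit$theta)), 1 / diag(S))
  expect_true(all(fit$theta[upper.tri(fit$theta)] == 0))
})

test_that("coordinate descent matches the ADMM oracle on seeded inputs", {
  set.seed(42)
  cases <- expand.grid(p = 3:6, rep = 1:2)
  for (k in seq_len(nrow(cases))) {
    S <- random_corr(cases$p[k], seed = 100 + k)
    for (lam in c(0, 0.05, 0.1, 0.3)) {
      fit <- glasso_fit(S, lam, tol = 1e-6)
      oracle <- glasso_admm_oracle(S, lam)
      gap <- abs(glasso_objective(fit$theta, S, lam) -
                   glasso_objective(oracle, S, lam))
      expect_lt(gap, 1e-4)
      expect_lt(max(abs(fit$theta - oracle)), 1e-3)
      expect_true(fit$converged)
      expect_lt(fit$max_kkt_residual, 1e-4)
    }
  }
})

test_that("KKT conditions and the dual trace hold on every converged fit", {
  for (seed in 1:6) {
    S <- random_corr(sample(3:8, 1), seed = seed)
    lam <- runif(1, 0.02, 0.4)
    fit <- glasso_fit(S, lam)
    expect_true(fit$converged)
    # stationarity, both active and inactive sets
    expect_lt(fit$max_kkt_residual, 1e-3)
    # dual objective log det W never decreases across sweeps
    expect_true(all(diff(fit$dual_trace) > -1e-7))
    # inverse consistency of the returned pair (W, Theta)
    expect_lt(max(abs(fit$sigma %*% fit$theta - diag(nrow(S)))), 1e-3)
    # positive definiteness
    expect_gt(min(eigen(fit$theta, only.values = TRUE)$values), 0)
  }
})

test_that("EBIC reduces to BIC at gamma 0 and to -2 loglik with no edges", {
  S <- random_corr(4, seed = 3)
  fit <- glasso_fit(S, 1)  # saturated: empty graph
  sc <- ebic_score(fit, S, n = 100, gamma = 0.7)
  expect_equal(sc$edge_count, 0)
  expect_equal(sc$score, -2 * sc$loglik)
  fit2 <- glasso_fit(S, 0.05)
  b0 <- ebic_score(fit2, S, n = 100, gamma = 0)
  expect_equal(b0$score, -2 * b0$loglik + b0$edge_count * log(100))
})

test_that("EBIC equals hand arithmetic on a hand-built precision", {
  theta <- diag(3)
  theta[1, 2] <- theta[2, 1] <- -0.3
  S <- solve(theta)
  fit <- list(theta = theta, labels = letters[1:3],
              edge_count = 1L)
  class(fit) <- "glasso_fit"
  sc <- ebic_score(fit, S, n = 100, gamma = 0.5)
  ll <- 100 / 2 * (log(det(theta)) - sum(diag(S %*% theta)))
  expect_equal(sc$loglik, ll)
  expect_equal(sc$score, -2 * ll + log(100) + 4 * 0.5 * log(3))
})

test_that("EBIC penalty selection favours sparsity and honours the grid", {
  S <- random_corr(5, seed = 9)
  one <- select_lambda_ebic(S, n = 60, lambdas = 0.2)
  expect_equal(one$lambda, 0.2)
  # independence: empty graph at every penalty
  sel_id <- select_lambda_ebic(diag(4), n = 100,
                               lambdas = c(0.5, 0.1, 0.01))
  expect_equal(sel_id$fit$edge_count, 0)
  # ties broken toward the larger penalty
  expect_equal(sel_id$lambda, 0.5)
  expect_error(select_lambda_ebic(S, n = 50, lambdas = numeric(0)),
               "nonempty")
})

test_that("partial correlations match the regression-residual oracle", {
  fit0 <- glasso_fit(diag(3), 0.1)
  expect_true(all(partial_correlations(fit0)$rho == 0))
  fit2 <- glasso_fit(matrix(c(1, 0.5, 0.5, 1), 2), 0)
  expect_equal(partial_correlations(fit2)$rho[1, 2], 0.5,
               tolerance = 1e-6)
  for (seed in 1:8) {
    p <- sample(3:6, 1)
    S <- random_corr(p, seed = 200 + seed)
    fit <- glasso_fit(S, runif(1, 0, 0.2), tol = 1e-6)
    rho <- partial_correlations(fit)$rho
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      expect_equal(rho[i, j], partial_cor_regression(fit$theta, i, j),
                   tolerance = 1e-8)
    }
    expect_equal(rho, t(rho))
    expect_true(all(abs(rho) <= 1 + 1e-12))
    expect_true(all(diag(rho) == 0))
  }
})

test_that("the display threshold hides |rho| < 0.1 and keeps 0.1", {
  rho <- diag(3) * 0
  rho[1, 2] <- rho[2, 1] <- 0.09
  rho[1, 3] <- rho[3, 1] <- 0.10
  net <- structure(list(labels = c("a", "b", "c"), rho = rho,
                        display_threshold = 0.1),
                   class = "pcor_network")
  shown <- network_edges(net)
  expect_equal(nrow(shown), 1)
  expect_equal(shown$from, "a")
  expect_equal(shown$to, "c")
  # threshold zero still hides exact zeros; all-zero matrix gives no edges
  net$rho[] <- 0
  expect_equal(nrow(network_edges(net, threshold = 0)), 0)
})

test_that("Rho-band filtering keeps variables by closed-interval pairs", {
  S <- diag(4)
  dimnames(S) <- list(letters[1:4], letters[1:4])
  S[1, 2] <- S[2, 1] <- 0.9
  S[3, 4] <- S[4, 3] <- 0.400
  sc <- structure(list(S = S, labels = letters[1:4], n = 50, p = 4,
                       method = "spearman", repaired = FALSE),
                  class = "corr_matrix")
  high <- band_filter(sc, c(0.8, 0.999))
  expect_equal(high$labels, c("a", "b"))
  low <- band_filter(sc, c(0.400, 0.599))
  expect_equal(low$labels, c("c", "d"))  # boundary 0.400 retained
  none <- band_filter(structure(list(S = diag(3), labels = letters[1:3],
                                     n = 50, p = 3, method = "spearman",
                                     repaired = FALSE),
                                class = "corr_matrix"),
                      c(0.4, 0.6))
  expect_equal(none$p, 0)
  expect_error(band_filter(sc, c(0.6, 0.4)), "band")
})
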