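test_that("identical specs give bit-identical cohorts", {
  spec <- cohort_spec(40, marginals = mini_marginals(), density = 0.1,
                      seed = 77)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$table, b$table)
  expect_identical(a$dass_items, b$dass_items)
  expect_identical(a$ffq_records, b$ffq_records)
  expect_identical(a$true_labels, b$true_labels)
})

test_that("an empty cohort has empty containers", {
  spec <- cohort_spec(0, marginals = mini_marginals(), density = 0.1,
                      seed = 1)
  co <- simulate_cohort(spec)
  expect_equal(nrow(co$table), 0)
  expect_equal(ncol(co$table), nrow(mini_marginals()))
  expect_equal(nrow(co$dass_items), 0)
  expect_equal(nrow(co$ffq_records), 0)
  expect_length(co$true_labels, 0)
})

test_that("lognormal anchoring reproduces the target median at large n", {
  marg <- rbind(
    data.frame(name = "triglycerides", family = "lognormal",
               median = 157.24, sd = 50.72, min = 52, max = 385.44,
               block = "cardiometabolic", group_effect = 0),
    data.frame(name = "other", family = "normal", median = 0, sd = 1,
               min = -10, max = 10, block = "generic", group_effect = 0))
  spec <- cohort_spec(10000, marginals = marg, density = 0, seed = 31)
  co <- simulate_cohort(spec, calibrate = FALSE)
  m <- stats::median(co$table$triglycerides)
  expect_lt(abs(m - 157.24) / 157.24, 0.02)
})

test_that("simulated SDs track the anchors for continuous families", {
  marg <- cohort_anchors()
  marg <- marg[marg$name %in% c("weight", "glucose", "insulin"), ]
  marg$group_effect <- 0
  spec <- cohort_spec(20000, marginals = marg, density = 0, seed = 9)
  co <- simulate_cohort(spec, calibrate = FALSE)
  for (v in marg$name) {
    expect_lt(abs(sd(co$table[[v]]) - marg$sd[marg$name == v]) /
                marg$sd[marg$name == v], 0.15)
  }
})

test_that("the calibrated MUO fraction lands near its target", {
  spec <- cohort_spec(5000, seed = 101)
  co <- simulate_cohort(spec)
  frac <- mean(co$true_labels == "MUO")
  expect_lt(abs(frac - spec$muo_fraction), 0.05)
  # labels are the metabolic classifier's own output (round trip)
  expect_identical(co$true_labels, classify_cohort(co$table)$label_idf)
  expect_true(is.finite(co$mismatch_rate))
})

test_that("copula transforms are monotone: ranks survive the mapping", {
  spec <- cohort_spec(200, marginals = mini_marginals(), density = 0.1,
                      seed = 15)
  co <- simulate_cohort(spec)
  continuous <- c("weight", "glucose", "triglycerides", "protein")
  for (v in continuous) {
    j <- match(v, spec$marginals$name)
    expect_equal(rank(co$table[[v]]), rank(co$latent[, j]))
  }
})

test_that("DASS items reproduce the psychological columns exactly", {
  spec <- cohort_spec(120, marginals = mini_marginals(), density = 0.1,
                      seed = 33)
  co <- simulate_cohort(spec)
  scored <- score_dass(co$dass_items)
  expect_identical(as.integer(scored$depression),
                   as.integer(co$table$depression))
  expect_identical(as.integer(scored$anxiety),
                   as.integer(co$table$anxiety))
  expect_identical(as.integer(scored$stress),
                   as.integer(co$table$stress))
  expect_true(all(co$dass_items %in% 0:3))
})

test_that("FFQ records score back to the intake columns", {
  spec <- cohort_spec(25, marginals = mini_marginals(), density = 0.1,
                      seed = 41)
  co <- simulate_cohort(spec)
  intake <- spec$marginals$name[spec$marginals$block == "intake"]
  for (pid in c(1, 13, 25)) {
    rec <- co$ffq_records[co$ffq_records$participant == pid, ]
    grams <- stats::setNames(
      ffq_to_daily_grams(rec$frequency_unit, rec$times, rec$portion_g),
      rec$food_id)
    tot <- nutrient_totals(grams, co$food_composition)
    expect_equal(unname(tot[intake]), unlist(co$table[pid, intake],
                                             use.names = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("latent covariance converges to the rescaled inverse precision", {
  g <- make_ground_truth_graph(10, 0.15, seed = 55)
  spec <- cohort_spec(50000, marginals = generic_marginals(10), graph = g,
                      group_effect = rep(0, 10), seed = 55)
  co <- simulate_cohort(spec, calibrate = FALSE)
  target <- stats::cov2cor(solve(g$precision))
  emp <- stats::cov(co$latent)
  expect_lt(max(abs(emp - target)), 0.02)
})

test_that("a non-positive-definite precision is refused with a diagnostic", {
  g <- make_ground_truth_graph(4, 0.5, seed = 2)
  g$precision[1, 1] <- -5
  spec <- cohort_spec(50, marginals = generic_marginals(4), graph = g,
                      seed = 1)
  expect_error(simulate_cohort(spec), "positive definite")
})

test_that("cohort specs validate their invariants", {
  expect_error(cohort_spec(-1), "nonnegative")
  expect_error(cohort_spec(10, muo_fraction = 1.2), "strictly in")
  bad <- cohort_anchors()
  bad$sd[1] <- 0
  expect_error(cohort_spec(10, marginals = bad), "positive")
  expect_error(
    cohort_spec(10, marginals = generic_marginals(3),
                graph = make_ground_truth_graph(4, 0.5, 1)),
    "match")
})

test_that("recovery metrics handle the empty and complete extremes", {
  # empty truth: EBIC keeps the empty graph, F1 = 1 by convention
  g0 <- make_ground_truth_graph(5, 0, seed = 3)
  spec0 <- cohort_spec(2000, marginals = generic_marginals(5), graph = g0,
                       group_effect = rep(0, 5), seed = 3)
  r0 <- recovery_experiment(spec0, n_lambda = 40)
  expect_equal(r0$edges_estimated, 0)
  expect_equal(r0$f1, 1)
  # complete strong graph: every edge recovered
  gc <- make_ground_truth_graph(5, 1, seed = 4, value_range = c(0.9, 1))
  specc <- cohort_spec(2000, marginals = generic_marginals(5), graph = gc,
                       group_effect = rep(0, 5), seed = 4)
  rc <- recovery_experiment(specc, n_lambda = 40)
  expect_equal(rc$recall, 1)
})
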