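edges_df <- function(from = character(0), to = character(0),
                     rho = numeric(0)) {
  data.frame(from = from, to = to, rho = rho, weight = abs(rho),
             sign = ifelse(rho > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

test_that("components: no edges means all singletons", {
  cc <- connected_components(edges_df(), letters[1:5])
  expect_length(cc$components, 5)
  expect_equal(cc$singleton_count, 5)
})

test_that("components: a chain groups together, isolates stay apart", {
  e <- edges_df(c("a", "b"), c("b", "c"), c(0.5, -0.4))
  cc <- connected_components(e, c("a", "b", "c", "d"))
  expect_length(cc$components, 2)
  expect_setequal(cc$components[[1]], c("a", "b", "c"))
  expect_equal(cc$components[[2]], "d")
  expect_equal(cc$singleton_count, 1)
})

test_that("components match a union-find oracle on random graphs", {
  set.seed(71)
  nodes <- sprintf("n%02d", 1:20)
  for (rep in 1:5) {
    m <- sample(5:25, 1)
    e <- edges_df(sample(nodes, m, TRUE), sample(nodes, m, TRUE),
                  runif(m, -1, 1))
    e <- e[e$from != e$to, ]
    cc <- connected_components(e, nodes)
    oracle <- components_union_find(e, nodes)
    canon <- function(groups) {
      sort(vapply(groups, function(g) paste(sort(g), collapse = "|"),
                  character(1)))
    }
    expect_equal(canon(cc$components), canon(oracle))
    # forest bound: components >= nodes - edges
    expect_gte(length(cc$components), length(nodes) - nrow(e))
  }
})

test_that("dangling edge endpoints are an error", {
  e <- edges_df("a", "zz", 0.5)
  expect_error(connected_components(e, c("a", "b")), "zz")
})

test_that("layouts are deterministic and centred", {
  e <- edges_df(c("a", "a", "b"), c("b", "c", "c"), c(0.5, 0.3, -0.2))
  l1 <- layout_fruchterman_reingold(e, c("a", "b", "c", "d"), seed = 4)
  l2 <- layout_fruchterman_reingold(e, c("a", "b", "c", "d"), seed = 4)
  expect_identical(l1, l2)
  expect_equal(c(mean(l1$x), mean(l1$y)), c(0, 0), tolerance = 1e-8)
  expect_true(all(is.finite(c(l1$x, l1$y))))
  # single node at the origin
  l0 <- layout_fruchterman_reingold(edges_df(), "solo", seed = 1)
  expect_equal(c(l0$x, l0$y), c(0, 0))
  # two connected nodes symmetric about the centroid
  l2n <- layout_fruchterman_reingold(edges_df("a", "b", 0.8),
                                     c("a", "b"), seed = 2)
  expect_equal(l2n$x[1] + l2n$x[2], 0, tolerance = 1e-8)
  expect_equal(l2n$y[1] + l2n$y[2], 0, tolerance = 1e-8)
  expect_error(layout_fruchterman_reingold(edges_df(), character(0)),
               "nonempty")
})

test_that("a heavy edge pulls its endpoints closest in a K4", {
  nodes <- c("a", "b", "c", "d")
  pairs <- t(combn(nodes, 2))
  rho <- ifelse(pairs[, 1] == "a" & pairs[, 2] == "b", 0.9, 0.2)
  e <- edges_df(pairs[, 1], pairs[, 2], rho)
  l <- layout_fruchterman_reingold(e, nodes, seed = 0, iterations = 500)
  d <- as.matrix(dist(cbind(l$x, l$y)))
  rownames(d) <- colnames(d) <- l$node
  off <- d[upper.tri(d)]
  expect_equal(d["a", "b"], min(off))
})

test_that("rendering draws only displayed edges with sign colours", {
  rho <- matrix(0, 3, 3)
  rho[1, 2] <- rho[2, 1] <- 0.5    # shown, green
  rho[1, 3] <- rho[3, 1] <- -0.45  # shown, red
  rho[2, 3] <- rho[3, 2] <- 0.05   # below threshold, hidden
  net <- structure(list(labels = c("a", "b", "c"), rho = rho,
                        display_threshold = 0.1),
                   class = "pcor_network")
  lay <- layout_fruchterman_reingold(network_edges(net), net$labels,
                                     seed = 0)
  path <- file.path(withr::local_tempdir(), "net.svg")
  render_network(net, lay, path)
  expect_true(file.exists(path))
  # the svg device encodes colours as rgb percentages:
  # forestgreen (34,139,34) and firebrick (178,34,34)
  svg <- paste(readLines(path), collapse = "\n")
  strokes <- regmatches(svg, gregexpr("stroke=\"rgb\\([^)]*\\)\"", svg))[[1]]
  n_green <- sum(grepl("13\\.3[0-9]*%, 54\\.5", strokes))
  n_red <- sum(grepl("69\\.8[0-9]*%, 13\\.3", strokes))
  expect_equal(n_green, 1)  # exactly one positive edge drawn
  expect_equal(n_red, 1)    # exactly one negative edge drawn
})

test_that("rendering an empty edge list still draws the nodes", {
  net <- structure(list(labels = c("a", "b"), rho = matrix(0, 2, 2),
                        display_threshold = 0.1),
                   class = "pcor_network")
  lay <- layout_fruchterman_reingold(edges_df(), net$labels, seed = 0)
  path <- file.path(withr::local_tempdir(), "empty.png")
  render_network(net, lay, path)
  expect_true(file.size(path) > 0)
  expect_error(render_network(net, lay, "x.gif"), "format")
  expect_error(render_network(net, lay[1, ], "x.png"), "cover")
})
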