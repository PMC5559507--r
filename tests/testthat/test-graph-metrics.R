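test_that("hand-derived fixtures reproduce the definitional values", {
  tri <- triangle_half()
  cc <- clustering_coefficient(tri)
  expect_equal(unname(cc$ci), rep(0.5, 3))
  expect_equal(cc$cw, 0.5)
  expect_equal(clustering_coefficient(tiny_graph(list(c(1, 2, 1), c(1, 3, 1),
                                                      c(2, 3, 1)), 3))$cw, 1)
  dyad <- tiny_graph(list(c(1, 2, 0.5)), 2)
  pl <- path_length(dyad)
  expect_equal(unname(pl$L["a", "b"]), 2)
  expect_equal(pl$lw, 2)
  star <- unit_star()
  expect_equal(unname(node_degree(star)), c(1, 1 / 3, 1 / 3, 1 / 3))
  expect_equal(degree_diversity(star), 2.0)
  expect_lt(degree_correlation(star), 0)
  expect_equal(clustering_coefficient(star)$cw, 0)
  path3 <- tiny_graph(list(c(1, 2, 1), c(2, 3, 1)), 3)
  rd <- radius_diameter(path3)
  expect_equal(unname(rd), c(1, 2))
  expect_equal(unname(path_length(path3)$L["a", "c"]), 2)
})

test_that("complete equal-weight graphs are fully regular", {
  K <- matrix(0.5, 4, 4); diag(K) <- 0
  expect_equal(unname(node_degree(K)), rep(0.5, 4))
  rd <- radius_diameter(K)
  expect_equal(unname(rd), c(2, 2))
  expect_true(is.nan(degree_correlation(K)))  # zero degree variance
  gl <- surrogate_normalize(K, 10, seed = 1)
  expect_identical(unname(gl[c("gamma", "lambda")]), c(1, 1))
})

test_that("disconnection propagates as infinities", {
  d0 <- matrix(0, 2, 2)
  expect_equal(path_length(d0)$lw, Inf)
  expect_equal(unname(radius_diameter(d0)), c(Inf, Inf))
  expect_error(degree_diversity(d0), "zero matrix")
  expect_equal(unname(node_degree(d0)), c(0, 0))
})

test_that("two unequal dyads are assortative", {
  W <- tiny_graph(list(c(1, 2, 0.9), c(3, 4, 0.2)), 4)
  expect_gt(degree_correlation(W), 0)
})

test_that("Kw is homogeneous of degree one in the weights", {
  set.seed(8)
  W <- as_sym <- matrix(0, 6, 6)
  W[upper.tri(W)] <- runif(15)
  W <- W + t(W)
  expect_equal(degree_diversity(3 * W), 3 * degree_diversity(W),
               tolerance = 1e-12)
})

test_that("surrogate normalisation is seed-deterministic", {
  set.seed(12)
  W <- matrix(0, 8, 8)
  W[upper.tri(W)] <- runif(28)
  W <- W + t(W)
  a <- surrogate_normalize(W, 25, seed = 3)
  b <- surrogate_normalize(W, 25, seed = 3)
  expect_identical(a, b)
  c <- surrogate_normalize(W, 25, seed = 4)
  expect_false(identical(unname(a), unname(c)))
})

test_that("modular weight structure yields Gamma above 1", {
  hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    n <- 22
    block <- rep(1:2, each = 11)
    W <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      w <- if (block[i] == block[j]) runif(1, 0.5, 0.9) else
        runif(1, 0.05, 0.15)
      W[i, j] <- W[j, i] <- w
    }
    unname(surrogate_normalize(W, 20, seed = s)["gamma"]) > 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("scalar measures are invariant to node relabelling", {
  set.seed(9)
  W <- matrix(0, 7, 7)
  W[upper.tri(W)] <- sample(c(0, 0.25, 0.5, 1), 21, replace = TRUE)
  W <- W + t(W)
  perm <- sample(7)
  Wp <- W[perm, perm]
  for (f in list(function(x) clustering_coefficient(x)$cw,
                 function(x) path_length(x)$lw,
                 degree_diversity,
                 function(x) unname(radius_diameter(x)))) {
    expect_equal(f(W), f(Wp), tolerance = 1e-12)
  }
  expect_equal(sort(node_degree(W)), sort(unname(node_degree(Wp))),
               tolerance = 1e-12)
})

test_that("all measures agree with the brute-force oracle on 3-node graphs", {
  v <- validate_graph_metrics(3, n_surrogates = 10, seed = 2)
  expect_equal(v$n_graphs, 64)
  expect_lt(max(v$max_abs_diff), 1e-10)
})

test_that("graph_metrics returns the full eight-measure row", {
  W <- triangle_half()
  W <- rbind(cbind(W, 0), 0)  # pad to 4 nodes for surrogates
  W[4, 1] <- W[1, 4] <- 0.25
  rownames(W) <- colnames(W) <- letters[1:4]
  gm <- graph_metrics(W, n_surrogates = 10, seed = 1)
  expect_named(gm, c("degree", "cw", "gamma", "lw", "lambda", "rw", "kw",
                     "radius", "diameter", "n_surrogates"))
  expect_true(all(is.finite(unlist(gm[c("degree", "cw", "lw", "kw")]))))
})
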