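test_that("contiguity weights are symmetric, row-standardized and island-aware", {
  L <- small_lattice(cell_size = 0.15)
  w <- L$w
  # interior cell: 6 neighbors with weight 1/6 each
  k <- lengths(w$neighbors)
  i6 <- which(k == 6L)[1]
  expect_equal(w$weights[[i6]], rep(1 / 6, 6))
  # every non-island row sums to 1
  expect_true(all(abs(vapply(w$weights[k > 0], sum, numeric(1)) - 1) < 1e-12))
  # symmetry of the underlying adjacency
  for (i in seq_along(w$neighbors)) {
    for (j in w$neighbors[[i]]) expect_true(i %in% w$neighbors[[j]])
  }
})

test_that("global Moran's I matches the double-loop oracle and ape::Moran.I", {
  set.seed(7)
  for (rep in 1:3) {
    L <- small_lattice(cell_size = c(0.3, 0.25, 0.22)[rep])
    n <- length(L$w$ids)
    expect_lte(n, 20)
    x <- rnorm(n)
    got <- global_morans_i(x, L$w, n_perm = 0)
    expect_equal(got$I, oracle_global_moran(x, weights_matrix(L$w)),
                 tolerance = 1e-12)
    expect_equal(got$expected, -1 / (n - 1))
    # independent cross-check against ape's implementation
    if (requireNamespace("ape", quietly = TRUE)) {
      ref <- ape::Moran.I(x, weights_matrix(L$w))
      expect_equal(got$I, ref$observed, tolerance = 1e-9)
    }
  }
})

test_that("E[I] closed form and the sign of perfect alternation", {
  # expected value: -1/(n-1)
  L <- small_lattice(cell_size = 0.22)
  x <- rnorm(length(L$w$ids))
  expect_equal(global_morans_i(x, L$w, n_perm = 0)$expected,
               -1 / (length(L$w$ids) - 1))
  # two-color alternation on a path graph: strong negative autocorrelation
  path_w <- structure(list(
    ids = 1:6,
    neighbors = list(2L, c(1L, 3L), c(2L, 4L), c(3L, 5L), c(4L, 6L), 5L),
    weights = list(1, c(.5, .5), c(.5, .5), c(.5, .5), c(.5, .5), 1),
    style = "W", islands = integer(0)), class = "spatial_weights")
  expect_lt(global_morans_i(rep(c(1, -1), 3), path_w, n_perm = 0)$I, 0)
})

test_that("constant values are rejected with a zero-variance error", {
  L <- small_lattice(cell_size = 0.3)
  x <- rep(2, length(L$w$ids))
  expect_error(global_morans_i(x, L$w), "zero variance")
  expect_error(local_morans_i(x, L$w), "zero variance")
  expect_error(getis_ord_gistar(x, L$w), "zero variance")
})

test_that("local Moran matches the oracle and satisfies the global identity", {
  set.seed(21)
  for (rep in 1:3) {
    L <- small_lattice(cell_size = 0.22)
    n <- length(L$w$ids)
    x <- rnorm(n)
    li <- local_morans_i(x, L$w, n_perm = 0)
    expect_equal(li$Ii, oracle_local_moran(x, weights_matrix(L$w)),
                 tolerance = 1e-12)
    # sum_i I_i = S0 * I (= n * I on island-free lattices)
    s0 <- sum(unlist(L$w$weights))
    expect_equal(sum(li$Ii), s0 * attr(li, "global_I"), tolerance = 1e-9)
    # quadrant codes agree with the signs of (z, lag)
    expect_identical(li$quadrant,
                     paste0(ifelse(li$z > 0, "H", "L"),
                            ifelse(li$lag > 0, "H", "L")))
  }
})

test_that("a lone spike is HL and its neighbors lean LH", {
  L <- small_lattice(cell_size = 0.15)
  w <- L$w
  k <- lengths(w$neighbors)
  center <- which(k == 6L)[3]
  x <- rep(0, length(w$ids)) + rnorm(length(w$ids), 0, 1e-6)
  x[center] <- 10
  li <- local_morans_i(x, w, n_perm = 0)
  expect_identical(li$quadrant[center], "HL")
  expect_true(all(li$quadrant[w$neighbors[[center]]] == "LH"))
})

test_that("permutation p-values are reproducible and flag planted structure", {
  L <- small_lattice(cell_size = 0.15)
  n <- length(L$w$ids)
  set.seed(3)
  x <- rnorm(n)
  g1 <- global_morans_i(x, L$w, n_perm = 199, seed = 9)
  g2 <- global_morans_i(x, L$w, n_perm = 199, seed = 9)
  expect_identical(g1$p_value, g2$p_value)
  l1 <- local_morans_i(x, L$w, n_perm = 99, seed = 9)
  l2 <- local_morans_i(x, L$w, n_perm = 99, seed = 9)
  expect_identical(l1$p_value, l2$p_value)
  expect_true(all(l1$p_value > 0 & l1$p_value <= 1, na.rm = TRUE))
})

test_that("Gi* matches the hand-coded double-loop oracle", {
  set.seed(5)
  for (cs in c(0.3, 0.25, 0.22)) {
    L <- small_lattice(cell_size = cs)
    x <- rnorm(length(L$w$ids))
    Wbin <- weights_matrix(contiguity_weights(L$grid, style = "B"))
    expect_equal(getis_ord_gistar(x, L$w)$gistar, oracle_gistar(x, Wbin),
                 tolerance = 1e-9)
  }
})

test_that("Gi* flags a planted cluster of maxima hot and is antisymmetric", {
  L <- small_lattice(cell_size = 0.1)  # ~60 cells: cluster is a small patch
  w <- L$w
  n <- length(w$ids)
  set.seed(5)
  x <- rnorm(n, 10, 0.1)
  # plant a cluster of maxima on an interior cell and its neighbors
  center <- which(lengths(w$neighbors) == 6L)[4]
  clust <- c(center, w$neighbors[[center]])
  x[clust] <- 20
  gs <- getis_ord_gistar(x, w)
  expect_true(all(gs$category[clust] == "hot"))
  # negating the input swaps hot and cold
  neg <- getis_ord_gistar(-x, w)
  expect_equal(neg$gistar, -gs$gistar, tolerance = 1e-12)
  expect_identical(neg$category[gs$category == "hot"],
                   rep("cold", sum(gs$category == "hot")))
  # classification is monotone in the z-score
  ord <- order(gs$gistar)
  cat_ord <- gs$category[ord]
  expect_true(all(diff(match(cat_ord, c("cold", "not_significant", "hot"))) >= 0))
})
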