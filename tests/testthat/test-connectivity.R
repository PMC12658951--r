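test_that("dispersal kernel matches its closed form with a hard cutoff", {
  expect_equal(dispersal_kernel(0, 0.3, 1000, s = 1), 1.0)
  expect_equal(dispersal_kernel(1500, 0.3, 1000), 0)           # beyond d_max
  expect_equal(dispersal_kernel(1000, 0.3, 1000, s = 0.5),
               0.5 * exp(-1 / 0.3), tolerance = 1e-12)
  expect_equal(dispersal_kernel(1000, 0.3, 1000, s = 0.5), 0.017837,
               tolerance = 1e-5)
  # vectorized, kernel value at d slightly above/below the cutoff
  d <- c(999.999, 1000, 1000.001)
  k <- dispersal_kernel(d, 0.3, 1000)
  expect_true(k[1] > 0 && k[2] > 0 && k[3] == 0)
  expect_error(dispersal_kernel(-1, 0.3, 1000), "nonnegative")
})

two_cell_matrix <- function(q1 = 1, q2 = 1, d_max = 1000) {
  sp <- strip_species(5, c(0L, 1L), d_max = d_max, quality = c(q1, q2))
  dt <- least_cost_distances(build_traversal_graph(sp$habitat$grid),
                             habitat_cells(sp$habitat), cutoff = d_max)
  build_connectivity_matrix(sp, dt)
}

test_that("connectivity matrices scale rows by donor quality, zero diagonal", {
  K <- two_cell_matrix()
  expect_equal(as.matrix(K$K),
               matrix(c(0, exp(-250 / 300), exp(-250 / 300), 0), 2, 2))
  expect_equal(K$K[1, 2], 0.43460, tolerance = 1e-5)

  Ka <- two_cell_matrix(q1 = 0.5, q2 = 1)
  expect_equal(Ka$K[1, 2], 0.21730, tolerance = 1e-5)
  expect_equal(Ka$K[2, 1], 0.43460, tolerance = 1e-5)
  # row scaling is exact: K_varied = diag(s) %*% K_uniform
  expect_identical(as.matrix(Ka$K), diag(c(0.5, 1)) %*% as.matrix(K$K))

  # a single habitat cell has no pairs
  sp1 <- strip_species(3, 0L, d_max = 1000)
  dt1 <- least_cost_distances(build_traversal_graph(sp1$habitat$grid),
                              habitat_cells(sp1$habitat), cutoff = 1000)
  K1 <- build_connectivity_matrix(sp1, dt1)
  expect_equal(dim(K1$K), c(1L, 1L))
  expect_equal(Matrix::nnzero(K1$K), 0)

  # cutoff mismatch is a hard error
  sp <- strip_species(5, c(0L, 1L), d_max = 900)
  expect_error(build_connectivity_matrix(
    sp, least_cost_distances(build_traversal_graph(sp$habitat$grid),
                             habitat_cells(sp$habitat), cutoff = 1000)),
    "cutoff")
})

test_that("generational matrices are true matrix powers", {
  K <- two_cell_matrix(d_max = 2000)
  a <- as.numeric(K$K[1, 2])
  K3 <- generational_matrix(K, 3)
  expect_equal(as.matrix(K3$K), matrix(c(0, a^3, a^3, 0), 2, 2),
               tolerance = 1e-15)
  expect_identical(as.matrix(generational_matrix(K, 1)$K), as.matrix(K$K))
  expect_error(generational_matrix(K, 0), ">= 1")
  expect_error(generational_matrix(K3, 2), "g = 1")

  # hand-checked antidiagonal example
  sp <- strip_species(5, c(0L, 1L), d_max = 10000)
  Kh <- two_cell_matrix(d_max = 10000)
  Kh$K[1, 2] <- 0.5; Kh$K[2, 1] <- 0.5
  expect_equal(as.matrix(generational_matrix(Kh, 3)$K),
               matrix(c(0, 0.125, 0.125, 0), 2, 2))

  # sparse power equals a naive dense triple product on random matrices
  set.seed(77)
  for (rep in 1:5) {
    n <- 10
    M <- matrix(stats::runif(n * n) * (stats::runif(n * n) < 0.4), n, n)
    diag(M) <- 0
    K10 <- seaconn:::new_connectivity_matrix(
      methods::as(Matrix::Matrix(M, sparse = TRUE), "generalMatrix"),
      seq_len(n) - 1L, "r", 1L, FALSE)
    dense <- M %*% M %*% M
    expect_equal(as.matrix(generational_matrix(K10, 3)$K), dense,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("exports and imports are row and column sums on the grid", {
  K <- two_cell_matrix()
  grid <- seascape_grid(1, 5, 250)
  ex <- exports(K, grid)
  expect_equal(layer_values_at(ex, c(0L, 1L)), rep(0.43460, 2),
               tolerance = 1e-5)
  expect_true(all(ex$values[, 3:5] == 0))
  expect_equal(unname(imports(K)), rep(0.43460, 2), tolerance = 1e-5)

  Ka <- two_cell_matrix(q1 = 0.5, q2 = 1)
  expect_equal(unname(imports(Ka)), c(0.43460, 0.21730), tolerance = 1e-5)
  exa <- layer_values_at(exports(Ka, grid), c(0L, 1L))
  expect_equal(exa, c(0.21730, 0.43460), tolerance = 1e-5)

  # exports and imports both total the matrix grand sum
  expect_equal(sum(exa), sum(imports(Ka)))
})

test_that("uniform quality gives symmetric K and K^g; exports equal imports", {
  set.seed(99)
  f <- random_field(15, 15, p_land = 0.2, disturb = FALSE)
  grid <- seascape_grid(15, 15, 250, water = f$water)
  q <- matrix(0, 15, 15)
  wc <- which(f$water)
  q[sample(wc, 40)] <- 1
  sp <- species_profile("u", habitat_layer(grid, q), d_max = 2000)
  dt <- least_cost_distances(build_traversal_graph(grid),
                             habitat_cells(sp$habitat), cutoff = 2000)
  K <- build_connectivity_matrix(sp, dt)
  expect_equal(as.matrix(K$K), t(as.matrix(K$K)))
  K3 <- generational_matrix(K, 3)
  expect_equal(as.matrix(K3$K), t(as.matrix(K3$K)), tolerance = 1e-12)
  expect_equal(unname(layer_values_at(exports(K3, grid), K3$cells)),
               unname(imports(K3)), tolerance = 1e-12)
})

test_that("stepping stones link cells beyond d_max over multiple generations", {
  # A (0) - B (4) - C (8): neighbours 1000 m apart, ends 2000 m apart.
  # With a zero diagonal, K^g holds paths of exactly g dispersal events, so
  # the two-step link A-B-C appears at g = 2 (and at g = 3 on a longer chain).
  sp <- strip_species(9, c(0L, 4L, 8L), d_max = 1200)
  dt <- least_cost_distances(build_traversal_graph(sp$habitat$grid),
                             habitat_cells(sp$habitat), cutoff = 1200)
  K <- build_connectivity_matrix(sp, dt)
  expect_equal(K$K[1, 3], 0) # out of direct reach
  expect_gt(generational_matrix(K, 2)$K[1, 3], 0) # via the stepping stone

  # A - B - C - D chain: the far ends connect at exactly three generations
  sp4 <- strip_species(13, c(0L, 4L, 8L, 12L), d_max = 1200)
  dt4 <- least_cost_distances(build_traversal_graph(sp4$habitat$grid),
                              habitat_cells(sp4$habitat), cutoff = 1200)
  K4 <- build_connectivity_matrix(sp4, dt4)
  expect_equal(K4$K[1, 4], 0)
  expect_equal(generational_matrix(K4, 2)$K[1, 4], 0)
  expect_gt(generational_matrix(K4, 3)$K[1, 4], 0)
})

test_that("kernel entries never increase when a distance grows", {
  sp <- strip_species(9, c(0L, 2L, 5L), d_max = 1500)
  dt <- least_cost_distances(build_traversal_graph(sp$habitat$grid),
                             habitat_cells(sp$habitat), cutoff = 1500)
  K <- build_connectivity_matrix(sp, dt)
  dt2 <- dt
  dt2$dist[1, 2] <- dt2$dist[1, 2] + 100
  dt2$dist[2, 1] <- dt2$dist[2, 1] + 100
  K2 <- build_connectivity_matrix(sp, dt2)
  expect_true(all(as.matrix(generational_matrix(K2, 3)$K) <=
                  as.matrix(generational_matrix(K, 3)$K) + 1e-15))
})
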