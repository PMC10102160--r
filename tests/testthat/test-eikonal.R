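test_that("local updates match closed forms and the bisection oracle", {
  expect_equal(local_update(c(1, 3), c(1, 1), 1, Inf), 2)
  expect_equal(local_update(c(0, 0), c(1, 1), 1, 2), 1 / sqrt(2))
  expect_equal(local_update(c(0, 10), c(1, 1), 1, 2), 1)  # far neighbor inactive
  for (p in c(1, 2, 3.5, Inf))
    expect_equal(local_update(0, 1, 1, p), 1)
  expect_error(local_update(numeric(), numeric(), 1), "empty")
  expect_error(local_update(0, -1, 1), "positive")
  expect_error(local_update(0, 1, 0), "positive")
  set.seed(31)
  for (trial in 1:40) {
    m <- sample(1:6, 1)
    a <- rnorm(m)
    w <- runif(m, 0.2, 3)
    C <- runif(1, 0.1, 2)
    for (p in c(1, 2, 4, Inf)) {
      got <- local_update(a, 1 / sqrt(w), C, p)
      want <- oracle_local_solve(a, w, C, p)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("arrival values equal hop distance for unit weights and h = 1", {
  g <- weighted_graph(4, cbind(i = 1:3, j = 2:4, w = 1))
  expect_identical(solve_eikonal(eikonal_spec(g, 1, p = Inf)),
                   c(0, 1, 2, 3))
  set.seed(32)
  for (trial in 1:8) {
    n <- sample(10:40, 1)
    g <- random_connected_graph(n, unit = TRUE)
    seeds <- sample(n, sample(1:3, 1))
    u <- solve_eikonal(eikonal_spec(g, seeds, p = Inf))
    expect_equal(u, oracle_hop_distance(g, seeds))
  }
})

test_that("the label-setting solver agrees with exhaustive relaxation", {
  set.seed(33)
  for (trial in 1:6) {
    n <- sample(10:50, 1)
    g <- random_connected_graph(n)
    seeds <- sample(n, sample(1:3, 1))
    hv <- runif(n, 0.5, 2)
    for (p in c(1, 2, Inf)) {
      got <- solve_eikonal(eikonal_spec(g, seeds, h = hv, p = p))
      want <- oracle_eikonal_relax(g, seeds, hv, p)
      expect_lt(max(abs(got - want)), 1e-9)
    }
  }
})

test_that("p = 2 grid arrivals match an independent fast-marching pass", {
  H <- 9; W <- 11
  g <- build_grid_graph(matrix(0, H, W), 4, similarity_config("constant"))
  seed_rc <- c(5, 6)
  spec <- eikonal_spec(g, grid_graph_vid(seed_rc[1], seed_rc[2], W), p = 2)
  u <- solve_eikonal(spec)
  want <- oracle_fmm_grid(H, W, seed_rc)
  # grid oracle is column-major (r, c); package order is row-major vertices
  want_v <- as.numeric(t(want))
  expect_lt(max(abs(u - want_v)), 1e-9)
})

test_that("arrival maps scale linearly with the potential", {
  set.seed(34)
  g <- random_connected_graph(20)
  u1 <- solve_eikonal(eikonal_spec(g, 3, h = 1, p = 2))
  u3 <- solve_eikonal(eikonal_spec(g, 3, h = 3, p = 2))
  expect_equal(u3, 3 * u1, tolerance = 1e-10)
  # seeds may carry nonzero initial values
  uoff <- solve_eikonal(eikonal_spec(g, 3, values = 2, h = 1, p = Inf))
  u0 <- solve_eikonal(eikonal_spec(g, 3, h = 1, p = Inf))
  expect_equal(uoff, u0 + 2, tolerance = 1e-10)
  # unreachable vertices report +Inf
  giso <- weighted_graph(3, cbind(1, 2, 1))
  expect_equal(solve_eikonal(eikonal_spec(giso, 1, p = Inf))[3], Inf)
})

test_that("label fronts partition the graph with the documented tie rule", {
  g5 <- weighted_graph(5, cbind(i = 1:4, j = 2:5, w = 1))
  res <- propagate_labels(g5, list(1, 5), h = 1, p = Inf)
  # vertex 3 is equidistant; the smaller label index wins
  expect_identical(res$labels, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(res$arrival, c(0, 1, 2, 1, 0))
  # single label covers everything; disjoint components stay separate
  expect_true(all(propagate_labels(g5, list(2))$labels == 1L))
  g2c <- weighted_graph(4, cbind(i = c(1, 3), j = c(2, 4), w = 1))
  r2 <- propagate_labels(g2c, list(1, 3))
  expect_identical(r2$labels, c(1L, 1L, 2L, 2L))
  expect_error(propagate_labels(g5, list(c(1, 2), c(2, 5))), "disjoint")
  # every region contains its seeds
  set.seed(35)
  g <- random_connected_graph(30)
  seeds <- list(c(1, 2), 15, 30)
  r <- propagate_labels(g, seeds, h = 1, p = Inf)
  for (li in seq_along(seeds))
    expect_true(all(r$labels[seeds[[li]]] == li))
  expect_false(anyNA(r$labels))
})

test_that("label maps are invariant to vertex relabeling up to the tie rule", {
  set.seed(36)
  n <- 20
  g <- random_connected_graph(n)
  seeds <- list(2, 17)
  hv <- runif(n, 0.5, 2)
  r1 <- propagate_labels(g, seeds, h = hv, p = Inf)
  perm <- sample(n)
  inv <- order(perm)
  ed <- g$edges
  gp <- weighted_graph(n, cbind(i = perm[ed$i], j = perm[ed$j], w = ed$w))
  r2 <- propagate_labels(gp, lapply(seeds, function(s) perm[s]),
                         h = hv[inv], p = Inf)
  expect_equal(r2$arrival[perm], r1$arrival)
  # no exact ties in this weighted instance, so labels transport exactly
  expect_identical(r2$labels[perm], r1$labels)
})

test_that("superpixels cover the image with one seed per region", {
  img <- matrix(0.5, 12, 12)
  sp <- superpixels(img, 6)
  expect_equal(sort(unique(as.integer(sp$regions))), 1:length(sp$seeds))
  expect_false(anyNA(sp$regions))
  # each region contains its own seed
  lab_v <- as.integer(t(sp$regions))
  expect_identical(lab_v[sp$seeds], seq_along(sp$seeds))
  # constant image, spacing dividing both sides: equal region sizes
  expect_true(all(table(sp$regions) == 36))
  # a strong vertical edge is not straddled
  two <- matrix(0.1, 12, 12); two[, 7:12] <- 0.9
  sp2 <- superpixels(two, 6, similarity_config("exponential", sigma = 0.1))
  left <- as.integer(sp2$regions[, 1:6]); right <- as.integer(sp2$regions[, 7:12])
  expect_length(intersect(unique(left), unique(right)), 0)
  # degenerate spacing
  expect_error(superpixels(img, 1), "spacing")
  expect_error(superpixels(img, 30), "larger")
})

test_that("semi-supervised classification recovers well-separated classes", {
  set.seed(37)
  fx <- generate_blob_features(fixture_config("blob_features", seed = 37,
                                              dim = 200, classes = 2,
                                              separation = 30))
  res <- classify_semi_supervised(fx$features, fx$labels, 0.1, k = 5, p = 1)
  expect_equal(res$accuracy, 1)
  # all samples seeded: trivially perfect and nothing to evaluate
  res_all <- classify_semi_supervised(fx$features, fx$labels,
                                      seeds = seq_len(200), k = 5, p = 1)
  expect_true(all(res_all$predicted == fx$labels))
  expect_error(classify_semi_supervised(fx$features, fx$labels,
                                        seeds = which(fx$labels == 1),
                                        k = 5),
               "seed")
})
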