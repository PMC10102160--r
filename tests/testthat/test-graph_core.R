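test_that("similarity maps match their closed forms and are monotone", {
  cfgc <- similarity_config("constant")
  cfge <- similarity_config("exponential", sigma = 1)
  cfgi <- similarity_config("inverse")
  expect_equal(similarity_weight(c(0, 1, 57), cfgc), c(1, 1, 1))
  expect_equal(similarity_weight(0, cfge), 1)
  expect_equal(similarity_weight(0, cfgi), 1)
  s <- 1.7
  expect_equal(similarity_weight(s^2, similarity_config("exponential",
                                                        sigma = s)),
               exp(-1))
  expect_error(similarity_weight(-1, cfgc), "nonnegative")
  d <- sort(runif(50, 0, 5))
  expect_true(all(diff(similarity_weight(d, cfge)) <= 0))
  expect_true(all(diff(similarity_weight(d, cfgi)) <= 0))
  expect_true(all(similarity_weight(d, cfge) > 0 &
                  similarity_weight(d, cfge) <= 1))
})

test_that("grid graphs enumerate lattice edges for 4- and 8-adjacency", {
  cfg <- similarity_config("constant")
  g22 <- build_grid_graph(matrix(0.3, 2, 2), 4, cfg)
  expect_equal(g22$n, 4L)
  expect_equal(nrow(g22$edges), 4L)
  expect_true(all(g22$edges$w == 1))
  expect_equal(nrow(build_grid_graph(matrix(0, 3, 3), 4, cfg)$edges), 12L)
  expect_equal(nrow(build_grid_graph(matrix(0, 2, 2), 8, cfg)$edges), 6L)
  expect_error(build_grid_graph(array(0, c(0, 3, 1)), 4, cfg))
})

test_that("patch extraction replicates borders and orders windows row-major", {
  ramp <- matrix(1:9 / 9, 3, 3, byrow = TRUE)   # row-major values 1..9
  P <- extract_patches(ramp, 3)
  # center pixel (2,2) = vertex 5: the whole image in row-major order
  expect_equal(P[5, ], as.numeric(1:9 / 9))
  expect_equal(ncol(P), 9L)
  expect_error(extract_patches(ramp, 2), "odd")
  # n = 1 returns the pixel values themselves
  expect_equal(drop(extract_patches(ramp, 1)), as.numeric(t(ramp)))
  # constant image: all patches identical
  Pc <- extract_patches(matrix(0.4, 4, 5), 3)
  expect_equal(max(dist(Pc)), 0)
  # corner replicate padding: top-left patch of the ramp
  expect_equal(P[1, ], c(1, 1, 2, 1, 1, 2, 4, 4, 5) / 9)
})

test_that("k-NN and epsilon graphs agree with brute-force enumeration", {
  cfg <- similarity_config("constant")
  gk <- build_knn_graph(matrix(c(0, 1, 10)), 1, cfg)
  expect_equal(as.matrix(gk$edges[, 1:2]),
               matrix(c(1L, 2L, 2L, 3L), 2), ignore_attr = TRUE)
  ge <- build_epsilon_graph(matrix(c(0, 1, 3)), 1, cfg)
  expect_equal(nrow(ge$edges), 1L)
  expect_equal(c(ge$edges$i, ge$edges$j), c(1L, 2L))
  # complete graph cases
  X <- matrix(rnorm(12), 6)
  expect_equal(nrow(build_knn_graph(X, 5, cfg)$edges), 15L)
  expect_equal(nrow(build_epsilon_graph(X, 1e3, cfg)$edges), 15L)
  # tiny epsilon: empty edge set
  expect_equal(nrow(build_epsilon_graph(matrix(c(0, 5, 9)), 0.1,
                                        cfg)$edges), 0L)
  # duplicate points, k = 1: single edge with weight similarity_weight(0)
  gd <- build_knn_graph(matrix(c(0, 0)), 1,
                        similarity_config("exponential", sigma = 2))
  expect_equal(nrow(gd$edges), 1L)
  expect_equal(gd$edges$w, 1)
  # randomized brute-force oracle
  set.seed(42)
  for (trial in 1:5) {
    X <- matrix(rnorm(2 * 60), 60)
    D <- as.matrix(dist(X))
    eps <- quantile(D[upper.tri(D)], 0.2)
    ge <- build_epsilon_graph(X, eps, cfg)
    want <- which(upper.tri(D) & D <= eps, arr.ind = TRUE)
    expect_equal(nrow(ge$edges), nrow(want))
    k <- 4L
    gk <- build_knn_graph(X, k, cfg)
    # brute force union-of-kNN relation
    pairs <- matrix(0L, 0, 2)
    for (x in 1:60) {
      nb <- order(D[x, ])[2:(k + 1)]
      pairs <- rbind(pairs, cbind(pmin(x, nb), pmax(x, nb)))
    }
    pairs <- unique(pairs)
    expect_equal(nrow(gk$edges), nrow(pairs))
  }
})

test_that("RAG collapses regions and knn_extend adds long-range edges", {
  cfg <- similarity_config("constant")
  # 4-path split 2|2 -> single RAG edge
  base <- weighted_graph(4, cbind(i = 1:3, j = 2:4, w = 1),
                         payload = matrix(c(0, 0, 1, 1)))
  rag <- build_rag(c(1, 1, 2, 2), base, cfg)
  expect_equal(rag$n, 2L)
  expect_equal(nrow(rag$edges), 1L)
  expect_equal(drop(rag$payload), c(0, 1))
  # singleton regions reproduce the base graph
  iso <- build_rag(1:4, base, cfg)
  expect_equal(iso$edges[, 1:2], base$edges[, 1:2])
  # one region: no edges
  one <- build_rag(rep(1, 4), base, cfg)
  expect_equal(one$n, 1L)
  expect_equal(nrow(one$edges), 0L)
  expect_error(build_rag(c(1, NA, 2, 2), base, cfg))
  # knn_extend: k = 0 unchanged; identical means across clusters get linked
  expect_identical(knn_extend(rag, 0)$edges, rag$edges)
  two <- weighted_graph(4, cbind(i = c(1, 3), j = c(2, 4), w = 1),
                        payload = matrix(c(0, 5, 0.01, 5.01)))
  ext <- knn_extend(two, 1, cfg)
  expect_true(nrow(ext$edges) > nrow(two$edges))
  # re-adding an existing edge keeps the count
  ext2 <- knn_extend(ext, 1, cfg)
  expect_equal(nrow(ext2$edges), nrow(ext$edges))
})

test_that("constructed graphs satisfy the structural invariants", {
  set.seed(7)
  graphs <- list(
    build_grid_graph(matrix(runif(30), 5, 6), 4,
                     similarity_config(sigma = 1)),
    build_knn_graph(matrix(rnorm(40), 20), 3, similarity_config(sigma = 1)),
    build_epsilon_graph(matrix(rnorm(30), 15), 1.5,
                        similarity_config("inverse")),
    random_connected_graph(25)
  )
  for (g in graphs) {
    expect_true(validate_graph(g))
    # symmetric weights by storage; spot-check the neighbor API
    for (x in sample(g$n, 5)) {
      for (y in neighbors(g, x)) {
        expect_identical(edge_weight(g, x, y), edge_weight(g, y, x))
        expect_gt(edge_weight(g, x, y), 0)
      }
    }
    expect_equal(edge_weight(g, 1, 1), 0)
  }
  expect_error(weighted_graph(3, cbind(1, 1, 1)), "loop")
  expect_error(weighted_graph(3, cbind(1, 2, 0)), "positive")
  expect_error(weighted_graph(3, cbind(1, 4, 1)), "range")
})
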