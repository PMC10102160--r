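path_graph <- function(n) weighted_graph(n, cbind(i = 1:(n - 1), j = 2:n,
                                                  w = 1))

test_that("dirichlet_spec validates its invariants", {
  g <- path_graph(5)
  expect_error(dirichlet_spec(g, integer(), 1), "nonempty")
  expect_error(dirichlet_spec(g, c(1, 5), c(0, 1), interior = c(1, 3)),
               "disjoint")
  # interior component with no boundary contact
  g2 <- weighted_graph(4, cbind(i = c(1, 3), j = c(2, 4), w = 1))
  expect_error(dirichlet_spec(g2, 1, 1, interior = c(2, 3, 4)),
               "no path")
  expect_silent(dirichlet_spec(g, c(1, 5), c(0, 0, 0, 0, 1)))
})

test_that("one averaging step matches the closed form on a 3-path", {
  g <- path_graph(3)
  spec <- dirichlet_spec(g, boundary = c(1, 3), g_values = c(0, 0, 1))
  v <- nla_step(c(0, 0, 1), game_params(1, 1, 0), spec)
  expect_equal(v, c(0, 0.5, 1))
  # fixed point stays fixed; constants stay constant
  vfix <- c(0, 0.5, 1)
  expect_equal(nla_step(vfix, game_params(1, 1, 0), spec), vfix)
  specc <- dirichlet_spec(g, boundary = c(1, 3), g_values = c(2, 2, 2))
  expect_equal(nla_step(c(2, 2, 2), game_params(p = 4), specc), c(2, 2, 2))
})

test_that("paths solve to the linear profile for infinity- and mean-Laplacian", {
  g <- path_graph(5)
  spec <- dirichlet_spec(g, boundary = c(1, 5), g_values = c(0, 0, 0, 0, 1))
  for (pr in list(game_params(1, 1, 0), game_params(0, 0, 1))) {
    sol <- solve_dirichlet(spec, pr, tol = 1e-8)
    expect_true(sol$report$converged)
    expect_lt(max(abs(sol$u - c(0, 0.25, 0.5, 0.75, 1))), 1e-5)
  }
})

test_that("gamma = 1 solutions match the dense linear-system oracle", {
  set.seed(21)
  for (trial in 1:8) {
    n <- sample(10:40, 1)
    g <- random_connected_graph(n)
    boundary <- sample(n, max(2, round(n / 4)))
    gvals <- numeric(n)
    gvals[boundary] <- rnorm(length(boundary))
    spec <- dirichlet_spec(g, boundary, gvals)
    sol <- solve_dirichlet(spec, game_params(0, 0, 1), tol = 1e-8)
    want <- dense_mean_laplacian_solution(g, boundary, gvals)
    expect_lt(max(abs(sol$u - want)), 1e-5)
  }
})

test_that("maximum principle and comparison hold for h = 0", {
  set.seed(22)
  for (trial in 1:6) {
    n <- sample(8:25, 1)
    g <- random_connected_graph(n)
    boundary <- sample(n, max(2, round(n / 3)))
    g1 <- numeric(n); g1[boundary] <- runif(length(boundary), -1, 1)
    pr <- random_simplex_params()
    s1 <- solve_dirichlet(dirichlet_spec(g, boundary, g1), pr, tol = 1e-9)
    expect_gte(min(s1$u), min(g1[boundary]) - 1e-8)
    expect_lte(max(s1$u), max(g1[boundary]) + 1e-8)
    # comparison: raise the boundary data, the solution rises everywhere
    g2 <- g1; g2[boundary] <- g2[boundary] + runif(length(boundary), 0, 1)
    s2 <- solve_dirichlet(dirichlet_spec(g, boundary, g2), pr, tol = 1e-9)
    expect_true(all(s2$u >= s1$u - 1e-7))
  }
})

test_that("the iteration is nonexpansive in the initial guess", {
  set.seed(23)
  g <- random_connected_graph(15)
  boundary <- c(1, 2, 3)
  gv <- numeric(15); gv[boundary] <- c(-1, 0, 1)
  pr <- game_params(p = 3)
  u <- rnorm(15); v <- rnorm(15)
  u[boundary] <- gv[boundary]; v[boundary] <- gv[boundary]
  spec <- dirichlet_spec(g, boundary, gv)
  for (it in 1:20) {
    un <- nla_step(u, pr, spec)
    vn <- nla_step(v, pr, spec)
    expect_lte(max(abs(un - vn)), max(abs(u - v)) + 1e-12)
    u <- un; v <- vn
  }
  # and nl_average itself is nonexpansive
  a <- rnorm(15); b <- rnorm(15)
  expect_lte(max(abs(nl_average(g, a, pr) - nl_average(g, b, pr))),
             max(abs(a - b)) + 1e-12)
})

test_that("Gauss-Seidel sweeps reach the same fixed point as Jacobi", {
  set.seed(24)
  g <- random_connected_graph(20)
  boundary <- sample(20, 5)
  gv <- numeric(20); gv[boundary] <- rnorm(5)
  spec <- dirichlet_spec(g, boundary, gv)
  for (pr in list(game_params(1, 1, 0), game_params(p = 3))) {
    ja <- solve_dirichlet(spec, pr, tol = 1e-10)
    gs <- solve_dirichlet(spec, pr, tol = 1e-10, sweep = "gauss-seidel")
    expect_lt(max(abs(ja$u - gs$u)), 1e-8)
    expect_lte(gs$report$iterations, ja$report$iterations)
  }
})

test_that("source terms enter as u - NLA(u) = h", {
  # single interior vertex between two boundary vertices: u = (g0+g2)/2 + h
  g <- path_graph(3)
  spec <- dirichlet_spec(g, boundary = c(1, 3), g_values = c(0.2, 0, 1),
                         h = c(0, 0.3, 0))
  sol <- solve_dirichlet(spec, game_params(1, 1, 0), tol = 1e-10)
  expect_equal(sol$u[2], (0.2 + 1) / 2 + 0.3, tolerance = 1e-8)
  expect_lt(sol$report$residual, 1e-8)
})

test_that("parabolic evolution converges to the elliptic solution", {
  g <- path_graph(5)
  gv <- c(0, 0, 0, 0, 1)
  pr <- game_params(1, 1, 0)
  spec <- dirichlet_spec(g, c(1, 5), gv)
  sol <- solve_dirichlet(spec, pr, tol = 1e-10)
  # dt = 1 clamped evolution is exactly the averaging iteration
  ev1 <- evolve_parabolic(g, c(0, 0, 0, 0, 1), pr, dt = 1, steps = 200,
                          boundary = c(1, 5), g_values = gv)
  expect_lt(max(abs(ev1 - sol$u)), 1e-6)
  ev05 <- evolve_parabolic(g, c(0, 0, 0, 0, 1), pr, dt = 0.5, steps = 400,
                           boundary = c(1, 5), g_values = gv)
  expect_lt(max(abs(ev05 - sol$u)), 1e-6)
  # constant initial state, h = 0, no clamp: trajectory constant
  traj <- evolve_parabolic(g, rep(1.5, 5), pr, dt = 0.7, steps = 5,
                           keep = "all")
  for (st in traj) expect_equal(st, rep(1.5, 5))
  expect_error(evolve_parabolic(g, rep(0, 5), pr, dt = 1.5, steps = 1),
               "dt")
})

test_that("inpainting restores constant and piecewise-constant regions", {
  # constant image with a hole: exact fill
  mask <- matrix(FALSE, 10, 10); mask[4:6, 4:6] <- TRUE
  r <- inpaint(matrix(0.7, 10, 10), mask, tol = 1e-8)
  expect_equal(max(abs(r$image - 0.7)), 0)
  # two-tone image, hole strictly inside one tone
  fx <- generate_test_image(fixture_config("two_tone_image", seed = 1,
                                           dim = c(12, 12)))
  mask2 <- matrix(FALSE, 12, 12); mask2[5:7, 9:11] <- TRUE
  r2 <- inpaint(fx$truth, mask2, tol = 1e-8)
  expect_lt(max(abs(r2$image - fx$truth)), 1e-3)
  expect_error(inpaint(matrix(1, 4, 4), matrix(TRUE, 4, 4)), "known")
})

test_that("colorization diffuses scribble colors across clusters", {
  pc <- generate_point_cloud(fixture_config("point_cloud_clusters",
                                            seed = 5, dim = 50))
  res <- colorize(pc$coords, pc$scribbles,
                  pc$colors[pc$scribbles, , drop = FALSE], k = 8,
                  tol = 1e-8)
  expect_lt(max(abs(res$colors - pc$colors)), 1e-3)
  expect_error(colorize(pc$coords, integer(), pc$colors[0, , drop = FALSE]),
               "scribble")
})
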