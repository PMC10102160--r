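# Random instances and independent oracles used across the suite.

# Random connected graph: random spanning tree plus extra random edges.
# Weights default to the similarity range (0, 1]; several operator
# properties (dilation/erosion monotonicity, comparison principles) hold on
# that range, which is what every weight construction in the package emits.
random_connected_graph <- function(n, extra = n, wmin = 0.2, wmax = 1,
                                   unit = FALSE) {
  i <- integer(0); j <- integer(0)
  if (n > 1L) {
    perm <- sample(n)
    for (k in 2:n) {
      i <- c(i, perm[k])
      j <- c(j, perm[sample(k - 1L, 1L)])
    }
  }
  if (extra > 0L && n > 2L) {
    a <- sample(n, extra, replace = TRUE)
    b <- sample(n, extra, replace = TRUE)
    ok <- a != b
    i <- c(i, a[ok]); j <- c(j, b[ok])
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  dup <- duplicated(cbind(lo, hi))
  lo <- lo[!dup]; hi <- hi[!dup]
  w <- if (unit) rep(1, length(lo)) else runif(length(lo), wmin, wmax)
  weighted_graph(n, cbind(i = lo, j = hi, w = w))
}

random_simplex_params <- function() {
  a <- runif(1); b <- runif(1)
  g <- 1 - (a + b) / 2        # in [0, 1] since (a+b)/2 <= 1
  game_params(a, b, g)
}

# --- Dirichlet oracle: dense linear solve for the gamma = 1 (weighted mean
# Laplacian) problem, assembled directly from the definition.
dense_mean_laplacian_solution <- function(g, boundary, gvals, h = 0) {
  n <- g$n
  W <- matrix(0, n, n)
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges$i[r]; j <- g$edges$j[r]; w <- g$edges$w[r]
    W[i, j] <- w; W[j, i] <- w
  }
  P <- W / rowSums(W)
  interior <- setdiff(seq_len(n), boundary)
  hv <- rep_len(h, n)
  u <- numeric(n)
  u[boundary] <- gvals[boundary]
  A <- diag(length(interior)) - P[interior, interior, drop = FALSE]
  b <- P[interior, boundary, drop = FALSE] %*% gvals[boundary] + hv[interior]
  u[interior] <- solve(A, b)
  u
}

# --- Eikonal oracles -------------------------------------------------------

# Independent single-vertex solve: numeric root of
# sum_i w_i^(p/2) ((x - a_i)^+)^p = C^p (bisection, no sorting/incremental
# scheme shared with the implementation).
oracle_local_solve <- function(a, w, C, p) {
  if (is.infinite(p)) return(min(a + C / sqrt(w)))
  f <- function(x) sum(w^(p / 2) * pmax(x - a, 0)^p) - C^p
  lo <- min(a); hi <- max(a) + C / sqrt(min(w)) + 1
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Bellman-Ford style relaxation to a fixed point; uses all current neighbor
# values, not a settlement order.
oracle_eikonal_relax <- function(g, seeds, h = 1, p = Inf, values = 0,
                                 sweeps = 10000) {
  n <- g$n
  hv <- rep_len(h, n)
  u <- rep(Inf, n)
  u[seeds] <- rep_len(values, length(seeds))
  for (s in seq_len(sweeps)) {
    changed <- FALSE
    for (x in setdiff(seq_len(n), seeds)) {
      nb <- neighbors(g, x)
      if (length(nb) == 0L) next
      fin <- is.finite(u[nb])
      if (!any(fin)) next
      w <- vapply(nb[fin], function(y) edge_weight(g, x, y), numeric(1))
      cand <- oracle_local_solve(u[nb[fin]], w, hv[x], p)
      if (cand < u[x] - 1e-12) { u[x] <- cand; changed <- TRUE }
    }
    if (!changed) break
  }
  u
}

# Independent fast marching on a uniform 4-neighbor grid (unit weights,
# p = 2): arrays only, naive linear min search over the trial set, local
# solve of sum_nb ((x - a)^+)^2 = h^2 by bisection over settled neighbors
# (non-settled neighbors are clamped out of the sum at the solution).
oracle_fmm_grid <- function(H, W, seed_rc, h = 1, p = 2) {
  u <- matrix(Inf, H, W)
  state <- matrix(0L, H, W)      # 0 far, 1 trial, 2 settled
  u[seed_rc[1], seed_rc[2]] <- 0
  state[seed_rc[1], seed_rc[2]] <- 1L
  nbrs <- function(r, c) {
    out <- list()
    if (r > 1) out <- c(out, list(c(r - 1, c)))
    if (r < H) out <- c(out, list(c(r + 1, c)))
    if (c > 1) out <- c(out, list(c(r, c - 1)))
    if (c < W) out <- c(out, list(c(r, c + 1)))
    out
  }
  upd <- function(r, c) {
    a <- c()
    for (nb in nbrs(r, c))
      if (state[nb[1], nb[2]] == 2L) a <- c(a, u[nb[1], nb[2]])
    if (length(a) == 0L) return(Inf)
    oracle_local_solve(a, rep(1, length(a)), h, p)
  }
  repeat {
    trial <- which(state == 1L)
    if (length(trial) == 0L) break
    x <- trial[which.min(u[trial])]
    state[x] <- 2L
    r <- (x - 1L) %% H + 1L; c <- (x - 1L) %/% H + 1L
    for (d in nbrs(r, c)) {
      if (state[d[1], d[2]] == 2L) next
      u[d[1], d[2]] <- min(u[d[1], d[2]], upd(d[1], d[2]))
      state[d[1], d[2]] <- 1L
    }
  }
  u
}

# Hop distance by plain BFS.
oracle_hop_distance <- function(g, seeds) {
  d <- rep(Inf, g$n)
  d[seeds] <- 0
  frontier <- seeds
  k <- 0
  while (length(frontier)) {
    k <- k + 1
    nxt <- integer(0)
    for (x in frontier) for (y in neighbors(g, x))
      if (d[y] > k) { d[y] <- k; nxt <- c(nxt, y) }
    frontier <- unique(nxt)
  }
  d
}

grid_graph_vid <- function(r, c, W) (r - 1L) * W + c
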