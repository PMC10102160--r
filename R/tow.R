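#' Tug-of-War game specification
#'
#' A two-player zero-sum random-turn game on a weighted graph: a token at an
#' interior vertex moves to player I's choice with probability
#' \code{alpha / 2}, to player II's choice with probability \code{beta / 2},
#' and to a random neighbor (drawn proportionally to the edge weights, so
#' the expected value of the random move is the nonlocal mean) with
#' probability \code{gamma}. Play stops at a boundary vertex with terminal
#' payoff \code{g}; the running payoff \code{h} accrues at every interior
#' visit. The game value solves the fixed-point equation
#' \code{u = NLA(u) + h} on the interior with \code{u = g} on the boundary.
#'
#' @param g a \code{weighted_graph}.
#' @param boundary vertex indices with terminal payoff.
#' @param g_values terminal payoff (full-length or per-boundary vector).
#' @param params a \code{\link{game_params}}.
#' @param h running payoff (scalar or per-vertex), default 0.
#' @param max_steps episode cap for simulation, default \code{1e5}.
#' @param seed RNG seed used by \code{\link{simulate_game}}.
#' @return an object of class \code{game_spec}.
#' @export
game_spec <- function(g, boundary, g_values, params, h = 0, max_steps = 1e5,
                      seed = 1L) {
  stopifnot(inherits(g, "weighted_graph"), inherits(params, "game_params"))
  boundary <- sort(unique(as.integer(boundary)))
  if (length(boundary) == 0L) stop("boundary must be nonempty")
  gv <- as.numeric(g_values)
  if (length(gv) == length(boundary) && length(boundary) != g$n) {
    full <- numeric(g$n); full[boundary] <- gv; gv <- full
  }
  if (length(gv) != g$n) stop("'g_values' must cover the boundary")
  interior <- setdiff(seq_len(g$n), boundary)
  .check_solvable(g, interior, boundary)
  hv <- rep_len(as.numeric(h), g$n)
  structure(list(graph = g, boundary = boundary, interior = interior,
                 g_values = gv, params = params, h = hv,
                 max_steps = as.integer(max_steps), seed = as.integer(seed)),
            class = "game_spec")
}

#' Pairwise move probability
#'
#' When both players have committed to targets \code{y} and \code{z}, the
#' token moves to \code{y} with probability
#' \code{sqrt(w(x,y)) / (sqrt(w(x,y)) + sqrt(w(x,z)))}: heavier (more
#' similar) edges are favored, and equal weights give a fair coin.
#'
#' @param w_xy,w_xz positive edge weights.
#' @return probability in \code{(0, 1)}.
#' @export
move_probability <- function(w_xy, w_xz) {
  if (any(w_xy <= 0) || any(w_xz <= 0)) stop("weights must be positive")
  sqrt(w_xy) / (sqrt(w_xy) + sqrt(w_xz))
}

#' Dynamic programming operator of the game
#'
#' One application of the value recursion: \code{NLA(u) + h} on the
#' interior, \code{g} on the boundary. Its fixed point is the game value;
#' for \code{alpha = beta = 1}, \code{gamma = 0} it coincides pointwise with
#' the max-min form \code{max_y min_z [P(x,y,z) u(y) + (1 - P) u(z)]} over
#' neighbor pairs.
#'
#' @param u current value estimate (length-\code{n} numeric).
#' @param spec a \code{\link{game_spec}}.
#' @param step iteration index (per-step parameter fields).
#' @return updated value vector.
#' @export
dpp_operator <- function(u, spec, step = 1L) {
  stopifnot(inherits(spec, "game_spec"))
  g <- spec$graph
  v <- drop(nl_average(g, u, spec$params, step)) + spec$h
  v[spec$boundary] <- spec$g_values[spec$boundary]
  v
}

#' Game value by fixed-point iteration
#'
#' Iterates \code{\link{dpp_operator}} from the boundary data (0 inside)
#' until the sup-norm update drops below \code{tol}. The result is the same
#' fixed point computed by \code{\link{solve_dirichlet}} on the equivalent
#' Dirichlet problem.
#'
#' @param spec a \code{\link{game_spec}}.
#' @param tol sup-norm tolerance, default \code{1e-10}.
#' @param max_iter iteration cap.
#' @return list with \code{u} (value vector), \code{iterations},
#'   \code{converged}.
#' @export
value_iteration <- function(spec, tol = 1e-10, max_iter = 1e6) {
  stopifnot(inherits(spec, "game_spec"))
  u <- numeric(spec$graph$n)
  u[spec$boundary] <- spec$g_values[spec$boundary]
  it <- 0L
  repeat {
    it <- it + 1L
    v <- dpp_operator(u, spec, step = it)
    upd <- max(abs(v - u))
    u <- v
    if (upd <= tol || it >= max_iter) break
  }
  list(u = u, iterations = it, converged = upd <= tol)
}

#' Monte-Carlo simulation of the game
#'
#' Plays \code{n_playouts} episodes from \code{start} with both players
#' following greedy strategies read from a value function (default: the
#' \code{\link{value_iteration}} fixed point): player I moves to the
#' neighbor (or stays) maximizing the value, player II to the minimizer,
#' and the random move samples a neighbor proportionally to edge weight.
#' For \code{alpha = beta = 1} on non-unit weights the pairwise rule applies
#' instead: the token goes to player I's choice with probability
#' \code{P(x, y, z)} and to player II's otherwise. Each episode accumulates
#' \code{h} at visited interior vertices and ends with \code{g} at the
#' absorbing boundary vertex. On unit-weight graphs the estimate is a
#' consistent stochastic oracle for the deterministic fixed point; for
#' general weights and \code{gamma > 0} it is exploratory only.
#'
#' Episodes hitting the step cap are excluded from the mean and counted in
#' \code{capped}. The spec's seed makes results bit-reproducible.
#'
#' @param spec a \code{\link{game_spec}}.
#' @param start starting vertex.
#' @param n_playouts number of episodes.
#' @param value_fun optional value vector guiding the greedy strategies.
#' @return a \code{value_estimate}: list with \code{mean}, \code{se}
#'   (sample sd / sqrt(n)), \code{n}, \code{capped}, \code{start},
#'   \code{seed}.
#' @export
simulate_game <- function(spec, start, n_playouts = 1e4, value_fun = NULL) {
  stopifnot(inherits(spec, "game_spec"))
  g <- spec$graph
  start <- as.integer(start)
  if (start %in% spec$boundary) {
    est <- list(mean = spec$g_values[start], se = 0, n = n_playouts,
                capped = 0L, start = start, seed = spec$seed)
    class(est) <- "value_estimate"
    return(est)
  }
  if (is.null(value_fun)) value_fun <- value_iteration(spec)$u
  v <- as.numeric(value_fun)
  ca <- g$cache
  n <- g$n
  # greedy targets over I(x) U {x}
  U <- matrix(v[ca$nbr], nrow = n)
  U[ca$w == 0] <- NA
  pick <- function(best) {
    out <- integer(n)
    for (x in seq_len(n)) {
      cand <- c(x, ca$nbr[x, !is.na(U[x, ])])
      vals <- v[cand]
      out[x] <- cand[if (best) which.max(vals) else which.min(vals)]
    }
    out
  }
  mv_max <- pick(TRUE)
  mv_min <- pick(FALSE)
  cw <- t(apply(ca$w, 1, cumsum))            # cumulative weights per vertex
  if (is.null(dim(cw))) cw <- matrix(cw, nrow = n)
  totw <- ca$strength
  pr <- .resolve_params(spec$params, n)
  is_bnd <- logical(n); is_bnd[spec$boundary] <- TRUE
  pairwise <- all(abs(pr$alpha - 1) < 1e-12) && all(abs(pr$beta - 1) < 1e-12)
  set.seed(spec$seed)
  pos <- rep(start, n_playouts)
  payoff <- numeric(n_playouts)
  active <- rep(TRUE, n_playouts)
  steps <- 0L
  while (any(active) && steps < spec$max_steps) {
    steps <- steps + 1L
    idx <- which(active)
    x <- pos[idx]
    payoff[idx] <- payoff[idx] + spec$h[x]
    m <- length(idx)
    coin <- stats::runif(m)
    nxt <- integer(m)
    if (pairwise) {
      y <- mv_max[x]; z <- mv_min[x]
      if (all(abs(ca$wd - 1) < 1e-12)) {         # unit weights: fair coin
        wy <- rep(1, m); wz <- rep(1, m)
      } else {
        wy <- ifelse(y == x, 1, .edge_w_fast(ca, x, y))
        wz <- ifelse(z == x, 1, .edge_w_fast(ca, x, z))
      }
      # a stay is realized with the weight of the forgone edge balanced out:
      # when both picks are proper neighbors the printed pairwise rule applies;
      # a pick equal to x (inactive clamp) uses weight 1 against weight 1.
      wy[y == x & z == x] <- 1; wz[y == x & z == x] <- 1
      P <- move_probability(wy, wz)
      nxt <- ifelse(coin < P, y, z)
    } else {
      a2 <- pr$alpha[x] / 2; b2 <- pr$beta[x] / 2
      to_max <- coin < a2
      to_min <- !to_max & coin < a2 + b2
      rnd <- !(to_max | to_min)
      nxt[to_max] <- mv_max[x[to_max]]
      nxt[to_min] <- mv_min[x[to_min]]
      if (any(rnd)) {
        xr <- x[rnd]
        r <- stats::runif(sum(rnd)) * totw[xr]
        slot <- rowSums(cw[xr, , drop = FALSE] < r) + 1L
        slot <- pmin(slot, ca$deg[xr])
        nxt[rnd] <- ca$nbr[cbind(xr, slot)]
      }
    }
    pos[idx] <- nxt
    done <- is_bnd[nxt]
    if (any(done)) {
      fin <- idx[done]
      payoff[fin] <- payoff[fin] + spec$g_values[pos[fin]]
      active[fin] <- FALSE
    }
  }
  capped <- sum(active)
  vals <- payoff[!active]
  est <- list(mean = mean(vals),
              se = if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals))
                   else 0,
              n = length(vals), capped = capped, start = start,
              seed = spec$seed)
  class(est) <- "value_estimate"
  est
}

.edge_w_fast <- function(ca, x, y) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    rng <- (ca$off[x[i]] + 1L):ca$off[x[i] + 1L]
    k <- match(y[i], ca$to[rng])
    out[i] <- if (is.na(k)) 0 else ca$wd[rng][k]
  }
  out
}

#' @export
print.value_estimate <- function(x, ...) {
  cat(sprintf(
    "value_estimate: start %d, mean %.6g +/- %.3g (SE), n = %d, capped = %d\n",
    x$start, x$mean, x$se, x$n, x$capped))
  invisible(x)
}
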