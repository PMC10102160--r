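#' Tug-of-War game parameters
#'
#' The probability triple \code{(alpha, beta, gamma)} of the generalized
#' random-turn game: player I moves with probability \code{alpha / 2},
#' player II with \code{beta / 2}, and the token moves at random with
#' probability \code{gamma}, subject to the simplex constraint
#' \code{(alpha + beta) / 2 + gamma = 1}. Each entry may be a scalar, a
#' per-vertex vector, or a function of the iteration step returning either
#' (the time-dependent game). Alternatively, \code{p >= 2} derives
#' \code{alpha = beta = (p - 2) / p}, \code{gamma = 2 / p}, the game
#' p-Laplacian row of the parameter dictionary.
#'
#' @param alpha,beta,gamma nonnegative scalars, per-vertex vectors, or
#'   functions of the step index.
#' @param p optional real \code{>= 2}; when given, overrides the triple.
#' @param strict enforce the simplex constraint (default). Formal parameter
#'   rows that drop the random-move mass -- e.g. \code{(0, 1, 0)}, whose
#'   game operator is \code{-(1/2) |grad- u|_inf}, half the eikonal
#'   operator -- require \code{strict = FALSE}; such triples are valid in
#'   \code{\link{delta_abg}} but are not probability distributions and give
#'   no convergent averaging iteration.
#' @return an object of class \code{game_params}.
#' @examples
#' game_params(1, 1, 0)        # infinity-Laplacian
#' game_params(p = 4)          # game 4-Laplacian: alpha = beta = gamma = 1/2
#' @export
game_params <- function(alpha = NULL, beta = NULL, gamma = NULL, p = NULL,
                        strict = TRUE) {
  if (!is.null(p)) {
    if (!is.numeric(p) || p < 2) stop("'p' must be >= 2")
    alpha <- beta <- (p - 2) / p
    gamma <- 2 / p
  }
  if (is.null(alpha) || is.null(beta) || is.null(gamma))
    stop("provide (alpha, beta, gamma) or p")
  pr <- structure(list(alpha = alpha, beta = beta, gamma = gamma, p = p,
                       strict = strict),
                  class = "game_params")
  if (strict && !is.function(alpha) && !is.function(beta) &&
      !is.function(gamma))
    .check_simplex(alpha, beta, gamma)
  pr
}

.check_simplex <- function(a, b, g, tol = 1e-10) {
  if (any(a < -tol) || any(b < -tol) || any(g < -tol))
    stop("alpha, beta, gamma must be nonnegative")
  if (any(abs((a + b) / 2 + g - 1) > tol))
    stop("(alpha + beta)/2 + gamma must equal 1")
  invisible(TRUE)
}

# Evaluate params at a step on a graph with n vertices -> list of length-n
# coefficient vectors.
.resolve_params <- function(params, n, step = 1L) {
  stopifnot(inherits(params, "game_params"))
  ev <- function(f) {
    v <- if (is.function(f)) f(step) else f
    if (length(v) == 1L) rep(as.numeric(v), n) else {
      if (length(v) != n) stop("per-vertex parameter field has wrong length")
      as.numeric(v)
    }
  }
  a <- ev(params$alpha); b <- ev(params$beta); g <- ev(params$gamma)
  if (isTRUE(params$strict)) .check_simplex(a, b, g)
  list(alpha = a, beta = b, gamma = g)
}

.as_signal <- function(g, u) {
  u <- if (is.matrix(u)) u else matrix(as.numeric(u), ncol = 1L)
  if (nrow(u) != g$n) stop("signal length does not match vertex count")
  if (any(!is.finite(u))) stop("signal must be finite")
  u
}

.drop_signal <- function(u, was_vector) if (was_vector) drop(u) else u

.require_no_isolated <- function(g, vertices = NULL) {
  deg <- g$cache$deg
  bad <- if (is.null(vertices)) any(deg == 0L) else any(deg[vertices] == 0L)
  if (bad) stop("graph has isolated vertices; operators are undefined there")
}

.row_max <- function(M) as.vector(Reduce(pmax, asplit(M, 2)))

# sqrt(w)-scaled signed differences to neighbors, n x maxdeg, pads -> 0.
.sw_diff <- function(g, u) {
  ca <- g$cache
  U <- matrix(u[ca$nbr], nrow = g$n)
  ca$sw * (U - u)
}

#' Upwind gradient norms
#'
#' One-sided discrete gradients on a weighted graph: the positive part
#' keeps increases toward neighbors, the negative part keeps decreases,
#' each scaled by \code{sqrt(w(x, y))}. For \code{p = Inf} the norm is the
#' maximum over neighbors; for finite \code{p >= 1} it is
#' \code{(sum_y w(x,y)^(p/2) ((u(y) - u(x))^{+/-})^p)^(1/p)}.
#'
#' @param g a \code{weighted_graph} without isolated vertices.
#' @param u single-channel signal (length-\code{n} numeric).
#' @param sign \code{"+"} or \code{"-"}.
#' @param p norm index in \code{[1, Inf]}.
#' @return numeric vector of per-vertex norms (all nonnegative).
#' @export
grad_norm <- function(g, u, sign = c("+", "-"), p = Inf) {
  sign <- match.arg(sign)
  if (p < 1) stop("'p' must be >= 1")
  u <- drop(.as_signal(g, u))
  if (is.matrix(u)) stop("gradient norms take single-channel signals")
  .require_no_isolated(g)
  D <- .sw_diff(g, u)
  Dp <- if (sign == "+") pmax(D, 0) else pmax(-D, 0)
  if (is.infinite(p)) .row_max(Dp) else rowSums(Dp^p)^(1 / p)
}

#' @rdname grad_norm
#' @param x single vertex index.
#' @export
upwind_gradient_norm <- function(g, u, x, sign = c("+", "-"), p = Inf) {
  x <- as.integer(x)
  if (g$cache$deg[x] == 0L) stop("isolated vertex")
  grad_norm(g, u, sign, p)[x]
}

#' Graph Laplacians
#'
#' \code{laplacian_2} is the weighted-mean Laplacian
#' \code{(sum_y w u(y)) / (sum_y w) - u(x)}; \code{laplacian_inf} is
#' \code{(|grad+|_inf - |grad-|_inf) / 2}, whose harmonic functions are
#' discrete optimal-Lipschitz extensions; \code{game_p_laplacian} is the
#' convex combination \code{((p - 2)/p) laplacian_inf + (2/p) laplacian_2}.
#'
#' @inheritParams grad_norm
#' @return numeric vector over vertices.
#' @export
laplacian_2 <- function(g, u) {
  u <- drop(.as_signal(g, u))
  .require_no_isolated(g)
  ca <- g$cache
  U <- matrix(u[ca$nbr], nrow = g$n)
  rowSums(ca$w * U) / ca$strength - u
}

#' @rdname laplacian_2
#' @export
laplacian_inf <- function(g, u) {
  (grad_norm(g, u, "+", Inf) - grad_norm(g, u, "-", Inf)) / 2
}

#' @rdname laplacian_2
#' @param p real \code{>= 2}.
#' @export
game_p_laplacian <- function(g, u, p) {
  if (p < 2) stop("'p' must be >= 2")
  ((p - 2) / p) * laplacian_inf(g, u) + (2 / p) * laplacian_2(g, u)
}

# channel-wise application of a single-channel operator
.per_channel <- function(g, u, f) {
  was_vec <- !is.matrix(u)
  U <- .as_signal(g, u)
  out <- U
  for (ch in seq_len(ncol(U))) out[, ch] <- f(U[, ch])
  .drop_signal(out, was_vec)
}

#' Nonlocal morphology on weighted graphs
#'
#' Nonlocal dilation \code{NLD(u) = u + |grad+ u|_inf}, erosion
#' \code{NLE(u) = u - |grad- u|_inf} and mean \code{NLM(u) = u + lap2(u)}.
#' With unit weights these reduce to the classical morphological operators
#' over \code{I(x) U {x}} (the one-sided clamps make \code{NLD >= u >= NLE}
#' pointwise, so the center value participates). Multi-channel signals are
#' processed per channel.
#'
#' @inheritParams grad_norm
#' @param u numeric vector or \code{n x C} matrix.
#' @return same shape as \code{u}.
#' @export
nl_dilation <- function(g, u)
  .per_channel(g, u, function(v) v + grad_norm(g, v, "+", Inf))

#' @rdname nl_dilation
#' @export
nl_erosion <- function(g, u)
  .per_channel(g, u, function(v) v - grad_norm(g, v, "-", Inf))

#' @rdname nl_dilation
#' @export
nl_mean <- function(g, u)
  .per_channel(g, u, function(v) v + laplacian_2(g, v))

#' Nonlocal averaging operator
#'
#' The convex combination
#' \code{NLA(u) = (alpha/2) NLD(u) + (beta/2) NLE(u) + gamma NLM(u)} that
#' encodes one step of the generalized Tug-of-War game: best move, worst
#' move and random move weighted by the game probabilities. It is an
#' averaging operator (normalized, homogeneous, translation-invariant,
#' monotone), hence nonexpansive in the sup norm, and its output at each
#' vertex lies within the local range \code{[min, max]} over
#' \code{I(x) U {x}}.
#'
#' @inheritParams nl_dilation
#' @param params a \code{\link{game_params}}.
#' @param step iteration index forwarded to per-step parameter fields.
#' @return same shape as \code{u}.
#' @export
nl_average <- function(g, u, params, step = 1L) {
  pr <- .resolve_params(params, g$n, step)
  .per_channel(g, u, function(v) {
    (pr$alpha / 2) * (v + grad_norm(g, v, "+", Inf)) +
      (pr$beta / 2) * (v - grad_norm(g, v, "-", Inf)) +
      pr$gamma * (v + laplacian_2(g, v))
  })
}

# single-vertex NLA on a (possibly multi-channel) signal matrix, used by
# sequential (Gauss-Seidel) sweeps; pr is a resolved parameter list
.nla_vertex <- function(g, U, pr, x) {
  ca <- g$cache
  if (ca$deg[x] == 0L) stop("isolated vertex")
  rng <- (ca$off[x] + 1L):ca$off[x + 1L]
  nb <- ca$to[rng]
  sw <- sqrt(ca$wd[rng])
  w <- ca$wd[rng]
  out <- numeric(ncol(U))
  for (ch in seq_len(ncol(U))) {
    d <- sw * (U[nb, ch] - U[x, ch])
    nld <- U[x, ch] + max(pmax(d, 0))
    nle <- U[x, ch] - max(pmax(-d, 0))
    nlm <- sum(w * U[nb, ch]) / sum(w)
    out[ch] <- (pr$alpha[x] / 2) * nld + (pr$beta[x] / 2) * nle +
      pr$gamma[x] * nlm
  }
  out
}

#' Parameterized game operator
#'
#' \code{delta_abg(u) = (alpha/2) |grad+ u|_inf - (beta/2) |grad- u|_inf +
#' gamma lap2(u)}; algebraically identical to \code{nl_average(u) - u}.
#' Specializations: \code{(1, 1, 0)} is the infinity-Laplacian,
#' \code{(0, 0, 1)} the weighted-mean Laplacian,
#' \code{((p-2)/p, (p-2)/p, 2/p)} the game p-Laplacian, and
#' \code{(0, 1, 0)} yields \code{-|grad- u|_inf}, the (negated) eikonal
#' operator.
#'
#' @inheritParams nl_average
#' @return same shape as \code{u}.
#' @export
delta_abg <- function(g, u, params, step = 1L) {
  pr <- .resolve_params(params, g$n, step)
  .per_channel(g, u, function(v) {
    (pr$alpha / 2) * grad_norm(g, v, "+", Inf) -
      (pr$beta / 2) * grad_norm(g, v, "-", Inf) +
      pr$gamma * laplacian_2(g, v)
  })
}
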