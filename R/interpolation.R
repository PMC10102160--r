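#' Dirichlet problem specification
#'
#' Describes the interpolation problem \code{-delta_abg u = h} on an
#' interior set \code{A} with \code{u = g} on the boundary \code{dA}.
#' The boundary must be nonempty and disjoint from the interior, and every
#' connected component of the interior subgraph must touch the boundary
#' (otherwise the problem has no data to interpolate there).
#'
#' @param g a \code{weighted_graph}.
#' @param boundary vertex indices of \code{dA}.
#' @param g_values boundary data: numeric vector/matrix over all \code{n}
#'   vertices (interior entries ignored) or over \code{boundary} in order.
#' @param interior vertex indices of \code{A}; defaults to the complement of
#'   \code{boundary}.
#' @param h source term on the interior: scalar or per-vertex (full-length)
#'   vector/matrix; default 0.
#' @param u0 initial guess on the interior; scalar or full-length signal;
#'   default 0.
#' @return an object of class \code{dirichlet_spec}.
#' @export
dirichlet_spec <- function(g, boundary, g_values, interior = NULL, h = 0,
                           u0 = 0) {
  stopifnot(inherits(g, "weighted_graph"))
  boundary <- sort(unique(as.integer(boundary)))
  if (length(boundary) == 0L) stop("boundary must be nonempty")
  if (any(boundary < 1L | boundary > g$n)) stop("boundary vertex out of range")
  if (is.null(interior)) interior <- setdiff(seq_len(g$n), boundary)
  interior <- sort(unique(as.integer(interior)))
  if (length(intersect(interior, boundary)))
    stop("interior and boundary must be disjoint")
  gv <- if (is.matrix(g_values)) g_values else matrix(as.numeric(g_values),
                                                      ncol = 1L)
  if (nrow(gv) == length(boundary) && length(boundary) != g$n) {
    full <- matrix(0, g$n, ncol(gv))
    full[boundary, ] <- gv
    gv <- full
  }
  if (nrow(gv) != g$n) stop("'g_values' must cover the boundary")
  if (any(!is.finite(gv[boundary, ]))) stop("boundary values must be finite")
  expand <- function(v, C) {
    m <- if (is.matrix(v)) v else matrix(as.numeric(v),
                                         nrow = if (length(v) == 1L) 1L else length(v))
    if (nrow(m) == 1L) m <- matrix(m, g$n, max(ncol(m), C), byrow = TRUE)
    if (ncol(m) == 1L && C > 1L) m <- matrix(m, g$n, C)
    if (nrow(m) != g$n || ncol(m) != C) stop("field has wrong shape")
    m
  }
  C <- ncol(gv)
  hm <- expand(h, C)
  u0m <- expand(u0, C)
  .check_solvable(g, interior, boundary)
  structure(list(graph = g, interior = interior, boundary = boundary,
                 g_values = gv, h = hm, u0 = u0m, channels = C,
                 vector_input = !is.matrix(g_values)),
            class = "dirichlet_spec")
}

# every interior component must reach the boundary
.check_solvable <- function(g, interior, boundary) {
  .require_no_isolated(g, interior)
  reach <- logical(g$n)
  reach[boundary] <- TRUE
  in_int <- logical(g$n); in_int[interior] <- TRUE
  # BFS from boundary through interior vertices
  frontier <- boundary
  ca <- g$cache
  while (length(frontier)) {
    nxt <- integer()
    for (x in frontier) {
      if (ca$deg[x] == 0L) next
      nb <- ca$to[(ca$off[x] + 1L):ca$off[x + 1L]]
      new <- nb[in_int[nb] & !reach[nb]]
      reach[new] <- TRUE
      nxt <- c(nxt, new)
    }
    frontier <- nxt
  }
  if (!all(reach[interior]))
    stop("an interior component has no path to the boundary")
  invisible(TRUE)
}

#' One synchronous averaging step
#'
#' Applies \code{v = NLA(u) + h} on the interior and re-imposes \code{v = g}
#' on the boundary: the Jacobi-style fixed-point map whose limit solves the
#' Dirichlet problem.
#'
#' @param u current iterate (full-length signal).
#' @param params a \code{\link{game_params}}.
#' @param spec a \code{\link{dirichlet_spec}}.
#' @param step iteration index (forwarded to per-step parameter fields).
#' @return updated signal, same shape as \code{u}.
#' @export
nla_step <- function(u, params, spec, step = 1L) {
  stopifnot(inherits(spec, "dirichlet_spec"))
  g <- spec$graph
  was_vec <- !is.matrix(u)
  U <- .as_signal(g, u)
  V <- nl_average(g, U, params, step)
  V <- if (is.matrix(V)) V else matrix(V, ncol = 1L)
  V <- V + spec$h
  V[spec$boundary, ] <- spec$g_values[spec$boundary, ]
  .drop_signal(V, was_vec)
}

#' Solve the elliptic Dirichlet interpolation problem
#'
#' Iterates \code{\link{nla_step}} from the initial guess until the sup-norm
#' update falls below \code{tol} or \code{max_iter} is reached. For
#' \code{h = 0} the iterates and the limit obey the maximum principle:
#' every value stays within \code{[min g, max g]} per channel.
#' Non-convergence is reported, not raised.
#'
#' @param spec a \code{\link{dirichlet_spec}}.
#' @param params a \code{\link{game_params}} (default
#'   \code{game_params(1, 1, 0)}, the infinity-Laplacian).
#' @param tol sup-norm update tolerance (default \code{1e-6}).
#' @param max_iter iteration cap (default \code{1e5}).
#' @param sweep \code{"jacobi"} (synchronous, the default and the exact
#'   averaging-filter iteration) or \code{"gauss-seidel"} (in-place
#'   sequential updates in vertex order; same fixed point, often fewer
#'   iterations).
#' @return list with \code{u} (solution signal, vector if the boundary data
#'   was a vector) and \code{report}, a \code{solve_report} with fields
#'   \code{iterations}, \code{update_norm}, \code{residual} (the true
#'   fixed-point residual \code{max |u - NLA(u) - h|} on the interior),
#'   \code{converged}, \code{seconds}.
#' @export
solve_dirichlet <- function(spec, params = game_params(1, 1, 0), tol = 1e-6,
                            max_iter = 1e5,
                            sweep = c("jacobi", "gauss-seidel")) {
  stopifnot(inherits(spec, "dirichlet_spec"))
  sweep <- match.arg(sweep)
  t0 <- proc.time()[["elapsed"]]
  g <- spec$graph
  U <- spec$u0
  U[spec$boundary, ] <- spec$g_values[spec$boundary, ]
  it <- 0L
  upd <- Inf
  while (it < max_iter) {
    it <- it + 1L
    if (sweep == "jacobi") {
      V <- nla_step(U, params, spec, step = it)
      V <- if (is.matrix(V)) V else matrix(V, ncol = 1L)
    } else {
      V <- U
      pr <- .resolve_params(params, g$n, it)
      for (x in spec$interior)
        V[x, ] <- .nla_vertex(g, V, pr, x) + spec$h[x, ]
    }
    upd <- max(abs(V - U))
    U <- V
    if (upd <= tol) break
  }
  NLA <- nl_average(spec$graph, U, params, step = it)
  NLA <- if (is.matrix(NLA)) NLA else matrix(NLA, ncol = 1L)
  res <- max(abs((U - NLA - spec$h)[spec$interior, ]))
  report <- structure(list(iterations = it, update_norm = upd,
                           residual = res, converged = upd <= tol,
                           seconds = proc.time()[["elapsed"]] - t0),
                      class = "solve_report")
  list(u = .drop_signal(U, spec$vector_input && spec$channels == 1L),
       report = report)
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf(
    "solve_report: %d iterations, update %.3g, residual %.3g, %s (%.2fs)\n",
    x$iterations, x$update_norm, x$residual,
    if (x$converged) "converged" else "NOT converged", x$seconds))
  invisible(x)
}

#' Explicit Euler evolution of the parabolic problem
#'
#' Integrates \code{du/dt = NLA(u) - u + h} with step \code{dt} in
#' \code{(0, 1]}; the update is a convex combination of \code{u} and
#' \code{NLA(u) + h}, hence monotone and stable. With \code{dt = 1} and a
#' clamped boundary this is exactly the repeated averaging step of
#' \code{\link{solve_dirichlet}}. Per-step parameter fields are evaluated at
#' each step index, giving the time-dependent game.
#'
#' @param g a \code{weighted_graph}.
#' @param u0 initial signal (vector or \code{n x C}).
#' @param params a \code{\link{game_params}}.
#' @param h source term (scalar or full-length signal), default 0.
#' @param dt time step in \code{(0, 1]}.
#' @param steps number of Euler steps (\code{>= 0}).
#' @param boundary optional vertex set clamped to \code{g_values} after
#'   every step.
#' @param g_values boundary values (full-length or over \code{boundary}).
#' @param keep \code{"last"} (default) or \code{"all"} states.
#' @return the final signal, or a list of signals (including the initial
#'   state) when \code{keep = "all"}.
#' @export
evolve_parabolic <- function(g, u0, params, h = 0, dt = 1, steps,
                             boundary = NULL, g_values = NULL,
                             keep = c("last", "all")) {
  keep <- match.arg(keep)
  if (!is.numeric(dt) || dt <= 0 || dt > 1) stop("'dt' must be in (0, 1]")
  if (steps < 0) stop("'steps' must be >= 0")
  was_vec <- !is.matrix(u0)
  U <- .as_signal(g, u0)
  H <- if (length(h) == 1L) matrix(h, g$n, ncol(U)) else .as_signal(g, h)
  GV <- NULL
  if (!is.null(boundary)) {
    boundary <- as.integer(boundary)
    GV <- if (is.matrix(g_values)) g_values else
      matrix(as.numeric(g_values), ncol = 1L)
    if (nrow(GV) == length(boundary) && length(boundary) != g$n) {
      full <- matrix(0, g$n, ncol(GV)); full[boundary, ] <- GV; GV <- full
    }
    U[boundary, ] <- GV[boundary, ]
  }
  states <- if (keep == "all") vector("list", steps + 1L) else NULL
  if (keep == "all") states[[1L]] <- .drop_signal(U, was_vec)
  for (s in seq_len(steps)) {
    NLA <- nl_average(g, U, params, step = s)
    NLA <- if (is.matrix(NLA)) NLA else matrix(NLA, ncol = 1L)
    U <- U + dt * (NLA - U + H)
    if (!is.null(boundary)) U[boundary, ] <- GV[boundary, ]
    if (keep == "all") states[[s + 1L]] <- .drop_signal(U, was_vec)
  }
  if (keep == "all") states else .drop_signal(U, was_vec)
}

#' Image inpainting by nonlocal averaging
#'
#' Reconstructs the masked region of an image by solving the Dirichlet
#' problem on a grid graph: masked pixels form the interior, all known
#' pixels the boundary, and the default game parameters
#' \code{(alpha, beta, gamma) = (1, 1, 0)} diffuse with the
#' infinity-Laplacian (discrete optimal-Lipschitz extension of the known
#' values). Weights are photometric; patches overlapping the hole are
#' computed after filling the hole with the mean of the known pixels.
#'
#' @param image \code{H x W} or \code{H x W x C} array in \code{[0, 1]}.
#' @param mask logical or 0/1 \code{H x W} matrix; nonzero marks pixels to
#'   reconstruct.
#' @param params a \code{\link{game_params}}; default \code{(1, 1, 0)}.
#' @param cfg a \code{\link{similarity_config}}; default exponential
#'   patch-3 weights with automatic sigma.
#' @param adjacency 4 or 8.
#' @param tol,max_iter solver controls.
#' @return list with \code{image} (reconstructed array), \code{report}, and
#'   \code{graph}.
#' @export
inpaint <- function(image, mask, params = game_params(1, 1, 0),
                    cfg = similarity_config(patch = 3), adjacency = 4,
                    tol = 1e-6, max_iter = 1e5) {
  arr <- .as_image_array(image)
  H <- dim(arr)[1]; W <- dim(arr)[2]; C <- dim(arr)[3]
  msk <- matrix(as.logical(mask != 0), H, W)
  if (all(msk)) stop("mask covers the whole image: no known data")
  hole <- which(t(msk))            # row-major vertex ids
  known <- setdiff(seq_len(H * W), hole)
  # fill the hole with the known mean before computing photometric weights
  filled <- arr
  for (ch in seq_len(C)) {
    plane <- filled[, , ch]
    plane[msk] <- mean(plane[!msk])
    filled[, , ch] <- plane
  }
  g <- build_grid_graph(filled, adjacency = adjacency, cfg = cfg)
  vals <- matrix(aperm(arr, c(2, 1, 3)), nrow = H * W)
  spec <- dirichlet_spec(g, boundary = known, g_values = vals,
                         interior = hole, u0 = vals)
  sol <- solve_dirichlet(spec, params, tol = tol, max_iter = max_iter)
  U <- if (is.matrix(sol$u)) sol$u else matrix(sol$u, ncol = 1L)
  out <- aperm(array(U, c(W, H, C)), c(2, 1, 3))
  if (is.matrix(image)) out <- out[, , 1L]
  list(image = out, report = sol$report, graph = g)
}

#' Scribble-based colorization
#'
#' Diffuses colors from a sparse set of scribbled samples over a
#' k-NN graph built on the available geometry/intensity payload (3D
#' coordinates plus luminance for point clouds, intensity for images).
#' Uncolored samples form the interior of a Dirichlet problem whose boundary
#' data are the scribble colors; the initial guess is the mean scribble
#' color.
#'
#' @param payload numeric matrix, one row per sample (coordinates and/or
#'   intensity features used for similarity).
#' @param scribbles integer indices of colored samples.
#' @param colors numeric matrix with one color row per scribbled sample
#'   (e.g. RGB in \code{[0, 1]}).
#' @param k neighbors for the similarity graph (default 10).
#' @param params a \code{\link{game_params}}; default \code{(1, 1, 0)}.
#' @param cfg a \code{\link{similarity_config}}.
#' @param tol,max_iter solver controls.
#' @return list with \code{colors} (full \code{n x C} matrix),
#'   \code{report}, \code{graph}.
#' @export
colorize <- function(payload, scribbles, colors, k = 10,
                     params = game_params(1, 1, 0),
                     cfg = similarity_config(), tol = 1e-6, max_iter = 1e5) {
  X <- as.matrix(payload)
  scribbles <- as.integer(scribbles)
  if (length(scribbles) == 0L) stop("no scribbles given")
  colors <- as.matrix(colors)
  if (nrow(colors) != length(scribbles))
    stop("one color row per scribble required")
  g <- build_knn_graph(X, k, cfg)
  gv <- matrix(rep(colMeans(colors), each = g$n), g$n)
  gv[scribbles, ] <- colors
  spec <- dirichlet_spec(g, boundary = scribbles, g_values = gv,
                         u0 = matrix(rep(colMeans(colors), each = g$n), g$n))
  sol <- solve_dirichlet(spec, params, tol = tol, max_iter = max_iter)
  U <- if (is.matrix(sol$u)) sol$u else matrix(sol$u, ncol = 1L)
  list(colors = U, report = sol$report, graph = g)
}
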