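# Binary min-heap with lexicographic (key, tie) ordering and lazy deletion.
# tie encodes (label index, vertex index) so equal arrival values settle in a
# documented deterministic order: smaller label first, then smaller vertex.
.heap_new <- function(cap = 64L) {
  env <- new.env(parent = emptyenv())
  env$k <- numeric(cap); env$t <- numeric(cap); env$v <- integer(cap)
  env$size <- 0L
  env
}

.heap_less <- function(h, a, b) {
  h$k[a] < h$k[b] || (h$k[a] == h$k[b] && h$t[a] < h$t[b])
}

.heap_push <- function(h, key, tie, val) {
  s <- h$size + 1L
  if (s > length(h$k)) {
    grow <- length(h$k) * 2L
    h$k <- c(h$k, numeric(grow)); h$t <- c(h$t, numeric(grow))
    h$v <- c(h$v, integer(grow))
  }
  h$k[s] <- key; h$t[s] <- tie; h$v[s] <- val; h$size <- s
  while (s > 1L) {
    p <- s %/% 2L
    if (.heap_less(h, s, p)) {
      h$k[c(p, s)] <- h$k[c(s, p)]; h$t[c(p, s)] <- h$t[c(s, p)]
      h$v[c(p, s)] <- h$v[c(s, p)]
      s <- p
    } else break
  }
}

.heap_pop <- function(h) {
  if (h$size == 0L) return(NULL)
  top <- list(key = h$k[1L], tie = h$t[1L], val = h$v[1L])
  s <- h$size
  h$k[1L] <- h$k[s]; h$t[1L] <- h$t[s]; h$v[1L] <- h$v[s]
  h$size <- s - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L
    m <- i
    if (l <= h$size && .heap_less(h, l, m)) m <- l
    if (r <= h$size && .heap_less(h, r, m)) m <- r
    if (m == i) break
    h$k[c(i, m)] <- h$k[c(m, i)]; h$t[c(i, m)] <- h$t[c(m, i)]
    h$v[c(i, m)] <- h$v[c(m, i)]
    i <- m
  }
  top
}

#' Local eikonal update
#'
#' Solves the one-vertex discrete eikonal equation given the known arrival
#' values \code{a} of settled neighbors, slownesses \code{k = 1/sqrt(w)} and
#' right-hand side \code{C = h(x)}. For \code{p = Inf} the unique solution
#' is the closed form \code{min_i(a_i + k_i C)}. For finite \code{p} it is
#' the unique root of \code{sum_i k_i^{-p} ((x - a_i)^+)^p = C^p}, computed
#' by the standard incremental scheme: sort \code{a} ascending and add terms
#' while the candidate exceeds the next \code{a_i} (for \code{p = 2} on a
#' uniform grid this is the Osher--Sethian update).
#'
#' @param a numeric vector of neighbor arrival values (finite).
#' @param k positive slownesses, same length as \code{a}.
#' @param C positive right-hand side.
#' @param p norm index: \code{1}, \code{2}, \code{Inf}, or any real
#'   \code{>= 1}.
#' @return the updated arrival value (a scalar \code{> min(a)}).
#' @export
local_update <- function(a, k, C, p = Inf) {
  m <- length(a)
  if (m == 0L) stop("empty neighbor list")
  if (length(k) != m) stop("'a' and 'k' must have the same length")
  if (any(k <= 0)) stop("slownesses must be positive")
  if (C <= 0) stop("'C' must be positive")
  if (is.infinite(p)) return(min(a + k * C))
  if (p < 1) stop("'p' must be >= 1")
  o <- order(a)
  a <- a[o]; k <- k[o]
  b <- k^(-p)                                # = w^(p/2)
  if (p == 1) {
    sb <- cumsum(b); sba <- cumsum(b * a)
    for (mm in seq_len(m)) {
      x <- (C + sba[mm]) / sb[mm]
      if (mm == m || x <= a[mm + 1L]) return(x)
    }
  } else if (p == 2) {
    sb <- cumsum(b); sba <- cumsum(b * a); sba2 <- cumsum(b * a^2)
    for (mm in seq_len(m)) {
      disc <- sba[mm]^2 - sb[mm] * (sba2[mm] - C^2)
      x <- (sba[mm] + sqrt(max(disc, 0))) / sb[mm]
      if (mm == m || x <= a[mm + 1L]) return(x)
    }
  } else {
    f <- function(x, mm) sum(b[seq_len(mm)] * (x - a[seq_len(mm)])^p) - C^p
    for (mm in seq_len(m)) {
      hi <- min(a[seq_len(mm)] + k[seq_len(mm)] * C)
      x <- stats::uniroot(f, mm = mm, lower = a[mm], upper = hi,
                          extendInt = "upX", tol = 1e-13)$root
      if (mm == m || x <= a[mm + 1L]) return(x)
    }
  }
  stop("local update failed")  # unreachable: last mm always returns
}

#' Eikonal problem specification
#'
#' Seeds with optional nonzero initial values (e.g. distance-to-reference
#' maps), a strictly positive potential \code{h} off the seeds, and the norm
#' index \code{p}.
#'
#' @param g a \code{weighted_graph}.
#' @param seeds vertex indices of the seed set (nonempty).
#' @param values initial arrival values on the seeds (scalar or per-seed),
#'   default 0.
#' @param h potential: scalar or per-vertex positive vector, default 1.
#' @param p norm index (\code{1}, \code{2} or \code{Inf}).
#' @return an object of class \code{eikonal_spec}.
#' @export
eikonal_spec <- function(g, seeds, values = 0, h = 1, p = Inf) {
  stopifnot(inherits(g, "weighted_graph"))
  seeds <- as.integer(seeds)
  if (length(seeds) == 0L) stop("seed set must be nonempty")
  if (anyDuplicated(seeds)) stop("duplicate seeds")
  if (any(seeds < 1L | seeds > g$n)) stop("seed out of range")
  values <- rep_len(as.numeric(values), length(seeds))
  hv <- rep_len(as.numeric(h), g$n)
  off <- setdiff(seq_len(g$n), seeds)
  if (any(hv[off] <= 0)) stop("'h' must be strictly positive off the seeds")
  structure(list(graph = g, seeds = seeds, values = values, h = hv, p = p),
            class = "eikonal_spec")
}

# Core label-setting solver. labels: optional integer per seed.
.eikonal_run <- function(g, seeds, seed_values, h, p, labels = NULL) {
  n <- g$n
  ca <- g$cache
  u <- rep(Inf, n)
  lab <- rep(NA_integer_, n)
  state <- integer(n)                 # 0 far, 1 trial, 2 settled
  tie_of <- function(l, v) {
    li <- if (is.na(l)) 0 else l
    li * (n + 1) + v
  }
  hp <- .heap_new()
  sl <- if (is.null(labels)) rep(NA_integer_, length(seeds)) else labels
  u[seeds] <- seed_values
  lab[seeds] <- sl
  state[seeds] <- 1L
  for (s in seq_along(seeds))
    .heap_push(hp, seed_values[s], tie_of(sl[s], seeds[s]), seeds[s])
  last <- -Inf
  while (!is.null(top <- .heap_pop(hp))) {
    x <- top$val
    if (state[x] == 2L) next
    if (top$key > u[x] + 1e-15) next       # stale entry
    state[x] <- 2L
    stopifnot(u[x] >= last - 1e-12)        # monotone causality
    last <- u[x]
    if (ca$deg[x] == 0L) next
    rng <- (ca$off[x] + 1L):ca$off[x + 1L]
    for (idx in seq_along(rng)) {
      y <- ca$to[rng[idx]]
      if (state[y] == 2L) next
      # recompute from all settled neighbors of y
      if (ca$deg[y] == 0L) next
      rngy <- (ca$off[y] + 1L):ca$off[y + 1L]
      nb <- ca$to[rngy]
      ws <- ca$wd[rngy]
      ok <- state[nb] == 2L
      if (!any(ok)) next
      cand <- local_update(u[nb[ok]], 1 / sqrt(ws[ok]), h[y], p)
      newlab <- NA_integer_
      if (!is.null(labels)) {
        # label of the front that arrives first: argmin a_i + k_i C,
        # ties to smaller label then smaller vertex
        val <- u[nb[ok]] + h[y] / sqrt(ws[ok])
        cl <- lab[nb[ok]]
        ord <- order(val, cl, nb[ok])[1L]
        newlab <- cl[ord]
      }
      if (cand < u[y] - 1e-15 ||
          (!is.null(labels) && cand <= u[y] + 1e-15 && !is.na(newlab) &&
           (is.na(lab[y]) || newlab < lab[y]))) {
        u[y] <- min(u[y], cand)
        lab[y] <- newlab
        state[y] <- 1L
        .heap_push(hp, u[y], tie_of(lab[y], y), y)
      }
    }
  }
  list(u = u, labels = lab)
}

#' Solve the graph eikonal equation
#'
#' Computes the generalized distance map \code{u} with \code{u = values} on
#' the seeds and the discrete eikonal equation (positive-part upwind
#' gradient norm equal to \code{h}) elsewhere, by a monotone Dijkstra-like
#' label-setting sweep: vertices settle in nondecreasing order of value and
#' are never revisited, each settlement triggering the explicit
#' \code{\link{local_update}} at its unsettled neighbors. Vertices
#' unreachable from the seeds keep value \code{Inf}.
#'
#' @param spec an \code{\link{eikonal_spec}}.
#' @return numeric vector of arrival values (\code{Inf} = unreachable).
#' @export
solve_eikonal <- function(spec) {
  stopifnot(inherits(spec, "eikonal_spec"))
  .eikonal_run(spec$graph, spec$seeds, spec$values, spec$h, spec$p)$u
}

#' Multi-label front propagation
#'
#' Runs a single multi-source eikonal sweep in which every seed carries a
#' label; each vertex receives the label of the front that reaches it first,
#' fronts stopping where they meet. Ties (exactly equal arrival values) go
#' to the smaller label index, then the smaller vertex index. The resulting
#' label map partitions the reachable vertices and every region contains its
#' own seeds.
#'
#' @param g a \code{weighted_graph}.
#' @param seeds list of per-label vertex vectors (disjoint, nonempty), or an
#'   integer vector over vertices with 0/NA = unseeded.
#' @param h positive potential (scalar or per-vertex), default 1.
#' @param p norm index, default \code{Inf}.
#' @param values optional per-seed initial values (default 0).
#' @return list with \code{labels} (integer per vertex, NA = unreachable)
#'   and \code{arrival} (numeric per vertex).
#' @export
propagate_labels <- function(g, seeds, h = 1, p = Inf, values = 0) {
  stopifnot(inherits(g, "weighted_graph"))
  if (!is.list(seeds)) {
    sv <- as.integer(seeds)
    if (length(sv) != g$n) stop("seed vector must cover all vertices")
    ids <- sort(unique(sv[!is.na(sv) & sv > 0L]))
    seeds <- lapply(ids, function(l) which(!is.na(sv) & sv == l))
  }
  if (any(lengths(seeds) == 0L)) stop("every label needs at least one seed")
  sv <- unlist(seeds, use.names = FALSE)
  if (anyDuplicated(sv)) stop("seed sets must be disjoint")
  labs <- rep(seq_along(seeds), lengths(seeds))
  vals <- rep_len(as.numeric(values), length(sv))
  hv <- rep_len(as.numeric(h), g$n)
  off <- setdiff(seq_len(g$n), sv)
  if (any(hv[off] <= 0)) stop("'h' must be strictly positive off the seeds")
  res <- .eikonal_run(g, sv, vals, hv, p, labels = labs)
  list(labels = res$labels, arrival = res$u)
}

#' Superpixel decomposition
#'
#' Partitions an image by dilating a regular lattice of seeds with
#' multi-label front propagation (\code{h = 1}) on a photometrically
#' weighted 4-adjacency grid graph: fronts grow fast inside homogeneous
#' regions and slow across contrast edges, so the regions respect image
#' structure. Region count equals seed count and every region contains its
#' seed.
#'
#' @param image \code{H x W} or \code{H x W x C} array.
#' @param spacing seed lattice spacing in pixels (\code{>= 2}, at most the
#'   smaller image side).
#' @param cfg a \code{\link{similarity_config}} for the photometric weights
#'   (default exponential on raw pixel values).
#' @param p norm index, default \code{Inf}.
#' @return list with \code{regions} (\code{H x W} integer matrix),
#'   \code{seeds} (vertex ids), \code{graph}.
#' @export
superpixels <- function(image, spacing, cfg = similarity_config(), p = Inf) {
  arr <- .as_image_array(image)
  H <- dim(arr)[1]; W <- dim(arr)[2]
  spacing <- as.integer(spacing)
  if (spacing < 2L) stop("'spacing' must be >= 2")
  if (spacing > max(H, W)) stop("'spacing' larger than the image")
  rs <- seq.int(min((spacing + 1L) %/% 2L, H), H, by = spacing)
  cs <- seq.int(min((spacing + 1L) %/% 2L, W), W, by = spacing)
  seeds <- as.integer(outer(rs - 1L, cs, function(r, c) r * W + c))
  g <- build_grid_graph(arr, adjacency = 4, cfg = cfg)
  res <- propagate_labels(g, lapply(seeds, identity), h = 1, p = p)
  regions <- matrix(res$labels, H, W, byrow = TRUE)
  list(regions = regions, seeds = seeds, graph = g)
}

#' Semi-supervised classification by label propagation
#'
#' Emulates graph-based classification of feature tables (e.g. cell
#' morphology descriptors): a k-NN similarity graph is built on the feature
#' rows, a stratified fraction of samples is revealed as labeled seeds, and
#' the eikonal fronts (\code{h = 1}) propagate the labels to the rest.
#' Accuracy is measured on the non-seed samples against the held-out truth.
#' Seed sampling uses the current RNG state; set a seed for reproducibility.
#'
#' @param features numeric matrix, one sample per row.
#' @param truth label vector (factor/integer/character) per sample.
#' @param labeled_fraction fraction of samples revealed per class
#'   (default 0.1; at least one seed per class).
#' @param k neighbors for the graph (default 10).
#' @param p norm index for the fronts (default 1).
#' @param cfg a \code{\link{similarity_config}}.
#' @param seeds optional explicit seed indices (overrides sampling).
#' @return list with \code{predicted} (labels per sample), \code{seeds},
#'   \code{accuracy} (overall, on non-seeds), \code{per_class} accuracy,
#'   \code{graph}.
#' @export
classify_semi_supervised <- function(features, truth, labeled_fraction = 0.1,
                                     k = 10, p = 1,
                                     cfg = similarity_config(),
                                     seeds = NULL) {
  X <- as.matrix(features)
  truth <- as.factor(truth)
  if (nrow(X) != length(truth)) stop("one truth label per sample required")
  lev <- levels(truth)
  if (is.null(seeds)) {
    seeds <- unlist(lapply(lev, function(l) {
      idx <- which(truth == l)
      if (length(idx) == 0L) stop("class without samples")
      ns <- max(1L, round(labeled_fraction * length(idx)))
      sort(sample(idx, ns))
    }))
  }
  seeds <- as.integer(seeds)
  if (!all(lev %in% truth[seeds])) stop("every class needs at least one seed")
  g <- build_knn_graph(X, k, cfg)
  seed_list <- lapply(seq_along(lev),
                      function(li) seeds[truth[seeds] == lev[li]])
  res <- propagate_labels(g, seed_list, h = 1, p = p)
  predicted <- factor(lev[res$labels], levels = lev)
  eval_idx <- setdiff(which(!is.na(res$labels)), seeds)
  acc <- mean(predicted[eval_idx] == truth[eval_idx])
  per_class <- vapply(lev, function(l) {
    idx <- eval_idx[truth[eval_idx] == l]
    if (length(idx) == 0L) NA_real_ else mean(predicted[idx] == l)
  }, numeric(1))
  list(predicted = predicted, seeds = seeds, accuracy = acc,
       per_class = per_class, arrival = res$arrival, graph = g)
}
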