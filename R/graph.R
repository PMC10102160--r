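#' Finite weighted graph
#'
#' Constructs a finite, simple, undirected graph with strictly positive,
#' symmetric edge weights. This is the common substrate for every operator and
#' solver in the package: vertices may carry an optional payload (pixel
#' intensities, patch vectors, 3D coordinates, morphological feature rows)
#' that graph builders use to compute similarity weights.
#'
#' Edges are stored once with \code{i < j}; weights below \code{prune} are
#' dropped so that the neighborhood \code{I(x) = {y : w(x,y) > 0}} stays
#' well-defined. Vertices are 1-based.
#'
#' @param n number of vertices (positive integer).
#' @param edges matrix or data.frame with columns \code{i}, \code{j},
#'   \code{w}: one row per undirected edge, \code{w > 0}. May be empty.
#' @param payload optional numeric matrix with \code{n} rows of per-vertex
#'   feature vectors.
#' @param coords optional numeric matrix with \code{n} rows of spatial
#'   coordinates (pixel positions, 3D points).
#' @param prune weights strictly below this threshold are removed
#'   (default \code{1e-12}).
#' @return an object of class \code{weighted_graph} with fields \code{n},
#'   \code{edges} (data.frame \code{i,j,w}), \code{payload}, \code{coords}.
#' @examples
#' g <- weighted_graph(3, cbind(i = c(1, 2), j = c(2, 3), w = c(1, 2)))
#' neighbors(g, 2)
#' @export
weighted_graph <- function(n, edges = NULL, payload = NULL, coords = NULL,
                           prune = 1e-12) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("'n' must be a positive integer")
  if (is.null(edges) || NROW(edges) == 0L) {
    ed <- data.frame(i = integer(), j = integer(), w = numeric())
  } else {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 3L) stop("'edges' needs columns i, j, w")
    names(edges)[1:3] <- c("i", "j", "w")
    i <- as.integer(edges$i); j <- as.integer(edges$j); w <- as.numeric(edges$w)
    if (anyNA(i) || anyNA(j) || anyNA(w)) stop("edges contain NA")
    if (any(i < 1L | i > n | j < 1L | j > n)) stop("edge endpoint out of range")
    if (any(i == j)) stop("self-loops are not allowed")
    if (any(w <= 0)) stop("edge weights must be strictly positive")
    keep <- w >= prune
    i <- i[keep]; j <- j[keep]; w <- w[keep]
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- (lo - 1) * as.double(n) + hi
    if (anyDuplicated(key)) {
      # collapse duplicates, requiring consistent weights (symmetry check)
      ord <- order(key)
      key <- key[ord]; lo <- lo[ord]; hi <- hi[ord]; w <- w[ord]
      grp <- cumsum(!duplicated(key))
      wmin <- tapply(w, grp, min); wmax <- tapply(w, grp, max)
      if (max(wmax - wmin) > 1e-9 * max(1, max(wmax)))
        stop("duplicate edge listed with inconsistent weights")
      first <- !duplicated(key)
      lo <- lo[first]; hi <- hi[first]; w <- as.numeric(wmax)
    }
    ed <- data.frame(i = lo, j = hi, w = w)
  }
  if (!is.null(payload)) {
    payload <- as.matrix(payload)
    storage.mode(payload) <- "double"
    if (nrow(payload) != n) stop("'payload' must have n rows")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    if (nrow(coords) != n) stop("'coords' must have n rows")
  }
  g <- structure(list(n = n, edges = ed, payload = payload, coords = coords),
                 class = "weighted_graph")
  g$cache <- .graph_cache(g)
  g
}

# Per-vertex neighbor tables padded to the maximum degree: nbr (index, pad 1),
# w / sw (weight and sqrt-weight, pad 0). Padding contributes 0 to every
# operator because the padded weight is 0.
.graph_cache <- function(g) {
  n <- g$n; ed <- g$edges
  from <- c(ed$i, ed$j); to <- c(ed$j, ed$i); wd <- c(ed$w, ed$w)
  deg <- tabulate(from, nbins = n)
  D <- max(1L, deg)
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]; wd <- wd[ord]
  slot <- sequence(deg)
  nbr <- matrix(1L, n, D)
  wm <- matrix(0, n, D)
  idx <- cbind(from, slot)
  nbr[idx] <- to
  wm[idx] <- wd
  list(deg = deg, nbr = nbr, w = wm, sw = sqrt(wm), strength = rowSums(wm),
       from = from, to = to, wd = wd,
       off = c(0L, cumsum(deg)))  # adjacency runs in (from,to,wd), CSR-style
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("weighted_graph: %d vertices, %d edges", x$n, nrow(x$edges)))
  if (!is.null(x$payload))
    cat(sprintf(", payload dim %d", ncol(x$payload)))
  if (!is.null(x$coords))
    cat(sprintf(", coords dim %d", ncol(x$coords)))
  cat("\n")
  invisible(x)
}

#' Neighbors of a vertex
#'
#' @param g a \code{weighted_graph}.
#' @param x vertex index.
#' @return integer vector of neighbor indices (possibly empty), sorted.
#' @export
neighbors <- function(g, x) {
  stopifnot(inherits(g, "weighted_graph"))
  x <- as.integer(x)
  if (x < 1L || x > g$n) stop("vertex out of range")
  ca <- g$cache
  if (ca$deg[x] == 0L) return(integer())
  ca$to[(ca$off[x] + 1L):ca$off[x + 1L]]
}

#' Edge weight lookup
#'
#' Returns \code{w(x, y)}, which is 0 when \code{(x, y)} is not an edge.
#' @inheritParams neighbors
#' @param y vertex index.
#' @export
edge_weight <- function(g, x, y) {
  nb <- neighbors(g, x)
  k <- match(as.integer(y), nb)
  if (is.na(k)) return(0)
  ca <- g$cache
  ca$wd[(ca$off[as.integer(x)] + 1L):ca$off[as.integer(x) + 1L]][k]
}

#' Vertex degrees
#' @inheritParams neighbors
#' @export
degrees <- function(g) g$cache$deg

#' Structural validation of a weighted graph
#'
#' Checks the defining invariants: symmetric positive weights on edges and
#' only there, no self-loops or duplicate edges, neighbor queries consistent
#' with the edge set. Intended for tests and for validating graphs read from
#' files.
#'
#' @param g a \code{weighted_graph}.
#' @return \code{TRUE} invisibly; stops with a message on violation.
#' @export
validate_graph <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  ed <- g$edges
  if (nrow(ed)) {
    if (any(ed$i == ed$j)) stop("self-loop present")
    if (any(ed$w <= 0)) stop("non-positive edge weight")
    key <- (pmin(ed$i, ed$j) - 1) * as.double(g$n) + pmax(ed$i, ed$j)
    if (anyDuplicated(key)) stop("duplicate edge")
  }
  # neighbor table symmetric by construction; verify round trip
  for (x in seq_len(min(g$n, 50L))) {
    for (y in neighbors(g, x)) {
      if (!(x %in% neighbors(g, y))) stop("asymmetric adjacency")
      if (abs(edge_weight(g, x, y) - edge_weight(g, y, x)) > 0)
        stop("asymmetric weight")
    }
  }
  invisible(TRUE)
}

#' Connected components
#'
#' @param g a \code{weighted_graph}.
#' @return integer vector of component labels (1-based, by discovery order).
#' @export
graph_components <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  comp <- integer(g$n)
  ca <- g$cache
  cur <- 0L
  for (s in seq_len(g$n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      x <- queue[[1L]]; queue <- queue[-1L]
      if (ca$deg[x] == 0L) next
      nb <- ca$to[(ca$off[x] + 1L):ca$off[x + 1L]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' @rdname graph_components
#' @export
is_connected <- function(g) {
  if (g$n == 1L) return(TRUE)
  all(graph_components(g) == 1L)
}

# --- graph builders ---------------------------------------------------------

#' Grid graph from an image
#'
#' One vertex per pixel of an \code{H x W x C} image (a matrix is treated as
#' single-channel), edges between 4- or 8-adjacent pixels, and weights
#' obtained from the configured similarity on the photometric payload (raw
#' pixel values for \code{patch = 1}, patch vectors for odd \code{patch > 1}).
#' Pixel \code{(r, c)} maps to vertex \code{(r - 1) * W + c}.
#'
#' @param image numeric array \code{H x W} or \code{H x W x C}, values
#'   typically in \code{[0, 1]}.
#' @param adjacency 4 or 8.
#' @param cfg a \code{\link{similarity_config}}; its \code{patch} field
#'   selects the photometric payload (default raw values).
#' @return a \code{weighted_graph} with pixel-value payload (or patch payload)
#'   and \code{(row, col)} coords.
#' @export
build_grid_graph <- function(image, adjacency = 4, cfg = similarity_config()) {
  arr <- .as_image_array(image)
  H <- dim(arr)[1]; W <- dim(arr)[2]
  if (H < 1 || W < 1) stop("empty image")
  n <- H * W
  vid <- function(r, c) (r - 1L) * W + c
  rr <- rep(seq_len(H), each = W)
  cc <- rep(seq_len(W), times = H)
  pairs <- list()
  add <- function(dr, dc) {
    r2 <- rr + dr; c2 <- cc + dc
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    cbind(vid(rr[ok], cc[ok]), vid(r2[ok], c2[ok]))
  }
  pairs[[1]] <- add(0L, 1L)
  pairs[[2]] <- add(1L, 0L)
  if (adjacency == 8) {
    pairs[[3]] <- add(1L, 1L)
    pairs[[4]] <- add(1L, -1L)
  } else if (adjacency != 4) stop("'adjacency' must be 4 or 8")
  pr <- do.call(rbind, pairs)
  np <- if (is.null(cfg$patch)) 1L else cfg$patch
  payload <- if (np > 1L) extract_patches(arr, np) else
    matrix(aperm(arr, c(2, 1, 3)), nrow = n)  # row-major pixel order
  d <- .payload_distance(payload, pr[, 1], pr[, 2], cfg)
  cfg <- .resolve_sigma(cfg, d)
  w <- similarity_weight(d, cfg)
  weighted_graph(n, cbind(i = pr[, 1], j = pr[, 2], w = w),
                 payload = payload, coords = cbind(row = rr, col = cc))
}

#' k-nearest-neighbor graph
#'
#' Connects each sample to its \code{k} nearest neighbors under Euclidean
#' distance on the feature rows; the directed relation is symmetrized by
#' union (an edge exists if either endpoint selects the other) unless
#' \code{mutual = TRUE}, which keeps only mutual selections. Distance ties
#' are broken by sample index.
#'
#' @param features numeric matrix, one sample per row.
#' @param k number of neighbors, \code{1 <= k < nrow(features)}.
#' @param cfg a \code{\link{similarity_config}}.
#' @param mutual symmetrize by intersection instead of union.
#' @return a \code{weighted_graph} with the feature rows as payload.
#' @export
build_knn_graph <- function(features, k, cfg = similarity_config(),
                            mutual = FALSE) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  m <- nrow(X)
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be positive")
  if (k >= m) stop("'k' must be smaller than the number of samples")
  D <- as.matrix(stats::dist(X))
  sel <- matrix(0L, m, k)
  for (x in seq_len(m)) {
    o <- order(D[x, ])          # stable: ties by index
    o <- o[o != x]
    sel[x, ] <- o[seq_len(k)]
  }
  i <- rep(seq_len(m), each = k)
  j <- as.integer(t(sel))
  if (mutual) {
    key <- paste(pmin(i, j), pmax(i, j))
    keep <- key %in% key[duplicated(key)]
    i <- i[keep]; j <- j[keep]
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  dup <- duplicated((lo - 1) * as.double(m) + hi)
  lo <- lo[!dup]; hi <- hi[!dup]
  d <- .payload_distance(X, lo, hi, cfg)
  cfg <- .resolve_sigma(cfg, d)
  w <- similarity_weight(d, cfg)
  weighted_graph(m, cbind(i = lo, j = hi, w = w), payload = X)
}

#' Epsilon-neighborhood graph
#'
#' Connects two samples whenever their Euclidean payload distance is at most
#' \code{eps}. With constant weights this is the Euclidean graph used to
#' relate the game operators to their lattice counterparts.
#'
#' @inheritParams build_knn_graph
#' @param eps positive radius.
#' @return a \code{weighted_graph} (possibly disconnected; solvers validate
#'   connectivity themselves).
#' @export
build_epsilon_graph <- function(features, eps, cfg = similarity_config()) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("'eps' must be a positive scalar")
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  m <- nrow(X)
  D <- as.matrix(stats::dist(X))
  idx <- which(upper.tri(D) & D <= eps, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(weighted_graph(m, NULL, payload = X))
  d <- .payload_distance(X, idx[, 1], idx[, 2], cfg)
  cfg <- .resolve_sigma(cfg, d)
  w <- similarity_weight(d, cfg)
  weighted_graph(m, cbind(i = idx[, 1], j = idx[, 2], w = w), payload = X)
}

#' Region adjacency graph
#'
#' Collapses a base graph to one vertex per region of a partition: regions
#' are adjacent iff some pair of their members is adjacent in the base graph.
#' Region payloads are the means of member payloads and weights come from the
#' configured similarity on those means.
#'
#' @param region_map integer vector over base vertices; must cover every
#'   vertex (a partition).
#' @param base the base \code{weighted_graph} (payload required for
#'   similarity weighting).
#' @param cfg a \code{\link{similarity_config}}.
#' @return a \code{weighted_graph} over regions; region ids are the sorted
#'   unique values of \code{region_map}.
#' @export
build_rag <- function(region_map, base, cfg = similarity_config()) {
  stopifnot(inherits(base, "weighted_graph"))
  region_map <- as.integer(region_map)
  if (length(region_map) != base$n || anyNA(region_map))
    stop("'region_map' must assign a region to every vertex")
  ids <- sort(unique(region_map))
  R <- length(ids)
  rid <- match(region_map, ids)
  payload <- NULL
  if (!is.null(base$payload))
    payload <- apply(base$payload, 2, function(col) tapply(col, rid, mean))
  if (!is.null(payload)) payload <- matrix(payload, nrow = R)
  ed <- base$edges
  ri <- rid[ed$i]; rj <- rid[ed$j]
  cross <- ri != rj
  if (!any(cross))
    return(weighted_graph(R, NULL, payload = payload))
  lo <- pmin(ri[cross], rj[cross]); hi <- pmax(ri[cross], rj[cross])
  dup <- duplicated((lo - 1) * as.double(R) + hi)
  lo <- lo[!dup]; hi <- hi[!dup]
  if (is.null(payload)) {
    w <- rep(1, length(lo))
  } else {
    d <- .payload_distance(payload, lo, hi, cfg)
    cfg <- .resolve_sigma(cfg, d)
    w <- similarity_weight(d, cfg)
  }
  weighted_graph(R, cbind(i = lo, j = hi, w = w), payload = payload)
}

#' Extend a region graph with k-NN edges on region means
#'
#' Adds to an existing graph (typically a RAG) the k-nearest-neighbor edges
#' computed on the vertex payloads (region mean colors/features), letting
#' labels propagate beyond spatial adjacency. Existing edges are kept; new
#' edges get similarity weights on the payload distance.
#'
#' @param graph a \code{weighted_graph} with payload.
#' @param k number of nearest neighbors to add; \code{k = 0} returns the
#'   graph unchanged.
#' @param cfg a \code{\link{similarity_config}}.
#' @export
knn_extend <- function(graph, k, cfg = similarity_config()) {
  stopifnot(inherits(graph, "weighted_graph"))
  k <- as.integer(k)
  if (k == 0L) return(graph)
  if (is.null(graph$payload)) stop("payload required for k-NN extension")
  if (k >= graph$n) stop("'k' must be smaller than the vertex count")
  kg <- build_knn_graph(graph$payload, k, cfg)
  ed <- rbind(graph$edges, kg$edges)
  key <- (pmin(ed$i, ed$j) - 1) * as.double(graph$n) + pmax(ed$i, ed$j)
  ed <- ed[!duplicated(key), ]
  weighted_graph(graph$n, ed, payload = graph$payload, coords = graph$coords)
}

.as_image_array <- function(image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("'image' must be an H x W or H x W x C numeric array")
  storage.mode(image) <- "double"
  image
}
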