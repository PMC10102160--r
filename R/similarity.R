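#' Similarity configuration
#'
#' Describes how edge weights are derived from payload distances. Three
#' similarity maps are supported: \code{constant} (\code{s = 1}, purely
#' geometric graphs), \code{exponential} (\code{s = exp(-d / sigma^2)}) and
#' \code{inverse} (\code{s = 1 / (d + 1)}). The scale \code{sigma} may be a
#' global scalar or left \code{NULL}, in which case builders estimate it as
#' the mean nonzero distance among the candidate edges.
#'
#' @param kind one of \code{"exponential"}, \code{"constant"},
#'   \code{"inverse"}.
#' @param sigma positive scale for the exponential map, or \code{NULL} for
#'   automatic estimation.
#' @param patch odd patch side length for photometric image weighting
#'   (\code{NULL} or 1 uses raw pixel values).
#' @param distance \code{"euclidean"} or \code{"sqeuclidean"} on payload
#'   vectors.
#' @return an object of class \code{similarity_config}.
#' @export
similarity_config <- function(kind = c("exponential", "constant", "inverse"),
                              sigma = NULL, patch = NULL,
                              distance = c("euclidean", "sqeuclidean")) {
  kind <- match.arg(kind)
  distance <- match.arg(distance)
  if (!is.null(sigma)) {
    if (!is.numeric(sigma) || any(sigma <= 0)) stop("'sigma' must be positive")
  }
  if (!is.null(patch)) {
    patch <- as.integer(patch)
    if (patch < 1L || patch %% 2L == 0L) stop("'patch' must be odd and >= 1")
  }
  structure(list(kind = kind, sigma = sigma, patch = patch,
                 distance = distance),
            class = "similarity_config")
}

#' Similarity weight of a payload distance
#'
#' Maps a nonnegative distance to an edge weight in \code{(0, 1]}:
#' 1 for \code{constant}, \code{exp(-d / sigma^2)} for \code{exponential},
#' \code{1 / (d + 1)} for \code{inverse}. Similar vertices get weights near
#' 1, dissimilar ones near 0.
#'
#' @param d nonnegative distance (vectorized).
#' @param cfg a \code{\link{similarity_config}} with \code{sigma} set when
#'   \code{kind = "exponential"}.
#' @return numeric vector of weights in \code{(0, 1]}.
#' @export
similarity_weight <- function(d, cfg = similarity_config()) {
  if (any(d < 0)) stop("distance must be nonnegative")
  switch(cfg$kind,
    constant = rep(1, length(d)),
    exponential = {
      if (is.null(cfg$sigma)) stop("'sigma' required for exponential kind")
      exp(-d / cfg$sigma^2)
    },
    inverse = 1 / (d + 1)
  )
}

#' Patch vectors of an image
#'
#' For each pixel, the values of the \code{n x n} window centred at it,
#' concatenated in row-major window order (channels innermost). Borders use
#' replicate padding. Rows are in row-major pixel order, matching the vertex
#' numbering of \code{\link{build_grid_graph}}.
#'
#' @param image \code{H x W} matrix or \code{H x W x C} array.
#' @param n odd window side length.
#' @return numeric matrix \code{(H * W) x (n^2 * C)}.
#' @export
extract_patches <- function(image, n) {
  arr <- .as_image_array(image)
  n <- as.integer(n)
  if (n < 1L || n %% 2L == 0L) stop("'n' must be odd and >= 1")
  H <- dim(arr)[1]; W <- dim(arr)[2]; C <- dim(arr)[3]
  half <- (n - 1L) %/% 2L
  out <- matrix(0, H * W, n * n * C)
  rows <- rep(seq_len(H), each = W)   # row-major pixel order
  cols <- rep(seq_len(W), times = H)
  col0 <- 0L
  for (dr in seq.int(-half, half)) {
    for (dc in seq.int(-half, half)) {
      r2 <- pmin(pmax(rows + dr, 1L), H)   # replicate padding
      c2 <- pmin(pmax(cols + dc, 1L), W)
      for (ch in seq_len(C)) {
        out[, col0 + ch] <- arr[cbind(r2, c2, ch)]
      }
      col0 <- col0 + C
    }
  }
  out
}

# Distance between payload rows i and j under cfg$distance.
.payload_distance <- function(payload, i, j, cfg) {
  if (is.null(payload)) return(rep(0, length(i)))
  di <- payload[i, , drop = FALSE] - payload[j, , drop = FALSE]
  d2 <- rowSums(di * di)
  if (cfg$distance == "sqeuclidean") d2 else sqrt(d2)
}

# Global sigma default: mean nonzero distance among candidate edges.
.resolve_sigma <- function(cfg, d) {
  if (cfg$kind != "exponential" || !is.null(cfg$sigma)) return(cfg)
  pos <- d[d > 0]
  cfg$sigma <- if (length(pos)) sqrt(mean(pos)) else 1
  cfg
}
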