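#' Synthetic fixture configuration
#'
#' Declares a reproducible synthetic data set: piecewise-constant or
#' textured images with optional missing regions, colored point clouds with
#' scribbles, or multi-class Gaussian feature clouds emulating tabulated
#' cell-morphology descriptors. Every fixture is a pure function of its
#' configuration; the seed is mandatory so regeneration is bit-identical.
#'
#' @param kind one of \code{"ramp_image"}, \code{"two_tone_image"},
#'   \code{"textured_image"}, \code{"holed_image"},
#'   \code{"point_cloud_clusters"}, \code{"blob_features"}.
#' @param seed RNG seed (mandatory).
#' @param dim image dimensions \code{c(H, W)} (images) or sample count
#'   (features/clouds).
#' @param noise additive Gaussian noise sd on image intensities or feature
#'   jitter (default 0).
#' @param classes number of classes/primitives (default 4 for features,
#'   2 for clouds).
#' @param separation ratio of inter-centroid distance to within-class sd
#'   for \code{blob_features} (default 6) and cluster gap scale for point
#'   clouds.
#' @param hole integer vector \code{c(h, w)}: size of the centered masked
#'   region for \code{holed_image}/\code{two_tone_image} (default none).
#' @param features feature dimension for \code{blob_features} (default 10).
#' @return an object of class \code{fixture_config}.
#' @export
fixture_config <- function(kind = c("ramp_image", "two_tone_image",
                                    "textured_image", "holed_image",
                                    "point_cloud_clusters", "blob_features"),
                           seed, dim = c(16L, 16L), noise = 0,
                           classes = NULL, separation = 6, hole = NULL,
                           features = 10L) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("'seed' is mandatory")
  if (separation <= 0) stop("'separation' must be positive")
  if (is.null(classes))
    classes <- if (kind == "blob_features") 4L else 2L
  structure(list(kind = kind, seed = as.integer(seed), dim = dim,
                 noise = noise, classes = as.integer(classes),
                 separation = separation, hole = hole,
                 features = as.integer(features)),
            class = "fixture_config")
}

#' Generate a synthetic test image
#'
#' Deterministic per seed. \code{ramp_image}: horizontal linear ramp.
#' \code{two_tone_image}: vertical split between two tones.
#' \code{textured_image}: sinusoidal texture plus noise.
#' \code{holed_image}: two-tone image with a centered rectangular mask of
#' removed pixels. The complete image is always returned as ground truth,
#' alongside the mask of removed pixels (empty when no hole is requested).
#'
#' @param cfg a \code{\link{fixture_config}} with an image kind.
#' @return list with \code{image} (hole pixels zeroed), \code{mask}
#'   (logical \code{H x W}), \code{truth} (complete image).
#' @export
generate_test_image <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(cfg$seed)
  H <- as.integer(cfg$dim[1]); W <- as.integer(cfg$dim[2])
  img <- switch(cfg$kind,
    ramp_image = matrix(rep((seq_len(W) - 1) / max(1, W - 1), each = H), H, W),
    two_tone_image = ,
    holed_image = {
      m <- matrix(0.2, H, W)
      m[, seq_len(W) > W / 2] <- 0.8
      m
    },
    textured_image = {
      r <- matrix(seq_len(H), H, W); c <- matrix(seq_len(W), H, W, byrow = TRUE)
      0.5 + 0.25 * sin(2 * pi * r / 5) * cos(2 * pi * c / 7)
    },
    stop("'", cfg$kind, "' is not an image kind"))
  if (cfg$noise > 0)
    img <- pmin(pmax(img + matrix(stats::rnorm(H * W, sd = cfg$noise), H, W),
                     0), 1)
  mask <- matrix(FALSE, H, W)
  hole <- cfg$hole
  if (is.null(hole) && cfg$kind == "holed_image") hole <- c(4L, 4L)
  if (!is.null(hole)) {
    hh <- as.integer(hole[1]); hw <- as.integer(hole[2])
    r0 <- (H - hh) %/% 2L; c0 <- (W - hw) %/% 2L
    mask[r0 + seq_len(hh), c0 + seq_len(hw)] <- TRUE
  }
  out <- img
  out[mask] <- 0
  list(image = out, mask = mask, truth = img)
}

#' Generate Gaussian blob features
#'
#' \code{n} samples in \code{d} dimensions from \code{c} isotropic Gaussian
#' classes with unit within-class sd; class centroids are drawn per seed and
#' rescaled so the minimum inter-centroid distance equals
#' \code{separation}. Defaults (\code{n = 400, d = 10, c = 4}) mirror a
#' small multi-class cytology-style feature table.
#'
#' @param cfg a \code{\link{fixture_config}} with kind
#'   \code{"blob_features"}; \code{dim} is the sample count.
#' @return list with \code{features} (\code{n x d} matrix) and \code{labels}
#'   (integer vector).
#' @export
generate_blob_features <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(cfg$seed)
  n <- as.integer(cfg$dim[1])
  if (is.na(n) || n < cfg$classes) n <- 400L
  d <- cfg$features
  c <- cfg$classes
  centroids <- matrix(stats::rnorm(c * d), c, d)
  if (c > 1L) {
    dmin <- min(stats::dist(centroids))
    centroids <- centroids * (cfg$separation / dmin)
  }
  labels <- rep(seq_len(c), length.out = n)
  X <- centroids[labels, , drop = FALSE] + matrix(stats::rnorm(n * d), n, d)
  if (cfg$noise > 0) X <- X + matrix(stats::rnorm(n * d, sd = cfg$noise), n, d)
  list(features = X, labels = labels)
}

#' Generate a colored point cloud with scribbles
#'
#' Two geometric primitives -- a plane patch and a sphere above it -- each
#' with a flat color and one scribbled vertex, emulating the inputs of
#' scribble-based 3D colorization.
#'
#' @param cfg a \code{\link{fixture_config}} with kind
#'   \code{"point_cloud_clusters"}; \code{dim} is the points-per-primitive
#'   count.
#' @return list with \code{coords} (\code{n x 3}), \code{colors}
#'   (\code{n x 3} truth), \code{scribbles} (one vertex per primitive),
#'   \code{primitive} (integer per point).
#' @export
generate_point_cloud <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(cfg$seed)
  m <- as.integer(cfg$dim[1])
  if (is.na(m) || m < 4L) m <- 100L
  plane <- cbind(stats::runif(m), stats::runif(m), 0)
  th <- stats::runif(m, 0, 2 * pi); ph <- acos(stats::runif(m, -1, 1))
  r <- 0.3
  sphere <- cbind(0.5 + r * sin(ph) * cos(th),
                  0.5 + r * sin(ph) * sin(th),
                  cfg$separation / 2 + r * cos(ph))
  coords <- rbind(plane, sphere)
  if (cfg$noise > 0)
    coords <- coords + matrix(stats::rnorm(6 * m, sd = cfg$noise), 2 * m)
  cols <- rbind(matrix(rep(c(0.9, 0.2, 0.1), each = m), m),
                matrix(rep(c(0.1, 0.3, 0.9), each = m), m))
  list(coords = coords, colors = cols,
       scribbles = c(1L, m + 1L),
       primitive = rep(1:2, each = m))
}
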