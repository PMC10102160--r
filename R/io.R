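#' Image I/O
#'
#' Reads/writes PNG and TIFF raster images, mapping channels to doubles in
#' \code{[0, 1]}. Single-channel files come back as \code{H x W} matrices,
#' multi-channel ones as \code{H x W x C} arrays. Masks are ordinary
#' single-channel images where nonzero marks selected pixels.
#'
#' @param path file path; format chosen by extension (.png, .tif, .tiff).
#' @return numeric matrix or array.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension: ", ext))
  img
}

#' @rdname load_image
#' @param image numeric matrix or array with values in \code{[0, 1]}
#'   (clamped on write).
#' @export
save_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(image, 0), 1)
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path),
    stop("unsupported image extension: ", ext))
  invisible(path)
}

#' Colored point cloud I/O
#'
#' Supports ASCII PLY (properties x, y, z, red, green, blue) and plain
#' whitespace XYZRGB text (six columns). Colors are bytes 0--255 in the
#' files and doubles in \code{[0, 1]} in memory.
#'
#' @param path file path (.ply or anything else = XYZRGB text).
#' @return list with \code{coords} (\code{n x 3}) and \code{colors}
#'   (\code{n x 3} in \code{[0, 1]}, or NULL when absent).
#' @export
load_pointcloud <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (tolower(tools::file_ext(path)) == "ply") return(.read_ply(path))
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) < 3L) stop("XYZ file needs at least 3 columns: ", path)
  coords <- as.matrix(tab[, 1:3])
  colors <- if (ncol(tab) >= 6L) as.matrix(tab[, 4:6]) / 255 else NULL
  list(coords = coords, colors = colors)
}

#' @rdname load_pointcloud
#' @param cloud list with \code{coords} and optional \code{colors}.
#' @export
save_pointcloud <- function(cloud, path) {
  coords <- as.matrix(cloud$coords)
  colors <- cloud$colors
  if (tolower(tools::file_ext(path)) == "ply") {
    n <- nrow(coords)
    hdr <- c("ply", "format ascii 1.0", sprintf("element vertex %d", n),
             "property float x", "property float y", "property float z")
    if (!is.null(colors))
      hdr <- c(hdr, "property uchar red", "property uchar green",
               "property uchar blue")
    hdr <- c(hdr, "end_header")
    body <- if (is.null(colors)) {
      apply(coords, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))
    } else {
      rgb <- round(pmin(pmax(colors, 0), 1) * 255)
      sapply(seq_len(n), function(i)
        paste(c(format(coords[i, ], trim = TRUE), rgb[i, ]), collapse = " "))
    }
    writeLines(c(hdr, body), path)
  } else {
    rgb <- if (is.null(colors)) NULL else round(pmin(pmax(colors, 0), 1) * 255)
    tab <- if (is.null(rgb)) coords else cbind(coords, rgb)
    utils::write.table(tab, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

.read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || trimws(lines[1]) != "ply")
    stop("not a PLY file (missing 'ply' magic at line 1): ", path)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header without end_header: ", path)
  hdr <- trimws(lines[seq_len(end)])
  if (!any(grepl("^format ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  vline <- grep("^element vertex", hdr, value = TRUE)
  if (length(vline) != 1L) stop("PLY: missing 'element vertex' line: ", path)
  n <- as.integer(sub("^element vertex\\s+", "", vline))
  props <- sub("^property\\s+\\S+\\s+", "", grep("^property", hdr, value = TRUE))
  need <- c("x", "y", "z")
  if (!all(need %in% props)) stop("PLY: x/y/z properties required: ", path)
  body <- lines[(end + 1L):(end + n)]
  tab <- utils::read.table(text = body, header = FALSE)
  if (ncol(tab) != length(props))
    stop(sprintf("PLY: %d properties declared but %d columns at line %d",
                 length(props), ncol(tab), end + 1L))
  colnames(tab) <- props
  coords <- as.matrix(tab[, need])
  colors <- NULL
  if (all(c("red", "green", "blue") %in% props))
    colors <- as.matrix(tab[, c("red", "green", "blue")]) / 255
  list(coords = coords, colors = colors)
}

#' Feature table and seed CSV I/O
#'
#' \code{load_features} reads a CSV with a header row, one sample per row;
#' non-numeric columns (e.g. a label column) are returned separately.
#' \code{load_seeds} reads a two-column CSV \code{vertex,label} (1-based
#' vertex ids).
#'
#' @param path CSV path.
#' @return \code{load_features}: list with \code{features} (numeric matrix)
#'   and \code{extra} (data.frame of non-numeric columns, possibly empty).
#' @export
load_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  num <- vapply(tab, is.numeric, logical(1))
  list(features = as.matrix(tab[, num, drop = FALSE]),
       extra = tab[, !num, drop = FALSE])
}

#' @rdname load_features
#' @export
load_seeds <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("vertex", "label") %in% names(tab)))
    stop("seed CSV needs columns 'vertex' and 'label': ", path)
  tab
}

#' Edge-list CSV I/O
#'
#' Undirected edge lists \code{x,y,w} with each edge listed once and 1-based
#' vertex ids; weights must be strictly positive.
#'
#' @param path CSV path with header \code{x,y,w}.
#' @param n vertex count (default: the largest endpoint).
#' @return a \code{weighted_graph}.
#' @export
load_edgelist <- function(path, n = NULL) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 3L) stop("edge list needs columns x, y, w: ", path)
  names(tab)[1:3] <- c("x", "y", "w")
  bad <- which(!is.finite(tab$w) | tab$w <= 0)
  if (length(bad))
    stop(sprintf("non-positive weight at data line %d of %s", bad[1], path))
  if (is.null(n)) n <- max(tab$x, tab$y)
  weighted_graph(n, cbind(i = tab$x, j = tab$y, w = tab$w))
}

#' @rdname load_edgelist
#' @param g a \code{weighted_graph}.
#' @export
save_edgelist <- function(g, path) {
  stopifnot(inherits(g, "weighted_graph"))
  ed <- g$edges
  utils::write.csv(data.frame(x = ed$i, y = ed$j, w = ed$w), path,
                   row.names = FALSE)
  invisible(path)
}
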