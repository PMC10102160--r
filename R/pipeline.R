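#' Run an end-to-end pipeline
#'
#' Dispatches one of the application pipelines on files or generated
#' fixtures and writes its artifacts plus a JSON run manifest (config hash,
#' package version, seed, solver report) next to them. All pipelines are
#' pure functions of (config, seed): repeated runs produce identical
#' artifacts.
#'
#' Commands and their main config fields:
#' \describe{
#'   \item{inpaint}{\code{image}, \code{mask} (paths) or \code{fixture};
#'     \code{alpha,beta,gamma}, \code{patch}, \code{sigma}, \code{tol}.}
#'   \item{colorize}{\code{input} (PLY/XYZ) + \code{scribbles} (CSV
#'     \code{vertex,label} ignored; colors read from the cloud) or
#'     \code{fixture}; \code{knn}.}
#'   \item{superpixels}{\code{image} or \code{fixture}; \code{spacing}.}
#'   \item{segment}{\code{image}, \code{seeds} (CSV \code{vertex,label});
#'     \code{p}.}
#'   \item{cluster}{\code{features} (CSV) + \code{labels} column/CSV or
#'     \code{fixture}; \code{knn}, \code{p}, \code{labeled_fraction}.}
#'   \item{solve-eikonal}{\code{graph} (edge-list CSV), \code{seeds};
#'     \code{p}.}
#'   \item{simulate}{\code{graph}, \code{boundary} (CSV
#'     \code{vertex,value}), \code{alpha,beta,gamma}, \code{start},
#'     \code{n}, \code{seed}.}
#'   \item{generate}{\code{fixture} kind + fields of
#'     \code{\link{fixture_config}}.}
#'   \item{demo}{runs every pipeline on generated fixtures.}
#' }
#'
#' @param command pipeline name (see above).
#' @param config named list of options; must include \code{seed} where
#'   randomness is involved and may include \code{out} (output directory,
#'   default \code{tempdir()}).
#' @return list of in-memory results; artifacts and \code{manifest.json}
#'   are written under \code{config$out}.
#' @export
run_pipeline <- function(command, config = list()) {
  out_dir <- config[["out"]]  %||% tempdir()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config[["seed"]] %||% 1L)
  res <- switch(command,
    inpaint = .pl_inpaint(config, out_dir, seed),
    colorize = .pl_colorize(config, out_dir, seed),
    superpixels = .pl_superpixels(config, out_dir, seed),
    segment = .pl_segment(config, out_dir, seed),
    cluster = .pl_cluster(config, out_dir, seed),
    `solve-eikonal` = .pl_eikonal(config, out_dir, seed),
    simulate = .pl_simulate(config, out_dir, seed),
    generate = .pl_generate(config, out_dir, seed),
    demo = .pl_demo(config, out_dir, seed),
    stop("unknown command: ", command)
  )
  manifest <- list(
    command = command,
    config = config[setdiff(names(config), "out")],
    config_hash = config_hash(config[setdiff(names(config), "out")]),
    package_version = as.character(utils::packageVersion("graphtow")),
    seed = seed,
    report = res$report_summary %||% NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(res)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialization; changes iff the configuration
#' changes.
#' @param config named list.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  ord <- config[order(names(config))]
  jsonlite::write_json(ord, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.report_summary <- function(rep) {
  if (is.null(rep)) return(NULL)
  list(iterations = rep$iterations, update_norm = rep$update_norm,
       residual = rep$residual, converged = rep$converged)
}

.pl_params <- function(config) {
  if (!is.null(config$p)) return(game_params(p = as.numeric(config$p)))
  game_params(config$alpha %||% 1, config$beta %||% 1, config$gamma %||% 0)
}

.pl_inpaint <- function(config, out_dir, seed) {
  if (!is.null(config$image)) {
    img <- load_image(config$image)
    mask <- load_image(config$mask) != 0
    if (length(dim(mask)) == 3L) mask <- mask[, , 1]
  } else {
    fx <- generate_test_image(fixture_config("holed_image", seed = seed,
                                             dim = config$dim %||% c(16, 16),
                                             hole = config$hole %||% c(4, 4)))
    img <- fx$image; mask <- fx$mask
  }
  sigma <- config$sigma
  if (identical(sigma, "auto")) sigma <- NULL
  cfg <- similarity_config(patch = config$patch %||% 3, sigma = sigma)
  res <- inpaint(img, mask, params = .pl_params(config), cfg = cfg,
                 tol = config$tol %||% 1e-6)
  save_image(res$image, file.path(out_dir, "inpainted.png"))
  res$report_summary <- .report_summary(res$report)
  res
}

.pl_colorize <- function(config, out_dir, seed) {
  if (!is.null(config$input)) {
    cloud <- load_pointcloud(config$input)
    sc <- load_seeds(config$scribbles)$vertex
    cols <- cloud$colors[sc, , drop = FALSE]
    payload <- cloud$coords
  } else {
    fx <- generate_point_cloud(fixture_config("point_cloud_clusters",
                                              seed = seed,
                                              dim = config$dim %||% 100,
                                              separation =
                                                config$separation %||% 6))
    payload <- fx$coords
    sc <- fx$scribbles
    cols <- fx$colors[sc, , drop = FALSE]
    cloud <- list(coords = fx$coords)
  }
  res <- colorize(payload, sc, cols, k = config$knn %||% 10,
                  params = .pl_params(config), tol = config$tol %||% 1e-6)
  save_pointcloud(list(coords = cloud$coords, colors = res$colors),
                  file.path(out_dir, "colorized.ply"))
  res$report_summary <- .report_summary(res$report)
  res
}

.pl_superpixels <- function(config, out_dir, seed) {
  img <- if (!is.null(config$image)) load_image(config$image) else
    generate_test_image(fixture_config("two_tone_image", seed = seed,
                                       dim = config$dim %||% c(24, 24)))$image
  res <- superpixels(img, spacing = config$spacing %||% 8)
  save_label_image(res$regions, file.path(out_dir, "regions.png"))
  utils::write.csv(data.frame(vertex = seq_along(t(res$regions)),
                              label = as.integer(t(res$regions))),
                   file.path(out_dir, "regions.csv"), row.names = FALSE)
  res
}

.pl_segment <- function(config, out_dir, seed) {
  img <- load_image(config$image)
  sd <- load_seeds(config$seeds)
  arr <- .as_image_array(img)
  g <- build_grid_graph(arr, adjacency = 4, similarity_config())
  labs <- sort(unique(sd$label))
  seed_list <- lapply(labs, function(l) sd$vertex[sd$label == l])
  res <- propagate_labels(g, seed_list, h = 1,
                          p = .parse_p(config$p %||% Inf))
  H <- dim(arr)[1]; W <- dim(arr)[2]
  regions <- matrix(res$labels, H, W, byrow = TRUE)
  save_label_image(regions, file.path(out_dir, "labels.png"))
  utils::write.csv(data.frame(vertex = seq_len(H * W),
                              label = res$labels),
                   file.path(out_dir, "labels.csv"), row.names = FALSE)
  list(regions = regions, arrival = res$arrival)
}

.pl_cluster <- function(config, out_dir, seed) {
  if (!is.null(config$features)) {
    ft <- load_features(config$features)
    X <- ft$features
    truth <- if (ncol(ft$extra)) ft$extra[[1]] else
      stop("feature CSV needs a label column for evaluation")
  } else {
    fx <- generate_blob_features(fixture_config("blob_features", seed = seed,
                                                dim = config$n %||% 400))
    X <- fx$features; truth <- fx$labels
  }
  set.seed(seed)
  res <- classify_semi_supervised(
    X, truth, labeled_fraction = config$labeled_fraction %||% 0.1,
    k = config$knn %||% 10, p = .parse_p(config$p %||% 1))
  utils::write.csv(data.frame(sample = seq_along(res$predicted),
                              predicted = res$predicted),
                   file.path(out_dir, "pred.csv"), row.names = FALSE)
  res
}

.pl_eikonal <- function(config, out_dir, seed) {
  g <- load_edgelist(config$graph)
  sd <- load_seeds(config$seeds)
  spec <- eikonal_spec(g, sd$vertex, h = config$h %||% 1,
                       p = .parse_p(config$p %||% Inf))
  u <- solve_eikonal(spec)
  utils::write.csv(data.frame(vertex = seq_len(g$n), value = u),
                   file.path(out_dir, "arrival.csv"), row.names = FALSE)
  list(arrival = u)
}

.pl_simulate <- function(config, out_dir, seed) {
  g <- load_edgelist(config$graph)
  bd <- utils::read.csv(config$boundary)
  spec <- game_spec(g, bd$vertex, bd$value, .pl_params(config),
                    h = config$h %||% 0, seed = seed)
  est <- simulate_game(spec, start = config$start,
                       n_playouts = config$n %||% 1e4)
  jsonlite::write_json(list(mean = est$mean, se = est$se, n = est$n,
                            capped = est$capped, seed = est$seed),
                       file.path(out_dir, "estimate.json"),
                       auto_unbox = TRUE, digits = NA)
  est
}

.pl_generate <- function(config, out_dir, seed) {
  kind <- config$fixture %||% "holed_image"
  cfg <- fixture_config(kind, seed = seed,
                        dim = config$dim %||% c(16, 16),
                        noise = config$noise %||% 0,
                        separation = config$separation %||% 6)
  if (kind == "blob_features") {
    fx <- generate_blob_features(cfg)
    utils::write.csv(data.frame(fx$features, label = fx$labels),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
  } else if (kind == "point_cloud_clusters") {
    fx <- generate_point_cloud(cfg)
    save_pointcloud(list(coords = fx$coords, colors = fx$colors),
                    file.path(out_dir, "cloud.ply"))
    utils::write.csv(data.frame(vertex = fx$scribbles,
                                label = seq_along(fx$scribbles)),
                     file.path(out_dir, "scribbles.csv"), row.names = FALSE)
  } else {
    fx <- generate_test_image(cfg)
    save_image(fx$image, file.path(out_dir, "image.png"))
    save_image(fx$mask * 1, file.path(out_dir, "mask.png"))
    save_image(fx$truth, file.path(out_dir, "truth.png"))
  }
  fx
}

.pl_demo <- function(config, out_dir, seed) {
  sub <- function(cmd, cfg) {
    cfg$seed <- seed
    cfg$out <- file.path(out_dir, cmd)
    run_pipeline(cmd, cfg)
  }
  list(
    inpaint = sub("inpaint", list()),
    colorize = sub("colorize", list(dim = 60)),
    superpixels = sub("superpixels", list(dim = c(24, 24), spacing = 8)),
    cluster = sub("cluster", list(n = 200))
  )
}

.parse_p <- function(p) {
  if (is.character(p)) p <- if (tolower(p) %in% c("inf", "infinity")) Inf
                            else as.numeric(p)
  p
}

#' Write a label map as an indexed-color PNG
#'
#' Labels 1..K are mapped to a fixed qualitative palette (up to 255
#' labels); NA becomes black.
#'
#' @param regions integer matrix of labels.
#' @param path output PNG path.
#' @export
save_label_image <- function(regions, path) {
  K <- max(regions, na.rm = TRUE)
  pal <- grDevices::hcl.colors(max(K, 2L), "Dark 3")
  rgb <- grDevices::col2rgb(pal) / 255
  H <- nrow(regions); W <- ncol(regions)
  out <- array(0, c(H, W, 3))
  idx <- regions
  idx[is.na(idx)] <- 0L
  for (ch in 1:3) {
    plane <- matrix(0, H, W)
    sel <- idx > 0L
    plane[sel] <- rgb[ch, idx[sel]]
    out[, , ch] <- plane
  }
  save_image(out, path)
}
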