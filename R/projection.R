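#' Channel tags
#'
#' A channel is `"<plane>_<statistic>"`, e.g. `"axial_mean"`. Planes are
#' `axial`, `coronal`, `sagittal`; statistics are `mean`, `std` (the six
#' standard channels) plus the optional `skew` and `kurtosis` extensions.
#' The canonical ordering is planes in (axial, coronal, sagittal) order and
#' statistics in (mean, std, skew, kurtosis) order; dataset packing always
#' stores channels in this order.
#'
#' @param planes,statistics subsets of the planes/statistics to cross.
#' @return character vector of channel tags in canonical order.
#' @export
channel_tags <- function(planes = c("axial", "coronal", "sagittal"),
                         statistics = c("mean", "std")) {
  planes <- match.arg(planes, c("axial", "coronal", "sagittal"), several.ok = TRUE)
  statistics <- match.arg(statistics, c("mean", "std", "skew", "kurtosis"),
                          several.ok = TRUE)
  tags <- as.vector(t(outer(planes, statistics, paste, sep = "_")))
  order_channels(tags)
}

all_planes <- c("axial", "coronal", "sagittal")
all_statistics <- c("mean", "std", "skew", "kurtosis")

parse_channel <- function(tag) {
  parts <- strsplit(tag, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !(parts[1] %in% all_planes) ||
      !(parts[2] %in% all_statistics))
    stop("invalid channel tag: '", tag, "'")
  list(plane = parts[1], statistic = parts[2])
}

order_channels <- function(tags) {
  tags <- unique(tags)
  for (t in tags) parse_channel(t)
  key <- vapply(tags, function(t) {
    p <- parse_channel(t)
    match(p$plane, all_planes) * 10L + match(p$statistic, all_statistics)
  }, integer(1))
  tags[order(key)]
}

# axis collapsed by each plane's projection
plane_axis <- c(axial = 3L, coronal = 2L, sagittal = 1L)

reduce_mean_axis <- function(a, axis) {
  switch(axis,
         colMeans(a, dims = 1L),                      # axis 1 -> (d2, d3)
         rowMeans(aperm(a, c(1L, 3L, 2L)), dims = 2L), # axis 2 -> (d1, d3)
         rowMeans(a, dims = 2L))                      # axis 3 -> (d1, d2)
}

#' Project a 3D volume into 2D moment images
#'
#' Each requested channel collapses the volume along its plane's normal
#' axis over the full (padded) extent, computing a per-pixel statistic
#' across slices: arithmetic mean, population standard deviation
#' (divide-by-N), or the standardized central third/fourth moments (skew,
#' kurtosis; defined as 0 wherever the std is 0).
#'
#' @param vol a [brain_volume()], already on the common grid.
#' @param channels character vector of channel tags (see [channel_tags()]).
#' @return an object of class `projection_set`: a named list of 2D images
#'   (in canonical channel order) plus subject metadata.
#' @export
project <- function(vol, channels = channel_tags()) {
  stopifnot(inherits(vol, "brain_volume"))
  if (length(channels) == 0L) stop("empty channel set")
  channels <- order_channels(channels)
  planes <- unique(vapply(channels, function(t) parse_channel(t)$plane, ""))
  images <- list()
  for (pl in planes) {
    ax <- plane_axis[[pl]]
    stats_here <- vapply(
      channels[startsWith(channels, paste0(pl, "_"))],
      function(t) parse_channel(t)$statistic, "")
    m1 <- reduce_mean_axis(vol$data, ax)
    need2 <- any(stats_here %in% c("std", "skew", "kurtosis"))
    if (need2) {
      m2 <- reduce_mean_axis(vol$data^2, ax)
      v <- pmax(m2 - m1^2, 0)
      sdv <- sqrt(v)
    }
    for (st in stats_here) {
      img <- switch(st,
        mean = m1,
        std = sdv,
        skew = {
          m3 <- reduce_mean_axis(vol$data^3, ax)
          mu3 <- m3 - 3 * m1 * m2 + 2 * m1^3
          ifelse(sdv > 1e-12, mu3 / sdv^3, 0)
        },
        kurtosis = {
          m3 <- reduce_mean_axis(vol$data^3, ax)
          m4 <- reduce_mean_axis(vol$data^4, ax)
          mu4 <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
          ifelse(sdv > 1e-12, pmax(mu4, 0) / sdv^4, 0)
        })
      images[[paste0(pl, "_", st)]] <- img
    }
  }
  structure(list(subject_id = vol$subject_id, age = vol$age,
                 images = images[order_channels(names(images))],
                 grid = vol$shape),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat("projection_set for", x$subject_id, "with channels:",
      paste(names(x$images), collapse = ", "), "\n")
  invisible(x)
}

plane_image_dims <- function(grid) {
  list(axial = grid[c(1L, 2L)], coronal = grid[c(1L, 3L)],
       sagittal = grid[c(2L, 3L)])
}

#' Pack a cohort of projections into per-split, per-plane arrays
#'
#' Projects every volume (padding to the common grid first) and stores the
#' images contiguously, one 4D array `[H, W, channel, subject]` per plane
#' per split (plane arrays are kept separate because plane image shapes
#' differ). Subject order within each split follows the manifest; the
#' channel dimension follows the canonical channel order. Keeping the whole
#' training set resident in one object is what makes epoch loops cheap:
#' training never re-reads volume files.
#'
#' @param cohort a `phantom_cohort`, or the path of a `manifest.csv`
#'   written by [generate_cohort()] (columns subject_id, age, split, path).
#' @param channels channel tags to compute (default the six standard ones).
#' @param grid common grid; defaults to the cohort's own grid (elementwise
#'   max of the input shapes when reading from a manifest).
#' @return an object of class `packed_projections`.
#' @export
pack_dataset <- function(cohort, channels = channel_tags(), grid = NULL) {
  channels <- order_channels(channels)
  if (length(channels) == 0L) stop("empty channel set")
  if (is.character(cohort)) {
    manifest <- utils::read.csv(cohort, stringsAsFactors = FALSE)
    vols <- NULL
    manifest_path <- cohort
  } else {
    stopifnot(inherits(cohort, "phantom_cohort"))
    manifest <- cohort$subjects
    vols <- cohort$volumes
    manifest_path <- NULL
  }
  n <- nrow(manifest)
  get_vol <- function(i) {
    if (!is.null(vols)) vols[[manifest$subject_id[i]]]
    else load_volume(manifest$path[i], subject_id = manifest$subject_id[i],
                     age = manifest$age[i])
  }
  if (is.null(grid)) {
    if (!is.null(vols)) grid <- grid_spec(cohort$params$grid_shape)
    else {
      shapes <- t(vapply(seq_len(n), function(i) dim(RNifti::readNifti(manifest$path[i])),
                         integer(3)))
      grid <- grid_spec(apply(shapes, 2, max))
    }
  } else if (!inherits(grid, "grid_spec")) grid <- grid_spec(grid)

  planes <- unique(vapply(channels, function(t) parse_channel(t)$plane, ""))
  planes <- all_planes[all_planes %in% planes]
  pdims <- plane_image_dims(grid$target_shape)
  splits <- split(seq_len(n), factor(manifest$split, c("train", "val", "test")))
  offenders <- character(0)
  data <- list()
  for (sp in names(splits)) {
    idx <- splits[[sp]]
    if (length(idx) == 0L) next
    arrs <- lapply(planes, function(pl) {
      ch <- channels[startsWith(channels, paste0(pl, "_"))]
      array(0, dim = c(pdims[[pl]], length(ch), length(idx)),
            dimnames = list(NULL, NULL, ch, manifest$subject_id[idx]))
    })
    names(arrs) <- planes
    for (k in seq_along(idx)) {
      i <- idx[k]
      vol <- get_vol(i)
      if (any(vol$shape > grid$target_shape)) {
        offenders <- c(offenders, manifest$subject_id[i])
        next
      }
      ps <- project(pad_to_grid(vol, grid), channels)
      for (pl in planes) {
        ch <- dimnames(arrs[[pl]])[[3]]
        for (ci in seq_along(ch)) arrs[[pl]][, , ci, k] <- ps$images[[ch[ci]]]
      }
    }
    data[[sp]] <- list(x = arrs, ages = as.numeric(manifest$age[idx]),
                       subject_id = manifest$subject_id[idx])
  }
  if (length(offenders) > 0L)
    stop("volumes exceed the common grid: ", paste(offenders, collapse = ", "))
  structure(list(splits = data, channels = channels,
                 grid = grid$target_shape,
                 manifest_hash = manifest_hash(manifest)),
            class = "packed_projections")
}

manifest_hash <- function(manifest) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  utils::write.csv(manifest, tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

#' @export
print.packed_projections <- function(x, ...) {
  cat("packed_projections on grid", paste(x$grid, collapse = "x"),
      "with channels:", paste(x$channels, collapse = ", "), "\n")
  for (sp in names(x$splits))
    cat(" ", sp, ":", length(x$splits[[sp]]$ages), "subjects\n")
  invisible(x)
}

#' Subset a packed dataset by channels
#'
#' @param packed a `packed_projections` object.
#' @param channels channel tags to keep (must be present).
#' @return a `packed_projections` with only those channels.
#' @export
select_channels <- function(packed, channels) {
  stopifnot(inherits(packed, "packed_projections"))
  channels <- order_channels(channels)
  missing <- setdiff(channels, packed$channels)
  if (length(missing) > 0L)
    stop("channels not in dataset: ", paste(missing, collapse = ", "))
  planes <- unique(vapply(channels, function(t) parse_channel(t)$plane, ""))
  planes <- all_planes[all_planes %in% planes]
  out <- packed
  out$channels <- channels
  for (sp in names(out$splits)) {
    x <- out$splits[[sp]]$x
    x <- x[planes]
    for (pl in planes) {
      keep <- intersect(dimnames(x[[pl]])[[3]], channels)
      x[[pl]] <- x[[pl]][, , keep, , drop = FALSE]
    }
    out$splits[[sp]]$x <- x
  }
  out
}

#' Save / load a packed dataset
#'
#' The on-disk form is a single serialized container holding the per-plane
#' arrays per split plus metadata (channel order, grid, manifest hash).
#'
#' @param packed a `packed_projections` object.
#' @param path destination file.
#' @return `save_packed` returns `path` invisibly; `load_packed` the object.
#' @export
save_packed <- function(packed, path) {
  stopifnot(inherits(packed, "packed_projections"))
  saveRDS(packed, path)
  invisible(path)
}

#' @rdname save_packed
#' @export
load_packed <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "packed_projections"))
  obj
}

#' Export projection images as PNG for visual inspection
#'
#' @param pset a `projection_set`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
export_projection_png <- function(pset, path) {
  stopifnot(inherits(pset, "projection_set"))
  nc <- length(pset$images)
  grDevices::png(path, width = 300 * nc, height = 320)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, nc), mar = c(1, 1, 2, 1))
  for (tag in names(pset$images)) {
    img <- pset$images[[tag]]
    graphics::image(img[, rev(seq_len(ncol(img)))], axes = FALSE, main = tag,
                    col = grDevices::gray.colors(256, 0, 1))
  }
  invisible(path)
}
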