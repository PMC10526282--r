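#' Augmentation configuration
#'
#' Offline augmentation expands the training projections with randomly
#' perturbed copies: a small affine perturbation (scaling, shearing,
#' rotation composed about the image centre) followed by an elastic
#' deformation (Gaussian-smoothed random displacement field). Perturbation
#' magnitudes are deliberately small so that anatomy stays plausible.
#'
#' @param n_copies perturbed copies per original (default 3, giving a
#'   4x training set).
#' @param scale_range multiplicative scale interval around 1.
#' @param shear_range maximal shear angle, degrees.
#' @param rotation_range maximal rotation angle, degrees.
#' @param elastic_alpha displacement magnitude in pixels (0 disables).
#' @param elastic_sigma smoothing of the displacement field, pixels.
#' @param seed integer seed for the whole augmented set.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(n_copies = 3L,
                           scale_range = c(0.95, 1.05),
                           shear_range = 5,
                           rotation_range = 5,
                           elastic_alpha = 2,
                           elastic_sigma = 8,
                           seed = 1L) {
  stopifnot(n_copies >= 0, length(scale_range) == 2L,
            scale_range[1] <= 1, scale_range[2] >= 1,
            shear_range >= 0, rotation_range >= 0,
            elastic_alpha >= 0, elastic_sigma > 0)
  structure(list(n_copies = as.integer(n_copies), scale_range = scale_range,
                 shear_range = shear_range, rotation_range = rotation_range,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 seed = as.integer(seed)),
            class = "augment_config")
}

# Dense Gaussian smoothing operator along one dimension (rows renormalized
# at the borders), used to smooth elastic displacement fields.
gauss_operator <- function(n, sigma) {
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, `-`)^2 / (2 * sigma^2))
  K / rowSums(K)
}

# Draw one geometric transform for images of size dims = c(H, W) from the
# current RNG stream and return a warp closure. All channels of one plane
# of one pseudo-subject share a single warp.
make_warp <- function(dims, config) {
  H <- dims[1]; W <- dims[2]
  s <- runif(1, config$scale_range[1], config$scale_range[2])
  shear <- runif(1, -config$shear_range, config$shear_range) * pi / 180
  theta <- runif(1, -config$rotation_range, config$rotation_range) * pi / 180
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  Sh <- matrix(c(1, 0, tan(shear), 1), 2)
  A <- R %*% Sh %*% diag(c(s, s))
  Minv <- solve(A)
  if (config$elastic_alpha > 0) {
    Kh <- gauss_operator(H, config$elastic_sigma)
    Kw <- gauss_operator(W, config$elastic_sigma)
    dr <- config$elastic_alpha * (Kh %*% matrix(runif(H * W, -1, 1), H) %*% t(Kw))
    dc <- config$elastic_alpha * (Kh %*% matrix(runif(H * W, -1, 1), H) %*% t(Kw))
  } else dr <- dc <- 0
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  r <- matrix(seq_len(H), H, W)
  c_ <- matrix(seq_len(W), H, W, byrow = TRUE)
  src_r <- cr + Minv[1, 1] * (r - cr) + Minv[1, 2] * (c_ - cc) + dr
  src_c <- cc + Minv[2, 1] * (r - cr) + Minv[2, 2] * (c_ - cc) + dc
  function(img) bilinear_sample(img, src_r, src_c)
}

# Bilinear interpolation with zero fill outside the image.
bilinear_sample <- function(img, src_r, src_c) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- numeric(length(ri))
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    out
  }
  ri <- as.vector(r0); ci <- as.vector(c0)
  frv <- as.vector(fr); fcv <- as.vector(fc)
  out <- (1 - frv) * (1 - fcv) * val(ri, ci) +
    frv * (1 - fcv) * val(ri + 1, ci) +
    (1 - frv) * fcv * val(ri, ci + 1) +
    frv * fcv * val(ri + 1, ci + 1)
  matrix(out, H, W)
}

#' Apply one random perturbation to a 2D image
#'
#' Applies scale, shear and rotation as one composed affine about the image
#' centre, then an elastic deformation; out-of-bounds samples are filled
#' with 0 (the background value of the projections). Deterministic given
#' `draw_seed`.
#'
#' @param img numeric matrix.
#' @param config an [augment_config()].
#' @param draw_seed integer seed for this particular draw.
#' @return a matrix of the same shape as `img`.
#' @export
augment_image <- function(img, config, draw_seed) {
  if (!is.matrix(img)) stop("augment_image needs a 2D image (matrix)")
  if (any(!is.finite(img))) stop("image contains non-finite values")
  warp <- with_local_seed(draw_seed, make_warp(dim(img), config))
  warp(img)
}

#' Expand the training split with augmented copies
#'
#' Produces `(1 + n_copies)` times the original training set: each copy is
#' perturbed independently per pseudo-subject, with all channels of one
#' plane of one pseudo-subject sharing a single geometric transform (mean
#' and std images of a plane are views of the same anatomy and must deform
#' together). Ages are copied unchanged. Augmentation is train-only;
#' requesting another split is refused.
#'
#' @param packed a `packed_projections` dataset.
#' @param config an [augment_config()].
#' @param split split to augment; only `"train"` is accepted.
#' @return a `packed_projections` with the enlarged training split.
#' @export
build_augmented_set <- function(packed, config, split = "train") {
  stopifnot(inherits(packed, "packed_projections"),
            inherits(config, "augment_config"))
  if (!identical(split, "train"))
    stop("augmentation is train-only; refusing to augment the '", split, "' split")
  if (is.null(packed$splits$train)) stop("dataset has no train split")
  if (config$n_copies == 0L) return(packed)
  tr <- packed$splits$train
  planes <- names(tr$x)
  n <- length(tr$ages)
  out <- lapply(planes, function(pl) {
    d <- dim(tr$x[[pl]])
    array(0, dim = c(d[1], d[2], d[3], d[4] * (1L + config$n_copies)))
  })
  names(out) <- planes
  ids <- character(n * (1L + config$n_copies))
  for (pl in planes) out[[pl]][, , , seq_len(n)] <- tr$x[[pl]]
  ids[seq_len(n)] <- tr$subject_id
  for (k in seq_len(config$n_copies)) {
    off <- k * n
    for (i in seq_len(n)) {
      for (pi in seq_along(planes)) {
        pl <- planes[pi]
        d <- dim(out[[pl]])
        warp <- with_local_seed(mix_seed(config$seed, k, i, pi),
                                make_warp(d[1:2], config))
        for (ci in seq_len(d[3]))
          out[[pl]][, , ci, off + i] <- warp(tr$x[[pl]][, , ci, i])
      }
      ids[off + i] <- paste0(tr$subject_id[i], "_aug", k)
    }
  }
  packed$splits$train <- list(x = out,
                              ages = rep(tr$ages, 1L + config$n_copies),
                              subject_id = ids)
  for (pl in planes)
    dimnames(packed$splits$train$x[[pl]]) <-
      c(dimnames(tr$x[[pl]])[1:3], list(ids))
  packed
}
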