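# Per-pixel brute-force oracle: loop over slices along the reduced axis and
# compute the moment with elementary arithmetic, independent of project().
brute_project <- function(a, plane, statistic) {
  ax <- c(axial = 3L, coronal = 2L, sagittal = 1L)[[plane]]
  keep <- setdiff(1:3, ax)
  d <- dim(a)
  out <- matrix(0, d[keep[1]], d[keep[2]])
  for (i in seq_len(d[keep[1]])) {
    for (j in seq_len(d[keep[2]])) {
      v <- switch(ax,
                  a[, i, j],   # sagittal: reduce axis 1
                  a[i, , j],   # coronal: reduce axis 2
                  a[i, j, ])   # axial: reduce axis 3
      n <- length(v)
      m <- sum(v) / n
      s <- sqrt(sum((v - m)^2) / n)
      out[i, j] <- switch(statistic,
        mean = m,
        std = s,
        skew = if (s > 1e-12) sum((v - m)^3) / n / s^3 else 0,
        kurtosis = if (s > 1e-12) sum((v - m)^4) / n / s^4 else 0)
    }
  }
  out
}

test_that("moment projections have closed-form values on constant and binary volumes", {
  cvol <- brain_volume(array(0.4, dim = c(6, 5, 4)))
  ps <- project(cvol, channel_tags())
  expect_equal(ps$images$axial_mean, matrix(0.4, 6, 5))
  expect_true(all(abs(ps$images$axial_std) < 1e-12))
  expect_true(all(abs(ps$images$sagittal_std) < 1e-12))

  # values {0, 2} along each reduced axis: mean 1, population std 1
  a <- array(0, dim = c(2, 2, 2)); a[, , 1] <- 0; a[, , 2] <- 2
  ps2 <- project(brain_volume(a), c("axial_mean", "axial_std"))
  expect_equal(ps2$images$axial_mean, matrix(1, 2, 2))
  expect_equal(ps2$images$axial_std, matrix(1, 2, 2))
})

test_that("all moment projections match the brute-force slice loop", {
  for (seed in 1:5) {
    v <- random_volume(c(16, 16, 12), seed = 100 + seed)
    tags <- channel_tags(statistics = c("mean", "std", "skew", "kurtosis"))
    ps <- project(v, tags)
    for (tag in tags) {
      pc <- strsplit(tag, "_")[[1]]
      expect_equal(ps$images[[tag]], brute_project(v$data, pc[1], pc[2]),
                   tolerance = 1e-6, label = tag)
    }
  }
})

test_that("projection respects symmetry and conservation properties", {
  v <- random_volume(c(12, 10, 8), seed = 9)
  ps <- project(v, channel_tags())
  # flipping along a non-reduced axis flips the image
  vf <- brain_volume(v$data[12:1, , ])
  psf <- project(vf, channel_tags())
  expect_equal(psf$images$axial_mean, ps$images$axial_mean[12:1, ])
  expect_equal(psf$images$coronal_std, ps$images$coronal_std[12:1, ])
  # shuffling slices along the reduced axis leaves the projection unchanged
  perm <- with_seed_local(5, sample(8))
  vs <- brain_volume(v$data[, , perm])
  expect_equal(project(vs, "axial_std")$images$axial_std, ps$images$axial_std)
  # conservation: mean image x slice count sums to the volume total
  expect_equal(sum(ps$images$axial_mean) * 8, sum(v$data))
  expect_equal(sum(ps$images$sagittal_mean) * 12, sum(v$data))
})

test_that("axial mean images of jitter-free phantoms are left-right symmetric", {
  p <- phantom_params(grid_shape = c(24, 24, 20), subject_variability = 0,
                      noise_sigma = 0, seed = 3)
  ps <- project(generate_phantom(p, 60, 1), "axial_mean")
  img <- ps$images$axial_mean
  expect_equal(img, img[nrow(img):1, ], tolerance = 1e-8)
})

test_that("packing stores canonical channel order, manifest subject order and round-trips", {
  pk <- tiny_packed()
  expect_equal(pk$channels, c("axial_mean", "axial_std", "coronal_mean",
                              "coronal_std", "sagittal_mean", "sagittal_std"))
  expect_equal(dim(pk$splits$train$x$axial)[3], 2L)
  expect_equal(dim(pk$splits$train$x$axial)[4], 8L)  # floor(0.7 * 12)
  expect_equal(dimnames(pk$splits$train$x$axial)[[3]],
               c("axial_mean", "axial_std"))

  # packed content equals a direct projection of the same subject
  co <- generate_cohort(tiny_params(seed = 42L), 12)
  sid <- pk$splits$val$subject_id[1]
  ps <- project(co$volumes[[sid]], channel_tags())
  expect_equal(pk$splits$val$x$coronal[, , "coronal_std", sid],
               ps$images$coronal_std, ignore_attr = TRUE)

  # determinism and save/load round trip
  pk2 <- pack_dataset(generate_cohort(tiny_params(seed = 42L), 12))
  expect_identical(pk$splits$train$x, pk2$splits$train$x)
  path <- tempfile(fileext = ".rds")
  save_packed(pk, path)
  expect_identical(load_packed(path)$splits, pk$splits)
})

test_that("packing from a manifest on disk matches in-memory packing", {
  dir <- tempfile("cohort-")
  co <- generate_cohort(tiny_params(seed = 77L), 8, out_dir = dir)
  pk_mem <- pack_dataset(co)
  pk_disk <- pack_dataset(file.path(dir, "manifest.csv"),
                          grid = co$params$grid_shape)
  expect_equal(pk_disk$splits$train$x$axial, pk_mem$splits$train$x$axial,
               tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})

test_that("empty channel sets and channel subsetting behave", {
  expect_error(project(random_volume(c(4, 4, 4), 1), character(0)), "empty")
  expect_error(pack_dataset(tiny_packed(), channels = character(0)))
  sub <- select_channels(tiny_packed(), c("axial_std", "sagittal_std"))
  expect_equal(sub$channels, c("axial_std", "sagittal_std"))
  expect_equal(names(sub$splits$train$x), c("axial", "sagittal"))
  expect_error(select_channels(tiny_packed(), "axial_skew"), "not in dataset")
})
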