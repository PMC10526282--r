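#' Parameters of the aging-brain phantom generator
#'
#' The phantom is an ellipsoidal "head" whose outer shell mimics cortical
#' gray matter and whose central low-intensity ellipsoid mimics the
#' ventricles. Aging is encoded as linear cortical thinning and linear
#' ventricular expansion; per-subject anatomy is varied by jittering the
#' ellipsoid axes. Intensities live on the [0, 1] scale of a gray-matter
#' likelihood map.
#'
#' Length defaults are derived from the grid so that the same relative
#' anatomy is produced at any resolution: the shell starts at 10% of the
#' smallest grid dimension and loses half its thickness across the age
#' range, while the ventricle starts at 8% and doubles. These rates are of
#' the order of (exaggerated) lifetime cortical thinning and ventricular
#' growth, chosen once so that the age signal is strong enough to learn
#' from a few hundred phantoms.
#'
#' @param grid_shape integer vector of 3 voxel counts, each >= 16. Default
#'   `c(64, 64, 52)`, a quarter-scale version of a 256 x 256 x 208
#'   acquisition grid.
#' @param age_range closed age interval in years (default `c(44, 82)`).
#' @param shell_thickness_at_44 gray-matter shell thickness in voxels at the
#'   youngest age. Default `0.10 * min(grid_shape)`.
#' @param thinning_rate shell thinning in voxels per year (> 0). Default
#'   halves the shell over the age range.
#' @param ventricle_radius_at_44 ventricle radius in voxels at the youngest
#'   age. Default `0.08 * min(grid_shape)`.
#' @param ventricle_growth_rate ventricle growth in voxels per year (>= 0).
#'   Default doubles the radius over the age range.
#' @param subject_variability std of the multiplicative per-subject jitter
#'   applied to the ellipsoid semi-axes (dimensionless; default 0.03).
#' @param noise_sigma std of additive Gaussian noise on the [0, 1] intensity
#'   scale, clipped after addition (default 0.05).
#' @param seed integer master seed for the cohort.
#' @return an object of class `phantom_params`.
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_params <- function(grid_shape = c(64L, 64L, 52L),
                           age_range = c(44L, 82L),
                           shell_thickness_at_44 = NULL,
                           thinning_rate = NULL,
                           ventricle_radius_at_44 = NULL,
                           ventricle_growth_rate = NULL,
                           subject_variability = 0.03,
                           noise_sigma = 0.05,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must be 3 integers, each >= 16")
  if (length(age_range) != 2L || age_range[2] <= age_range[1])
    stop("age_range must be an increasing interval")
  span <- diff(age_range)
  m <- min(grid_shape)
  if (is.null(shell_thickness_at_44)) shell_thickness_at_44 <- 0.10 * m
  if (is.null(thinning_rate)) thinning_rate <- 0.5 * shell_thickness_at_44 / span
  if (is.null(ventricle_radius_at_44)) ventricle_radius_at_44 <- 0.08 * m
  if (is.null(ventricle_growth_rate)) ventricle_growth_rate <- ventricle_radius_at_44 / span
  if (thinning_rate <= 0) stop("thinning_rate must be > 0")
  if (ventricle_growth_rate < 0) stop("ventricle_growth_rate must be >= 0")
  if (thinning_rate * span >= shell_thickness_at_44)
    stop("shell would vanish within the age range: ",
         "thinning_rate * (age_max - age_min) must stay below shell_thickness_at_44")
  if (subject_variability < 0 || noise_sigma < 0)
    stop("subject_variability and noise_sigma must be >= 0")
  structure(list(grid_shape = grid_shape,
                 age_range = as.numeric(age_range),
                 shell_thickness_at_44 = shell_thickness_at_44,
                 thinning_rate = thinning_rate,
                 ventricle_radius_at_44 = ventricle_radius_at_44,
                 ventricle_growth_rate = ventricle_growth_rate,
                 subject_variability = subject_variability,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Run code under a temporary RNG state; restores the caller's stream.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# Small deterministic seed combiner, kept below 2^31.
mix_seed <- function(...) {
  x <- 0
  for (v in c(...)) x <- (x * 69069 + as.numeric(v) + 1) %% 2147483647
  as.integer(x)
}

# Soft (~1 voxel wide) indicator of the interior of an ellipsoid.
# rho2: array of squared normalized radii; scale: voxel size of the edge.
soft_inside <- function(rho2, scale, edge = 0.8) {
  stats::plogis((1 - sqrt(rho2)) * scale / edge)
}

ellipsoid_rho2 <- function(grid_shape, centre, axes) {
  dx2 <- ((seq_len(grid_shape[1]) - centre[1]) / axes[1])^2
  dy2 <- ((seq_len(grid_shape[2]) - centre[2]) / axes[2])^2
  dz2 <- ((seq_len(grid_shape[3]) - centre[3]) / axes[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

#' Generate one aging-brain phantom volume
#'
#' Deterministic given `(params, age, subject_seed)`: the per-subject
#' morphology jitter is drawn from `subject_seed` (so the same synthetic
#' subject can be rendered at several ages with consistent anatomy), and the
#' noise field is drawn from the same stream.
#'
#' @param params a [phantom_params()] object.
#' @param age age in years; must lie within `params$age_range`.
#' @param subject_seed integer identifying the synthetic subject.
#' @param subject_id subject label stored in the volume (default derived
#'   from `subject_seed`).
#' @return a [brain_volume()] with intensities in [0, 1].
#' @export
generate_phantom <- function(params, age, subject_seed,
                             subject_id = sprintf("sub-%06d", subject_seed)) {
  stopifnot(inherits(params, "phantom_params"))
  if (age < params$age_range[1] || age > params$age_range[2])
    stop("age ", age, " outside the phantom age range [",
         params$age_range[1], ", ", params$age_range[2], "]")
  gs <- params$grid_shape
  base_axes <- c(0.42 * gs[1], 0.45 * gs[2], 0.42 * gs[3])
  centre0 <- (gs + 1) / 2

  draws <- with_local_seed(mix_seed(params$seed, subject_seed), {
    list(axis_jitter = 1 + rnorm(3, 0, params$subject_variability),
         shift = rnorm(3, 0, params$subject_variability * min(gs) / 2),
         noise = if (params$noise_sigma > 0)
           array(rnorm(prod(gs), 0, params$noise_sigma), dim = gs) else 0)
  })

  axes <- base_axes * draws$axis_jitter
  centre <- centre0 + draws$shift
  dt <- age - params$age_range[1]
  thickness <- params$shell_thickness_at_44 - params$thinning_rate * dt
  vent_r <- params$ventricle_radius_at_44 + params$ventricle_growth_rate * dt

  in_outer <- soft_inside(ellipsoid_rho2(gs, centre, axes), mean(axes))
  in_inner <- soft_inside(ellipsoid_rho2(gs, centre, pmax(axes - thickness, 1)),
                          mean(axes) - thickness)
  vent_axes <- vent_r * c(1, 1.25, 0.95)
  in_vent <- soft_inside(ellipsoid_rho2(gs, centre, vent_axes), mean(vent_axes))

  v <- 0.85 * (in_outer - in_inner) + 0.25 * (in_inner - in_vent) + 0.05 * in_vent
  v <- v + draws$noise
  v <- pmin(pmax(v, 0), 1)
  brain_volume(v, subject_id = subject_id, age = age)
}

#' Sample integer ages uniformly over an age range
#'
#' @param n number of ages to draw.
#' @param age_range closed interval in years.
#' @param seed integer seed.
#' @return integer vector of length `n`.
#' @export
sample_ages <- function(n, age_range = c(44L, 82L), seed = 1L) {
  with_local_seed(mix_seed(seed, 271828L),
                  sample(seq(age_range[1], age_range[2]), n, replace = TRUE))
}

#' Generate a phantom cohort with train/validation/test split
#'
#' Ages are sampled uniformly over integer years of `params$age_range`
#' unless an explicit `ages` vector is given. The split assigns
#' `floor(0.7 n)` subjects to training and `floor(0.15 n)` to validation,
#' with the remainder (absorbing the rounding) to test; assignment order is
#' a seeded permutation, so the whole cohort is reproducible from
#' `(params, n)`.
#'
#' @param params a [phantom_params()] object.
#' @param n number of subjects (must be large enough that all three splits
#'   are non-empty; n >= 7 under the default fractions).
#' @param ages optional explicit integer ages of length `n`.
#' @param out_dir if non-`NULL`, volumes are written there as NIfTI
#'   (`.nii.gz`) together with a `manifest.csv` (subject_id, age, split,
#'   path).
#' @param keep_volumes keep the generated volumes in memory in the returned
#'   object (default `TRUE` when `out_dir` is `NULL`).
#' @param fractions train/val/test fractions (default `c(0.70, 0.15, 0.15)`).
#' @return an object of class `phantom_cohort` with elements `subjects`
#'   (data.frame: subject_id, age, split, path), `volumes` (named list of
#'   [brain_volume()] or `NULL`) and `params`.
#' @export
generate_cohort <- function(params, n, ages = NULL, out_dir = NULL,
                            keep_volumes = is.null(out_dir),
                            fractions = c(0.70, 0.15, 0.15)) {
  stopifnot(inherits(params, "phantom_params"))
  n <- as.integer(n)
  if (n < 3L) stop("need at least 3 subjects")
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  n_test <- n - n_train - n_val
  if (min(n_train, n_val, n_test) < 1L)
    stop("cohort of ", n, " subjects cannot fill all three splits")

  if (is.null(ages)) {
    ages <- sample_ages(n, params$age_range, params$seed)
  } else {
    if (length(ages) != n) stop("ages must have length n")
    if (any(ages < params$age_range[1] | ages > params$age_range[2]))
      stop("explicit ages outside the phantom age range")
  }
  ids <- sprintf("sub-%04d", seq_len(n))
  perm <- with_local_seed(mix_seed(params$seed, 314159L), sample.int(n))
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "val"
  split[perm[n_train + n_val + seq_len(n_test)]] <- "test"

  subjects <- data.frame(subject_id = ids, age = as.integer(ages),
                         split = split, path = NA_character_,
                         stringsAsFactors = FALSE)
  volumes <- if (keep_volumes) vector("list", n) else NULL
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    vol <- generate_phantom(params, ages[i], subject_seed = i, subject_id = ids[i])
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, paste0(ids[i], ".nii.gz"))
      save_volume(vol, p)
      subjects$path[i] <- p
    }
    if (keep_volumes) volumes[[i]] <- vol
  }
  if (keep_volumes) names(volumes) <- ids
  if (!is.null(out_dir))
    utils::write.csv(subjects, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  structure(list(subjects = subjects, volumes = volumes, params = params),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("phantom cohort:", nrow(x$subjects), "subjects on grid",
      paste(x$params$grid_shape, collapse = "x"), "\n")
  print(table(x$subjects$split))
  invisible(x)
}
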