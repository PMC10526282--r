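# Small fixtures shared across test files; everything is generated in code.

tiny_params <- function(seed = 1L, noise_sigma = 0.05, ...) {
  phantom_params(grid_shape = c(16L, 16L, 16L), seed = seed,
                 noise_sigma = noise_sigma, ...)
}

small_params <- function(seed = 1L, ...) {
  phantom_params(grid_shape = c(32L, 32L, 28L), seed = seed, ...)
}

# memoize expensive fixtures within one test run
fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, fixture_env)) assign(key, force(expr), fixture_env)
  get(key, fixture_env)
}

tiny_packed <- function() memo("tiny_packed", {
  pack_dataset(generate_cohort(tiny_params(seed = 42L), 12))
})

random_volume <- function(shape, seed) {
  with_seed_local(seed, brain_volume(array(runif(prod(shape)), dim = shape)))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}
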