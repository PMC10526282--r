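test_that("model specs validate their inputs", {
  expect_error(model_spec(depth = 15), "unsupported depth")
  expect_error(model_spec(width = 0.7), "unsupported width")
  expect_error(model_spec(channels = character(0)), "empty")
  expect_error(model_spec(channels = "axial_banana"), "invalid channel")
  expect_error(model_spec(channels = c("axial_mean", "axial_std", "coronal_mean"),
                          iso = TRUE), "same number of channels")
})

test_that("parameter breakdown satisfies the sharing identities", {
  a6 <- channel_tags()
  non_iso <- count_parameters(build_model(model_spec(13, 1, a6, iso = FALSE)))
  iso <- count_parameters(build_model(model_spec(13, 1, a6, iso = TRUE)))
  pc <- non_iso$per_component
  expect_equal(non_iso$total_trainable, Reduce(`+`, pc))
  # three identical stacks
  expect_equal(pc$stack_axial, pc$stack_coronal)
  expect_equal(pc$stack_axial, pc$stack_sagittal)
  # iso = one stack + the same head
  expect_equal(iso$total_trainable, pc$stack_axial + pc$head)
  expect_equal(iso$per_component$head, pc$head)
  # 6-channel minus 3-channel = 3 extra input channels x 4 filters x 3 x 3
  m3 <- count_parameters(build_model(model_spec(13, 1,
    channel_tags(statistics = "mean"))))
  expect_equal(non_iso$total_trainable - m3$total_trainable, 108L)
})

test_that("parameter counts are invariant to dropout placement", {
  a6 <- channel_tags()
  conv <- count_parameters(build_model(
    model_spec(13, 1, a6, dropout_placement = "between_conv")))
  dense <- count_parameters(build_model(
    model_spec(13, 1, a6, dropout_placement = "between_dense")))
  expect_equal(conv$total_trainable, dense$total_trainable)
})

test_that("forward pass returns one finite scalar per subject", {
  pk <- tiny_packed()
  spec <- model_spec(13, 0.5)
  net <- build_model(spec, init_seed = 3)
  xb <- lapply(spec$planes, function(pl) pk$splits$train$x[[pl]][, , , 1:5, drop = FALSE])
  res <- model_forward(net, xb)
  expect_length(res$preds, 5L)
  expect_true(all(is.finite(res$preds)))
})

test_that("iso stacks produce identical features for identical inputs", {
  # feed the same image to all three planes of an iso model: the three
  # 256w-feature blocks agree, so predictions must match a permuted-plane run
  spec <- model_spec(13, 0.5, iso = TRUE)
  net <- build_model(spec, init_seed = 9)
  img <- array(runif(16 * 16 * 2 * 3), dim = c(16, 16, 2, 3))
  xb <- list(img, img, img)
  r1 <- model_forward(net, xb)
  # permuting the planes changes nothing when inputs and weights are shared
  r2 <- model_forward(net, xb[c(2, 3, 1)])
  expect_equal(r1$preds, r2$preds, tolerance = 1e-12)
  # a non-iso model with the same inputs does not have this symmetry
  net2 <- build_model(model_spec(13, 0.5, iso = FALSE), init_seed = 9)
  r3 <- model_forward(net2, xb)
  r4 <- model_forward(net2, list(img * 2, img, img))
  expect_false(isTRUE(all.equal(r3$preds, r4$preds)))
})

test_that("checkpoints round-trip bit-exactly and validate the architecture", {
  pk <- tiny_packed()
  spec <- model_spec(13, 0.5)
  net <- build_model(spec, init_seed = 1)
  xb <- lapply(spec$planes, function(pl) pk$splits$train$x[[pl]][, , , 1:2, drop = FALSE])
  before <- model_forward(net, xb)$preds
  path <- tempfile(fileext = ".rds")
  save_weights(net, path)
  net2 <- load_weights(path)
  expect_identical(net2$theta, net$theta)
  expect_identical(model_forward(net2, xb)$preds, before)
  # checkpoint is self-describing
  expect_equal(net2$spec$depth, 13L)
  # loading into a different architecture errors naming the field
  expect_error(load_weights(path, expect_spec = model_spec(19, 0.5)),
               "mismatch in 'depth'")
  expect_error(load_weights(path, expect_spec = model_spec(13, 1)),
               "mismatch in 'width'")
})

test_that("gradients match finite differences on a tiny model", {
  pk <- tiny_packed()
  spec <- model_spec(13, 0.5, dropout_conv = 0)
  net <- build_model(spec, init_seed = 2)
  xb <- lapply(spec$planes, function(pl) pk$splits$train$x[[pl]][, , , 1:3, drop = FALSE])
  y <- pk$splits$train$ages[1:3]
  g <- model_forward(net, xb, y, training = TRUE, want_grad = TRUE)$grad
  idx <- with_seed_local(4, sample(length(net$theta), 12))
  eps <- 1e-6
  for (i in idx) {
    perturb <- function(h) {
      n2 <- net; n2$theta[i] <- n2$theta[i] + h
      model_forward(n2, xb, y, training = TRUE)$loss
    }
    num <- (perturb(eps) - perturb(-eps)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})
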