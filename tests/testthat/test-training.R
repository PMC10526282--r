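test_that("one epoch trains, writes a checkpoint and validates inputs", {
  pk <- tiny_packed()
  spec <- model_spec(13, 0.5)
  net <- build_model(spec, init_seed = 1)
  ck <- tempfile(fileext = ".rds")
  res <- train(net, pk, train_config(epochs = 1, batch_size = 4, seed = 1,
                                     checkpoint_path = ck))
  expect_true(file.exists(ck))
  expect_length(res$train_loss, 1L)
  expect_equal(res$best_epoch, 1L)

  # channel mismatch and empty split are rejected
  expect_error(train(net, select_channels(pk, "axial_mean"),
                     train_config(epochs = 1)), "channel mismatch")
  pk_noval <- pk; pk_noval$splits$val <- NULL
  expect_error(train(net, pk_noval, train_config(epochs = 1)), "empty split")
})

test_that("identical seeds give identical loss curves; the best checkpoint is the minimum", {
  pk <- tiny_packed()
  cfg <- function() train_config(epochs = 4, batch_size = 4, seed = 7,
                                 checkpoint_path = tempfile(fileext = ".rds"))
  r1 <- train(build_model(model_spec(13, 0.5), init_seed = 2), pk, cfg())
  r2 <- train(build_model(model_spec(13, 0.5), init_seed = 2), pk, cfg())
  expect_identical(r1$train_loss, r2$train_loss)
  expect_identical(r1$val_loss, r2$val_loss)
  expect_identical(r1$best_model$theta, r2$best_model$theta)

  expect_equal(r1$best_val_loss, min(r1$val_loss))
  expect_true(all(r1$best_val_loss <= r1$val_loss))
  expect_equal(r1$val_loss[r1$best_epoch], r1$best_val_loss)
})

test_that("the network can learn a constant-age cohort", {
  p <- tiny_params(seed = 31)
  co <- generate_cohort(p, 14, ages = rep(60L, 14))
  pk <- pack_dataset(co)
  net <- build_model(model_spec(13, 0.5), init_seed = 5)
  res <- train(net, pk, train_config(epochs = 30, batch_size = 8, seed = 5))
  expect_lt(min(res$train_loss), res$train_loss[1])
  expect_lt(res$best_val_loss, 10)  # within ~3 years of the constant
})

test_that("training never touches volume files once the dataset is packed", {
  dir <- tempfile("cohort-")
  co <- generate_cohort(tiny_params(seed = 12), 10, out_dir = dir,
                        keep_volumes = FALSE)
  pk <- pack_dataset(file.path(dir, "manifest.csv"),
                     grid = co$params$grid_shape)
  unlink(dir, recursive = TRUE)  # sources gone; epochs must not re-read them
  net <- build_model(model_spec(13, 0.5), init_seed = 1)
  res <- train(net, pk, train_config(epochs = 2, batch_size = 4, seed = 2))
  expect_length(res$val_loss, 2L)
})

test_that("predictions align with the manifest, survive checkpoint reload, and track age", {
  pk <- tiny_packed()
  net <- build_model(model_spec(13, 0.5), init_seed = 3)
  res <- train(net, pk, train_config(epochs = 3, batch_size = 4, seed = 3))
  preds <- predict_ages(res$best_model, pk, "test")
  expect_length(preds, length(pk$splits$test$ages))
  reloaded <- load_weights(res$checkpoint)
  expect_identical(predict_ages(reloaded, pk, "test"), preds)
  expect_error(predict_ages(res$best_model, select_channels(pk, "axial_mean"),
                            "test"), "channel mismatch")
})

test_that("a trained model recovers a positive age correlation on phantoms", {
  p <- small_params(seed = 21)
  co <- generate_cohort(p, 60)
  pk <- pack_dataset(co)
  net <- build_model(model_spec(13, 0.5), init_seed = 6)
  res <- train(net, pk, train_config(epochs = 40, batch_size = 16, seed = 6))
  preds <- predict_ages(res$best_model, pk, "val")
  expect_gt(cor(preds, pk$splits$val$ages), 0)
})
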