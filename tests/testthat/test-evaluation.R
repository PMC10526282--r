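test_that("metrics have their closed-form values", {
  expect_equal(evaluate(c(50, 60, 70), c(50, 60, 70))$mae, 0)
  expect_equal(evaluate(c(50, 60, 70), c(50, 60, 70))$rmse, 0)
  expect_equal(evaluate(c(50, 60, 70), c(50, 60, 70))$r2, 1)

  r <- evaluate(c(1, 2, 4), c(1, 2, 3))
  expect_equal(r$mae, 1 / 3)
  expect_equal(r$rmse, 1 / sqrt(3))
  expect_equal(r$r2, 1 - 1 / sum((c(1, 2, 4) - 7 / 3)^2))

  expect_error(evaluate(1:3, 1:4), "length mismatch")
  expect_error(evaluate(1, 1), "at least 2")
})

test_that("MAE never exceeds RMSE", {
  for (seed in 1:20) {
    with_seed_local(seed, {
      y <- runif(30, 44, 82)
      yh <- y + rnorm(30, 0, 5)
      r <- evaluate(y, yh)
      expect_lte(r$mae, r$rmse + 1e-12)
      expect_lte(r$r2, 1)
    })
  }
})

test_that("scatter export writes the pairs CSV and a plot", {
  r <- evaluate(44:53, 44:53 + rnorm(10))
  base <- tempfile()
  paths <- export_scatter(r, base)
  got <- read.csv(paste0(base, ".csv"))
  expect_equal(nrow(got), 10L)
  expect_equal(got$true_age, 44:53)
  expect_gt(file.size(paste0(base, ".png")), 0)
  # re-export is byte-identical
  base2 <- tempfile()
  export_scatter(r, base2)
  expect_identical(readLines(paste0(base, ".csv")),
                   readLines(paste0(base2, ".csv")))
})

test_that("marginal contributions equal brute-force averaging on a hand-built table", {
  # two channels, one learning rate: contribution of c is
  # loss({other}) - loss({other, c}), averaged over the single valid pair
  tab2 <- data.frame(subset = c("axial_mean", "axial_std",
                                "axial_mean+axial_std"),
                     lr = 0.003, loss = c(10, 8, 5))
  mc2 <- marginal_contributions(tab2)
  expect_equal(mc2$contribution[mc2$channel == "axial_mean"], 8 - 5)
  expect_equal(mc2$contribution[mc2$channel == "axial_std"], 10 - 5)

  # three channels, two learning rates: hand-enumerate the subset pairs
  ch <- c("axial_mean", "axial_std", "coronal_mean")
  subsets <- unlist(lapply(1:3, combn, x = ch, simplify = FALSE),
                    recursive = FALSE)
  key <- function(s) paste(sort(match(s, ch)), collapse = "")
  loss_fun <- function(s, lr) 20 - 3 * ("axial_std" %in% s) -
    1 * ("axial_mean" %in% s) - 0.5 * ("coronal_mean" %in% s) + 100 * lr
  rows <- do.call(rbind, lapply(c(0.003, 0.001), function(lr)
    do.call(rbind, lapply(subsets, function(s)
      data.frame(subset = paste(sort(s), collapse = "+"), lr = lr,
                 loss = loss_fun(s, lr))))))
  mc <- marginal_contributions(rows)
  # the additive construction makes every pairwise delta equal the weight
  expect_equal(mc$contribution[mc$channel == "axial_std"], 3)
  expect_equal(mc$contribution[mc$channel == "axial_mean"], 1)
  expect_equal(mc$contribution[mc$channel == "coronal_mean"], 0.5)
  # each channel has pairs (S, S+c) with S nonempty: 3 per lr for 3 channels
  expect_equal(unique(mc$n_pairs), 6L)
})

test_that("ablation trains every non-empty subset per learning rate", {
  pk <- select_channels(tiny_packed(), c("axial_mean", "axial_std"))
  tab <- run_ablation(pk, spec_template = model_spec(13, 0.5),
                      learning_rates = c(0.003, 0.001),
                      epochs = 1L, batch_size = 4L, seed = 1)
  expect_equal(nrow(tab$losses), 3L * 2L)  # 2^2 - 1 subsets x 2 rates
  expect_equal(sort(unique(tab$losses$subset)),
               sort(c("axial_mean", "axial_std", "axial_mean+axial_std")))
  expect_true(all(is.finite(tab$losses$loss)))
  expect_equal(nrow(tab$contributions), 2L)
  expect_error(run_ablation(select_channels(pk, "axial_mean")), "at least 2")
})
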