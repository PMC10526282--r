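#' Accuracy metrics for age prediction
#'
#' MAE and RMSE in years, plus the coefficient of determination
#' r^2 = 1 - SS_res / SS_tot with SS_tot taken about the mean of the true
#' ages. r^2 is reported with the usual caveat that its interpretation for
#' non-linear predictors is loose; no significance testing is attached.
#'
#' @param true_ages,predicted_ages equal-length numeric vectors (n >= 2).
#' @return an object of class `eval_report` with `mae`, `rmse`, `r2`, `n`
#'   and the per-subject `pairs` data frame.
#' @export
evaluate <- function(true_ages, predicted_ages) {
  if (length(true_ages) != length(predicted_ages))
    stop("length mismatch: ", length(true_ages), " true vs ",
         length(predicted_ages), " predicted")
  n <- length(true_ages)
  if (n < 2L) stop("need at least 2 subjects to evaluate")
  err <- predicted_ages - true_ages
  ss_res <- sum(err^2)
  ss_tot <- sum((true_ages - mean(true_ages))^2)
  structure(list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
                 r2 = 1 - ss_res / ss_tot, n = n,
                 pairs = data.frame(true_age = true_ages,
                                    predicted_age = predicted_ages)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("n = %d  MAE = %.3f years  RMSE = %.3f years  r2 = %.3f\n",
              x$n, x$mae, x$rmse, x$r2))
  invisible(x)
}

#' Export a predicted-vs-real age scatter
#'
#' Writes `<path>.csv` with the (true, predicted) pairs and `<path>.png`
#' with a scatter plot against the identity line.
#'
#' @param report an `eval_report` from [evaluate()].
#' @param path output path without extension.
#' @return named character vector with the two file paths, invisibly.
#' @export
export_scatter <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  csv <- paste0(path, ".csv")
  png <- paste0(path, ".png")
  utils::write.csv(report$pairs, csv, row.names = FALSE)
  grDevices::png(png, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  lim <- range(report$pairs)
  graphics::plot(report$pairs$true_age, report$pairs$predicted_age,
                 xlim = lim, ylim = lim, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = "real age (years)", ylab = "predicted age (years)",
                 main = sprintf("MAE %.2f  RMSE %.2f  r2 %.3f",
                                report$mae, report$rmse, report$r2))
  graphics::abline(0, 1, col = "gray40", lty = 2)
  invisible(c(csv = csv, png = png))
}

subset_key <- function(tags) paste(order_channels(tags), collapse = "+")

#' Per-channel marginal contributions from a loss table
#'
#' The marginal contribution of a channel c is the mean, over all ordered
#' subset pairs (S, S + c) with S non-empty and c not in S -- and jointly
#' over the learning rates present in the table -- of
#' `loss(S) - loss(S + c)`: the average decrease in loss when adding the
#' channel.
#'
#' @param losses data frame with columns `subset` (channel tags joined by
#'   `"+"`), `lr` and `loss`.
#' @return data frame with columns `channel` and `contribution`, in
#'   canonical channel order.
#' @export
marginal_contributions <- function(losses) {
  stopifnot(all(c("subset", "lr", "loss") %in% names(losses)))
  sets <- lapply(strsplit(losses$subset, "+", fixed = TRUE), order_channels)
  channels <- order_channels(unique(unlist(sets)))
  keys <- paste(vapply(sets, paste, "", collapse = "+"), losses$lr)
  loss_of <- stats::setNames(losses$loss, keys)
  out <- lapply(channels, function(ch) {
    deltas <- c()
    for (i in seq_along(sets)) {
      S <- sets[[i]]
      if (ch %in% S) next
      key_with <- paste(subset_key(c(S, ch)), losses$lr[i])
      if (!key_with %in% names(loss_of)) next
      deltas <- c(deltas, losses$loss[i] - loss_of[[key_with]])
    }
    data.frame(channel = ch,
               contribution = if (length(deltas)) mean(deltas) else NA_real_,
               n_pairs = length(deltas))
  })
  do.call(rbind, out)
}

#' Channel-ablation study
#'
#' Trains one model per non-empty subset of the dataset's channels and per
#' learning rate (the empty set is untrainable and is excluded), records
#' the best validation loss of each training, and summarizes per-channel
#' marginal contributions with [marginal_contributions()].
#'
#' @param packed a `packed_projections` containing all channels of
#'   interest (at least 2).
#' @param spec_template a [model_spec()] whose depth/width/iso/dropout
#'   settings are reused for every subset (its channel set is ignored).
#' @param learning_rates learning rates to cross with the subsets
#'   (default `c(0.003, 0.001)`).
#' @param epochs,batch_size training budget per subset (desk scale).
#' @param seed integer seed; each training derives its own init and
#'   shuffling seed from it.
#' @return an object of class `ablation_table`: `losses` (per subset x
#'   learning rate) and `contributions` (per channel).
#' @export
run_ablation <- function(packed, spec_template = model_spec(width = 0.5),
                         learning_rates = c(0.003, 0.001),
                         epochs = 10L, batch_size = 16L, seed = 1L) {
  stopifnot(inherits(packed, "packed_projections"))
  channels <- packed$channels
  if (length(channels) < 2L)
    stop("ablation needs at least 2 channels in the dataset")
  subsets <- unlist(lapply(seq_along(channels), function(k)
    utils::combn(channels, k, simplify = FALSE)), recursive = FALSE)
  rows <- list()
  for (li in seq_along(learning_rates)) {
    lr <- learning_rates[li]
    for (si in seq_along(subsets)) {
      sub <- subsets[[si]]
      spec <- model_spec(depth = spec_template$depth,
                         width = spec_template$width,
                         channels = sub, iso = spec_template$iso,
                         dropout_placement = spec_template$dropout_placement,
                         dropout_conv = spec_template$dropout_conv,
                         dropout_dense = spec_template$dropout_dense)
      net <- build_model(spec, init_seed = mix_seed(seed, li, si))
      res <- train(net, select_channels(packed, sub),
                   train_config(learning_rate = lr, epochs = epochs,
                                batch_size = batch_size,
                                seed = mix_seed(seed, li, si, 7L)))
      rows[[length(rows) + 1L]] <- data.frame(
        subset = subset_key(sub), lr = lr, loss = res$best_val_loss)
    }
  }
  losses <- do.call(rbind, rows)
  structure(list(losses = losses,
                 contributions = marginal_contributions(losses)),
            class = "ablation_table")
}

#' @export
print.ablation_table <- function(x, ...) {
  cat("ablation over", nrow(x$losses), "trainings\n")
  print(x$contributions, row.names = FALSE)
  invisible(x)
}
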