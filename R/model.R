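#' Architecture specification of the three-stream projection network
#'
#' Each anatomical plane with at least one selected channel gets its own 2D
#' convolutional stack (identical topology across planes; identical weights
#' when `iso = TRUE`). A stack is `depth` 3x3 convolutions whose filter
#' count starts at `round(4 * width)` and doubles at every resolution
#' reduction up to `round(256 * width)` (two convolutions per resolution
#' level for depth 13, three for 19, four for 25, plus a single top layer).
#' Batch normalization follows every 2nd / 3rd / 4th convolution (whose
#' bias is then omitted), in the order convolution -> batch norm ->
#' activation -> dropout. Each stack ends in a global mean pool producing
#' `round(256 * width)` features; the per-plane features are concatenated
#' and fed through a dense head ending in one node with linear output.
#'
#' @param depth convolution layers per stack: 13, 19 or 25.
#' @param width filter width multiplier: 0.5, 1 or 2.
#' @param channels channel tags the model consumes (see [channel_tags()]);
#'   grouped by plane, so each plane's stack sees 1 or 2 input channels.
#' @param iso share one set of stack weights (and batch-norm statistics)
#'   across the planes; requires every present plane to have the same
#'   number of channels.
#' @param dropout_placement `"between_conv"` (rate `dropout_conv` after
#'   every normalized convolution) or `"between_dense"` (rate
#'   `dropout_dense` between the dense layers).
#' @param dropout_conv,dropout_dense dropout probabilities (defaults 0.2
#'   and 0.3).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(depth = 13L, width = 1,
                       channels = channel_tags(),
                       iso = FALSE,
                       dropout_placement = c("between_conv", "between_dense"),
                       dropout_conv = 0.2, dropout_dense = 0.3) {
  if (!depth %in% c(13L, 19L, 25L))
    stop("unsupported depth ", depth, "; must be 13, 19 or 25")
  if (!width %in% c(0.5, 1, 2))
    stop("unsupported width multiplier ", width, "; must be 0.5, 1 or 2")
  if (length(channels) == 0L) stop("empty channel subset")
  channels <- order_channels(channels)
  dropout_placement <- match.arg(dropout_placement)
  planes <- unique(vapply(channels, function(t) parse_channel(t)$plane, ""))
  planes <- all_planes[all_planes %in% planes]
  cin <- vapply(planes, function(pl)
    sum(startsWith(channels, paste0(pl, "_"))), integer(1))
  if (iso && length(unique(cin)) > 1L)
    stop("iso weight sharing requires the same number of channels per plane")
  structure(list(depth = as.integer(depth), width = width,
                 channels = channels, planes = planes,
                 channels_per_plane = cin, iso = isTRUE(iso),
                 dropout_placement = dropout_placement,
                 dropout_conv = dropout_conv, dropout_dense = dropout_dense,
                 features_per_stack = as.integer(round(256 * width))),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec: depth", x$depth, "width", x$width,
      if (x$iso) "iso" else "non-iso", "\n  channels:",
      paste(x$channels, collapse = ", "), "\n  dropout:",
      x$dropout_placement, "\n")
  invisible(x)
}

# filter sequence and regularization layout of one conv stack
stack_layers <- function(depth, width) {
  per_level <- c(`13` = 2L, `19` = 3L, `25` = 4L)[[as.character(depth)]]
  base <- c(rep(c(4L, 8L, 16L, 32L, 64L, 128L), each = per_level), 256L)
  idx <- seq_along(base)
  list(filters = as.integer(round(width * base)),
       bn = idx %% per_level == 0L,
       pool = idx %% per_level == 0L,
       per_level = per_level)
}

head_sizes <- function(width) as.integer(c(round(width * c(64, 256, 640)), 10L, 1L))

glorot <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

#' Build a three-stream projection network
#'
#' Allocates and initializes all trainable parameters (Glorot-uniform
#' weights, zero biases, unit batch-norm scales) in one flat vector,
#' together with the layout the C++ engine consumes. Initialization is
#' deterministic given `init_seed`.
#'
#' @param spec a [model_spec()].
#' @param init_seed integer seed for weight initialization.
#' @return an object of class `projage_model`.
#' @export
build_model <- function(spec, init_seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  sl <- stack_layers(spec$depth, spec$width)
  theta <- numeric(0)
  state <- numeric(0)
  desc <- list()
  add_param <- function(component, kind, values) {
    off <- length(theta)              # 0-based offset
    theta <<- c(theta, values)
    desc[[length(desc) + 1L]] <<- data.frame(
      component = component, kind = kind, offset = off,
      length = length(values), stringsAsFactors = FALSE)
    off
  }
  add_state <- function(n_channels) {
    off <- length(state)
    state <<- c(state, rep(0, n_channels), rep(1, n_channels)) # mean, var
    off
  }

  with_local_seed(mix_seed(init_seed, 424243L), {
    make_stack <- function(component, cin) {
      L <- length(sl$filters)
      w_off <- b_off <- g_off <- be_off <- st_off <- rep(-1L, L)
      prev <- cin
      for (l in seq_len(L)) {
        f <- sl$filters[l]
        w_off[l] <- add_param(component, "conv_w",
                              glorot(f * 9L * prev, 9L * prev, 9L * f))
        if (sl$bn[l]) {
          g_off[l] <- add_param(component, "bn_gamma", rep(1, f))
          be_off[l] <- add_param(component, "bn_beta", rep(0, f))
          st_off[l] <- add_state(f)
        } else {
          b_off[l] <- add_param(component, "conv_b", rep(0, f))
        }
        prev <- f
      }
      drop <- sl$bn & (spec$dropout_placement == "between_conv")
      list(filters = as.integer(sl$filters), bn = sl$bn, pool = sl$pool,
           drop = drop, in_channels = as.integer(cin),
           w_off = as.integer(w_off), b_off = as.integer(b_off),
           g_off = as.integer(g_off), be_off = as.integer(be_off),
           st_off = as.integer(st_off))
    }

    if (spec$iso) {
      shared <- make_stack("stack_shared", spec$channels_per_plane[1])
      stacks <- rep(list(shared), length(spec$planes))
    } else {
      stacks <- lapply(seq_along(spec$planes), function(p)
        make_stack(paste0("stack_", spec$planes[p]), spec$channels_per_plane[p]))
    }
    names(stacks) <- spec$planes

    hs <- head_sizes(spec$width)
    hin <- length(spec$planes) * spec$features_per_stack
    hbn <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
    hbias <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
    hrelu <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
    hdrop <- c(TRUE, TRUE, TRUE, FALSE, FALSE) &
      (spec$dropout_placement == "between_dense")
    hw_off <- hb_off <- hg_off <- hbe_off <- hst_off <- rep(-1L, length(hs))
    prev <- hin
    for (l in seq_along(hs)) {
      hw_off[l] <- add_param("head", "dense_w",
                             glorot(hs[l] * prev, prev, hs[l]))
      if (hbn[l]) {
        hg_off[l] <- add_param("head", "bn_gamma", rep(1, hs[l]))
        hbe_off[l] <- add_param("head", "bn_beta", rep(0, hs[l]))
        hst_off[l] <- add_state(hs[l])
      } else if (hbias[l]) {
        hb_off[l] <- add_param("head", "dense_b", rep(0, hs[l]))
      }
      prev <- hs[l]
    }
    head <- list(sizes = as.integer(hs), bn = hbn, bias = hbias,
                 relu = hrelu, drop = hdrop,
                 w_off = as.integer(hw_off), b_off = as.integer(hb_off),
                 g_off = as.integer(hg_off), be_off = as.integer(hbe_off),
                 st_off = as.integer(hst_off))

    plan <- list(stacks = stacks, head = head,
                 drop_rate_conv = spec$dropout_conv,
                 drop_rate_dense = spec$dropout_dense,
                 bn_momentum = 0.1, bn_eps = 1e-5)
    structure(list(spec = spec, theta = theta, state = state, plan = plan,
                   desc = do.call(rbind, desc)),
              class = "projage_model")
  })
}

#' Count trainable parameters
#'
#' Exact integer count of all trainable scalars: convolution weights and
#' biases, dense weights and biases, and batch-norm scale/shift pairs
#' (running statistics are state, not parameters). Shared (iso) stack
#' parameters are counted once.
#'
#' @param net a `projage_model` from [build_model()].
#' @return an object of class `parameter_count` with elements
#'   `total_trainable` and `per_component` (per stack, head, and the
#'   batch-norm share).
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "projage_model"))
  comp <- tapply(net$desc$length, net$desc$component, sum)
  bn <- sum(net$desc$length[net$desc$kind %in% c("bn_gamma", "bn_beta")])
  structure(list(total_trainable = length(net$theta),
                 per_component = as.list(comp), bn_parameters = bn),
            class = "parameter_count")
}

#' @export
print.parameter_count <- function(x, ...) {
  cat("trainable parameters:", format(x$total_trainable, big.mark = ","), "\n")
  for (nm in names(x$per_component))
    cat(" ", nm, ":", format(x$per_component[[nm]], big.mark = ","), "\n")
  cat("  (batch-norm scale/shift:", x$bn_parameters, ")\n")
  invisible(x)
}

#' Run the network forward on a batch
#'
#' @param net a `projage_model`.
#' @param xbatch named list of input arrays `[H, W, C, B]`, one per plane in
#'   the model's plane order.
#' @param y optional target ages (enables loss/gradient).
#' @param training use batch statistics, apply dropout, update running
#'   batch-norm state.
#' @param want_grad also return the gradient of the MSE loss.
#' @param dropout_seed integer seed for the dropout masks of this call.
#' @return list with `preds`, `loss`, updated `state`, and optionally `grad`.
#' @keywords internal
#' @export
model_forward <- function(net, xbatch, y = NULL, training = FALSE,
                          want_grad = FALSE, dropout_seed = 0L) {
  stopifnot(inherits(net, "projage_model"))
  .cnn_run(net$theta, net$state, net$plan, unname(xbatch),
           if (is.null(y)) numeric(0) else as.numeric(y),
           training, want_grad, as.integer(dropout_seed))
}

#' Save / load model weights
#'
#' The checkpoint embeds the full [model_spec()] so it is self-describing;
#' loading verifies the architecture and restores parameters bit-exactly.
#'
#' @param net a `projage_model`.
#' @param path checkpoint file.
#' @param expect_spec optional [model_spec()]; loading errors if the
#'   checkpoint's architecture differs, naming the mismatched field.
#' @return `save_weights` returns `path` invisibly; `load_weights` returns
#'   a `projage_model`.
#' @export
save_weights <- function(net, path) {
  stopifnot(inherits(net, "projage_model"))
  saveRDS(list(spec = net$spec, theta = net$theta, state = net$state), path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path, expect_spec = NULL) {
  ck <- readRDS(path)
  if (!is.list(ck) || is.null(ck$spec) || is.null(ck$theta))
    stop("not a projage checkpoint: ", path)
  if (!is.null(expect_spec)) {
    stopifnot(inherits(expect_spec, "model_spec"))
    for (field in c("depth", "width", "channels", "iso", "dropout_placement")) {
      if (!identical(ck$spec[[field]], expect_spec[[field]]))
        stop("checkpoint architecture mismatch in '", field, "': checkpoint has ",
             paste(ck$spec[[field]], collapse = ","), ", expected ",
             paste(expect_spec[[field]], collapse = ","))
    }
  }
  net <- build_model(ck$spec)
  if (length(net$theta) != length(ck$theta))
    stop("checkpoint parameter vector has wrong length")
  net$theta <- ck$theta
  net$state <- ck$state
  net
}

#' @export
print.projage_model <- function(x, ...) {
  print(x$spec)
  cat("parameters:", format(length(x$theta), big.mark = ","), "\n")
  invisible(x)
}
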