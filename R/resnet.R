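#' Architecture configuration for the 1D pre-activation residual network
#'
#' Describes the breathing-pattern classifier: a plain 1x5 stem convolution
#' (Stage 0), an optional size-reducing bottleneck residual unit at the front
#' (Stage 1, kernel 3 or 5, stride 2), three stages of pre-activation
#' bottleneck residual units with bottleneck widths (w, w, 4w), (2w, 2w, 8w),
#' (4w, 4w, 16w) for base width w, a final batch-norm + ReLU, global average
#' pooling over time, and a fully connected classifier.  Stride-2
#' downsampling sits in the first convolution of the first unit of Stages 1,
#' 3 and 4.  The `ds` variant drops Stage 1 entirely; its inputs are expected
#' to be pre-downsampled to half length (see [downsample_windows()]).
#'
#' With the defaults (`blocks_per_stage = 12`) the `stage1_k5` variant has
#' 113 weighted layers (convolutional + fully connected).
#'
#' @param variant `"stage1_k5"`, `"stage1_k3"` (front residual unit with a
#'   1x5 or 1x3 middle kernel), or `"ds"` (no front unit, pre-downsampled
#'   input).
#' @param input_channels number of signal channels (1 or 2).
#' @param input_length temporal length of the network input in samples;
#'   default 64 for the `stage1_*` variants and 32 for `ds`.
#' @param num_classes number of output classes.
#' @param blocks_per_stage residual units in each of Stages 2-4.
#' @param base_width channel width of the stem and the Stage-2 bottleneck.
#' @return An object of class `"resnet_config"`.
#' @seealso [build_resnet()], [count_weighted_layers()], [layer_account()]
#' @export
resnet_config <- function(variant = c("stage1_k5", "stage1_k3", "ds"),
                          input_channels = 1L,
                          input_length = NULL,
                          num_classes = 3L,
                          blocks_per_stage = 12L,
                          base_width = 16L) {
  variant <- match.arg(variant)
  if (is.null(input_length))
    input_length <- if (variant == "ds") 32L else 64L
  input_length <- as.integer(input_length)
  input_channels <- as.integer(input_channels)
  blocks_per_stage <- as.integer(blocks_per_stage)
  if (blocks_per_stage < 1L) stop("blocks_per_stage must be >= 1")
  if (input_channels < 1L) stop("input_channels must be >= 1")
  n_halvings <- if (variant == "ds") 2L else 3L
  if (input_length %% (2L^n_halvings) != 0L)
    stop("input_length must be divisible by ", 2L^n_halvings,
         " for variant '", variant, "' (each stride-2 stage halves it)")
  structure(
    list(variant = variant,
         input_channels = input_channels,
         input_length = input_length,
         num_classes = as.integer(num_classes),
         blocks_per_stage = blocks_per_stage,
         base_width = as.integer(base_width),
         stage1_kernel = switch(variant, stage1_k3 = 3L, stage1_k5 = 5L,
                                ds = NA_integer_)),
    class = "resnet_config")
}

#' @export
print.resnet_config <- function(x, ...) {
  cat("1D pre-activation ResNet configuration\n")
  cat("  variant:          ", x$variant, "\n")
  cat("  input:            ", x$input_channels, "channel(s) x",
      x$input_length, "samples\n")
  cat("  blocks per stage: ", x$blocks_per_stage, "(Stages 2-4)\n")
  cat("  classes:          ", x$num_classes, "\n")
  cat("  weighted layers:  ", count_weighted_layers(x), "\n")
  invisible(x)
}

# stage plan: list of per-stage descriptors derived from the config
.stage_plan <- function(config) {
  w <- config$base_width
  plan <- list()
  if (config$variant != "ds") {
    plan$stage1 <- list(widths = c(w, w, w), out = w,
                        kernel = config$stage1_kernel, stride = 2L,
                        blocks = 1L)
  }
  plan$stage2 <- list(widths = c(w, w, 4L * w), out = 4L * w,
                      kernel = 3L, stride = 1L,
                      blocks = config$blocks_per_stage)
  plan$stage3 <- list(widths = c(2L * w, 2L * w, 8L * w), out = 8L * w,
                      kernel = 3L, stride = 2L,
                      blocks = config$blocks_per_stage)
  plan$stage4 <- list(widths = c(4L * w, 4L * w, 16L * w), out = 16L * w,
                      kernel = 3L, stride = 2L,
                      blocks = config$blocks_per_stage)
  plan
}

.new_conv <- function(k, C_in, C_out, stride, init = TRUE) {
  list(k = as.integer(k), C_in = as.integer(C_in), C_out = as.integer(C_out),
       stride = as.integer(stride), pad = as.integer(k %/% 2L),
       W = if (init) he_init(k, C_in, C_out) else
         matrix(0, k * C_in, C_out))
}

.new_bottleneck <- function(stage, C_in, widths, C_out, kernel, stride,
                            projection) {
  convs <- list(
    .new_conv(1L, C_in, widths[1L], stride),
    .new_conv(kernel, widths[1L], widths[2L], 1L),
    .new_conv(1L, widths[2L], C_out, 1L))
  bns <- list(new_bn(C_in), new_bn(widths[1L]), new_bn(widths[2L]))
  proj <- if (projection) .new_conv(1L, C_in, C_out, stride) else NULL
  list(type = "bottleneck", stage = stage, convs = convs, bns = bns,
       proj = proj)
}

#' Build a 1D pre-activation residual network
#'
#' Instantiates the architecture described by a [resnet_config()] with
#' He fan-in initialised convolution weights (no conv biases; batch-norm
#' scale 1, shift 0) and a zero-initialised... classifier bias.  The same
#' seed always yields identical initial weights.
#'
#' @param config a [resnet_config()].
#' @param seed integer seed for weight initialisation, or `NULL` to use the
#'   current RNG state.
#' @return An object of class `"resnet1d"`: the network with its parameters
#'   and batch-norm running statistics.
#' @export
build_resnet <- function(config, seed = NULL) {
  stopifnot(inherits(config, "resnet_config"))
  with_seed(seed, {
    w <- config$base_width
    units <- list(list(type = "conv", stage = "stage0",
                       conv = .new_conv(5L, config$input_channels, w, 1L)))
    plan <- .stage_plan(config)
    C_in <- w
    for (sname in names(plan)) {
      st <- plan[[sname]]
      for (b in seq_len(st$blocks)) {
        first <- b == 1L
        stride <- if (first) st$stride else 1L
        projection <- first && (stride != 1L || C_in != st$out)
        units[[length(units) + 1L]] <-
          .new_bottleneck(sname, C_in, st$widths, st$out, st$kernel, stride,
                          projection)
        C_in <- st$out
      }
    }
    model <- list(config = config,
                  units = units,
                  bn_final = new_bn(C_in),
                  fc = list(W = he_init(1L, C_in, config$num_classes),
                            b = rep(0, config$num_classes)),
                  feature_dim = C_in)
    class(model) <- "resnet1d"
    model
  })
}

#' @export
print.resnet1d <- function(x, ...) {
  cfg <- x$config
  cat("1D pre-activation ResNet (", cfg$variant, ")\n", sep = "")
  cat("  input:  ", cfg$input_channels, "x", cfg$input_length, "\n")
  cat("  units:  ", length(x$units) - 1L, "bottleneck residual units\n")
  cat("  layers: ", count_weighted_layers(cfg), "weighted layers\n")
  cat("  params: ", format(count_parameters(x), big.mark = ","),
      "(main path)\n")
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

.unit_forward <- function(unit, A, L, N, training, with_cache) {
  if (unit$type == "conv") {
    cv <- unit$conv
    out <- conv1d_forward(A, cv$W, L, N, cv$k, cv$stride, cv$pad)
    return(list(out = out, L = conv_out_len(L, cv$k, cv$stride, cv$pad),
                unit = unit,
                cache = if (with_cache) list(A = A, L = L)))
  }
  cache <- if (with_cache) list(L = L) else NULL
  acts <- A
  Lc <- L
  a1 <- NULL
  for (i in 1:3) {
    bf <- bn_forward(acts, unit$bns[[i]], training)
    if (training) unit$bns[[i]] <- bf$bn
    a <- relu(bf$y)
    if (i == 1L) a1 <- a
    if (with_cache) {
      cache[[paste0("bn", i)]] <- list(xhat = bf$xhat, invstd = bf$invstd)
      cache[[paste0("a", i)]] <- a
      cache[[paste0("L", i)]] <- Lc
    }
    cv <- unit$convs[[i]]
    acts <- conv1d_forward(a, cv$W, Lc, N, cv$k, cv$stride, cv$pad)
    Lc <- conv_out_len(Lc, cv$k, cv$stride, cv$pad)
  }
  sc <- if (is.null(unit$proj)) A else
    conv1d_forward(a1, unit$proj$W, L, N, 1L, unit$proj$stride, 0L)
  list(out = acts + sc, L = Lc, unit = unit, cache = cache)
}

.unit_backward <- function(unit, cache, dOut, N) {
  if (unit$type == "conv") {
    cv <- unit$conv
    g <- conv1d_backward(dOut, cache$A, cv$W, cache$L, N, cv$k, cv$stride,
                         cv$pad)
    return(list(grads = list(dW = list(g$dW)), dA = g$dA))
  }
  dW <- vector("list", 3L)
  dgamma <- vector("list", 3L)
  dbeta <- vector("list", 3L)
  d <- dOut
  for (i in 3:1) {
    cv <- unit$convs[[i]]
    a <- cache[[paste0("a", i)]]
    g <- conv1d_backward(d, a, cv$W, cache[[paste0("L", i)]], N,
                         cv$k, cv$stride, cv$pad)
    dW[[i]] <- g$dW
    da <- g$dA
    if (i == 1L && !is.null(unit$proj)) {
      # the shortcut branch feeds dOut straight into the projection conv
      gp <- conv1d_backward(dOut, a, unit$proj$W, cache$L, N, 1L,
                            unit$proj$stride, 0L)
      da <- da + gp$dA
      dWp <- gp$dW
    }
    bb <- bn_backward(relu_backward(da, a), cache[[paste0("bn", i)]],
                      unit$bns[[i]])
    d <- bb$dA
    dgamma[[i]] <- bb$dgamma
    dbeta[[i]] <- bb$dbeta
  }
  dA <- d
  if (is.null(unit$proj)) {
    dA <- dA + dOut
    dWp <- NULL
  }
  list(grads = list(dW = dW, dWp = dWp, dgamma = dgamma, dbeta = dbeta),
       dA = dA)
}

# full forward pass; returns logits plus (optionally) caches for backprop
forward_net <- function(model, A, N, training = FALSE, with_cache = FALSE) {
  L <- model$config$input_length
  stopifnot(ncol(A) == L * N, nrow(A) == model$config$input_channels)
  caches <- if (with_cache) vector("list", length(model$units))
  stage_lengths <- integer(0)
  for (u in seq_along(model$units)) {
    uf <- .unit_forward(model$units[[u]], A, L, N, training, with_cache)
    if (training) model$units[[u]] <- uf$unit
    A <- uf$out
    L <- uf$L
    if (with_cache) caches[[u]] <- uf$cache
    stage_lengths[model$units[[u]]$stage] <- L
  }
  bf <- bn_forward(A, model$bn_final, training)
  if (training) model$bn_final <- bf$bn
  af <- relu(bf$y)
  P <- gap_forward(af, L, N)                    # C x N
  Z <- model$fc$W %*% P + model$fc$b            # K x N
  out <- list(logits = t(Z), model = model, L_final = L,
              stage_lengths = stage_lengths, pooled_dim = nrow(P))
  if (with_cache) {
    out$caches <- caches
    out$final <- list(bn = list(xhat = bf$xhat, invstd = bf$invstd),
                      af = af, P = P)
  }
  out
}

# dZ arrives channels-first (K x N), as produced by cross_entropy()
backward_net <- function(model, fwd, dZ, N) {
  fin <- fwd$final
  L <- fwd$L_final
  g_fc <- list(dW = tcrossprod(dZ, fin$P),
               db = .rowSums(dZ, nrow(dZ), ncol(dZ)))
  dP <- crossprod(model$fc$W, dZ)               # C x N
  dA <- gap_backward(dP, L, N)
  bb <- bn_backward(relu_backward(dA, fin$af), fin$bn, model$bn_final)
  dA <- bb$dA
  g_final <- list(dgamma = bb$dgamma, dbeta = bb$dbeta)
  g_units <- vector("list", length(model$units))
  for (u in rev(seq_along(model$units))) {
    ub <- .unit_backward(model$units[[u]], fwd$caches[[u]], dA, N)
    g_units[[u]] <- ub$grads
    dA <- ub$dA
  }
  list(units = g_units, bn_final = g_final, fc = g_fc)
}

#' Run a forward pass and return class logits
#'
#' Inference-mode forward pass (batch-norm uses running statistics), so the
#' result is deterministic for a fixed model.
#'
#' @param model a [build_resnet()] model.
#' @param x windows as an `n x channels x length` array (or a
#'   `channels x length` matrix for a single window).
#' @param batch_size forward passes are chunked to bound memory.
#' @return an `n x num_classes` matrix of logits.
#' @export
resnet_logits <- function(model, x, batch_size = 256L) {
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  stopifnot(length(dim(x)) == 3L)
  cfg <- model$config
  if (dim(x)[2L] != cfg$input_channels)
    stop("expected ", cfg$input_channels, " channel(s), got ", dim(x)[2L])
  if (dim(x)[3L] != cfg$input_length)
    stop("expected input length ", cfg$input_length, ", got ", dim(x)[3L])
  n <- dim(x)[1L]
  out <- matrix(NA_real_, n, cfg$num_classes)
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    A <- windows_to_matrix(x[ix, , , drop = FALSE])
    out[ix, ] <- forward_net(model, A, length(ix))$logits
  }
  if (any(!is.finite(out))) stop("non-finite logits produced")
  out
}

# (n, C, L) array -> channels-first C x (L*n) activation matrix
windows_to_matrix <- function(x) {
  a <- aperm(x, c(2L, 3L, 1L))          # (C, L, n)
  dim(a) <- c(dim(x)[2L], dim(x)[3L] * dim(x)[1L])
  a
}

#' Predicted class indices from logits
#'
#' Ties are broken toward the lowest class index.
#'
#' @param logits an `n x num_classes` matrix.
#' @return integer vector of 1-based class indices.
#' @export
predict_class_index <- function(logits) {
  max.col(logits, ties.method = "first")
}

# ---- accounting ------------------------------------------------------------

#' Count weighted layers of an architecture
#'
#' Counts convolutional and fully connected layers only: batch norm, ReLU and
#' pooling carry no counted weights, and projection shortcuts are excluded.
#' With 12 blocks per stage the `stage1_k5` variant counts 113 layers
#' (1 stem + 3 in Stage 1 + 3 x 12 x 3 in Stages 2-4 + 1 classifier).
#'
#' @param config a [resnet_config()] (a full model is also accepted).
#' @return integer layer count.
#' @export
count_weighted_layers <- function(config) {
  if (inherits(config, "resnet1d")) config <- config$config
  stopifnot(inherits(config, "resnet_config"))
  stage1 <- if (config$variant == "ds") 0L else 3L
  1L + stage1 + 3L * 3L * config$blocks_per_stage + 1L
}

# per-layer ledger rows for one model at a given input length
.layer_rows <- function(model, input_length) {
  rows <- list()
  L <- input_length
  add <- function(stage, layer, k, C_in, C_out, L_out, shortcut = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, layer = layer, kernel = k, C_in = C_in, C_out = C_out,
      L_out = L_out, params = k * C_in * C_out,
      flops = 2 * k * C_in * C_out * L_out,
      bn_params = 0, shortcut = shortcut)
  }
  for (unit in model$units) {
    if (unit$type == "conv") {
      cv <- unit$conv
      L <- conv_out_len(L, cv$k, cv$stride, cv$pad)
      add(unit$stage, "conv", cv$k, cv$C_in, cv$C_out, L)
      next
    }
    L_in <- L
    for (i in 1:3) {
      cv <- unit$convs[[i]]
      L <- conv_out_len(L, cv$k, cv$stride, cv$pad)
      add(unit$stage, paste0("conv", i), cv$k, cv$C_in, cv$C_out, L)
      rows[[length(rows)]]$bn_params <- 2 * cv$C_in   # preceding BN
    }
    if (!is.null(unit$proj))
      add(unit$stage, "projection", 1L, unit$proj$C_in, unit$proj$C_out, L,
          shortcut = TRUE)
  }
  fin <- data.frame(stage = "head", layer = "fc", kernel = 1L,
                    C_in = model$feature_dim,
                    C_out = model$config$num_classes, L_out = 1L,
                    params = model$feature_dim * model$config$num_classes +
                      model$config$num_classes,
                    flops = 2 * model$feature_dim * model$config$num_classes,
                    bn_params = 2 * model$feature_dim,  # final BN
                    shortcut = FALSE)
  do.call(rbind, c(rows, list(fin)))
}

#' Per-layer parameter and FLOP ledger
#'
#' Builds the per-layer accounting table: kernel size, channel fan, output
#' length, parameter count (convolutions are bias-free; batch-norm scale and
#' shift are attributed to the convolution they precede; the classifier keeps
#' its bias) and FLOPs for one forward pass counted as 2 per
#' multiply-accumulate over convolutions and the classifier only.
#' Projection-shortcut convolutions are tabulated but flagged, and the
#' headline totals follow the main-path convention that reproduces the
#' published 0.7 M parameter / 15 M FLOP figures; shortcut totals are
#' reported alongside.
#'
#' @param model a [build_resnet()] model or a [resnet_config()].
#' @param input_length temporal input length used for the FLOP column;
#'   defaults to the configured input length.
#' @return an object of class `"layer_account"`: the per-layer data frame
#'   plus totals.
#' @export
layer_account <- function(model, input_length = NULL) {
  if (inherits(model, "resnet_config")) model <- build_resnet(model, seed = 1L)
  stopifnot(inherits(model, "resnet1d"))
  if (is.null(input_length)) input_length <- model$config$input_length
  rows <- .layer_rows(model, input_length)
  main <- !rows$shortcut
  out <- list(
    layers = rows,
    input_length = input_length,
    weighted_layer_count = count_weighted_layers(model$config),
    parameter_count = sum(rows$params[main]) + sum(rows$bn_params[main]),
    flop_count = sum(rows$flops[main]),
    shortcut_parameter_count = sum(rows$params[!main]),
    shortcut_flop_count = sum(rows$flops[!main]))
  class(out) <- "layer_account"
  out
}

#' @export
print.layer_account <- function(x, ...) {
  per_stage <- aggregate(cbind(params = x$layers$params + x$layers$bn_params,
                               flops = x$layers$flops),
                         by = list(stage = x$layers$stage,
                                   shortcut = x$layers$shortcut), FUN = sum)
  cat("Layer account (input length ", x$input_length, ")\n", sep = "")
  cat("  weighted layers (conv + fc): ", x$weighted_layer_count, "\n")
  cat(sprintf("  parameters (main path):       %s  (%.1f M)\n",
              format(x$parameter_count, big.mark = ","),
              x$parameter_count / 1e6))
  cat(sprintf("  FLOPs (main path):            %s  (%.1f M)\n",
              format(x$flop_count, big.mark = ","), x$flop_count / 1e6))
  cat(sprintf("  + projection shortcuts:       %s params, %s FLOPs\n",
              format(x$shortcut_parameter_count, big.mark = ","),
              format(x$shortcut_flop_count, big.mark = ",")))
  cat("\nPer-stage totals:\n")
  print(per_stage, row.names = FALSE)
  invisible(x)
}

#' Total trainable parameters
#'
#' Sums convolution weights (bias-free), batch-norm scales and shifts, and
#' the classifier weight and bias.  By default projection-shortcut
#' convolutions are excluded — the main-path accounting convention under
#' which the default architecture reports 0.7 M parameters; set
#' `include_shortcuts = TRUE` for the full trainable total.
#'
#' @param model a [build_resnet()] model or [resnet_config()].
#' @param include_shortcuts count projection-shortcut convolutions too.
#' @return integer parameter count.
#' @export
count_parameters <- function(model, include_shortcuts = FALSE) {
  acc <- layer_account(model)
  n <- acc$parameter_count
  if (include_shortcuts) n <- n + acc$shortcut_parameter_count
  n
}

#' FLOPs for one forward pass
#'
#' Counts 2 FLOPs per multiply-accumulate over main-path convolutions and
#' the classifier at the stated input length; batch norm, ReLU, pooling and
#' (by default) projection shortcuts are excluded.  Under this convention the
#' default architecture at input length 64 reports 15 M FLOPs.
#'
#' @inheritParams count_parameters
#' @param input_length temporal input length; defaults to the configured one.
#' @return numeric FLOP count.
#' @export
count_flops <- function(model, input_length = NULL,
                        include_shortcuts = FALSE) {
  acc <- layer_account(model, input_length)
  n <- acc$flop_count
  if (include_shortcuts) n <- n + acc$shortcut_flop_count
  n
}

#' Temporal lengths after each stage
#'
#' @param config a [resnet_config()] or model.
#' @return named integer vector of output lengths per stage plus the pooled
#'   feature dimension (`features`).
#' @export
resnet_shapes <- function(config) {
  if (inherits(config, "resnet_config")) config <- build_resnet(config, 1L)
  rows <- .layer_rows(config, config$config$input_length)
  main <- rows[!rows$shortcut & rows$layer != "fc", ]
  lens <- tapply(main$L_out, main$stage, function(z) z[length(z)])
  stages <- unique(main$stage)
  c(stats::setNames(as.integer(lens[stages]), stages),
    features = config$feature_dim)
}

#' Halve signal length for the downsampling (ds) variant
#'
#' The `ds` control variant replaces the front residual unit by halving the
#' input signal: by default every second sample is kept; `"average"` averages
#' consecutive pairs instead.
#'
#' @param x windows array `n x channels x length` (even length).
#' @param method `"subsample"` (default) or `"average"`.
#' @return array `n x channels x length/2`.
#' @export
downsample_windows <- function(x, method = c("subsample", "average")) {
  method <- match.arg(method)
  stopifnot(length(dim(x)) == 3L, dim(x)[3L] %% 2L == 0L)
  L <- dim(x)[3L]
  odd <- seq(1L, L, by = 2L)
  if (method == "subsample") return(x[, , odd, drop = FALSE])
  (x[, , odd, drop = FALSE] + x[, , odd + 1L, drop = FALSE]) / 2
}
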