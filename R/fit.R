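#' Fit a breathing-pattern classifier
#'
#' The main fitting function: trains a 1D pre-activation residual network on
#' labeled NIRS windows with the standard recipe (SGD, momentum 0.9, batch
#' 64, learning rate 0.1 divided by 10 every 30 epochs, cross-entropy loss,
#' training from scratch).  Inputs are per-window zero-mean normalized by
#' default; for the `ds` variant, windows at the native 64-sample length are
#' halved first (every second sample).  Both preprocessing choices are
#' stored in the fitted object and re-applied by `predict`.
#'
#' @param x a `"nirs_windows"` set (labels taken from it) or an
#'   `n x channels x length` array.
#' @param y class labels (factor or integer), required when `x` is an array.
#' @param arch architecture variant: `"stage1_k5"` (default), `"stage1_k3"`,
#'   or `"ds"`; ignored when `config` is given.
#' @param channels optional channel subset (see [select_channels()]) applied
#'   when `x` is a window set; default uses the single O2Hb channel when
#'   present, otherwise all channels.
#' @param config optional [resnet_config()] overriding `arch` (used for toy
#'   architectures).
#' @param train a [train_config()].
#' @param normalize per-window zero-mean input normalization (default TRUE).
#' @param downsample method used to halve inputs for the `ds` variant.
#' @param seed one integer seed controlling initialisation and shuffling;
#'   identical seed and data give an identical fit.
#' @param verbose print per-epoch progress.
#' @return an object of class `"nirsnet"`.
#' @examples
#' ws <- make_synthetic_dataset(12, seed = 1)
#' toy <- resnet_config("stage1_k5", blocks_per_stage = 1)
#' fit <- nirsnet(ws, config = toy, train = train_config(epochs = 2,
#'                batch_size = 8), seed = 1)
#' predict(fit, ws[1:3])
#' @export
nirsnet <- function(x, y = NULL, arch = c("stage1_k5", "stage1_k3", "ds"),
                    channels = NULL, config = NULL, train = train_config(),
                    normalize = TRUE,
                    downsample = c("subsample", "average"), seed = NULL,
                    verbose = FALSE) {
  arch <- if (is.null(config)) match.arg(arch) else config$variant
  downsample <- match.arg(downsample)
  stopifnot(inherits(train, "train_config"))
  if (inherits(x, "nirs_windows")) {
    if (is.null(channels))
      channels <- if ("O2Hb" %in% x$channels) "O2Hb" else x$channels
    x <- select_channels(x, channels)
    y <- x$label
    xa <- x$x
  } else {
    if (is.null(y)) stop("y is required when x is an array")
    stopifnot(length(dim(x)) == 3L)
    xa <- x
    channels <- if (is.null(channels))
      paste0("ch", seq_len(dim(x)[2L])) else channels
  }
  y <- factor(y)
  classes <- levels(y)
  if (anyNA(y)) stop("labels contain NA")
  if (normalize) xa <- xa - as.vector(apply(xa, c(1L, 2L), mean))
  did_downsample <- FALSE
  if (arch == "ds") {
    target <- if (is.null(config)) dim(xa)[3L] %/% 2L else
      config$input_length
    if (dim(xa)[3L] == 2L * target) {
      xa <- downsample_windows(xa, downsample)
      did_downsample <- TRUE
    }
  }
  if (is.null(config))
    config <- resnet_config(arch, input_channels = dim(xa)[2L],
                            input_length = dim(xa)[3L],
                            num_classes = length(classes))
  fit <- with_seed(seed, {
    model <- build_resnet(config)
    train_resnet(model, xa, as.integer(y), train, verbose = verbose)
  })
  structure(list(model = fit$model, history = fit$history,
                 classes = classes, channels = channels,
                 normalize = normalize, arch = arch,
                 downsample = if (did_downsample) downsample else NULL,
                 train = train, seed = seed, call = match.call()),
            class = "nirsnet")
}

# apply the fit-time preprocessing to new windows and return the array
.prep_newdata <- function(object, newdata) {
  if (inherits(newdata, "nirs_windows")) {
    newdata <- select_channels(newdata, object$channels)
    xa <- newdata$x
  } else if (is.array(newdata) && length(dim(newdata)) == 3L) {
    xa <- newdata
  } else stop("newdata must be a nirs_windows set or an n x C x L array")
  if (object$normalize) xa <- xa - as.vector(apply(xa, c(1L, 2L), mean))
  if (!is.null(object$downsample) &&
      dim(xa)[3L] == 2L * object$model$config$input_length)
    xa <- downsample_windows(xa, object$downsample)
  xa
}

#' Predict from a fitted breathing-pattern classifier
#'
#' @param object a fitted [nirsnet()] model.
#' @param newdata a `"nirs_windows"` set or an `n x channels x length`
#'   array; fit-time channel selection, normalization and downsampling are
#'   re-applied.
#' @param type `"class"` (factor of predicted conditions; ties go to the
#'   lowest class index), `"prob"` (softmax probabilities) or `"logit"`.
#' @param ... unused.
#' @return factor, or an `n x classes` matrix for `"prob"`/`"logit"`.
#' @export
predict.nirsnet <- function(object, newdata,
                            type = c("class", "prob", "logit"), ...) {
  type <- match.arg(type)
  xa <- .prep_newdata(object, newdata)
  Z <- resnet_logits(object$model, xa)
  colnames(Z) <- object$classes
  switch(type,
         logit = Z,
         prob = softmax_rows(Z),
         class = factor(object$classes[predict_class_index(Z)],
                        levels = object$classes))
}

#' @export
print.nirsnet <- function(x, ...) {
  cat("Breathing-pattern classifier (1D pre-activation ResNet)\n")
  cat("  variant:", x$arch, " channels:",
      paste(x$channels, collapse = "+"), "\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  ep <- nrow(x$history)
  cat(sprintf("  trained %d epochs; final training loss %.4f, accuracy %.2f%%\n",
              ep, x$history$loss[ep], x$history$train_accuracy[ep]))
  invisible(x)
}

#' @export
summary.nirsnet <- function(object, ...) {
  acc <- layer_account(object$model)
  out <- list(fit = object, account = acc)
  class(out) <- "summary.nirsnet"
  out
}

#' @export
print.summary.nirsnet <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$account)
  invisible(x)
}

#' @export
coef.nirsnet <- function(object, ...) {
  m <- object$model
  out <- list()
  for (u in seq_along(m$units)) {
    unit <- m$units[[u]]
    nm <- paste0(unit$stage, if (unit$type == "bottleneck") paste0(".u", u))
    if (unit$type == "conv") {
      out[[paste0(nm, ".conv")]] <- unit$conv$W
    } else {
      for (i in 1:3) {
        out[[paste0(nm, ".conv", i)]] <- unit$convs[[i]]$W
        out[[paste0(nm, ".bn", i, ".gamma")]] <- unit$bns[[i]]$gamma
        out[[paste0(nm, ".bn", i, ".beta")]] <- unit$bns[[i]]$beta
      }
      if (!is.null(unit$proj)) out[[paste0(nm, ".proj")]] <- unit$proj$W
    }
  }
  out[["bn_final.gamma"]] <- m$bn_final$gamma
  out[["bn_final.beta"]] <- m$bn_final$beta
  out[["fc.W"]] <- m$fc$W
  out[["fc.b"]] <- m$fc$b
  out
}

#' Plot training history
#'
#' Loss and training accuracy per epoch, with the learning-rate drops
#' marked.
#'
#' @param x a fitted [nirsnet()] model.
#' @param ... passed to [plot()].
#' @export
plot.nirsnet <- function(x, ...) {
  h <- x$history
  op <- par(mfrow = c(1L, 2L), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  drops <- which(diff(h$lr) < 0)
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "training loss",
       main = "loss", ...)
  abline(v = h$epoch[drops + 1L], lty = 3L, col = "grey50")
  plot(h$epoch, h$train_accuracy, type = "l", xlab = "epoch",
       ylab = "training accuracy (%)", main = "accuracy", ...)
  abline(v = h$epoch[drops + 1L], lty = 3L, col = "grey50")
  invisible(x)
}

#' Evaluate a fitted classifier on held-out windows
#'
#' @param object a fitted [nirsnet()] model.
#' @param newdata a labeled `"nirs_windows"` set.
#' @return an [eval_report()].
#' @export
evaluate_model <- function(object, newdata) {
  stopifnot(inherits(object, "nirsnet"), inherits(newdata, "nirs_windows"))
  pred <- predict(object, newdata)
  eval_report(as.character(pred), as.character(newdata$label),
              class_order = levels(newdata$label))
}

#' Repeated train/evaluate experiment
#'
#' Runs `n_repeats` independent train-and-evaluate cycles with distinct
#' seeds derived from the master seed, reporting per-run test accuracy plus
#' the (mean, STD, best) summary.  By default each run re-draws both the
#' split and the initialisation; `resplit = FALSE` fixes the split from the
#' master seed and re-draws only the initialisation.
#'
#' @param windows a labeled `"nirs_windows"` set (all windows; each run
#'   splits it).
#' @param arch,channels,config,train,normalize passed to [nirsnet()].
#' @param split a [split_spec()] (its `seed` element is ignored; per-run
#'   seeds are derived from `seed`).
#' @param n_repeats number of runs (default 5).
#' @param resplit re-draw the split each run (default TRUE).
#' @param seed master seed; the whole experiment is reproducible from it.
#' @param verbose print per-run progress.
#' @return an object of class `"nirsnet_experiment"`: per-run accuracies,
#'   the summary triple, and the best run's [eval_report()].
#' @export
run_experiment <- function(windows, arch = "stage1_k5", channels = NULL,
                           config = NULL, train = train_config(),
                           split = split_spec(), n_repeats = 5L,
                           resplit = TRUE, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(windows, "nirs_windows"), n_repeats >= 1L)
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                             2L * n_repeats),
                                  nrow = n_repeats))
  runs <- data.frame(run = seq_len(n_repeats), split_seed = NA_integer_,
                     fit_seed = NA_integer_, accuracy = NA_real_)
  reports <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    split_seed <- if (resplit) seeds[r, 1L] else seeds[1L, 1L]
    fit_seed <- seeds[r, 2L]
    sp <- split_windows(windows, split_spec(split$train_fraction,
                                            split$mode, split_seed))
    fit <- nirsnet(sp$train, arch = arch, channels = channels,
                   config = config, train = train, seed = fit_seed)
    reports[[r]] <- evaluate_model(fit, sp$test)
    runs$split_seed[r] <- split_seed
    runs$fit_seed[r] <- fit_seed
    runs$accuracy[r] <- reports[[r]]$accuracy
    if (verbose)
      message(sprintf("run %d/%d: test accuracy %.2f%%", r, n_repeats,
                      runs$accuracy[r]))
  }
  best <- which.max(runs$accuracy)
  summary_triple <- list(mean = mean(runs$accuracy),
                         sd = if (n_repeats > 1L) stats::sd(runs$accuracy)
                         else 0,
                         best = runs$accuracy[best])
  reports[[best]]$repeats <- summary_triple
  structure(list(runs = runs, mean = summary_triple$mean,
                 sd = summary_triple$sd, best = summary_triple$best,
                 best_report = reports[[best]], reports = reports,
                 arch = arch, n_repeats = n_repeats, seed = seed),
            class = "nirsnet_experiment")
}

#' @export
print.nirsnet_experiment <- function(x, ...) {
  cat(sprintf("Repeated experiment (%s, %d runs)\n", x$arch, x$n_repeats))
  cat(sprintf("  mean accuracy %.2f%%, STD %.3f, best %.2f%%\n",
              x$mean, x$sd, x$best))
  cat("  per-run: ",
      paste(sprintf("%.2f", x$runs$accuracy), collapse = ", "), "\n")
  invisible(x)
}
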