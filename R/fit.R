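#' Step-decay learning-rate schedule
#'
#' Learning rate at a given (zero-based) epoch under step decay:
#' `lr0 * gamma^floor(epoch / step)`. The published recipe starts at 1e-4
#' and halves every 200 epochs.
#'
#' @param epoch Zero-based epoch index (vectorized).
#' @param lr0 Initial learning rate.
#' @param step Epochs between decays.
#' @param gamma Multiplicative decay factor in (0, 1).
#' @return Learning rate(s).
#' @examples
#' lr_schedule(c(0, 199, 200, 400))  # 1e-4 1e-4 5e-5 2.5e-5
#' @export
lr_schedule <- function(epoch, lr0 = 1e-4, step = 200L, gamma = 0.5) {
  lr0 * gamma^floor(epoch / step)
}

#' Fit the FMHA-AE denoiser
#'
#' Trains the autoencoder to map noisy segments onto their clean targets by
#' minimizing the mean-squared error with Adam under a step-decay learning
#' rate. The published recipe is batch size 32, initial learning rate 1e-4
#' halved every 200 epochs, 1000 epochs. Training is fully reproducible:
#' weights come from `model$config$seed` and the mini-batch order from
#' `seed`.
#'
#' @param model An [fmha_init()] model (an `fmha_fit` may also be passed to
#'   continue from trained weights).
#' @param pairs Training data, a [segment_pairs()] object whose segment
#'   length matches the model configuration.
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size.
#' @param lr Initial learning rate.
#' @param lr_step,lr_gamma Step-decay schedule: the rate is multiplied by
#'   `lr_gamma` every `lr_step` epochs (see [lr_schedule()]).
#' @param seed Integer seed for the mini-batch shuffling.
#' @param validation Optional `segment_pairs` evaluated (forward pass only)
#'   after every epoch; its loss is logged alongside the training loss.
#' @param precision `"single"` (default; the training precision) or
#'   `"double"`.
#' @param verbose Print per-epoch losses.
#' @return An object of class `"fmha_fit"`: the trained `model`, a `history`
#'   data frame (`epoch`, `lr`, `train_loss`, `test_loss`) and the call
#'   settings. Methods: `print`, `summary`, `plot` (loss curves), `predict`
#'   (denoise), `residuals`, `coef`.
#' @export
fit_fmha <- function(model, pairs, epochs = 1000L, batch_size = 32L,
                     lr = 1e-4, lr_step = 200L, lr_gamma = 0.5, seed = 1L,
                     validation = NULL, precision = c("single", "double"),
                     verbose = FALSE) {
  precision <- match.arg(precision)
  if (inherits(model, "fmha_fit")) model <- model$model
  stopifnot(inherits(model, "fmha_model"), inherits(pairs, "segment_pairs"))
  if (length(pairs) == 0L) stop("no training pairs")
  if (nrow(pairs$noisy) != model$config$segment_length)
    stop("segment length ", nrow(pairs$noisy), " does not match the model (",
         model$config$segment_length, ")")
  if (!(lr_gamma > 0 && lr_gamma < 1)) stop("lr_gamma must be in (0, 1)")
  if (epochs < 1L || batch_size < 1L || lr <= 0 || lr_step < 1L)
    stop("epochs, batch_size, lr and lr_step must be positive")
  Xv <- matrix(numeric(0), nrow(pairs$noisy), 0L); Yv <- Xv
  if (!is.null(validation)) {
    stopifnot(inherits(validation, "segment_pairs"))
    Xv <- validation$noisy; Yv <- validation$clean
  }
  res <- fmha_train_cpp(model$params, pairs$noisy, pairs$clean, Xv, Yv,
                        .cfg_list(model$config),
                        as.integer(epochs), as.integer(batch_size),
                        lr, as.integer(lr_step), lr_gamma, as.integer(seed),
                        verbose, precision == "single")
  model$params <- as.numeric(res$params)
  structure(list(
    model = model,
    history = data.frame(epoch = seq_len(epochs), lr = res$lr,
                         train_loss = res$train_loss, test_loss = res$test_loss),
    settings = list(epochs = epochs, batch_size = batch_size, lr = lr,
                    lr_step = lr_step, lr_gamma = lr_gamma, seed = seed,
                    precision = precision, n_train = length(pairs),
                    n_validation = if (is.null(validation)) 0L else length(validation))),
    class = "fmha_fit")
}

#' @export
print.fmha_fit <- function(x, ...) {
  s <- x$settings
  cat("Fitted FMHA-AE denoiser\n")
  print(x$model)
  cat(sprintf("  trained %d epochs on %d pairs (batch %d, Adam, lr %g halved every %d epochs)\n",
              s$epochs, s$n_train, s$batch_size, s$lr, s$lr_step))
  cat(sprintf("  final training MSE: %.6g", tail(x$history$train_loss, 1L)))
  if (s$n_validation > 0L)
    cat(sprintf("   test MSE: %.6g", tail(x$history$test_loss, 1L)))
  cat("\n")
  invisible(x)
}

#' @export
summary.fmha_fit <- function(object, ...) {
  print(object)
  h <- object$history
  cat("\nLoss history (selected epochs):\n")
  show <- unique(pmax(1L, round(seq(1L, nrow(h), length.out = min(10L, nrow(h))))))
  print(h[show, ], row.names = FALSE)
  invisible(h)
}

#' @export
plot.fmha_fit <- function(x, log = "y", ...) {
  h <- x$history
  has_val <- any(is.finite(h$test_loss))
  matplot(h$epoch, cbind(h$train_loss, if (has_val) h$test_loss),
          type = "l", lty = 1, col = c("black", "firebrick"),
          xlab = "epoch", ylab = "MSE loss", log = log, ...)
  legend("topright", legend = c("train", if (has_val) "test"),
         col = c("black", "firebrick"), lty = 1, bty = "n")
  invisible(h)
}

#' @export
predict.fmha_fit <- function(object, newdata, ...) {
  predict(object$model, newdata,
          precision = object$settings$precision %||% "single", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.fmha_fit <- function(object, ...) object$model$params

#' Residuals of a fitted denoiser on paired data
#'
#' Denoises the noisy segments of `pairs` and returns the residual against
#' the clean targets (`denoised - clean`).
#'
#' @param object An `fmha_fit`.
#' @param pairs A [segment_pairs()] object.
#' @param ... Unused.
#' @return A `segment_length x n` matrix of residuals.
#' @export
residuals.fmha_fit <- function(object, pairs, ...) {
  stopifnot(inherits(pairs, "segment_pairs"))
  predict(object, pairs$noisy) - pairs$clean
}
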