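#' Build an (untrained) FMHA-AE network
#'
#' Assembles the full autoencoder for a given configuration: input layer
#' (1x1 channel-expanding convolution + one residual block), `depth`
#' feature-shuffle self-attention encoder stages, `depth - 1`
#' channel-attention shortcut blocks, `depth` feature-shuffle cross-attention
#' decoder stages all cross-attending to the encoder bottleneck, and the
#' output layer (residual block + 1x1 convolution back to one channel).
#' Shortcut outputs are merged into the decoder path by element-wise
#' addition at the matching resolution; the bottleneck-side decoder stage
#' receives no shortcut.
#'
#' Weights are initialized with the fan-in uniform rule
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))` (biases use their weight's fan-in);
#' normalization gains start at one and shifts at zero. Initialization is
#' fully determined by `config$seed`.
#'
#' @param config An [fmha_config()] object.
#' @return An object of class `"fmha_model"`: a list with `config`, the flat
#'   parameter vector `params`, and the tensor `layout` table.
#' @examples
#' m <- fmha_init(fmha_config(channels = 16, depth = 2, segment_length = 64))
#' count_parameters(m)
#' @export
fmha_init <- function(config) {
  stopifnot(inherits(config, "fmha_config"))
  layout <- fmha_layout_cpp(.cfg_list(config))
  n <- sum(layout$nrow * layout$ncol)
  params <- numeric(n)
  .with_seed(config$seed, {
    fan <- 1
    for (i in seq_len(nrow(layout))) {
      nm <- layout$tensor[i]
      sz <- layout$nrow[i] * layout$ncol[i]
      idx <- layout$offset[i] + seq_len(sz) - 1
      if (grepl("\\.ln[12]\\.g$", nm)) {
        params[idx] <- 1
      } else if (grepl("\\.ln[12]\\.b$", nm)) {
        params[idx] <- 0
      } else if (grepl("\\.(W1|W2|Wq|Wk|Wv|Wo|W)$", nm)) {
        fan <- layout$nrow[i]
        params[idx] <- runif(sz, -1 / sqrt(fan), 1 / sqrt(fan))
      } else {
        # bias: layout lists each bias directly after its weight
        params[idx] <- runif(sz, -1 / sqrt(fan), 1 / sqrt(fan))
      }
    }
  })
  structure(list(config = config, params = params, layout = layout),
            class = "fmha_model")
}

#' Count trainable parameters
#'
#' Exact number of trainable scalars (weights, biases, normalization gains
#' and shifts) in a model, a configuration, or one named block of the
#' architecture.
#'
#' @param x An `fmha_model`, `fmha_fit` or `fmha_config` object.
#' @param block Optional block prefix: `"input"`, `"enc1"` ... `"enc<depth>"`,
#'   `"sc1"` ..., `"dec1"` ..., or `"output"`. Default counts the whole model.
#' @return A non-negative integer (0 for a block prefix matching nothing).
#' @examples
#' count_parameters(fmha_config(), block = "enc1")   # 395264
#' @export
count_parameters <- function(x, block = NULL) {
  if (inherits(x, "fmha_fit")) x <- x$model
  layout <- if (inherits(x, "fmha_model")) x$layout
            else if (inherits(x, "fmha_config")) fmha_layout_cpp(.cfg_list(x))
            else stop("x must be an fmha_model, fmha_fit or fmha_config")
  if (!is.null(block)) {
    keep <- grepl(paste0("^", block, "\\."), layout$tensor)
    layout <- layout[keep, , drop = FALSE]
  }
  as.integer(sum(layout$nrow * layout$ncol))
}

#' Per-block architecture table
#'
#' Summarizes the architecture the way the model is usually reported: one
#' row per block with its trainable-parameter count and input/output sizes
#' (`channels x length`).
#'
#' @param config An [fmha_config()] object (or an `fmha_model`/`fmha_fit`,
#'   whose configuration is used).
#' @return A data frame with columns `block`, `parameters`, `input_size`,
#'   `output_size`, plus a final `Total` row.
#' @export
parameter_table <- function(config) {
  if (inherits(config, "fmha_fit")) config <- config$model$config
  if (inherits(config, "fmha_model")) config <- config$config
  stopifnot(inherits(config, "fmha_config"))
  C <- config$channels; N <- config$segment_length; d <- config$depth
  sz <- function(ch, n) sprintf("%d x %d", ch, n)
  rows <- list(c("Input Layer", count_parameters(config, "input"), sz(1, N), sz(C, N)))
  for (s in seq_len(d))
    rows[[length(rows) + 1L]] <-
      c(sprintf("FMHSA Encoder %d", s), count_parameters(config, paste0("enc", s)),
        sz(C, N %/% 2L^(s - 1L)), sz(C, N %/% 2L^s))
  for (s in seq_len(d - 1L))
    rows[[length(rows) + 1L]] <-
      c(sprintf("MHSA Shortcut %d", s), count_parameters(config, paste0("sc", s)),
        sz(C, N %/% 2L^s), sz(C, N %/% 2L^s))
  for (s in seq_len(d))
    rows[[length(rows) + 1L]] <-
      c(sprintf("FMHCA Decoder %d", d - s + 1L), count_parameters(config, paste0("dec", s)),
        sz(C, N %/% 2L^(d - s + 1L)), sz(C, N %/% 2L^(d - s)))
  rows[[length(rows) + 1L]] <-
    c("Output Layer", count_parameters(config, "output"), sz(C, N), sz(1, N))
  out <- data.frame(block = vapply(rows, `[`, "", 1L),
                    parameters = as.integer(vapply(rows, `[`, "", 2L)),
                    input_size = vapply(rows, `[`, "", 3L),
                    output_size = vapply(rows, `[`, "", 4L),
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(block = "Total", parameters = sum(out$parameters),
                        input_size = sz(1, N), output_size = sz(1, N)))
}

# flat parameter vector -> named list of matrices, following the layout
.param_list <- function(model) {
  layout <- model$layout
  out <- vector("list", nrow(layout))
  names(out) <- layout$tensor
  for (i in seq_len(nrow(layout))) {
    sz <- layout$nrow[i] * layout$ncol[i]
    out[[i]] <- matrix(model$params[layout$offset[i] + seq_len(sz) - 1],
                       layout$nrow[i], layout$ncol[i])
  }
  out
}

.vec <- function(m) as.numeric(m)

# nested weight list for one stage prefix ("enc3", "sc1", "dec2", ...)
.stage_params <- function(pl, prefix) {
  g <- function(nm) pl[[paste0(prefix, ".", nm)]]
  out <- list(
    attn = list(Wq = g("attn.Wq"), bq = .vec(g("attn.bq")),
                Wk = g("attn.Wk"), bk = .vec(g("attn.bk")),
                Wv = g("attn.Wv"), bv = .vec(g("attn.bv")),
                Wo = g("attn.Wo"), bo = .vec(g("attn.bo"))),
    ln1 = list(g = .vec(g("ln1.g")), b = .vec(g("ln1.b"))),
    ffn = list(W1 = g("ffn.W1"), b1 = .vec(g("ffn.b1")),
               W2 = g("ffn.W2"), b2 = .vec(g("ffn.b2"))),
    ln2 = list(g = .vec(g("ln2.g")), b = .vec(g("ln2.b"))))
  if (!is.null(g("res.W1")))
    out$res <- list(W1 = g("res.W1"), b1 = .vec(g("res.b1")),
                    W2 = g("res.W2"), b2 = .vec(g("res.b2")))
  if (!is.null(g("pw.W")))
    out$pw <- list(W = g("pw.W"), b = .vec(g("pw.b")))
  out
}

#' Extract the weights of one block as plain matrices
#'
#' Returns the named weight list for a block of the model, in the form the
#' reference block functions ([residual_block()], [mhsa()],
#' [encoder_block()], ...) expect.
#'
#' @param model An `fmha_model` or `fmha_fit`.
#' @param block Block prefix: `"input"`, `"enc1"`, `"sc1"`, `"dec1"`,
#'   `"output"`, etc.
#' @return A nested list of weight matrices and bias vectors.
#' @export
fmha_block_params <- function(model, block) {
  if (inherits(model, "fmha_fit")) model <- model$model
  stopifnot(inherits(model, "fmha_model"))
  pl <- .param_list(model)
  if (!any(grepl(paste0("^", block, "\\."), names(pl))))
    stop("no block named '", block, "' in this model")
  if (block %in% c("input", "output")) {
    g <- function(nm) pl[[paste0(block, ".", nm)]]
    return(list(pw = list(W = g("pw.W"), b = .vec(g("pw.b"))),
                res = list(W1 = g("res.W1"), b1 = .vec(g("res.b1")),
                           W2 = g("res.W2"), b2 = .vec(g("res.b2")))))
  }
  .stage_params(pl, block)
}

#' Reference forward pass in pure R
#'
#' Runs one segment through the network using the exported R block
#' implementations only. Slow but transparent; it exists as the independent
#' oracle for the compiled forward pass.
#'
#' @param model An `fmha_model` (or `fmha_fit`).
#' @param x Numeric vector of length `segment_length`.
#' @return Numeric vector of the same length: the reconstructed segment.
#' @export
fmha_forward_ref <- function(model, x) {
  if (inherits(model, "fmha_fit")) model <- model$model
  cfg <- model$config
  stopifnot(length(x) == cfg$segment_length)
  pl <- .param_list(model)
  k <- cfg$kernel; h <- cfg$heads; d <- cfg$depth
  inp <- fmha_block_params(model, "input")
  xm <- matrix(as.numeric(x), nrow = 1L)
  a <- t(.add_row(t(xm) %*% inp$pw$W, inp$pw$b))
  f <- residual_block(a, inp$res, k)
  enc_out <- vector("list", d)
  for (s in seq_len(d)) {
    f <- encoder_block(f, .stage_params(pl, paste0("enc", s)), h, k)
    enc_out[[s]] <- f
  }
  e <- enc_out[[d]]
  sc_out <- vector("list", d - 1L)
  for (s in seq_len(d - 1L))
    sc_out[[s]] <- channel_mhsa(enc_out[[s]], .stage_params(pl, paste0("sc", s)), h)
  f <- e
  for (s in seq_len(d)) {
    if (s > 1L) f <- f + sc_out[[d - s + 1L]]
    f <- decoder_block(f, e, .stage_params(pl, paste0("dec", s)), h, k)
  }
  outp <- fmha_block_params(model, "output")
  r <- residual_block(f, outp$res, k)
  as.numeric(t(.add_row(t(r) %*% outp$pw$W, outp$pw$b)))
}

#' Denoise segments with a model
#'
#' Runs the compiled forward pass. Accepts a single segment (vector), a
#' `segment_length x n` matrix of segments in columns, or a long signal whose
#' length is a multiple of the segment length (denoised segment-wise and
#' re-concatenated).
#'
#' @param object An `fmha_model`.
#' @param newdata Numeric vector or matrix of noisy input.
#' @param precision `"single"` (the training precision, default) or
#'   `"double"`.
#' @param ... Unused.
#' @return Denoised data with the same shape as `newdata`.
#' @export
predict.fmha_model <- function(object, newdata,
                               precision = c("single", "double"), ...) {
  precision <- match.arg(precision)
  N <- object$config$segment_length
  vec_in <- !is.matrix(newdata)
  X <- if (is.matrix(newdata)) newdata else {
    if (length(newdata) %% N != 0L)
      stop("input length ", length(newdata), " is not a multiple of the ",
           "segment length ", N)
    matrix(as.numeric(newdata), nrow = N)
  }
  if (nrow(X) != N)
    stop("segments must have ", N, " rows, got ", nrow(X))
  Y <- fmha_forward_cpp(object$params, X, .cfg_list(object$config),
                        precision == "single")
  if (vec_in) as.numeric(Y) else Y
}

#' Save / load a model checkpoint
#'
#' Checkpoints are R's native serialized form (RDS) holding a versioned list
#' with the configuration (including its initialization seed) and the flat
#' weight vector.
#'
#' @param model An `fmha_model` or `fmha_fit` (the embedded model is saved).
#' @param file Checkpoint path.
#' @return `save_fmha()` returns `file` invisibly; `load_fmha()` returns the
#'   restored `fmha_model`.
#' @export
save_fmha <- function(model, file) {
  if (inherits(model, "fmha_fit")) model <- model$model
  stopifnot(inherits(model, "fmha_model"))
  saveRDS(list(format = "ecgfmha-checkpoint", version = 1L,
               config = unclass(model$config), params = model$params), file)
  invisible(file)
}

#' @rdname save_fmha
#' @export
load_fmha <- function(file) {
  ck <- readRDS(file)
  if (!identical(ck$format, "ecgfmha-checkpoint"))
    stop("not an ecgfmha checkpoint: ", file)
  if (!identical(ck$version, 1L))
    stop("unsupported checkpoint version: ", ck$version)
  cfg <- do.call(fmha_config, ck$config)
  m <- structure(list(config = cfg, params = ck$params,
                      layout = fmha_layout_cpp(.cfg_list(cfg))),
                 class = "fmha_model")
  if (length(m$params) != sum(m$layout$nrow * m$layout$ncol))
    stop("checkpoint weight vector does not match its configuration")
  m
}

#' @export
print.fmha_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("FMHA-AE model: C = %d, depth = %d, heads = %d, d_ff = %d, segment %d\n",
              cfg$channels, cfg$depth, cfg$heads, cfg$d_ff, cfg$segment_length))
  cat(sprintf("  %s trainable parameters in %d tensors\n",
              format(length(x$params), big.mark = ","), nrow(x$layout)))
  invisible(x)
}

#' @export
summary.fmha_model <- function(object, ...) {
  tab <- parameter_table(object$config)
  print(object)
  cat("\n")
  print(tab, row.names = FALSE)
  invisible(tab)
}
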