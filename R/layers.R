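# Pure-R reference implementations of the network blocks. These operate on
# channel-major feature maps (C x L) and are deliberately written as plain
# matrix algebra: they are the readable specification of each block and the
# oracle the compiled forward pass is tested against. Weight containers are
# plain named lists; see fmha_block_params() for extracting them from a model.

# tokens-major helpers ------------------------------------------------------

.add_row <- function(X, b) sweep(X, 2L, b, "+")

.im2col_r <- function(Xt, k) {
  # Xt: L x C tokens-major; returns L x (C*k), zero padding, tap-major columns
  L <- nrow(Xt); C <- ncol(Xt); pad <- (k - 1L) %/% 2L
  out <- matrix(0, L, C * k)
  for (t in 0:(k - 1L)) {
    j <- seq_len(L) + (t - pad)
    ok <- j >= 1L & j <= L
    out[ok, (t * C + 1L):(t * C + C)] <- Xt[j[ok], , drop = FALSE]
  }
  out
}

.conv1d <- function(x, W, b, kernel) {
  # x: C_in x L; W: (C_in*kernel) x C_out; same-length convolution
  t(.add_row(.im2col_r(t(x), kernel) %*% W, b))
}

.softmax_rows <- function(S) {
  S <- exp(S - apply(S, 1L, max))
  S / rowSums(S)
}

#' Residual convolution block
#'
#' Two same-channel 1-D convolutions (length `kernel`, padding
#' `(kernel-1)/2`, stride 1) with a ReLU between them, added back onto the
#' input and passed through a final ReLU:
#' `y = ReLU(conv2(ReLU(conv1(x))) + x)`.
#'
#' @param x Feature map, a numeric `C x L` matrix.
#' @param params List with convolution weights `W1`, `W2` (each
#'   `(C*kernel) x C`, tap-major rows as built by [fmha_block_params()]) and
#'   bias vectors `b1`, `b2` (length `C`).
#' @param kernel Convolution length (odd).
#' @return A `C x L` matrix, same shape as `x`.
#' @export
residual_block <- function(x, params, kernel = 5L) {
  if (!is.matrix(x)) stop("x must be a C x L matrix")
  C <- nrow(x)
  if (ncol(params$W1) != C)
    stop("weight/channel mismatch: weights are for ", ncol(params$W1),
         " channels, input has ", C)
  h <- pmax(.conv1d(x, params$W1, params$b1, kernel), 0)
  y <- .conv1d(h, params$W2, params$b2, kernel) + x
  pmax(y, 0)
}

#' Position-wise feed-forward network
#'
#' Applies `FFN(X) = max(0, X W1 + b1) W2 + b2` independently at every time
#' step, with hidden width `d_ff = ncol(params$W1)`.
#'
#' @param x Feature map, `C x L`.
#' @param params List with `W1` (`C x d_ff`), `b1`, `W2` (`d_ff x C`), `b2`.
#' @return A `C x L` matrix.
#' @export
ffn <- function(x, params) {
  X <- t(x)
  H <- pmax(.add_row(X %*% params$W1, params$b1), 0)
  t(.add_row(H %*% params$W2, params$b2))
}

#' Layer normalization over the channel axis
#'
#' Normalizes each time step across its `C` channel values (mean 0,
#' variance 1, `eps = 1e-5`), then applies the learned per-channel gain and
#' shift.
#'
#' @param x Feature map, `C x L`.
#' @param gamma,beta Numeric vectors of length `C`.
#' @param eps Variance floor.
#' @return A `C x L` matrix.
#' @export
layer_norm <- function(x, gamma, beta, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  istd <- 1 / sqrt(colMeans(xc^2) + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  sweep(sweep(xhat, 1L, gamma, "*"), 1L, beta, "+")
}

#' Multi-head self-attention over time steps
#'
#' The `L` columns of the feature map are treated as tokens of dimension `C`.
#' Queries, keys and values are linear projections of the tokens; each of the
#' `h` heads attends with `softmax(Q_i K_i' / sqrt(d_k)) V_i`
#' (`d_k = C/h`), the heads are concatenated and projected by `Wo`.
#'
#' @param x Feature map, `C x L`.
#' @param params List with `Wq`, `Wk`, `Wv`, `Wo` (each `C x C`) and bias
#'   vectors `bq`, `bk`, `bv`, `bo`.
#' @param heads Number of attention heads; must divide `C`.
#' @param return_attention If `TRUE` also return the per-head `L x L`
#'   attention maps (each row sums to one).
#' @return A `C x L` matrix, or a list `(output, attention)` when
#'   `return_attention = TRUE`.
#' @export
mhsa <- function(x, params, heads = 4L, return_attention = FALSE) {
  C <- nrow(x)
  if (C %% heads != 0L) stop("channels (", C, ") not divisible by heads (", heads, ")")
  dk <- C %/% heads
  X <- t(x)
  Q <- .add_row(X %*% params$Wq, params$bq)
  K <- .add_row(X %*% params$Wk, params$bk)
  V <- .add_row(X %*% params$Wv, params$bv)
  out <- matrix(0, nrow(X), C)
  att <- vector("list", heads)
  for (i in seq_len(heads)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    A <- .softmax_rows(Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk))
    out[, cols] <- A %*% V[, cols, drop = FALSE]
    att[[i]] <- A
  }
  y <- t(.add_row(out %*% params$Wo, params$bo))
  if (return_attention) list(output = y, attention = att) else y
}

#' Multi-head cross-attention
#'
#' Queries come from the decoder-path feature map `f`; keys and values from
#' the encoder bottleneck `e`. Per head the attention map has shape
#' `L_f x L_e`; output shape equals the shape of `f`.
#'
#' @param f Query feature map, `C x L_f`.
#' @param e Key/value feature map, `C x L_e` (same channel width as `f`).
#' @inheritParams mhsa
#' @return A `C x L_f` matrix, or a list with the attention maps.
#' @export
mhca <- function(f, e, params, heads = 4L, return_attention = FALSE) {
  C <- nrow(f)
  if (nrow(e) != C)
    stop("channel mismatch: queries have ", C, " channels, keys/values have ", nrow(e))
  dk <- C %/% heads
  Fq <- t(f); Ek <- t(e)
  Q <- .add_row(Fq %*% params$Wq, params$bq)
  K <- .add_row(Ek %*% params$Wk, params$bk)
  V <- .add_row(Ek %*% params$Wv, params$bv)
  out <- matrix(0, nrow(Fq), C)
  att <- vector("list", heads)
  for (i in seq_len(heads)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    A <- .softmax_rows(Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk))
    out[, cols] <- A %*% V[, cols, drop = FALSE]
    att[[i]] <- A
  }
  y <- t(.add_row(out %*% params$Wo, params$bo))
  if (return_attention) list(output = y, attention = att) else y
}

# channel-correlation attention core used by the shortcut blocks: attention
# maps are d_k x d_k between channels, scaled by 1/sqrt(L)
.chan_attention <- function(x, params, heads, return_attention = FALSE) {
  C <- nrow(x); L <- ncol(x); dk <- C %/% heads
  X <- t(x)
  Q <- .add_row(X %*% params$Wq, params$bq)
  K <- .add_row(X %*% params$Wk, params$bk)
  V <- .add_row(X %*% params$Wv, params$bv)
  out <- matrix(0, L, C)
  att <- vector("list", heads)
  for (i in seq_len(heads)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    A <- .softmax_rows(t(Q[, cols, drop = FALSE]) %*% K[, cols, drop = FALSE] / sqrt(L))
    out[, cols] <- V[, cols, drop = FALSE] %*% A
    att[[i]] <- A
  }
  y <- t(.add_row(out %*% params$Wo, params$bo))
  if (return_attention) list(output = y, attention = att) else y
}

#' Channel-attention shortcut block
#'
#' The shortcut connections between matching encoder and decoder resolutions.
#' Structurally an attention + feed-forward block like the encoder's, but the
#' attention is computed *between channels*: per head the map is
#' `softmax(Q_i' K_i / sqrt(L))`, a `d_k x d_k` matrix, so the block's
#' parameter count does not depend on the sequence length. Post-norm
#' residual wiring: `y1 = LN(x + Attn(x))`, `y2 = LN(y1 + FFN(y1))`.
#'
#' @param x Feature map, `C x L`.
#' @param params Nested list with elements `attn` (projections `Wq`, `bq`,
#'   ..., `Wo`, `bo`), `ln1`/`ln2` (gains `g`, shifts `b`) and `ffn`, as
#'   produced by [fmha_block_params()].
#' @param heads Attention head count.
#' @param return_attention If `TRUE`, also return the per-head channel
#'   attention maps.
#' @return A `C x L` matrix (or a list with the attention maps).
#' @export
channel_mhsa <- function(x, params, heads = 4L, return_attention = FALSE) {
  a <- .chan_attention(x, params$attn, heads, return_attention)
  ao <- if (return_attention) a$output else a
  y1 <- layer_norm(x + ao, params$ln1$g, params$ln1$b)
  y2 <- layer_norm(y1 + ffn(y1, params$ffn), params$ln2$g, params$ln2$b)
  if (return_attention) list(output = y2, attention = a$attention) else y2
}

#' Encoder stage: residual block, feature unshuffle, self-attention, FFN
#'
#' One feature-shuffle multi-head self-attention encoder stage:
#' residual block, feature unshuffle (`C -> 2C`, `L -> L/2`), point-wise
#' convolution back to `C` channels, self-attention with post-norm residual,
#' feed-forward with post-norm residual. Halves the feature length.
#'
#' @param x Feature map, `C x L` with even `L`.
#' @param params Nested list with elements `res`, `pw` (`W`, `b`), `attn`,
#'   `ln1`, `ffn`, `ln2` as produced by [fmha_block_params()].
#' @param heads Attention head count.
#' @param kernel Residual-block convolution length.
#' @return A `C x L/2` matrix.
#' @export
encoder_block <- function(x, params, heads = 4L, kernel = 5L) {
  if (ncol(x) %% 2L != 0L)
    stop("encoder stage needs an even feature length, got L = ", ncol(x))
  r <- residual_block(x, params$res, kernel)
  u <- feature_unshuffle(r)
  p <- t(.add_row(t(u) %*% params$pw$W, params$pw$b))
  y1 <- layer_norm(p + mhsa(p, params$attn, heads), params$ln1$g, params$ln1$b)
  y2 <- layer_norm(y1 + ffn(y1, params$ffn), params$ln2$g, params$ln2$b)
  y2
}

#' Decoder stage: residual block, feature shuffle, cross-attention, FFN
#'
#' One feature-shuffle multi-head cross-attention decoder stage:
#' residual block, point-wise convolution `C -> 2C`, feature shuffle
#' (`2C -> C`, `L -> 2L`), cross-attention against the encoder bottleneck
#' with post-norm residual, feed-forward with post-norm residual. Doubles the
#' feature length.
#'
#' @param x Feature map, `C x L`.
#' @param e Encoder bottleneck, `C x L_e`.
#' @inheritParams encoder_block
#' @return A `C x 2L` matrix.
#' @export
decoder_block <- function(x, e, params, heads = 4L, kernel = 5L) {
  if (nrow(e) != nrow(x))
    stop("channel mismatch: decoder path has ", nrow(x),
         " channels, bottleneck has ", nrow(e))
  r <- residual_block(x, params$res, kernel)
  p <- t(.add_row(t(r) %*% params$pw$W, params$pw$b))
  u <- feature_shuffle(p)
  y1 <- layer_norm(u + mhca(u, e, params$attn, heads), params$ln1$g, params$ln1$b)
  y2 <- layer_norm(y1 + ffn(y1, params$ffn), params$ln2$g, params$ln2$b)
  y2
}
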