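#' 1-D feature unshuffle: de-interleave length into channels
#'
#' Rearranges a `CH x N` feature map into a `2CH x N/2` map by splitting each
#' channel into its even- and odd-indexed samples. Writing indices from zero,
#' `out[2k, j] = x[k, 2j]` and `out[2k+1, j] = x[k, 2j+1]`. This is the
#' lossless down-sampling step of the encoder: spatial information moves into
#' the channel dimension, no value is dropped.
#'
#' @param x Numeric matrix, channels in rows, samples in columns; the number
#'   of columns must be even.
#' @return A numeric matrix with twice the rows and half the columns of `x`.
#' @seealso [feature_shuffle()] for the exact inverse.
#' @examples
#' feature_unshuffle(matrix(1:4, nrow = 1))  # [[1,3],[2,4]]
#' @export
feature_unshuffle <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix (CH x N)")
  n <- ncol(x)
  if (n %% 2L != 0L)
    stop("feature_unshuffle() requires an even feature length, got N = ", n)
  ch <- nrow(x)
  out <- matrix(0, 2L * ch, n %/% 2L)
  out[seq(1L, 2L * ch, by = 2L), ] <- x[, seq(1L, n, by = 2L), drop = FALSE]
  out[seq(2L, 2L * ch, by = 2L), ] <- x[, seq(2L, n, by = 2L), drop = FALSE]
  out
}

#' 1-D feature shuffle: interleave channels into length
#'
#' Exact inverse of [feature_unshuffle()]: consecutive channel pairs of a
#' `2CH x N/2` map are interleaved sample-wise into a `CH x N` map
#' (`out[k, i] = x[2k, i/2]` for even `i`, `x[2k+1, (i-1)/2]` for odd `i`,
#' zero-based). This is the lossless up-sampling step of the decoder.
#'
#' @param x Numeric matrix with an even number of rows.
#' @return A numeric matrix with half the rows and twice the columns of `x`.
#' @examples
#' feature_shuffle(rbind(c(1, 3), c(2, 4)))  # back to [[1,2,3,4]]
#' @export
feature_shuffle <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix (CH x N)")
  ch <- nrow(x)
  if (ch %% 2L != 0L)
    stop("feature_shuffle() requires an even channel count, got CH = ", ch)
  n2 <- ncol(x)
  out <- matrix(0, ch %/% 2L, 2L * n2)
  out[, seq(1L, 2L * n2, by = 2L)] <- x[seq(1L, ch, by = 2L), , drop = FALSE]
  out[, seq(2L, 2L * n2, by = 2L)] <- x[seq(2L, ch, by = 2L), , drop = FALSE]
  out
}
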