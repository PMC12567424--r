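#' Model configuration for the FMHA-AE network
#'
#' Collects the architectural hyper-parameters of the autoencoder. The
#' defaults reproduce the published architecture: 128 channels after input
#' expansion, 7 encoder/decoder stages, 4 attention heads, a feed-forward
#' hidden width of `4 * channels`, length-5 residual convolutions and
#' 1024-sample input segments.
#'
#' @param channels Channel width `C` after the input 1x1 convolution.
#' @param depth Number of encoder (and decoder) stages; each encoder stage
#'   halves the feature length, so `segment_length` must be divisible by
#'   `2^depth`.
#' @param heads Attention head count `h`; must divide `channels`
#'   (per-head width `d_k = channels / heads`).
#' @param d_ff Feed-forward hidden width; defaults to `4 * channels`.
#' @param kernel Residual-block convolution length (odd; default 5 with
#'   padding `(kernel-1)/2` so lengths are preserved).
#' @param segment_length Input segment length in samples.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `"fmha_config"`.
#' @examples
#' fmha_config()                      # published architecture
#' fmha_config(channels = 32, depth = 4, segment_length = 256)
#' @export
fmha_config <- function(channels = 128L, depth = 7L, heads = 4L,
                        d_ff = 4L * channels, kernel = 5L,
                        segment_length = 1024L, seed = 1L) {
  channels <- as.integer(channels); depth <- as.integer(depth)
  heads <- as.integer(heads); d_ff <- as.integer(d_ff)
  kernel <- as.integer(kernel); segment_length <- as.integer(segment_length)
  if (channels < 1L || depth < 1L || heads < 1L || d_ff < 1L)
    stop("channels, depth, heads and d_ff must all be positive")
  if (channels %% heads != 0L)
    stop("channels (", channels, ") must be divisible by heads (", heads,
         "): d_k = channels/heads")
  if (kernel %% 2L != 1L)
    stop("kernel must be odd so padding (kernel-1)/2 preserves length, got ", kernel)
  if (segment_length %% 2L^depth != 0L)
    stop("segment_length (", segment_length, ") must be divisible by 2^depth (",
         2L^depth, ") so the bottleneck length is a whole number of samples")
  structure(list(channels = channels, depth = depth, heads = heads,
                 d_ff = d_ff, kernel = kernel,
                 segment_length = segment_length, seed = as.integer(seed)),
            class = "fmha_config")
}

#' @export
print.fmha_config <- function(x, ...) {
  cat("FMHA-AE configuration\n")
  cat(sprintf("  channels (C):      %d\n", x$channels))
  cat(sprintf("  depth:             %d encoder + %d decoder stages, %d shortcuts\n",
              x$depth, x$depth, x$depth - 1L))
  cat(sprintf("  heads (h):         %d  (d_k = %d)\n", x$heads, x$channels %/% x$heads))
  cat(sprintf("  d_ff:              %d\n", x$d_ff))
  cat(sprintf("  kernel:            %d\n", x$kernel))
  cat(sprintf("  segment length:    %d  (bottleneck %d)\n",
              x$segment_length, x$segment_length %/% 2L^x$depth))
  invisible(x)
}

# config as the plain list the compiled code expects
.cfg_list <- function(config) {
  config[c("channels", "depth", "heads", "d_ff", "kernel", "segment_length")]
}
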