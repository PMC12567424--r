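#' Signal-to-noise power ratios
#'
#' `snr_in_ratio()` compares the clean signal with its noisy version,
#' `snr_out_ratio()` with the denoised reconstruction. Both return the plain
#' power ratio `sum(x^2) / sum((x - y)^2)` (dimensionless); decibels enter
#' only in [snr_improvement_db()]. Perfect agreement gives `Inf`.
#'
#' @param clean Clean reference signal.
#' @param noisy,denoised Signal to compare against, same length as `clean`.
#' @return A positive number (possibly `Inf`).
#' @export
snr_in_ratio <- function(clean, noisy) {
  .check_pair(clean, noisy)
  den <- sum((clean - noisy)^2)
  if (den == 0) return(Inf)
  sum(clean^2) / den
}

#' @rdname snr_in_ratio
#' @export
snr_out_ratio <- function(clean, denoised) snr_in_ratio(clean, denoised)

#' SNR improvement in decibels
#'
#' `10*log10(SNR_out) - 10*log10(SNR_in)`: the decibel gain of the denoiser
#' over the raw noisy signal. Positive values mean the reconstruction is
#' closer to the clean signal than the noisy input was; negative values mean
#' the denoiser made things worse.
#'
#' @param clean Clean reference signal.
#' @param noisy Noisy input signal.
#' @param denoised Denoiser output.
#' @return SNR improvement in dB.
#' @export
snr_improvement_db <- function(clean, noisy, denoised) {
  10 * log10(snr_out_ratio(clean, denoised)) - 10 * log10(snr_in_ratio(clean, noisy))
}

#' Percentage root-mean-square difference
#'
#' `100 * sqrt(sum((clean - denoised)^2) / sum(clean^2))`. A reconstruction
#' equal to the clean signal scores 0 percent; an all-zero reconstruction
#' scores exactly 100 percent.
#'
#' @inheritParams snr_improvement_db
#' @return PRD in percent (non-negative).
#' @export
prd_percent <- function(clean, denoised) {
  .check_pair(clean, denoised)
  e <- sum(clean^2)
  if (e == 0) stop("PRD is undefined for an all-zero clean signal")
  100 * sqrt(sum((clean - denoised)^2) / e)
}

#' Root-mean-square error
#'
#' @inheritParams snr_improvement_db
#' @return `sqrt(mean((clean - denoised)^2))`.
#' @export
rmse <- function(clean, denoised) {
  .check_pair(clean, denoised)
  sqrt(mean((clean - denoised)^2))
}

#' Mean-squared-error training loss
#'
#' Mean of the squared differences over all elements of two equally shaped
#' arrays (the loss minimized during training).
#'
#' @param target,output Numeric vectors/matrices of identical shape.
#' @return A non-negative number.
#' @export
mse_loss <- function(target, output) {
  if (length(target) != length(output))
    stop("shape mismatch: target has ", length(target),
         " elements, output has ", length(output))
  mean((target - output)^2)
}

.check_pair <- function(a, b) {
  if (length(a) != length(b))
    stop("signals must have equal length (", length(a), " vs ", length(b), ")")
  if (length(a) < 1L) stop("signals must be non-empty")
  invisible(NULL)
}
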