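#' Evaluate a denoiser over noise levels
#'
#' Runs a denoiser over paired test segments, computes per-segment SNR
#' improvement, PRD and RMSE, and aggregates them by nominal input SNR.
#' Aggregation is an unweighted mean over segments within each level; the
#' final `Avg.` row is the unweighted mean of the per-level values.
#'
#' @param denoiser Either a function mapping a noisy segment (numeric
#'   vector) to its denoised version, or a fitted model
#'   (`fmha_fit` / `fmha_model`), or a [filter_spec()] for a classical
#'   baseline.
#' @param pairs A [segment_pairs()] test set.
#' @return An object of class `"metrics_report"`: a data frame with columns
#'   `noise_level_db` (one row per level, plus `"Avg."`), `n_segments`,
#'   `snr_imp_db`, `prd_percent`, `rmse`.
#' @examples
#' pairs <- generate_dataset(12, snr_levels = c(0, 6), seed = 1)
#' evaluate_denoiser(identity, pairs)   # identity: 0 dB improvement
#' @export
evaluate_denoiser <- function(denoiser, pairs) {
  stopifnot(inherits(pairs, "segment_pairs"))
  f <- .as_denoise_fun(denoiser)
  levels <- sort(unique(pairs$snr_db))
  rows <- list()
  for (lv in levels) {
    idx <- which(pairs$snr_db == lv)
    if (length(idx) == 0L) { warning("no segments at ", lv, " dB; level omitted"); next }
    sn <- pr <- rm <- numeric(length(idx))
    for (j in seq_along(idx)) {
      cl <- pairs$clean[, idx[j]]; no <- pairs$noisy[, idx[j]]
      de <- f(no)
      sn[j] <- snr_improvement_db(cl, no, de)
      pr[j] <- prd_percent(cl, de)
      rm[j] <- rmse(cl, de)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(noise_level_db = as.character(lv), n_segments = length(idx),
                 snr_imp_db = mean(sn), prd_percent = mean(pr), rmse = mean(rm))
  }
  out <- do.call(rbind, rows)
  avg <- data.frame(noise_level_db = "Avg.", n_segments = sum(out$n_segments),
                    snr_imp_db = mean(out$snr_imp_db),
                    prd_percent = mean(out$prd_percent), rmse = mean(out$rmse))
  structure(rbind(out, avg), class = c("metrics_report", "data.frame"))
}

.as_denoise_fun <- function(denoiser) {
  if (is.function(denoiser)) return(denoiser)
  if (inherits(denoiser, c("fmha_fit", "fmha_model")))
    return(function(x) predict(denoiser, x))
  if (inherits(denoiser, "filter_spec"))
    return(switch(denoiser$method,
                  fir = function(x) fir_denoise(x, denoiser),
                  iir = function(x) iir_denoise(x, denoiser),
                  dwt = function(x) dwt_denoise(x, denoiser)))
  stop("denoiser must be a function, a fitted model, or a filter_spec")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("Denoising metrics by nominal input SNR\n")
  y <- data.frame(`Input SNR` = paste0(x$noise_level_db,
                                       ifelse(x$noise_level_db == "Avg.", "", " dB")),
                  n = x$n_segments,
                  `SNR_imp (dB)` = round(x$snr_imp_db, digits),
                  `PRD (%)` = round(x$prd_percent, digits),
                  RMSE = signif(x$rmse, digits), check.names = FALSE)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as CSV
#'
#' Columnar text mirroring the standard report layout
#' (`noise_level_db, snr_imp_db, prd_percent, rmse`).
#'
#' @param report A `metrics_report` from [evaluate_denoiser()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_metrics_report <- function(report, file) {
  write.csv(as.data.frame(report), file, row.names = FALSE)
  invisible(file)
}
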