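test_that("the step-decay schedule halves the rate every decay period", {
  expect_equal(lr_schedule(c(0, 199, 200, 399, 400)),
               c(1e-4, 1e-4, 5e-5, 5e-5, 2.5e-5))
  expect_equal(lr_schedule(0, lr0 = 2e-3, step = 10, gamma = 0.1), 2e-3)
  expect_equal(lr_schedule(25, lr0 = 2e-3, step = 10, gamma = 0.1), 2e-5)
})

make_tiny_fit <- function(epochs = 4L, seed = 2L) {
  pairs <- generate_dataset(48, snr_levels = 0, seed = 5, segment_length = 128)
  m <- fmha_init(fmha_config(channels = 8, depth = 2, heads = 2, d_ff = 32,
                             segment_length = 128, seed = 1))
  list(pairs = pairs,
       fit = fit_fmha(m, pairs, epochs = epochs, batch_size = 16, seed = seed))
}

test_that("training reduces the loss and logs the schedule", {
  tf <- make_tiny_fit(epochs = 6L)
  h <- tf$fit$history
  expect_identical(nrow(h), 6L)
  expect_equal(h$lr, rep(1e-4, 6))
  expect_lt(h$train_loss[6], h$train_loss[1])
  expect_true(all(is.finite(h$train_loss)))
})

test_that("training is bit-reproducible for a fixed seed pair", {
  a <- make_tiny_fit(seed = 2L)
  b <- make_tiny_fit(seed = 2L)
  expect_identical(a$fit$history$train_loss, b$fit$history$train_loss)
  expect_identical(coef(a$fit), coef(b$fit))
  c2 <- make_tiny_fit(seed = 3L)
  expect_false(identical(coef(a$fit), coef(c2$fit)))
})

test_that("validation losses are logged per epoch when requested", {
  pairs <- generate_dataset(40, snr_levels = 0, seed = 6, segment_length = 128)
  sp <- split_dataset(pairs, 0.8, seed = 1)
  m <- fmha_init(fmha_config(channels = 8, depth = 2, heads = 2, d_ff = 32,
                             segment_length = 128, seed = 1))
  fit <- fit_fmha(m, sp$train, epochs = 3, batch_size = 16, seed = 2,
                  validation = sp$test)
  expect_true(all(is.finite(fit$history$test_loss)))
  # logged validation loss is the plain MSE of the forward pass
  pred <- predict(fit, sp$test$noisy)
  expect_equal(tail(fit$history$test_loss, 1),
               mse_loss(sp$test$clean, pred), tolerance = 1e-5)
})

test_that("fit methods expose predictions, residuals and coefficients", {
  tf <- make_tiny_fit()
  expect_identical(length(coef(tf$fit)), count_parameters(tf$fit))
  r <- residuals(tf$fit, tf$pairs)
  expect_identical(dim(r), dim(tf$pairs$noisy))
  expect_equal(r, predict(tf$fit, tf$pairs$noisy) - tf$pairs$clean)
  expect_output(print(tf$fit), "trained 4 epochs")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(tf$fit); grDevices::dev.off()
  expect_true(file.exists(f)); unlink(f)
  expect_error(fit_fmha(tf$fit, tf$pairs, epochs = 0), "positive")
})

test_that("evaluation reports per-level metrics with an unweighted average", {
  pairs <- generate_dataset(24, snr_levels = c(0, 6, 12), seed = 7,
                            segment_length = 128)
  rep_id <- evaluate_denoiser(identity, pairs)
  expect_identical(rep_id$noise_level_db, c("0", "6", "12", "Avg."))
  expect_equal(rep_id$snr_imp_db, rep(0, 4), tolerance = 1e-10)
  # an oracle denoiser returning the clean signal is perfect
  oracle <- local({
    i <- 0
    function(x) { i <<- i + 1; pairs$clean[, i] }
  })
  rep_or <- evaluate_denoiser(oracle, pairs)
  expect_equal(rep_or$prd_percent, rep(0, 4), tolerance = 1e-10)
  expect_equal(rep_or$rmse, rep(0, 4), tolerance = 1e-12)
  expect_true(all(rep_or$snr_imp_db[1:3] > 0))
  # the average row is the unweighted mean of the level rows
  lv <- rep_id[rep_id$noise_level_db != "Avg.", ]
  av <- rep_id[rep_id$noise_level_db == "Avg.", ]
  expect_equal(av$prd_percent, mean(lv$prd_percent))
  expect_equal(av$rmse, mean(lv$rmse))
  f <- tempfile(fileext = ".csv")
  write_metrics_report(rep_id, f)
  back <- read.csv(f)
  expect_identical(nrow(back), 4L)
  expect_identical(names(back),
                   c("noise_level_db", "n_segments", "snr_imp_db",
                     "prd_percent", "rmse"))
  unlink(f)
})

test_that("a filter_spec can be evaluated directly as a denoiser", {
  pairs <- generate_dataset(6, snr_levels = 6, seed = 8, segment_length = 1024)
  rep_fir <- evaluate_denoiser(filter_spec("fir"), pairs)
  expect_identical(nrow(rep_fir), 2L)
  expect_true(all(is.finite(rep_fir$snr_imp_db)))
})
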