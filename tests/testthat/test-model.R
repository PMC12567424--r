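# a tiny configuration used for the numerically exhaustive checks
tiny_cfg <- function(seed = 3L)
  fmha_config(channels = 8, depth = 2, heads = 2, d_ff = 16,
              segment_length = 32, seed = seed)

test_that("configuration invariants are enforced with named constraints", {
  expect_error(fmha_config(channels = 30, heads = 4), "divisible by heads")
  expect_error(fmha_config(segment_length = 1000), "divisible by 2\\^depth")
  expect_error(fmha_config(kernel = 4), "odd")
  cfg <- fmha_config()
  expect_identical(cfg$d_ff, 512L)   # 4 x d_model default
  expect_identical(cfg$channels %/% cfg$heads, 32L)
})

test_that("per-block trainable-parameter counts follow the closed forms", {
  cfg <- fmha_config()
  C <- 128L; k <- 5L; dff <- 512L
  res <- 2L * (C * C * k + C)
  attn <- 4L * (C * C + C)
  ffnp <- (C * dff + dff) + (dff * C + C)
  ln2x <- 4L * C
  expect_identical(count_parameters(cfg, "input"), (C + C) + res)
  expect_identical(count_parameters(cfg, "enc1"),
                   res + (2L * C * C + C) + attn + ffnp + ln2x)
  expect_identical(count_parameters(cfg, "sc1"), attn + ffnp + ln2x)
  expect_identical(count_parameters(cfg, "dec1"),
                   res + (C * 2L * C + 2L * C) + attn + ffnp + ln2x)
  expect_identical(count_parameters(cfg, "output"), res + (C + 1L))
  # a block prefix matching nothing counts zero
  expect_identical(count_parameters(cfg, "enc99"), 0L)
  # whole model = sum over the table
  tab <- parameter_table(cfg)
  expect_identical(count_parameters(cfg),
                   tab$parameters[tab$block == "Total"])
  expect_identical(sum(tab$parameters[tab$block != "Total"]),
                   tab$parameters[tab$block == "Total"])
})

test_that("shortcut parameter counts do not depend on the sequence length", {
  a <- fmha_config(segment_length = 1024)
  b <- fmha_config(segment_length = 512)
  for (s in 1:6)
    expect_identical(count_parameters(a, paste0("sc", s)),
                     count_parameters(b, paste0("sc", s)))
  # all six shortcut stages are identical in size
  cnts <- vapply(1:6, function(s) count_parameters(a, paste0("sc", s)), 1L)
  expect_identical(length(unique(cnts)), 1L)
})

test_that("compiled forward pass agrees with the pure-R reference blocks", {
  m <- fmha_init(tiny_cfg())
  set.seed(30)
  for (i in 1:3) {
    x <- rnorm(32)
    ref <- fmha_forward_ref(m, x)
    expect_equal(as.numeric(predict(m, x, precision = "double")), ref,
                 tolerance = 1e-10)
    expect_equal(as.numeric(predict(m, x, precision = "single")), ref,
                 tolerance = 1e-4)
  }
  # batched forward equals segment-by-segment forward
  X <- matrix(rnorm(32 * 4), 32)
  Y <- predict(m, X, precision = "double")
  for (j in 1:4)
    expect_equal(Y[, j], as.numeric(predict(m, X[, j], precision = "double")),
                 tolerance = 1e-12)
})

test_that("analytic gradients match central differences on every tensor", {
  cfg <- tiny_cfg()
  m <- fmha_init(cfg)
  set.seed(31)
  x <- matrix(rnorm(32)); y <- matrix(rnorm(32))
  lg <- ecgfmha:::fmha_loss_grad_cpp(m$params, x, y, ecgfmha:::.cfg_list(cfg))
  expect_true(all(is.finite(lg$grad)))
  loss_at <- function(p)
    ecgfmha:::fmha_loss_grad_cpp(p, x, y, ecgfmha:::.cfg_list(cfg))$loss
  # probe a few entries of every tensor
  idx <- integer(0)
  for (i in seq_len(nrow(m$layout))) {
    sz <- m$layout$nrow[i] * m$layout$ncol[i]
    take <- sample.int(sz, min(2L, sz))
    idx <- c(idx, m$layout$offset[i] + take - 1)
  }
  eps <- 1e-5
  for (i in idx) {
    p1 <- m$params; p1[i] <- p1[i] + eps
    p2 <- m$params; p2[i] <- p2[i] - eps
    num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
    expect_lt(abs(num - lg$grad[i]) / max(1e-6, abs(num) + abs(lg$grad[i])), 1e-3)
  }
})

test_that("gradient reaches every tensor (no dead branches)", {
  cfg <- tiny_cfg()
  m <- fmha_init(cfg)
  set.seed(32)
  lg <- ecgfmha:::fmha_loss_grad_cpp(m$params, matrix(rnorm(32)),
                                     matrix(rnorm(32)), ecgfmha:::.cfg_list(cfg))
  for (i in seq_len(nrow(m$layout))) {
    sz <- m$layout$nrow[i] * m$layout$ncol[i]
    seg <- lg$grad[m$layout$offset[i] + seq_len(sz) - 1]
    expect_gt(max(abs(seg)), 0, label = paste("grad of", m$layout$tensor[i]))
  }
})

test_that("forward pass is deterministic and finite; init depends only on seed", {
  cfg <- tiny_cfg(seed = 9)
  m1 <- fmha_init(cfg); m2 <- fmha_init(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- fmha_init(tiny_cfg(seed = 10))
  expect_false(identical(m1$params, m3$params))
  x <- matrix(sin(1:32 / 3))
  expect_identical(predict(m1, x), predict(m1, x))
  expect_true(all(is.finite(predict(m1, x))))
})

test_that("checkpoints round-trip through save and load", {
  m <- fmha_init(tiny_cfg(seed = 77))
  f <- tempfile(fileext = ".rds")
  save_fmha(m, f)
  m2 <- load_fmha(f)
  expect_identical(m2$params, m$params)
  expect_identical(unclass(m2$config), unclass(m$config))
  x <- rnorm(32)
  expect_identical(predict(m2, x), predict(m, x))
  saveRDS(list(a = 1), f)
  expect_error(load_fmha(f), "not an ecgfmha checkpoint")
  unlink(f)
})

test_that("predict validates segment shape", {
  m <- fmha_init(tiny_cfg())
  expect_error(predict(m, rnorm(33)), "not a multiple")
  expect_error(predict(m, matrix(rnorm(16), 16)), "32")
  # a long vector is segmented, denoised and re-concatenated
  v <- rnorm(96)
  out <- predict(m, v)
  expect_identical(length(out), 96L)
  expect_equal(out[33:64], as.numeric(predict(m, v[33:64])), tolerance = 1e-6)
})
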