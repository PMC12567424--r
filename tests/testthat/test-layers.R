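test_that("the residual block reduces to ReLU(x) with zero weights", {
  C <- 6L; L <- 20L; k <- 5L
  zero <- list(W1 = matrix(0, C * k, C), b1 = numeric(C),
               W2 = matrix(0, C * k, C), b2 = numeric(C))
  set.seed(20)
  x <- matrix(rnorm(C * L), C, L)
  expect_equal(residual_block(x, zero, k), pmax(x, 0))
  rp <- list(W1 = matrix(rnorm(C * k * C, sd = 0.1), C * k, C), b1 = rnorm(C),
             W2 = matrix(rnorm(C * k * C, sd = 0.1), C * k, C), b2 = rnorm(C))
  y <- residual_block(x, rp, k)
  expect_identical(dim(y), dim(x))
  expect_true(all(y >= 0))
  expect_error(residual_block(matrix(0, C + 1, L), rp, k), "channel mismatch")
})

test_that("same-length convolution matches a direct sliding-window oracle", {
  set.seed(21)
  C <- 3L; L <- 12L; k <- 5L; pad <- 2L
  x <- matrix(rnorm(C * L), C, L)
  W <- matrix(rnorm(C * k * C), C * k, C)
  b <- rnorm(C)
  got <- ecgfmha:::.conv1d(x, W, b, k)
  want <- matrix(0, C, L)
  for (co in 1:C) for (j in 1:L) {
    acc <- b[co]
    for (t in 0:(k - 1)) for (ci in 1:C) {
      jj <- j + t - pad
      if (jj >= 1 && jj <= L) acc <- acc + x[ci, jj] * W[t * C + ci, co]
    }
    want[co, j] <- acc
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("self-attention matches a three-nested-loop oracle and is row-stochastic", {
  set.seed(22)
  C <- 8L; L <- 4L; h <- 2L
  p <- rand_attn_params(C)
  x <- matrix(rnorm(C * L), C, L)
  got <- mhsa(x, p, h, return_attention = TRUE)
  want <- attention_oracle(t(x), t(x), p, h)
  expect_equal(got$output, t(want), tolerance = 1e-10)
  for (A in got$attention) {
    expect_equal(rowSums(A), rep(1, L), tolerance = 1e-6)
    expect_identical(dim(A), c(L, L))
  }
  # single token: the attention weight is the scalar 1, so the output is
  # (x Wv + bv) Wo + bo regardless of the query/key projections
  x1 <- matrix(rnorm(C), C, 1L)
  v <- sweep(t(x1) %*% p$Wv, 2, p$bv, "+")
  expect_equal(mhsa(x1, p, h), t(sweep(v %*% p$Wo, 2, p$bo, "+")), tolerance = 1e-12)
  p2 <- p; p2$Wq <- matrix(rnorm(C * C), C)
  expect_equal(mhsa(x1, p, h), mhsa(x1, p2, h), tolerance = 1e-12)
})

test_that("cross-attention takes queries from F and keys/values from E", {
  set.seed(23)
  C <- 8L; Lf <- 4L; Le <- 2L; h <- 2L
  p <- rand_attn_params(C)
  f <- matrix(rnorm(C * Lf), C, Lf)
  e <- matrix(rnorm(C * Le), C, Le)
  got <- mhca(f, e, p, h, return_attention = TRUE)
  want <- attention_oracle(t(f), t(e), p, h)
  expect_equal(got$output, t(want), tolerance = 1e-10)
  for (A in got$attention) {
    expect_identical(dim(A), c(Lf, Le))
    expect_equal(rowSums(A), rep(1, Lf), tolerance = 1e-6)
  }
  # a single key/value token: every attention weight is exactly 1
  e1 <- matrix(rnorm(C), C, 1L)
  g1 <- mhca(f, e1, p, h, return_attention = TRUE)
  for (A in g1$attention) expect_equal(as.numeric(A), rep(1, Lf))
  expect_error(mhca(f, matrix(0, C + 2, 3), p, h), "channel mismatch")
})

test_that("the feed-forward network is position-wise with a ReLU between layers", {
  set.seed(24)
  C <- 8L; dff <- 16L; L <- 3L
  p <- rand_ffn_params(C, dff)
  x <- matrix(rnorm(C * L), C, L)
  got <- ffn(x, p)
  # per-position loop oracle
  want <- matrix(0, C, L)
  for (j in 1:L) {
    hdn <- pmax(as.numeric(x[, j] %*% p$W1) + p$b1, 0)
    want[, j] <- as.numeric(hdn %*% p$W2) + p$b2
  }
  expect_equal(got, want, tolerance = 1e-12)
  z <- list(W1 = matrix(0, C, dff), b1 = numeric(dff),
            W2 = matrix(0, dff, C), b2 = rnorm(C))
  expect_equal(ffn(x, z), matrix(z$b2, C, L), tolerance = 1e-12)
})

test_that("layer normalization standardizes each time step over channels", {
  set.seed(25)
  x <- matrix(rnorm(6 * 10, mean = 3, sd = 2), 6, 10)
  y <- layer_norm(x, rep(1, 6), rep(0, 6))
  expect_equal(colMeans(y), numeric(10), tolerance = 1e-10)
  expect_equal(apply(y, 2, function(v) mean(v^2)), rep(1, 10), tolerance = 1e-4)
  g <- rnorm(6); b <- rnorm(6)
  expect_equal(layer_norm(x, g, b), sweep(sweep(y, 1, g, "*"), 1, b, "+"),
               tolerance = 1e-12)
})

test_that("channel attention maps are row-stochastic and length-agnostic in shape", {
  set.seed(26)
  C <- 8L; h <- 2L; dff <- 16L
  p <- list(attn = rand_attn_params(C),
            ln1 = list(g = rep(1, C), b = numeric(C)),
            ffn = rand_ffn_params(C, dff),
            ln2 = list(g = rep(1, C), b = numeric(C)))
  for (L in c(16L, 5L)) {
    x <- matrix(rnorm(C * L), C, L)
    got <- channel_mhsa(x, p, h, return_attention = TRUE)
    expect_identical(dim(got$output), c(C, L))
    for (A in got$attention) {
      expect_identical(dim(A), c(C %/% h, C %/% h))
      expect_equal(rowSums(A), rep(1, C %/% h), tolerance = 1e-6)
    }
  }
})

test_that("encoder and decoder stages halve and double the feature length", {
  set.seed(27)
  C <- 8L; h <- 2L; dff <- 16L; k <- 5L
  mk_stage <- function(pw_in, pw_out) list(
    res = list(W1 = matrix(rnorm(C * k * C, sd = .1), C * k, C), b1 = rnorm(C),
               W2 = matrix(rnorm(C * k * C, sd = .1), C * k, C), b2 = rnorm(C)),
    pw = list(W = matrix(rnorm(pw_in * pw_out, sd = .1), pw_in, pw_out),
              b = rnorm(pw_out)),
    attn = rand_attn_params(C),
    ln1 = list(g = rep(1, C), b = numeric(C)),
    ffn = rand_ffn_params(C, dff),
    ln2 = list(g = rep(1, C), b = numeric(C)))
  x <- matrix(rnorm(C * 32), C, 32)
  enc <- encoder_block(x, mk_stage(2L * C, C), h, k)
  expect_identical(dim(enc), c(C, 16L))
  e <- matrix(rnorm(C * 4), C, 4)
  dec <- decoder_block(enc, e, mk_stage(C, 2L * C), h, k)
  expect_identical(dim(dec), c(C, 32L))
  expect_error(encoder_block(x[, 1:31], mk_stage(2L * C, C), h, k), "even")
})
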