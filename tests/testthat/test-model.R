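test_that("attention is the identity for a single spot and uniform for zeros", {
  fx <- matrix(c(1.3, -0.2, 4), 1, 3)
  expect_equal(attention(fx), fx)
  z <- matrix(0, 6, 4)
  at <- attention(z)
  expect_equal(at, z)
  S <- ressat:::attention_full(z, 4)$S
  expect_equal(S, matrix(1 / 6, 6, 6))
})

test_that("attention matches the brute-force oracle and is row-stochastic", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(2:12, 1); d <- sample(2:8, 1)
    fx <- matrix(rnorm(n * d, sd = 2), n, d)
    expect_equal(attention(fx), bf_attention(fx), tolerance = 1e-6)
    S <- ressat:::attention_full(fx, d)$S
    expect_equal(rowSums(S), rep(1, n), tolerance = 1e-6)
    expect_true(all(S >= 0))
  }
})

test_that("attention is permutation-equivariant", {
  set.seed(7)
  fx <- matrix(rnorm(24), 8, 3)
  p <- sample(8)
  expect_equal(attention(fx)[p, ], attention(fx[p, ]), tolerance = 1e-12)
})

test_that("attention rejects non-finite input and bad scale", {
  fx <- matrix(c(1, NA, 0, 1), 2, 2)
  expect_error(attention(fx), "non-finite")
  expect_error(attention(matrix(1, 2, 2), scale_dim = -1), "positive")
})

test_that("attended rows stay in the convex hull of the direct rows", {
  set.seed(21)
  fx <- matrix(rnorm(40), 10, 4)
  at <- attention(fx)
  for (g in 1:4) {
    expect_gte(min(at[, g]), min(fx[, g]) - 1e-12)
    expect_lte(max(at[, g]), max(fx[, g]) + 1e-12)
  }
})

test_that("dual loss decomposes additively and matches hand values", {
  y <- matrix(1, 1, 1)
  rep1 <- dual_loss(y, matrix(0, 1, 1), matrix(3, 1, 1))
  expect_equal(rep1$l_direct, 1)
  expect_equal(rep1$l_attended, 4)
  expect_equal(rep1$l_total, 5)

  perfect <- dual_loss(y, y, y)
  expect_identical(perfect$l_total, 0)

  set.seed(5)
  yt <- matrix(rnorm(12), 4, 3)
  pd <- matrix(rnorm(12), 4, 3)
  pa <- matrix(rnorm(12), 4, 3)
  got <- dual_loss(yt, pd, pa)
  acc_d <- 0; acc_a <- 0
  for (i in 1:4) for (j in 1:3) {
    acc_d <- acc_d + (yt[i, j] - pd[i, j])^2
    acc_a <- acc_a + (yt[i, j] - pa[i, j])^2
  }
  expect_equal(got$l_direct, acc_d / 12, tolerance = 1e-9)
  expect_equal(got$l_attended, acc_a / 12, tolerance = 1e-9)
  expect_identical(got$l_total, got$l_direct + got$l_attended)
  expect_error(dual_loss(yt, pd[1:3, ], pa), "shape")
})

test_that("forward_direct handles the empty batch and duplicates deterministically", {
  m <- spot_predictor(4, patch_size = 16L, channels = c(2L, 3L, 4L),
                      hidden_dim = 6L, seed = 2)
  empty <- patch_set(array(0, dim = c(0, 3, 16, 16)), character(0))
  out0 <- forward_direct(m, empty)
  expect_equal(dim(out0), c(0L, 4L))

  arr <- array(runif(2 * 3 * 16 * 16, 0, 255), dim = c(2, 3, 16, 16))
  arr[2, , , ] <- arr[1, , , ]
  ps <- patch_set(arr, c("a", "b"))
  out <- forward_direct(m, ps)
  expect_equal(out["a", ], out["b", ], ignore_attr = TRUE)
  expect_identical(forward_direct(m, ps), out)
})

test_that("forward_direct rejects a patch-size mismatch", {
  m <- spot_predictor(2, patch_size = 16L, seed = 1)
  ps <- patch_set(array(0, dim = c(1, 3, 32, 32)), "a")
  expect_error(forward_direct(m, ps), "does not match")
})

test_that("the CNN forward pass matches a direct-convolution oracle", {
  # independently re-trace tiny_cnn (P = 16: stem is the identity) with
  # quadruple-loop convolutions on plain arrays
  set.seed(33)
  P <- 16L
  m <- spot_predictor(3, patch_size = P, backbone_kind = "tiny_cnn",
                      channels = c(2L, 2L, 3L), hidden_dim = 4L, seed = 8)
  arr <- array(runif(1 * 3 * P * P, 0, 255), dim = c(1, 3, P, P))
  got <- forward_direct(m, patch_set(arr, "s"))

  x <- aperm(arr[1, , , ], c(2, 3, 1)) / 127.5 - 1 # H x W x C
  w <- m$weights
  to_arr <- function(W_mat, cin, cout) {
    # package weight rows are ordered (offset dw-fast within dh, channel)
    a <- array(0, dim = c(3, 3, cin, cout))
    k <- 1L
    for (dh in 1:3) for (dw in 1:3) {
      for (ci in 1:cin) {
        a[dh, dw, ci, ] <- W_mat[(k - 1L) * cin + ci, ]
      }
      k <- k + 1L
    }
    a
  }
  relu <- function(a) pmax(a, 0)
  pool2 <- function(a) {
    H <- dim(a)[1] / 2; W <- dim(a)[2] / 2; C <- dim(a)[3]
    out <- array(0, dim = c(H, W, C))
    for (h in 1:H) for (wd in 1:W) for (cc in 1:C)
      out[h, wd, cc] <- mean(a[(2 * h - 1):(2 * h), (2 * wd - 1):(2 * wd), cc])
    out
  }
  h1 <- pool2(relu(bf_conv3(x, to_arr(w$conv1_W, 3, 2), w$conv1_b)))
  h2 <- pool2(relu(bf_conv3(h1, to_arr(w$conv2_W, 2, 2), w$conv2_b)))
  h3 <- relu(bf_conv3(h2, to_arr(w$conv3_W, 2, 3), w$conv3_b))
  emb <- apply(h3, 3, mean)
  hid <- relu(as.vector(emb %*% w$head_W1) + w$head_b1)
  expected <- as.vector(hid %*% w$head_W2) + w$head_b2
  expect_equal(as.vector(got), expected, tolerance = 1e-10)
})

test_that("forward_full returns consistent branches", {
  set.seed(9)
  m <- spot_predictor(3, patch_size = 16L, channels = c(2L, 2L, 3L),
                      hidden_dim = 4L, seed = 4)
  arr <- array(runif(5 * 3 * 16 * 16, 0, 255), dim = c(5, 3, 16, 16))
  ps <- patch_set(arr, paste0("s", 1:5))
  both <- forward_full(m, ps)
  expect_equal(both$pred_attended,
               attention(both$pred_direct, ncol(both$pred_direct)),
               ignore_attr = TRUE)

  one <- patch_set(arr[1, , , , drop = FALSE], "s1")
  b1 <- forward_full(m, one)
  expect_equal(b1$pred_attended, b1$pred_direct)
})

test_that("uniform mixing of identical prediction rows is the identity", {
  fx <- matrix(rep(c(0.4, -1.2, 2), each = 7), 7, 3)
  expect_equal(attention(fx), fx, tolerance = 1e-12)
})

test_that("a 64-spot tiny_cnn forward stays inside the smoke-test budget", {
  m <- spot_predictor(10, patch_size = 64L, seed = 1)
  arr <- array(runif(64 * 3 * 64 * 64, 0, 255), dim = c(64, 3, 64, 64))
  ps <- patch_set(arr, sprintf("s%02d", 1:64))
  invisible(forward_full(m, ps)) # warm the index caches
  elapsed <- system.time(forward_full(m, ps))[["elapsed"]]
  expect_lt(elapsed, 1)
})
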