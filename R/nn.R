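# Internal neural-network primitives.
#
# Batch activations are stored as a dense matrix `mat` of shape
# (B*H*W) x C with rows ordered batch-major then row-major in pixels:
# row = (b-1)*H*W + (h-1)*W + w. Convolutions are 3x3, stride 1,
# zero-padded, realized as an im2col gather followed by one matrix
# multiplication; gather index tables are cached per (B, H, W). All
# gradients are derived by hand; no autodiff framework is involved.

.nn_cache <- new.env(parent = emptyenv())

act <- function(mat, B, H, W) list(mat = mat, B = B, H = H, W = W)

# Gather table for a 3x3 zero-padded convolution: (B*H*W) x 9 source-row
# indices, with the sentinel B*H*W + 1 pointing at an appended zero row.
conv3_idx <- function(B, H, W) {
  key <- sprintf("c3_%d_%d_%d", B, H, W)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  hh <- rep(seq_len(H), each = W)
  ww <- rep(seq_len(W), H)
  offs <- expand.grid(dw = -1:1, dh = -1:1) # dh slow => column blocks by dh
  idx1 <- matrix(NA_integer_, H * W, 9L)
  for (j in seq_len(9L)) {
    sh <- hh + offs$dh[j]; sw <- ww + offs$dw[j]
    ok <- sh >= 1L & sh <= H & sw >= 1L & sw <= W
    src <- (sh - 1L) * W + sw
    src[!ok] <- NA_integer_
    idx1[, j] <- src
  }
  base <- rep((seq_len(B) - 1L) * H * W, each = H * W)
  idx <- idx1[rep(seq_len(H * W), B), , drop = FALSE] + base
  idx[is.na(idx)] <- B * H * W + 1L
  .nn_cache[[key]] <- idx
  idx
}

conv3_forward <- function(x, W_mat, b_vec) {
  idx <- conv3_idx(x$B, x$H, x$W)
  padded <- rbind(x$mat, 0)
  cin <- ncol(x$mat)
  xcol <- matrix(0, nrow(x$mat), 9L * cin)
  for (j in seq_len(9L))
    xcol[, ((j - 1L) * cin + 1L):(j * cin)] <- padded[idx[, j], , drop = FALSE]
  out <- xcol %*% W_mat
  out <- sweep(out, 2L, b_vec, "+")
  list(out = act(out, x$B, x$H, x$W),
       cache = list(xcol = xcol, idx = idx, cin = cin, W_mat = W_mat,
                    n = nrow(x$mat)))
}

conv3_backward <- function(dout, cache) {
  dW <- crossprod(cache$xcol, dout$mat)
  db <- colSums(dout$mat)
  dxcol <- dout$mat %*% t(cache$W_mat)
  cin <- cache$cin
  dx <- matrix(0, cache$n + 1L, cin)
  for (j in seq_len(9L)) {
    # each offset maps output pixels to distinct input rows (pad row aside)
    tgt <- cache$idx[, j]
    part <- dxcol[, ((j - 1L) * cin + 1L):(j * cin), drop = FALSE]
    dx[tgt, ] <- dx[tgt, , drop = FALSE] + part
  }
  list(dx = act(dx[-(cache$n + 1L), , drop = FALSE], dout$B, dout$H, dout$W),
       dW = dW, db = db)
}

relu_forward <- function(x) {
  mask <- x$mat > 0
  list(out = act(x$mat * mask, x$B, x$H, x$W), cache = mask)
}

relu_backward <- function(dout, mask) act(dout$mat * mask, dout$B, dout$H, dout$W)

pool2_idx <- function(B, H, W) {
  key <- sprintf("p2_%d_%d_%d", B, H, W)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Ho <- H %/% 2L; Wo <- W %/% 2L
  h2 <- rep(seq_len(Ho), each = Wo)
  w2 <- rep(seq_len(Wo), Ho)
  idx1 <- matrix(0L, Ho * Wo, 4L)
  k <- 1L
  for (a in 0:1) for (b in 0:1) {
    idx1[, k] <- (2L * h2 - 2L + a) * W + (2L * w2 - 1L + b)
    k <- k + 1L
  }
  base <- rep((seq_len(B) - 1L) * H * W, each = Ho * Wo)
  idx <- idx1[rep(seq_len(Ho * Wo), B), , drop = FALSE] + base
  .nn_cache[[key]] <- idx
  idx
}

pool2_forward <- function(x) {
  idx <- pool2_idx(x$B, x$H, x$W)
  m <- (x$mat[idx[, 1], , drop = FALSE] + x$mat[idx[, 2], , drop = FALSE] +
        x$mat[idx[, 3], , drop = FALSE] + x$mat[idx[, 4], , drop = FALSE]) / 4
  list(out = act(m, x$B, x$H %/% 2L, x$W %/% 2L),
       cache = list(idx = idx, n_in = nrow(x$mat), H = x$H, W = x$W))
}

pool2_backward <- function(dout, cache) {
  dx <- matrix(0, cache$n_in, ncol(dout$mat))
  g <- dout$mat / 4
  for (k in 1:4) dx[cache$idx[, k], ] <- dx[cache$idx[, k], , drop = FALSE] + g
  act(dx, dout$B, cache$H, cache$W)
}

# Adaptive average pooling to a fixed out_hw x out_hw spatial size,
# expressed as one cached sparse matrix per (B, H, W, out_hw).
adapt_pool_mat <- function(B, H, W, out_hw) {
  key <- sprintf("ap_%d_%d_%d_%d", B, H, W, out_hw)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  bins <- function(n) {
    lo <- floor((seq_len(out_hw) - 1L) * n / out_hw) + 1L
    hi <- ceiling(seq_len(out_hw) * n / out_hw)
    list(lo = lo, hi = hi)
  }
  rb <- bins(H); cb <- bins(W)
  for (i in seq_len(out_hw)) for (j in seq_len(out_hw)) {
    r <- rb$lo[i]:rb$hi[i]; c <- cb$lo[j]:cb$hi[j]
    src <- as.vector(outer((r - 1L) * W, c, `+`))
    orow <- (i - 1L) * out_hw + j
    rows <- c(rows, rep(orow, length(src)))
    cols <- c(cols, src)
    vals <- c(vals, rep(1 / length(src), length(src)))
  }
  P1 <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                             dims = c(out_hw^2, H * W))
  Pb <- Matrix::bdiag(rep(list(P1), B))
  .nn_cache[[key]] <- Pb
  Pb
}

adapt_pool_forward <- function(x, out_hw) {
  if (x$H == out_hw && x$W == out_hw)
    return(list(out = x, cache = list(identity = TRUE)))
  Pb <- adapt_pool_mat(x$B, x$H, x$W, out_hw)
  list(out = act(as.matrix(Pb %*% x$mat), x$B, out_hw, out_hw),
       cache = list(identity = FALSE, Pb = Pb, H = x$H, W = x$W))
}

adapt_pool_backward <- function(dout, cache) {
  if (isTRUE(cache$identity)) return(dout)
  act(as.matrix(Matrix::crossprod(cache$Pb, dout$mat)),
      dout$B, cache$H, cache$W)
}

gap_forward <- function(x) {
  grp <- rep(seq_len(x$B), each = x$H * x$W)
  out <- rowsum(x$mat, grp) / (x$H * x$W)
  list(out = out, cache = list(B = x$B, H = x$H, W = x$W))
}

gap_backward <- function(dout, cache) {
  act(dout[rep(seq_len(cache$B), each = cache$H * cache$W), , drop = FALSE] /
        (cache$H * cache$W),
      cache$B, cache$H, cache$W)
}

dense_forward <- function(x_mat, W_mat, b_vec) {
  out <- sweep(x_mat %*% W_mat, 2L, b_vec, "+")
  list(out = out, cache = x_mat)
}

dense_backward <- function(dout, cache, W_mat) {
  list(dx = dout %*% t(W_mat), dW = crossprod(cache, dout), db = colSums(dout))
}

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# Converts an N x 3 x P x P patch array (0-255) to the internal
# activation layout, rescaled to [-1, 1].
patches_to_act <- function(arr) {
  d <- dim(arr)
  x <- arr / 127.5 - 1
  # target row order: w fastest, then h, then b; columns = channels
  m <- aperm(x, c(4L, 3L, 1L, 2L)) # (w, h, b, ch)
  dim(m) <- c(d[4] * d[3] * d[1], 3L)
  # aperm gave (w, h, b) nesting with b slowest only if dims ordered so;
  # (w,h,b,ch) flattens w fastest, then h, then b -- as required.
  act(m, d[1], d[3], d[4])
}
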