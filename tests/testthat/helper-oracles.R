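# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops, no shared code with the package
# implementation) so they are credible references.

# Scaled dot-product self-attention, one row at a time.
bf_attention <- function(fx, scale_dim = ncol(fx)) {
  n <- nrow(fx); d <- ncol(fx)
  out <- matrix(0, n, d)
  for (i in seq_len(n)) {
    logits <- numeric(n)
    for (j in seq_len(n))
      logits[j] <- sum(fx[i, ] * fx[j, ]) / sqrt(scale_dim)
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    for (j in seq_len(n)) out[i, ] <- out[i, ] + w[j] * fx[j, ]
  }
  out
}

# Pearson correlation from the covariance / sd definition.
bf_pcc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  cv <- sum((x - mx) * (y - my)) / (n - 1)
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  if (sx == 0 || sy == 0) return(NA_real_)
  cv / (sx * sy)
}

# Mean per-gene correlation by an explicit per-gene loop.
bf_mean_pcc <- function(truth, pred) {
  rs <- numeric(0)
  for (g in seq_len(ncol(truth))) {
    r <- bf_pcc(truth[, g], pred[, g])
    if (!is.na(r)) rs <- c(rs, r)
  }
  mean(rs)
}

# Top-k' HEG metric: sort genes by mean predicted expression, then
# average the per-gene correlations of the winners.
bf_top_heg <- function(truth, pred, k_prime) {
  mu <- apply(pred, 2, mean)
  ord <- order(-mu, colnames(pred))
  ids <- colnames(pred)[ord[seq_len(k_prime)]]
  rs <- numeric(0)
  for (g in ids) {
    r <- bf_pcc(truth[, g], pred[, g])
    if (!is.na(r)) rs <- c(rs, r)
  }
  list(mean = mean(rs), ids = ids)
}

# Per-section variance ranking and union, by explicit sorting.
bf_hvg_union <- function(mats, n_hvg) {
  tops <- lapply(mats, function(m) {
    v <- numeric(ncol(m))
    for (g in seq_len(ncol(m))) v[g] <- stats::var(m[, g])
    names(v) <- colnames(m)
    ord <- order(-v, colnames(m))
    colnames(m)[ord[seq_len(n_hvg)]]
  })
  sort(Reduce(union, tops))
}

# Moran's I with rook adjacency on an (array_row, array_col) grid,
# computed by the textbook double loop.
bf_morans_i <- function(values, array_row, array_col) {
  n <- length(values)
  xbar <- mean(values)
  num <- 0; wsum <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    w <- as.numeric(abs(array_row[i] - array_row[j]) +
                      abs(array_col[i] - array_col[j]) == 1)
    num <- num + w * (values[i] - xbar) * (values[j] - xbar)
    wsum <- wsum + w
  }
  den <- sum((values - xbar)^2)
  (n / wsum) * (num / den)
}

# Direct (quadruple-loop) 3x3 zero-padded convolution on an
# (H, W, Cin) array; weights indexed [dh, dw, cin, cout].
bf_conv3 <- function(x, w_arr, b_vec) {
  H <- dim(x)[1]; W <- dim(x)[2]
  cin <- dim(x)[3]; cout <- dim(w_arr)[4]
  out <- array(0, dim = c(H, W, cout))
  for (h in 1:H) for (wd in 1:W) for (co in 1:cout) {
    acc <- b_vec[co]
    for (dh in -1:1) for (dw in -1:1) {
      sh <- h + dh; sw <- wd + dw
      if (sh >= 1 && sh <= H && sw >= 1 && sw <= W)
        for (ci in 1:cin)
          acc <- acc + x[sh, sw, ci] * w_arr[dh + 2, dw + 2, ci, co]
    }
    out[h, wd, co] <- acc
  }
  out
}
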