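#' Construct a spot-expression predictor
#'
#' Builds the composed model: an image backbone `F` mapping a
#' `3 x P x P` patch to an embedding, and a two-layer refinement head
#' `G` mapping the embedding to a `d`-dimensional expression prediction.
#' The non-parametric self-attention module that mixes predictions
#' across spots ([attention()]) has no weights and therefore lives
#' outside the parameter set.
#'
#' Backbones:
#' \describe{
#'   \item{`tiny_cnn`}{an adaptive average-pool stem to 16x16 followed by
#'     three 3x3 conv blocks (ReLU, 2x2 average pooling) and global
#'     average pooling; the compact test/benchmark backbone.}
#'   \item{`resnet`}{the residual variant: a stem convolution followed by
#'     two residual blocks (two 3x3 convs each, identity skip) with
#'     pooling between, then global average pooling.}
#'   \item{`frozen_linear`}{the backbone-ablation control: a frozen random
#'     linear map over flattened 8x-downsampled grayscale pixels; only
#'     the head `G` trains.}
#' }
#'
#' @param n_genes output dimension `d` of the head.
#' @param patch_size patch side in pixels (even, >= 8).
#' @param backbone_kind `"tiny_cnn"`, `"resnet"`, or `"frozen_linear"`.
#' @param channels integer vector of three channel widths for the conv
#'   blocks (the residual backbone uses the last entry throughout).
#' @param hidden_dim width of the head's hidden layer.
#' @param seed integer seed for weight initialization.
#' @return An object of class `spot_predictor`.
#' @export
spot_predictor <- function(n_genes, patch_size = 224L,
                           backbone_kind = c("tiny_cnn", "resnet",
                                             "frozen_linear"),
                           channels = c(8L, 16L, 32L), hidden_dim = 64L,
                           seed = 1L) {
  backbone_kind <- match.arg(backbone_kind)
  patch_size <- as.integer(patch_size)
  if (patch_size < 8L || patch_size %% 2L != 0L)
    abort("`patch_size` must be an even integer >= 8.")
  if (n_genes < 1L) abort("`n_genes` must be >= 1.")
  set.seed(as.integer(seed))
  ch <- as.integer(channels)
  w <- list()
  frozen <- NULL
  if (backbone_kind == "tiny_cnn") {
    w$conv1_W <- he_init(9L * 3L, ch[1], 27)
    w$conv1_b <- numeric(ch[1])
    w$conv2_W <- he_init(9L * ch[1], ch[2], 9 * ch[1])
    w$conv2_b <- numeric(ch[2])
    w$conv3_W <- he_init(9L * ch[2], ch[3], 9 * ch[2])
    w$conv3_b <- numeric(ch[3])
    emb <- ch[3]
  } else if (backbone_kind == "resnet") {
    C <- ch[3]
    w$conv0_W <- he_init(9L * 3L, C, 27)
    w$conv0_b <- numeric(C)
    for (blk in c("r1", "r2")) {
      w[[paste0(blk, "a_W")]] <- he_init(9L * C, C, 9 * C)
      w[[paste0(blk, "a_b")]] <- numeric(C)
      w[[paste0(blk, "b_W")]] <- he_init(9L * C, C, 9 * C)
      w[[paste0(blk, "b_b")]] <- numeric(C)
    }
    emb <- C
  } else {
    side <- max(2L, patch_size %/% 8L)
    emb <- 64L
    frozen <- matrix(rnorm(side^2 * emb, sd = sqrt(1 / side^2)), side^2, emb)
  }
  w$head_W1 <- he_init(emb, hidden_dim, emb)
  w$head_b1 <- numeric(hidden_dim)
  w$head_W2 <- matrix(rnorm(hidden_dim * n_genes, sd = sqrt(1 / hidden_dim)),
                      hidden_dim, n_genes)
  w$head_b2 <- numeric(n_genes)
  structure(list(backbone_kind = backbone_kind, patch_size = patch_size,
                 n_genes = as.integer(n_genes), channels = ch,
                 hidden_dim = as.integer(hidden_dim), embedding_dim = emb,
                 weights = w, frozen = frozen, seed = as.integer(seed)),
            class = "spot_predictor")
}

#' @export
print.spot_predictor <- function(x, ...) {
  n_par <- sum(vapply(x$weights, length, 1L))
  cat(sprintf("<spot_predictor> backbone \"%s\", patch %d px, %d genes, %d trainable parameters\n",
              x$backbone_kind, x$patch_size, x$n_genes, n_par))
  invisible(x)
}

# Forward pass through F and G with optional backprop caches.
model_forward <- function(model, x_act, keep_cache = FALSE) {
  w <- model$weights
  caches <- list()
  if (model$backbone_kind == "frozen_linear") {
    side <- max(2L, model$patch_size %/% 8L)
    gray <- rowMeans(x_act$mat)
    g_act <- act(matrix(gray, ncol = 1L), x_act$B, x_act$H, x_act$W)
    ap <- adapt_pool_forward(g_act, side)
    z <- matrix(ap$out$mat, nrow = x_act$B, byrow = TRUE) # B x side^2
    e <- z %*% model$frozen
  } else if (model$backbone_kind == "tiny_cnn") {
    st <- adapt_pool_forward(x_act, 16L); caches$stem <- st$cache
    h <- st$out
    for (k in 1:3) {
      cv <- conv3_forward(h, w[[paste0("conv", k, "_W")]],
                          w[[paste0("conv", k, "_b")]])
      caches[[paste0("conv", k)]] <- cv$cache
      rl <- relu_forward(cv$out)
      caches[[paste0("relu", k)]] <- rl$cache
      h <- rl$out
      if (k < 3) {
        pl <- pool2_forward(h)
        caches[[paste0("pool", k)]] <- pl$cache
        h <- pl$out
      }
    }
    gp <- gap_forward(h); caches$gap <- gp$cache
    e <- gp$out
  } else { # resnet
    st <- adapt_pool_forward(x_act, 16L); caches$stem <- st$cache
    cv0 <- conv3_forward(st$out, w$conv0_W, w$conv0_b); caches$conv0 <- cv0$cache
    rl0 <- relu_forward(cv0$out); caches$relu0 <- rl0$cache
    h <- rl0$out
    for (blk in c("r1", "r2")) {
      cva <- conv3_forward(h, w[[paste0(blk, "a_W")]], w[[paste0(blk, "a_b")]])
      rla <- relu_forward(cva$out)
      cvb <- conv3_forward(rla$out, w[[paste0(blk, "b_W")]],
                           w[[paste0(blk, "b_b")]])
      s <- act(h$mat + cvb$out$mat, h$B, h$H, h$W) # identity skip
      rls <- relu_forward(s)
      caches[[blk]] <- list(cva = cva$cache, rla = rla$cache,
                            cvb = cvb$cache, rls = rls$cache)
      h <- rls$out
      pl <- pool2_forward(h)
      caches[[paste0(blk, "_pool")]] <- pl$cache
      h <- pl$out
    }
    gp <- gap_forward(h); caches$gap <- gp$cache
    e <- gp$out
  }
  d1 <- dense_forward(e, w$head_W1, w$head_b1); caches$head1 <- d1$cache
  hrel <- d1$out > 0
  caches$head_relu <- hrel
  d2 <- dense_forward(d1$out * hrel, w$head_W2, w$head_b2)
  caches$head2 <- d2$cache
  list(pred = d2$out, caches = if (keep_cache) caches else NULL)
}

# Backward pass: dpred (N x d) -> gradients for every trainable weight.
model_backward <- function(model, dpred, caches) {
  w <- model$weights
  g <- list()
  b2 <- dense_backward(dpred, caches$head2, w$head_W2)
  g$head_W2 <- b2$dW; g$head_b2 <- b2$db
  dh1 <- b2$dx * caches$head_relu
  b1 <- dense_backward(dh1, caches$head1, w$head_W1)
  g$head_W1 <- b1$dW; g$head_b1 <- b1$db
  de <- b1$dx
  if (model$backbone_kind == "frozen_linear") {
    return(g) # frozen backbone: no further gradients
  }
  if (model$backbone_kind == "tiny_cnn") {
    dh <- gap_backward(de, caches$gap)
    for (k in 3:1) {
      if (k < 3) dh <- pool2_backward(dh, caches[[paste0("pool", k)]])
      dh <- relu_backward(dh, caches[[paste0("relu", k)]])
      cb <- conv3_backward(dh, caches[[paste0("conv", k)]])
      g[[paste0("conv", k, "_W")]] <- cb$dW
      g[[paste0("conv", k, "_b")]] <- cb$db
      dh <- cb$dx
    }
  } else {
    dh <- gap_backward(de, caches$gap)
    for (blk in c("r2", "r1")) {
      dh <- pool2_backward(dh, caches[[paste0(blk, "_pool")]])
      cc <- caches[[blk]]
      dh <- relu_backward(dh, cc$rls)
      # skip connection: gradient flows both through convs and identity
      cbb <- conv3_backward(dh, cc$cvb)
      g[[paste0(blk, "b_W")]] <- cbb$dW
      g[[paste0(blk, "b_b")]] <- cbb$db
      da <- relu_backward(cbb$dx, cc$rla)
      cba <- conv3_backward(da, cc$cva)
      g[[paste0(blk, "a_W")]] <- cba$dW
      g[[paste0(blk, "a_b")]] <- cba$db
      dh <- act(dh$mat + cba$dx$mat, dh$B, dh$H, dh$W)
    }
    dh <- relu_backward(dh, caches$relu0)
    cb0 <- conv3_backward(dh, caches$conv0)
    g$conv0_W <- cb0$dW; g$conv0_b <- cb0$db
  }
  g
}

#' Direct forward pass `G(F(X))`
#'
#' Maps every patch through the backbone and refinement head, returning
#' the per-spot expression predictions before any spot mixing.
#' Deterministic given fixed weights.
#'
#' @param model a [spot_predictor()].
#' @param patches a [patch_set()] sized per the model.
#' @return An `N x d` numeric matrix with spot ids as rownames.
#' @export
forward_direct <- function(model, patches) {
  stopifnot(inherits(model, "spot_predictor"), inherits(patches, "patch_set"))
  if (patch_side(patches) != model$patch_size)
    abort(sprintf("patch size %d does not match the model's configured %d.",
                  patch_side(patches), model$patch_size))
  n <- dim(patches)[1]
  if (n == 0L) {
    out <- matrix(numeric(0), 0L, model$n_genes)
    rownames(out) <- character(0)
    return(out)
  }
  x <- patches_to_act(patches$patches)
  pred <- model_forward(model, x, keep_cache = FALSE)$pred
  rownames(pred) <- patches$spot_ids
  pred
}

#' Non-parametric self-attention over spots
#'
#' Scaled dot-product self-attention with `Q = K = V = fx`: returns
#' `softmax(Q K' / sqrt(scale_dim)) V`, the row-stochastic mixing of
#' per-spot predictions by their pairwise similarity. The module has no
#' learned parameters; softmax rows are computed with per-row max
#' subtraction for numerical stability.
#'
#' @param fx numeric `N x d` matrix of per-spot refined predictions.
#' @param scale_dim positive scalar; the key dimension `d` whose square
#'   root scales the logits. Defaults to `ncol(fx)`.
#' @return An `N x d` matrix of attended predictions.
#' @export
attention <- function(fx, scale_dim = ncol(fx)) {
  fx <- as.matrix(fx)
  if (nrow(fx) < 1L) abort("attention needs at least one spot.")
  if (!all(is.finite(fx))) abort("attention input contains non-finite entries.")
  if (!is.numeric(scale_dim) || scale_dim <= 0)
    abort("`scale_dim` must be positive.")
  attention_full(fx, scale_dim)$out
}

# Returns both the attended output and the weight matrix S (needed for
# backprop and the row-stochasticity checks).
attention_full <- function(fx, scale_dim = ncol(fx)) {
  z <- fx %*% t(fx) / sqrt(scale_dim)
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  s <- e / rowSums(e)
  list(out = s %*% fx, S = s)
}

# d(loss)/d(fx) given d(loss)/d(out); S from attention_full(fx).
attention_backward <- function(fx, S, dout, scale_dim = ncol(fx)) {
  gs <- dout %*% t(fx)              # N x N, dL/dS
  dz <- S * (gs - rowSums(gs * S))  # softmax Jacobian, row-wise
  t(S) %*% dout + (dz %*% fx + t(dz) %*% fx) / sqrt(scale_dim)
}

#' Dual mean-squared-error objective
#'
#' The training objective sums two MSE terms: the direct branch
#' `G(F(X))` against the targets, and the attended branch
#' `A(G(F(X)))` against the same targets. Each term is the mean of the
#' squared residuals over all `N x d` entries; the total is their exact
#' sum.
#'
#' @param y_true,pred_direct,pred_attended numeric `N x d` matrices of
#'   identical shape.
#' @return A `loss_report`: list with `l_direct`, `l_attended`,
#'   `l_total`.
#' @export
dual_loss <- function(y_true, pred_direct, pred_attended) {
  y_true <- as.matrix(y_true)
  pred_direct <- as.matrix(pred_direct)
  pred_attended <- as.matrix(pred_attended)
  if (!identical(dim(y_true), dim(pred_direct)) ||
      !identical(dim(y_true), dim(pred_attended)))
    abort("all three matrices must share one shape.")
  l_direct <- mean((y_true - pred_direct)^2)
  l_attended <- mean((y_true - pred_attended)^2)
  loss_report(l_direct, l_attended)
}

loss_report <- function(l_direct, l_attended) {
  structure(list(l_direct = l_direct, l_attended = l_attended,
                 l_total = l_direct + l_attended),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("<loss_report> direct %.6g + attended %.6g = %.6g\n",
              x$l_direct, x$l_attended, x$l_total))
  invisible(x)
}

#' Full forward pass: direct and attended branches
#'
#' Computes `pred_direct = G(F(X))` and
#' `pred_attended = attention(pred_direct)` over the spot set of the
#' call, returning both so callers can evaluate either branch (the
#' no-SAT ablation uses `pred_direct`).
#'
#' @inheritParams forward_direct
#' @return A list with matrices `pred_direct` and `pred_attended`.
#' @export
forward_full <- function(model, patches) {
  pred_direct <- forward_direct(model, patches)
  pred_attended <- if (nrow(pred_direct) == 0L) pred_direct else
    attention(pred_direct, scale_dim = ncol(pred_direct))
  rownames(pred_attended) <- rownames(pred_direct)
  list(pred_direct = pred_direct, pred_attended = pred_attended)
}
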