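#' Training configuration
#'
#' Optimization settings for [fit_spot_predictor()]. Adam is the
#' optimizer; all randomness (weight init, epoch shuffling) derives from
#' `seed`. `use_sat` toggles the attended branch of the dual objective
#' (the self-attention ablation); `use_backbone` toggles the image
#' backbone (when `FALSE`, `F` becomes a frozen random linear map over
#' downsampled grayscale pixels and only the head trains).
#'
#' @param epochs positive integer, full passes over the spots.
#' @param batch_size spots per optimization step; must be >= 2 when
#'   `use_sat` is `TRUE` (attention over a single spot is a no-op).
#' @param learning_rate positive scalar Adam step size.
#' @param seed integer controlling all randomness.
#' @param use_sat logical, train the attended branch.
#' @param use_backbone logical, train a convolutional backbone.
#' @param backbone_kind `"tiny_cnn"` or `"resnet"` (ignored when
#'   `use_backbone = FALSE`).
#' @param attention_scope `"batch"` (attention over each minibatch during
#'   training) or `"section"` (attention over all spots each step).
#' @param channels,hidden_dim architecture widths, see
#'   [spot_predictor()].
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 128L,
                         learning_rate = 1e-4, seed = 1L, use_sat = TRUE,
                         use_backbone = TRUE,
                         backbone_kind = c("tiny_cnn", "resnet"),
                         attention_scope = c("batch", "section"),
                         channels = c(8L, 16L, 32L), hidden_dim = 64L) {
  backbone_kind <- match.arg(backbone_kind)
  attention_scope <- match.arg(attention_scope)
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (epochs < 1L) abort("`epochs` must be >= 1.")
  if (isTRUE(use_sat) && batch_size < 2L)
    abort("`batch_size` must be >= 2 when `use_sat` is TRUE.")
  if (batch_size < 1L) abort("`batch_size` must be >= 1.")
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 use_sat = isTRUE(use_sat), use_backbone = isTRUE(use_backbone),
                 backbone_kind = backbone_kind,
                 attention_scope = attention_scope,
                 channels = as.integer(channels),
                 hidden_dim = as.integer(hidden_dim)),
            class = "train_config")
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)
}

adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(weights = weights, state = state)
}

#' Fit a spot predictor with the dual MSE objective
#'
#' Trains `F` and `G` by Adam over minibatches of spots. In each step
#' the direct branch predicts every spot of the minibatch from its
#' patch, the attended branch mixes those predictions by non-parametric
#' self-attention over the minibatch (or over the whole section when
#' `attention_scope = "section"`), and the summed MSE of both branches
#' is backpropagated. With `use_sat = FALSE` no gradient flows through
#' attention and the objective reduces to the direct MSE; the attended
#' loss column then simply mirrors the direct one for logging symmetry
#' and `sat_active` is `FALSE` in the history.
#'
#' @param patches a [patch_set()] of training patches.
#' @param targets an [expression_matrix()] with layer `"normalized"` or
#'   `"corrected"`, rows aligned to `patches` spot ids.
#' @param config a [train_config()].
#' @return A `ressat_model`: list with the fitted `model`, a
#'   `loss_history` tibble (one row per epoch: `epoch`, `l_direct`,
#'   `l_attended`, `l_total`, `sat_active`), the `config`, the gene ids,
#'   and a `config_fingerprint` hash.
#' @export
fit_spot_predictor <- function(patches, targets, config = train_config()) {
  stopifnot(inherits(patches, "patch_set"),
            inherits(targets, "expression_matrix"),
            inherits(config, "train_config"))
  if (!targets$layer %in% c("normalized", "corrected"))
    abort("targets must carry the normalized or corrected layer.")
  if (!identical(patches$spot_ids, rownames(targets$values)))
    abort("patches and targets are misaligned: spot ids differ in content or order.")
  y <- targets$values
  n <- nrow(y); d <- ncol(y)
  if (n < 1L) abort("cannot fit on zero spots.")

  kind <- if (config$use_backbone) config$backbone_kind else "frozen_linear"
  model <- spot_predictor(n_genes = d, patch_size = patch_side(patches),
                          backbone_kind = kind, channels = config$channels,
                          hidden_dim = config$hidden_dim, seed = config$seed)
  x_all <- patches_to_act(patches$patches)
  hw <- x_all$H * x_all$W
  state <- adam_init(model$weights)
  set.seed(config$seed + 1L)
  history <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- if (n > 1L) sample.int(n) else 1L
    if (config$attention_scope == "section") {
      batches <- list(ord)
    } else {
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    }
    ep_ld <- 0; ep_la <- 0; ep_n <- 0
    for (bs in batches) {
      rows <- as.vector(outer(seq_len(hw), (bs - 1L) * hw, `+`))
      xb <- act(x_all$mat[rows, , drop = FALSE], length(bs), x_all$H, x_all$W)
      yb <- y[bs, , drop = FALSE]
      fw <- model_forward(model, xb, keep_cache = TRUE)
      pd <- fw$pred
      nb <- length(bs)
      if (config$use_sat) {
        at <- attention_full(pd, d)
        pa <- at$out
        rep_loss <- dual_loss(yb, pd, pa)
        dpa <- 2 * (pa - yb) / (nb * d)
        dpd <- 2 * (pd - yb) / (nb * d) +
          attention_backward(pd, at$S, dpa, d)
      } else {
        l_dir <- mean((yb - pd)^2)
        rep_loss <- loss_report(l_dir, l_dir)
        dpd <- 2 * (pd - yb) / (nb * d)
      }
      if (!is.finite(rep_loss$l_total))
        abort(sprintf("non-finite loss at epoch %d; lower the learning rate.",
                      epoch))
      grads <- model_backward(model, dpd, fw$caches)
      upd <- adam_step(model$weights, grads, state, config$learning_rate)
      model$weights <- upd$weights
      state <- upd$state
      ep_ld <- ep_ld + rep_loss$l_direct * nb
      ep_la <- ep_la + rep_loss$l_attended * nb
      ep_n <- ep_n + nb
    }
    history[[epoch]] <- tibble(epoch = epoch,
                               l_direct = ep_ld / ep_n,
                               l_attended = ep_la / ep_n,
                               l_total = (ep_ld + ep_la) / ep_n,
                               sat_active = config$use_sat)
  }

  fingerprint <- hash_object(list(config = unclass(config), n = n, d = d,
                                  patch_size = patch_side(patches)))
  structure(list(model = model, loss_history = bind_rows(history),
                 config = config, gene_ids = colnames(y),
                 target_layer = targets$layer,
                 config_fingerprint = fingerprint),
            class = "ressat_model")
}

#' @export
print.ressat_model <- function(x, ...) {
  last <- x$loss_history[nrow(x$loss_history), ]
  cat(sprintf("<ressat_model> %s backbone, %d genes, %d epochs (final L = %.5g), SAT %s\n",
              x$model$backbone_kind, length(x$gene_ids),
              nrow(x$loss_history), last$l_total,
              if (x$config$use_sat) "on" else "off"))
  invisible(x)
}

#' Predict expression for a section
#'
#' Runs the fitted model over every patch of a query section. With
#' `use_sat = TRUE` the non-parametric attention is applied once over
#' all spots of the section jointly (the transductive full-section
#' scope); with `FALSE` the direct branch is returned (the no-SAT
#' ablation).
#'
#' @param object a fitted `ressat_model`.
#' @param patches a [patch_set()] for the query section.
#' @param use_sat logical; apply attention over the whole query section.
#' @param ... unused.
#' @return An [expression_matrix()] with layer `"predicted"`.
#' @export
predict.ressat_model <- function(object, patches, use_sat = TRUE, ...) {
  stopifnot(inherits(patches, "patch_set"))
  if (patch_side(patches) != object$model$patch_size)
    abort(sprintf("query patch size %d differs from the model's %d.",
                  patch_side(patches), object$model$patch_size))
  pred <- forward_direct(object$model, patches)
  if (isTRUE(use_sat) && nrow(pred) > 1L)
    pred <- attention(pred, scale_dim = ncol(pred))
  rownames(pred) <- patches$spot_ids
  colnames(pred) <- object$gene_ids
  expression_matrix(pred, layer = "predicted")
}

#' @rdname tidy-ressat
#' @method tidy ressat_model
#' @export
tidy.ressat_model <- function(x, ...) x$loss_history

#' Summaries of a fitted model
#'
#' `tidy()` returns the per-epoch loss history; `glance()` returns a
#' one-row summary (final losses, epochs, configuration flags).
#'
#' @param x a `ressat_model`.
#' @param ... unused.
#' @name tidy-ressat
#' @method glance ressat_model
#' @export
glance.ressat_model <- function(x, ...) {
  last <- x$loss_history[nrow(x$loss_history), ]
  tibble(epochs = nrow(x$loss_history),
         l_direct = last$l_direct, l_attended = last$l_attended,
         l_total = last$l_total, use_sat = x$config$use_sat,
         use_backbone = x$config$use_backbone,
         backbone = x$model$backbone_kind,
         n_genes = length(x$gene_ids),
         fingerprint = x$config_fingerprint)
}

#' Loss-curve plot for a fitted model
#'
#' @param object a `ressat_model`.
#' @param ... unused.
#' @return A ggplot of the per-epoch direct, attended, and total losses.
#' @method autoplot ressat_model
#' @export
autoplot.ressat_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$loss_history,
                            c("l_direct", "l_attended", "l_total"),
                            names_to = "term", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single RDS file carrying a format version, the
#' backbone kind, the gene list, the configuration fingerprint, and all
#' weights, so later predictions are reproducible and gene-aligned.
#'
#' @param model a `ressat_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the `ressat_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ressat_model"))
  saveRDS(list(format = "ressat_checkpoint_v1",
               package_version = as.character(packageVersion("ressat")),
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "ressat_checkpoint_v1"))
    abort("not a ressat checkpoint.")
  obj$model
}

# Generics re-exported in broom style ------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy
#' @importFrom generics glance
#' @export
generics::glance
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2L, compress = FALSE)
  unname(tools::md5sum(f))
}
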