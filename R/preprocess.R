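#' Preprocessing configuration
#'
#' Collects the knobs of the preprocessing stage: patch side in pixels,
#' the total-count normalization target, the number of highly variable
#' genes taken per section, and the batch-correction method applied to
#' the normalized, HVG-restricted sections.
#'
#' `target_sum = 1e4` is the community default for spot-level data; the
#' patch side is defined in pixels (the canonical full-scale value is
#' 224, roughly a 55 um Visium spot at full resolution).
#'
#' @param patch_size even integer >= 8, patch side in pixels.
#' @param target_sum positive scalar, per-spot total after scaling.
#' @param n_hvg integer >= 1, highly variable genes kept per section.
#' @param batch_correction `"none"`, `"center_scale"`, or
#'   `"external_harmony"` (a user-supplied hook, see [batch_correct()]).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(patch_size = 224L, target_sum = 1e4,
                              n_hvg = 1000L,
                              batch_correction = c("center_scale", "none",
                                                   "external_harmony")) {
  batch_correction <- match.arg(batch_correction)
  patch_size <- as.integer(patch_size)
  if (patch_size < 8L || patch_size %% 2L != 0L)
    abort("`patch_size` must be an even integer >= 8.")
  if (!is.numeric(target_sum) || target_sum <= 0)
    abort("`target_sum` must be positive.")
  n_hvg <- as.integer(n_hvg)
  if (n_hvg < 1L) abort("`n_hvg` must be >= 1.")
  structure(list(patch_size = patch_size, target_sum = target_sum,
                 n_hvg = n_hvg, batch_correction = batch_correction),
            class = "preprocess_config")
}

#' Extract image patches centered on spots
#'
#' Cuts one `patch_size x patch_size` RGB window per in-tissue spot,
#' centered at the spot's pixel coordinate. Windows reaching past the
#' slide border are padded with constant white (255), which matches the
#' H&E background without fabricating tissue. Row order follows the
#' spot grid.
#'
#' @param image a [slide_image()].
#' @param spots a [spot_grid()]; only `in_tissue` spots produce patches.
#' @param patch_size even integer, patch side in pixels.
#' @return A [patch_set()] of dimension `N x 3 x P x P`.
#' @export
extract_patches <- function(image, spots, patch_size = 224L) {
  stopifnot(inherits(image, "slide_image"), inherits(spots, "spot_grid"))
  patch_size <- as.integer(patch_size)
  if (patch_size < 8L || patch_size %% 2L != 0L)
    abort("`patch_size` must be an even integer >= 8.")
  keep <- spots[spots$in_tissue, , drop = FALSE]
  n <- nrow(keep)
  P <- patch_size
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  half <- P %/% 2L
  out <- array(255, dim = c(n, 3L, P, P))
  for (i in seq_len(n)) {
    cr <- round(keep$pxl_row[i]); cc <- round(keep$pxl_col[i])
    if (cr < 0 || cr >= H || cc < 0 || cc >= W)
      abort(sprintf("spot %s center (%d, %d) lies outside the %d x %d image.",
                    keep$barcode[i], cr, cc, H, W))
    # 0-based window rows cr-half .. cr+half-1; clip to the image
    r0 <- cr - half; c0 <- cc - half
    rows <- max(r0, 0L):min(r0 + P - 1L, H - 1L)
    cols <- max(c0, 0L):min(c0 + P - 1L, W - 1L)
    win <- image$pixels[rows + 1L, cols + 1L, , drop = FALSE]
    out[i, , (rows - r0) + 1L, (cols - c0) + 1L] <-
      aperm(win, c(3L, 1L, 2L))
  }
  patch_set(out, keep$barcode)
}

#' Total-count and log normalization
#'
#' Scales each spot's counts so the row total equals `target_sum`, then
#' applies `log(1 + v)`. Spots with zero total count are an error (drop
#' them first, see [drop_empty_spots()]): their scale factor is
#' undefined.
#'
#' @param expr an [expression_matrix()] with layer `"counts"`.
#' @param target_sum positive scalar.
#' @return An [expression_matrix()] with layer `"normalized"`.
#' @export
normalize_expression <- function(expr, target_sum = 1e4) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$layer != "counts")
    abort("normalize_expression expects the counts layer.")
  if (!is.numeric(target_sum) || target_sum <= 0)
    abort("`target_sum` must be positive.")
  totals <- rowSums(expr$values)
  if (any(totals == 0)) {
    bad <- rownames(expr$values)[totals == 0]
    abort(sprintf("spot(s) with zero total count: %s%s — filter empty spots before normalizing.",
                  paste(head(bad, 5), collapse = ", "),
                  if (length(bad) > 5) ", ..." else ""))
  }
  v <- log1p(expr$values / totals * target_sum)
  expression_matrix(v, layer = "normalized", gene_meta = expr$gene_meta)
}

#' Drop spots with zero total counts
#'
#' Removes spots whose counts sum to zero (their normalization scale
#' factor is undefined), with a warning stating how many were dropped.
#'
#' @param dataset a [spatial_dataset()] with a counts layer.
#' @return The dataset without empty spots.
#' @export
drop_empty_spots <- function(dataset) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  totals <- rowSums(dataset$expression$values)
  if (all(totals > 0)) return(dataset)
  keep <- totals > 0
  warn(sprintf("dropping %d spot(s) with zero total counts.", sum(!keep)))
  spots <- dataset$spots[keep, , drop = FALSE]
  class(spots) <- class(dataset$spots)
  expr <- expression_matrix(dataset$expression$values[keep, , drop = FALSE],
                            layer = dataset$expression$layer,
                            gene_meta = dataset$expression$gene_meta)
  spatial_dataset(dataset$image, spots, expr, dataset$section_id)
}

#' Union of per-section highly variable genes
#'
#' Ranks genes within each section by the variance of their normalized
#' expression (ties broken lexicographically by gene id), takes the top
#' `n_hvg` per section, and returns the sorted union. The result size
#' lies in `[n_hvg, n_sections * n_hvg]`.
#'
#' @param sections list of [expression_matrix()] objects with layer
#'   `"normalized"` sharing one gene space.
#' @param n_hvg integer, genes kept per section.
#' @return Sorted character vector of gene ids.
#' @export
select_hvg_union <- function(sections, n_hvg = 1000L) {
  if (!is.list(sections) || length(sections) < 1L)
    abort("`sections` must be a non-empty list of expression matrices.")
  genes <- gene_ids(sections[[1]])
  for (s in sections) {
    stopifnot(inherits(s, "expression_matrix"))
    if (s$layer != "normalized")
      abort("select_hvg_union expects normalized layers.")
    if (!setequal(gene_ids(s), genes))
      abort("all sections must share one gene space (run align_sections first).")
  }
  n_hvg <- as.integer(n_hvg)
  if (n_hvg > length(genes))
    abort(sprintf("n_hvg (%d) exceeds the number of genes (%d).",
                  n_hvg, length(genes)))
  tops <- lapply(sections, function(s) {
    v <- apply(s$values, 2L, stats::var)
    ord <- order(-v, colnames(s$values))
    colnames(s$values)[ord[seq_len(n_hvg)]]
  })
  sort(Reduce(union, tops))
}

#' Batch correction across sections
#'
#' Adjusts normalized, HVG-restricted sections for section-level batch
#' effects. `"none"` passes values through; `"center_scale"` subtracts
#' each section's per-gene mean and divides by the per-gene standard
#' deviation pooled across sections (genes with zero pooled variance are
#' divided by 1); `"external_harmony"` delegates to a user-supplied
#' callable implementing the Harmony-style correction with the same
#' (sections in, sections out) contract, and validates shapes on return.
#' All methods return the `"corrected"` layer.
#'
#' @param sections list of [expression_matrix()] objects with identical
#'   gene lists.
#' @param method `"none"`, `"center_scale"`, or `"external_harmony"`.
#' @param hook function taking and returning the list of value matrices;
#'   required when `method = "external_harmony"`.
#' @return List of corrected [expression_matrix()] objects.
#' @export
batch_correct <- function(sections,
                          method = c("center_scale", "none",
                                     "external_harmony"),
                          hook = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(sections), length(sections) >= 1L)
  genes <- gene_ids(sections[[1]])
  for (s in sections) {
    stopifnot(inherits(s, "expression_matrix"))
    if (!identical(gene_ids(s), genes))
      abort("all sections must carry identical, identically ordered gene lists.")
  }
  as_corrected <- function(s, values) {
    expression_matrix(values, layer = "corrected", gene_meta = s$gene_meta)
  }
  if (method == "none")
    return(lapply(sections, function(s) as_corrected(s, s$values)))

  if (method == "external_harmony") {
    if (!is.function(hook))
      abort("method \"external_harmony\" requires a callable `hook`.")
    out <- hook(lapply(sections, function(s) s$values))
    if (!is.list(out) || length(out) != length(sections))
      abort("batch-correction hook must return one matrix per section.")
    for (i in seq_along(out)) {
      if (!identical(dim(out[[i]]), dim(sections[[i]]$values)))
        abort(sprintf("hook returned wrong shape for section %d.", i))
      dimnames(out[[i]]) <- dimnames(sections[[i]]$values)
    }
    return(map2(sections, out, as_corrected))
  }

  # center_scale: per-section centering, pooled-sd scaling
  centered <- lapply(sections, function(s) {
    sweep(s$values, 2L, colMeans(s$values), "-")
  })
  n_tot <- sum(vapply(centered, nrow, 1L))
  ss <- Reduce(`+`, lapply(centered, function(m) colSums(m^2)))
  dof <- n_tot - length(sections)
  pooled_sd <- if (dof > 0) sqrt(ss / dof) else rep(0, length(genes))
  pooled_sd[pooled_sd < 1e-12] <- 1
  map2(sections, centered, function(s, m) {
    as_corrected(s, sweep(m, 2L, pooled_sd, "/"))
  })
}

#' Run the full preprocessing chain on two aligned sections
#'
#' Applies the stage order align genes -> drop empty spots -> normalize
#' -> HVG union -> restrict -> batch correct, and extracts patches,
#' returning model-ready inputs for the train-on-one/test-on-the-other
#' protocol.
#'
#' @param a,b [spatial_dataset()] objects with counts layers.
#' @param config a [preprocess_config()].
#' @param hook optional callable for `external_harmony`.
#' @param target_layer train on `"corrected"` (default) or stop at
#'   `"normalized"` values.
#' @return A list with `patches` (list of two [patch_set()]s), `targets`
#'   (list of two [expression_matrix()]s), `datasets` (the aligned,
#'   filtered datasets) and `genes` (the HVG union).
#' @export
preprocess_sections <- function(a, b, config = preprocess_config(),
                                hook = NULL,
                                target_layer = c("corrected", "normalized")) {
  target_layer <- match.arg(target_layer)
  stopifnot(inherits(config, "preprocess_config"))
  aligned <- align_sections(a, b)
  ds <- lapply(aligned, drop_empty_spots)
  normalized <- lapply(ds, function(d)
    normalize_expression(d$expression, target_sum = config$target_sum))
  genes <- select_hvg_union(normalized, n_hvg = config$n_hvg)
  restricted <- lapply(normalized, function(e) {
    idx <- match(genes, colnames(e$values))
    expression_matrix(e$values[, idx, drop = FALSE], layer = "normalized",
                      gene_meta = if (is.null(e$gene_meta)) NULL else
                        e$gene_meta[idx, , drop = FALSE])
  })
  targets <- if (target_layer == "corrected") {
    batch_correct(restricted, method = config$batch_correction, hook = hook)
  } else restricted
  patches <- lapply(ds, function(d)
    extract_patches(d$image, d$spots, patch_size = config$patch_size))
  list(patches = patches, targets = targets, datasets = ds, genes = genes)
}
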