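#' Pearson correlation coefficient
#'
#' The covariance of the two vectors divided by the product of their
#' standard deviations. If either vector has zero variance the
#' correlation is mathematically undefined and `NA` is returned (with a
#' message) rather than an error, so downstream means can exclude and
#' count such genes.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return A scalar in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2L) abort("pcc needs at least two observations.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    inform("pcc undefined: zero variance in an input vector.")
    return(NA_real_)
  }
  stats::cor(x, y)
}

# Vectorized per-gene (column-wise) Pearson correlation between two
# matrices of identical shape; NA for zero-variance columns.
colwise_pcc <- function(a, b) {
  ca <- sweep(a, 2L, colMeans(a), "-")
  cb <- sweep(b, 2L, colMeans(b), "-")
  num <- colSums(ca * cb)
  den <- sqrt(colSums(ca^2) * colSums(cb^2))
  out <- ifelse(den > 0, num / den, NA_real_)
  names(out) <- colnames(a)
  out
}

check_matched <- function(y_true, y_pred) {
  stopifnot(inherits(y_true, "expression_matrix"),
            inherits(y_pred, "expression_matrix"))
  if (!identical(dim(y_true$values), dim(y_pred$values)))
    abort("observed and predicted matrices differ in shape.")
  if (!identical(rownames(y_true$values), rownames(y_pred$values)))
    abort("observed and predicted matrices differ in spot order.")
  if (!identical(colnames(y_true$values), colnames(y_pred$values)))
    abort("observed and predicted matrices differ in gene order.")
}

#' Mean per-gene correlation over all genes
#'
#' Computes the Pearson correlation of each gene's observed and
#' predicted values across spots, then averages over the genes whose
#' correlation is defined; zero-variance genes are excluded and counted.
#'
#' @param y_true,y_pred [expression_matrix()] objects with matched spot
#'   and gene orderings.
#' @return A list: `mean_all` (the average), `per_gene` (tibble of
#'   `gene_id`, `pcc`), `k_used` (genes entering the mean), and
#'   `n_undefined`.
#' @export
mean_pcc_all <- function(y_true, y_pred) {
  check_matched(y_true, y_pred)
  r <- colwise_pcc(y_true$values, y_pred$values)
  list(mean_all = mean(r, na.rm = TRUE),
       per_gene = tibble(gene_id = names(r), pcc = unname(r)),
       k_used = sum(!is.na(r)),
       n_undefined = sum(is.na(r)))
}

#' Mean correlation of the top highly expressed genes
#'
#' Ranks genes by their mean expression across spots in the predicted
#' matrix (descending, ties broken lexicographically by gene id), takes
#' the top `k_prime`, and averages their per-gene correlations
#' (undefined correlations are excluded and counted). Ranking on the
#' observed matrix instead is available for sensitivity analysis.
#'
#' @inheritParams mean_pcc_all
#' @param k_prime number of highly expressed genes (default 50).
#' @param rank_by `"predicted"` (default) or `"observed"`.
#' @return A list: `mean_top_heg`, `heg_ids` (the `k_prime` selected
#'   ids), `n_undefined_heg`.
#' @export
mean_pcc_top_heg <- function(y_true, y_pred, k_prime = 50L,
                             rank_by = c("predicted", "observed")) {
  rank_by <- match.arg(rank_by)
  check_matched(y_true, y_pred)
  k_prime <- as.integer(k_prime)
  if (k_prime > ncol(y_true$values))
    abort(sprintf("k_prime (%d) exceeds the number of genes (%d).",
                  k_prime, ncol(y_true$values)))
  if (k_prime < 1L) abort("`k_prime` must be >= 1.")
  basis <- if (rank_by == "predicted") y_pred$values else y_true$values
  mu <- colMeans(basis)
  ord <- order(-mu, colnames(basis))
  heg <- colnames(basis)[ord[seq_len(k_prime)]]
  r <- colwise_pcc(y_true$values[, heg, drop = FALSE],
                   y_pred$values[, heg, drop = FALSE])
  list(mean_top_heg = mean(r, na.rm = TRUE),
       heg_ids = heg,
       n_undefined_heg = sum(is.na(r)))
}

#' Evaluation report for a predicted section
#'
#' Bundles the per-gene correlations with the two summary metrics: the
#' mean correlation over all genes with defined correlation, and the
#' mean correlation of the top `k_prime` highly expressed genes in the
#' predicted matrix. Correlations are computed across the spots of the
#' (held-out) section passed in.
#'
#' @inheritParams mean_pcc_top_heg
#' @return An object of class `eval_report` with fields `per_gene`
#'   (tibble: `gene_id`, `pcc`, `mean_pred`, `is_heg`), `mean_all`,
#'   `mean_top_heg`, `k_used`, `heg_ids`, `n_undefined`, `k_prime`.
#' @export
eval_report <- function(y_true, y_pred, k_prime = 50L,
                        rank_by = c("predicted", "observed")) {
  rank_by <- match.arg(rank_by)
  all_part <- mean_pcc_all(y_true, y_pred)
  top_part <- mean_pcc_top_heg(y_true, y_pred, k_prime = k_prime,
                               rank_by = rank_by)
  per_gene <- all_part$per_gene
  per_gene$mean_pred <- unname(colMeans(y_pred$values))
  per_gene$is_heg <- per_gene$gene_id %in% top_part$heg_ids
  structure(list(per_gene = per_gene,
                 mean_all = all_part$mean_all,
                 mean_top_heg = top_part$mean_top_heg,
                 k_used = all_part$k_used,
                 heg_ids = top_part$heg_ids,
                 n_undefined = all_part$n_undefined,
                 k_prime = as.integer(k_prime)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> mean PCC %.4f over %d genes (%d undefined); top-%d HEG mean PCC %.4f\n",
              x$mean_all, x$k_used, x$n_undefined, x$k_prime, x$mean_top_heg))
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_gene

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(mean_all = x$mean_all, mean_top_heg = x$mean_top_heg,
         k_used = x$k_used, n_undefined = x$n_undefined,
         k_prime = x$k_prime)
}

#' Histogram of per-gene correlations
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- object$per_gene[!is.na(object$per_gene$pcc), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pcc)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_all, linetype = "dashed") +
    ggplot2::labs(x = "per-gene Pearson correlation", y = "genes") +
    ggplot2::theme_minimal()
}

#' Side-by-side spatial plot of observed vs predicted expression
#'
#' Draws the spots of a section at their pixel coordinates, colored by a
#' gene's observed and predicted expression in two panels that share one
#' color scale whose limits are the range of the union of both vectors.
#'
#' @param dataset_truth a [spatial_dataset()] holding the observed
#'   values and spot coordinates.
#' @param y_pred an [expression_matrix()] of predictions with the same
#'   spots.
#' @param gene_id the gene to display (must exist in both matrices).
#' @param out_path optional PNG path; when given the plot is written
#'   there.
#' @return The ggplot object, invisibly.
#' @export
spatial_gene_plot <- function(dataset_truth, y_pred, gene_id,
                              out_path = NULL) {
  stopifnot(inherits(dataset_truth, "spatial_dataset"),
            inherits(y_pred, "expression_matrix"))
  obs_mat <- dataset_truth$expression$values
  if (!gene_id %in% colnames(obs_mat) || !gene_id %in% colnames(y_pred$values))
    abort(sprintf("gene %s absent from the observed or predicted matrix.",
                  gene_id))
  common <- intersect(rownames(obs_mat), rownames(y_pred$values))
  if (length(common) == 0L) abort("no shared spots between truth and prediction.")
  spots <- dataset_truth$spots
  idx <- match(common, spots$barcode)
  df <- tibble(
    barcode = common,
    pxl_row = spots$pxl_row[idx],
    pxl_col = spots$pxl_col[idx],
    observed = obs_mat[common, gene_id],
    predicted = y_pred$values[common, gene_id]
  )
  lims <- range(c(df$observed, df$predicted))
  long <- tidyr::pivot_longer(df, c("observed", "predicted"),
                              names_to = "panel", values_to = "expression")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pxl_col,
                                          y = .data$pxl_row,
                                          colour = .data$expression)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_colour_viridis_c(limits = lims) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = gene_id, x = NULL, y = NULL,
                  colour = "expression") +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, p, width = 8, height = 4, dpi = 120,
                    device = "png")
  }
  invisible(p)
}
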