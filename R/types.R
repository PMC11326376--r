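#' Slide image
#'
#' A full-resolution RGB histology image. Pixels are stored as a numeric
#' `H x W x 3` array with values in `[0, 255]` (8-bit scale); the optional
#' `microns_per_pixel` records the physical resolution when known.
#'
#' @param pixels numeric array of dimension `c(H, W, 3)` with values in
#'   `[0, 255]`.
#' @param microns_per_pixel optional positive scalar, microns per pixel.
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(pixels, microns_per_pixel = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    abort("`pixels` must be an H x W x 3 array (exactly 3 channels).")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    abort("slide image must have at least one row and one column of pixels.")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    abort("pixel values must lie in [0, 255] with no missing values.")
  if (!is.null(microns_per_pixel)) {
    if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
        microns_per_pixel <= 0)
      abort("`microns_per_pixel` must be a single positive number.")
    microns_per_pixel <- as.numeric(microns_per_pixel)
  }
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel),
            class = "slide_image")
}

#' @export
dim.slide_image <- function(x) dim(x$pixels)

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  mpp <- if (is.null(x$microns_per_pixel)) "unknown" else
    sprintf("%.3f um/px", x$microns_per_pixel)
  cat(sprintf("<slide_image> %d x %d px, 3 channels, resolution %s\n",
              d[1], d[2], mpp))
  invisible(x)
}

#' Spot grid
#'
#' The table of barcoded capture spots on a slide: barcode, tissue flag,
#' integer array coordinates, and 0-based pixel coordinates `(pxl_row,
#' pxl_col)` on the matching [slide_image()] (row = y, col = x, matching
#' array indexing of the image raster).
#'
#' @param barcode character vector of unique spot barcodes.
#' @param in_tissue logical vector, whether the spot overlaps tissue.
#' @param array_row,array_col optional integer array coordinates.
#' @param pxl_row,pxl_col numeric 0-based pixel coordinates of spot centers.
#' @return A tibble of class `spot_grid`.
#' @export
spot_grid <- function(barcode, in_tissue, pxl_row, pxl_col,
                      array_row = NA_integer_, array_col = NA_integer_) {
  if (anyDuplicated(barcode))
    abort("spot barcodes must be unique.")
  tb <- tibble(
    barcode = as.character(barcode),
    in_tissue = as.logical(in_tissue),
    array_row = as.integer(array_row),
    array_col = as.integer(array_col),
    pxl_row = as.numeric(pxl_row),
    pxl_col = as.numeric(pxl_col)
  )
  if (any(!is.finite(tb$pxl_row)) || any(!is.finite(tb$pxl_col)))
    abort("pixel coordinates must be finite.")
  if (any(tb$pxl_row < 0) || any(tb$pxl_col < 0))
    abort("pixel coordinates must be >= 0.")
  class(tb) <- c("spot_grid", class(tibble()))
  tb
}

#' Spot by gene expression matrix
#'
#' A dense spots-by-genes matrix with unique row (barcode) and column
#' (gene id) labels, tagged with the processing `layer` it represents.
#' Counts layers must be non-negative integers.
#'
#' @param values numeric matrix, spots in rows, genes in columns, with
#'   complete `dimnames`.
#' @param layer one of `"counts"`, `"normalized"`, `"corrected"`,
#'   `"predicted"`.
#' @param gene_meta optional tibble of per-gene metadata (e.g. symbols),
#'   one row per gene in column order.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values,
                              layer = c("counts", "normalized", "corrected",
                                        "predicted"),
                              gene_meta = NULL) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix (spots x genes).")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("`values` must carry spot barcodes as rownames and gene ids as colnames.")
  if (anyDuplicated(rownames(values)))
    abort("spot labels of an expression matrix must be unique.")
  if (anyDuplicated(colnames(values)))
    abort("gene labels of an expression matrix must be unique.")
  if (layer == "counts") {
    if (anyNA(values) || min(values) < 0)
      abort("counts must be non-negative with no missing values.")
    if (max(abs(values - round(values))) > 1e-8)
      abort("counts must be integer-valued; found non-integer entries.")
  }
  if (!is.null(gene_meta) && nrow(gene_meta) != ncol(values))
    abort("`gene_meta` must have one row per gene.")
  structure(list(values = values, layer = layer, gene_meta = gene_meta),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d spots x %d genes, layer \"%s\"\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

spot_ids <- function(x) UseMethod("spot_ids")
#' @export
spot_ids.expression_matrix <- function(x) rownames(x$values)
#' @export
spot_ids.spot_grid <- function(x) x$barcode
#' @export
spot_ids.spatial_dataset <- function(x) x$spots$barcode

gene_ids <- function(x) UseMethod("gene_ids")
#' @export
gene_ids.expression_matrix <- function(x) colnames(x$values)
#' @export
gene_ids.spatial_dataset <- function(x) colnames(x$expression$values)

#' One spatial section
#'
#' Bundles a slide image, its spot grid, and the matching expression
#' matrix for one tissue section. Expression rows must agree with the
#' spot grid in content and order.
#'
#' @param image a [slide_image()].
#' @param spots a [spot_grid()].
#' @param expression an [expression_matrix()] whose rows match `spots`.
#' @param section_id character scalar naming the section.
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(image, spots, expression, section_id = "section") {
  stopifnot(inherits(image, "slide_image"),
            inherits(spots, "spot_grid"),
            inherits(expression, "expression_matrix"))
  if (!identical(spots$barcode, rownames(expression$values)))
    abort("spot order of `spots` and `expression` must agree exactly.")
  structure(list(image = image, spots = spots, expression = expression,
                 section_id = as.character(section_id)),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> \"%s\": %d spots (%d in tissue), %d genes, image %d x %d\n",
              x$section_id, nrow(x$spots), sum(x$spots$in_tissue),
              ncol(x$expression$values), dim(x$image)[1], dim(x$image)[2]))
  invisible(x)
}

#' Patch set
#'
#' The stack of fixed-size RGB patches aligned to spots, stored as an
#' `N x 3 x P x P` numeric array on the 0-255 scale, with a spot id per
#' row.
#'
#' @param patches numeric array `c(N, 3, P, P)`.
#' @param spot_ids character vector of length `N`.
#' @return An object of class `patch_set`.
#' @export
patch_set <- function(patches, spot_ids) {
  d <- dim(patches)
  if (length(d) != 4L || d[2] != 3L || d[3] != d[4])
    abort("`patches` must be an N x 3 x P x P array.")
  if (d[1] != length(spot_ids))
    abort("`spot_ids` must have one entry per patch.")
  structure(list(patches = patches, spot_ids = as.character(spot_ids)),
            class = "patch_set")
}

#' @export
dim.patch_set <- function(x) dim(x$patches)

#' @export
print.patch_set <- function(x, ...) {
  d <- dim(x$patches)
  cat(sprintf("<patch_set> %d patches, %d x %d px\n", d[1], d[3], d[4]))
  invisible(x)
}

patch_side <- function(x) dim(x$patches)[3]
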