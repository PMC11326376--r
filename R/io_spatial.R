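#' Read a SpaceRanger-style spatial dataset
#'
#' Reads one Visium-style section from a directory laid out the way the
#' 10x SpaceRanger pipeline writes it: a sparse MatrixMarket count matrix
#' with barcode and feature TSVs (`filtered_feature_bc_matrix/`, gzipped
#' variants accepted), a spot-position CSV (`spatial/tissue_positions.csv`
#' headered v2 or headerless v1 `tissue_positions_list.csv`), and an RGB
#' slide image (PNG). Spots are filtered to `in_tissue == 1` and the
#' count rows are reordered to the position-table order.
#'
#' Pixel coordinates are kept 0-based as `(row, col) = (y, x)`, mapping
#' the `pxl_row_in_fullres` / `pxl_col_in_fullres` columns directly onto
#' image array indexing. Feature IDs (first column of `features.tsv`)
#' are the canonical gene key; symbols are kept as metadata.
#'
#' @param dir_path directory containing the section.
#' @param section_id optional name for the section; defaults to the
#'   directory basename.
#' @return A [spatial_dataset()] whose expression carries the `"counts"`
#'   layer.
#' @export
read_visium <- function(dir_path, section_id = NULL) {
  if (!dir.exists(dir_path))
    abort(sprintf("dataset directory not found: %s", dir_path))
  if (is.null(section_id)) section_id <- basename(normalizePath(dir_path))

  pos_path <- find_one_of(dir_path, c(
    "spatial/tissue_positions.csv", "spatial/tissue_positions.csv.gz",
    "spatial/tissue_positions_list.csv", "spatial/tissue_positions_list.csv.gz",
    "tissue_positions.csv", "tissue_positions_list.csv"),
    what = "spot position table (tissue_positions.csv)")
  mtx_path <- find_one_of(dir_path, c(
    "filtered_feature_bc_matrix/matrix.mtx",
    "filtered_feature_bc_matrix/matrix.mtx.gz",
    "matrix.mtx", "matrix.mtx.gz"),
    what = "count matrix (matrix.mtx)")
  img_path <- find_one_of(dir_path, c(
    "image.png", "spatial/image.png", "spatial/tissue_image.png",
    "tissue_image.png", "image.tif", "image.tiff"),
    what = "slide image (image.png)")

  positions <- read_positions_csv(pos_path)
  n_all <- nrow(positions)
  positions <- positions[positions$in_tissue, , drop = FALSE]
  if (n_all - nrow(positions) > 0)
    inform(sprintf("read_visium: dropped %d barcode(s) not in tissue.",
                   n_all - nrow(positions)))

  mat_dir <- dirname(mtx_path)
  bc_path <- find_one_of(mat_dir, c("barcodes.tsv", "barcodes.tsv.gz"),
                         what = "barcodes.tsv")
  ft_path <- find_one_of(mat_dir, c("features.tsv", "features.tsv.gz",
                                    "genes.tsv", "genes.tsv.gz"),
                         what = "features.tsv")
  barcodes <- readLines(maybe_gz(bc_path))
  features <- utils::read.delim(maybe_gz(ft_path), header = FALSE,
                                stringsAsFactors = FALSE)
  counts <- Matrix::readMM(maybe_gz(mtx_path)) # features x barcodes
  if (nrow(counts) != nrow(features) || ncol(counts) != length(barcodes))
    abort("matrix.mtx dimensions do not match barcodes/features files.")

  missing <- setdiff(positions$barcode, barcodes)
  if (length(missing) > 0)
    abort(sprintf(
      "%d barcode(s) present in positions but absent from the matrix; first offenders: %s",
      length(missing), paste(head(missing, 5), collapse = ", ")))

  col_idx <- match(positions$barcode, barcodes)
  values <- t(as.matrix(counts[, col_idx, drop = FALSE]))
  rownames(values) <- positions$barcode
  colnames(values) <- as.character(features[[1]])
  gene_meta <- tibble(gene_id = as.character(features[[1]]),
                      symbol = if (ncol(features) >= 2)
                        as.character(features[[2]]) else
                        as.character(features[[1]]))

  meta_path <- file.path(dir_path, "slide_meta.json")
  mpp <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$microns_per_pixel))
      mpp <- as.numeric(meta$microns_per_pixel)
    if (!is.null(meta$section_id)) section_id <- meta$section_id
  }

  img <- read_slide_png(img_path, microns_per_pixel = mpp)
  spots <- spot_grid(barcode = positions$barcode,
                     in_tissue = positions$in_tissue,
                     array_row = positions$array_row,
                     array_col = positions$array_col,
                     pxl_row = positions$pxl_row,
                     pxl_col = positions$pxl_col)
  expr <- expression_matrix(values, layer = "counts", gene_meta = gene_meta)
  spatial_dataset(img, spots, expr, section_id = section_id)
}

#' Write a spatial dataset in SpaceRanger-style layout
#'
#' Persists a [spatial_dataset()] so that [read_visium()] round-trips it:
#' `filtered_feature_bc_matrix/{matrix.mtx,barcodes.tsv,features.tsv}`,
#' `spatial/tissue_positions.csv` (headered), `image.png`, and a small
#' `slide_meta.json` carrying the section id and optional resolution.
#'
#' @param dataset a [spatial_dataset()] with a `"counts"` expression layer.
#' @param dir_path output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_dataset <- function(dataset, dir_path) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  values <- dataset$expression$values
  if (ncol(values) == 0L) abort("cannot write a dataset with an empty gene set.")
  if (max(abs(values - round(values))) > 1e-8)
    abort("counts must be integers; found non-integer entries in the counts layer.")
  if (dataset$expression$layer != "counts")
    abort("write_dataset expects the counts layer.")
  dir.create(file.path(dir_path, "filtered_feature_bc_matrix"),
             recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir_path, "spatial"), showWarnings = FALSE)
  if (!dir.exists(dir_path)) abort(sprintf("cannot create directory %s", dir_path))

  mat_dir <- file.path(dir_path, "filtered_feature_bc_matrix")
  Matrix::writeMM(Matrix::Matrix(t(values), sparse = TRUE),
                  file.path(mat_dir, "matrix.mtx"))
  writeLines(rownames(values), file.path(mat_dir, "barcodes.tsv"))
  gm <- dataset$expression$gene_meta
  symbols <- if (!is.null(gm)) gm$symbol else colnames(values)
  utils::write.table(
    data.frame(colnames(values), symbols, "Gene Expression"),
    file.path(mat_dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  pos <- dataset$spots
  utils::write.table(
    data.frame(barcode = pos$barcode,
               in_tissue = as.integer(pos$in_tissue),
               array_row = pos$array_row, array_col = pos$array_col,
               pxl_row_in_fullres = pos$pxl_row,
               pxl_col_in_fullres = pos$pxl_col),
    file.path(dir_path, "spatial", "tissue_positions.csv"),
    sep = ",", quote = FALSE, row.names = FALSE, col.names = TRUE)

  png::writePNG(dataset$image$pixels / 255, file.path(dir_path, "image.png"))
  jsonlite::write_json(
    list(section_id = dataset$section_id,
         microns_per_pixel = dataset$image$microns_per_pixel),
    file.path(dir_path, "slide_meta.json"), auto_unbox = TRUE, null = "null")
  invisible(dir_path)
}

#' Restrict two sections to their common gene universe
#'
#' Intersects the gene lists of two sections and restricts both
#' expression matrices to the shared genes in lexicographic order, so a
#' single gene space underlies highly-variable-gene selection and
#' training. Spots are untouched. Idempotent.
#'
#' @param a,b [spatial_dataset()] objects with counts layers.
#' @return A list of the two aligned datasets, named `a` and `b`.
#' @export
align_sections <- function(a, b) {
  stopifnot(inherits(a, "spatial_dataset"), inherits(b, "spatial_dataset"))
  shared <- sort(intersect(gene_ids(a), gene_ids(b)))
  if (length(shared) == 0L)
    abort("the two sections share no genes; cannot align.")
  list(a = restrict_dataset_genes(a, shared),
       b = restrict_dataset_genes(b, shared))
}

restrict_dataset_genes <- function(dataset, genes) {
  expr <- dataset$expression
  idx <- match(genes, colnames(expr$values))
  if (anyNA(idx)) abort("gene list contains ids absent from the dataset.")
  gm <- expr$gene_meta
  if (!is.null(gm)) gm <- gm[idx, , drop = FALSE]
  dataset$expression <- expression_matrix(
    expr$values[, idx, drop = FALSE], layer = expr$layer, gene_meta = gm)
  dataset
}

# -- internal readers ---------------------------------------------------

find_one_of <- function(dir_path, candidates, what) {
  for (cand in candidates) {
    p <- file.path(dir_path, cand)
    if (file.exists(p)) return(p)
  }
  abort(sprintf("missing %s under %s (looked for: %s)",
                what, dir_path, paste(candidates, collapse = ", ")))
}

maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

# Accepts both the headerless v1 dialect and the headered v2 dialect,
# auto-detected from the first line.
read_positions_csv <- function(path) {
  con <- maybe_gz(path)
  first <- readLines(con, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- utils::read.csv(maybe_gz(path), header = has_header,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 6)
    abort(sprintf("position table %s has %d columns; expected 6 (barcode, in_tissue, array_row, array_col, pxl_row_in_fullres, pxl_col_in_fullres)",
                  path, ncol(df)))
  names(df)[1:6] <- c("barcode", "in_tissue", "array_row", "array_col",
                      "pxl_row", "pxl_col")
  df$barcode <- as.character(df$barcode)
  df$in_tissue <- as.integer(df$in_tissue) == 1L
  df[1:6]
}

read_slide_png <- function(path, microns_per_pixel = NULL) {
  if (grepl("\\.tiff?$", path)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      abort("reading TIFF images requires the 'tiff' package.")
    px <- tiff::readTIFF(path)
  } else {
    px <- png::readPNG(path)
  }
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  slide_image(round(px * 255), microns_per_pixel = microns_per_pixel)
}
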