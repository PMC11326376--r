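# Small in-code fixtures shared across tests.

# A deterministic checkerboard slide (period-8 tiles, channel-distinct).
make_checker_image <- function(H = 64L, W = 64L) {
  px <- array(0, dim = c(H, W, 3L))
  tile <- outer(seq_len(H) - 1L, seq_len(W) - 1L,
                function(r, c) ((r %/% 8L) + (c %/% 8L)) %% 2L)
  px[, , 1] <- 40 + 180 * tile
  px[, , 2] <- 220 - 160 * tile
  px[, , 3] <- 127
  slide_image(px)
}

# A valid spatial dataset with n in-tissue spots on a small grid.
make_test_dataset <- function(n_spots = 6L, n_genes = 5L, seed = 1L,
                              section_id = "fixture",
                              gene_ids = sprintf("G%02d", seq_len(n_genes))) {
  set.seed(seed)
  side <- ceiling(sqrt(n_spots))
  r <- (seq_len(n_spots) - 1L) %/% side
  c <- (seq_len(n_spots) - 1L) %% side
  spacing <- 16L
  spots <- spot_grid(barcode = sprintf("BC%03d", seq_len(n_spots)),
                     in_tissue = TRUE,
                     array_row = r, array_col = c,
                     pxl_row = spacing + r * spacing,
                     pxl_col = spacing + c * spacing)
  counts <- matrix(rpois(n_spots * n_genes, 20), n_spots, n_genes,
                   dimnames = list(spots$barcode, gene_ids))
  img <- make_checker_image(spacing * (side + 1L), spacing * (side + 1L))
  spatial_dataset(img, spots,
                  expression_matrix(counts, layer = "counts"),
                  section_id = section_id)
}

# Tiny learnable patch/target pair: constant-colour patches whose three
# channel intensities linearly determine the targets (noise-free), so a
# mean-pooling CNN can fit them exactly.
make_learnable_set <- function(n_spots = 8L, n_genes = 4L, P = 16L,
                               seed = 1L) {
  set.seed(seed)
  cols <- matrix(runif(n_spots * 3L, 0.1, 0.9), n_spots, 3L)
  arr <- array(0, dim = c(n_spots, 3L, P, P))
  for (i in seq_len(n_spots)) for (ch in 1:3)
    arr[i, ch, , ] <- 255 * cols[i, ch]
  wmap <- matrix(rnorm(3L * n_genes), 3L, n_genes)
  y <- cols %*% wmap
  dimnames(y) <- list(sprintf("P%02d", seq_len(n_spots)),
                      sprintf("G%02d", seq_len(n_genes)))
  list(patches = patch_set(arr, rownames(y)),
       targets = expression_matrix(y, layer = "normalized"))
}
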