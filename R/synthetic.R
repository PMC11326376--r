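#' Simulation configuration
#'
#' Parameters of the two-section synthetic benchmark generator. Spots
#' sit on a regular grid; a small number of latent tissue factors vary
#' smoothly over the grid (smoothed Gaussian noise with the given length
#' scale, in spot units), drive per-gene expected expression through a
#' non-negative loading matrix and a softplus link, and are rendered
#' into the slide image as per-spot disc tint and blob texture so a
#' convolutional encoder can decode them. Counts are negative binomial
#' around the expected rates, scaled to an expected per-spot depth.
#'
#' Defaults are the desk-scale benchmark: a 16x16 grid per section
#' (256 spots), 60 genes, 4 latent factors, 64 px spot spacing,
#' Visium-like depth 5000 and dispersion 2 (strong overdispersion),
#' length scale 4 spots, full image encoding, and a moderate additive
#' batch shift between the two sections.
#'
#' @param seed integer master seed.
#' @param n_rows,n_cols spot grid dimensions (>= 2 each).
#' @param spot_spacing_px pixel distance between neighboring spots.
#' @param n_genes number of genes.
#' @param n_latent number of latent tissue factors (<= n_genes).
#' @param spatial_length_scale smoothness of the latent fields, in spot
#'   units.
#' @param image_encoding_strength in `[0, 1]`; 0 renders texture carrying
#'   no information about the latents, 1 encodes them fully.
#' @param count_depth expected total counts per spot.
#' @param noise_dispersion negative binomial size parameter; `Inf` gives
#'   Poisson noise.
#' @param section_shift magnitude of the additive per-gene log-rate
#'   batch effect applied to the second section.
#' @param render_noise_sd standard deviation (on the `[0, 1]` latent
#'   scale) of the per-spot rendering noise: the tint and blob density
#'   drawn for a spot encode a noisy realization of its latents, not
#'   their exact values, emulating the finite, ambiguous evidence a real
#'   histology patch carries about tissue state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_rows = 16L, n_cols = 16L,
                       spot_spacing_px = 64L, n_genes = 60L, n_latent = 4L,
                       spatial_length_scale = 4,
                       image_encoding_strength = 1,
                       count_depth = 5000, noise_dispersion = 2,
                       section_shift = 0.3, render_noise_sd = 0.25) {
  if (n_rows < 2L || n_cols < 2L)
    abort("the spot grid needs at least 2 rows and 2 columns.")
  if (n_latent > n_genes) abort("`n_latent` must not exceed `n_genes`.")
  if (n_latent < 1L || n_genes < 1L) abort("`n_latent` and `n_genes` must be >= 1.")
  if (spatial_length_scale <= 0) abort("`spatial_length_scale` must be positive.")
  if (image_encoding_strength < 0 || image_encoding_strength > 1)
    abort("`image_encoding_strength` must lie in [0, 1].")
  if (count_depth <= 0 || noise_dispersion <= 0)
    abort("`count_depth` and `noise_dispersion` must be positive.")
  if (spot_spacing_px < 8L) abort("`spot_spacing_px` must be >= 8 px.")
  if (render_noise_sd < 0) abort("`render_noise_sd` must be >= 0.")
  structure(list(seed = as.integer(seed), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 spot_spacing_px = as.integer(spot_spacing_px),
                 n_genes = as.integer(n_genes), n_latent = as.integer(n_latent),
                 spatial_length_scale = spatial_length_scale,
                 image_encoding_strength = image_encoding_strength,
                 count_depth = count_depth,
                 noise_dispersion = noise_dispersion,
                 section_shift = section_shift,
                 render_noise_sd = render_noise_sd),
            class = "sim_config")
}

# Gaussian-smoothed white noise on the grid, standardized to mean 0 /
# sd 1. Convolution is edge-normalized (divided by the smoothed all-ones
# field) so borders are not dimmed.
smooth_field <- function(n_rows, n_cols, length_scale) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  r <- max(1L, ceiling(2.5 * length_scale))
  k1 <- exp(-((-r):r)^2 / (2 * length_scale^2))
  pad_conv <- function(m) {
    # separable convolution with zero padding, rows then columns
    out <- matrix(0, nrow(m), ncol(m))
    for (s in (-r):r) {
      if (abs(s) >= nrow(m)) next
      w <- k1[s + r + 1L]
      rows_src <- max(1, 1 - s):min(nrow(m), nrow(m) - s)
      rows_dst <- rows_src + s
      out[rows_dst, ] <- out[rows_dst, ] + w * m[rows_src, ]
    }
    out2 <- matrix(0, nrow(m), ncol(m))
    for (s in (-r):r) {
      if (abs(s) >= ncol(m)) next
      w <- k1[s + r + 1L]
      cols_src <- max(1, 1 - s):min(ncol(m), ncol(m) - s)
      cols_dst <- cols_src + s
      out2[, cols_dst] <- out2[, cols_dst] + w * out[, cols_src]
    }
    out2
  }
  sm <- pad_conv(z) / pad_conv(matrix(1, n_rows, n_cols))
  (sm - mean(sm)) / stats::sd(sm)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Shared "biology" of a section pair: loadings, intercepts, and the
# per-gene batch-shift direction. Each gene loads mainly on one latent.
sim_shared_params <- function(config) {
  set.seed(config$seed * 101L %% 2147483647L)
  L <- config$n_latent; G <- config$n_genes
  primary <- rep_len(seq_len(L), G)
  loadings <- matrix(runif(L * G, 0, 0.25), L, G)
  loadings[cbind(primary, seq_len(G))] <- runif(G, 1.2, 2.2)
  intercepts <- runif(G, -1, 0.5)
  shift_dir <- rnorm(G)
  gene_ids <- sprintf("GENE%03d", seq_len(G))
  colnames(loadings) <- gene_ids
  list(loadings = loadings, intercepts = intercepts, shift_dir = shift_dir,
       gene_ids = gene_ids)
}

#' Simulate one tissue section
#'
#' Draws the latent fields, expected rates, counts, and the rendered
#' slide image for one section. All randomness derives from
#' `config$seed` and `section_index`; the second section receives the
#' additive batch shift on its log-rates.
#'
#' @param config a [sim_config()].
#' @param section_index 1 or 2.
#' @param shared optional shared parameters from a paired call
#'   (internal); drawn from the seed when `NULL`.
#' @return A list with `dataset` (a [spatial_dataset()], counts layer)
#'   and `truth` (class `sim_truth`: `latent_fields` spots x n_latent,
#'   `loadings`, `clean_rates`, `shared`).
#' @export
simulate_section <- function(config, section_index = 1L, shared = NULL) {
  stopifnot(inherits(config, "sim_config"))
  section_index <- as.integer(section_index)
  if (is.null(shared)) shared <- sim_shared_params(config)
  set.seed((config$seed * 101L + section_index * 7919L) %% 2147483647L)

  nr <- config$n_rows; nc <- config$n_cols
  n_spots <- nr * nc
  # latent fields, one smooth surface per factor
  z <- vapply(seq_len(config$n_latent), function(l)
    as.vector(t(smooth_field(nr, nc, config$spatial_length_scale))),
    numeric(n_spots)) # spots x L; spot order row-major (row, then col)

  eta <- sweep(z %*% shared$loadings, 2L, shared$intercepts, "+")
  if (section_index == 2L && config$section_shift != 0)
    eta <- sweep(eta, 2L, config$section_shift * shared$shift_dir, "+")
  clean_rates <- softplus(eta)

  mu <- clean_rates / rowSums(clean_rates) * config$count_depth
  counts <- matrix(0L, n_spots, config$n_genes)
  if (is.finite(config$noise_dispersion) && config$noise_dispersion < 1e6) {
    counts[] <- rnbinom(length(mu), size = config$noise_dispersion,
                        mu = as.vector(mu))
  } else {
    counts[] <- rpois(length(mu), as.vector(mu))
  }

  barcodes <- sprintf("S%d_spot_%04d", section_index, seq_len(n_spots))
  rownames(counts) <- barcodes
  colnames(counts) <- shared$gene_ids

  sp <- config$spot_spacing_px
  grid_r <- rep(seq_len(nr) - 1L, each = nc)
  grid_c <- rep(seq_len(nc) - 1L, nr)
  pxl_row <- sp + grid_r * sp
  pxl_col <- sp + grid_c * sp
  H <- sp * (nr + 1L); W <- sp * (nc + 1L)

  img <- render_section_image(H, W, pxl_row, pxl_col, z, config)

  spots <- spot_grid(barcode = barcodes, in_tissue = TRUE,
                     array_row = grid_r, array_col = grid_c,
                     pxl_row = pxl_row, pxl_col = pxl_col)
  expr <- expression_matrix(counts, layer = "counts",
                            gene_meta = tibble(gene_id = shared$gene_ids,
                                               symbol = shared$gene_ids))
  ds <- spatial_dataset(slide_image(img), spots, expr,
                        section_id = sprintf("synthetic_section_%d",
                                             section_index))
  truth <- structure(list(latent_fields = z, loadings = shared$loadings,
                          clean_rates = clean_rates, shared = shared),
                     class = "sim_truth")
  list(dataset = ds, truth = truth)
}

# Renders per-spot discs on a white slide: base tint per channel encodes
# the first up-to-3 latents, blob count encodes the next latent. Each
# spot renders a NOISY realization of its latents (render_noise_sd on
# the [0, 1] scale, Poisson-sampled blob count): a patch carries finite,
# ambiguous evidence about the tissue state, as a real H&E patch does.
# With encoding strength 0 the appearance carries no information about
# the latents at all.
render_section_image <- function(H, W, pxl_row, pxl_col, z, config) {
  img <- array(255, dim = c(H, W, 3L))
  s <- config$image_encoding_strength
  a <- pnorm(z) # map latents to [0, 1]
  a <- a + matrix(rnorm(length(a), 0, config$render_noise_sd),
                  nrow(a), ncol(a))
  a <- pmin(pmax(a, 0), 1)
  n_ch <- min(3L, ncol(a))
  blob_latent <- if (ncol(a) >= 4L) a[, 4L] else NULL
  r0 <- max(4L, round(config$spot_spacing_px * 0.42))
  # precompute disc offsets
  off <- expand.grid(dr = -r0:r0, dc = -r0:r0)
  off <- off[off$dr^2 + off$dc^2 <= r0^2, ]
  blob_r <- 3L
  boff <- expand.grid(dr = -blob_r:blob_r, dc = -blob_r:blob_r)
  boff <- boff[boff$dr^2 + boff$dc^2 <= blob_r^2, ]
  for (i in seq_along(pxl_row)) {
    cr <- pxl_row[i] + 1L; cc <- pxl_col[i] + 1L
    rows <- pmin(pmax(cr + off$dr, 1L), H)
    cols <- pmin(pmax(cc + off$dc, 1L), W)
    tint <- numeric(3L)
    for (ch in 1:3) {
      enc <- if (ch <= n_ch) s * a[i, ch] + (1 - s) * 0.5 else 0.5
      tint[ch] <- 255 - 140 * enc
      img[cbind(rows, cols, ch)] <- tint[ch]
    }
    bfrac <- if (is.null(blob_latent)) 0.5 else
      s * blob_latent[i] + (1 - s) * 0.5
    n_blob <- rpois(1L, 4 + 18 * bfrac)
    if (n_blob > 0) {
      brc <- cbind(round(runif(n_blob, -r0 * 0.7, r0 * 0.7)),
                   round(runif(n_blob, -r0 * 0.7, r0 * 0.7)))
      for (b in seq_len(n_blob)) {
        rr <- pmin(pmax(cr + brc[b, 1] + boff$dr, 1L), H)
        cc2 <- pmin(pmax(cc + brc[b, 2] + boff$dc, 1L), W)
        for (ch in 1:3)
          img[cbind(rr, cc2, ch)] <- tint[ch] * 0.35
      }
    }
  }
  noise <- array(rnorm(length(img), 0, 3), dim = dim(img))
  img <- pmin(pmax(round(img + noise), 0), 255)
  img
}

#' Simulate a two-section pair
#'
#' Generates two sections that share their gene loadings (shared
#' biology) but have independent latent-field draws and, when
#' `section_shift > 0`, an additive per-gene batch effect on the second
#' section — mirroring the train-on-one-section, test-on-the-other
#' protocol.
#'
#' @param config a [sim_config()].
#' @return A list with `section1`, `section2` ([spatial_dataset()]s) and
#'   `truth1`, `truth2` (`sim_truth` objects referencing equal loading
#'   matrices).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  shared <- sim_shared_params(config)
  s1 <- simulate_section(config, 1L, shared = shared)
  s2 <- simulate_section(config, 2L, shared = shared)
  list(section1 = s1$dataset, section2 = s2$dataset,
       truth1 = s1$truth, truth2 = s2$truth)
}
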