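test_that("a patch centered on a whole image reproduces the image", {
  px <- array(runif(224 * 224 * 3, 0, 255), dim = c(224, 224, 3))
  img <- slide_image(px)
  spots <- spot_grid("s1", TRUE, pxl_row = 112, pxl_col = 112)
  ps <- extract_patches(img, spots, 224L)
  expect_equal(dim(ps$patches), c(1L, 3L, 224L, 224L))
  expect_equal(ps$patches[1, , , ], aperm(px, c(3, 1, 2)))
})

test_that("a corner spot gets white padding in the out-of-image region", {
  img <- make_checker_image(64, 64)
  spots <- spot_grid("s1", TRUE, pxl_row = 0, pxl_col = 0)
  ps <- extract_patches(img, spots, 32L)
  # rows/cols hanging above/left of the image are white
  expect_true(all(ps$patches[1, , 1:16, ] == 255))
  expect_true(all(ps$patches[1, , , 1:16] == 255))
  expect_false(all(ps$patches[1, , 17:32, 17:32] == 255))
})

test_that("patch content equals an independently sliced window", {
  img <- make_checker_image(64, 64)
  spots <- spot_grid(c("a", "b"), TRUE,
                     pxl_row = c(30, 17), pxl_col = c(22, 40))
  P <- 16L
  ps <- extract_patches(img, spots, P)
  for (i in 1:2) {
    r0 <- c(30, 17)[i] - P / 2; c0 <- c(22, 40)[i] - P / 2
    manual <- img$pixels[(r0 + 1):(r0 + P), (c0 + 1):(c0 + P), ]
    expect_equal(ps$patches[i, , , ], aperm(manual, c(3, 1, 2)))
  }
})

test_that("patches are produced only for in-tissue spots, in grid order", {
  img <- make_checker_image(64, 64)
  spots <- spot_grid(c("a", "b", "c"), c(TRUE, FALSE, TRUE),
                     pxl_row = c(20, 30, 40), pxl_col = c(20, 30, 40))
  ps <- extract_patches(img, spots, 16L)
  expect_identical(ps$spot_ids, c("a", "c"))
  expect_equal(dim(ps$patches)[1], 2L)
})

test_that("spot centers outside the image raise a named error", {
  img <- make_checker_image(32, 32)
  spots <- spot_grid("runaway", TRUE, pxl_row = 50, pxl_col = 10)
  expect_error(extract_patches(img, spots, 16L), "runaway")
})

test_that("normalization matches hand-computed values", {
  m <- matrix(c(2, 2, 1, 3), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("g1", "g2")))
  ex <- expression_matrix(m, "counts")
  out <- normalize_expression(ex, target_sum = 4)
  expect_equal(unname(out$values["s1", ]), c(log(3), log(3)))
  out8 <- normalize_expression(ex, target_sum = 8)
  expect_equal(unname(out8$values["s2", ]), c(log(3), log(7)))
  expect_identical(out$layer, "normalized")
})

test_that("normalization conserves the target row total pre-log", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(3:10, 1); g <- sample(2:8, 1)
    m <- matrix(rpois(n * g, 15) + 1, n, g,
                dimnames = list(sprintf("s%d", 1:n), sprintf("g%d", 1:g)))
    ts <- sample(c(100, 1e4, 7), 1)
    out <- normalize_expression(expression_matrix(m, "counts"), ts)
    expect_equal(rowSums(exp(out$values) - 1), setNames(rep(ts, n), rownames(m)),
                 tolerance = 1e-9)
  }
})

test_that("zero-total spots are an error for normalization and droppable upstream", {
  m <- matrix(c(1, 2, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("ok", "empty"), c("g1", "g2")))
  expect_error(normalize_expression(expression_matrix(m, "counts")), "empty")
  ds <- make_test_dataset(n_spots = 4L, n_genes = 3L, seed = 9L)
  ds$expression$values[2, ] <- 0
  expect_warning(out <- drop_empty_spots(ds), "1 spot")
  expect_identical(nrow(out$spots), 3L)
})

test_that("HVG union obeys its bounds for identical and disjoint top sets", {
  set.seed(1)
  base <- matrix(rnorm(40), 10, 4,
                 dimnames = list(sprintf("s%d", 1:10), sprintf("g%d", 1:4)))
  e <- expression_matrix(base, "normalized")
  expect_length(select_hvg_union(list(e, e), 2L), 2L)

  # engineer disjoint top-2 sets on a shared 4-gene space
  m1 <- base; m2 <- base
  m1[, 1:2] <- m1[, 1:2] * 10 # section 1 tops: g1, g2
  m2[, 3:4] <- m2[, 3:4] * 10 # section 2 tops: g3, g4
  u <- select_hvg_union(list(expression_matrix(m1, "normalized"),
                             expression_matrix(m2, "normalized")), 2L)
  expect_identical(u, c("g1", "g2", "g3", "g4"))
})

test_that("HVG union matches the brute-force variance-sort oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    m1 <- matrix(rnorm(60, sd = runif(6, 0.2, 3)), 10, 6, byrow = TRUE,
                 dimnames = list(sprintf("s%d", 1:10), sprintf("g%d", 1:6)))
    m2 <- matrix(rnorm(60, sd = runif(6, 0.2, 3)), 10, 6, byrow = TRUE,
                 dimnames = list(sprintf("t%d", 1:10), sprintf("g%d", 1:6)))
    got <- select_hvg_union(list(expression_matrix(m1, "normalized"),
                                 expression_matrix(m2, "normalized")), 2L)
    expect_identical(got, bf_hvg_union(list(m1, m2), 2L))
    expect_gte(length(got), 2L)
    expect_lte(length(got), 4L)
  }
})

test_that("HVG selection is invariant to gene column permutation", {
  set.seed(4)
  m <- matrix(rnorm(50), 10, 5,
              dimnames = list(sprintf("s%d", 1:10), sprintf("g%d", 1:5)))
  perm <- sample(5)
  u1 <- select_hvg_union(list(expression_matrix(m, "normalized")), 3L)
  u2 <- select_hvg_union(list(expression_matrix(m[, perm], "normalized")), 3L)
  expect_identical(u1, u2)
})

test_that("HVG errors when n_hvg exceeds the gene count", {
  m <- matrix(rnorm(20), 10, 2,
              dimnames = list(sprintf("s%d", 1:10), c("g1", "g2")))
  expect_error(select_hvg_union(list(expression_matrix(m, "normalized")), 3L),
               "exceeds")
})

test_that("batch_correct none is the identity on values", {
  set.seed(2)
  m <- matrix(rnorm(30), 10, 3,
              dimnames = list(sprintf("s%d", 1:10), sprintf("g%d", 1:3)))
  e <- expression_matrix(m, "normalized")
  out <- batch_correct(list(e), method = "none")
  expect_equal(out[[1]]$values, m)
  expect_identical(out[[1]]$layer, "corrected")
})

test_that("center_scale centers every section per gene and matches hand arithmetic", {
  set.seed(3)
  m1 <- matrix(rnorm(12, mean = 5), 4, 3,
               dimnames = list(sprintf("a%d", 1:4), sprintf("g%d", 1:3)))
  m2 <- matrix(rnorm(15, mean = -2), 5, 3,
               dimnames = list(sprintf("b%d", 1:5), sprintf("g%d", 1:3)))
  out <- batch_correct(list(expression_matrix(m1, "normalized"),
                            expression_matrix(m2, "normalized")),
                       method = "center_scale")
  for (o in out) {
    expect_true(all(abs(colMeans(o$values)) < 1e-9))
    expect_true(all(is.finite(o$values)))
  }
  # explicit pooled-sd oracle
  for (g in 1:3) {
    c1 <- m1[, g] - mean(m1[, g]); c2 <- m2[, g] - mean(m2[, g])
    pooled <- sqrt((sum(c1^2) + sum(c2^2)) / (4 + 5 - 2))
    expect_equal(unname(out[[1]]$values[, g]), unname(c1 / pooled),
                 tolerance = 1e-12)
    expect_equal(unname(out[[2]]$values[, g]), unname(c2 / pooled),
                 tolerance = 1e-12)
  }
})

test_that("zero-variance genes survive center_scale with unit divisor", {
  m1 <- matrix(c(3, 3, 3, 1, 2, 4), 3, 2,
               dimnames = list(sprintf("a%d", 1:3), c("flat", "varies")))
  out <- batch_correct(list(expression_matrix(m1, "normalized")),
                       method = "center_scale")
  expect_equal(unname(out[[1]]$values[, "flat"]), c(0, 0, 0))
  expect_true(all(is.finite(out[[1]]$values)))
})

test_that("the external correction hook is validated on return", {
  m <- matrix(rnorm(12), 4, 3,
              dimnames = list(sprintf("s%d", 1:4), sprintf("g%d", 1:3)))
  e <- expression_matrix(m, "normalized")
  good <- function(xs) lapply(xs, function(x) x * 2)
  out <- batch_correct(list(e), method = "external_harmony", hook = good)
  expect_equal(out[[1]]$values, m * 2)
  bad <- function(xs) lapply(xs, function(x) x[, 1:2])
  expect_error(batch_correct(list(e), method = "external_harmony", hook = bad),
               "shape")
  expect_error(batch_correct(list(e), method = "external_harmony"), "hook")
})
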