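test_that("pcc reproduces the textbook values", {
  expect_equal(pcc(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pcc(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pcc(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
})

test_that("pcc is symmetric, affine-invariant, and matches its closed form", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- pcc(x, y)
    expect_equal(r, pcc(y, x), tolerance = 1e-12)
    expect_equal(r, pcc(2.5 * x + 7, y), tolerance = 1e-12)
    expect_equal(r, bf_pcc(x, y), tolerance = 1e-12)
    expect_gte(r, -1); expect_lte(r, 1)
  }
})

test_that("pcc returns an undefined marker for zero variance, not an error", {
  expect_message(r <- pcc(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r))
  expect_error(pcc(1, c(1, 2)), "equal length")
  expect_error(pcc(1, 2), "two observations")
})

make_pair <- function(n, g, seed, pred_fun = NULL) {
  set.seed(seed)
  t_m <- matrix(rnorm(n * g), n, g,
                dimnames = list(sprintf("s%d", 1:n), sprintf("g%02d", 1:g)))
  p_m <- if (is.null(pred_fun)) {
    matrix(rnorm(n * g), n, g, dimnames = dimnames(t_m))
  } else pred_fun(t_m)
  list(truth = expression_matrix(t_m, "normalized"),
       pred = expression_matrix(p_m, "predicted"))
}

test_that("mean_pcc_all is exact for perfect and anti-symmetric toys", {
  pr <- make_pair(10, 4, 1, pred_fun = identity)
  expect_equal(mean_pcc_all(pr$truth, pr$pred)$mean_all, 1.0)

  set.seed(2)
  t_m <- matrix(rnorm(16), 8, 2,
                dimnames = list(sprintf("s%d", 1:8), c("up", "down")))
  p_m <- cbind(up = t_m[, "up"], down = -t_m[, "down"])
  rownames(p_m) <- rownames(t_m)
  got <- mean_pcc_all(expression_matrix(t_m, "normalized"),
                      expression_matrix(p_m, "predicted"))
  expect_equal(got$mean_all, 0.0, tolerance = 1e-12)
})

test_that("mean_pcc_all matches the brute-force per-gene loop", {
  for (seed in 1:5) {
    pr <- make_pair(10, 6, seed)
    got <- mean_pcc_all(pr$truth, pr$pred)
    expect_equal(got$mean_all, bf_mean_pcc(pr$truth$values, pr$pred$values),
                 tolerance = 1e-12)
    expect_identical(got$k_used + got$n_undefined, 6L)
  }
})

test_that("zero-variance genes are excluded and counted, never coerced", {
  pr <- make_pair(8, 3, 9)
  pr$pred$values[, 2] <- 5 # flat prediction column
  got <- mean_pcc_all(pr$truth, pr$pred)
  expect_identical(got$n_undefined, 1L)
  expect_identical(got$k_used, 2L)
  expect_true(is.na(got$per_gene$pcc[2]))
  expect_equal(got$mean_all,
               mean(got$per_gene$pcc, na.rm = TRUE), tolerance = 1e-15)
})

test_that("mean_pcc_all is invariant under joint gene permutation", {
  pr <- make_pair(12, 5, 4)
  perm <- c(3, 5, 1, 4, 2)
  a <- mean_pcc_all(pr$truth, pr$pred)$mean_all
  b <- mean_pcc_all(
    expression_matrix(pr$truth$values[, perm], "normalized"),
    expression_matrix(pr$pred$values[, perm], "predicted"))$mean_all
  expect_equal(a, b, tolerance = 1e-15)
})

test_that("the HEG metric reduces to mean_pcc_all at k_prime = k", {
  pr <- make_pair(10, 5, 6)
  full <- mean_pcc_top_heg(pr$truth, pr$pred, k_prime = 5)
  expect_equal(full$mean_top_heg, mean_pcc_all(pr$truth, pr$pred)$mean_all,
               tolerance = 1e-12)
})

test_that("perfectly predicted top genes give a HEG mean of 1", {
  set.seed(8)
  n <- 12
  t_m <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(sprintf("s%d", 1:n), sprintf("g%02d", 1:6)))
  p_m <- matrix(rnorm(n * 6), n, 6, dimnames = dimnames(t_m))
  # genes 1:3 most expressed in prediction AND perfectly predicted
  p_m[, 1:3] <- t_m[, 1:3] + 100
  got <- mean_pcc_top_heg(expression_matrix(t_m, "normalized"),
                          expression_matrix(p_m, "predicted"), k_prime = 3)
  expect_identical(sort(got$heg_ids), c("g01", "g02", "g03"))
  expect_equal(got$mean_top_heg, 1.0, tolerance = 1e-12)
})

test_that("the HEG metric matches the brute-force ranking oracle", {
  for (seed in 1:5) {
    pr <- make_pair(9, 7, seed + 20)
    got <- mean_pcc_top_heg(pr$truth, pr$pred, k_prime = 3)
    oracle <- bf_top_heg(pr$truth$values, pr$pred$values, 3)
    expect_equal(got$mean_top_heg, oracle$mean, tolerance = 1e-12)
    expect_identical(got$heg_ids, oracle$ids)
  }
  pr <- make_pair(9, 4, 1)
  expect_error(mean_pcc_top_heg(pr$truth, pr$pred, k_prime = 5), "exceeds")
})

test_that("eval_report assembles consistent summaries and tidiers", {
  pr <- make_pair(10, 6, 13)
  rep <- eval_report(pr$truth, pr$pred, k_prime = 3)
  expect_s3_class(rep, "eval_report")
  expect_identical(rep$k_used + rep$n_undefined, 6L)
  expect_length(rep$heg_ids, 3L)
  td <- tidy(rep)
  expect_identical(td$gene_id, sprintf("g%02d", 1:6))
  expect_identical(sum(td$is_heg), 3L)
  gl <- glance(rep)
  expect_identical(names(gl),
                   c("mean_all", "mean_top_heg", "k_used", "n_undefined",
                     "k_prime"))
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("spatial_gene_plot writes a non-empty file with shared color limits", {
  ds <- make_test_dataset(n_spots = 9L, n_genes = 4L, seed = 15L)
  set.seed(1)
  pred_vals <- ds$expression$values + matrix(rnorm(36), 9, 4)
  pred <- expression_matrix(pred_vals, "predicted")
  out <- withr::local_tempfile(fileext = ".png")
  p <- spatial_gene_plot(ds, pred, "G01", out_path = out)
  expect_true(file.exists(out))
  expect_gt(file.size(out), 0)
  lims <- range(c(ds$expression$values[, "G01"], pred_vals[, "G01"]))
  sc <- p$scales$get_scales("colour")
  expect_equal(sc$limits, lims)
  expect_error(spatial_gene_plot(ds, pred, "NOPE"), "absent")
})

test_that("identical observed and predicted values give identical panels", {
  ds <- make_test_dataset(n_spots = 6L, n_genes = 3L, seed = 16L)
  pred <- expression_matrix(ds$expression$values + 0, "predicted")
  p <- spatial_gene_plot(ds, pred, "G02")
  df <- ggplot2::ggplot_build(p)$data[[1]]
  panels <- split(df, df$PANEL)
  expect_equal(panels[[1]]$colour, panels[[2]]$colour)
  expect_equal(panels[[1]]$x, panels[[2]]$x)
})
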