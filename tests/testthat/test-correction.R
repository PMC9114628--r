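test_that("the fitted model is orthonormal with deterministic signs", {
  set.seed(71)
  x <- matrix(rnorm(200 * 30, 5), 200, 30)
  fit <- fit_correction_model(x, 10)
  v <- fit$model$loadings
  expect_equal(crossprod(v), diag(10), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(fit$model$gene_std > 0))
  # dominant entry of every component is positive
  expect_true(all(apply(v, 2, function(col) col[which.max(abs(col))] > 0)))
  fit2 <- fit_correction_model(x, 10)
  expect_identical(fit$model$loadings, fit2$model$loadings)
  expect_error(fit_correction_model(x, 31), "k")
})

test_that("low-rank structure is captured exactly at matching k", {
  set.seed(72)
  # rank-2 signal plus per-gene offsets
  u <- matrix(rnorm(100 * 2), 100, 2)
  w <- matrix(rnorm(2 * 20), 2, 20)
  x <- sweep(u %*% w, 2, runif(20, 5, 10), "+")
  fit <- fit_correction_model(x, 2)
  s <- sweep(sweep(x, 2, fit$model$gene_mean), 2, fit$model$gene_std, "/")
  expect_equal(fit$embedding %*% t(fit$model$loadings), s, tolerance = 1e-8)
})

test_that("constant genes are clamped and ignored by the components", {
  set.seed(73)
  x <- cbind(matrix(rnorm(50 * 5, 10), 50, 5), const = 3)
  fit <- fit_correction_model(x, 3)
  expect_equal(unname(fit$model$gene_std[6]), 1)
  expect_equal(max(abs(fit$model$loadings[6, ])), 0, tolerance = 1e-10)
})

test_that("inverse transformation round-trips at full rank", {
  set.seed(74)
  x <- matrix(abs(rnorm(60 * 15, 5)), 60, 15)
  fit <- fit_correction_model(x, 15)
  xhat <- inverse_correct(fit$model, fit$embedding)
  expect_equal(xhat, x, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(attr(xhat, "clipped"), 0)

  # zero embedding reconstructs the gene means (all positive here)
  x0 <- inverse_correct(fit$model, matrix(0, 60, 15))
  expect_equal(x0, matrix(fit$model$gene_mean, 60, 15, byrow = TRUE),
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(inverse_correct(fit$model, fit$embedding[, 1:5]), "columns")
})

test_that("embedding shifts map linearly back to expression space", {
  set.seed(75)
  x <- matrix(abs(rnorm(40 * 10, 8, 1)), 40, 10)
  fit <- fit_correction_model(x, 10)
  delta <- rnorm(10, 0, 0.1)
  shifted <- sweep(fit$embedding, 2, delta, "+")
  xs <- inverse_correct(fit$model, shifted)
  expected_shift <- sweep(matrix(delta, 40, 10, byrow = TRUE) %*%
                            t(fit$model$loadings),
                          2, fit$model$gene_std, "*")
  expect_equal(xs - inverse_correct(fit$model, fit$embedding),
               expected_shift, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("reconstruction error decreases in k and negative values clip", {
  set.seed(76)
  x <- matrix(abs(rnorm(50 * 12, 4)), 50, 12)
  errs <- vapply(c(2, 5, 9, 12), function(k) {
    fit <- fit_correction_model(x, k)
    raw <- sweep(sweep(fit$embedding %*% t(fit$model$loadings),
                       2, fit$model$gene_std, "*"),
                 2, fit$model$gene_mean, "+")
    sqrt(mean((raw - x)^2))
  }, 0)
  expect_false(is.unsorted(rev(errs)))
  expect_lt(errs[4], 1e-8)

  # a large negative embedding forces clipping, which is reported
  fit <- fit_correction_model(x, 12)
  xneg <- inverse_correct(fit$model, fit$embedding - 50)
  expect_true(all(xneg >= 0))
  expect_gt(attr(xneg, "clipped"), 0)
})

test_that("a planted in-span batch offset is removed by known-offset correction", {
  set.seed(77)
  fx <- generate_atlas(synthetic_atlas_spec(seed = 77, n_genes = 50,
                                            n_cells_per_type = 125))
  tab <- assemble_atlas(fx)          # 500 cells, 50 genes
  x <- as.matrix(tab$values)
  batch2 <- fx$truth$batch == "batch2"

  # corrupt: additive gene-space shift confined to the model's span
  fit0 <- fit_correction_model(x, 50)
  delta_gene <- sweep(matrix(rnorm(50, 0, 0.3), 1) %*%
                        t(fit0$model$loadings) %*% fit0$model$loadings,
                      2, fit0$model$gene_std, "*")
  xb <- x
  xb[batch2, ] <- sweep(xb[batch2, ], 2, as.numeric(delta_gene), "+")

  # fit on the corrupted data; express the known offset in its embedding
  fit <- fit_correction_model(xb, 50)
  z <- fit$embedding
  dz <- as.numeric((delta_gene / matrix(fit$model$gene_std, 1)) %*%
                     fit$model$loadings)
  z[batch2, ] <- sweep(z[batch2, ], 2, dz, "-")
  xhat <- inverse_correct(fit$model, z)
  expect_lt(sqrt(mean((xhat - x)^2)), 1e-4)
})

test_that("per-organ orchestration fits one model per organ", {
  fx <- generate_atlas(synthetic_atlas_spec(seed = 78, n_genes = 30,
                                            n_cells_per_type = 20))
  tab <- assemble_atlas(fx)
  out <- correct_per_organ(tab, k = 10)
  expect_s3_class(out, "unified_table")
  expect_identical(out$metadata, tab$metadata)
  expect_equal(dim(out), dim(tab))
  # identity correction at reduced k is a PCA smoother, not a copy
  expect_false(identical(as.matrix(out$values), as.matrix(tab$values)))
  full <- correct_per_organ(tab, k = 30)
  expect_equal(as.matrix(full$values), as.matrix(tab$values),
               tolerance = 1e-6)
})
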