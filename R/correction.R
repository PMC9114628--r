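#' Fit a PCA correction model
#'
#' Scales each gene of the normalized matrix to zero mean and unit
#' standard deviation (zero-variance genes keep their values: std is
#' clamped to 1) and extracts the top-k principal components. The model
#' stores per-gene mean, std and the orthonormal loading matrix, which is
#' all that is needed to invert an externally batch-corrected embedding
#' back to a corrected expression matrix with [inverse_correct()] — the
#' embedding correction itself (e.g. Harmony) is the caller's choice.
#'
#' Loading signs are fixed deterministically: the largest-magnitude entry
#' of each component is made positive.
#'
#' @param x Cells-by-genes matrix of normalized values (dense or sparse).
#' @param k Number of components; must not exceed `min(n_cells, n_genes)`.
#'   The assembly convention is 100.
#' @return List with `model` (a `correction_model`: `gene_mean`,
#'   `gene_std`, `loadings` genes-by-k, `k`) and `embedding` (cells-by-k
#'   scores `Z = S %*% loadings` of the scaled matrix `S`).
#' @export
fit_correction_model <- function(x, k = 100) {
  x <- as.matrix(x)
  if (k < 1 || k > min(dim(x))) {
    stop(sprintf("k = %d must lie in 1..min(n_cells, n_genes) = %d",
                 k, min(dim(x))), call. = FALSE)
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  s <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  sv <- svd(s, nu = 0, nv = k)
  v <- sv$v
  # deterministic sign: dominant entry of each component positive
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  model <- structure(
    list(gene_mean = mu, gene_std = sdv, loadings = v, k = k,
         genes = colnames(x)),
    class = "correction_model"
  )
  list(model = model, embedding = s %*% v)
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("correction_model: %d genes, k = %d components\n",
              length(x$gene_mean), x$k))
  invisible(x)
}

#' Invert a corrected embedding back to expression space
#'
#' The inverse transformation: the corrected embedding is projected back
#' through the loadings, multiplied by the original per-gene standard
#' deviation and shifted by the original mean,
#' `X_hat = (Z %*% t(loadings)) * std + mean`. Reconstructed values below
#' zero are clipped to 0 (expression is non-negative); the number of
#' clipped entries is reported in the `clipped` attribute.
#'
#' @param model A `correction_model` from [fit_correction_model()].
#' @param embedding Cells-by-k corrected embedding (e.g. the model's own
#'   embedding after batch integration).
#' @return Cells-by-genes matrix of corrected normalized values, with
#'   attribute `clipped` (count of negative entries set to 0).
#' @export
inverse_correct <- function(model, embedding) {
  stopifnot(inherits(model, "correction_model"))
  embedding <- as.matrix(embedding)
  if (ncol(embedding) != model$k) {
    stop(sprintf("embedding has %d columns; model expects k = %d",
                 ncol(embedding), model$k), call. = FALSE)
  }
  xhat <- embedding %*% t(model$loadings)
  xhat <- sweep(sweep(xhat, 2, model$gene_std, "*"), 2, model$gene_mean, "+")
  clipped <- sum(xhat < 0)
  xhat[xhat < 0] <- 0
  colnames(xhat) <- model$genes
  attr(xhat, "clipped") <- clipped
  xhat
}

#' Per-organ batch correction orchestration
#'
#' Fits one correction model per organ on the cells of that organ (batch
#' structure rarely transfers across organs, so correction is applied
#' within each), passes each per-organ embedding through a caller-supplied
#' correction function, and inverts the corrected embeddings back to
#' expression space.
#'
#' @param table A [unified_table()].
#' @param correct_embedding Function `(embedding, metadata) ->` corrected
#'   embedding of the same shape; defaults to the identity (no
#'   integration), in which case the output is the PCA reconstruction.
#' @param k Components per organ model; truncated to each organ's size.
#' @return A [unified_table()] with corrected values (clipped at 0);
#'   metadata unchanged.
#' @export
correct_per_organ <- function(table, correct_embedding = function(z, meta) z,
                              k = 100) {
  stopifnot(inherits(table, "unified_table"))
  vals <- as.matrix(table$values)
  organs <- unique(table$metadata$organ)
  for (org in organs) {
    i <- which(table$metadata$organ == org)
    kk <- min(k, length(i), ncol(vals))
    fit <- fit_correction_model(vals[i, , drop = FALSE], kk)
    z <- correct_embedding(fit$embedding, table$metadata[i, , drop = FALSE])
    vals[i, ] <- inverse_correct(fit$model, z)
  }
  out <- unified_table(table$gene_axis)
  out <- insert_cells(out, vals, table$metadata)
  out
}
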