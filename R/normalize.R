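#' Undo a log transform applied upstream
#'
#' Datasets arrive log-transformed in assorted bases; the assembly pipeline
#' first maps each value v back to raw scale as `base^v - 1` (pseudo-count
#' 1), so that library-size normalization sees comparable inputs. Zeros are
#' a fixed point.
#'
#' @param matrix Numeric matrix (dense or sparse), finite and non-negative.
#' @param log_base Base of the incoming log transform: `exp(1)`, 2 or 10.
#' @return Matrix of the same shape on raw scale.
#' @export
delog <- function(matrix, log_base = exp(1)) {
  stopifnot(is.numeric(log_base), length(log_base) == 1L, log_base > 1)
  if (inherits(matrix, "Matrix")) {
    m <- as(as(matrix, "CsparseMatrix"), "generalMatrix")
    if (any(!is.finite(m@x))) stop("non-finite values in input", call. = FALSE)
    m@x <- expm1(m@x * log(log_base))
    m
  } else {
    if (any(!is.finite(matrix))) stop("non-finite values in input", call. = FALSE)
    expm1(matrix * log(log_base))
  }
}

#' Library-size normalization
#'
#' Rescales each cell's counts to a common sequencing depth and applies
#' `log1p`: for cell i with library size `L_i = sum_g counts[g, i] > 0`,
#' `value[g, i] = ln(1 + counts[g, i] * scale_factor / L_i)`. Cells with an
#' empty library stay all-zero and are reported via the `zero_library`
#' attribute (their 0-based column indices); dropping them is a QC decision
#' left to the caller.
#'
#' @param counts Gene-by-cell count matrix (dense or sparse), non-negative.
#' @param scale_factor Target reads per cell; the assembly convention is
#'   10,000.
#' @return Sparse matrix of normalized values with attribute `zero_library`.
#' @examples
#' m <- normalize_library_size(matrix(c(1, 1, 2), ncol = 1))
#' sum(expm1(m@x))  # 10000: depth is exactly restored per cell
#' @export
normalize_library_size <- function(counts, scale_factor = 10000) {
  stopifnot(is.numeric(scale_factor), length(scale_factor) == 1L,
            scale_factor > 0)
  m <- as(as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
          "generalMatrix")
  if (length(m@x) && any(m@x < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  lib <- Matrix::colSums(m)
  zero <- which(lib == 0) - 1L
  scale <- ifelse(lib > 0, scale_factor / lib, 0)
  # column-scale then log1p on the nonzero pattern
  out <- m %*% Matrix::Diagonal(ncol(m), scale)
  out <- as(as(out, "CsparseMatrix"), "generalMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m)
  attr(out, "zero_library") <- as.integer(zero)
  out
}
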