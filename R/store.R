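#' The 17-column cell metadata schema
#'
#' Field names of the per-cell metadata record of a [unified_table()]. All
#' fields are text; a missing value is stored as the empty string, never as
#' `NA`, so that string comparisons in queries are total.
#'
#' @return Character vector of the 17 field names.
#' @export
metadata_fields <- function() {
  c("user_id", "study_id", "cell_id", "organ", "region", "subregion",
    "seq_tech", "sample_status", "donor_id", "donor_gender", "donor_age",
    "original_name", "cl_name", "uhaf_name", "tissue_type", "cell_type",
    "marker_gene")
}

#' Create a unified table (uGT)
#'
#' The unified table holds, for every cell, its full expression vector over
#' one fixed gene axis plus the 17 metadata columns, all addressable by a
#' contiguous 0-based integer row key (the cid). Expression values are
#' normalized (non-negative reals); raw counts live upstream in the ingest
#' pipeline (see [normalize_library_size()]).
#'
#' @param gene_axis Character vector of unique approved gene symbols fixing
#'   the column axis of the table.
#' @return An empty `unified_table` object (0 cells) over `gene_axis`.
#' @seealso [insert_cells()], [fetch()], [query_cells()], [save_atlas()]
#' @examples
#' tab <- unified_table(c("PTPRC", "CD3D", "CD3E"))
#' tab <- insert_cells(tab,
#'   expr = matrix(c(1, 0.5, 0), nrow = 1,
#'                 dimnames = list(NULL, c("PTPRC", "CD3D", "CD3E"))),
#'   meta = data.frame(organ = "Heart", cell_type = "T cell"))
#' n_cells(tab)
#' @export
unified_table <- function(gene_axis) {
  gene_axis <- as.character(gene_axis)
  if (length(gene_axis) == 0L) stop("gene_axis must be non-empty", call. = FALSE)
  if (anyDuplicated(gene_axis)) {
    stop("gene_axis entries must be unique", call. = FALSE)
  }
  if (any(is.na(gene_axis) | gene_axis == "")) {
    stop("gene_axis entries must be non-empty strings", call. = FALSE)
  }
  meta <- as.data.frame(
    matrix(character(0), nrow = 0, ncol = length(metadata_fields()),
           dimnames = list(NULL, metadata_fields())),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      gene_axis = gene_axis,
      values = Matrix::Matrix(0, nrow = 0, ncol = length(gene_axis),
                              sparse = TRUE),
      metadata = meta
    ),
    class = "unified_table"
  )
}

#' Number of cells in a unified table
#' @param table A [unified_table()].
#' @return Integer cell count.
#' @export
n_cells <- function(table) {
  stopifnot(inherits(table, "unified_table"))
  nrow(table$values)
}

#' @export
dim.unified_table <- function(x) c(nrow(x$values), length(x$gene_axis))

#' @export
print.unified_table <- function(x, ...) {
  cat(sprintf("unified_table: %d cells x %d genes\n",
              nrow(x$values), length(x$gene_axis)))
  nz <- Matrix::nnzero(x$values)
  cat(sprintf("  nonzero entries: %d (density %.3g)\n", nz,
              if (prod(dim(x)) > 0) nz / prod(dim(x)) else 0))
  orgs <- setdiff(unique(x$metadata$organ), "")
  if (length(orgs)) {
    cat("  organs:", paste(utils::head(sort(orgs), 8), collapse = ", "),
        if (length(orgs) > 8) "..." else "", "\n")
  }
  invisible(x)
}

# normalize user metadata into the full 17-column character frame
coerce_metadata <- function(meta, n) {
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n) {
    stop(sprintf("metadata has %d records for %d cells", nrow(meta), n),
         call. = FALSE)
  }
  unknown <- setdiff(names(meta), metadata_fields())
  if (length(unknown)) {
    stop("unknown metadata field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- as.data.frame(
    matrix("", nrow = n, ncol = length(metadata_fields()),
           dimnames = list(NULL, metadata_fields())),
    stringsAsFactors = FALSE
  )
  for (f in names(meta)) {
    v <- as.character(meta[[f]])
    v[is.na(v)] <- ""
    out[[f]] <- v
  }
  rownames(out) <- NULL
  out
}

#' Append cells to a unified table
#'
#' New rows receive the next contiguous cids; existing rows are unchanged.
#'
#' @param table A [unified_table()].
#' @param expr Expression matrix (dense or sparse). With
#'   `orientation = "cell_by_gene"` (default) rows are cells and columns
#'   must match the table's gene axis; with `orientation = "gene_by_cell"`
#'   the input is transposed on ingestion, the layout most upstream
#'   pipelines emit.
#' @param meta Data frame (or coercible) of per-cell metadata; columns must
#'   be a subset of [metadata_fields()]; missing fields are filled with the
#'   empty string. `NULL` means all-empty metadata.
#' @param orientation Orientation of `expr`.
#' @return The updated `unified_table`.
#' @export
insert_cells <- function(table, expr, meta = NULL,
                         orientation = c("cell_by_gene", "gene_by_cell")) {
  stopifnot(inherits(table, "unified_table"))
  orientation <- match.arg(orientation)
  expr <- as(as(Matrix::Matrix(expr, sparse = TRUE), "CsparseMatrix"),
             "generalMatrix")
  if (orientation == "gene_by_cell") expr <- Matrix::t(expr)
  if (ncol(expr) != length(table$gene_axis)) {
    stop(sprintf("expression has %d gene columns but gene_axis has %d",
                 ncol(expr), length(table$gene_axis)), call. = FALSE)
  }
  if (!is.null(colnames(expr)) &&
      !identical(colnames(expr), table$gene_axis)) {
    stop("expression column names do not match the table gene_axis",
         call. = FALSE)
  }
  v <- expr@x
  if (length(v) && (any(!is.finite(v)) || any(v < 0))) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  meta <- coerce_metadata(meta, nrow(expr))
  dimnames(expr) <- NULL
  table$values <- rbind(table$values, expr)
  table$metadata <- rbind(table$metadata, meta)
  rownames(table$metadata) <- NULL
  table
}

#' All cell ids in the table
#'
#' @param table A [unified_table()].
#' @return Integer vector `0:(n-1)` (empty for an empty table).
#' @export
get_all_rows <- function(table) {
  stopifnot(inherits(table, "unified_table"))
  n <- nrow(table$values)
  if (n == 0L) integer(0) else 0:(n - 1L)
}

check_cids <- function(table, rows) {
  if (is.null(rows)) return(get_all_rows(table))
  rows <- as.integer(rows)
  if (anyNA(rows) || any(rows < 0L) || any(rows >= nrow(table$values))) {
    stop("cids must lie in 0..n-1", call. = FALSE)
  }
  if (is.unsorted(rows, strictly = TRUE)) rows <- sort(unique(rows))
  rows
}

# split requested columns into metadata fields and gene symbols
resolve_columns <- function(table, cols) {
  if (is.null(cols) || identical(cols, "ALL")) {
    cols <- c(table$gene_axis, metadata_fields())
  }
  is_meta <- cols %in% metadata_fields()
  is_gene <- cols %in% table$gene_axis
  bad <- cols[!is_meta & !is_gene]
  if (length(bad)) {
    stop("unknown column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  list(cols = cols, is_gene = is_gene)
}

#' Fetch a slice of the unified table
#'
#' Retrieves the requested columns (gene symbols and/or metadata fields) for
#' a set of cells, optionally restricted by a logic-expression filter
#' evaluated on those cells. Gene columns come back numeric, metadata
#' columns as text; the returned data frame carries the surviving cids in
#' its `"cids"` attribute (and as row names).
#'
#' @param table A [unified_table()].
#' @param rows Integer cids (0-based) or `NULL` for all cells.
#' @param cols Character vector of column names, or `"ALL"` (default) for
#'   every gene column followed by the 17 metadata columns.
#' @param row_filter Optional filter: a query string or a parsed
#'   [parse_expression()] tree, evaluated per cell; only passing cells are
#'   returned.
#' @param include_children,ontology,numeric_fields Passed to the filter
#'   evaluation; see [query_cells()].
#' @return A data frame slice, rows in cid order, with attribute `cids`.
#' @export
fetch <- function(table, rows = NULL, cols = "ALL", row_filter = NULL,
                  include_children = FALSE, ontology = NULL,
                  numeric_fields = character()) {
  stopifnot(inherits(table, "unified_table"))
  rows <- check_cids(table, rows)
  rc <- resolve_columns(table, cols)
  if (!is.null(row_filter)) {
    keep <- eval_expression(row_filter, table, rows,
                            include_children = include_children,
                            ontology = ontology,
                            numeric_fields = numeric_fields)
    rows <- rows[keep]
  }
  idx <- rows + 1L
  out <- vector("list", length(rc$cols))
  names(out) <- rc$cols
  for (j in seq_along(rc$cols)) {
    if (rc$is_gene[j]) {
      out[[j]] <- as.numeric(table$values[idx, match(rc$cols[j], table$gene_axis)])
    } else {
      out[[j]] <- table$metadata[[rc$cols[j]]][idx]
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE,
                       check.names = FALSE)
  if (nrow(out) == 0L && length(rows) > 0L) {
    # zero-column request still carries its rows
    out <- as.data.frame(matrix(nrow = length(rows), ncol = 0))
  }
  rownames(out) <- if (length(rows)) as.character(rows) else NULL
  attr(out, "cids") <- rows
  out
}

#' Distinct values of one column over a set of cells
#'
#' @param table A [unified_table()].
#' @param rows Integer cids or `NULL` for all cells.
#' @param column One metadata field or gene symbol.
#' @return The set (unique, sorted) of values over the given rows:
#'   character for metadata columns, numeric for gene columns.
#' @export
get_column_set <- function(table, rows = NULL, column) {
  stopifnot(inherits(table, "unified_table"), length(column) == 1L)
  rows <- check_cids(table, rows)
  rc <- resolve_columns(table, column)
  idx <- rows + 1L
  if (rc$is_gene[1]) {
    sort(unique(as.numeric(table$values[idx, match(column, table$gene_axis)])))
  } else {
    sort(unique(table$metadata[[column]][idx]))
  }
}

# full-precision MatrixMarket coordinate writer; Matrix::writeMM trims to
# %g precision which would break exact persistence round-trips
write_mm_full <- function(m, path) {
  m <- as(as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"), "TsparseMatrix")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate real general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), length(m@x)), con)
  if (length(m@x)) {
    writeLines(sprintf("%d %d %s", m@i + 1L, m@j + 1L,
                       formatC(m@x, format = "g", digits = 17)), con)
  }
  invisible(path)
}

#' Persist a unified table as an atlas directory
#'
#' Writes the four-file interchange convention: `matrix.mtx` (MatrixMarket
#' coordinate real general, 1-based indices, cells as rows), `rows.txt`
#' (cids, one per line), `cols.txt` (gene symbols, one per line) and
#' `metadata.csv` (header row, UTF-8). [load_atlas()] reconstructs a table
#' equal to the saved one.
#'
#' @param table A [unified_table()].
#' @param directory Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
save_atlas <- function(table, directory) {
  stopifnot(inherits(table, "unified_table"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_mm_full(table$values, file.path(directory, "matrix.mtx"))
  writeLines(as.character(get_all_rows(table)), file.path(directory, "rows.txt"))
  writeLines(table$gene_axis, file.path(directory, "cols.txt"))
  utils::write.csv(table$metadata, file.path(directory, "metadata.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(directory)
}

atlas_file <- function(directory, name) {
  p <- file.path(directory, name)
  if (!file.exists(p)) {
    stop(sprintf("atlas directory is missing '%s'", name), call. = FALSE)
  }
  p
}

#' Load a unified table from an atlas directory
#'
#' @param directory Directory written by [save_atlas()].
#' @return The reconstructed [unified_table()].
#' @export
load_atlas <- function(directory) {
  mtx <- atlas_file(directory, "matrix.mtx")
  values <- tryCatch(Matrix::readMM(mtx), error = function(e) {
    stop(sprintf("matrix.mtx is not a readable MatrixMarket file: %s",
                 conditionMessage(e)), call. = FALSE)
  })
  values <- as(as(values, "CsparseMatrix"), "generalMatrix")
  cids <- readLines(atlas_file(directory, "rows.txt"))
  genes <- readLines(atlas_file(directory, "cols.txt"))
  if (length(cids) != nrow(values)) {
    stop(sprintf("rows.txt has %d lines but matrix.mtx has %d rows",
                 length(cids), nrow(values)), call. = FALSE)
  }
  if (length(genes) != ncol(values)) {
    stop(sprintf("cols.txt has %d lines but matrix.mtx has %d columns",
                 length(genes), ncol(values)), call. = FALSE)
  }
  if (length(cids) && !identical(as.integer(cids), seq_len(length(cids)) - 1L)) {
    stop("rows.txt: cids are not contiguous 0..n-1", call. = FALSE)
  }
  meta <- utils::read.csv(atlas_file(directory, "metadata.csv"),
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(), fileEncoding = "UTF-8")
  if (!identical(names(meta), metadata_fields())) {
    stop("metadata.csv: header does not match the 17-column schema",
         call. = FALSE)
  }
  if (nrow(meta) != nrow(values)) {
    stop(sprintf("metadata.csv has %d records but matrix.mtx has %d rows",
                 nrow(meta), nrow(values)), call. = FALSE)
  }
  tab <- unified_table(genes)
  tab$values <- values
  tab$metadata <- meta
  tab
}
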