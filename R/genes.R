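#' Construct a gene symbol table
#'
#' Holds the closed list of approved symbols that fixes the atlas gene axis
#' plus the map from previous/withdrawn/alias symbols to approved ones.
#'
#' @param approved Ordered character vector of unique approved symbols.
#' @param alias_map Named character vector: names are alias symbols, values
#'   the approved symbol each resolves to. May be empty.
#' @return A `gene_symbol_table` object.
#' @export
gene_symbol_table <- function(approved, alias_map = character()) {
  approved <- as.character(approved)
  if (anyDuplicated(approved)) {
    stop("duplicate approved symbol", call. = FALSE)
  }
  if (any(approved == "" | is.na(approved))) {
    stop("approved symbols must be non-empty strings", call. = FALSE)
  }
  alias_map <- unlist(alias_map)
  if (length(alias_map)) {
    alias_map <- vapply(alias_map, as.character, "")
    if (is.null(names(alias_map)) || any(names(alias_map) == "")) {
      stop("alias_map must be a named vector (alias -> approved)", call. = FALSE)
    }
    if (!all(alias_map %in% approved)) {
      stop("alias points to unknown approved symbol: ",
           paste(setdiff(alias_map, approved), collapse = ", "), call. = FALSE)
    }
    if (any(names(alias_map) %in% approved)) {
      stop("symbol is both approved and an alias: ",
           paste(intersect(names(alias_map), approved), collapse = ", "),
           call. = FALSE)
    }
    dup <- names(alias_map)[duplicated(names(alias_map))]
    if (length(dup)) {
      stop("alias mapped more than once: ", paste(unique(dup), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(approved = approved, alias_map = alias_map),
            class = "gene_symbol_table")
}

#' @export
print.gene_symbol_table <- function(x, ...) {
  cat(sprintf("gene_symbol_table: %d approved symbols, %d aliases\n",
              length(x$approved), length(x$alias_map)))
  invisible(x)
}

#' Read a gene symbol table from TSV
#'
#' Expects a tab-separated file with header columns `approved` and `alias`;
#' one row per approved symbol. The `alias` field may be empty or hold
#' several aliases separated by `|`.
#'
#' @param path File path.
#' @return A [gene_symbol_table()].
#' @export
load_symbol_table <- function(path) {
  df <- utils::read.csv(path, sep = "\t", colClasses = "character",
                        na.strings = character(), check.names = FALSE)
  if (!all(c("approved", "alias") %in% names(df))) {
    stop("symbol table must have columns 'approved' and 'alias'", call. = FALSE)
  }
  aliases <- strsplit(df$alias, "|", fixed = TRUE)
  n_al <- lengths(aliases)
  alias_map <- character(0)
  if (any(n_al > 0)) {
    alias_map <- stats::setNames(rep(df$approved, n_al), unlist(aliases))
    alias_map <- alias_map[names(alias_map) != ""]
  }
  gene_symbol_table(df$approved, alias_map)
}

#' Unify gene identifiers onto the approved symbol axis
#'
#' Maps every input gene name onto the approved axis: approved names map to
#' themselves, alias names via the alias map, and anything else is dropped
#' (reported). Names resolving to the same approved symbol have their counts
#' summed; approved genes absent from the input become zero rows. The output
#' axis is exactly the approved list, in table order, regardless of input
#' order — so every processed dataset shares one gene coordinate system.
#'
#' @param matrix Gene-by-cell count matrix (dense or sparse) with row names
#'   giving the input gene identifiers.
#' @param symbols A [gene_symbol_table()].
#' @return A list with
#'   \describe{
#'     \item{matrix}{sparse gene-by-cell matrix over the full approved axis;}
#'     \item{report}{list with `unmapped` (dropped input names),
#'       `unmapped_total` (their total counts), and `collisions`
#'       (data frame: approved symbol, number of input rows merged).}
#'   }
#' @export
unify_symbols <- function(matrix, symbols) {
  stopifnot(inherits(symbols, "gene_symbol_table"))
  m <- as(as(Matrix::Matrix(matrix, sparse = TRUE), "CsparseMatrix"),
          "generalMatrix")
  nm <- rownames(m)
  if (is.null(nm) || any(nm == "")) {
    stop("input gene names must be non-empty row names", call. = FALSE)
  }
  if (length(m@x) && any(m@x < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  target <- ifelse(nm %in% symbols$approved, nm,
                   unname(symbols$alias_map[nm]))
  mapped <- !is.na(target)
  unmapped <- nm[!mapped]
  unmapped_total <- if (any(!mapped)) sum(m[!mapped, , drop = FALSE]) else 0
  ti <- match(target[mapped], symbols$approved)
  # aggregation matrix: approved x mapped-input rows
  agg <- Matrix::sparseMatrix(i = ti, j = seq_along(ti), x = 1,
                              dims = c(length(symbols$approved), length(ti)))
  out <- agg %*% m[mapped, , drop = FALSE]
  out <- as(as(out, "CsparseMatrix"), "generalMatrix")
  rownames(out) <- symbols$approved
  colnames(out) <- colnames(m)
  tab <- table(target[mapped])
  coll <- tab[tab > 1]
  collisions <- data.frame(approved = names(coll),
                           n_merged = as.integer(coll),
                           stringsAsFactors = FALSE)
  list(matrix = out,
       report = list(unmapped = unmapped,
                     unmapped_total = unmapped_total,
                     collisions = collisions))
}
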