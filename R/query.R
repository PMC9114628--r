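#' @name query-language
#' @title The logic-expression query language
#' @description
#' Cells are selected "in data" with boolean expressions over metadata
#' fields and gene expression, e.g.
#'
#' ```
#' (organ==Heart) && (cell_type == T cell) && (PTPRC > 0.5) &&
#'   ((CD3D >= 0.5) || (CD3E >= 0.5))
#' ```
#'
#' Grammar: comparisons `column op value` with `op` one of `==`, `!=`,
#' `>`, `>=`, `<`, `<=`, combined with `!` (NOT), `&&` (AND), `||` (OR).
#' Precedence NOT > AND > OR, left-associative, parentheses override.
#' Whitespace around tokens is ignored; a comparison's value runs to the
#' next logical operator or closing parenthesis and is trimmed, so
#' unquoted multi-word values like `T cell` parse. String comparisons are
#' exact and case-sensitive; ordering operators apply only to numeric
#' columns (genes, or metadata fields declared numeric).
NULL

QUERY_OPS <- c("==", "!=", ">=", "<=", ">", "<")  # longest match first

cmp_node <- function(column, op, value) {
  list(kind = "cmp", column = column, op = op, value = value)
}

parse_error <- function(msg, pos) {
  stop(sprintf("query parse error at position %d: %s", pos, msg),
       call. = FALSE)
}

# recursive-descent parser over a character-split string; returns
# list(node, pos). Values are raw text: they extend to the next '&&',
# '||' or ')' and are trimmed.
new_parser <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)

  peek2 <- function(pos) {
    if (pos + 1L <= n) paste0(chars[pos], chars[pos + 1L]) else ""
  }
  skip_ws <- function(pos) {
    while (pos <= n && grepl("^\\s$", chars[pos])) pos <- pos + 1L
    pos
  }

  parse_or <- function(pos) {
    r <- parse_and(pos)
    children <- list(r$node)
    pos <- skip_ws(r$pos)
    while (pos <= n && peek2(pos) == "||") {
      r <- parse_and(pos + 2L)
      children <- c(children, list(r$node))
      pos <- skip_ws(r$pos)
    }
    node <- if (length(children) == 1L) children[[1]] else
      list(kind = "or", children = children)
    list(node = node, pos = pos)
  }

  parse_and <- function(pos) {
    r <- parse_not(pos)
    children <- list(r$node)
    pos <- skip_ws(r$pos)
    while (pos <= n && peek2(pos) == "&&") {
      r <- parse_not(pos + 2L)
      children <- c(children, list(r$node))
      pos <- skip_ws(r$pos)
    }
    node <- if (length(children) == 1L) children[[1]] else
      list(kind = "and", children = children)
    list(node = node, pos = pos)
  }

  parse_not <- function(pos) {
    pos <- skip_ws(pos)
    if (pos <= n && chars[pos] == "!" && peek2(pos) != "!=") {
      r <- parse_not(pos + 1L)
      return(list(node = list(kind = "not", child = r$node), pos = r$pos))
    }
    parse_primary(pos)
  }

  parse_primary <- function(pos) {
    pos <- skip_ws(pos)
    if (pos > n) parse_error("expected a comparison or '('", pos)
    if (chars[pos] == "(") {
      r <- parse_or(pos + 1L)
      p <- skip_ws(r$pos)
      if (p > n || chars[p] != ")") parse_error("unbalanced '('", pos)
      return(list(node = r$node, pos = p + 1L))
    }
    if (chars[pos] == ")") parse_error("unbalanced ')'", pos)
    parse_comparison(pos)
  }

  parse_comparison <- function(pos) {
    # locate the operator: first occurrence of a canonical token
    op_pos <- NA_integer_; op <- NA_character_
    p <- pos
    while (p <= n) {
      ch <- chars[p]
      if (ch %in% c("(", ")", "&", "|")) break
      two <- peek2(p)
      if (two %in% c("==", "!=", ">=", "<=")) {
        op_pos <- p; op <- two; break
      }
      if (ch %in% c(">", "<")) { op_pos <- p; op <- ch; break }
      if (ch %in% c("=", "!")) {
        parse_error(sprintf("'%s' is not an operator (use %s)", ch,
                            paste(QUERY_OPS, collapse = " ")), p)
      }
      p <- p + 1L
    }
    if (is.na(op_pos)) parse_error("no comparison operator found", pos)
    column <- if (op_pos == pos) "" else
      trimws(paste(chars[pos:(op_pos - 1L)], collapse = ""))
    if (column == "") parse_error("missing column name", pos)
    vstart <- op_pos + nchar(op)
    p <- vstart
    while (p <= n) {
      if (chars[p] == ")") break
      if (peek2(p) %in% c("&&", "||")) break
      if (chars[p] == "(") parse_error("'(' inside a comparison value", p)
      p <- p + 1L
    }
    value <- trimws(paste(chars[vstart:min(p - 1L, n)], collapse = ""))
    if (vstart > n || value == "") parse_error("missing comparison value", vstart)
    list(node = cmp_node(column, op, value), pos = p)
  }

  function() {
    r <- parse_or(1L)
    pos <- skip_ws(r$pos)
    if (pos <= n) {
      parse_error(sprintf("unexpected trailing input '%s'",
                          paste(chars[pos:n], collapse = "")), pos)
    }
    r$node
  }
}

#' Parse a query string
#'
#' See [query-language] for the grammar. The returned tree has node kinds
#' `cmp` (fields `column`, `op`, `value` — the value kept as raw trimmed
#' text), `and` / `or` (field `children`, n-ary, in source order) and `not`
#' (field `child`).
#'
#' @param text Query string.
#' @return A `query_expression` tree.
#' @examples
#' parse_expression("organ==Heart && (CD3D >= 0.5 || CD3E >= 0.5)")
#' @export
parse_expression <- function(text) {
  if (inherits(text, "query_expression")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty query", call. = FALSE)
  node <- new_parser(text)()
  structure(node, class = "query_expression")
}

#' Render a query tree back to text
#'
#' Produces a canonical string that reparses to the same tree:
#' comparisons are written bare, composite children are parenthesized.
#'
#' @param expr A [parse_expression()] tree (or inner node).
#' @return A query string.
#' @export
unparse_expression <- function(expr) {
  wrap <- function(node) {
    s <- unparse_expression(node)
    if (node$kind == "cmp") s else paste0("(", s, ")")
  }
  switch(expr$kind,
    cmp = paste(expr$column, expr$op, expr$value),
    not = paste0("!", wrap(expr$child)),
    and = paste(vapply(expr$children, wrap, ""), collapse = " && "),
    or = paste(vapply(expr$children, wrap, ""), collapse = " || "),
    stop("unknown node kind: ", expr$kind, call. = FALSE)
  )
}

#' @export
print.query_expression <- function(x, ...) {
  cat("query_expression:", unparse_expression(x), "\n")
  invisible(x)
}

# columns referenced by an expression tree
expr_columns <- function(node) {
  switch(node$kind,
    cmp = node$column,
    not = expr_columns(node$child),
    unique(unlist(lapply(node$children, expr_columns)))
  )
}

# Evaluate an expression over the given cids; returns a logical vector
# aligned with `rows`. Equality on `cell_type` (is_a) and `organ`
# (is_a + part_of) expands to the ontology subtree under include_children.
eval_expression <- function(expr, table, rows = NULL,
                            include_children = FALSE, ontology = NULL,
                            numeric_fields = character()) {
  expr <- parse_expression(expr)
  rows <- check_cids(table, rows)
  idx <- rows + 1L
  if (include_children && is.null(ontology)) {
    stop("include_children requires an ontology", call. = FALSE)
  }

  eval_node <- function(node) {
    switch(node$kind,
      and = Reduce(`&`, lapply(node$children, eval_node)),
      or = Reduce(`|`, lapply(node$children, eval_node)),
      not = !eval_node(node$child),
      cmp = eval_cmp(node)
    )
  }

  eval_cmp <- function(node) {
    col <- node$column
    is_gene <- col %in% table$gene_axis
    if (!is_gene && !col %in% metadata_fields()) {
      stop(sprintf("unknown column '%s' in query", col), call. = FALSE)
    }
    numeric_col <- is_gene || col %in% numeric_fields
    if (numeric_col) {
      x <- if (is_gene) {
        as.numeric(table$values[idx, match(col, table$gene_axis)])
      } else {
        suppressWarnings(as.numeric(table$metadata[[col]][idx]))
      }
      v <- suppressWarnings(as.numeric(node$value))
      if (is.na(v)) {
        stop(sprintf("non-numeric value '%s' for numeric column '%s'",
                     node$value, col), call. = FALSE)
      }
      r <- switch(node$op,
                  "==" = x == v, "!=" = x != v, ">" = x > v,
                  ">=" = x >= v, "<" = x < v, "<=" = x <= v)
      r[is.na(r)] <- FALSE  # unparseable text in a numeric field never matches
      return(r)
    }
    x <- table$metadata[[col]][idx]
    if (!node$op %in% c("==", "!=")) {
      stop(sprintf(
        "ordering operator '%s' on text column '%s' (declare it in numeric_fields to compare numerically)",
        node$op, col), call. = FALSE)
    }
    targets <- node$value
    if (include_children && col %in% c("cell_type", "organ")) {
      et <- if (col == "cell_type") "is_a" else c("is_a", "part_of")
      targets <- descendants(ontology, node$value, et)
    }
    hit <- x %in% targets
    if (node$op == "==") hit else !hit
  }

  res <- eval_node(expr)
  if (length(rows) == 0L) logical(0) else res
}

#' Select cells by a logic expression ("in data" cell sorting)
#'
#' Evaluates a query over every cell of the table and returns the cids of
#' the cells satisfying it. With `include_children = TRUE`, an equality
#' comparison on `cell_type` matches any label in the is_a subtree of the
#' named type, and one on `organ` matches the is_a + part_of subtree — so
#' `cell_type == T cell` also selects cells annotated with T-cell subtypes.
#' Gene comparisons evaluate against the stored normalized values.
#'
#' @param table A [unified_table()].
#' @param condition Query string or [parse_expression()] tree.
#' @param include_children Expand equality on ontology-indexed fields to
#'   the whole subtree.
#' @param ontology A [uhaf_ontology()]; required when `include_children`.
#' @param numeric_fields Metadata fields (e.g. `donor_age`) to compare
#'   numerically; by default all metadata comparisons are textual and
#'   ordering operators on them are errors.
#' @return Integer vector of cids, strictly increasing.
#' @examples
#' tab <- unified_table(c("CD3D"))
#' tab <- insert_cells(tab, matrix(c(0.7, 0.9, 0.1), ncol = 1),
#'                     data.frame(organ = c("Heart", "Lung", "Heart")))
#' query_cells(tab, "organ==Heart && CD3D>=0.5")
#' @export
query_cells <- function(table, condition, include_children = FALSE,
                        ontology = NULL, numeric_fields = character()) {
  stopifnot(inherits(table, "unified_table"))
  rows <- get_all_rows(table)
  if (length(rows) == 0L) {
    parse_expression(condition)  # still validate syntax
    return(integer(0))
  }
  keep <- eval_expression(condition, table, rows,
                          include_children = include_children,
                          ontology = ontology,
                          numeric_fields = numeric_fields)
  rows[keep]
}

#' Organ-by-cell-type cross table
#'
#' Counts cells per (organ, cell type) pair over a selection — the summary
#' behind per-organ composition views of a sorted cell set.
#'
#' @param table A [unified_table()].
#' @param rows Integer cids or `NULL` for all cells.
#' @return Integer matrix, rows = organs, columns = cell types, both sorted
#'   lexicographically; empty labels appear as the `""` row/column when
#'   present so that marginals always equal subset sizes.
#' @export
celltype_organ_crosstab <- function(table, rows = NULL) {
  stopifnot(inherits(table, "unified_table"))
  rows <- check_cids(table, rows)
  idx <- rows + 1L
  organ <- table$metadata$organ[idx]
  ctype <- table$metadata$cell_type[idx]
  if (length(idx) == 0L) {
    return(matrix(integer(0), 0, 0))
  }
  tab <- base::table(factor(organ, levels = sort(unique(organ))),
                     factor(ctype, levels = sort(unique(ctype))))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- c("organ", "cell_type")
  m
}
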