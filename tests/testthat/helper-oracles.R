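# Independent oracles and random-instance generators shared by the suite.
# The query oracle deliberately evaluates one cell at a time with plain
# scalar logic, sharing no code with the vectorized engine it checks.

# scalar per-cell evaluation of a parsed expression tree
brute_eval_cell <- function(node, table, cid, include_children = FALSE,
                            ontology = NULL) {
  if (node$kind == "and") {
    for (ch in node$children) {
      if (!brute_eval_cell(ch, table, cid, include_children, ontology)) {
        return(FALSE)
      }
    }
    return(TRUE)
  }
  if (node$kind == "or") {
    for (ch in node$children) {
      if (brute_eval_cell(ch, table, cid, include_children, ontology)) {
        return(TRUE)
      }
    }
    return(FALSE)
  }
  if (node$kind == "not") {
    return(!brute_eval_cell(node$child, table, cid, include_children,
                            ontology))
  }
  col <- node$column
  if (col %in% table$gene_axis) {
    x <- as.numeric(table$values[cid + 1L, match(col, table$gene_axis)])
    v <- as.numeric(node$value)
    return(switch(node$op,
                  "==" = x == v, "!=" = x != v, ">" = x > v,
                  ">=" = x >= v, "<" = x < v, "<=" = x <= v))
  }
  x <- table$metadata[[col]][cid + 1L]
  if (include_children && col %in% c("cell_type", "organ")) {
    et <- if (col == "cell_type") "is_a" else c("is_a", "part_of")
    set <- descendants(ontology, node$value, et)
    return(if (node$op == "==") x %in% set else !(x %in% set))
  }
  if (node$op == "==") x == node$value else x != node$value
}

brute_query <- function(table, expr, include_children = FALSE,
                        ontology = NULL) {
  expr <- parse_expression(expr)
  cids <- get_all_rows(table)
  keep <- vapply(cids, function(cid) {
    brute_eval_cell(expr, table, cid, include_children, ontology)
  }, logical(1))
  cids[keep]
}

# small random table over a few genes/labels for randomized query checks
random_table <- function(n_cells = 25, genes = paste0("G", 1:6)) {
  tab <- unified_table(genes)
  expr <- matrix(round(runif(n_cells * length(genes)) *
                         rbinom(n_cells * length(genes), 1, 0.6), 2),
                 nrow = n_cells)
  meta <- data.frame(
    organ = sample(c("Heart", "Lung", "Brain"), n_cells, replace = TRUE),
    cell_type = sample(c("T cell", "B cell", "Macrophage", ""), n_cells,
                       replace = TRUE),
    donor_gender = sample(c("Male", "Female", ""), n_cells, replace = TRUE),
    stringsAsFactors = FALSE
  )
  insert_cells(tab, expr, meta)
}

# random comparison / expression text over the random_table vocabulary
random_comparison <- function(genes) {
  if (runif(1) < 0.5) {
    col <- sample(genes, 1)
    op <- sample(c("==", "!=", ">", ">=", "<", "<="), 1)
    val <- format(round(runif(1), 2))
  } else {
    col <- sample(c("organ", "cell_type", "donor_gender"), 1)
    op <- sample(c("==", "!="), 1)
    val <- sample(c("Heart", "Lung", "T cell", "B cell", "Male"), 1)
  }
  paste(col, op, val)
}

random_expression <- function(genes, depth = 2) {
  if (depth <= 0 || runif(1) < 0.35) {
    return(random_comparison(genes))
  }
  kind <- sample(c("and", "or", "not"), 1)
  if (kind == "not") {
    return(paste0("!(", random_expression(genes, depth - 1), ")"))
  }
  op <- if (kind == "and") " && " else " || "
  n <- sample(2:3, 1)
  parts <- replicate(n, paste0("(", random_expression(genes, depth - 1), ")"))
  paste(parts, collapse = op)
}

# random AST built directly (for parse/unparse round-trips)
random_ast <- function(depth = 3) {
  if (depth <= 0 || runif(1) < 0.3) {
    node <- list(kind = "cmp",
                 column = sample(c("organ", "cell_type", "G1", "G2"), 1),
                 op = sample(c("==", "!=", ">", ">=", "<", "<="), 1),
                 value = sample(c("Heart", "T cell", "0.5", "1", "x y"), 1))
    return(node)
  }
  kind <- sample(c("and", "or", "not"), 1)
  if (kind == "not") {
    list(kind = "not", child = random_ast(depth - 1))
  } else {
    list(kind = kind,
         children = replicate(sample(2:3, 1), random_ast(depth - 1),
                              simplify = FALSE))
  }
}

# strip the class attribute so parsed trees compare to raw list ASTs
as_plain_ast <- function(x) {
  x <- unclass(x)
  if (x$kind == "not") x$child <- as_plain_ast(x$child)
  if (x$kind %in% c("and", "or")) {
    x$children <- lapply(x$children, as_plain_ast)
  }
  x
}

# four-node diamond + chain ontology used across uhaf/annotate tests
toy_immune_ontology <- function() {
  nodes <- data.frame(
    name = c("Blood", "T cell", "CD4 T cell", "CD8 T cell", "Treg",
             "B cell", "Dendritic cell", "cDC1"),
    kind = c("organ", rep("cell_type", 7)),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    child = c("CD4 T cell", "CD8 T cell", "Treg", "cDC1",
              "T cell", "B cell", "Dendritic cell"),
    parent = c("T cell", "T cell", "CD4 T cell", "Dendritic cell",
               "Blood", "Blood", "Blood"),
    type = c("is_a", "is_a", "is_a", "is_a",
             "part_of", "part_of", "part_of"),
    stringsAsFactors = FALSE
  )
  uhaf_ontology(nodes, edges)
}

# build predicted/truth label vectors realizing a confusion matrix
labels_from_confusion <- function(cm, labels = rownames(cm)) {
  truth <- character(0); pred <- character(0)
  for (i in seq_len(nrow(cm))) {
    for (j in seq_len(ncol(cm))) {
      truth <- c(truth, rep(labels[i], cm[i, j]))
      pred <- c(pred, rep(labels[j], cm[i, j]))
    }
  }
  list(truth = truth, predicted = pred)
}
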