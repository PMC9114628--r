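#' Quantitative gene portrait
#'
#' Summarizes one gene's expression distribution per group (organ or cell
#' type): cell count, number and fraction of expressing cells (value > 0),
#' and the median plus quartiles of the nonzero values — zeros are
#' truncated before summarizing, matching how expression distributions are
#' portrayed.
#'
#' @param table A [unified_table()].
#' @param gene Gene symbol on the table's axis.
#' @param group_by Grouping metadata field, `"organ"` or `"cell_type"`.
#' @return Data frame with one row per non-empty group: `group`,
#'   `n_cells`, `n_nonzero`, `pct_expr`, `median_nonzero` (`NA` when no
#'   cell expresses the gene), `q25`, `q75`.
#' @export
gene_portrait <- function(table, gene, group_by = c("organ", "cell_type")) {
  stopifnot(inherits(table, "unified_table"))
  group_by <- match.arg(group_by)
  j <- match(gene, table$gene_axis)
  if (is.na(j)) stop(sprintf("unknown gene '%s'", gene), call. = FALSE)
  x <- as.numeric(table$values[, j])
  g <- table$metadata[[group_by]]
  keep <- g != ""
  x <- x[keep]; g <- g[keep]
  groups <- sort(unique(g))
  rows <- lapply(groups, function(grp) {
    v <- x[g == grp]
    nz <- v[v > 0]
    data.frame(
      group = grp,
      n_cells = length(v),
      n_nonzero = length(nz),
      pct_expr = length(nz) / length(v),
      median_nonzero = if (length(nz)) stats::median(nz) else NA_real_,
      q25 = if (length(nz)) unname(stats::quantile(nz, 0.25)) else NA_real_,
      q75 = if (length(nz)) unname(stats::quantile(nz, 0.75)) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(group = character(0), n_cells = integer(0),
                      n_nonzero = integer(0), pct_expr = numeric(0),
                      median_nonzero = numeric(0), q25 = numeric(0),
                      q75 = numeric(0))
  }
  attr(out, "gene") <- gene
  attr(out, "group_by") <- group_by
  out
}

# Two-sided Wilcoxon rank-sum per column of x between groups, normal
# approximation with tie correction and continuity correction (the large-n
# path of stats::wilcox.test, vectorized over genes).
ranksum_pvalues <- function(x, in_group) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  N <- n1 + n2
  apply(x, 2, function(v) {
    r <- rank(v)
    W <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- base::table(v)
    sigma2 <- (n1 * n2 / 12) *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)  # all values tied
    z <- W - n1 * n2 / 2
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  })
}

#' Marker genes of a cell type
#'
#' Compares each gene's expression in the named cell type against all
#' other annotated cells with a two-sided Wilcoxon rank-sum test (normal
#' approximation with tie correction), adjusts p-values over the tested
#' genes, and keeps genes that pass the marker filters: adjusted p-value
#' at most 0.05, expressed (value > 0) in at least 25% of the in-group
#' cells, positive fold change. The top 50 genes by log fold change are
#' returned, largest first.
#'
#' Fold change is computed on de-logged values with a unit pseudo-count:
#' `log_fc = ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`, so
#' it reads as a fold change on expression scale.
#'
#' @param table A [unified_table()] of normalized values.
#' @param cell_type Cell-type label defining the in-group.
#' @param ontology Optional [uhaf_ontology()].
#' @param include_children With an ontology, the in-group is every label
#'   in the is_a subtree of `cell_type`.
#' @param p_adjust `"bonferroni"` (default) or `"BH"`.
#' @param max_genes Marker list length cap (default 50).
#' @param min_pct Minimum in-group expressing fraction (default 0.25).
#' @param alpha Adjusted p-value cutoff (default 0.05).
#' @return Data frame of marker records sorted by `log_fc` descending:
#'   `gene`, `log_fc`, `p_value`, `p_adj`, `pct_in`, `pct_out`.
#' @export
celltype_markers <- function(table, cell_type, ontology = NULL,
                             include_children = FALSE,
                             p_adjust = c("bonferroni", "BH"),
                             max_genes = 50, min_pct = 0.25, alpha = 0.05) {
  stopifnot(inherits(table, "unified_table"))
  p_adjust <- match.arg(p_adjust)
  labels <- table$metadata$cell_type
  targets <- cell_type
  if (include_children) {
    if (is.null(ontology)) stop("include_children requires an ontology",
                                call. = FALSE)
    targets <- descendants(ontology, cell_type, "is_a")
  }
  annotated <- labels != ""
  in_group <- annotated & labels %in% targets
  out_group <- annotated & !labels %in% targets
  if (!any(in_group) || !any(out_group)) {
    stop("in-group and out-group must both be non-empty", call. = FALSE)
  }
  x <- as.matrix(table$values[in_group | out_group, , drop = FALSE])
  grp <- in_group[in_group | out_group]
  p <- ranksum_pvalues(x, grp)
  p_adj <- stats::p.adjust(p, method = ifelse(p_adjust == "BH", "BH",
                                              "bonferroni"))
  x_in <- x[grp, , drop = FALSE]
  x_out <- x[!grp, , drop = FALSE]
  log_fc <- log((colMeans(expm1(x_in)) + 1) / (colMeans(expm1(x_out)) + 1))
  pct_in <- colMeans(x_in > 0)
  pct_out <- colMeans(x_out > 0)
  rec <- data.frame(gene = table$gene_axis, log_fc = unname(log_fc),
                    p_value = unname(p), p_adj = unname(p_adj),
                    pct_in = unname(pct_in), pct_out = unname(pct_out),
                    stringsAsFactors = FALSE)
  rec <- rec[rec$p_adj <= alpha & rec$pct_in >= min_pct & rec$log_fc > 0, ,
             drop = FALSE]
  rec <- rec[order(-rec$log_fc, rec$gene), , drop = FALSE]
  rec <- utils::head(rec, max_genes)
  rownames(rec) <- NULL
  rec
}

#' Cell-type composition of an organ
#'
#' Counts and fractions of annotated cell types among one organ's cells.
#' Cells without a cell-type label are excluded, so fractions sum to 1
#' over the non-empty labels.
#'
#' @param table A [unified_table()].
#' @param organ Organ label (must occur in the table).
#' @return Data frame `cell_type`, `n_cells`, `fraction`, sorted by label.
#' @export
organ_composition <- function(table, organ) {
  stopifnot(inherits(table, "unified_table"))
  if (!organ %in% table$metadata$organ) {
    stop(sprintf("unknown organ '%s'", organ), call. = FALSE)
  }
  ct <- table$metadata$cell_type[table$metadata$organ == organ]
  ct <- ct[ct != ""]
  if (length(ct) == 0L) {
    return(data.frame(cell_type = character(0), n_cells = integer(0),
                      fraction = numeric(0)))
  }
  tab <- base::table(ct)
  data.frame(cell_type = names(tab), n_cells = as.integer(tab),
             fraction = as.integer(tab) / length(ct),
             stringsAsFactors = FALSE)
}
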