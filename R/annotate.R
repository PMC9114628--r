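#' Build a customized label reference
#'
#' Selects reference cells with a query (any logic expression, e.g.
#' `organ==Heart`), takes their expression slice, labels (`uhaf_name`) and
#' provenance (`study_id`). Cells without a label are excluded with a
#' warning listing their cids; an empty selection is an error.
#'
#' @param table A [unified_table()].
#' @param condition Query string or expression tree; see [query_cells()].
#' @param include_children,ontology Passed to [query_cells()]. When an
#'   ontology is supplied, labels absent from it trigger a warning (they
#'   remain usable for transfer, but is-a evaluation cannot credit them).
#' @return A `reference_set`: list with `expression` (cells-by-genes
#'   sparse matrix), `labels`, `study_id`, `cids`, `gene_axis`.
#' @export
build_reference <- function(table, condition, include_children = FALSE,
                            ontology = NULL) {
  stopifnot(inherits(table, "unified_table"))
  cids <- query_cells(table, condition, include_children = include_children,
                      ontology = ontology)
  if (length(cids) == 0L) {
    stop("reference condition matched no cells", call. = FALSE)
  }
  labels <- table$metadata$uhaf_name[cids + 1L]
  unlab <- cids[labels == ""]
  if (length(unlab)) {
    warning(sprintf("excluding %d unlabeled cell(s): cid %s", length(unlab),
                    paste(utils::head(unlab, 10), collapse = ", ")),
            call. = FALSE)
    keep <- labels != ""
    cids <- cids[keep]; labels <- labels[keep]
    if (length(cids) == 0L) {
      stop("no labeled cells left for the reference", call. = FALSE)
    }
  }
  if (!is.null(ontology)) {
    missing <- setdiff(unique(labels), ontology$nodes$name)
    if (length(missing)) {
      warning("reference label(s) not in the ontology: ",
              paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(expression = table$values[cids + 1L, , drop = FALSE],
         labels = labels,
         study_id = table$metadata$study_id[cids + 1L],
         cids = cids,
         gene_axis = table$gene_axis),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d cells, %d labels, %d studies\n",
              length(x$cids), length(unique(x$labels)),
              length(unique(x$study_id[x$study_id != ""]))))
  invisible(x)
}

#' K-nearest-neighbour label transfer
#'
#' For each query cell, finds its k nearest reference cells by Euclidean
#' distance in the shared embedding and lets them vote: majority label
#' wins; ties are broken in favour of the tied label with the smallest
#' summed distance, then lexicographically.
#'
#' @param reference_embedding,query_embedding Numeric matrices with the
#'   same number of columns (e.g. a corrected 100-dimensional embedding).
#' @param reference_labels One label per reference row.
#' @param k Neighbourhood size; the transfer convention is 10 votes.
#' @return Character vector of predicted labels, one per query row.
#' @export
knn_transfer <- function(reference_embedding, reference_labels,
                         query_embedding, k = 10) {
  ref <- as.matrix(reference_embedding)
  qry <- as.matrix(query_embedding)
  if (ncol(ref) != ncol(qry)) {
    stop(sprintf("embedding dimensions differ: reference %d, query %d",
                 ncol(ref), ncol(qry)), call. = FALSE)
  }
  if (length(reference_labels) != nrow(ref)) {
    stop("one label per reference cell required", call. = FALSE)
  }
  if (k < 1 || k > nrow(ref)) {
    stop(sprintf("k = %d must lie in 1..%d (reference size)", k, nrow(ref)),
         call. = FALSE)
  }
  labels <- as.character(reference_labels)
  ref_sq <- rowSums(ref^2)
  vapply(seq_len(nrow(qry)), function(i) {
    d2 <- ref_sq - 2 * drop(ref %*% qry[i, ]) + sum(qry[i, ]^2)
    d2[d2 < 0] <- 0
    nn <- order(d2)[seq_len(k)]
    votes <- base::table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(lb) sum(d2[nn][labels[nn] == lb]), 0)
      top <- top[sums == min(sums)]
      top <- sort(top)
    }
    top[[1]]
  }, "")
}

#' Evaluate a label transfer
#'
#' Scores predictions against truth. A prediction is correct when it
#' equals the truth or, with `allow_is_a = TRUE`, when it is an is_a
#' ancestor of the truth — predicting a more general type (e.g. a cDC1
#' cell called a dendritic cell) is biologically right, only less
#' specific. Reports accuracy with an exact (Clopper-Pearson) 95% binomial
#' confidence interval, Cohen's kappa and the confusion matrix. Kappa and
#' the confusion matrix always use the raw labels: mixing hierarchy credit
#' into the chance correction is not well defined.
#'
#' @param predicted,truth Equal-length character label vectors.
#' @param ontology A [uhaf_ontology()]; required when `allow_is_a`.
#' @param allow_is_a Grant credit for is_a-ancestor predictions.
#' @param conf_level Confidence level of the accuracy interval.
#' @return A `transfer_result`: list with `accuracy`, `conf_int`, `kappa`,
#'   `confusion` (truth in rows, predictions in columns), `n`,
#'   `n_correct`, `correct` (per-cell logical).
#' @examples
#' r <- evaluate_transfer(c("A", "A", "B"), c("A", "B", "B"))
#' r$accuracy
#' @export
evaluate_transfer <- function(predicted, truth, ontology = NULL,
                              allow_is_a = FALSE, conf_level = 0.95) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  n <- length(truth)
  if (n == 0L) stop("no predictions to evaluate", call. = FALSE)
  correct <- predicted == truth
  if (allow_is_a) {
    if (is.null(ontology)) stop("allow_is_a requires an ontology", call. = FALSE)
    todo <- which(!correct)
    anc_cache <- new.env(parent = emptyenv())
    for (i in todo) {
      key <- truth[i]
      if (is.null(anc_cache[[key]])) {
        anc_cache[[key]] <- ancestors(ontology, key, "is_a")
      }
      if (predicted[i] %in% anc_cache[[key]]) correct[i] <- TRUE
    }
  }
  n_correct <- sum(correct)
  acc <- n_correct / n
  # Clopper-Pearson exact interval
  alpha <- 1 - conf_level
  lo <- if (n_correct == 0) 0 else stats::qbeta(alpha / 2, n_correct,
                                                n - n_correct + 1)
  hi <- if (n_correct == n) 1 else stats::qbeta(1 - alpha / 2, n_correct + 1,
                                                n - n_correct)
  lev <- sort(unique(c(truth, predicted)))
  cm <- base::table(factor(truth, levels = lev),
                    factor(predicted, levels = lev))
  cm <- matrix(as.integer(cm), nrow = length(lev),
               dimnames = list(truth = lev, predicted = lev))
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  structure(
    list(accuracy = acc, conf_int = c(lower = lo, upper = hi),
         conf_level = conf_level, kappa = kappa, confusion = cm,
         n = n, n_correct = n_correct, correct = correct,
         allow_is_a = allow_is_a),
    class = "transfer_result"
  )
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("transfer_result: n = %d\n", x$n))
  cat(sprintf("  accuracy: %.4f (%d%% CI [%.4f, %.4f])%s\n", x$accuracy,
              round(100 * x$conf_level), x$conf_int[["lower"]],
              x$conf_int[["upper"]],
              if (x$allow_is_a) " with is-a credit" else ""))
  cat(sprintf("  kappa:    %.4f (strict labels)\n", x$kappa))
  invisible(x)
}
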