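test_that("gene portraits summarize nonzero expression per group", {
  tab <- unified_table("CD3D")
  tab <- insert_cells(tab, matrix(c(0, 0, 2, 4, 0, 5), ncol = 1),
                      data.frame(organ = c(rep("Heart", 4), "Lung", "Brain")))
  p <- gene_portrait(tab, "CD3D", "organ")
  h <- p[p$group == "Heart", ]
  expect_equal(h$n_cells, 4)
  expect_equal(h$pct_expr, 0.5)
  expect_equal(h$median_nonzero, 3)
  l <- p[p$group == "Lung", ]
  expect_equal(l$pct_expr, 0)
  expect_true(is.na(l$median_nonzero))
  b <- p[p$group == "Brain", ]
  expect_equal(b$pct_expr, 1)
  expect_equal(b$median_nonzero, 5)
  expect_error(gene_portrait(tab, "NOPE"), "unknown gene")
})

test_that("gene portraits agree with a naive per-group recomputation", {
  set.seed(33)
  fx <- generate_atlas(synthetic_atlas_spec(seed = 33, n_genes = 40,
                                            n_cells_per_type = 30))
  tab <- assemble_atlas(fx)
  for (g in sample(tab$gene_axis, 5)) {
    p <- gene_portrait(tab, g, "cell_type")
    x <- as.numeric(tab$values[, match(g, tab$gene_axis)])
    for (i in seq_len(nrow(p))) {
      v <- x[tab$metadata$cell_type == p$group[i]]
      expect_equal(p$n_cells[i], length(v))
      expect_equal(p$pct_expr[i], mean(v > 0))
      expect_equal(p$median_nonzero[i],
                   if (any(v > 0)) median(v[v > 0]) else NA_real_)
    }
  }
})

test_that("rank-sum p-values match stats::wilcox.test's normal path", {
  set.seed(44)
  x <- cbind(rnorm(40), c(rnorm(25), rnorm(15, 2)),
             sample(0:3, 40, TRUE))  # heavy ties in column 3
  grp <- rep(c(TRUE, FALSE), c(25, 15))
  p <- cellensemble:::ranksum_pvalues(x, grp)
  for (j in 1:3) {
    ref <- suppressWarnings(
      stats::wilcox.test(x[grp, j], x[!grp, j], exact = FALSE,
                         correct = TRUE))$p.value
    expect_equal(p[j], ref, tolerance = 1e-12)
  }
})

test_that("marker tables recover planted markers and apply the filters", {
  fx <- generate_atlas(synthetic_atlas_spec(seed = 5, n_genes = 80,
                                            n_cells_per_type = 60,
                                            marker_fold = 4))
  tab <- assemble_atlas(fx)
  mk <- celltype_markers(tab, "T cell", fx$ontology, include_children = TRUE)
  planted <- fx$truth$markers$gene[fx$truth$markers$cell_type == "T cell"]
  expect_true(all(planted %in% mk$gene))
  expect_true(all(mk$p_adj <= 0.05))
  expect_true(all(mk$pct_in >= 0.25))
  expect_true(all(mk$log_fc > 0))
  expect_lte(nrow(mk), 50)
  expect_false(is.unsorted(rev(mk$log_fc)))

  # low-prevalence genes are excluded regardless of fold change
  tab2 <- unified_table(c("A", "B"))
  vals <- cbind(A = c(rep(9, 3), rep(0, 27), rep(0, 30)),
                B = c(rep(3, 30), rep(0.1, 30)))
  tab2 <- insert_cells(tab2, vals,
                       data.frame(cell_type = rep(c("X", "Y"), each = 30)))
  mk2 <- celltype_markers(tab2, "X")
  expect_false("A" %in% mk2$gene)  # 10% in-group prevalence
  expect_true("B" %in% mk2$gene)

  expect_error(celltype_markers(tab2, "Z"), "non-empty")
})

test_that("identically distributed groups yield an empty marker list", {
  set.seed(55)
  tab <- unified_table(paste0("G", 1:30))
  vals <- matrix(rpois(200 * 30, 3), nrow = 200)
  tab <- insert_cells(tab, vals,
                      data.frame(cell_type = rep(c("X", "Y"), each = 100)))
  mk <- celltype_markers(tab, "X")
  # Bonferroni at 0.05 over 30 null genes: expect none, tolerate nothing
  # beyond the controlled error (P(any) <= 0.05)
  expect_lte(nrow(mk), 1)
})

test_that("marker lists are invariant to cell-order permutation", {
  fx <- generate_atlas(synthetic_atlas_spec(seed = 6, n_genes = 40,
                                            n_cells_per_type = 30))
  tab <- assemble_atlas(fx)
  mk1 <- celltype_markers(tab, "Macrophage", fx$ontology,
                          include_children = TRUE)
  set.seed(66)
  perm <- sample(nrow(tab$values))
  tabp <- unified_table(tab$gene_axis)
  tabp <- insert_cells(tabp, as.matrix(tab$values)[perm, , drop = FALSE],
                       tab$metadata[perm, , drop = FALSE])
  mk2 <- celltype_markers(tabp, "Macrophage", fx$ontology,
                          include_children = TRUE)
  expect_equal(mk1, mk2, tolerance = 1e-10)
})

test_that("organ composition counts and fractions", {
  tab <- unified_table("G1")
  tab <- insert_cells(tab, matrix(0, 5, 1),
                      data.frame(organ = c(rep("Heart", 4), "Lung"),
                                 cell_type = c("T cell", "T cell", "T cell",
                                               "B cell", "")))
  oc <- organ_composition(tab, "Heart")
  expect_equal(oc$cell_type, c("B cell", "T cell"))
  expect_equal(oc$n_cells, c(1L, 3L))
  expect_equal(oc$fraction, c(0.25, 0.75))
  expect_equal(sum(oc$fraction), 1, tolerance = 1e-12)

  # organ present but with no annotated cells -> empty result
  expect_equal(nrow(organ_composition(tab, "Lung")), 0L)
  expect_error(organ_composition(tab, "Kidney"), "unknown organ")

  single <- organ_composition(
    insert_cells(unified_table("G1"), matrix(0, 2, 1),
                 data.frame(organ = rep("Brain", 2),
                            cell_type = rep("Neuron", 2))), "Brain")
  expect_equal(single$fraction, 1)
})
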