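test_that("the worked sorting expression parses to the documented tree", {
  txt <- paste("(organ==Heart) && (cell_type == T cell) && (PTPRC > 0.5)",
               "&& ((CD3D >= 0.5) || (CD3E >= 0.5))")
  ast <- as_plain_ast(parse_expression(txt))
  expect_equal(ast$kind, "and")
  expect_length(ast$children, 4)
  expect_equal(ast$children[[1]],
               list(kind = "cmp", column = "organ", op = "==",
                    value = "Heart"))
  expect_equal(ast$children[[2]]$value, "T cell")
  expect_equal(ast$children[[3]],
               list(kind = "cmp", column = "PTPRC", op = ">", value = "0.5"))
  expect_equal(ast$children[[4]]$kind, "or")
  expect_equal(vapply(ast$children[[4]]$children, `[[`, "", "column"),
               c("CD3D", "CD3E"))
})

test_that("precedence is NOT > AND > OR with parentheses overriding", {
  ast <- as_plain_ast(parse_expression("A==x || B==y && !C==z"))
  expect_equal(ast$kind, "or")
  expect_equal(ast$children[[1]]$column, "A")
  expect_equal(ast$children[[2]]$kind, "and")
  expect_equal(ast$children[[2]]$children[[2]]$kind, "not")
  expect_equal(ast$children[[2]]$children[[2]]$child$column, "C")

  ast2 <- as_plain_ast(parse_expression("(A==x || B==y) && C==z"))
  expect_equal(ast2$kind, "and")
  expect_equal(ast2$children[[1]]$kind, "or")

  one <- as_plain_ast(parse_expression("PTPRC > 0.5"))
  expect_equal(one, list(kind = "cmp", column = "PTPRC", op = ">",
                         value = "0.5"))
  # unquoted multi-word values survive with surrounding space trimmed
  expect_equal(as_plain_ast(parse_expression("cell_type ==  T cell "))$value,
               "T cell")
})

test_that("malformed queries fail with positioned parse errors", {
  expect_error(parse_expression("organ==Heart &&"), "position")
  expect_error(parse_expression("(organ==Heart"), "unbalanced")
  expect_error(parse_expression("organ==Heart)"), "trailing")
  expect_error(parse_expression("organ=="), "missing comparison value")
  expect_error(parse_expression("==Heart"), "missing column")
  expect_error(parse_expression(""), "empty")
  # the typeset variant with split tokens is rejected, not guessed at
  expect_error(parse_expression("organ = = Heart"), "not an operator")
})

test_that("parse/unparse round-trips generated ASTs", {
  set.seed(101)
  for (i in 1:250) {
    ast <- random_ast()
    txt <- unparse_expression(structure(ast, class = "query_expression"))
    expect_identical(as_plain_ast(parse_expression(txt)), ast)
  }
})

test_that("query_cells matches a per-row brute-force oracle", {
  set.seed(202)
  genes <- paste0("G", 1:6)
  for (i in 1:60) {
    tab <- random_table(n_cells = 20, genes = genes)
    for (j in 1:5) {
      txt <- random_expression(genes)
      expect_identical(query_cells(tab, txt), brute_query(tab, txt),
                       label = txt)
    }
  }
})

test_that("query semantics: toy rows, empty tables, complement laws", {
  tab <- unified_table("CD3D")
  tab <- insert_cells(tab, matrix(c(0.7, 0.9, 0.1, 0.5, 0.0), ncol = 1),
                      data.frame(organ = c("Heart", "Lung", "Heart",
                                           "Heart", "Heart")))
  expect_equal(query_cells(tab, "organ==Heart && CD3D>=0.5"), c(0L, 3L))
  expect_equal(query_cells(tab, "CD3D>=0.5"), c(0L, 1L, 3L))

  empty <- unified_table("CD3D")
  expect_equal(query_cells(empty, "CD3D>=0.5"), integer(0))
  expect_error(query_cells(empty, "CD3D >="), "parse error")

  # De Morgan over the row set
  a <- "organ==Heart"; b <- "CD3D>=0.5"
  conj <- query_cells(tab, paste(a, "&&", b))
  expect_equal(query_cells(tab, paste0("!(", a, " && ", b, ")")),
               setdiff(get_all_rows(tab), conj))
  expect_equal(query_cells(tab, paste0("!(", a, ") || !(", b, ")")),
               setdiff(get_all_rows(tab), conj))

  expect_error(query_cells(tab, "bogus==1"), "unknown column")
  expect_error(query_cells(tab, "organ>Heart"), "ordering operator")
})

test_that("donor_age compares textually unless declared numeric", {
  tab <- unified_table("G1")
  tab <- insert_cells(tab, matrix(0, 3, 1),
                      data.frame(donor_age = c("9", "40", "")))
  expect_error(query_cells(tab, "donor_age>10"), "ordering")
  expect_equal(query_cells(tab, "donor_age>10", numeric_fields = "donor_age"),
               1L)
  expect_equal(query_cells(tab, "donor_age==40"), 1L)
})

test_that("include_children expands equality over the ontology subtree", {
  ont <- toy_immune_ontology()
  tab <- unified_table("G1")
  tab <- insert_cells(tab, matrix(0, 4, 1),
                      data.frame(organ = "Blood",
                                 cell_type = c("T cell", "CD4 T cell",
                                               "Treg", "B cell")))
  expect_equal(query_cells(tab, "cell_type==T cell"), 0L)
  withc <- query_cells(tab, "cell_type==T cell", include_children = TRUE,
                       ontology = ont)
  expect_equal(withc, 0:2)

  # identical to the explicit union over descendant labels
  union <- sort(unique(unlist(lapply(
    descendants(ont, "T cell", "is_a"),
    function(lb) query_cells(tab, paste0("cell_type==", lb))))))
  expect_equal(withc, as.integer(union))

  # superset property and complement semantics of !=
  expect_true(all(query_cells(tab, "cell_type==T cell") %in% withc))
  expect_equal(query_cells(tab, "cell_type!=T cell", include_children = TRUE,
                           ontology = ont),
               setdiff(get_all_rows(tab), withc))

  # organ equality expands through part_of as well
  tab2 <- insert_cells(unified_table("G1"), matrix(0, 2, 1),
                       data.frame(organ = c("Blood", "T cell")))
  expect_equal(query_cells(tab2, "organ==Blood", include_children = TRUE,
                           ontology = ont), 0:1)

  expect_error(query_cells(tab, "cell_type==T cell",
                           include_children = TRUE), "ontology")
  expect_error(query_cells(tab, "cell_type==Platelet",
                           include_children = TRUE, ontology = ont),
               "unknown")
})

test_that("organ x cell-type cross table counts with sorted labels", {
  tab <- unified_table("G1")
  tab <- insert_cells(tab, matrix(0, 3, 1),
                      data.frame(organ = c("Heart", "Heart", "Lung"),
                                 cell_type = c("T cell", "B cell", "T cell")))
  ct <- celltype_organ_crosstab(tab)
  expect_equal(rownames(ct), c("Heart", "Lung"))
  expect_equal(colnames(ct), c("B cell", "T cell"))
  expect_equal(unname(ct), matrix(c(1L, 0L, 1L, 1L), 2))
  expect_equal(rowSums(ct), c(Heart = 2, Lung = 1))

  expect_equal(dim(celltype_organ_crosstab(tab, integer(0))), c(0L, 0L))
  one <- celltype_organ_crosstab(tab, 2L)
  expect_equal(unname(one), matrix(1L))
  expect_equal(sum(one), 1)
})
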