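Package: cellensemble
Title: Cell-Centric Assembly, Querying and Annotation of Single-Cell Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An embedded toolkit for cell-centric assembly of single-cell
    transcriptomic atlases. Provides a unified table store holding sparse
    normalized expression together with a 17-column cell metadata schema, a
    combinatorial logic-expression query language for "in data" cell sorting,
    a hierarchical cell annotation ontology (typed DAG with is-a / part-of
    edges, marker references and Cell Ontology mapping), HGNC-style gene
    symbol unification onto a fixed approved axis, library-size
    normalization, quantitative portraits of genes, cell types and organs
    (including Wilcoxon rank-sum marker tables), PCA scale-inverse-transform
    batch correction, k-nearest-neighbour label transfer with is-a-aware
    evaluation, and a synthetic atlas generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
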