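#' Specification of a synthetic atlas
#'
#' Describes the world a [generate_atlas()] run creates: a toy anatomy of
#' organs with per-organ cell types (each with one is_a subtype),
#' negative-binomial baseline counts with planted marker genes, a batch
#' plan scaling library sizes, and alias corruption of gene names so the
#' unification step has work to do.
#'
#' @param seed RNG seed; generation is deterministic given the seed.
#' @param n_genes Number of genes on the approved axis.
#' @param organs Named list: organ name -> character vector of its cell
#'   types.
#' @param n_cells_per_type Cells generated per cell type.
#' @param markers_per_type Marker genes planted per cell type
#'   (disjoint across types).
#' @param marker_fold Mean fold-up of a planted marker inside its type
#'   (> 1).
#' @param dispersion Negative-binomial dispersion (NB size = 1 /
#'   dispersion); 0.1 is a standard droplet-data stand-in.
#' @param batches Data frame with columns `name` and `multiplier`
#'   (library-size multiplier, > 0) and optionally `offset` (an additive
#'   embedding-space batch shift magnitude, carried in the truth record for
#'   correction experiments); cells are assigned round-robin.
#' @param alias_rate Fraction of genes whose name is replaced by an alias
#'   recorded in the symbol table.
#' @param subtype_fraction Fraction of each type's cells labeled with the
#'   is_a subtype instead of the parent type.
#' @return A validated `synthetic_atlas_spec` list.
#' @export
synthetic_atlas_spec <- function(seed = 1,
                                 n_genes = 200,
                                 organs = list(
                                   Heart = c("T cell", "Cardiomyocyte cell"),
                                   Lung = c("Epithelial cell", "Macrophage")
                                 ),
                                 n_cells_per_type = 200,
                                 markers_per_type = 3,
                                 marker_fold = 4,
                                 dispersion = 0.1,
                                 batches = data.frame(
                                   name = c("batch1", "batch2"),
                                   multiplier = c(1, 2)
                                 ),
                                 alias_rate = 0.1,
                                 subtype_fraction = 0.5) {
  types <- unlist(organs, use.names = FALSE)
  if (anyDuplicated(types)) {
    stop("cell types must be unique across organs", call. = FALSE)
  }
  if (marker_fold <= 1) stop("marker_fold must exceed 1", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  if (length(types) * markers_per_type > n_genes) {
    stop("more planted markers than genes", call. = FALSE)
  }
  batches <- as.data.frame(batches, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "multiplier") %in% names(batches)))
  if (any(batches$multiplier <= 0)) {
    stop("batch multipliers must be positive", call. = FALSE)
  }
  if (alias_rate < 0 || alias_rate >= 1) {
    stop("alias_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(seed = seed, n_genes = n_genes, organs = organs,
         n_cells_per_type = n_cells_per_type,
         markers_per_type = markers_per_type, marker_fold = marker_fold,
         dispersion = dispersion, batches = batches,
         alias_rate = alias_rate, subtype_fraction = subtype_fraction),
    class = "synthetic_atlas_spec"
  )
}

# toy 3-level hierarchy: body -> organ -> tissue -> cell type -> subtype
toy_uhaf <- function(organs, markers = NULL) {
  nodes <- data.frame(name = "Human body", kind = "system",
                      stringsAsFactors = FALSE)
  edges <- data.frame(child = character(0), parent = character(0),
                      type = character(0), stringsAsFactors = FALSE)
  for (org in names(organs)) {
    tis <- paste(org, "tissue")
    nodes <- rbind(nodes,
                   data.frame(name = org, kind = "organ"),
                   data.frame(name = tis, kind = "tissue_type"))
    edges <- rbind(edges,
                   data.frame(child = org, parent = "Human body",
                              type = "part_of"),
                   data.frame(child = tis, parent = org, type = "part_of"))
    for (ct in organs[[org]]) {
      sub <- paste(ct, "subtype")
      nodes <- rbind(nodes,
                     data.frame(name = ct, kind = "cell_type"),
                     data.frame(name = sub, kind = "cell_type"))
      edges <- rbind(edges,
                     data.frame(child = ct, parent = tis, type = "part_of"),
                     data.frame(child = sub, parent = ct, type = "is_a"))
    }
  }
  uhaf_ontology(nodes, edges, markers)
}

#' Generate a synthetic atlas with known ground truth
#'
#' Draws negative-binomial counts for every cell of every planted type
#' (marker genes' means multiplied by the planned fold inside their type,
#' per-batch library multipliers applied), builds the matching toy
#' ontology, metadata records and alias-corrupted gene symbol table, and
#' returns the ground truth needed to verify every downstream step.
#'
#' @param spec A [synthetic_atlas_spec()].
#' @return List with
#' \describe{
#'   \item{counts}{gene-by-cell integer sparse matrix; row names are the
#'     (possibly aliased) gene names as a raw dataset would present them;}
#'   \item{metadata}{17-column data frame (organ, cell_type, tissue_type,
#'     uhaf_name, study_id = batch, cell_id, original_name filled);}
#'   \item{ontology}{the toy [uhaf_ontology()] with planted markers
#'     attached as data-derived references;}
#'   \item{symbol_table}{[gene_symbol_table()] with the alias map used for
#'     corruption;}
#'   \item{truth}{list: `labels` (assigned label per cell), `base_type`
#'     (parent type per cell), `organ`, `batch`, `markers` (data frame
#'     organ / cell_type / gene / fold), `aliased` (named map approved ->
#'     alias), `base_mean` (per-gene baseline NB mean), `spec`.}
#' }
#' @export
generate_atlas <- function(spec = synthetic_atlas_spec()) {
  stopifnot(inherits(spec, "synthetic_atlas_spec"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  genes <- sprintf("GENE%04d", seq_len(spec$n_genes))
  base_mean <- rgamma(spec$n_genes, shape = 2, rate = 1)
  types <- unlist(spec$organs, use.names = FALSE)
  organ_of <- rep(names(spec$organs), lengths(spec$organs))

  marker_idx <- matrix(sample.int(spec$n_genes,
                                  length(types) * spec$markers_per_type),
                       nrow = length(types), byrow = TRUE)
  truth_markers <- data.frame(
    organ = rep(organ_of, each = spec$markers_per_type),
    cell_type = rep(types, each = spec$markers_per_type),
    gene = genes[as.vector(t(marker_idx))],
    fold = spec$marker_fold,
    stringsAsFactors = FALSE
  )

  n_total <- length(types) * spec$n_cells_per_type
  batch <- rep_len(spec$batches$name, n_total)
  mult <- rep_len(spec$batches$multiplier, n_total)
  size <- 1 / spec$dispersion

  counts <- matrix(0L, nrow = spec$n_genes, ncol = n_total)
  base_type <- character(n_total)
  organ <- character(n_total)
  label <- character(n_total)
  col <- 0L
  for (t in seq_along(types)) {
    mu_t <- base_mean
    mu_t[marker_idx[t, ]] <- mu_t[marker_idx[t, ]] * spec$marker_fold
    n_sub <- round(spec$subtype_fraction * spec$n_cells_per_type)
    for (i in seq_len(spec$n_cells_per_type)) {
      col <- col + 1L
      counts[, col] <- rnbinom(spec$n_genes, size = size,
                               mu = mu_t * mult[col])
      base_type[col] <- types[t]
      organ[col] <- organ_of[t]
      label[col] <- if (i <= n_sub) paste(types[t], "subtype") else types[t]
    }
  }
  rownames(counts) <- genes
  colnames(counts) <- sprintf("cell%05d", seq_len(n_total))

  # alias corruption: a fraction of genes present themselves by an alias
  n_alias <- floor(spec$alias_rate * spec$n_genes)
  alias_map <- character(0)
  aliased <- character(0)
  if (n_alias > 0) {
    which_alias <- sample.int(spec$n_genes, n_alias)
    alias_names <- paste0(genes[which_alias], "-ALT")
    alias_map <- stats::setNames(genes[which_alias], alias_names)
    aliased <- stats::setNames(alias_names, genes[which_alias])
    rownames(counts)[which_alias] <- alias_names
  }
  symbol_table <- gene_symbol_table(genes, alias_map)

  meta <- data.frame(
    study_id = batch,
    cell_id = colnames(counts),
    organ = organ,
    cell_type = label,
    tissue_type = paste(organ, "tissue"),
    uhaf_name = label,
    original_name = label,
    stringsAsFactors = FALSE
  )
  ontology <- toy_uhaf(spec$organs,
                       data.frame(node = truth_markers$cell_type,
                                  gene = truth_markers$gene,
                                  provenance = "data",
                                  stringsAsFactors = FALSE))
  list(
    counts = as(as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
                "generalMatrix"),
    metadata = meta,
    ontology = ontology,
    symbol_table = symbol_table,
    truth = list(labels = label, base_type = base_type, organ = organ,
                 batch = batch, markers = truth_markers, aliased = aliased,
                 base_mean = stats::setNames(base_mean, genes), spec = spec)
  )
}

#' Assemble a generated fixture into a unified table
#'
#' Runs the standard ingest pipeline on a [generate_atlas()] result:
#' unify gene symbols onto the approved axis, library-size normalize
#' (scale 10,000), transpose to cells-by-genes and insert with metadata.
#'
#' @param fixture A [generate_atlas()] result.
#' @param scale_factor Passed to [normalize_library_size()].
#' @return A [unified_table()] over the fixture's approved gene axis.
#' @export
assemble_atlas <- function(fixture, scale_factor = 10000) {
  uni <- unify_symbols(fixture$counts, fixture$symbol_table)
  norm <- normalize_library_size(uni$matrix, scale_factor)
  tab <- unified_table(fixture$symbol_table$approved)
  insert_cells(tab, norm, fixture$metadata, orientation = "gene_by_cell")
}
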