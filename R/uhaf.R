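#' Node kinds of the annotation hierarchy
#'
#' Macroscopic kinds (system, organ, region, subregion) describe anatomy;
#' microscopic kinds (tissue_type, cell_type) describe cell identity.
#'
#' @return Character vector of the six kinds.
#' @export
uhaf_kinds <- function() {
  c("system", "organ", "region", "subregion", "tissue_type", "cell_type")
}

# Kahn's algorithm; returns NULL when acyclic, else node names on a cycle
find_cycle <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(factor(edges$parent, levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  active <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  queue <- nodes[indeg == 0L]
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    active[v] <- FALSE
    for (p in edges$parent[edges$child == v]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (any(active)) names(active)[active] else NULL
}

#' Construct an annotation ontology (uHAF)
#'
#' A typed directed acyclic graph of anatomical and cell-identity entities.
#' Edges point child -> parent and are typed `is_a` (specialization between
#' microscopic nodes of the same kind) or `part_of` (containment, may cross
#' kinds). Microscopic nodes can carry marker-gene references with a
#' provenance tag, and a curated map to Cell Ontology preferred labels
#' backs [map_to_cell_ontology()].
#'
#' @param nodes Data frame with columns `name` (unique) and `kind`
#'   (one of [uhaf_kinds()]); an `id` column is optional and kept if given.
#' @param edges Data frame with columns `child`, `parent`, `type`
#'   (`"is_a"` or `"part_of"`). May be empty.
#' @param markers Optional data frame with columns `node`, `gene`,
#'   `provenance`; duplicated (node, gene) pairs are collapsed keeping the
#'   first provenance tag.
#' @param cl_map Optional named character vector: curated ontology name ->
#'   Cell Ontology preferred label.
#' @return A `uhaf_ontology` object.
#' @export
uhaf_ontology <- function(nodes, edges = NULL, markers = NULL,
                          cl_map = character()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "kind") %in% names(nodes)))
  nodes$name <- as.character(nodes$name)
  nodes$kind <- as.character(nodes$kind)
  if (anyDuplicated(nodes$name)) {
    stop("duplicate node name: ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad_kind <- setdiff(nodes$kind, uhaf_kinds())
  if (length(bad_kind)) {
    stop("unknown node kind: ", paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(child = character(0), parent = character(0),
                        type = character(0), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    stopifnot(all(c("child", "parent", "type") %in% names(edges)))
    for (f in c("child", "parent", "type")) edges[[f]] <- as.character(edges[[f]])
  }
  bad_type <- setdiff(edges$type, c("is_a", "part_of"))
  if (length(bad_type)) {
    stop("unknown edge type: ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  missing_node <- setdiff(c(edges$child, edges$parent), nodes$name)
  if (length(missing_node)) {
    stop("edge references unknown node: ",
         paste(missing_node, collapse = ", "), call. = FALSE)
  }
  kind_of <- stats::setNames(nodes$kind, nodes$name)
  isa <- edges[edges$type == "is_a", , drop = FALSE]
  bad_isa <- kind_of[isa$child] != kind_of[isa$parent] |
    !(kind_of[isa$child] %in% c("tissue_type", "cell_type"))
  if (any(bad_isa)) {
    stop("is_a edges must connect microscopic nodes of the same kind",
         call. = FALSE)
  }
  cyc <- find_cycle(nodes$name, edges)
  if (!is.null(cyc)) {
    stop("ontology edges contain a cycle involving: ",
         paste(cyc, collapse = ", "), call. = FALSE)
  }
  if (is.null(markers) || NROW(markers) == 0L) {
    markers <- data.frame(node = character(0), gene = character(0),
                          provenance = character(0), stringsAsFactors = FALSE)
  } else {
    markers <- as.data.frame(markers, stringsAsFactors = FALSE)
    stopifnot(all(c("node", "gene") %in% names(markers)))
    if (is.null(markers$provenance)) markers$provenance <- "knowledge"
    bad <- setdiff(markers$node, nodes$name)
    if (length(bad)) {
      stop("marker references unknown node: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    markers <- markers[!duplicated(markers[c("node", "gene")]), , drop = FALSE]
    rownames(markers) <- NULL
  }
  cl_map <- unlist(cl_map)
  if (length(cl_map)) {
    cl_map <- stats::setNames(as.character(cl_map), names(cl_map))
    if (is.null(names(cl_map)) || any(names(cl_map) == "")) {
      stop("cl_map must be named (ontology name -> CL label)", call. = FALSE)
    }
  } else {
    cl_map <- character(0)
  }
  structure(list(nodes = nodes, edges = edges, markers = markers,
                 cl_map = cl_map),
            class = "uhaf_ontology")
}

#' @export
print.uhaf_ontology <- function(x, ...) {
  cat(sprintf("uhaf_ontology: %d nodes, %d edges (%d is_a, %d part_of), %d marker refs\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$type == "is_a"),
              sum(x$edges$type == "part_of"), nrow(x$markers)))
  tab <- table(x$nodes$kind)
  cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read an ontology from JSON
#'
#' Expects an object with arrays `nodes` (`name`, `kind`, optional `id`),
#' `edges` (`child`, `parent`, `type`), optional `markers` (`node`, `gene`,
#' `provenance`) and optional object `cl_map` (name -> CL label).
#'
#' @param path JSON file path.
#' @return A validated [uhaf_ontology()].
#' @export
load_ontology <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(obj$nodes)) stop("ontology file has no 'nodes' array", call. = FALSE)
  cl_map <- character(0)
  if (!is.null(obj$cl_map)) cl_map <- unlist(obj$cl_map)
  uhaf_ontology(obj$nodes, obj$edges, obj$markers, cl_map)
}

#' Write an ontology to JSON
#'
#' Inverse of [load_ontology()].
#'
#' @param ontology A [uhaf_ontology()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_ontology <- function(ontology, path) {
  stopifnot(inherits(ontology, "uhaf_ontology"))
  obj <- list(nodes = ontology$nodes, edges = ontology$edges,
              markers = ontology$markers,
              cl_map = as.list(ontology$cl_map))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

check_node <- function(ontology, name) {
  if (!name %in% ontology$nodes$name) {
    stop(sprintf("unknown ontology name '%s'", name), call. = FALSE)
  }
  invisible(name)
}

# BFS over the edge list; direction "down" follows parent -> child
# (descendants), "up" follows child -> parent (ancestors). File order of
# edges is preserved within each frontier so ties are deterministic.
walk_edges <- function(ontology, name, edge_types, direction) {
  check_node(ontology, name)
  e <- ontology$edges[ontology$edges$type %in% edge_types, , drop = FALSE]
  from <- if (direction == "down") e$parent else e$child
  to <- if (direction == "down") e$child else e$parent
  seen <- name
  frontier <- name
  while (length(frontier)) {
    nxt <- to[from %in% frontier]
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Subtree of an ontology node
#'
#' Returns the node plus everything reachable beneath it through edges of
#' the given types; a node on several paths is counted once. This is the
#' closure behind `include_children` query semantics.
#'
#' @param ontology A [uhaf_ontology()].
#' @param name Node name.
#' @param edge_types Edge types to traverse (default both).
#' @return Character vector of node names, the queried node first, then in
#'   breadth-first edge-file order.
#' @export
descendants <- function(ontology, name, edge_types = c("is_a", "part_of")) {
  stopifnot(inherits(ontology, "uhaf_ontology"))
  walk_edges(ontology, name, edge_types, "down")
}

#' Ancestors of an ontology node
#'
#' The node plus everything reachable upward through edges of the given
#' types. With `edge_types = "is_a"` this is the generalization chain used
#' for is-a-aware transfer evaluation.
#'
#' @inheritParams descendants
#' @return Character vector of node names, the queried node first.
#' @export
ancestors <- function(ontology, name, edge_types = c("is_a", "part_of")) {
  stopifnot(inherits(ontology, "uhaf_ontology"))
  walk_edges(ontology, name, edge_types, "up")
}

#' Marker references of a node
#'
#' @param ontology A [uhaf_ontology()].
#' @param name Microscopic node name.
#' @return Data frame with columns `gene`, `provenance` (deduplicated by
#'   symbol, first provenance kept).
#' @export
marker_refs <- function(ontology, name) {
  stopifnot(inherits(ontology, "uhaf_ontology"))
  check_node(ontology, name)
  m <- ontology$markers[ontology$markers$node == name, c("gene", "provenance")]
  rownames(m) <- NULL
  m
}

#' Compose a uHAF name
#'
#' The standardized cluster label `organ-tissue_type-cell_type-markers`. A
#' cluster whose cell type cannot be resolved (empty, or absent from the
#' ontology when one is supplied) is labelled `"Unclassified"`.
#'
#' @param organ,tissue_type,cell_type Entity names (may be empty strings).
#' @param markers Character vector of marker gene symbols supporting the
#'   call; joined with `","`. Empty leaves the trailing part empty.
#' @param ontology Optional [uhaf_ontology()] used to resolve `cell_type`.
#' @return The composed label, or `"Unclassified"`.
#' @examples
#' compose_uhaf_name("Heart", "muscle tissue", "Cardiomyocyte cell", "TNNT2")
#' @export
compose_uhaf_name <- function(organ, tissue_type, cell_type,
                              markers = character(), ontology = NULL) {
  if (is.na(cell_type) || cell_type == "" ||
      (!is.null(ontology) && !cell_type %in% ontology$nodes$name)) {
    return("Unclassified")
  }
  paste(organ, tissue_type, cell_type,
        paste(markers, collapse = ","), sep = "-")
}

#' Map a uHAF cell type to a Cell Ontology label
#'
#' Deterministic three-stage resolution: (1) exact whole-string match of
#' the name against the CL preferred labels; (2) otherwise walk the is_a
#' parents upward (breadth-first, file order breaking ties among multiple
#' parents) and return the first parent whose name matches exactly;
#' (3) otherwise the curated `cl_map`; else `"none"`.
#'
#' @param ontology A [uhaf_ontology()].
#' @param uhaf_cell_type Cell-type node name (must exist in the ontology).
#' @param cl_terms Character vector of Cell Ontology preferred labels.
#' @return A CL label, or `"none"`.
#' @export
map_to_cell_ontology <- function(ontology, uhaf_cell_type, cl_terms) {
  stopifnot(inherits(ontology, "uhaf_ontology"))
  check_node(ontology, uhaf_cell_type)
  chain <- walk_edges(ontology, uhaf_cell_type, "is_a", "up")
  hit <- chain[chain %in% cl_terms]
  if (length(hit)) return(hit[[1]])
  if (uhaf_cell_type %in% names(ontology$cl_map)) {
    return(unname(ontology$cl_map[[uhaf_cell_type]]))
  }
  "none"
}
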