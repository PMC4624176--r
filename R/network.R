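#' Build an interaction graph from an edge list
#'
#' Drops self-loops and duplicate edges (ignoring orientation) and
#' returns an undirected `igraph` graph with an edge attribute `type`
#' (`"genetic"` or `"physical"`).
#'
#' @param edges `data.frame` with columns `gene_a`, `gene_b` and
#'   optionally `type`.
#' @return an undirected `igraph` object.
#' @export
interaction_graph <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  if (!"type" %in% names(edges)) edges$type <- "genetic"
  g <- igraph::graph_from_data_frame(
    edges[c("gene_a", "gene_b", "type")], directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(type = "first"))
}

#' Extract the one-linker candidate subnetwork
#'
#' Restricts a global interaction graph to the candidate genes and the
#' minimal context connecting them: every candidate–candidate edge is
#' kept, and (with `allow_missing = 1`) a non-candidate node is admitted
#' as a *linker* only if it is directly adjacent to at least two
#' distinct candidates — i.e. it bridges a candidate pair through a
#' single intervening gene.  Only the linker's edges to candidates are
#' retained.  Candidates connected solely through paths of two or more
#' non-candidates are not connected in the output.  A non-candidate
#' adjacent to a single candidate bridges nothing and is excluded.
#'
#' @param graph an `igraph` graph or an edge-list `data.frame`.
#' @param candidates character vector of candidate gene names.
#' @param allow_missing 0 (candidate-candidate edges only) or 1 (admit
#'   one-linker bridges).
#' @return the extracted subnetwork as an undirected `igraph` graph
#'   (nodes carry a logical attribute `candidate`).  Candidates with no
#'   retained edge are dropped.
#' @export
extract_subnetwork <- function(graph, candidates, allow_missing = 1) {
  if (!allow_missing %in% c(0, 1))
    stop("allow_missing must be 0 or 1")
  g <- if (igraph::is_igraph(graph)) graph else interaction_graph(graph)
  nodes <- igraph::V(g)$name
  cand <- intersect(candidates, nodes)

  ends <- igraph::as_edgelist(g)
  a_c <- ends[, 1] %in% cand
  b_c <- ends[, 2] %in% cand
  keep <- a_c & b_c
  if (allow_missing == 1) {
    ## linkers: non-candidates adjacent to >= 2 distinct candidates
    cc_edge <- xor(a_c, b_c)
    linker_of <- ifelse(a_c, ends[, 2], ends[, 1])
    cand_of <- ifelse(a_c, ends[, 1], ends[, 2])
    deg <- tapply(cand_of[cc_edge], linker_of[cc_edge],
                  function(z) length(unique(z)))
    linkers <- names(deg)[deg >= 2]
    keep <- keep | (cc_edge & linker_of %in% linkers)
  }
  sub <- igraph::subgraph_from_edges(g, which(keep), delete.vertices = TRUE)
  igraph::V(sub)$candidate <- igraph::V(sub)$name %in% cand
  sub
}

#' Summary counts of an extracted subnetwork
#'
#' @param sub subnetwork from [extract_subnetwork()].
#' @param candidates character vector of candidate genes.
#' @return list with `n_candidates` (candidate genes present),
#'   `n_genes` (all nodes), `n_edges`, `n_components`, and `membership`
#'   (data.frame: gene, candidate, component).
#' @export
summarize_network <- function(sub, candidates) {
  if (igraph::vcount(sub) == 0L) {
    return(list(n_candidates = 0L, n_genes = 0L, n_edges = 0L,
                n_components = 0L,
                membership = data.frame(gene = character(0),
                                        candidate = logical(0),
                                        component = integer(0))))
  }
  comp <- igraph::components(sub)
  nodes <- igraph::V(sub)$name
  list(n_candidates = sum(nodes %in% candidates),
       n_genes = length(nodes),
       n_edges = igraph::ecount(sub),
       n_components = comp$no,
       membership = data.frame(gene = nodes,
                               candidate = nodes %in% candidates,
                               component = as.integer(comp$membership),
                               stringsAsFactors = FALSE))
}
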