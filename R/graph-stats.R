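#' Summary statistics of a pangenome graph
#'
#' Counts nodes (segments), edges (links) and total sequence length, and
#' reports two degree summaries. `mean_degree` is edges/nodes, the statistic
#' conventionally printed for graphs built with variation-graph toolkits;
#' `mean_incident_degree` is 2*edges/nodes, the average number of link ends
#' incident to a node.
#'
#' @param graph A `pangenome_graph`.
#' @return One-row tibble: `node_count`, `edge_count`, `total_length`,
#'   `mean_degree`, `mean_incident_degree`, `sample_count`, `path_count`.
#' @examples
#' g <- pangenome_graph(tibble::tibble(id = "1", sequence = "ACGT",
#'                                     length = 4L))
#' graph_stats(g)
#' @export
graph_stats <- function(graph) {
  stopifnot(inherits(graph, "pangenome_graph"))
  n <- nrow(graph$segments)
  e <- nrow(graph$links)
  tibble(
    node_count = n,
    edge_count = e,
    total_length = sum(graph$segments$length),
    mean_degree = mean_node_degree(n, e),
    mean_incident_degree = if (n == 0L) 0 else 2 * e / n,
    sample_count = dplyr::n_distinct(graph$paths$sample),
    path_count = nrow(graph$paths)
  )
}

#' Mean node degree of a graph from its node and edge counts
#'
#' Defined as `edge_count / node_count`. An empty graph has degree 0 (with a
#' warning) rather than raising a division error.
#'
#' @param node_count,edge_count Non-negative counts.
#' @return A real number.
#' @examples
#' mean_node_degree(87934214, 121720974) # ~1.38, rounds to 1.4
#' @export
mean_node_degree <- function(node_count, edge_count) {
  if (node_count == 0) {
    warn("graph has no nodes; reporting mean degree 0")
    return(0)
  }
  edge_count / node_count
}

#' Per-sample node coverage of a pangenome graph
#'
#' A segment is covered by a sample iff any of that sample's paths traverses
#' it, in either orientation; repeated traversal counts once (set
#' semantics). This is the substrate of [attribute_novel_sequence()].
#'
#' @param graph A `pangenome_graph`.
#' @return Tibble with columns `sample`, `segment`, one row per distinct
#'   (sample, covered segment) pair.
#' @export
sample_coverage <- function(graph) {
  stopifnot(inherits(graph, "pangenome_graph"))
  p <- graph$paths
  if (!nrow(p)) return(tibble(sample = character(), segment = character()))
  tibble(sample = rep(p$sample, map_int(p$steps, nrow)),
         segment = unlist(map(p$steps, "segment"))) |>
    distinct()
}

#' @method glance pangenome_graph
#' @export
glance.pangenome_graph <- function(x, ...) graph_stats(x)

#' @method tidy pangenome_graph
#' @export
tidy.pangenome_graph <- function(x, ...) {
  lens <- segment_lengths(x)
  p <- x$paths
  tibble(
    sample = p$sample, haplotype = p$haplotype, contig = p$contig,
    line_type = p$line_type,
    n_steps = map_int(p$steps, nrow),
    bp = map_dbl(p$steps, ~ sum(lens[.x$segment]))
  )
}
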