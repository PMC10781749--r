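# Gene-neighborhood (contiguity) analysis: which system components are
# encoded next to each other across genomes.

#' Find neighboring component-gene pairs
#'
#' Two component genes on the same replicon are neighbors iff fewer than
#' `g_max` genes lie between them and none of the intervening genes
#' encodes another key component. Every qualifying unordered pair of
#' genes is emitted exactly once; pairs of the same component (paralog
#' adjacency, e.g. tssD-tssD) are emitted and flagged.
#'
#' Note the deliberate contrast with [cluster_hits()]: here an
#' intervening key-component gene blocks the pair, whereas cluster
#' chains are never broken by intervening genes.
#'
#' @param genes A gene table with component assignments.
#' @param key_components Character vector of component names considered;
#'   only genes carrying one of these form pairs.
#' @param g_max Strict upper bound on the intervening-gene count
#'   (default 10: "less than 10 genes apart").
#' @param blocking Components whose intervening genes block a pair
#'   (default: `key_components`).
#' @param dedup_per_genome If `TRUE`, repeated occurrences of the same
#'   component pair within one genome are collapsed to one.
#' @return Data frame with columns `component_a`, `component_b`
#'   (sorted so a <= b), `genome_id`, `replicon_id`, `gap`, `paralog`.
#' @export
find_neighbor_pairs <- function(genes, key_components, g_max = 10,
                                blocking = key_components,
                                dedup_per_genome = FALSE) {
  hits <- genes[!is.na(genes$component) &
                  genes$component %in% key_components, , drop = FALSE]
  empty <- data.frame(component_a = character(), component_b = character(),
                      genome_id = character(), replicon_id = character(),
                      gap = integer(), paralog = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) < 2L) return(empty)
  hits <- hits[order(hits$genome_id, hits$replicon_id, hits$rank), ,
               drop = FALSE]
  key <- paste(hits$genome_id, hits$replicon_id, sep = "|")
  res <- lapply(split(hits, factor(key, levels = unique(key))), function(h) {
    n <- nrow(h)
    if (n < 2L) return(NULL)
    blocker <- h$component %in% blocking
    rows <- list()
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        gap <- h$rank[j] - h$rank[i] - 1L
        if (gap >= g_max) break  # ranks sorted: later j only farther
        # a key-component gene strictly between blocks the pair
        between <- seq_len(n) > i & seq_len(n) < j
        if (any(blocker[between])) next
        ab <- sort(c(h$component[i], h$component[j]))
        rows[[length(rows) + 1L]] <- data.frame(
          component_a = ab[1L], component_b = ab[2L],
          genome_id = h$genome_id[1L], replicon_id = h$replicon_id[1L],
          gap = gap, paralog = ab[1L] == ab[2L],
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  if (dedup_per_genome) {
    k <- paste(res$genome_id, res$component_a, res$component_b)
    res <- res[!duplicated(k), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

#' Build the weighted component-contiguity graph
#'
#' Nodes are component names; an undirected edge connects two components
#' with weight equal to the number of times they were found to be
#' neighbors across the input (self-loops record paralog adjacencies).
#'
#' @param pairs Output of [find_neighbor_pairs()].
#' @param nodes Optional node set (default: components seen in `pairs`).
#' @param normalize Divide weights by `n_systems`.
#' @param n_systems Number of systems for normalization.
#' @return An `igraph` undirected graph with edge attribute `weight`.
#' @export
build_contiguity_graph <- function(pairs, nodes = NULL, normalize = FALSE,
                                   n_systems = NULL) {
  if (normalize) {
    if (is.null(n_systems) || n_systems == 0)
      stop("normalization requires n_systems > 0", call. = FALSE)
  }
  if (is.null(nodes))
    nodes <- sort(unique(c(pairs$component_a, pairs$component_b)))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(pairs)) {
    key <- paste(pairs$component_a, pairs$component_b, sep = "\r")
    w <- table(key)
    ends <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(matrix(
      match(ends, nodes), ncol = 2L))))
    igraph::E(g)$weight <- as.numeric(w)
    if (normalize) igraph::E(g)$weight <- igraph::E(g)$weight / n_systems
  }
  g
}

#' Edge list of a contiguity graph
#' @param graph An `igraph` graph with `weight` edge attribute.
#' @return Data frame `source`, `target`, `weight`, sorted by
#'   decreasing weight then lexicographically.
#' @export
graph_edge_list <- function(graph) {
  if (igraph::ecount(graph) == 0L)
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(graph)
  df <- data.frame(source = pmin(el[, 1L], el[, 2L]),
                   target = pmax(el[, 1L], el[, 2L]),
                   weight = igraph::E(graph)$weight,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$weight, df$source, df$target), ]
  rownames(df) <- NULL
  df
}

#' Export a contiguity graph
#'
#' Writes GraphML (node id = component, edge attribute `weight`) or a
#' plain edge TSV with columns `source`, `target`, `weight`. Output is
#' byte-stable for identical input.
#'
#' @param graph An `igraph` graph.
#' @param path Output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    write_tsv(graph_edge_list(graph), path)
  }
  invisible(path)
}

#' Read back an exported edge TSV
#' @param path Path written by [export_graph()] with `format="edge_tsv"`.
#' @return The edge-list data frame.
#' @export
read_edge_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
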