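# Independent brute-force oracles and small fixture builders. The
# oracles implement the rules literally (O(n^2) closure / all-pairs)
# and share no code with the package internals they check.

# Partition of component genes into clusters by transitive closure over
# all pairs with (rank difference - 1) <= d_max. Returns, per
# (genome, replicon), a list of sorted rank vectors.
oracle_cluster_partition <- function(genes, components, d_max) {
  hits <- genes[!is.na(genes$component) & genes$component %in% components, ]
  out <- list()
  for (key in unique(paste(hits$genome_id, hits$replicon_id, sep = "|"))) {
    h <- hits[paste(hits$genome_id, hits$replicon_id, sep = "|") == key, ]
    n <- nrow(h)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n) for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && abs(h$rank[i] - h$rank[j]) - 1L <= d_max) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    roots <- vapply(seq_len(n), find, 0L)
    cl <- split(h$rank, roots)
    out[[key]] <- unname(lapply(cl, sort))
  }
  out
}

# canonical form of a clustering for comparison
canonical_partition <- function(parts) {
  lapply(parts, function(p) p[order(vapply(p, min, 0))])
}

# partition implied by cluster_hits() output
clustered_to_partition <- function(clustered) {
  out <- list()
  for (key in unique(paste(clustered$genome_id, clustered$replicon_id,
                           sep = "|"))) {
    h <- clustered[paste(clustered$genome_id, clustered$replicon_id,
                         sep = "|") == key, ]
    out[[key]] <- unname(lapply(split(h$rank, h$cluster_id), sort))
  }
  out
}

# All-pairs literal application of the neighbor rule: fewer than g_max
# intervening genes and no key-component gene strictly between.
oracle_neighbor_pairs <- function(genes, key_components, g_max = 10) {
  rows <- list()
  for (key in unique(paste(genes$genome_id, genes$replicon_id, sep = "|"))) {
    g <- genes[paste(genes$genome_id, genes$replicon_id, sep = "|") == key, ]
    h <- g[!is.na(g$component) & g$component %in% key_components, ]
    h <- h[order(h$rank), ]
    n <- nrow(h)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      gap <- h$rank[j] - h$rank[i] - 1L
      if (gap >= g_max) next
      between <- h$rank > h$rank[i] & h$rank < h$rank[j]
      if (any(between)) next
      ab <- sort(c(h$component[i], h$component[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        component_a = ab[1], component_b = ab[2],
        genome_id = h$genome_id[1], replicon_id = h$replicon_id[1],
        gap = gap, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(component_a = character(), component_b = character(),
                      genome_id = character(), replicon_id = character(),
                      gap = integer()))
  do.call(rbind, rows)
}

pair_multiset <- function(df) {
  sort(paste(df$genome_id, df$replicon_id, df$component_a,
             df$component_b, df$gap))
}

# A bare gene table from ranks and components on one replicon.
toy_genes <- function(components_by_rank, n_genes = NULL,
                      genome_id = "G1", replicon_id = "c1") {
  ranks <- as.integer(names(components_by_rank))
  if (is.null(n_genes)) n_genes <- max(ranks) + 1L
  comp <- rep(NA_character_, n_genes)
  comp[ranks + 1L] <- unlist(components_by_rank)
  data.frame(genome_id = genome_id, replicon_id = replicon_id,
             rank = seq_len(n_genes) - 1L, strand = "+",
             locus_tag = sprintf("%s_%04d", genome_id, seq_len(n_genes)),
             component = comp, score = ifelse(is.na(comp), NA_real_, 50),
             stringsAsFactors = FALSE)
}

# Random gene tables with sparse component assignments, for the
# oracle-equivalence sweeps.
random_gene_tables <- function(n_genomes, n_genes, components,
                               hit_rate = 0.03, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_genomes), function(i) {
    gid <- sprintf("R%03d", i)
    comp <- rep(NA_character_, n_genes)
    hit <- runif(n_genes) < hit_rate
    comp[hit] <- sample(components, sum(hit), replace = TRUE)
    data.frame(genome_id = gid, replicon_id = paste0(gid, "_c1"),
               rank = seq_len(n_genes) - 1L, strand = "+",
               locus_tag = sprintf("%s_%05d", gid, seq_len(n_genes)),
               component = comp,
               score = ifelse(is.na(comp), NA_real_, 50),
               stringsAsFactors = FALSE)
  }))
}
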