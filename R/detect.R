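# Quorum-based system detection: cluster component-carrying genes by
# co-localization, then evaluate the model quorum per genome.

#' Cluster component-carrying genes into candidate loci
#'
#' Two component genes belong to the same cluster iff a chain of
#' component genes connects them in which every consecutive pair is
#' separated by at most `d_max` intervening genes (rank difference minus
#' one). Intervening genes of any kind, component or not, never break a
#' chain: chains are built over component genes only. Clusters are
#' maximal. On replicons declared circular the wrap-around gap between
#' the last and first component gene is also considered.
#'
#' @param genes A gene table (see [load_gene_table()]); only rows whose
#'   `component` belongs to `model` take part.
#' @param model A `system_model` supplying the component set and
#'   `inter_gene_max_distance`.
#' @param replicons Optional data frame with columns `replicon_id`,
#'   `topology` (`"linear"` or `"circular"`) and `n_genes`; replicons
#'   not listed default to linear.
#' @return The component-gene subset of `genes`, ordered by replicon and
#'   rank, with an added `cluster_id` column (`genome|replicon|k`).
#' @export
cluster_hits <- function(genes, model, replicons = NULL) {
  stopifnot(inherits(model, "system_model"))
  d_max <- model$inter_gene_max_distance
  hits <- genes[!is.na(genes$component) &
                  genes$component %in% model$components$name, , drop = FALSE]
  if (!nrow(hits)) {
    hits$cluster_id <- character(0)
    return(hits)
  }
  hits <- hits[order(hits$genome_id, hits$replicon_id, hits$rank), ,
               drop = FALSE]
  key <- paste(hits$genome_id, hits$replicon_id, sep = "|")
  out <- lapply(split(hits, factor(key, levels = unique(key))), function(h) {
    gaps <- diff(h$rank) - 1L
    cl <- cumsum(c(1L, as.integer(gaps > d_max)))
    if (!is.null(replicons) && nrow(h) > 1L && max(cl) > 1L) {
      info <- replicons[replicons$replicon_id == h$replicon_id[1L], ,
                        drop = FALSE]
      if (nrow(info) && identical(info$topology[1L], "circular")) {
        wrap_gap <- info$n_genes[1L] - max(h$rank) - 1L + min(h$rank)
        if (wrap_gap <= d_max)  # merge terminal cluster into the first
          cl[cl == max(cl)] <- 1L
      }
    }
    h$cluster_id <- paste(h$genome_id[1L], h$replicon_id[1L],
                          match(cl, unique(cl)), sep = "|")
    h
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize locus clusters
#'
#' @param clustered Output of [cluster_hits()].
#' @return One row per cluster: genome, replicon, member count, rank
#'   span and the sorted component list (comma-joined).
#' @export
locus_summary <- function(clustered) {
  if (!nrow(clustered))
    return(data.frame(genome_id = character(), replicon_id = character(),
                      cluster_id = character(), n_genes = integer(),
                      span_min = integer(), span_max = integer(),
                      components = character()))
  sp <- split(clustered, clustered$cluster_id)
  res <- do.call(rbind, lapply(sp, function(h) {
    data.frame(genome_id = h$genome_id[1L], replicon_id = h$replicon_id[1L],
               cluster_id = h$cluster_id[1L], n_genes = nrow(h),
               span_min = min(h$rank), span_max = max(h$rank),
               components = paste(sort(h$component), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$genome_id, res$replicon_id, res$span_min), ]
  rownames(res) <- NULL
  res
}

new_detected_system <- function(genome_id, loci, model) {
  members <- do.call(rbind, loci)
  inventory <- table(members$component)
  inventory <- stats::setNames(as.integer(inventory), names(inventory))
  distinct <- names(inventory)
  mand <- mandatory_components(model)
  structure(
    list(genome_id = genome_id,
         loci = loci,
         inventory = inventory,
         n_loci = length(loci),
         n_distinct_components = length(distinct),
         n_mandatory_present = length(intersect(distinct, mand)),
         complete = length(intersect(distinct, mand)) >= model$min_mandatory &&
           length(distinct) >= model$min_total,
         model_name = model$name,
         model_components = model$components$name),
    class = "detected_system")
}

#' @export
print.detected_system <- function(x, ...) {
  cat("Detected system (", x$model_name, ") in ", x$genome_id, ": ",
      x$n_loci, " locus/loci, ", x$n_distinct_components,
      " distinct components (", x$n_mandatory_present, " mandatory) -> ",
      if (x$complete) "COMPLETE" else "incomplete", "\n", sep = "")
  invisible(x)
}

#' Evaluate the model quorum on clustered hits
#'
#' With the model's multi-locus option on, all clusters of a genome that
#' carry at least one model component are pooled into a single candidate
#' system per genome and the quorum is evaluated on the pooled distinct
#' components; otherwise every cluster is evaluated on its own. A
#' candidate is complete iff it reaches both the mandatory quorum and
#' the total-distinct quorum.
#'
#' @param clustered Output of [cluster_hits()] under the same model.
#' @param model The `system_model`.
#' @return A list of `detected_system` objects.
#' @export
evaluate_systems <- function(clustered, model) {
  stopifnot(inherits(model, "system_model"))
  if (!nrow(clustered)) return(list())
  by_genome <- split(clustered, clustered$genome_id)
  res <- lapply(by_genome, function(g) {
    loci <- split(g, g$cluster_id)
    loci <- loci[order(vapply(loci, function(h) min(h$rank), 0))]
    if (model$multi_loci) {
      list(new_detected_system(g$genome_id[1L], unname(loci), model))
    } else {
      lapply(unname(loci), function(h)
        new_detected_system(g$genome_id[1L], list(h), model))
    }
  })
  unname(unlist(res, recursive = FALSE))
}

#' Tabulate detected systems
#' @param systems List of `detected_system` objects.
#' @return One row per candidate system.
#' @export
systems_summary <- function(systems) {
  do.call(rbind, lapply(systems, function(s) {
    data.frame(genome_id = s$genome_id, n_loci = s$n_loci,
               n_genes = sum(s$inventory),
               n_distinct_components = s$n_distinct_components,
               n_mandatory_present = s$n_mandatory_present,
               complete = s$complete, stringsAsFactors = FALSE)
  }))
}

#' Membrane-complex completeness of a detected system
#'
#' Reports which of the five MC components (TssN, TssO, TssP, TssQ,
#' TssR) are present in a detected system. Aggregating the flags over a
#' census yields the per-component absence fractions.
#'
#' @param system A `detected_system` detected under a model that
#'   contains the five MC components.
#' @param components Component names to flag (default [mc_components()]).
#' @return Named logical vector of presence flags.
#' @export
mc_completeness <- function(system, components = mc_components()) {
  stopifnot(inherits(system, "detected_system"))
  missing <- setdiff(components, system$model_components)
  if (length(missing))
    stop("model '", system$model_name, "' lacks component(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  stats::setNames(components %in% names(system$inventory), components)
}

#' Per-component absence fractions over a census
#' @param systems List of `detected_system` objects.
#' @param components Components to tabulate.
#' @return Named numeric vector: fraction of systems lacking each
#'   component.
#' @export
absence_fractions <- function(systems, components = mc_components()) {
  flags <- t(vapply(systems, mc_completeness, logical(length(components)),
                    components = components))
  1 - colMeans(flags)
}

#' Genome-by-component copy-count matrix
#'
#' Rows are genomes, columns components, cells the number of gene copies
#' assigned to that component across all loci of the genome's detected
#' system. Genomes without a detected system get all-zero rows. Row sums
#' equal the total component copies per genome.
#'
#' @param systems List of `detected_system` objects.
#' @param genomes Genome labels for the rows (default: genomes of
#'   `systems`); extra labels yield zero rows.
#' @param components Column order (default: union over systems, sorted).
#' @return Integer matrix with dimnames.
#' @export
presence_absence_matrix <- function(systems, genomes = NULL,
                                    components = NULL) {
  sys_genomes <- vapply(systems, `[[`, "", "genome_id")
  if (is.null(genomes)) genomes <- sort(unique(sys_genomes))
  if (is.null(components))
    components <- sort(unique(unlist(lapply(systems, function(s)
      names(s$inventory)))))
  m <- matrix(0L, nrow = length(genomes), ncol = length(components),
              dimnames = list(genomes, components))
  for (s in systems) {
    if (!(s$genome_id %in% genomes)) next
    comps <- intersect(names(s$inventory), components)
    m[s$genome_id, comps] <- m[s$genome_id, comps] + s$inventory[comps]
  }
  m
}
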