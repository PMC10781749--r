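# Gene tables: one row per annotated gene with 0-based rank along its
# replicon. Ranks are always re-derived from coordinate order, never
# trusted from the input, so that "distance" means gene counts.

gene_table_columns <- c("genome_id", "replicon_id", "rank", "strand",
                        "locus_tag", "component", "score")

new_gene_table <- function(df) {
  df <- df[, gene_table_columns]
  rownames(df) <- NULL
  df
}

# Re-derive consecutive 0-based ranks per (genome, replicon) from the
# 1-based inclusive (start, end) coordinate order.
derive_ranks <- function(df) {
  key <- paste(df$genome_id, df$replicon_id, sep = "\r")
  ord <- order(key, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  key <- key[ord]
  df$rank <- stats::ave(seq_len(nrow(df)), key,
                        FUN = function(i) seq_along(i) - 1L)
  df
}

#' Load a per-genome gene table
#'
#' Reads annotated genes from a TSV table or a GFF3 file and returns a
#' normalized gene table: one row per gene with columns `genome_id`,
#' `replicon_id`, `rank`, `strand`, `locus_tag`, `component`, `score`.
#' Ranks are re-derived as consecutive 0-based indices along each
#' replicon in (start, end) order, regardless of source coordinates or
#' row order. Component labels not present in any supplied model are
#' dropped to `NA` with a warning.
#'
#' The TSV dialect expects columns `genome_id`, `replicon_id`, `start`,
#' `end`, `strand`, `locus_tag` and optionally `component` and `score`
#' (empty allowed). The GFF3 dialect uses CDS features only; the
#' component is read from the attribute named by `component_attr`, the
#' genome id defaults to the file name.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param models Optional list of `system_model`s used to vet component
#'   labels.
#' @param component_attr GFF3 attribute key carrying the component.
#' @param genome_id Genome label for GFF3 input (default: file name
#'   without extension).
#' @return A gene table data frame.
#' @export
load_gene_table <- function(path, dialect = c("tsv", "gff3"),
                            models = NULL,
                            component_attr = "t6ss_component",
                            genome_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("gene table not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
    required <- c("genome_id", "replicon_id", "start", "end", "strand",
                  "locus_tag")
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("gene table is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (is.null(df$component)) df$component <- NA_character_
    if (is.null(df$score)) df$score <- NA_real_
    df$component <- as.character(df$component)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("GFF3 reading requires the rtracklayer package", call. = FALSE)
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
    meta <- as.data.frame(gr)
    if (is.null(genome_id))
      genome_id <- sub("\\.[^.]*$", "", basename(path))
    tag <- meta$locus_tag
    if (is.null(tag)) tag <- meta$ID
    if (is.null(tag))
      stop("GFF3 CDS features carry neither locus_tag nor ID", call. = FALSE)
    comp <- meta[[component_attr]]
    if (is.null(comp)) comp <- rep(NA_character_, nrow(meta))
    df <- data.frame(genome_id = genome_id,
                     replicon_id = as.character(meta$seqnames),
                     start = meta$start, end = meta$end,
                     strand = as.character(meta$strand),
                     locus_tag = as.character(tag),
                     component = as.character(comp),
                     score = NA_real_,
                     stringsAsFactors = FALSE)
  }
  df$strand[!(df$strand %in% c("+", "-"))] <- "unknown"
  dup <- stats::aggregate(
    list(n = df$locus_tag),
    by = list(replicon = paste(df$genome_id, df$replicon_id),
              tag = df$locus_tag),
    FUN = length)
  if (any(dup$n > 1L))
    stop("duplicate locus_tag within a replicon: ",
         paste(utils::head(dup$tag[dup$n > 1L], 5), collapse = ", "),
         call. = FALSE)
  if (!is.null(models)) {
    known <- unique(unlist(lapply(models, function(m) m$components$name)))
    unknown <- setdiff(stats::na.omit(unique(df$component)), known)
    if (length(unknown)) {
      warning("dropping component label(s) absent from all models: ",
              paste(unknown, collapse = ", "), call. = FALSE)
      df$component[df$component %in% unknown] <- NA_character_
    }
  }
  df <- derive_ranks(df)
  new_gene_table(df)
}

#' Read an hmmer tabular hits file
#'
#' Parses `--tblout` (per-sequence) or `--domtblout` (per-domain) output
#' into a hits table with columns `locus_tag`, `component`, `evalue`,
#' `score`. The component is taken from the query name.
#'
#' @param path Path to the tabular file.
#' @param dialect `"tblout"` or `"domtblout"`.
#' @return Data frame of hits.
#' @export
read_hmmer_hits <- function(path, dialect = c("tblout", "domtblout")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(locus_tag = character(), component = character(),
                      evalue = numeric(), score = numeric()))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  # tblout: target(1) -(2) query(3) -(4) full-E(5) full-score(6) ...
  # domtblout: target(1) - tlen query(4) - qlen full-E(7) full-score(8) ...
  idx <- if (dialect == "tblout") c(tag = 1L, comp = 3L, e = 5L, s = 6L)
         else c(tag = 1L, comp = 4L, e = 7L, s = 8L)
  data.frame(
    locus_tag = vapply(fields, `[[`, "", idx[["tag"]]),
    component = vapply(fields, `[[`, "", idx[["comp"]]),
    evalue = as.numeric(vapply(fields, `[[`, "", idx[["e"]])),
    score = as.numeric(vapply(fields, `[[`, "", idx[["s"]])),
    stringsAsFactors = FALSE)
}

#' Assign components to genes from a hits table
#'
#' Applies per-component thresholds to a table of profile hits and
#' assigns to each gene at most one component: the best-scoring passing
#' hit, with ties broken by component name in lexicographic order. This
#' mirrors applying hmmer gathering thresholds (or an e-value cutoff for
#' components whose profiles lack one) downstream of the search itself.
#'
#' @param genes A gene table.
#' @param hits Data frame with columns `locus_tag`, `component`, `score`
#'   and optionally `evalue`.
#' @param policy Optional data frame with column `component` plus
#'   `min_score` and/or `max_evalue`; hits failing their component's
#'   thresholds are discarded. Components absent from the policy pass
#'   unconditionally.
#' @return The gene table with `component` and `score` overwritten by
#'   the winning assignments (`NA` where no hit passes).
#' @export
assign_components_from_hits <- function(genes, hits, policy = NULL) {
  stopifnot(all(c("locus_tag", "component", "score") %in% names(hits)))
  unknown <- !(hits$locus_tag %in% genes$locus_tag)
  if (any(unknown)) {
    warning(sum(unknown), " hit(s) reference unknown locus_tags; skipped",
            call. = FALSE)
    hits <- hits[!unknown, , drop = FALSE]
  }
  if (!is.null(policy)) {
    keep <- rep(TRUE, nrow(hits))
    m <- match(hits$component, policy$component)
    if (!is.null(policy$min_score)) {
      thr <- policy$min_score[m]
      keep <- keep & (is.na(thr) | hits$score >= thr)
    }
    if (!is.null(policy$max_evalue)) {
      thr <- policy$max_evalue[m]
      keep <- keep & (is.na(thr) | hits$evalue <= thr)
    }
    hits <- hits[keep, , drop = FALSE]
  }
  genes$component <- NA_character_
  genes$score <- NA_real_
  if (nrow(hits)) {
    # best hit per gene: max score, ties to lexicographically first component
    ord <- order(hits$locus_tag, -hits$score, hits$component)
    best <- hits[ord, ][!duplicated(hits$locus_tag[ord]), , drop = FALSE]
    m <- match(genes$locus_tag, best$locus_tag)
    genes$component <- best$component[m]
    genes$score <- best$score[m]
  }
  genes
}

#' Write a gene table as TSV
#'
#' Emits the external TSV dialect read back by [load_gene_table()]:
#' 1-based inclusive coordinates reconstructed from ranks when absent.
#'
#' @param genes A gene table (with or without `start`/`end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  if (is.null(genes$start)) {
    # synthesize non-overlapping 1-based coordinates from ranks
    genes$start <- genes$rank * 1000L + 1L
    genes$end <- genes$start + 899L
  }
  out <- genes[, c("genome_id", "replicon_id", "start", "end", "strand",
                   "locus_tag", "component", "score")]
  write_tsv(out, path)
  invisible(path)
}
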