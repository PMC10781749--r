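# Deterministic writers shared across stages: fixed column order, tab
# separation, no quoting, doubles at 6 significant digits.

format_cell <- function(x) {
  if (is.double(x)) {
    out <- vapply(x, function(v)
      if (is.na(v)) "" else format(signif(v, 6), scientific = FALSE,
                                   trim = TRUE), "")
    return(out)
  }
  out <- as.character(x)
  out[is.na(out)] <- ""
  out
}

#' Write a data frame as a deterministic TSV
#'
#' Tab-separated, header included, no quoting, `NA` as empty, doubles
#' formatted at 6 significant digits — so identical input yields
#' byte-identical files.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- as.data.frame(lapply(df, format_cell),
                       stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a genome-by-component matrix as TSV or tree-annotation text
#'
#' `tsv` writes the matrix with a leading `genome_id` column; read it
#' back with [read_matrix_tsv()], which round-trips exactly.
#' `tree_annotation_text` writes one comma-separated line per genome
#' label with a count field per component, a form consumable by
#' tree-annotation tools. Genome labels containing tab or comma
#' characters are sanitized (replaced by `_`) with a warning.
#'
#' @param m Matrix from [presence_absence_matrix()].
#' @param path Output path.
#' @param style `"tsv"` or `"tree_annotation_text"`.
#' @return `path`, invisibly.
#' @export
write_matrix_annotation <- function(m, path,
                                    style = c("tsv",
                                              "tree_annotation_text")) {
  style <- match.arg(style)
  labels <- rownames(m)
  bad <- grepl("[\t,]", labels)
  if (any(bad)) {
    warning("sanitizing genome label(s) containing separators",
            call. = FALSE)
    labels <- gsub("[\t,]", "_", labels)
  }
  if (style == "tsv") {
    df <- data.frame(genome_id = labels, as.data.frame(m),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, path)
  } else {
    lines <- c(paste0("LABELS,", paste(colnames(m), collapse = ",")),
               vapply(seq_len(nrow(m)), function(i)
                 paste(c(labels[i], m[i, ]), collapse = ","), ""))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a matrix TSV
#' @param path File written by [write_matrix_annotation()] with
#'   `style = "tsv"`.
#' @return Integer matrix with genome rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  m
}

#' Write a structure model as a minimal PDB file
#'
#' One ATOM record per Calpha, chain A, occupancy 1, B-factor 0 —
#' enough for [read_structure_ca()] and any standard PDB reader.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  resno <- as.integer(rownames(model$coords))
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(resno), resno,
    model$coords[, 1L], model$coords[, 2L], model$coords[, 3L])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the inputs, parameters and seed of an analysis run so that
#' outputs can be reproduced.
#'
#' @param path Output path.
#' @param inputs Named list or vector of input descriptions.
#' @param parameters Named list of parameters.
#' @param seed Seed used, if any.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, inputs = list(),
                               parameters = list(), seed = NULL) {
  manifest <- list(
    package = "t6sscan",
    version = as.character(utils::packageVersion("t6sscan")),
    inputs = inputs, parameters = parameters)
  if (!is.null(seed)) manifest$seed <- seed
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
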