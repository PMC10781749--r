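# Crosslinking mass-spectrometry validation of structure models:
# filter identifications, map intra-protein links onto Calpha traces,
# classify satisfied/violated at a distance threshold, summarize.

#' Read a crosslink identification table
#'
#' TSV columns: `protein_a`, `residue_a`, `protein_b`, `residue_b`,
#' `ld_score`, `delta_s` (the xQuest-style confidence metrics). The link
#' type (`intra`/`inter`) is derived from protein identity.
#'
#' @param path Path to the TSV.
#' @return Data frame of crosslinks with a `link_type` column.
#' @export
read_crosslinks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("protein_a", "residue_a", "protein_b", "residue_b",
                "ld_score", "delta_s")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("crosslink table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  validate_crosslinks(df)
}

validate_crosslinks <- function(df) {
  if (any(df$residue_a < 1L | df$residue_b < 1L))
    stop("crosslink residues must be 1-based (>= 1)", call. = FALSE)
  if (any(df$ld_score < 0))
    stop("negative ld score in crosslink table", call. = FALSE)
  df$link_type <- ifelse(df$protein_a == df$protein_b, "intra", "inter")
  df
}

# canonical unordered residue-pair key
crosslink_key <- function(df) {
  a <- paste(df$protein_a, df$residue_a, sep = ":")
  b <- paste(df$protein_b, df$residue_b, sep = ":")
  paste(pmin(a, b), pmax(a, b), sep = "--")
}

#' Filter crosslink identifications
#'
#' Keeps links with `ld_score >= min_ld` and `delta_s < max_delta_s`
#' (the defaults reproduce the standard xQuest/xProphet confidence
#' filter: ld score >= 25, deltaS < 0.95), then deduplicates to unique
#' unordered residue pairs, retaining the highest-scoring observation
#' of each.
#'
#' @param links Crosslink data frame (see [read_crosslinks()]).
#' @param min_ld Minimum ld score (inclusive).
#' @param max_delta_s Strict upper bound on deltaS.
#' @return The filtered, deduplicated data frame, with attribute
#'   `counts`: kept, dropped, deduplicated.
#' @export
filter_crosslinks <- function(links, min_ld = 25, max_delta_s = 0.95) {
  links <- validate_crosslinks(links)
  pass <- links$ld_score >= min_ld & links$delta_s < max_delta_s
  kept <- links[pass, , drop = FALSE]
  n_dropped <- sum(!pass)
  if (nrow(kept)) {
    key <- crosslink_key(kept)
    ord <- order(key, -kept$ld_score)
    kept <- kept[ord, ][!duplicated(key[ord]), , drop = FALSE]
  }
  rownames(kept) <- NULL
  attr(kept, "counts") <- c(kept = nrow(kept), dropped = n_dropped,
                            deduplicated = sum(pass) - nrow(kept))
  kept
}

#' Read a Calpha structure model from a PDB file
#'
#' Uses the first model's ATOM records, Calpha atoms only, altloc blank
#' or 'A'. Returns the per-residue coordinate map used by
#' [classify_links()].
#'
#' @param path Path to a PDB file.
#' @param protein Protein label (default: file name without extension).
#' @param chain Optional chain selector.
#' @return A `structure_model`: list with `protein`, `coords` (matrix
#'   with rownames = 1-based residue numbers) and `length`.
#' @export
read_structure_ca <- function(path, protein = NULL, chain = NULL) {
  if (is.null(protein)) protein <- sub("\\.[^.]*$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  sel <- pdb$atom$elety == "CA" & pdb$atom$type == "ATOM" &
    (is.na(pdb$atom$alt) | pdb$atom$alt %in% c("", "A"))
  if (!is.null(chain)) sel <- sel & pdb$atom$chain %in% chain
  atoms <- pdb$atom[sel, , drop = FALSE]
  atoms <- atoms[!duplicated(atoms$resno), , drop = FALSE]
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  rownames(coords) <- atoms$resno
  structure_model(protein, coords)
}

#' Build a structure model from coordinates
#' @param protein Protein label.
#' @param coords Numeric matrix (n x 3) of Calpha coordinates in
#'   Angstrom; rownames give 1-based residue numbers (default 1..n).
#' @return A `structure_model`.
#' @export
structure_model <- function(protein, coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, all(is.finite(coords)))
  if (is.null(rownames(coords))) rownames(coords) <- seq_len(nrow(coords))
  structure(list(protein = protein, coords = coords,
                 length = max(as.integer(rownames(coords)))),
            class = "structure_model")
}

ca_coord <- function(model, residue) {
  i <- match(as.character(residue), rownames(model$coords))
  if (is.na(i)) return(NULL)
  model$coords[i, ]
}

#' Classify crosslinks against structure models
#'
#' For intra-protein links whose two residues are modeled, computes the
#' Euclidean Calpha-Calpha distance and classifies the link as
#' satisfied when the distance is at most `d_thresh` (a link at exactly
#' the threshold is satisfied: violated means the distance exceeds the
#' crosslinker's maximal effective length). Inter-protein links, links
#' to unknown proteins with `strict = FALSE`, and links touching
#' unmodeled residues are reported as `unmapped` with a reason.
#'
#' @param links Filtered crosslink data frame.
#' @param structures Named list of `structure_model`s (names = protein
#'   labels; unnamed lists are named from each model's `protein`).
#' @param d_thresh Distance threshold in Angstrom (default 35, the
#'   effective maximum for a DSS crosslink between Calpha atoms).
#' @param strict Error on intra-protein links naming a protein with no
#'   structure (default TRUE).
#' @return `links` with added columns `distance`, `verdict`
#'   (`satisfied`/`violated`/`unmapped`), `reason`,
#'   `sequence_separation`.
#' @export
classify_links <- function(links, structures, d_thresh = 35,
                           strict = TRUE) {
  if (is.null(links$link_type)) links <- validate_crosslinks(links)
  if (inherits(structures, "structure_model"))
    structures <- list(structures)
  if (is.null(names(structures)) || any(!nzchar(names(structures))))
    names(structures) <- vapply(structures, `[[`, "", "protein")
  n <- nrow(links)
  links$distance <- NA_real_
  links$verdict <- NA_character_
  links$reason <- NA_character_
  links$sequence_separation <- ifelse(
    links$link_type == "intra", abs(links$residue_a - links$residue_b),
    NA_integer_)
  for (i in seq_len(n)) {
    if (links$link_type[i] == "inter") {
      links$verdict[i] <- "unmapped"
      links$reason[i] <- "inter-protein link"
      next
    }
    p <- links$protein_a[i]
    mod <- structures[[p]]
    if (is.null(mod)) {
      if (strict)
        stop("no structure model for protein '", p, "'", call. = FALSE)
      links$verdict[i] <- "unmapped"
      links$reason[i] <- "no structure model"
      next
    }
    xa <- ca_coord(mod, links$residue_a[i])
    xb <- ca_coord(mod, links$residue_b[i])
    if (is.null(xa) || is.null(xb)) {
      links$verdict[i] <- "unmapped"
      links$reason[i] <- "residue not modeled"
      next
    }
    d <- sqrt(sum((xa - xb)^2))
    links$distance[i] <- d
    links$verdict[i] <- if (d <= d_thresh) "satisfied" else "violated"
  }
  links
}

#' Summarize crosslink classifications
#'
#' Reports per-protein totals and violations over mapped (intra,
#' modeled) links, the overall violated fraction, and the number of
#' satisfied links whose residues are at least `long_range_sep`
#' residues apart in sequence (long-range links, the ones that validate
#' tertiary rather than local structure).
#'
#' @param classified Output of [classify_links()].
#' @param long_range_sep Minimum sequence separation for the long-range
#'   count (default 20).
#' @return List with `per_protein` (data frame), `n_mapped`,
#'   `n_violated`, `violated_fraction` (`NA` and `undefined = TRUE` when
#'   nothing is mapped), `violated_pct`, `violated_pct_rounded`,
#'   `n_long_range_satisfied`, `n_unmapped`, `n_inter`.
#' @export
violation_summary <- function(classified, long_range_sep = 20) {
  mapped <- classified[classified$verdict %in% c("satisfied", "violated"), ,
                       drop = FALSE]
  per_protein <- if (nrow(mapped)) {
    agg <- do.call(rbind, lapply(split(mapped, mapped$protein_a),
      function(m) data.frame(protein = m$protein_a[1L],
                             n_total = nrow(m),
                             n_violated = sum(m$verdict == "violated"),
                             stringsAsFactors = FALSE)))
    rownames(agg) <- NULL
    agg[order(agg$protein), ]
  } else {
    data.frame(protein = character(), n_total = integer(),
               n_violated = integer())
  }
  n_mapped <- nrow(mapped)
  n_violated <- sum(mapped$verdict == "violated")
  frac <- if (n_mapped) n_violated / n_mapped else NA_real_
  list(per_protein = per_protein,
       n_mapped = n_mapped,
       n_violated = n_violated,
       violated_fraction = frac,
       violated_pct = 100 * frac,
       violated_pct_rounded = if (n_mapped) round(100 * frac) else NA,
       undefined = n_mapped == 0L,
       n_long_range_satisfied = sum(
         mapped$verdict == "satisfied" &
           mapped$sequence_separation >= long_range_sep),
       n_unmapped = sum(classified$verdict == "unmapped"),
       n_inter = sum(classified$link_type == "inter"))
}
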