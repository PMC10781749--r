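# emPAI stoichiometry and the small wet-lab assay metrics.

#' Exponentially modified protein abundance index
#'
#' `emPAI = 10^(N_obs / N_obsable) - 1`, where `N_obs` is the number of
#' observed unique parent peptides of a protein and `N_obsable` the
#' number of observable peptides. emPAI is proportional to molar protein
#' abundance, which makes it usable for relative stoichiometry within a
#' purified complex.
#'
#' @param n_observed Observed unique peptide count(s).
#' @param n_observable Observable peptide count(s); must be >= 1.
#' @return emPAI value(s), vectorized.
#' @examples
#' empai(0, 10)   # 0
#' empai(10, 10)  # 9
#' empai(5, 10)   # 10^0.5 - 1
#' @export
empai <- function(n_observed, n_observable) {
  if (any(n_observable < 1))
    stop("n_observable must be >= 1", call. = FALSE)
  if (any(n_observed < 0))
    stop("n_observed must be >= 0", call. = FALSE)
  if (any(n_observed > n_observable))
    warning("n_observed exceeds n_observable for some proteins ",
            "(can occur with modified peptides)", call. = FALSE)
  10^(n_observed / n_observable) - 1
}

# round half away from zero (R's round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

#' Estimate complex stoichiometry from emPAI values
#'
#' The estimated copy number of each complex member is
#' `S_est = 2 * emPAI`; the relative integer stoichiometry divides every
#' `S_est` by the smallest positive one, scales by `reference_min` (the
#' integer assigned to the least abundant member, default 1) and rounds
#' half-up. Ordering of the integers follows the ordering of emPAI.
#'
#' The literature formula typesets ambiguously between
#' `2 * (10^x - 1)` and `(2 * 10^x) - 1`; the default is the former
#' (it equals `2 * emPAI` with emPAI in its canonical form);
#' `strict_typeset = TRUE` selects the latter.
#'
#' @param empai_values Named numeric vector of emPAI values (names =
#'   proteins), or a data frame with columns `protein` and `empai`.
#' @param reference_min Integer for the least abundant member.
#' @param strict_typeset Use `(2 * 10^x) - 1` instead of `2 * emPAI`.
#' @return Data frame with `protein`, `empai`, `estimated_copies`,
#'   `relative_integer`.
#' @export
estimated_stoichiometry <- function(empai_values, reference_min = 1,
                                    strict_typeset = FALSE) {
  if (is.data.frame(empai_values))
    empai_values <- stats::setNames(empai_values$empai,
                                    empai_values$protein)
  if (all(empai_values <= 0))
    stop("all emPAI values are zero; no stoichiometry to estimate",
         call. = FALSE)
  s_est <- if (strict_typeset) 2 * (empai_values + 1) - 1
           else 2 * empai_values
  ref <- min(s_est[s_est > 0])
  rel <- ifelse(s_est > 0,
                pmax(1L, round_half_up(s_est / ref * reference_min)), 0L)
  data.frame(protein = names(empai_values),
             empai = unname(empai_values),
             estimated_copies = unname(s_est),
             relative_integer = as.integer(unname(rel)),
             stringsAsFactors = FALSE)
}

#' Stoichiometry from peptide counts
#'
#' Convenience wrapper: computes emPAI per protein from observed and
#' observable peptide counts, then calls [estimated_stoichiometry()].
#'
#' @param counts Data frame with columns `protein`, `n_observed`,
#'   `n_observable`.
#' @inheritParams estimated_stoichiometry
#' @return As [estimated_stoichiometry()], with count columns kept.
#' @export
stoichiometry_from_counts <- function(counts, reference_min = 1,
                                      strict_typeset = FALSE) {
  e <- empai(counts$n_observed, counts$n_observable)
  res <- estimated_stoichiometry(stats::setNames(e, counts$protein),
                                 reference_min = reference_min,
                                 strict_typeset = strict_typeset)
  cbind(counts[, c("protein", "n_observed", "n_observable")],
        res[, c("empai", "estimated_copies", "relative_integer")])
}

#' Stoichiometry from replicated peptide counts
#'
#' Aggregates emPAI per protein across replicates (mean by default,
#' matching the usual practice of reporting the mean emPAI over
#' biological replicates) before forming relative integers. Pooling
#' across replicates stabilizes the ratio to the least abundant member,
#' whose single-replicate emPAI is the noisiest term in the ratio.
#'
#' @param counts Data frame with columns `replicate`, `protein`,
#'   `n_observed`, `n_observable`.
#' @param pool `"mean"` or `"median"` aggregation of per-replicate
#'   emPAI.
#' @inheritParams estimated_stoichiometry
#' @return As [estimated_stoichiometry()].
#' @export
pooled_stoichiometry <- function(counts, pool = c("mean", "median"),
                                 reference_min = 1,
                                 strict_typeset = FALSE) {
  pool <- match.arg(pool)
  e <- empai(counts$n_observed, counts$n_observable)
  agg <- tapply(e, counts$protein, if (pool == "mean") mean else
                  stats::median)
  estimated_stoichiometry(stats::setNames(as.numeric(agg), names(agg)),
                          reference_min = reference_min,
                          strict_typeset = strict_typeset)
}

#' Fully-tryptic peptides of a protein sequence
#'
#' Cleaves after K or R except when the next residue is P, with zero
#' missed cleavages.
#'
#' @param sequence Single amino-acid string (20-letter alphabet).
#' @return Character vector of peptides, in sequence order.
#' @export
tryptic_peptides <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  legal <- chars %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(legal))
    stop("illegal amino-acid character(s) at position(s): ",
         paste(which(!legal), collapse = ", "), call. = FALSE)
  n <- length(chars)
  if (!n) return(character())
  cut_after <- chars %in% c("K", "R") &
    c(chars[-1] != "P", FALSE)  # never cleave before P; no cut after last
  cut_after[n] <- TRUE
  ends <- which(cut_after)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  vapply(seq_along(ends), function(i)
    paste(chars[starts[i]:ends[i]], collapse = ""), "")
}

#' Count observable tryptic peptides
#'
#' The number of fully-cleaved tryptic peptides with length within
#' `[min_len, max_len]` — a simple proxy for the observable-peptide
#' count that enters emPAI when the search engine's own value is not
#' supplied.
#'
#' @inheritParams tryptic_peptides
#' @param min_len,max_len Peptide length window (defaults 6 and 30).
#' @return Integer count.
#' @export
tryptic_observable_peptides <- function(sequence, min_len = 6,
                                        max_len = 30) {
  peps <- tryptic_peptides(sequence)
  sum(nchar(peps) >= min_len & nchar(peps) <= max_len)
}

#' Competitive index of a bacterial competition assay
#'
#' `CI = (donor_final / recipient_final) / (donor_initial /
#' recipient_initial)`, from CFU counts. CI near 1 means no competitive
#' advantage; CI >> 1 means the donor outcompetes (kills) the recipient.
#'
#' @param donor_initial,recipient_initial,donor_final,recipient_final
#'   CFU counts; vectorized.
#' @param pseudo_count Added to every count before the ratio (off by
#'   default); use only to rescue zero recipient counts.
#' @return Competitive index value(s).
#' @export
competitive_index <- function(donor_initial, recipient_initial,
                              donor_final, recipient_final,
                              pseudo_count = 0) {
  counts <- cbind(donor_initial, recipient_initial, donor_final,
                  recipient_final)
  if (any(counts < 0)) stop("CFU counts must be >= 0", call. = FALSE)
  counts <- counts + pseudo_count
  if (any(counts[, c(2L, 4L)] == 0))
    stop("zero recipient CFU count; consider pseudo_count > 0",
         call. = FALSE)
  as.vector((counts[, 3L] / counts[, 4L]) / (counts[, 1L] / counts[, 2L]))
}

#' Blank-corrected, growth-normalized ELISA signal
#'
#' `(OD450 - blank_OD450) / OD600`: the secreted-protein ELISA readout
#' corrected for the uninoculated-media blank and normalized by the
#' starting culture density.
#'
#' @param od450 ELISA absorbance reading(s).
#' @param od600 Culture density; must be > 0.
#' @param blank_od450 Blank absorbance (default 0).
#' @return Normalized signal(s); negative values are returned with a
#'   warning.
#' @export
normalized_hcp_signal <- function(od450, od600, blank_od450 = 0) {
  if (any(od600 <= 0)) stop("od600 must be > 0", call. = FALSE)
  s <- (od450 - blank_od450) / od600
  if (any(s < 0))
    warning("negative normalized signal (reading below blank)",
            call. = FALSE)
  s
}
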