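# Seeded generators with ground truth, one per pipeline stage. All
# randomness is drawn inside with_seed(): the caller's RNG state is
# untouched and identical seeds give identical outputs.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate annotated genomes with implanted system loci
#'
#' Generates per-genome gene tables with background (component-free)
#' genes and an implanted operon of system components, in one of three
#' architectures: `contiguous` (one block), `split` (the template cut
#' into `k` blocks at random positions, placed far apart), or
#' `degraded` (a contiguous block with the listed components deleted).
#' Spurious isolated component hits are sprinkled on background genes
#' at the given per-gene rate. A truth record lists, per genome, the
#' implanted ranks, the architecture and the expected completeness
#' under `model`.
#'
#' @param model A `system_model`; the template must use its components.
#' @param n_genomes Number of genomes.
#' @param genes_per_replicon Genes per replicon (one replicon per
#'   genome by default).
#' @param architecture `"contiguous"`, `"split"` or `"degraded"`.
#' @param k Number of blocks for `split` (>= 2).
#' @param deleted_components Components removed for `degraded`.
#' @param operon_template Ordered component vector implanted (default:
#'   all model components in model order).
#' @param spurious_hit_rate Per-background-gene probability of a
#'   spurious component hit (<= 0.05).
#' @param seed Integer seed.
#' @return List with `genes` (a gene table over all genomes) and
#'   `truth` (data frame: genome, architecture, implanted ranks as a
#'   comma string, n_blocks, expected_complete, deleted components).
#' @export
simulate_genomes <- function(model, n_genomes = 10,
                             genes_per_replicon = 200,
                             architecture = c("contiguous", "split",
                                              "degraded"),
                             k = 2, deleted_components = character(),
                             operon_template = NULL,
                             spurious_hit_rate = 0, seed = 1) {
  architecture <- match.arg(architecture)
  stopifnot(inherits(model, "system_model"))
  if (is.null(operon_template)) operon_template <- model$components$name
  if (!all(operon_template %in% model$components$name))
    stop("operon_template contains non-model components", call. = FALSE)
  if (architecture == "split" && k < 2)
    stop("split architecture needs k >= 2", call. = FALSE)
  if (spurious_hit_rate < 0 || spurious_hit_rate > 0.05)
    stop("spurious_hit_rate must be in [0, 0.05]", call. = FALSE)
  template <- operon_template
  if (architecture == "degraded")
    template <- setdiff(template, deleted_components)
  if (length(template) > genes_per_replicon)
    stop("operon template longer than the replicon", call. = FALSE)
  with_seed(seed, {
    genomes <- lapply(seq_len(n_genomes), function(gi) {
      gid <- sprintf("G%04d", gi)
      rep_id <- paste0(gid, "_c1")
      n <- genes_per_replicon
      component <- rep(NA_character_, n)
      score <- rep(NA_real_, n)
      n_blocks <- if (architecture == "split") k else 1L
      if (n_blocks > length(template))
        stop("cannot split a ", length(template),
             "-gene template into ", n_blocks, " blocks", call. = FALSE)
      # cut the template into n_blocks consecutive chunks
      if (n_blocks > 1L) {
        cuts <- sort(sample(seq_len(length(template) - 1L),
                            n_blocks - 1L))
        blocks <- split(template,
                        findInterval(seq_along(template) - 1L, cuts) + 1L)
      } else blocks <- list(template)
      # place blocks without overlap, separated by > d_max background genes
      gap <- model$inter_gene_max_distance + 5L
      need <- sum(lengths(blocks)) + (length(blocks) - 1L) * gap
      if (need > n)
        stop("replicon too short for the requested split", call. = FALSE)
      slack <- n - need
      offsets <- sort(sample.int(slack + 1L, length(blocks),
                                 replace = TRUE)) - 1L
      implanted <- integer(0)
      placed_len <- 0L
      for (b in seq_along(blocks)) {
        at <- offsets[b] + placed_len + (b - 1L) * gap  # 0-based rank
        ranks <- seq.int(at, length.out = length(blocks[[b]]))
        component[ranks + 1L] <- blocks[[b]]
        score[ranks + 1L] <- 100
        implanted <- c(implanted, ranks)
        placed_len <- placed_len + length(blocks[[b]])
      }
      # spurious hits on background genes, well away from implants
      if (spurious_hit_rate > 0) {
        bg <- which(is.na(component))
        far <- bg[vapply(bg, function(i)
          all(abs(i - 1L - implanted) >
                model$inter_gene_max_distance + 1L), TRUE)]
        spur <- far[stats::runif(length(far)) < spurious_hit_rate]
        component[spur] <- sample(model$components$name, length(spur),
                                  replace = TRUE)
        score[spur] <- 30
      }
      genes <- data.frame(
        genome_id = gid, replicon_id = rep_id, rank = seq_len(n) - 1L,
        strand = sample(c("+", "-"), n, replace = TRUE),
        locus_tag = sprintf("%s_%05d", gid, seq_len(n)),
        component = component, score = score,
        stringsAsFactors = FALSE)
      mand <- mandatory_components(model)
      truth <- data.frame(
        genome_id = gid, architecture = architecture,
        n_blocks = n_blocks,
        implanted_ranks = paste(implanted, collapse = ","),
        expected_complete =
          length(intersect(template, mand)) >= model$min_mandatory &&
          length(unique(template)) >= model$min_total,
        deleted = paste(deleted_components, collapse = ","),
        stringsAsFactors = FALSE)
      list(genes = genes, truth = truth)
    })
    list(genes = do.call(rbind, lapply(genomes, `[[`, "genes")),
         truth = do.call(rbind, lapply(genomes, `[[`, "truth")))
  })
}

# one self-avoiding walk attempt; NULL when stuck
saw_attempt <- function(n_residues, spacing, min_dist) {
  coords <- matrix(NA_real_, n_residues, 3L)
  coords[1L, ] <- 0
  for (i in seq_len(n_residues - 1L)) {
    placed <- FALSE
    for (try in 1:60) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- coords[i, ] + spacing * u
      if (i >= 2L) {
        prev <- coords[seq_len(i - 1L), , drop = FALSE]
        d2 <- rowSums((prev - matrix(cand, nrow(prev), 3L,
                                     byrow = TRUE))^2)
        if (min(d2) < min_dist^2) next
      }
      coords[i + 1L, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  coords
}

#' Simulate a Calpha chain and a crosslink set of known composition
#'
#' Builds a self-avoiding random walk with a fixed 3.8 Angstrom step
#' (consecutive Calpha spacing) and a minimum pairwise distance of
#' 4.0 Angstrom between residues two or more apart in sequence, then
#' samples residue-pair crosslinks so that exactly
#' `round(n_links * target_violation_fraction)` of them have
#' Calpha-Calpha distance above `d_thresh`. All planted links receive
#' passing confidence scores (ld >= 25, deltaS < 0.95); `n_decoys`
#' additional links receive failing scores to exercise filtering. The
#' truth table labels every link.
#'
#' @param n_residues Chain length (default 300).
#' @param n_links Number of planted (filter-passing) links.
#' @param target_violation_fraction Fraction of planted links violated.
#' @param d_thresh Threshold defining violated during planting
#'   (default 35).
#' @param protein Protein label (default "SIM").
#' @param n_decoys Links with failing scores (default 0).
#' @param spacing Consecutive Calpha spacing (default 3.8).
#' @param min_dist Excluded-volume minimum distance (default 4.0).
#' @param seed Integer seed.
#' @return List with `structure` (a `structure_model`), `links`
#'   (crosslink data frame) and `truth` (per-link: key, planted verdict,
#'   true distance, decoy flag).
#' @export
simulate_structure_and_links <- function(n_residues = 300, n_links = 64,
                                         target_violation_fraction = 0.125,
                                         d_thresh = 35, protein = "SIM",
                                         n_decoys = 0, spacing = 3.8,
                                         min_dist = 4.0, seed = 1) {
  stopifnot(target_violation_fraction >= 0,
            target_violation_fraction <= 1,
            n_links <= n_residues * (n_residues - 1) / 2)
  with_seed(seed, {
    coords <- NULL
    for (restart in 1:50) {
      coords <- saw_attempt(n_residues, spacing, min_dist)
      if (!is.null(coords)) break
    }
    if (is.null(coords))
      stop("could not build a self-avoiding chain; increase n_residues",
           call. = FALSE)
    model <- structure_model(protein, coords)
    d <- as.matrix(stats::dist(coords))
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    pd <- d[pairs]
    n_viol <- round(n_links * target_violation_fraction)
    n_sat <- n_links - n_viol
    viol_pool <- which(pd > d_thresh)
    sat_pool <- which(pd <= d_thresh)
    if (length(viol_pool) < n_viol)
      stop("cannot place ", n_viol, " violated links on this chain; ",
           "increase n_residues", call. = FALSE)
    if (length(sat_pool) < n_sat)
      stop("cannot place ", n_sat, " satisfied links on this chain",
           call. = FALSE)
    take <- c(sample(viol_pool, n_viol), sample(sat_pool, n_sat))
    planted <- data.frame(
      protein_a = protein, residue_a = pairs[take, 1L],
      protein_b = protein, residue_b = pairs[take, 2L],
      ld_score = stats::runif(n_links, 25, 45),
      delta_s = stats::runif(n_links, 0, 0.94),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      residue_a = planted$residue_a, residue_b = planted$residue_b,
      true_distance = pd[take],
      planted_verdict = rep(c("violated", "satisfied"),
                            c(n_viol, n_sat)),
      decoy = FALSE, stringsAsFactors = FALSE)
    if (n_decoys > 0) {
      rest <- setdiff(seq_along(pd), take)
      dk <- sample(rest, n_decoys)
      fail_ld <- stats::runif(n_decoys) < 0.5
      decoys <- data.frame(
        protein_a = protein, residue_a = pairs[dk, 1L],
        protein_b = protein, residue_b = pairs[dk, 2L],
        ld_score = ifelse(fail_ld, stats::runif(n_decoys, 5, 24.9),
                          stats::runif(n_decoys, 25, 45)),
        delta_s = ifelse(fail_ld, stats::runif(n_decoys, 0, 0.94),
                         stats::runif(n_decoys, 0.95, 1)),
        stringsAsFactors = FALSE)
      planted <- rbind(planted, decoys)
      truth <- rbind(truth, data.frame(
        residue_a = decoys$residue_a, residue_b = decoys$residue_b,
        true_distance = pd[dk], planted_verdict = "decoy",
        decoy = TRUE, stringsAsFactors = FALSE))
    }
    ord <- sample(nrow(planted))
    list(structure = model, links = planted[ord, ],
         truth = truth[ord, ])
  })
}

#' Simulate peptide counts from known copy numbers
#'
#' Inverts the stoichiometry relation: a protein present at `copies`
#' copies has expected observed-peptide fraction
#' `p = log10(1 + copies/2)`, so that the emPAI pipeline recovers
#' `copies` exactly in the noiseless case. With `noise = "binomial"`,
#' `N_obs ~ Binomial(N_obsable, p)` per replicate (integer counts);
#' with `noise = "none"` the exact real-valued `N_obs = N_obsable * p`
#' is returned.
#'
#' @param true_copies Named numeric vector of true copy numbers (>= 0;
#'   zero-copy proteins yield `N_obs = 0`).
#' @param n_observable Observable peptides per protein (scalar or named
#'   vector).
#' @param noise `"none"` or `"binomial"`.
#' @param n_replicates Replicates (default 1).
#' @param seed Integer seed.
#' @return List with `counts` (data frame: replicate, protein,
#'   n_observed, n_observable) and `truth` (protein, true_copies).
#' @export
simulate_peptide_counts <- function(true_copies, n_observable = 40,
                                    noise = c("none", "binomial"),
                                    n_replicates = 1, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(!is.null(names(true_copies)), all(true_copies >= 0))
  proteins <- names(true_copies)
  if (length(n_observable) == 1L)
    n_observable <- stats::setNames(rep(n_observable, length(proteins)),
                                    proteins)
  p <- log10(1 + true_copies / 2)
  if (any(p > 1))
    stop("copy number(s) too high for the observable-peptide window ",
         "(implied N_obs > N_obsable): ",
         paste(proteins[p > 1], collapse = ", "), call. = FALSE)
  counts <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      n_obs <- if (noise == "binomial")
        stats::rbinom(length(proteins), n_observable[proteins], p)
      else n_observable[proteins] * p
      data.frame(replicate = r, protein = proteins,
                 n_observed = n_obs,
                 n_observable = unname(n_observable[proteins]),
                 stringsAsFactors = FALSE)
    }))
  })
  list(counts = counts,
       truth = data.frame(protein = proteins,
                          true_copies = unname(true_copies),
                          stringsAsFactors = FALSE))
}
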