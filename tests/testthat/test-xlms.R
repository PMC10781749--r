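test_that("confidence filtering applies ld >= 25 and deltaS < 0.95
           boundaries and deduplicates residue pairs", {
  links <- data.frame(
    protein_a = "P", residue_a = c(1, 2, 3, 4, 4, 20),
    protein_b = "P", residue_b = c(10, 11, 12, 20, 20, 4),
    ld_score = c(25.0, 24.9, 30, 28, 33, 31),
    delta_s = c(0.90, 0.5, 0.95, 0.2, 0.2, 0.2))
  out <- filter_crosslinks(links)
  counts <- attr(out, "counts")
  # ld 25.0 kept (inclusive), 24.9 dropped, deltaS 0.95 dropped (strict)
  expect_true(any(out$residue_a == 1))
  expect_false(any(out$residue_a == 2))
  expect_false(any(out$residue_a == 3))
  # 4-20 seen three times (one as 20-4): one survivor with the max ld
  dup <- out[(out$residue_a == 4 & out$residue_b == 20) |
               (out$residue_a == 20 & out$residue_b == 4), ]
  expect_equal(nrow(dup), 1)
  expect_equal(dup$ld_score, 33)
  expect_equal(unname(counts["dropped"]), 2L)
  expect_equal(unname(counts["deduplicated"]), 2L)
  expect_error(
    filter_crosslinks(transform(links, ld_score = ld_score - 100)),
    "negative")
})

test_that("filtering matches a brute-force dedup oracle on random links", {
  set.seed(303)
  n <- 100
  res <- matrix(sample(1:30, 2 * n, replace = TRUE), ncol = 2)
  links <- data.frame(
    protein_a = sample(c("A", "B"), n, replace = TRUE),
    residue_a = res[, 1], protein_b = "A", residue_b = res[, 2],
    ld_score = round(runif(n, 10, 45), 2),
    delta_s = round(runif(n, 0, 1), 3))
  out <- filter_crosslinks(links)
  # oracle: filter literally, group by unordered key, keep max ld
  pass <- links[links$ld_score >= 25 & links$delta_s < 0.95, ]
  key <- apply(pass, 1, function(r) paste(sort(c(
    paste(r[["protein_a"]], trimws(r[["residue_a"]])),
    paste(r[["protein_b"]], trimws(r[["residue_b"]])))), collapse = "|"))
  want <- sort(vapply(split(pass$ld_score, key), max, 0))
  got <- sort(out$ld_score)
  expect_equal(unname(got), unname(want))
  expect_equal(nrow(out), length(unique(key)))
})

test_that("classification against the packaged synthetic chain matches
           hand-computed distances and reasons", {
  pdb <- system.file("extdata", "synthetic_chain.pdb", package = "t6sscan")
  links <- read_crosslinks(system.file("extdata",
                                       "synthetic_crosslinks.tsv",
                                       package = "t6sscan"))
  mod <- read_structure_ca(pdb, protein = "TssX")
  expect_equal(mod$length, 20)
  expect_equal(unname(mod$coords[2, 3]) - unname(mod$coords[1, 3]), 3.8)
  out <- classify_links(filter_crosslinks(links), list(TssX = mod))
  by_key <- function(a, b) out[out$residue_a == a & out$residue_b == b, ]
  expect_equal(by_key(1, 5)$distance, 4 * 3.8)   # straight chain
  expect_equal(by_key(1, 5)$verdict, "satisfied")
  expect_equal(by_key(1, 19)$verdict, "violated")  # 18 * 3.8 = 68.4
  expect_equal(by_key(1, 25)$verdict, "unmapped")  # residue 25 not modeled
  expect_equal(by_key(3, 8)$verdict, "unmapped")   # inter-protein
  expect_equal(by_key(3, 8)$reason, "inter-protein link")
  expect_error(
    classify_links(data.frame(protein_a = "Zed", residue_a = 1,
                              protein_b = "Zed", residue_b = 2,
                              ld_score = 30, delta_s = 0.1,
                              link_type = "intra"),
                   list(TssX = mod)),
    "Zed")
})

test_that("a link at exactly the threshold distance is satisfied", {
  coords <- rbind(c(0, 0, 0), c(0, 0, 35.0), c(0, 0, 70.1))
  mod <- structure_model("P", coords)
  links <- data.frame(protein_a = "P", residue_a = c(1, 2),
                      protein_b = "P", residue_b = c(2, 3),
                      ld_score = 30, delta_s = 0.1, link_type = "intra")
  out <- classify_links(links, list(P = mod))
  expect_equal(out$verdict, c("satisfied", "violated"))  # 35.0 vs 35.1
})

test_that("verdicts equal an independent distance recomputation, are
           symmetric under residue swap, and are monotone in d_thresh", {
  sim <- simulate_structure_and_links(n_residues = 150, n_links = 200,
                                      target_violation_fraction = 0.2,
                                      seed = 44)
  links <- sim$links
  out <- classify_links(links, list(SIM = sim$structure))
  co <- sim$structure$coords
  for (i in seq_len(nrow(out))) {
    d <- sqrt(sum((co[out$residue_a[i], ] - co[out$residue_b[i], ])^2))
    expect_equal(out$distance[i], d)
    expect_equal(out$verdict[i], if (d <= 35) "satisfied" else "violated")
  }
  swapped <- transform(links, residue_a = links$residue_b,
                       residue_b = links$residue_a)
  out_sw <- classify_links(swapped, list(SIM = sim$structure))
  expect_equal(out_sw$verdict, out$verdict)
  expect_equal(out_sw$distance, out$distance)
  expect_equal(out_sw$sequence_separation, out$sequence_separation)
  n_viol <- vapply(c(10, 20, 35, 50, 80), function(th)
    sum(classify_links(links, list(SIM = sim$structure),
                       d_thresh = th)$verdict == "violated"), 0L)
  expect_true(all(diff(n_viol) <= 0))
})

test_that("on a 3.8-A chain every link is bounded by 3.8 x separation", {
  sim <- simulate_structure_and_links(n_residues = 120, n_links = 100,
                                      target_violation_fraction = 0.1,
                                      seed = 55)
  out <- classify_links(sim$links, list(SIM = sim$structure))
  expect_true(all(out$distance <= 3.8 * out$sequence_separation + 1e-9))
  short <- out$sequence_separation * 3.8 <= 35
  expect_true(all(out$verdict[short] == "satisfied"))
})

test_that("violation summaries report per-protein counts, the overall
           fraction and long-range satisfied links", {
  mk <- function(p, n, nviol, seps) data.frame(
    protein_a = p, residue_a = 1, protein_b = p,
    residue_b = 1 + seps, ld_score = 30, delta_s = 0.1,
    link_type = "intra", distance = 10,
    verdict = rep(c("violated", "satisfied"), c(nviol, n - nviol)),
    reason = NA, sequence_separation = seps)
  cls <- rbind(mk("TssQ", 18, 6, rep(30, 18)),
               mk("TssN", 3, 0, c(5, 25, 40)))
  s <- violation_summary(cls)
  pp <- s$per_protein
  expect_equal(pp$n_violated[pp$protein == "TssQ"], 6L)
  expect_equal(pp$n_total[pp$protein == "TssQ"], 18L)
  expect_equal(s$violated_fraction, 6 / 21)
  expect_equal(s$n_long_range_satisfied, 12 + 2)
  # all satisfied, separations {5,25,40} -> 2 long-range
  s2 <- violation_summary(mk("X", 3, 0, c(5, 25, 40)))
  expect_equal(s2$n_long_range_satisfied, 2L)
  expect_equal(s2$violated_pct, 0)
  # empty mapped set flagged undefined
  s3 <- violation_summary(mk("X", 1, 0, 5)[0, ])
  expect_true(s3$undefined)
  expect_true(is.na(s3$violated_fraction))
})

test_that("a planted violation fraction is recovered exactly", {
  sim <- simulate_structure_and_links(n_residues = 200, n_links = 64,
                                      target_violation_fraction = 0.125,
                                      n_decoys = 16, seed = 7)
  kept <- filter_crosslinks(sim$links)
  expect_equal(nrow(kept), 64)  # decoys fail the confidence filter
  s <- violation_summary(classify_links(kept, list(SIM = sim$structure)))
  expect_equal(s$n_violated, 8L)
  expect_equal(s$violated_pct, 12.5)
  expect_equal(s$violated_pct_rounded, 12)
})
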