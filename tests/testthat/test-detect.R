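model <- t6ss_iii_model()

test_that("cluster chaining respects the d_max boundary exactly", {
  # 10 intervening genes (ranks 5 and 16): one cluster at d_max = 10
  g <- toy_genes(list(`5` = "TssB", `16` = "TssC"), n_genes = 30)
  cl <- cluster_hits(g, model)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  # 11 intervening genes (ranks 5 and 17): two clusters
  g2 <- toy_genes(list(`5` = "TssB", `17` = "TssC"), n_genes = 30)
  cl2 <- cluster_hits(g2, model)
  expect_equal(length(unique(cl2$cluster_id)), 2L)
})

test_that("intervening component genes extend but never break a chain", {
  # B ... N ... C with per-step gaps <= d_max chains into one cluster
  g <- toy_genes(list(`0` = "TssB", `9` = "TssN", `18` = "TssC"),
                 n_genes = 40)
  expect_equal(length(unique(cluster_hits(g, model)$cluster_id)), 1L)
})

test_that("clustering matches the O(n^2) transitive-closure oracle and is
           permutation-invariant", {
  genes <- random_gene_tables(50, 400, model$components$name,
                              hit_rate = 0.04, seed = 101)
  cl <- cluster_hits(genes, model)
  expect_identical(
    canonical_partition(clustered_to_partition(cl)),
    canonical_partition(oracle_cluster_partition(
      genes, model$components$name, model$inter_gene_max_distance)))
  # shuffling input rows changes nothing
  set.seed(1)
  cl_shuf <- cluster_hits(genes[sample(nrow(genes)), ], model)
  expect_identical(clustered_to_partition(cl_shuf),
                   clustered_to_partition(cl))
})

test_that("circular replicons merge clusters across the origin", {
  g <- toy_genes(list(`1` = "TssB", `95` = "TssC"), n_genes = 100)
  reps <- data.frame(replicon_id = "c1", topology = "circular",
                     n_genes = 100)
  # wrap gap = 100 - 95 - 1 + 1 = 5 <= 10: one cluster when circular
  expect_equal(length(unique(cluster_hits(g, model, reps)$cluster_id)), 1L)
  # declared linear (the default): two clusters
  expect_equal(length(unique(cluster_hits(g, model)$cluster_id)), 2L)
  # a wrap gap beyond d_max stays split
  g2 <- toy_genes(list(`20` = "TssB", `60` = "TssC"), n_genes = 100)
  expect_equal(
    length(unique(cluster_hits(g2, model, reps)$cluster_id)), 2L)
})

test_that("the printed quorum decides completeness on pooled inventories", {
  # 8 distinct incl. one mandatory -> complete under Q_mand=1, Q_tot=8
  g <- toy_genes(stats::setNames(
    as.list(c("TssB", "TssC", "TssD", "TssE", "TssF", "TssG", "TssK",
              "TssN")), 0:7), n_genes = 20)
  sys <- evaluate_systems(cluster_hits(g, model), model)
  expect_length(sys, 1)
  expect_true(sys[[1]]$complete)
  # 7 distinct incl. TssN -> incomplete
  g2 <- toy_genes(stats::setNames(
    as.list(c("TssB", "TssC", "TssD", "TssE", "TssF", "TssG", "TssN")),
    0:6), n_genes = 20)
  sys2 <- evaluate_systems(cluster_hits(g2, model), model)
  expect_false(sys2[[1]]$complete)
  # 9 distinct but no mandatory -> incomplete
  g3 <- toy_genes(stats::setNames(
    as.list(c("TssB", "TssC", "TssD", "TssE", "TssF", "TssG", "TssH",
              "TssI", "TssK")), 0:8), n_genes = 20)
  expect_false(evaluate_systems(cluster_hits(g3, model),
                                model)[[1]]$complete)
})

test_that("a system split into four loci pools into one complete system", {
  sim <- simulate_genomes(model, n_genomes = 5, genes_per_replicon = 200,
                          architecture = "split", k = 4, seed = 21)
  sys <- evaluate_systems(cluster_hits(sim$genes, model), model)
  expect_length(sys, 5)
  for (s in sys) {
    expect_equal(s$n_loci, 4L)
    expect_true(s$complete)
    expect_equal(s$n_distinct_components, 14L)
  }
})

test_that("without multi-locus pooling each cluster stands alone", {
  m1 <- system_model("single", t6ss_iii_model()$components,
                     min_mandatory = 1, min_total = 8,
                     inter_gene_max_distance = 10, multi_loci = FALSE)
  sim <- simulate_genomes(m1, n_genomes = 3, genes_per_replicon = 200,
                          architecture = "split", k = 2, seed = 5)
  sys <- evaluate_systems(cluster_hits(sim$genes, m1), m1)
  expect_length(sys, 6)  # 2 candidates per genome
  # pooling never reduces the distinct count below the best single locus
  pooled <- evaluate_systems(cluster_hits(sim$genes, t6ss_iii_model()),
                             t6ss_iii_model())
  best_single <- max(vapply(sys, `[[`, 0L, "n_distinct_components"))
  expect_gte(pooled[[1]]$n_distinct_components, best_single)
})

test_that("mc_completeness flags exactly the absent MC components", {
  sim <- simulate_genomes(model, n_genomes = 2, genes_per_replicon = 100,
                          architecture = "degraded",
                          deleted_components = c("TssO", "TssQ", "TssR"),
                          seed = 9)
  sys <- evaluate_systems(cluster_hits(sim$genes, model), model)
  flags <- mc_completeness(sys[[1]])
  expect_equal(flags, c(TssN = TRUE, TssO = FALSE, TssP = TRUE,
                        TssQ = FALSE, TssR = FALSE))
  # a model without the MC components is a usage error
  u_sys <- evaluate_systems(
    cluster_hits(sim$genes, t6ss_universal_model()),
    t6ss_universal_model())
  expect_error(mc_completeness(u_sys[[1]]), "lacks")
})

test_that("a planted 30% tssO deletion census recovers the absence
           fraction within the binomial interval", {
  n <- 200
  set.seed(77)
  drop_o <- runif(n) < 0.30
  sims <- lapply(seq_len(n), function(i) {
    simulate_genomes(model, n_genomes = 1, genes_per_replicon = 60,
                     architecture = "degraded",
                     deleted_components = if (drop_o[i]) "TssO"
                                          else character(),
                     seed = 1000 + i)$genes
  })
  genes <- do.call(rbind, sims)
  genes$genome_id <- rep(sprintf("C%03d", seq_len(n)), each = 60)
  genes$replicon_id <- paste0(genes$genome_id, "_c1")
  genes$locus_tag <- paste0(genes$genome_id, "_", genes$locus_tag)
  sys <- evaluate_systems(cluster_hits(genes, model), model)
  frac <- absence_fractions(sys)[["TssO"]]
  expect_equal(frac, mean(drop_o))  # exact recovery of the planted census
  ci <- binom.test(sum(drop_o), n, 0.30)$conf.int
  expect_gte(0.30, ci[1] - 1e-12)
  expect_lte(0.30, ci[2] + 1e-12)
})

test_that("the presence/absence matrix recounts the inventories", {
  sim <- simulate_genomes(model, n_genomes = 4, genes_per_replicon = 100,
                          architecture = "contiguous", seed = 31)
  sys <- evaluate_systems(cluster_hits(sim$genes, model), model)
  m <- presence_absence_matrix(sys, genomes = c(sort(unique(
    sim$genes$genome_id)), "empty_genome"))
  expect_equal(nrow(m), 5)
  expect_equal(unname(m["empty_genome", ]), rep(0L, ncol(m)))
  expect_equal(unname(rowSums(m)[sys[[1]]$genome_id]),
               sum(sys[[1]]$inventory))
  # single-copy complete system: a row of ones over the 14 components
  expect_equal(unname(m["G0001", ]), rep(1L, 14))
  # multiple tssD copies are counted, not flattened
  g <- toy_genes(stats::setNames(
    as.list(c("TssD", "TssD", "TssD", "TssB", "TssC", "TssE", "TssF",
              "TssN")), 0:7), n_genes = 20)
  sys2 <- evaluate_systems(cluster_hits(g, model), model)
  m2 <- presence_absence_matrix(sys2)
  expect_equal(m2["G1", "TssD"], 3L)
})
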