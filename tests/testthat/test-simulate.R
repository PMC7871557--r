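test_that("simulated trees are Yule-shaped, depth-1 ultrametric and deterministic", {
  tr <- simulate_tree(2, seed = 5)
  depths <- ape::node.depth.edgelength(tr)[1:2]
  expect_equal(depths, c(1, 1))           # a single cherry, both tips at depth 1

  tr <- simulate_tree(40, seed = 1)
  expect_equal(ape::Ntip(tr), 40)
  expect_equal(tr$Nnode, 39)
  expect_equal(max(ape::node.depth.edgelength(tr)), 1)
  expect_setequal(tr$tip.label, sprintf("S%d", 1:40))

  expect_identical(ape::write.tree(simulate_tree(40, seed = 9)),
                   ape::write.tree(simulate_tree(40, seed = 9)))
  expect_false(identical(ape::write.tree(simulate_tree(40, seed = 9)),
                         ape::write.tree(simulate_tree(40, seed = 10))))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("focal clade selection honours monophyly and polyphyly", {
  tr <- simulate_tree(40, seed = 3)

  # one clade: the focal set is monophyletic
  f1 <- select_focal_clades(tr, 6, 1, seed = 2)
  idx <- match(f1, tr$tip.label)
  mrca <- ape::getMRCA(tr, idx)
  expect_setequal(ape::extract.clade(tr, mrca)$tip.label, f1)

  # two clades: sizes sum to n_focal and the union's MRCA is the root
  f2 <- select_focal_clades(tr, 10, 2, seed = 2)
  expect_length(f2, 10)
  expect_equal(ape::getMRCA(tr, match(f2, tr$tip.label)), ape::Ntip(tr) + 1L)

  # whole leaf set
  expect_setequal(select_focal_clades(tr, 40, 2, seed = 1), tr$tip.label)
})

test_that("gene-content limits behave: zero-rate keeps everything, certain loss empties focal", {
  b <- simulate_dataset(small_config(seed = 4))
  tr <- b$tree
  focal <- b$truth$focal_ids

  cfg0 <- simulation_config(n_strains = 30, n_focal = 6, n_families = 50,
                            n_planted_missing = 4, base_loss_prob = 0,
                            focal_extra_loss = 0, padding_genes = 20, seed = 4)
  evo0 <- evolve_gene_content(tr, cfg0, focal)
  expect_true(all(evo0$presence == 1L))

  cfg1 <- simulation_config(n_strains = 30, n_focal = 6, n_families = 50,
                            n_planted_missing = 4, focal_extra_loss = 1,
                            padding_genes = 20, seed = 4)
  evo1 <- evolve_gene_content(tr, cfg1, focal)
  expect_true(all(evo1$presence[evo1$truth$planted_missing, focal] == 0L))
})

test_that("raising the base loss rate never adds genes (common random numbers)", {
  b <- simulate_dataset(small_config(seed = 11))
  tr <- b$tree
  focal <- b$truth$focal_ids
  counts <- sapply(c(0.01, 0.03, 0.08), function(p) {
    cfg <- simulation_config(n_strains = 30, n_focal = 6, n_families = 150,
                             n_planted_missing = 4, base_loss_prob = p,
                             padding_genes = 20, seed = 11)
    colSums(evolve_gene_content(tr, cfg, focal)$presence)
  })
  expect_true(all(counts[, 2] <= counts[, 1]))
  expect_true(all(counts[, 3] <= counts[, 2]))
})

test_that("gene content carries phylogenetic signal: sisters are closer than cross-root pairs", {
  wins <- 0L
  reps <- 100L
  for (r in seq_len(reps)) {
    cfg <- simulation_config(n_strains = 10, n_focal = 2, n_families = 120,
                             n_planted_missing = 2, focal_extra_loss = 0,
                             padding_genes = 20, seed = 500 + r)
    tr <- simulate_tree(10, seed = 500 + r)
    evo <- evolve_gene_content(tr, cfg, character(0))
    d <- as.matrix(binary_distance(evo$presence))
    # one sister (cherry) pair and one pair spanning the root
    po <- ape::prop.part(tr)
    cherry <- Find(function(s) length(s) == 2, po)
    root_kids <- tr$edge[tr$edge[, 1] == ape::Ntip(tr) + 1L, 2]
    sides <- lapply(root_kids, function(k) {
      if (k <= ape::Ntip(tr)) k else po[[k - ape::Ntip(tr)]]
    })
    if (is.null(cherry) || length(sides) < 2) next
    cross <- c(sides[[1]][1], sides[[2]][1])
    lab <- tr$tip.label
    if (d[lab[cherry[1]], lab[cherry[2]]] < d[lab[cross[1]], lab[cross[2]]]) {
      wins <- wins + 1L
    }
  }
  expect_gt(wins / reps, 0.5)   # stochastically smaller, not deterministically
})

test_that("genome sizes follow the closed-form coupling", {
  cc <- tibble::tibble(strain_id = c("A", "B"), G = c(700L, 700L), K = c(800L, 800L))
  sz <- couple_genome_sizes(cc, padding = 0, kb_per_gene = 1,
                            size_noise_sd_mbp = 0, seed = 1)
  expect_equal(unname(sz), c(1.5, 1.5))   # 1500 genes at 1 kb/gene = 1.5 Mbp
  sz2 <- couple_genome_sizes(cc, padding = 500, kb_per_gene = 2,
                             size_noise_sd_mbp = 0, seed = 1)
  expect_equal(unname(sz2), c(4, 4))
})

test_that("noiseless synthetic data recovers the analytic class-G coupling slope", {
  cfg <- small_config(seed = 21, size_noise_sd_mbp = 0)
  b <- simulate_dataset(cfg)
  fit <- fit_class_regression(b$metadata, b$class_counts, "G")
  truth <- b$truth$true_slopes$true_slope[b$truth$true_slopes$class == "G"]
  expect_lt(abs(fit$slope / truth - 1), 0.25)
})

test_that("simulated bundles satisfy their own invariants and are reproducible", {
  cfg <- small_config(seed = 13)
  b <- simulate_dataset(cfg)

  expect_equal(nrow(b$metadata), 30)
  expect_equal(nrow(b$presence), 200)
  expect_equal(sum(b$metadata$is_focal), 6)
  expect_true(all(b$metadata$genome_size_mbp > 0))

  # class counts are exactly the per-class column sums of the presence matrix
  m <- as.matrix(b$presence[-1])
  rownames(m) <- b$presence$family_id
  cls <- b$truth$classes[b$presence$family_id]
  for (cl in c("G", "E", "K")) {
    expect_equal(b$class_counts[[cl]],
                 unname(colSums(m[cls == cl, b$class_counts$strain_id, drop = FALSE])))
  }

  # determinism
  b2 <- simulate_dataset(cfg)
  expect_equal(b$presence, b2$presence)
  expect_equal(b$metadata, b2$metadata)

  # a different seed changes the data
  b3 <- simulate_dataset(small_config(seed = 14))
  expect_false(identical(b$presence, b3$presence))

  # minimal configuration also passes validation
  tiny <- simulation_config(n_strains = 4, n_focal = 2, n_focal_clades = 1,
                            n_families = 20, n_planted_missing = 2,
                            padding_genes = 10, seed = 2)
  bt <- simulate_dataset(tiny)
  expect_equal(nrow(bt$metadata), 4)
})

test_that("bundle files round-trip through the readers", {
  cfg <- small_config(seed = 23)
  b <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  md <- read_genome_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$strain_id, b$metadata$strain_id)
  expect_equal(md$genome_size_mbp, b$metadata$genome_size_mbp)
  pm <- read_presence_matrix(file.path(dir, "presence.tsv"), min_prevalence = 0)
  expect_equal(pm, b$presence)
  cc <- read_class_counts(file.path(dir, "class_counts.tsv"))
  expect_equal(cc, b$class_counts)
  tr <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, md$strain_id)
})
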