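test_that("Yule trees have the right shape and are seed-deterministic", {
  tr <- simulate_yule_tree(8, seed = 3)
  expect_equal(length(tr$tip.label), 8)
  expect_equal(tr$Nnode, 7)
  expect_true(ape::is.binary(tr))
  expect_true(all(tr$edge.length >= 0))
  # ultrametric, scaled to the stated height
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(unname(depths[1:8]), rep(1, 8), tolerance = 1e-6)
  expect_identical(write_newick(tr), write_newick(simulate_yule_tree(8, seed = 3)))
  expect_false(identical(write_newick(tr), write_newick(simulate_yule_tree(8, seed = 4))))
  expect_equal(length(simulate_yule_tree(2, seed = 1)$tip.label), 2)
})

test_that("SPR transfers change the topology and log deterministically", {
  sp <- simulate_yule_tree(8, seed = 3)
  none <- apply_spr_transfers(sp, 0, seed = 1)
  expect_identical(write_newick(none$tree), write_newick(sp))
  expect_equal(nrow(none$log), 0)
  one <- apply_spr_transfers(sp, 1, seed = 4, leaf_only = TRUE)
  expect_gt(rf_distance(ape::unroot(one$tree), ape::unroot(sp))$rf, 0)
  expect_equal(nrow(one$log), 1)
  again <- apply_spr_transfers(sp, 1, seed = 4, leaf_only = TRUE)
  expect_identical(write_newick(again$tree), write_newick(one$tree))
  expect_identical(again$log, one$log)
  # general (subtree) moves also run and keep the leaf set
  gen <- apply_spr_transfers(sp, 2, seed = 9)
  expect_setequal(gen$tree$tip.label, sp$tip.label)
  expect_false(anyNA(gen$tree$edge.length))
})

test_that("sequence evolution follows the closed-form identity", {
  # zero branch lengths: all leaves identical
  flat <- parse_newick("((a:0,b:0):0,c:0);")
  s0 <- evolve_sequences(flat, 100, seed = 1)
  expect_equal(length(unique(s0)), 1)

  # two leaves at path distance 0.1: identity ~ 1/20 + (19/20) e^(-0.10526)
  two <- parse_newick("(a:0.05,b:0.05);")
  L <- 10000
  s <- evolve_sequences(two, L, seed = 2)
  obs <- mean(strsplit(s[["a"]], "")[[1]] == strsplit(s[["b"]], "")[[1]])
  p_same <- 1 / 20 + (19 / 20) * exp(-(20 / 19) * 0.1)
  expect_equal(p_same, 0.90509, tolerance = 1e-4)
  se <- sqrt(p_same * (1 - p_same) / L)
  expect_lt(abs(obs - p_same), 3 * se)

  # saturation: identity near 1/20
  sat <- evolve_sequences(parse_newick("(a:10,b:10);"), 10000, seed = 3)
  obs_sat <- mean(strsplit(sat[["a"]], "")[[1]] == strsplit(sat[["b"]], "")[[1]])
  expect_lt(abs(obs_sat - 0.05), 0.01)

  expect_error(evolve_sequences(parse_newick("(a,b);"), 10), "length")
})

test_that("mean pairwise identity converges to the closed form (LLN)", {
  d <- 0.2
  two <- parse_newick(sprintf("(a:%f,b:%f);", d / 2, d / 2))
  L <- 50000
  s <- evolve_sequences(two, L, seed = 11)
  obs <- mean(strsplit(s[["a"]], "")[[1]] == strsplit(s[["b"]], "")[[1]])
  p_same <- 1 / 20 + (19 / 20) * exp(-(20 / 19) * d)
  expect_lt(abs(obs - p_same) / p_same, 0.005)
})

test_that("NJ on evolved sequences recovers the generating topology", {
  hits <- 0
  reps <- 20
  for (seed in seq_len(reps)) {
    tr <- random_binary_tree(16, bl_range = c(0.02, 0.3), seed = seed, rooted = TRUE)
    seqs <- evolve_sequences(tr, 2000, seed = seed + 300)
    nj <- neighbor_joining(
      distance_matrix(seqs, distance_params(correction = "poisson")))
    if (rf_distance(ape::unroot(nj), ape::unroot(tr))$rf == 0) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("genome fixtures plant exact class counts and reproduce by seed", {
  fx <- generate_genome_fixtures(n_genomes = 10, fraction_incomplete = 0.3,
                                 fraction_fused_en = 0.2, fraction_fused_nb = 0,
                                 seed = 0)
  expect_equal(sum(fx$truth$status == "incomplete"), 3)
  expect_equal(sum(fx$truth$fused == "EN"), 2)
  # fused EN records have summed length 460 + 430 = 890
  en <- fx$truth$genome_id[fx$truth$fused == "EN"]
  for (g in en) {
    ann <- fx$genomes[[match(g, vapply(fx$genomes, `[[`, "", "genome_id"))]]
    fused_pid <- fx$truth$pid_E[fx$truth$genome_id == g]
    expect_equal(nchar(ann$genes$protein[ann$genes$protein_id == fused_pid]), 890)
  }
  # decoys sit far from the operon and are never chosen
  tab <- screen_genomes(fx$genomes)
  chosen <- unlist(tab[tab$status == "complete", paste0("pid_", c("H","D","K","E","N","B"))])
  expect_false(any(grepl("decoy", chosen)))
  # byte-for-byte reproducibility from the seed
  fx2 <- generate_genome_fixtures(n_genomes = 10, fraction_incomplete = 0.3,
                                  fraction_fused_en = 0.2, fraction_fused_nb = 0,
                                  seed = 0)
  expect_identical(fx$truth, fx2$truth)
  expect_identical(fx$genomes[[1]]$genes, fx2$genomes[[1]]$genes)
})

test_that("fixture files round-trip through the annotation reader", {
  fx <- generate_genome_fixtures(n_genomes = 3, seed = 2)
  dir <- withr::local_tempdir()
  write_genome_fixtures(fx, dir)
  g1 <- fx$genomes[[1]]
  back <- read_annotation_table(file.path(dir, paste0(g1$genome_id, ".tsv")),
                                file.path(dir, paste0(g1$genome_id, ".faa")),
                                "tsv", genome_id = g1$genome_id)
  expect_equal(back$genes[, c("symbol", "contig", "start", "end", "strand", "protein_id")],
               g1$genes[, c("symbol", "contig", "start", "end", "strand", "protein_id")])
  expect_equal(back$genes$protein, g1$genes$protein)
})
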