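test_that("bipartitions enumerate internal edges with canonical keys", {
  expect_equal(names(bipartitions(parse_newick("((A,B),(C,D));"))), "A,B")
  cat6 <- parse_newick("(((((A,B),C),D),E),F);")
  expect_setequal(names(bipartitions(cat6)), c("A,B", "A,B,C", "E,F"))
  expect_equal(length(bipartitions(parse_newick("(A,B,C,D,E);"))), 0)  # star
})

test_that("rf_distance matches hand counts and the phangorn oracle", {
  t1 <- parse_newick("((A,B),(C,D));")
  expect_equal(rf_distance(t1, t1)$rf, 0)
  t2 <- parse_newick("((A,C),(B,D));")
  r <- rf_distance(t1, t2)
  expect_equal(r$rf, 2)
  expect_equal(r$normalized, 1)
  # 6-leaf caterpillar vs balanced: ABCD|EF coincides with EF|ABCD, so the
  # trees share two splits and differ in two (oracle-verified)
  cat6 <- parse_newick("(((((A,B),C),D),E),F);")
  bal6 <- parse_newick("((A,B),(C,D),(E,F));")
  expect_equal(rf_distance(cat6, bal6)$rf, 2)
  expect_equal(rf_distance(cat6, bal6)$rf,
               as.integer(phangorn::RF.dist(ape::unroot(cat6), bal6)))
  expect_error(rf_distance(t1, parse_newick("((A,B),(C,E));")), "leaf sets")
})

test_that("rf_distance is a metric: zero iff same topology, symmetric", {
  labels <- paste0("t", 1:8)
  for (seed in 1:40) {
    t1 <- random_topology(labels, seed)
    t2 <- random_topology(labels, seed + 1000)
    r12 <- rf_distance(t1, t2)$rf
    expect_equal(r12, rf_distance(t2, t1)$rf)
    expect_equal(r12, as.integer(phangorn::RF.dist(t1, t2)))
    same <- write_newick(strip_lengths(t1)) == write_newick(strip_lengths(t2))
    expect_equal(r12 == 0, same)
    # triangle inequality spot-check
    t3 <- random_topology(labels, seed + 2000)
    expect_lte(rf_distance(t1, t3)$rf, r12 + rf_distance(t2, t3)$rf)
  }
})

test_that("majority consensus keeps strict-majority splits with supports", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  cons <- majority_consensus(list(t1, t1, t2))
  expect_equal(names(bipartitions(cons)), "A,B")
  expect_equal(as.numeric(cons$node.label[cons$node.label != ""]), 2 / 3,
               tolerance = 1e-4)
  # all three topologies once: star (no split above 1/3)
  t3 <- parse_newick("((A,D),(B,C));")
  expect_equal(length(bipartitions(majority_consensus(list(t1, t2, t3)))), 0)
  # k copies of one tree give that tree, support 1
  for (k in c(1, 2, 5)) {
    tr <- random_topology(paste0("x", 1:7), k)
    cons_k <- majority_consensus(rep(list(tr), k))
    expect_equal(rf_distance(cons_k, tr)$rf, 0)
    sup <- as.numeric(cons_k$node.label[nzchar(cons_k$node.label)])
    expect_true(all(sup == 1))
  }
  expect_error(majority_consensus(list(t1, parse_newick("((A,B),(C,E));"))),
               "leaf set")
})

test_that("consensus splits are pairwise compatible and match ape", {
  labels <- paste0("t", 1:9)
  for (seed in 1:10) {
    trees <- lapply(1:3, function(i) random_topology(labels, seed * 10 + i))
    cons <- majority_consensus(trees)
    bp <- bipartitions(cons)
    # pairwise compatibility: for any two splits one side pair is disjoint
    # or nested
    if (length(bp) > 1) {
      for (i in seq_along(bp)) for (j in seq_along(bp)) if (i < j) {
        A <- bp[[i]]; B <- bp[[j]]
        Ac <- setdiff(labels, A); Bc <- setdiff(labels, B)
        compat <- !length(intersect(A, B)) || !length(intersect(A, Bc)) ||
          !length(intersect(Ac, B)) || !length(intersect(Ac, Bc))
        expect_true(compat)
      }
    }
    # same splits as ape's strict-majority consensus
    ac <- ape::consensus(trees, p = 0.5 + 1e-9)
    expect_setequal(as.character(names(bp)),
                    as.character(names(bipartitions(ac))))
  }
})

test_that("quartet score counts matching resolved quartets", {
  t5 <- parse_newick("((A,B),(C,D),E);")
  expect_equal(quartet_score(t5, rep(list(t5), 3)), 3 * choose(5, 4))
  # single-quartet case: candidate AB|CD vs {AB|CD, AB|CD, AC|BD}
  q1 <- parse_newick("((A,B),(C,D));")
  q2 <- parse_newick("((A,C),(B,D));")
  expect_equal(quartet_score(q1, list(q1, q1, q2)), 2)
  # star gene tree contributes nothing
  expect_equal(quartet_score(q1, list(parse_newick("(A,B,C,D);"))), 0)
  # cross-check against the split-membership oracle on random inputs
  labels <- paste0("t", 1:7)
  for (seed in 1:10) {
    cand <- random_topology(labels, seed)
    gts <- lapply(1:3, function(i) random_topology(labels, seed * 7 + i))
    expect_equal(quartet_score(cand, gts), oracle_quartet_score(cand, gts))
  }
})

test_that("exact supertree equals the exhaustive enumeration oracle", {
  # all gene trees equal: that topology, score = #trees * C(n,4)
  t6 <- random_topology(paste0("g", 1:6), 1)
  st <- quartet_supertree(rep(list(t6), 4))
  expect_equal(attr(st, "mode"), "exact")
  expect_equal(attr(st, "score"), 4 * choose(6, 4))
  expect_equal(rf_distance(st, t6)$rf, 0)
  # majority quartet wins
  q1 <- parse_newick("((A,B),(C,D));")
  q2 <- parse_newick("((A,C),(B,D));")
  st2 <- quartet_supertree(list(q1, q1, q2))
  expect_equal(rf_distance(st2, q1)$rf, 0)
  # single gene tree: itself
  st3 <- quartet_supertree(list(t6))
  expect_equal(rf_distance(st3, t6)$rf, 0)
  # random inputs vs oracle: same maximal score; same topology when unique
  for (seed in 1:6) {
    n <- withr::with_seed(seed, sample(5:7, 1))
    labels <- paste0("t", seq_len(n))
    gts <- lapply(1:3, function(i) random_topology(labels, seed * 31 + i))
    st <- quartet_supertree(gts)
    orc <- oracle_supertree(gts)
    expect_equal(attr(st, "score"), orc$score)
    if (length(orc$trees) == 1)
      expect_equal(rf_distance(st, orc$trees[[1]])$rf, 0)
  }
})

test_that("greedy supertree mode finds the planted topology on clean input", {
  tr <- random_topology(paste0("g", 1:10), 3)
  st <- quartet_supertree(rep(list(tr), 3), exact_max_n = 8, seed = 5)
  expect_equal(attr(st, "mode"), "greedy")
  expect_equal(rf_distance(st, tr)$rf, 0)
  expect_equal(attr(st, "score"), 3 * choose(10, 4))
})

test_that("hgt_candidates recovers planted single and double leaf transfers", {
  # identical trees: no candidates
  tr <- random_topology(paste0("s", 1:8), 2)
  rep0 <- hgt_candidates(tr, tr)
  expect_equal(length(rep0$candidates), 0)
  expect_equal(rep0$initial_rf, 0)

  # single planted leaf SPR recovered exactly, residual 0
  for (seed in 1:20) {
    n <- withr::with_seed(seed, sample(8:16, 1))
    sp <- simulate_yule_tree(n, seed = seed)
    mv <- apply_spr_transfers(sp, 1, seed = seed + 500, leaf_only = TRUE)
    rep1 <- hgt_candidates(mv$tree, sp)
    expect_true(mv$log$pruned %in% rep1$candidates, label = seed)
    expect_equal(rep1$residual_rf, 0, label = seed)
  }

  # two independent transfers: both leaves reported
  sp <- simulate_yule_tree(12, seed = 77)
  mv2 <- apply_spr_transfers(sp, 2, seed = 78, leaf_only = TRUE)
  moved <- unique(mv2$log$pruned)
  rep2 <- hgt_candidates(mv2$tree, sp)
  expect_true(all(moved %in% rep2$candidates))

  # RF never increases along the removal sequence
  expect_true(all(rep2$removals$rf_after <= rep2$removals$rf_before))
})

test_that("cluster labels go to the nearest reference with tie-breaking", {
  D <- matrix(c(0, 0.4, 1.2,
                0.4, 0, 0.9,
                1.2, 0.9, 0), 3, 3,
              dimnames = list(c("q", "refI", "refII"), c("q", "refI", "refII")))
  refs <- tibble::tibble(ref_id = c("refI", "refII"), cluster = c("I", "II"))
  out <- assign_cluster("q", D, refs)
  expect_equal(out$cluster, "I")
  expect_equal(out$distance, 0.4)
  # distance 0 to a reference assigns its cluster
  D2 <- D; D2["q", "refII"] <- D2["refII", "q"] <- 0
  expect_equal(assign_cluster("q", D2, refs)$cluster, "II")
  # exact tie: alphabetically first reference wins
  D3 <- D; D3["q", "refII"] <- D3["refII", "q"] <- 0.4
  expect_equal(assign_cluster("q", D3, refs)$ref_id, "refI")
  expect_error(assign_cluster("q", D[1, 1, drop = FALSE],
                              refs), "no reference")
})

test_that("queries from a planted clade are assigned that clade's label", {
  # evolve sequences within two deep clades; references one per clade
  sp <- parse_newick("((r1:0.05,(q1:0.05,q2:0.05):0.02):0.6,(r2:0.05,(q3:0.05,q4:0.05):0.02):0.6);")
  seqs <- evolve_sequences(sp, 1000, seed = 9)
  D <- distance_matrix(seqs)
  refs <- tibble::tibble(ref_id = c("r1", "r2"), cluster = c("II", "III"))
  out <- assign_cluster(c("q1", "q2", "q3", "q4"), D, refs)
  expect_equal(out$cluster, c("II", "II", "III", "III"))
})
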