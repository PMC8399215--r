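test_that("pairwise alignment of identical and simple sequences", {
  pa <- pairwise_align("AAA", "AAA")
  expect_equal(pa$score, 12)  # 3 x BLOSUM62(A,A) = 4
  expect_equal(pa$a, "AAA")
  expect_equal(pa$b, "AAA")

  # self-alignment is gap-free with score = sum of diagonal entries
  s <- "MKTAYIAKQR"
  pa2 <- pairwise_align(s, s)
  b62 <- scoring_scheme()$matrix
  ch <- strsplit(s, "")[[1]]
  expect_equal(pa2$score, sum(b62[cbind(ch, ch)]))
  expect_equal(pa2$a, s)

  # one extra residue costs one gap opening: 3*4 - 10 = 2 (oracle-checked)
  pa3 <- pairwise_align("AAAA", "AAA")
  expect_equal(pa3$score, oracle_align_score("AAAA", "AAA"))
  expect_equal(pa3$score, 2)

  expect_error(pairwise_align("", "AAA"), "non-empty")
  expect_error(pairwise_align("AB1", "AAA"), "invalid")
})

test_that("pairwise score equals brute-force enumeration on short pairs", {
  scheme <- scoring_scheme()
  for (seed in 1:40) {
    pair <- withr::with_seed(seed, {
      lapply(1:2, function(i)
        paste(sample(c("A", "R", "W", "K", "G"), sample(1:7, 1), replace = TRUE),
              collapse = ""))
    })
    got <- pairwise_align(pair[[1]], pair[[2]], scheme)$score
    expect_equal(got, oracle_align_score(pair[[1]], pair[[2]], scheme),
                 label = paste(pair[[1]], pair[[2]]))
  }
})

test_that("alignment score is symmetric in its arguments", {
  for (seed in 1:10) {
    pair <- withr::with_seed(seed, lapply(1:2, function(i)
      paste(sample(c("A", "C", "D", "E", "F"), sample(2:30, 1), replace = TRUE),
            collapse = "")))
    expect_equal(pairwise_align(pair[[1]], pair[[2]])$score,
                 pairwise_align(pair[[2]], pair[[1]])$score)
  }
})

test_that("guide tree puts identical sequences in a cherry", {
  seqs <- c(x = "AAAAAAAAAA", y = "AAAAAAAAAA", z = "WWWWWWWWWW")
  gt <- build_guide_tree(seqs)
  expect_equal(sort(gt$tip.label), c("x", "y", "z"))
  biparts <- ape::prop.part(gt)
  cherry <- sort(gt$tip.label[biparts[[length(biparts)]]])
  expect_equal(cherry, c("x", "y"))
  # two sequences: a single cherry
  expect_equal(length(build_guide_tree(seqs[1:2])$tip.label), 2)
})

test_that("progressive alignment handles identity, insertions, and n = 2", {
  # identical sequences: gap-free, length preserved, any n
  for (n in c(2, 4, 7)) {
    seqs <- setNames(rep("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", n), paste0("s", 1:n))
    a <- progressive_align(seqs)
    expect_equal(a$length, nchar(seqs[[1]]))
    expect_false(any(grepl("-", a$seqs)))
  }

  # a 3-residue insertion in one of five otherwise identical sequences
  base <- "MKTAYIAKQRQISFVKSHFSRQ"
  ins <- paste0(substr(base, 1, 10), "WWW", substr(base, 11, nchar(base)))
  seqs <- c(a = base, b = base, c = ins, d = base, e = base)
  aln <- progressive_align(seqs)
  expect_equal(aln$length, nchar(base) + 3)
  expect_equal(unname(aln$seqs[["c"]]), ins)
  # the other rows gain a single contiguous 3-column gap block near the
  # insertion point (tie-breaking may slide it between identical residues)
  for (r in c("a", "b", "d", "e")) {
    row <- unname(aln$seqs[[r]])
    expect_equal(gsub("-", "", row), base)
    expect_match(row, "^[^-]+---[^-]+$")
  }

  # two sequences reduce to pairwise_align
  pa <- pairwise_align("MKTAYIAK", "MKTAYI")
  a2 <- progressive_align(c(p = "MKTAYIAK", q = "MKTAYI"))
  expect_equal(unname(a2$seqs), c(pa$a, pa$b))

  # row order follows input order
  expect_equal(names(aln$seqs), c("a", "b", "c", "d", "e"))
})

test_that("validate_alignment reports ragged rows, alphabet, all-gap columns", {
  ok <- new_alignment(c(a = "MKT-A", b = "MRTQA"))
  expect_equal(nrow(validate_alignment(ok)), 0)
  v <- validate_alignment(c(a = "MKT", b = "MKTA"))
  expect_true("unequal length" %in% v$check)
  v2 <- validate_alignment(c(a = "MK-A", b = "MR-A"))
  expect_true("all-gap column" %in% v2$check)
  expect_equal(v2$detail[v2$check == "all-gap column"], "3")
  v3 <- validate_alignment(c(a = "----", b = "MKTA"))
  expect_true("all-gap row" %in% v3$check)
})

test_that("concatenation builds the partitioned supermatrix and validates rows", {
  lens <- c(H = 290, D = 492, K = 520, E = 478, N = 455, B = 470)
  genomes <- c("g1", "g2", "g3")
  alns <- lapply(names(lens), function(r) {
    rows <- withr::with_seed(match(r, names(lens)), setNames(vapply(genomes, function(g)
      paste(sample(c("A", "C", "D", "-"), lens[[r]], replace = TRUE), collapse = ""), ""),
      genomes))
    new_alignment(rows, r)
  })
  names(alns) <- names(lens)
  cc <- concatenate(alns)
  expect_equal(cc$length, sum(lens))
  expect_equal(cc$partitions$role, c("H", "D", "K", "E", "N", "B"))
  expect_equal(cc$partitions$start[1], 0L)
  expect_equal(cc$partitions$end[1], 290L)

  # residue conservation per genome
  for (g in genomes) {
    n_res <- sum(vapply(alns, function(a)
      nchar(gsub("-", "", a$seqs[[g]])), 0))
    expect_equal(nchar(gsub("-", "", cc$seqs[[g]])), n_res)
  }

  # de-concatenation recovers the per-role alignments exactly
  back <- deconcatenate(cc)
  for (r in names(lens))
    expect_equal(back[[r]]$seqs[sort(genomes)], alns[[r]]$seqs[sort(genomes)])

  # single genome still concatenates
  one <- lapply(alns, function(a) new_alignment(a$seqs["g1"], a$role))
  expect_equal(concatenate(one)$length, sum(lens))

  # a genome missing from one role alignment is an error naming both
  broken <- alns
  broken$B <- new_alignment(broken$B$seqs[c("g1", "g2")], "B")
  expect_error(concatenate(broken), "B.*g3")
})
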