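# helpers to build small annotation fixtures in code
mk_gene <- function(symbol, start, aa, contig = "c1", pid = NULL) {
  tibble::tibble(symbol = symbol, contig = contig, start = as.integer(start),
                 end = as.integer(start + 3 * aa - 1), strand = "+",
                 protein_id = pid %||% paste0(symbol, "_", start),
                 protein = strrep("A", aa))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

six_roles <- c(H = "nifH", D = "nifD", K = "nifK", E = "nifE", N = "nifN", B = "nifB")
role_aa <- c(H = 290, D = 492, K = 520, E = 460, N = 430, B = 470)

mk_operon_genome <- function(id = "g1", start0 = 10000, gap = 200, drop = character(),
                             extra = NULL, taxon = c(phylum = "P1", genus = "G1")) {
  pos <- start0
  rows <- list()
  for (r in names(six_roles)) {
    if (r %in% drop) next
    rows[[r]] <- mk_gene(six_roles[[r]], pos, role_aa[[r]])
    pos <- pos + 3 * role_aa[[r]] + gap
  }
  genes <- dplyr::bind_rows(c(rows, list(extra)))
  genome_annotation(id, genes, taxon)
}

test_that("find_role_hits matches synonyms case-insensitively and sorts", {
  g <- mk_operon_genome(extra = dplyr::bind_rows(
    mk_gene("NIFH", 500000, 290, pid = "far_h"),
    mk_gene("nifA", 30000, 500)))
  hits <- find_role_hits(g, nif_roles())
  expect_equal(vapply(hits, nrow, 0L),
               c(H = 2L, D = 1L, K = 1L, E = 1L, N = 1L, B = 1L))
  # sorted by coordinate; regulator nifA matches no role
  expect_equal(hits$H$start, sort(hits$H$start))
  expect_false("nifA" %in% unlist(lapply(hits, `[[`, "symbol")))
})

test_that("fusion calls follow the length rule and partner-proximity veto", {
  rs <- nif_roles()
  # single 890-aa nifE, no nifN anywhere: fused EN (890 >= 0.7 * 890)
  g <- mk_operon_genome(drop = c("E", "N"),
                        extra = mk_gene("nifE", 200000, 890, pid = "fusEN"))
  f <- detect_fusions(find_role_hits(g, rs), rs)
  expect_equal(f$pair, "EN")
  expect_equal(f$protein_id, "fusEN")

  # separate full-length E and N nearby: no fusion
  g2 <- mk_operon_genome()
  expect_equal(nrow(detect_fusions(find_role_hits(g2, rs), rs)), 0)

  # 500-aa nifE with no nifN: below 0.7*(460+430)=623, no fusion, N missing
  g3 <- mk_operon_genome(drop = c("E", "N"),
                         extra = mk_gene("nifE", 200000, 500))
  f3 <- detect_fusions(find_role_hits(g3, rs), rs)
  expect_equal(nrow(f3), 0)
  cp3 <- resolve_complement(g3)
  expect_equal(cp3$status, "incomplete")
  expect_true("N" %in% cp3$missing_roles)

  # a record passing the length rule for both EN and NB is ambiguous
  g4 <- mk_operon_genome(drop = c("E", "N", "B"),
                         extra = mk_gene("nifN", 200000, 900, pid = "amb"))
  expect_error(detect_fusions(find_role_hits(g4, rs), rs), "amb")
})

test_that("fused records fill both roles and the complement is complete", {
  g <- mk_operon_genome(drop = c("E", "N"),
                        extra = mk_gene("nifE", 14000, 890, pid = "fusEN"))
  cp <- resolve_complement(g)
  expect_equal(cp$status, "complete")
  expect_equal(cp$fusion_flags, "EN")
  expect_equal(cp$chosen$protein_id[cp$chosen$role == "E"], "fusEN")
  expect_equal(cp$chosen$protein_id[cp$chosen$role == "N"], "fusEN")
})

test_that("paralogs resolve to the in-neighborhood copy by minimal span", {
  near <- mk_gene("nifH", 10000, 290, pid = "near")
  g <- mk_operon_genome(drop = "H",
                        extra = dplyr::bind_rows(near, mk_gene("nifH", 510000, 290, pid = "far")))
  cp <- resolve_complement(g)
  expect_equal(cp$status, "complete")
  expect_equal(cp$chosen$protein_id[cp$chosen$role == "H"], "near")

  # exhaustive oracle over both combinations agrees
  hits <- find_role_hits(g, nif_roles())
  spans <- vapply(c("near", "far"), function(pid) {
    rows <- dplyr::bind_rows(lapply(names(six_roles), function(r) {
      h <- hits[[r]]
      if (r == "H") h[h$protein_id == pid, ] else h
    }))
    max(rows$end) - min(rows$start)
  }, 0)
  expect_equal(unname(cp$span_bp), unname(min(spans)))
})

test_that("missing roles and cross-contig operons are incomplete", {
  g <- mk_operon_genome(drop = "B")
  cp <- resolve_complement(g)
  expect_equal(cp$status, "incomplete")
  expect_equal(cp$missing_roles, "B")

  # operon split over two contigs rejected under require_same_contig
  g2 <- mk_operon_genome()
  genes <- g2$genes
  genes$contig[genes$symbol == "nifB"] <- "c2"
  g2 <- genome_annotation("g1", genes, g2$taxon)
  cp2 <- resolve_complement(g2)
  expect_equal(cp2$status, "incomplete")
  expect_equal(cp2$reason, "cross_contig")
  # but allowed (with summed per-contig span) when the flag is off
  cp3 <- resolve_complement(g2, params = screen_params(require_same_contig = FALSE))
  expect_equal(cp3$status, "complete")
})

test_that("removing any one role from a complete genome flips the status", {
  for (r in names(six_roles)) {
    g <- mk_operon_genome(drop = r)
    expect_equal(resolve_complement(g)$status, "incomplete", label = r)
  }
})

test_that("greedy fallback agrees with exhaustive search on small instances", {
  for (seed in 1:15) {
    extra <- withr::with_seed(seed, {
      n_extra <- sample(1:3, 1)
      dplyr::bind_rows(lapply(seq_len(n_extra), function(i) {
        r <- sample(names(six_roles), 1)
        mk_gene(six_roles[[r]], sample(c(40000, 300000, 600000), 1) + i * 7000,
                role_aa[[r]], pid = paste0("x", i))
      }))
    })
    g <- mk_operon_genome(extra = extra)
    exact <- resolve_complement(g, params = screen_params())
    greedy <- resolve_complement(g, params = screen_params(combination_cap = 1))
    expect_true(greedy$span_bp >= exact$span_bp - 1e-9)
    expect_equal(exact$status, "complete")
    # with a unique co-located cluster the greedy answer is the exact one
    expect_equal(greedy$chosen$protein_id, exact$chosen$protein_id)
  }
})

test_that("screen_genomes matches planted truth and is deterministic", {
  fx <- generate_genome_fixtures(n_genomes = 10, fraction_incomplete = 0.3,
                                 fraction_fused_en = 0.2, fraction_fused_nb = 0,
                                 seed = 5)
  tab <- screen_genomes(fx$genomes)
  truth <- fx$truth[order(fx$truth$genome_id), ]
  expect_equal(sum(tab$status == "incomplete"), 3)
  expect_equal(sum(tab$fusion_flags == "EN"), 2)
  expect_equal(tab$status, truth$status)
  expect_equal(tab$fusion_flags, truth$fused)
  comp <- tab$status == "complete"
  for (r in names(six_roles))
    expect_equal(tab[[paste0("pid_", r)]][comp], truth[[paste0("pid_", r)]][comp])

  # byte-for-byte determinism of the report
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_complements(tab, f1)
  write_complements(screen_genomes(fx$genomes), f2)
  expect_identical(readLines(f1), readLines(f2))

  # summaries count complete genomes per taxon
  expect_equal(sum(attr(tab, "by_phylum")$n_complete), sum(comp))

  # duplicate genome ids rejected
  expect_error(screen_genomes(c(fx$genomes, fx$genomes[1])), "duplicate")
  # empty input: empty table
  expect_equal(nrow(screen_genomes(list())), 0)
})
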