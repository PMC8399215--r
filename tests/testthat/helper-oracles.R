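# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: alignment scores come from exhaustive path
# enumeration, quartet topologies from ape::prop.part splits, topology
# enumeration from phangorn::allTrees, RF cross-checks from phangorn.

# best global-alignment score by exhaustive enumeration of every gapped
# path (gap run of length L costs open + ext*(L-1)); exponential, for
# sequences of length <= 7 only
oracle_align_score <- function(a, b, scheme = nifphylo::scoring_scheme()) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- scheme$matrix
  open <- scheme$gap_open
  ext <- scheme$gap_extend
  rec <- function(i, j, prev) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, m[A[i], B[j]] + rec(i + 1, j + 1, 0L))
    if (i <= length(A))
      best <- max(best, -(if (prev == 1L) ext else open) + rec(i + 1, j, 1L))
    if (j <= length(B))
      best <- max(best, -(if (prev == 2L) ext else open) + rec(i, j + 1, 2L))
    best
  }
  rec(1L, 1L, 0L)
}

# quartet topology from the split set of a tree: 1 = ab|cd, 2 = ac|bd,
# 3 = ad|bc, 0 = unresolved; membership tested against ape::prop.part
oracle_split_membership <- function(tree) {
  tr <- ape::unroot(tree)
  pp <- ape::prop.part(tr)
  tips <- tr$tip.label
  memb <- matrix(FALSE, length(pp), length(tips), dimnames = list(NULL, tips))
  for (k in seq_along(pp)) memb[k, tips[pp[[k]]]] <- TRUE
  memb[-1, , drop = FALSE]  # drop the all-tips pseudo-root entry
}

oracle_quartet_topology <- function(memb, q) {
  if (nrow(memb) == 0) return(0L)
  s <- memb[, q, drop = FALSE]
  rs <- rowSums(s)
  for (k in which(rs == 2)) {
    inside <- q[s[k, ]]
    if (setequal(inside, q[1:2]) || setequal(inside, q[3:4])) return(1L)
    if (setequal(inside, q[c(1, 3)]) || setequal(inside, q[c(2, 4)])) return(2L)
    return(3L)
  }
  0L
}

# vectorised variant: topology (1/2/3/0) per quartet column of `qt`
oracle_quartet_topologies <- function(memb, qt) {
  m <- ncol(qt)
  if (nrow(memb) == 0) return(integer(m))
  M <- matrix(memb[, as.vector(qt)], nrow = nrow(memb))
  A1 <- M[, seq(1, 4 * m, 4), drop = FALSE]
  A2 <- M[, seq(2, 4 * m, 4), drop = FALSE]
  A3 <- M[, seq(3, 4 * m, 4), drop = FALSE]
  A4 <- M[, seq(4, 4 * m, 4), drop = FALSE]
  cnt <- A1 + A2 + A3 + A4
  code <- A1 * 8 + A2 * 4 + A3 * 2 + A4
  topo_map <- integer(15)
  topo_map[c(12, 3)] <- 1L; topo_map[c(10, 5)] <- 2L; topo_map[c(9, 6)] <- 3L
  out <- integer(m)
  for (q in seq_len(m)) {
    hit <- which(cnt[, q] == 2)
    if (length(hit)) out[q] <- topo_map[code[hit[1], q]]
  }
  out
}

oracle_quartet_score <- function(candidate, gene_trees) {
  mc <- oracle_split_membership(candidate)
  total <- 0L
  for (g in gene_trees) {
    tips <- sort(g$tip.label)
    if (length(tips) < 4) next
    qt <- combn(tips, 4)
    tg <- oracle_quartet_topologies(oracle_split_membership(g), qt)
    tc <- oracle_quartet_topologies(mc, qt)
    total <- total + sum(tg != 0L & tg == tc)
  }
  total
}

# exhaustive supertree search over phangorn::allTrees; gene-tree quartet
# topologies are computed once, candidates scored against them
oracle_supertree <- function(gene_trees) {
  leaves <- sort(unique(unlist(lapply(gene_trees, function(t) t$tip.label))))
  pre <- lapply(gene_trees, function(g) {
    tips <- sort(g$tip.label)
    if (length(tips) < 4) return(NULL)
    qt <- combn(tips, 4)
    list(qt = qt, tg = oracle_quartet_topologies(oracle_split_membership(g), qt))
  })
  pre <- Filter(Negate(is.null), pre)
  all_t <- phangorn::allTrees(length(leaves), rooted = FALSE, tip.label = leaves)
  scores <- vapply(all_t, function(cand) {
    mc <- oracle_split_membership(cand)
    tot <- 0L
    for (p in pre) {
      tc <- oracle_quartet_topologies(mc, p$qt)
      tot <- tot + sum(p$tg != 0L & p$tg == tc)
    }
    tot
  }, 0L)
  list(score = max(scores), trees = all_t[scores == max(scores)])
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# random unrooted binary topology without branch lengths, fixed labels
random_topology <- function(labels, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(length(labels), rooted = FALSE)
    tr$tip.label <- sample(labels)
    tr$edge.length <- NULL
    tr
  })
}

expect_same_topology <- function(t1, t2) {
  expect_identical(write_newick(strip_lengths(t1)), write_newick(strip_lengths(t2)))
}

strip_lengths <- function(tr) {
  tr$edge.length <- NULL
  tr$node.label <- NULL
  tr
}
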