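# Tree comparison: bipartitions, Robinson-Foulds, majority-rule consensus,
# quartet-score supertree search, HGT candidate detection, cluster labels.

# canonical key of the bipartition separating `side` from the rest of
# `universe`: the smaller side (ties: lexicographically smaller sorted
# label string), labels sorted and comma-joined
#' @noRd
bipartition_key <- function(side, universe) {
  side <- sort(side, method = "radix")
  other <- sort(setdiff(universe, side), method = "radix")
  ks <- paste(side, collapse = ",")
  ko <- paste(other, collapse = ",")
  if (length(side) < length(other)) return(ks)
  if (length(other) < length(side)) return(ko)
  if (ks <= ko) ks else ko
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' One bipartition per internal edge after unrooting; trivial splits (a
#' single leaf against the rest) are excluded. Each split is keyed by its
#' canonical smaller side.
#'
#' @param tree A `phylo`.
#' @return Named list of leaf-label vectors (the canonical side per split);
#'   names are canonical keys. Attribute `universe` holds the leaf set.
#' @export
bipartitions <- function(tree) {
  tr <- ape::unroot(tree)
  tips <- tr$tip.label
  n <- length(tips)
  out <- list()
  if (n >= 4 && tr$Nnode >= 2) {
    pp <- ape::prop.part(tr)
    # prop.part entry 1 is the pseudo-root (all tips); others are internal nodes
    for (k in seq_along(pp)[-1]) {
      side <- tips[pp[[k]]]
      if (length(side) <= 1 || length(side) >= n - 1) next
      key <- bipartition_key(side, tips)
      out[[key]] <- sort(if (paste(sort(side), collapse = ",") == key) side
                         else setdiff(tips, side))
    }
  }
  if (length(out))
    out <- out[order(names(out), method = "radix")]
  structure(out, universe = sort(tips))
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the nontrivial bipartition sets.
#' `normalized` divides by `2(n-3)`, the maximum for two binary n-leaf
#' trees. Both trees must be on the same leaf set; restrict them first
#' (e.g. with [ape::keep.tip()]) if they differ.
#'
#' @param t1,t2 `phylo` trees on identical leaf sets.
#' @return List with `rf` (integer) and `normalized` (real in `[0,1]`).
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  assert_that(identical(l1, l2),
    "trees have different leaf sets; restrict both to the shared leaves first")
  b1 <- names(bipartitions(t1)); b2 <- names(bipartitions(t2))
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  n <- length(l1)
  norm <- if (n > 3) rf / (2 * (n - 3)) else 0
  list(rf = as.integer(rf), normalized = norm)
}

#' Majority-rule consensus of trees
#'
#' Retains exactly the bipartitions present in a strict majority (> 50%) of
#' the input trees; such splits are always pairwise compatible, so they nest
#' into a (possibly polytomous) tree. Clade support values (occurrence
#' frequencies) are stored as internal node labels.
#'
#' @param trees List of `phylo` trees on one shared leaf set.
#' @return A `phylo` tree; internal `node.label` holds the support
#'   frequencies (6 digits).
#' @export
majority_consensus <- function(trees) {
  assert_that(length(trees) >= 1, "need at least one tree")
  tips <- sort(trees[[1]]$tip.label)
  for (t in trees)
    assert_that(identical(sort(t$tip.label), tips), "trees must share one leaf set")
  k <- length(trees)
  splits <- lapply(trees, bipartitions)
  keys <- unlist(lapply(splits, names))
  tab <- table(keys)
  keep <- names(tab)[tab / k > 0.5]
  freq <- as.numeric(tab[keep]) / k
  # clades relative to a reference leaf: the side NOT containing it
  ref <- tips[1]
  clades <- lapply(keep, function(key) {
    side <- NULL
    for (s in splits) if (key %in% names(s)) { side <- s[[key]]; break }
    if (ref %in% side) sort(setdiff(tips, side)) else sort(side)
  })
  ord <- order(vapply(clades, length, 0L), decreasing = TRUE)
  clades <- clades[ord]; freq <- freq[ord]

  build <- function(members, idx) {
    # idx: clade indices strictly inside `members`; maximal ones become children
    inside <- idx[vapply(idx, function(i)
      all(clades[[i]] %in% members) && length(clades[[i]]) < length(members), FALSE)]
    maximal <- inside[vapply(inside, function(i)
      !any(vapply(inside, function(j)
        j != i && all(clades[[i]] %in% clades[[j]]) &&
          length(clades[[j]]) > length(clades[[i]]), FALSE)), FALSE)]
    covered <- unique(unlist(clades[maximal]))
    loose <- setdiff(members, covered)
    parts <- c(
      vapply(sort(loose, method = "radix"), identity, ""),
      vapply(maximal, function(i)
        paste0(build(clades[[i]], setdiff(inside, i)), format_brlen(freq[i], 6L)), ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(build(tips, seq_along(clades)), ";")
  parse_newick(nwk)
}

# ---- quartet machinery ----------------------------------------------------

# tip-to-tip topological distances (every edge length 1) via BFS on the
# unrooted adjacency; own implementation, independent of edge ordering
#' @noRd
tip_distances <- function(tree) {
  tr <- ape::unroot(tree)
  n <- length(tr$tip.label)
  nn <- n + tr$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tr$edge))) {
    a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  D <- matrix(NA_real_, n, n, dimnames = list(tr$tip.label, tr$tip.label))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, nn)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    D[s, ] <- dist[seq_len(n)]
  }
  D
}

# resolve quartet topologies by the four-point condition on (topological)
# tree distances: for leaves (a,b,c,d) the true pairing has the strictly
# smallest pairwise-sum; equal sums (polytomy) -> unresolved (0)
# quartets: 4 x m character matrix of leaf labels
#' @noRd
quartet_topologies <- function(D, quartets) {
  a <- quartets[1, ]; b <- quartets[2, ]; c3 <- quartets[3, ]; d <- quartets[4, ]
  s1 <- D[cbind(a, b)] + D[cbind(c3, d)]
  s2 <- D[cbind(a, c3)] + D[cbind(b, d)]
  s3 <- D[cbind(a, d)] + D[cbind(b, c3)]
  topo <- integer(length(s1))
  topo[s1 < s2 & s1 < s3] <- 1L
  topo[s2 < s1 & s2 < s3] <- 2L
  topo[s3 < s1 & s3 < s2] <- 3L
  topo
}

#' Quartet score of a candidate tree against gene trees
#'
#' Sum over gene trees of the number of 4-leaf subsets whose induced
#' unrooted quartet topology matches between the candidate and the gene
#' tree. This is the objective maximised by quartet-based species-tree
#' estimation. Quartets left unresolved by a polytomy (in either tree)
#' count as non-matching.
#'
#' @param candidate A `phylo`; its leaves must cover every gene tree.
#' @param gene_trees List of `phylo` trees with leaves `subset of`
#'   candidate leaves.
#' @return Integer score.
#' @export
quartet_score <- function(candidate, gene_trees) {
  quartet_scorer(gene_trees)(candidate)
}

# precompute each gene tree's quartet list and topology vector once and
# return a fast closure scoring any candidate against them
#' @noRd
quartet_scorer <- function(gene_trees) {
  pre <- Filter(Negate(is.null), lapply(gene_trees, function(g) {
    tips <- sort(g$tip.label)
    if (length(tips) < 4) return(NULL)
    qt <- combn(tips, 4)
    list(qt = qt, tg = quartet_topologies(tip_distances(g), qt), tips = tips)
  }))
  function(candidate) {
    if (!length(pre)) return(0L)
    Dc <- tip_distances(candidate)
    total <- 0L
    for (p in pre) {
      assert_that(all(p$tips %in% candidate$tip.label),
                  "gene-tree leaves must be a subset of the candidate's")
      tc <- quartet_topologies(Dc, p$qt)
      total <- total + sum(p$tg != 0L & p$tg == tc)
    }
    as.integer(total)
  }
}

# insert a new tip in the middle of edge e of a (topology-only) phylo;
# own edge surgery with deterministic renumbering
#' @noRd
insert_tip <- function(tree, e, label) {
  t <- length(tree$tip.label)
  m <- tree$Nnode
  f <- function(x) ifelse(x <= t, x, x + 1L)  # old id -> new id
  E <- matrix(as.integer(f(tree$edge)), ncol = 2)
  w <- t + m + 2L                              # the new internal node
  p <- E[e, 1]; child <- E[e, 2]
  E[e, ] <- c(p, w)
  E <- rbind(E, c(w, child), c(w, t + 1L))
  out <- list(edge = E, tip.label = c(tree$tip.label, label),
              Nnode = m + 1L)
  class(out) <- "phylo"
  out
}

# all unrooted binary topologies on the given sorted leaves, built by
# stepwise insertion ((2n-5)!! trees)
#' @noRd
enumerate_topologies <- function(leaves) {
  leaves <- sort(leaves, method = "radix")
  n <- length(leaves)
  assert_that(n >= 3, "need at least three leaves")
  base <- parse_newick(paste0("(", paste(leaves[1:3], collapse = ","), ");"))
  trees <- list(base)
  for (k in seq_len(n)[-(1:3)]) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edge)), function(e) insert_tip(tr, e, leaves[k]))
    }), recursive = FALSE)
  }
  trees
}

#' Quartet-score supertree from gene trees
#'
#' Combines gene trees into a single tree maximising the quartet score. For
#' up to `exact_max_n` leaves every unrooted binary topology is scored
#' exhaustively and a global maximiser returned (score ties resolved to the
#' canonically smallest Newick string). For larger leaf sets a greedy
#' stepwise insertion (leaf order randomised from `seed`) followed by NNI
#' hill-climbing returns a local optimum.
#'
#' @param gene_trees List of `phylo` trees; the supertree is on the union of
#'   their leaves.
#' @param exact_max_n Largest leaf count for exhaustive search.
#' @param seed Integer seed for the greedy insertion order.
#' @return A `phylo` tree with attributes `score` (its quartet score) and
#'   `mode` (`"exact"` or `"greedy"`).
#' @export
quartet_supertree <- function(gene_trees, exact_max_n = 8L, seed = 1L) {
  assert_that(length(gene_trees) >= 1, "need at least one gene tree")
  leaves <- sort(unique(unlist(lapply(gene_trees, function(t) t$tip.label))),
                 method = "radix")
  n <- length(leaves)
  assert_that(n >= 4, "supertree needs at least four leaves")
  score_of <- quartet_scorer(gene_trees)

  if (n <= exact_max_n) {
    cands <- enumerate_topologies(leaves)
    scores <- vapply(cands, score_of, 0L)
    best <- which(scores == max(scores))
    if (length(best) > 1) {
      nwk <- vapply(cands[best], write_newick, "")
      best <- best[order(nwk, method = "radix")[1]]
    }
    out <- cands[[best[1]]]
    return(structure(out, score = max(scores), mode = "exact"))
  }

  ord <- with_seed(seed, sample(leaves))
  cur <- parse_newick(paste0("(", paste(sort(ord[1:3]), collapse = ","), ");"))
  for (k in 4:n) {
    cands <- lapply(seq_len(nrow(cur$edge)), insert_tip, tree = cur, label = ord[k])
    sub_gt <- lapply(gene_trees, function(g) {
      keep <- intersect(g$tip.label, ord[1:k])
      if (length(keep) >= 4 && length(keep) < length(g$tip.label))
        ape::keep.tip(g, keep)
      else if (length(keep) == length(g$tip.label)) g else NULL
    })
    sub_gt <- Filter(Negate(is.null), sub_gt)
    step_score <- quartet_scorer(sub_gt)
    sc <- vapply(cands, step_score, 0L)
    cur <- cands[[which.max(sc)]]
  }
  cur_score <- score_of(cur)
  repeat {
    nbrs <- tryCatch(phangorn::nni(cur), error = function(e) list())
    if (!length(nbrs)) break
    sc <- vapply(nbrs, score_of, 0L)
    if (max(sc) <= cur_score) break
    cur <- nbrs[[which.max(sc)]]
    cur_score <- max(sc)
  }
  structure(cur, score = cur_score, mode = "greedy")
}

# ---- HGT detection --------------------------------------------------------

#' Horizontal-transfer candidates from gene/species tree discordance
#'
#' Formalises tanglegram reading: both trees are restricted to their shared
#' leaves, then the leaf whose removal (from both trees) most reduces the
#' Robinson-Foulds distance is greedily pruned (alphabetical tie-break)
#' until the trees agree, `max_removals` is reached, or no removal helps.
#' Pruned leaves, in removal order, are the transfer candidates. Pruning
#' stops when fewer than five leaves remain (RF on < 4 leaves is trivially
#' zero).
#'
#' @param gene_tree,species_tree `phylo` trees (leaf sets are intersected).
#' @param max_removals Cap on the number of pruned leaves.
#' @return An `hgt_report`: list with `candidates` (pruned leaves plus any
#'   leaves tied with them at their removal step — equally reconciling
#'   leaves are indistinguishable discordance drivers), `removals` (tibble
#'   of leaf, rf_before, rf_after, tied), `initial_rf`,
#'   `initial_normalized`, `residual_rf`, `shared_leaves`,
#'   `dropped_unshared`.
#' @export
hgt_candidates <- function(gene_tree, species_tree, max_removals = 5L) {
  shared <- sort(intersect(gene_tree$tip.label, species_tree$tip.label))
  dropped <- sort(setdiff(union(gene_tree$tip.label, species_tree$tip.label), shared))
  assert_that(length(shared) >= 4, "need at least four shared leaves")
  gt <- ape::keep.tip(gene_tree, shared)
  st <- ape::keep.tip(species_tree, shared)
  rf0 <- rf_distance(gt, st)
  removals <- list()
  cands <- character()
  cur <- rf0$rf
  while (cur > 0 && length(removals) < max_removals &&
         length(gt$tip.label) >= 5) {
    leaves <- sort(gt$tip.label)
    after <- vapply(leaves, function(l)
      rf_distance(ape::drop.tip(gt, l), ape::drop.tip(st, l))$rf, 0L)
    if (min(after) >= cur) break
    tied <- leaves[after == min(after)]
    pick <- tied[1]  # leaves are sorted, so ties resolve alphabetically
    removals[[length(removals) + 1L]] <-
      tibble(leaf = pick, rf_before = as.integer(cur),
             rf_after = as.integer(after[[pick]]),
             tied = paste(tied, collapse = ","))
    cands <- unique(c(cands, tied))
    gt <- ape::drop.tip(gt, pick)
    st <- ape::drop.tip(st, pick)
    cur <- after[[pick]]
  }
  removals <- if (length(removals)) dplyr::bind_rows(removals) else
    tibble(leaf = character(), rf_before = integer(), rf_after = integer(),
           tied = character())
  structure(list(candidates = cands, removals = removals,
                 initial_rf = rf0$rf, initial_normalized = rf0$normalized,
                 residual_rf = as.integer(cur), shared_leaves = shared,
                 dropped_unshared = dropped),
            class = "hgt_report")
}

#' @export
print.hgt_report <- function(x, ...) {
  cat("<hgt_report> initial RF ", x$initial_rf,
      " (normalized ", format_brlen(x$initial_normalized, 4L), "), residual ",
      x$residual_rf, "\n", sep = "")
  if (length(x$candidates))
    cat("candidates:", paste(x$candidates, collapse = ", "), "\n")
  else cat("no transfer candidates\n")
  invisible(x)
}

#' Assign nitrogenase cluster labels by nearest reference
#'
#' Labels a query taxon with the cluster (sensu the classical nitrogenase
#' phylogroups I / II / III and their subclusters) of the reference sequence
#' at minimal Kimura distance, breaking ties alphabetically by reference id.
#'
#' @param query_ids Character vector of query taxa present in `D`.
#' @param D Distance matrix containing queries and references.
#' @param refs Tibble or data.frame with columns `ref_id`, `cluster` (or a
#'   named character vector ref_id -> cluster).
#' @return Tibble with `query_id`, `cluster`, `ref_id`, `distance`.
#' @export
assign_cluster <- function(query_ids, D, refs) {
  if (is.character(refs) && !is.null(names(refs)))
    refs <- tibble(ref_id = names(refs), cluster = unname(refs))
  refs <- as_tibble(refs)
  present <- refs$ref_id[refs$ref_id %in% rownames(D)]
  assert_that(length(present) >= 1, "no reference taxa present in the distance matrix")
  refs <- refs[match(present, refs$ref_id), ]
  refs <- refs[order(refs$ref_id, method = "radix"), ]
  dplyr::bind_rows(lapply(query_ids, function(q) {
    assert_that(q %in% rownames(D), paste0("query not in distance matrix: ", q))
    d <- D[q, refs$ref_id]
    i <- which.min(d)  # refs sorted by id, so ties resolve alphabetically
    tibble(query_id = q, cluster = refs$cluster[i],
           ref_id = refs$ref_id[i], distance = unname(d[i]))
  }))
}

#' Tanglegram leaf pairing export
#'
#' Pairs the shared leaves of two trees with their leaf order index in each
#' (for external tanglegram plotting).
#'
#' @param t1,t2 `phylo` trees.
#' @return Tibble with `leaf`, `order_tree1`, `order_tree2`.
#' @export
tanglegram_pairs <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  tibble(leaf = shared,
         order_tree1 = match(shared, t1$tip.label),
         order_tree2 = match(shared, t2$tip.label))
}
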