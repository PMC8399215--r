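# Neighbor joining with deterministic tie-breaking, plus rooting.

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ agglomeration: repeatedly join the pair (i, j) minimising
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j` with `R_i = sum_k d(i,k)`. Branch
#' lengths to the new node are `v_i = d(i,j)/2 + (R_i - R_j)/(2(n-2))`
#' (negatives clamped to 0, no redistribution); distances to the new node
#' are `d(u,k) = (d(i,k) + d(j,k) - d(i,j))/2`. Q-ties are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its smallest leaf). The result is unrooted, with a trifurcating
#' pseudo-root for n >= 3 and a single split edge (d/2 each side) for n = 2.
#'
#' @param D Symmetric distance matrix with unique taxon dimnames (or a
#'   `dist` object).
#' @return An unrooted `phylo` tree.
#' @examples
#' D <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' neighbor_joining(D)
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  labels <- rownames(D)
  assert_that(!is.null(labels) && !anyDuplicated(labels), "D needs unique taxon names")
  n <- nrow(D)
  assert_that(n >= 2, "need at least two taxa")
  assert_that(isTRUE(all.equal(D, t(D))), "D must be symmetric")

  bl <- function(x) format_brlen(max(x, 0), 12L)
  if (n == 2) {
    d <- D[1, 2]
    frags <- paste0(labels, ":", bl(d / 2))
    ord <- order(labels, method = "radix")
    return(parse_newick(paste0("(", paste(frags[ord], collapse = ","), ");")))
  }

  frag <- labels          # newick fragment per active cluster
  key <- labels           # smallest leaf label per cluster (tie-breaking)
  active <- seq_len(n)
  Dm <- D

  while (length(active) > 3) {
    m <- length(active)
    Da <- Dm[active, active, drop = FALSE]
    R <- rowSums(Da)
    Q <- (m - 2) * Da - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= abs(qmin) * 1e-12 + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    kk <- key[active]
    pair_key <- vapply(seq_len(nrow(cand)), function(r) {
      two <- sort(c(kk[cand[r, 1]], kk[cand[r, 2]]))
      paste(two, collapse = "")
    }, "")
    pick <- cand[order(pair_key, method = "radix")[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- Da[i, j]
    vi <- dij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    vj <- dij - vi
    ai <- active[i]; aj <- active[j]
    sub <- c(paste0(frag[ai], ":", bl(vi)), paste0(frag[aj], ":", bl(vj)))
    sub_keys <- c(key[ai], key[aj])
    ord <- order(sub_keys, method = "radix")
    new_frag <- paste0("(", paste(sub[ord], collapse = ","), ")")

    # distances from the new node to every other active cluster
    others <- active[-c(i, j)]
    dnew <- (Dm[ai, others] + Dm[aj, others] - dij) / 2
    u <- nrow(Dm) + 1L
    Dm <- rbind(cbind(Dm, 0), 0)
    Dm[u, others] <- dnew
    Dm[others, u] <- dnew
    frag[u] <- new_frag
    key[u] <- min(sub_keys)
    active <- c(others, u)
  }

  # final three-cluster junction: three-point formula
  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- (Dm[a, b] + Dm[a, c3] - Dm[b, c3]) / 2
  vb <- (Dm[a, b] + Dm[b, c3] - Dm[a, c3]) / 2
  vc <- (Dm[a, c3] + Dm[b, c3] - Dm[a, b]) / 2
  parts <- paste0(frag[c(a, b, c3)], ":", c(bl(va), bl(vb), bl(vc)))
  ord <- order(key[c(a, b, c3)], method = "radix")
  parse_newick(paste0("(", paste(parts[ord], collapse = ","), ");"))
}

#' Root an unrooted tree by outgroup or midpoint
#'
#' Outgroup mode checks that the outgroup is monophyletic under some rooting
#' (i.e. outgroup | rest is a split of the unrooted tree) and roots on the
#' edge separating it from the ingroup. Midpoint mode roots at the midpoint
#' of the longest leaf-to-leaf path. Branch lengths are conserved.
#'
#' @param tree An unrooted `phylo`.
#' @param outgroup Character vector of outgroup leaf labels (outgroup mode).
#' @param midpoint Use midpoint rooting instead.
#' @return A rooted `phylo`.
#' @export
root_tree <- function(tree, outgroup = NULL, midpoint = FALSE) {
  assert_that(!is.null(outgroup) || midpoint,
              "supply an outgroup or midpoint = TRUE")
  if (midpoint) {
    assert_that(!is.null(tree$edge.length), "midpoint rooting needs branch lengths")
    return(phangorn::midpoint(tree))
  }
  tips <- tree$tip.label
  assert_that(all(outgroup %in% tips), "outgroup leaves not all present in tree")
  n <- length(tips)
  og <- sort(outgroup)
  if (length(og) > 1 && length(og) < n - 1) {
    keys <- names(bipartitions(tree))
    og_key <- bipartition_key(og, tips)
    assert_that(og_key %in% keys,
      paste0("outgroup {", paste(og, collapse = ","),
             "} is not monophyletic under any rooting; conflicting with splits: ",
             paste(utils::head(keys, 3), collapse = " ; ")))
  }
  assert_that(length(og) < n, "outgroup cannot contain every leaf")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
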