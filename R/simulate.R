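# Seeded simulators: Yule species trees, SPR transfer events, Poisson
# protein evolution, and annotated genome fixtures with planted truth.

#' Simulate a Yule (pure-birth) species tree
#'
#' Standard Yule process: with k lineages the waiting time to the next
#' split is Exp(k * birth_rate) and a uniformly chosen lineage splits, until
#' n tips exist; tips end at the present after one more waiting time. The
#' ultrametric tree is rescaled so the root-to-tip height equals `height`
#' (expected substitutions/site). Tips are labelled `g0001`, `g0002`, ...
#'
#' @param n Number of leaves (>= 2).
#' @param birth_rate Positive birth rate (shape only; height is rescaled).
#' @param height Root-to-tip height after scaling.
#' @param seed Integer seed (same seed, same Newick).
#' @return A rooted binary ultrametric `phylo`.
#' @export
simulate_yule_tree <- function(n, birth_rate = 1, height = 1, seed = 1L) {
  assert_that(n >= 2, "need n >= 2")
  assert_that(birth_rate > 0 && height > 0, "rates must be positive")
  with_seed(seed, {
    birth <- c(0)          # birth time per lineage id
    children <- list(NULL)
    active <- 1L
    nid <- 1L
    t_now <- 0
    while (length(active) < n) {
      k <- length(active)
      t_now <- t_now + rexp(1, birth_rate * k)
      pick <- if (k == 1) active else active[sample.int(k, 1)]
      a <- nid + 1L; b <- nid + 2L; nid <- nid + 2L
      birth[a] <- birth[b] <- t_now
      children[a] <- list(NULL)
      children[b] <- list(NULL)
      children[[pick]] <- c(a, b)
      active <- c(setdiff(active, pick), a, b)
    }
    t_end <- t_now + rexp(1, birth_rate * n)

    # the tree starts at the first split (the root's own stem is dropped)
    t0 <- birth[children[[1]][1]]
    scale <- height / (t_end - t0)
    leaf_counter <- 0L
    rec <- function(id) {
      if (is.null(children[[id]])) {
        leaf_counter <<- leaf_counter + 1L
        lab <- sprintf("g%04d", leaf_counter)
        return(paste0(lab, ":", format_brlen((t_end - birth[id]) * scale, 10L)))
      }
      kids <- children[[id]]
      len <- (birth[kids[1]] - birth[id]) * scale
      paste0("(", rec(kids[1]), ",", rec(kids[2]), "):", format_brlen(len, 10L))
    }
    kids <- children[[1]]
    nwk <- paste0("(", rec(kids[1]), ",", rec(kids[2]), ");")
    parse_newick(nwk)
  })
}

#' Random binary tree with uniform branch lengths
#'
#' Convenience generator for additive-distance experiments: a random
#' topology ([ape::rtree()]) with i.i.d. uniform branch lengths.
#'
#' @param n Number of leaves.
#' @param bl_range Branch-length range (uniform draw).
#' @param seed Integer seed.
#' @param rooted Keep the tree rooted.
#' @return A `phylo`.
#' @export
random_binary_tree <- function(n, bl_range = c(0.02, 0.3), seed = 1L, rooted = FALSE) {
  with_seed(seed, {
    tr <- ape::rtree(n, rooted = rooted)
    tr$edge.length <- runif(nrow(tr$edge), bl_range[1], bl_range[2])
    tr
  })
}

# ---- SPR moves ------------------------------------------------------------

# phylo <-> nested-list representation (children, per-edge length, label)
#' @noRd
phylo_to_nlist <- function(tree) {
  ntip <- length(tree$tip.label)
  has_len <- !is.null(tree$edge.length)
  rec <- function(node, elen) {
    if (node <= ntip)
      return(list(label = tree$tip.label[node], len = elen, children = NULL))
    eidx <- which(tree$edge[, 1] == node)
    list(label = NULL, len = elen,
         children = lapply(eidx, function(e)
           rec(tree$edge[e, 2], if (has_len) tree$edge.length[e] else NA_real_)))
  }
  rec(ntip + 1L, NA_real_)
}

#' @noRd
nlist_to_newick <- function(node, top = TRUE) {
  s <- if (is.null(node$children)) node$label else
    paste0("(", paste(vapply(node$children, nlist_to_newick, "", top = FALSE),
                      collapse = ","), ")")
  if (!top && !is.na(node$len)) s <- paste0(s, ":", format_brlen(node$len, 10L))
  if (top) paste0(s, ";") else s
}

#' @noRd
nlist_leaves <- function(node) {
  if (is.null(node$children)) return(node$label)
  unlist(lapply(node$children, nlist_leaves))
}

# address every non-root node by its child-index path from the root
#' @noRd
nlist_paths <- function(node, prefix = integer()) {
  out <- if (length(prefix)) list(prefix) else list()
  if (!is.null(node$children))
    for (i in seq_along(node$children))
      out <- c(out, nlist_paths(node$children[[i]], c(prefix, i)))
  out
}

#' @noRd
nlist_get <- function(node, path) {
  for (i in path) node <- node$children[[i]]
  node
}

# remove the node at `path`; a parent left with one child is spliced out
# (its remaining child's edge absorbs the parent edge); if the root itself
# is left with a single internal child, that child becomes the new root
#' @noRd
nlist_prune <- function(node, path, is_root = TRUE) {
  if (length(path) == 1) {
    node$children[[path[1]]] <- NULL
  } else {
    node$children[[path[1]]] <- nlist_prune(node$children[[path[1]]],
                                            path[-1], is_root = FALSE)
  }
  if (length(node$children) == 1) {
    only <- node$children[[1]]
    if (is_root) {
      if (!is.null(only$children)) { only$len <- NA_real_; return(only) }
      return(node)
    }
    only$len <- only$len + node$len
    return(only)
  }
  node
}

# regraft `sub` onto the edge above the node at `path`, splitting it halfway
#' @noRd
nlist_regraft <- function(node, path, sub) {
  if (length(path) == 0) stop("cannot regraft onto the root")
  i <- path[1]
  if (length(path) == 1) {
    target <- node$children[[i]]
    half <- target$len / 2
    target$len <- half
    node$children[[i]] <- list(label = NULL, len = half,
                               children = list(target, sub))
    return(node)
  }
  node$children[[i]] <- nlist_regraft(node$children[[i]], path[-1], sub)
  node
}

#' Plant horizontal transfers by SPR moves
#'
#' Applies `k` sequential subtree-prune-regraft moves to a binary tree:
#' a prune edge and a regraft edge are drawn uniformly (the regraft edge
#' outside the pruned subtree), the pruned subtree keeps its pendant length
#' and is reattached at the midpoint of the regraft edge. Draws whose
#' resulting unrooted topology equals the pre-move topology are rejected
#' and redrawn; if no topology-changing move can be found the function
#' errors. Each accepted move is logged.
#'
#' @param tree Rooted binary `phylo` with >= 4 leaves and branch lengths.
#' @param k Number of transfer events (>= 0).
#' @param seed Integer seed.
#' @param leaf_only Restrict pruning to single leaves (one recipient per
#'   event), the regime used by the transfer-recovery studies.
#' @return List with `tree` (the gene tree) and `log`, a tibble with one
#'   row per move: `move`, `pruned` (comma-joined moved leaves), `from`
#'   (sibling leaves before the move), `to` (leaves below the regraft edge).
#' @export
apply_spr_transfers <- function(tree, k, seed = 1L, leaf_only = FALSE) {
  assert_that(k >= 0, "k must be >= 0")
  assert_that(length(tree$tip.label) >= 4, "tree must have >= 4 leaves")
  log_rows <- list()
  if (k == 0)
    return(list(tree = tree,
                log = tibble(move = integer(), pruned = character(),
                             from = character(), to = character())))
  cur <- tree
  with_seed(seed, {
    for (mv in seq_len(k)) {
      nl <- phylo_to_nlist(cur)
      all_leaves <- sort(nlist_leaves(nl))
      done <- FALSE
      for (attempt in seq_len(200)) {
        paths <- nlist_paths(nl)
        prune_ok <- Filter(function(p) {
          nd <- nlist_get(nl, p)
          lv <- nlist_leaves(nd)
          if (leaf_only && !is.null(nd$children)) return(FALSE)
          length(lv) <= length(all_leaves) - 2
        }, paths)
        pp <- prune_ok[[sample.int(length(prune_ok), 1)]]
        sub <- nlist_get(nl, pp)
        sub_leaves <- nlist_leaves(sub)
        rest <- nlist_prune(nl, pp)
        rpaths <- nlist_paths(rest)
        rp <- rpaths[[sample.int(length(rpaths), 1)]]
        target_leaves <- nlist_leaves(nlist_get(rest, rp))
        cand <- nlist_regraft(rest, rp, sub)
        cand_tree <- parse_newick(nlist_to_newick(cand))
        if (rf_distance(ape::unroot(cand_tree), ape::unroot(cur))$rf > 0) {
          log_rows[[length(log_rows) + 1L]] <- tibble(
            move = mv,
            pruned = paste(sort(sub_leaves), collapse = ","),
            from = paste(sort(setdiff(all_leaves, sub_leaves)), collapse = ","),
            to = paste(sort(target_leaves), collapse = ","))
          cur <- cand_tree
          done <- TRUE
          break
        }
      }
      assert_that(done, "could not find a topology-changing SPR move")
    }
  })
  list(tree = cur, log = dplyr::bind_rows(log_rows))
}

# ---- sequence evolution ---------------------------------------------------

#' Evolve protein sequences along a tree
#'
#' Poisson substitution process over 20 equally exchangeable states with a
#' uniform stationary distribution: along a branch of length d (expected
#' substitutions/site) each site retains its state with probability
#' `P(same) = 1/20 + (19/20) exp(-(20/19) d)` and otherwise switches to a
#' uniformly chosen different residue. The root sequence is uniform per
#' site. Optional discrete-gamma rate heterogeneity multiplies branch
#' lengths per site.
#'
#' @param tree `phylo` with branch lengths.
#' @param L Number of sites (>= 1).
#' @param rate Overall rate multiplier.
#' @param gamma_shape Optional shape alpha for discrete-gamma site rates
#'   (`NULL` = homogeneous, the default).
#' @param gamma_categories Number of discrete-gamma categories.
#' @param seed Integer seed.
#' @return Named character vector: leaf label -> sequence.
#' @export
evolve_sequences <- function(tree, L, rate = 1, gamma_shape = NULL,
                             gamma_categories = 4L, seed = 1L) {
  assert_that(L >= 1, "L must be >= 1")
  assert_that(!is.null(tree$edge.length) && !anyNA(tree$edge.length),
              "every branch needs a length")
  ntip <- length(tree$tip.label)
  with_seed(seed, {
    site_rate <- if (is.null(gamma_shape)) rep(1, L) else {
      cats <- phangorn::discrete.gamma(gamma_shape, gamma_categories)
      sample(cats, L, replace = TRUE)
    }
    out <- vector("list", ntip)
    root_seq <- sample.int(20L, L, replace = TRUE)
    evolve_branch <- function(parent_seq, d) {
      deff <- d * rate * site_rate
      p_change <- (19 / 20) * (1 - exp(-(20 / 19) * deff))
      hit <- runif(L) < p_change
      child <- parent_seq
      if (any(hit))
        child[hit] <- ((parent_seq[hit] - 1L +
                        sample.int(19L, sum(hit), replace = TRUE)) %% 20L) + 1L
      child
    }
    rec <- function(node, s) {
      eidx <- which(tree$edge[, 1] == node)
      for (e in eidx) {
        child <- tree$edge[e, 2]
        cs <- evolve_branch(s, tree$edge.length[e])
        if (child <= ntip) out[[child]] <<- cs else rec(child, cs)
      }
    }
    rec(ntip + 1L, root_seq)
    setNames(vapply(out, function(s) paste(AA20[s], collapse = ""), ""),
             tree$tip.label)
  })
}

#' One seeded transfer-recovery replicate
#'
#' Builds a Yule species tree, plants `k` leaf transfers by SPR to obtain a
#' gene tree, and (optionally) evolves sequences of length `L` along the
#' gene tree — the inputs for a gene-tree/species-tree discordance study
#' with known ground truth.
#'
#' @param n Number of taxa.
#' @param k Number of planted leaf transfers.
#' @param L Sequence length; `0` skips sequence evolution.
#' @param height Species-tree height (substitutions/site).
#' @param seed Integer seed.
#' @return List: `species_tree`, `gene_tree`, `transfer_log`, `moved`
#'   (planted leaf labels), `sequences` (`NULL` when `L = 0`).
#' @export
simulate_transfer_study <- function(n = 16L, k = 1L, L = 2000L, height = 1,
                                    seed = 1L) {
  sp <- simulate_yule_tree(n, height = height, seed = seed)
  tr <- apply_spr_transfers(sp, k, seed = seed + 10000L, leaf_only = TRUE)
  seqs <- if (L > 0) evolve_sequences(tr$tree, L, seed = seed + 20000L) else NULL
  list(species_tree = sp, gene_tree = tr$tree, transfer_log = tr$log,
       moved = tr$log$pruned, sequences = seqs)
}
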