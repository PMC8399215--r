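# Progressive multiple alignment: affine-gap pairwise/profile kernel (C++),
# k-mer UPGMA guide tree, post-order profile merges.

#' Protein alignment scoring scheme
#'
#' BLOSUM62 (from Biostrings) with affine gap penalties. A gap run of length
#' L costs `gap_open + gap_extend * (L - 1)`; terminal gaps are penalized
#' like internal ones. `X` scores 0 against every residue.
#'
#' @param matrix Name of a Biostrings substitution matrix (default
#'   `"BLOSUM62"`) or a numeric matrix with residue dimnames.
#' @param gap_open,gap_extend Positive gap penalties, `gap_open >= gap_extend`.
#' @return A list of class `scoring_scheme` with a 21x21 matrix over the 20
#'   canonical residues plus `X`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  assert_that(gap_open >= gap_extend && gap_extend > 0,
              "need gap_open >= gap_extend > 0")
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  assert_that(all(AA20 %in% rownames(matrix)), "matrix must cover the 20 residues")
  m <- matrix(0, 21, 21, dimnames = list(c(AA20, "X"), c(AA20, "X")))
  m[AA20, AA20] <- matrix[AA20, AA20]
  assert_that(isTRUE(all.equal(m, t(m))), "substitution matrix must be symmetric")
  structure(list(matrix = m, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

# residue count profile of a set of equally long gapped sequences:
# 21 x L matrix (20 residues + X); gaps carry no count
#' @noRd
seq_profile <- function(rows) {
  chars <- seq_char_matrix(rows)
  L <- ncol(chars)
  prof <- matrix(0, 21, L, dimnames = list(c(AA20, "X"), NULL))
  for (k in seq_len(21)) prof[k, ] <- colSums(chars == c(AA20, "X")[k])
  prof
}

# expand profile rows along a traceback path (1 = gap in B, 2 = gap in A)
#' @noRd
apply_path <- function(rowsA, rowsB, path) {
  la <- cumsum(path != 2)  # source column in A per output column (0 = gap)
  lb <- cumsum(path != 1)
  take <- function(rows, src, consume) {
    chars <- seq_char_matrix(rows)
    out <- matrix("-", nrow(chars), length(path))
    out[, consume] <- chars[, src[consume], drop = FALSE]
    apply(out, 1, paste, collapse = "")
  }
  newA <- take(rowsA, la, path != 2)
  newB <- take(rowsB, lb, path != 1)
  names(newA) <- names(rowsA); names(newB) <- names(rowsB)
  c(newA, newB)
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment of two protein sequences under a
#' [scoring_scheme()]. Deterministic tie-breaking: on equal score the
#' diagonal (match/mismatch) move is preferred over a gap in the first
#' sequence, which is preferred over a gap in the second.
#'
#' @param a,b Ungapped amino-acid sequences (single strings).
#' @param scheme A [scoring_scheme()].
#' @return List with `a`, `b` (gapped strings of equal length) and `score`.
#' @examples
#' pairwise_align("MKTA", "MKA")
#' @export
pairwise_align <- function(a, b, scheme = scoring_scheme()) {
  assert_that(is.character(a) && length(a) == 1 && nzchar(a), "a must be a non-empty sequence")
  assert_that(is.character(b) && length(b) == 1 && nzchar(b), "b must be a non-empty sequence")
  a <- toupper(a); b <- toupper(b)
  for (s in c(a, b)) {
    bad <- setdiff(unique(strsplit(s, "")[[1]]), AA_ALPHABET)
    assert_that(length(bad) == 0,
                paste0("invalid residue(s): ", paste(bad, collapse = ", ")))
  }
  res <- .align_profiles_cpp(seq_profile(a), seq_profile(b), scheme$matrix,
                             1, 1, scheme$gap_open, scheme$gap_extend)
  merged <- apply_path(c(a = a), c(b = b), res$path)
  list(a = unname(merged[1]), b = unname(merged[2]), score = res$score)
}

#' Build a UPGMA guide tree from k-mer distances
#'
#' Distances are `1 - |shared 3-mers| / min(#3-mers)` over the sets of
#' distinct 3-mers of each pair of sequences (0 between identical sequences;
#' 1 when either sequence is shorter than 3 residues and they differ). UPGMA
#' clustering (average linkage) on these distances gives the merge order for
#' progressive alignment; sequences are pre-sorted by id, which makes ties
#' (e.g. identical sequences) resolve to a caterpillar in label order.
#'
#' @param seqs Named character vector of ungapped sequences (>= 2).
#' @return A rooted `phylo` guide tree whose tips are the sequence names.
#' @export
build_guide_tree <- function(seqs) {
  assert_that(length(seqs) >= 2, "need at least two sequences")
  assert_that(!is.null(names(seqs)) && !anyDuplicated(names(seqs)),
              "sequences must have unique names")
  seqs <- seqs[order(names(seqs), method = "radix")]
  n <- length(seqs)
  kmers <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < 3) character() else
      unique(substring(s, 1:(L - 2), 3:L))
  })
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (identical(seqs[[i]], seqs[[j]])) { d <- 0 }
    else {
      mn <- min(length(kmers[[i]]), length(kmers[[j]]))
      d <- if (mn == 0) 1 else 1 - length(intersect(kmers[[i]], kmers[[j]])) / mn
    }
    D[i, j] <- D[j, i] <- d
  }
  hc <- hclust(as.dist(D), method = "average")
  ape::as.phylo(hc)
}

#' Progressive multiple sequence alignment
#'
#' Aligns sequences by post-order profile-profile merges along a guide tree
#' (built with [build_guide_tree()] unless supplied), using mean-of-pairs
#' column scoring under the [scoring_scheme()]. Output rows keep the input
#' order. With two sequences this reduces exactly to [pairwise_align()].
#'
#' @param seqs Named character vector of ungapped sequences.
#' @param guide Optional rooted `phylo` guide tree with tips = names(seqs).
#' @param scheme A [scoring_scheme()].
#' @param role Optional role name stored on the alignment.
#' @return A `nif_alignment` object.
#' @export
progressive_align <- function(seqs, guide = NULL, scheme = scoring_scheme(),
                              role = NA_character_) {
  assert_that(!is.null(names(seqs)) && !anyDuplicated(names(seqs)),
              "sequences must have unique names")
  if (length(seqs) == 1) return(new_alignment(seqs, role))
  if (is.null(guide)) guide <- build_guide_tree(seqs)
  assert_that(setequal(guide$tip.label, names(seqs)),
              "guide tree tips must match sequence names")
  merge_node <- function(node) {
    ntip <- length(guide$tip.label)
    if (node <= ntip) return(seqs[guide$tip.label[node]])
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    prof <- merge_node(kids[1])
    for (k in kids[-1]) {
      other <- merge_node(k)
      res <- .align_profiles_cpp(seq_profile(prof), seq_profile(other),
                                 scheme$matrix, length(prof), length(other),
                                 scheme$gap_open, scheme$gap_extend)
      prof <- apply_path(prof, other, res$path)
    }
    prof
  }
  rows <- merge_node(length(guide$tip.label) + 1L)
  new_alignment(rows[names(seqs)], role)
}

#' Construct an alignment object
#'
#' @param rows Named character vector of equally long gapped sequences.
#' @param role Optional role name.
#' @return A `nif_alignment`: list with `role`, `seqs`, `length`.
#' @export
new_alignment <- function(rows, role = NA_character_) {
  assert_that(!is.null(names(rows)) && !anyDuplicated(names(rows)),
              "alignment rows must have unique names")
  assert_that(length(unique(nchar(rows))) == 1, "alignment rows must be equal length")
  structure(list(role = role, seqs = rows, length = nchar(rows[[1]])),
            class = "nif_alignment")
}

#' @export
print.nif_alignment <- function(x, ...) {
  cat("<nif_alignment>", if (!is.na(x$role)) paste0("[", x$role, "]") else "",
      length(x$seqs), "rows x", x$length, "columns\n")
  invisible(x)
}

#' Validate an alignment
#'
#' Report-only checks: equal row lengths, alphabet (residues, `X`, `-`),
#' no all-gap rows, no all-gap columns.
#'
#' @param aln A `nif_alignment` or a named character vector of rows.
#' @return Tibble of violations (`check`, `detail`); zero rows when valid.
#' @export
validate_alignment <- function(aln) {
  rows <- if (inherits(aln, "nif_alignment")) aln$seqs else aln
  v <- list()
  add <- function(check, detail) v[[length(v) + 1L]] <<- tibble(check = check, detail = detail)
  if (length(unique(nchar(rows))) > 1) {
    add("unequal length", paste0("row lengths: ", paste(unique(nchar(rows)), collapse = ", ")))
    return(dplyr::bind_rows(v))
  }
  for (i in seq_along(rows)) {
    bad <- setdiff(unique(strsplit(rows[[i]], "")[[1]]), c(AA_ALPHABET, "-"))
    if (length(bad)) add("alphabet", paste0("row ", names(rows)[i], ": ",
                                            paste(bad, collapse = ", ")))
    if (grepl("^-*$", rows[[i]])) add("all-gap row", names(rows)[i])
  }
  if (length(rows) > 0 && nchar(rows[[1]]) > 0) {
    chars <- seq_char_matrix(rows)
    allgap <- which(colSums(chars != "-") == 0)
    for (cix in allgap) add("all-gap column", as.character(cix))
  }
  if (length(v)) dplyr::bind_rows(v) else tibble(check = character(), detail = character())
}

#' Concatenate per-role alignments into a supermatrix
#'
#' Joins per-role alignment rows genome by genome, in the stated role order,
#' and records the concatenation layout in a [partition_map()]. Every genome
#' must be present in every role alignment: the pipeline only concatenates
#' complete complements, and a missing row is an error naming the genome and
#' role.
#'
#' @param alns List of `nif_alignment` objects, one per role, named by or
#'   carrying their role.
#' @param roles A [role_set()] giving the role order.
#' @return A `nif_concat` object: `seqs` (rows, sorted by genome id),
#'   `partitions` (a [partition_map()]).
#' @export
concatenate <- function(alns, roles = nif_roles()) {
  nm <- names(alns) %||% vapply(alns, function(a) a$role, "")
  if (is.null(names(alns))) names(alns) <- nm
  assert_that(setequal(nm, roles$roles), "need exactly one alignment per role")
  alns <- alns[roles$roles]
  genomes <- sort(names(alns[[1]]$seqs), method = "radix")
  for (r in roles$roles) {
    miss <- setdiff(genomes, names(alns[[r]]$seqs))
    extra <- setdiff(names(alns[[r]]$seqs), genomes)
    assert_that(length(miss) == 0 && length(extra) == 0,
      paste0("genome set mismatch in role ", r, ": ",
             paste(c(miss, extra), collapse = ", ")))
  }
  lens <- vapply(alns, function(a) a$length, 0L)
  rows <- vapply(genomes, function(g)
    paste(vapply(roles$roles, function(r) unname(alns[[r]]$seqs[g]), ""),
          collapse = ""), "")
  pm <- partition_map(roles$roles, cumsum(c(0L, lens[-length(lens)])), cumsum(lens))
  structure(list(role = "concat", seqs = rows, length = sum(lens), partitions = pm),
            class = c("nif_concat", "nif_alignment"))
}

#' Split a concatenated alignment back into per-role alignments
#'
#' Inverse of [concatenate()] using the recorded partition map.
#'
#' @param concat A `nif_concat`.
#' @return Named list of `nif_alignment` objects in partition order.
#' @export
deconcatenate <- function(concat) {
  pm <- concat$partitions
  out <- lapply(seq_len(nrow(pm)), function(i) {
    rows <- substring(concat$seqs, pm$start[i] + 1L, pm$end[i])
    names(rows) <- names(concat$seqs)
    new_alignment(rows, pm$role[i])
  })
  setNames(out, pm$role)
}

#' Read / write aligned FASTA
#'
#' @param path Aligned FASTA path.
#' @param role Optional role name.
#' @return `read_alignment()`: a `nif_alignment`; `write_alignment()`:
#'   `path` invisibly.
#' @export
read_alignment <- function(path, role = NA_character_) {
  fa <- read_fasta(path, aligned = TRUE)
  new_alignment(setNames(fa$seq, fa$id), role)
}

#' @rdname read_alignment
#' @param aln A `nif_alignment`.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(setNames(aln$seqs, names(aln$seqs)), path)
}
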