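#' Parse a Newick tree string
#'
#' Wraps [ape::read.tree()] with stricter validation: unbalanced parentheses
#' are reported with their character offset, and duplicate leaf labels are an
#' error. Absent branch lengths stay absent (no `edge.length` on the result),
#' never silently zero.
#'
#' @param text A Newick string (single tree, terminated by `;`).
#' @return A `phylo` object.
#' @examples
#' parse_newick("((A:1,B:2):0.5,C:3);")
#' @export
parse_newick <- function(text) {
  assert_that(is.character(text) && length(text) == 1, "text must be a single string")
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced parenthesis at character offset ", i, call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("unbalanced parentheses: ", depth, " unclosed at character offset ",
         length(chars), call. = FALSE)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  assert_that(inherits(tr, "phylo"), paste0("Newick parse error in: ", text))
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  assert_that(length(dup) == 0,
              paste0("duplicate leaf label(s): ", paste(dup, collapse = ", ")))
  tr
}

#' Write a tree as canonical Newick
#'
#' Serialises a `phylo` object deterministically: at every internal node the
#' children are ordered by the lexicographically smallest leaf label in their
#' subtree, branch lengths are printed fixed-point at the given precision with
#' trailing zeros trimmed, and internal-node support values (from
#' `node.label`) are written as internal labels. Two trees with the same
#' topology, lengths and supports therefore always serialise to the same
#' string regardless of internal edge order.
#'
#' @param tree A `phylo` object.
#' @param precision Number of digits after the decimal point for branch
#'   lengths (trailing zeros removed).
#' @return A single Newick string ending in `;`.
#' @examples
#' write_newick(parse_newick("((B:2,A:1):0.5,C:3);"))  # children reordered
#' @export
write_newick <- function(tree, precision = 6L) {
  assert_that(inherits(tree, "phylo"), "tree must be a phylo object")
  ntip <- length(tree$tip.label)
  has_len <- !is.null(tree$edge.length)
  has_lab <- !is.null(tree$node.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])

  rec <- function(node) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
      return(list(str = lab, min = lab))
    }
    eidx <- kids[[as.character(node)]]
    parts <- lapply(eidx, function(e) {
      child <- rec(tree$edge[e, 2])
      s <- child$str
      if (has_len) s <- paste0(s, ":", format_brlen(tree$edge.length[e], precision))
      list(str = s, min = child$min)
    })
    ord <- order(vapply(parts, `[[`, "", "min"), method = "radix")
    lab <- if (has_lab) {
      nl <- tree$node.label[node - ntip]
      if (is.na(nl) || !nzchar(nl)) "" else nl
    } else ""
    list(str = paste0("(", paste(vapply(parts[ord], `[[`, "", "str"), collapse = ","),
                      ")", lab),
         min = min(vapply(parts, `[[`, "", "min")))
  }
  paste0(rec(ntip + 1L)$str, ";")
}

#' Build and validate a partition map
#'
#' A partition map records the concatenation layout of a supermatrix: an
#' ordered set of half-open, 0-based column intervals, one per gene role,
#' contiguous and covering the full alignment width.
#'
#' @param role Character vector of partition (role) names.
#' @param start,end Integer half-open 0-based column bounds.
#' @return A tibble with class `partition_map`.
#' @export
partition_map <- function(role, start, end) {
  pm <- tibble(role = as.character(role), start = as.integer(start),
               end = as.integer(end))
  assert_that(!anyDuplicated(pm$role), "partition roles must be unique")
  assert_that(all(pm$end > pm$start), "empty partition interval")
  if (nrow(pm) > 0) {
    assert_that(pm$start[1] == 0L, "partitions must start at column 0")
    if (nrow(pm) > 1)
      assert_that(all(pm$start[-1] == pm$end[-nrow(pm)]),
                  "partitions must be contiguous and non-overlapping")
  }
  class(pm) <- c("partition_map", class(pm))
  pm
}

#' Write a partition map in RAxML style
#'
#' One line per partition, `PROT, <name> = <start>-<end>` with 1-based
#' inclusive coordinates on output.
#'
#' @param pm A [partition_map()].
#' @return A single string (empty for an empty map).
#' @export
write_partitions <- function(pm) {
  if (nrow(pm) == 0) return("")
  paste(sprintf("PROT, %s = %d-%d", pm$role, pm$start + 1L, pm$end),
        collapse = "\n")
}
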