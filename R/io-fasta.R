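#' Read a protein FASTA file
#'
#' Parses a FASTA file of amino-acid sequences into a tibble, one row per
#' record. The record id is the first whitespace-delimited token of the
#' header; the remainder is kept as the description. Sequences are upper-cased
#' and validated against the 20 canonical residues plus `X` (and `-` when
#' `aligned = TRUE`).
#'
#' @param path Path to a FASTA text file.
#' @param aligned Allow gap characters (`-`) in sequences.
#' @return A tibble with columns `id`, `desc`, `seq`. An empty file yields a
#'   zero-row tibble.
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 nitrogenase iron protein", "MKT", ">p2", "GG"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, aligned = FALSE) {
  assert_that(file.exists(path), paste0("FASTA file not found: ", path))
  empty <- tibble(id = character(), desc = character(), seq = character())
  if (file.size(path) == 0) return(empty)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) return(empty)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(raw))
  names(seqs) <- NULL
  assert_that(!anyDuplicated(ids),
    paste0("duplicate FASTA ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  allowed <- c(AA_ALPHABET, if (aligned) "-")
  for (i in seq_along(seqs)) {
    if (!aligned && !nzchar(seqs[i]))
      stop("empty sequence for record '", ids[i], "'", call. = FALSE)
    bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), allowed)
    if (length(bad))
      stop("record '", ids[i], "' contains invalid character(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble(id = ids, desc = desc, seq = seqs)
}

#' Write sequences to FASTA
#'
#' Writes named sequences wrapped at 60 columns. Accepts either a tibble as
#' returned by [read_fasta()] or a named character vector.
#'
#' @param x Tibble with `id` (and optionally `desc`) and `seq` columns, or a
#'   named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    assert_that(!is.null(names(x)) && all(nzchar(names(x))),
                "sequences must be named")
    x <- tibble(id = names(x), desc = "", seq = unname(x))
  }
  hdr <- ifelse(nzchar(x$desc %||% ""), paste(x$id, x$desc), x$id)
  set <- Biostrings::BStringSet(setNames(x$seq, hdr))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
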