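# shared internal helpers

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# amino-acid alphabet accepted in sequence records; '-' only in aligned rows
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @noRd
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# run code under a fixed RNG seed without disturbing the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# fixed-point format with trailing zeros trimmed ("1.500000" -> "1.5", "1" stays "1")
#' @noRd
format_brlen <- function(x, precision = 6L) {
  s <- formatC(x, digits = precision, format = "f")
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

# TSV with optional '# '-prefixed comment lines above the header row
#' @noRd
write_tsv_commented <- function(tab, path, header = character()) {
  body <- sub("\n$", "", readr::format_tsv(tab))
  writeLines(c(if (length(header)) paste0("# ", header), body), path)
  invisible(path)
}

# split gapped/ungapped sequences into a character matrix (rows = sequences)
#' @noRd
seq_char_matrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) <= 1)
  do.call(rbind, strsplit(seqs, ""))
}
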