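# Kimura-corrected protein distances from alignments.

#' Distance computation parameters
#'
#' @param d_max Saturation cap (substitutions/site): distances whose Kimura
#'   argument falls at or below `exp(-d_max)` are set to `d_max`, as are
#'   pairs with too few jointly ungapped columns.
#' @param min_overlap Minimum number of jointly ungapped, non-`X` columns a
#'   pair needs for a usable distance; below it the pair is flagged and set
#'   to `d_max`.
#' @param correction `"kimura"` (default, the pipeline's user-facing
#'   correction) or `"poisson"`, the exact inversion of the 20-state
#'   equal-exchangeability model used by the simulator.
#' @return A list of class `distance_params`.
#' @export
distance_params <- function(d_max = 10, min_overlap = 50L,
                            correction = c("kimura", "poisson")) {
  assert_that(d_max > 0, "d_max must be > 0")
  assert_that(min_overlap >= 0, "min_overlap must be >= 0")
  structure(list(d_max = d_max, min_overlap = as.integer(min_overlap),
                 correction = match.arg(correction)),
            class = "distance_params")
}

#' Observed proportion of differing residues
#'
#' Pairwise deletion: columns where either row has a gap or `X` are excluded;
#' `p` is the fraction of mismatches over the remaining (overlap) columns.
#'
#' @param a,b Gapped sequences of equal length.
#' @return List with `p` (in `[0,1]`, `NA` when overlap is 0) and `overlap`.
#' @export
p_distance <- function(a, b) {
  assert_that(nchar(a) == nchar(b), "rows must be equal length")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  use <- !(ca %in% c("-", "X")) & !(cb %in% c("-", "X"))
  overlap <- sum(use)
  p <- if (overlap == 0) NA_real_ else sum(ca[use] != cb[use]) / overlap
  list(p = p, overlap = overlap)
}

#' Kimura correction for protein distances
#'
#' `d = -ln(1 - p - 0.2 p^2)`, the standard correction of observed protein
#' distance for multiple substitutions. The correction diverges as its
#' argument approaches 0 (around p = 0.854); arguments at or below
#' `exp(-d_max)` saturate to `d_max` by design.
#'
#' @param p Observed proportion(s) of differing residues, in `[0,1]`.
#' @param params A [distance_params()].
#' @return Corrected distance(s), capped at `d_max`.
#' @examples
#' kimura_correct(c(0, 0.1, 0.9))
#' @export
kimura_correct <- function(p, params = distance_params()) {
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p must be in [0,1]")
  arg <- 1 - p - 0.2 * p^2
  sat <- is.na(p) | arg <= exp(-params$d_max)
  ifelse(sat, params$d_max, -log(pmax(arg, exp(-params$d_max))))
}

#' Poisson correction for protein distances
#'
#' Exact distance inversion under the 20-state equal-exchangeability
#' Poisson model (the simulator's model): `d = -(19/20) ln(1 - (20/19) p)`.
#' Arguments at or below the saturation bound are capped at `d_max`.
#'
#' @inheritParams kimura_correct
#' @return Corrected distance(s), capped at `d_max`.
#' @export
poisson_correct <- function(p, params = distance_params()) {
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p must be in [0,1]")
  arg <- 1 - (20 / 19) * p
  bound <- exp(-(20 / 19) * params$d_max)
  sat <- is.na(p) | arg <= bound
  ifelse(sat, params$d_max, -(19 / 20) * log(pmax(arg, bound)))
}

#' Kimura-corrected distance matrix of an alignment
#'
#' All pairwise [p_distance()] values corrected with [kimura_correct()];
#' pairs with overlap below `min_overlap` are set to `d_max`. Symmetric with
#' a zero diagonal by construction.
#'
#' @param aln A `nif_alignment` (or `nif_concat`), or a named character
#'   vector of equally long gapped rows.
#' @param params A [distance_params()].
#' @return A symmetric numeric matrix with taxa as dimnames; attributes
#'   `overlap` (pair overlap counts) and `flagged` (logical, low-overlap
#'   pairs).
#' @export
distance_matrix <- function(aln, params = distance_params()) {
  rows <- if (inherits(aln, "nif_alignment")) aln$seqs else aln
  n <- length(rows)
  assert_that(n >= 2, "need at least two rows")
  chars <- seq_char_matrix(rows)
  usable <- !(chars %in% c("-", "X"))
  dim(usable) <- dim(chars)
  D <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  OV <- matrix(nchar(rows[[1]]), n, n, dimnames = dimnames(D))
  FL <- matrix(FALSE, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- usable[i, ] & usable[j, ]
    ov <- sum(use)
    OV[i, j] <- OV[j, i] <- ov
    if (ov < params$min_overlap) {
      D[i, j] <- D[j, i] <- params$d_max
      FL[i, j] <- FL[j, i] <- TRUE
    } else {
      p <- sum(chars[i, use] != chars[j, use]) / ov
      D[i, j] <- D[j, i] <- if (identical(params$correction, "poisson"))
        poisson_correct(p, params) else kimura_correct(p, params)
    }
  }
  structure(D, overlap = OV, flagged = FL)
}

#' Write a distance matrix as square PHYLIP-style TSV
#'
#' @param D Symmetric matrix with taxa dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  df <- as_tibble(as.data.frame(D), rownames = "taxon")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a square distance-matrix TSV written by [write_distance_matrix()]
#'
#' @param path Input path.
#' @return A symmetric numeric matrix with taxa dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
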