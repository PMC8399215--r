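#' Define a nitrogenase role set
#'
#' A role set names the gene roles a complement must cover, the annotation
#' symbols that count as each role (matched case-insensitively), the
#' reference median protein length per role (used by length-based fusion
#' detection), and which adjacent role pairs can occur as a single fused open
#' reading frame.
#'
#' @param roles Ordered character vector of role names.
#' @param synonyms Named list role -> character vector of accepted gene
#'   symbols.
#' @param median_length Named integer vector role -> reference median protein
#'   length (amino acids).
#' @param fusion_pairs Named list of adjacent role pairs that may be fused,
#'   e.g. `list(EN = c("E","N"))`; names are the fusion flags. Each entry may
#'   carry `attr(.,"symbols")`-style combined symbols via the `fusion_synonyms`
#'   argument.
#' @param fusion_synonyms Named list fusion flag -> accepted combined symbols.
#' @return An object of class `role_set`.
#' @export
role_set <- function(roles, synonyms, median_length,
                     fusion_pairs = list(), fusion_synonyms = list()) {
  assert_that(!anyDuplicated(roles), "role names must be unique")
  assert_that(all(roles %in% names(synonyms)), "every role needs synonyms")
  assert_that(all(roles %in% names(median_length)), "every role needs a median length")
  assert_that(all(median_length[roles] > 0), "reference lengths must be > 0")
  for (fp in fusion_pairs)
    assert_that(length(fp) == 2 && all(fp %in% roles),
                "fusion pairs must name two roles from the set")
  structure(list(roles = roles,
                 synonyms = lapply(synonyms, tolower),
                 median_length = median_length[roles],
                 fusion_pairs = fusion_pairs,
                 fusion_synonyms = lapply(fusion_synonyms, tolower)),
            class = "role_set")
}

#' The default NifHDKENB role set
#'
#' The six-gene minimal complement for molybdenum nitrogenase: structural
#' subunits NifH (dinitrogenase reductase) and NifD/NifK (dinitrogenase),
#' plus the FeMo-cofactor assembly proteins NifE, NifN and NifB. Presence of
#' all six in one genomic neighborhood is the screening criterion for
#' in-silico prediction of diazotrophy. Reference median lengths are typical
#' bacterial protein lengths per role; EN and NB are the two fusion-prone
#' adjacent pairs.
#'
#' @return A [role_set()].
#' @export
nif_roles <- function() {
  role_set(
    roles = c("H", "D", "K", "E", "N", "B"),
    synonyms = list(
      H = c("nifH", "nitrogenase iron protein"),
      D = c("nifD", "nitrogenase molybdenum-iron protein alpha chain"),
      K = c("nifK", "nitrogenase molybdenum-iron protein beta chain"),
      E = c("nifE"),
      N = c("nifN"),
      B = c("nifB")),
    median_length = c(H = 290L, D = 492L, K = 520L, E = 460L, N = 430L, B = 470L),
    fusion_pairs = list(EN = c("E", "N"), NB = c("N", "B")),
    fusion_synonyms = list(EN = c("nifEN", "nifE-N"), NB = c("nifNB", "nifN-B")))
}

#' Role sets for the alternative nitrogenase systems
#'
#' The vanadium (Vnf) and iron-only (Anf) nitrogenases are screened with
#' their three structural genes only; alternative systems frequently lack
#' their own ENB cofactor-assembly genes, so the six-gene criterion does not
#' apply to them.
#'
#' @return A [role_set()].
#' @export
vnf_roles <- function() {
  role_set(roles = c("H", "D", "K"),
           synonyms = list(H = "vnfH", D = "vnfD", K = "vnfK"),
           median_length = c(H = 290L, D = 475L, K = 460L))
}

#' @rdname vnf_roles
#' @export
anf_roles <- function() {
  role_set(roles = c("H", "D", "K"),
           synonyms = list(H = "anfH", D = "anfD", K = "anfK"),
           median_length = c(H = 275L, D = 520L, K = 460L))
}

#' Screening parameters
#'
#' @param window_bp Neighborhood window W in base pairs: paralog copies and
#'   fusion partners are judged co-located when within this distance. The
#'   default comfortably contains known nif operons while excluding distal
#'   paralogs.
#' @param fusion_frac Minimum fraction of the summed reference median lengths
#'   of an adjacent role pair that a single record must reach to be called a
#'   fusion. Tolerates terminal truncation while excluding single-domain
#'   records.
#' @param combination_cap Maximum number of per-role candidate combinations
#'   to enumerate exhaustively when resolving paralogs; beyond it a greedy
#'   nearest-to-anchor fallback is used.
#' @param require_same_contig Reject complements whose chosen records span
#'   contigs (draft assemblies may split operons; disable to sum per-contig
#'   spans instead).
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(window_bp = 25000L, fusion_frac = 0.7,
                          combination_cap = 100000L, require_same_contig = TRUE) {
  assert_that(window_bp > 0, "window_bp must be > 0")
  assert_that(fusion_frac > 0 && fusion_frac <= 1, "fusion_frac must be in (0,1]")
  assert_that(combination_cap >= 1, "combination_cap must be >= 1")
  structure(list(window_bp = as.numeric(window_bp), fusion_frac = fusion_frac,
                 combination_cap = as.numeric(combination_cap),
                 require_same_contig = isTRUE(require_same_contig)),
            class = "screen_params")
}
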