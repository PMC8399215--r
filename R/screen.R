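# Complement screening: find role hits, call EN/NB fusions by length,
# resolve paralogs by genomic-neighborhood co-location.

# gap in bp between two gene intervals on the same contig (0 if overlapping),
# Inf across contigs
#' @noRd
record_gap <- function(c1, s1, e1, c2, s2, e2) {
  ifelse(c1 == c2, pmax(0, pmax(s1, s2) - pmin(e1, e2)), Inf)
}

#' Find annotated hits per role
#'
#' Lists, for every role in the set, the gene records whose symbol matches a
#' role synonym (case-insensitive). Records carrying a combined fusion symbol
#' (e.g. `nifEN`) are listed under both roles of the pair. Hits are ordered
#' by (contig, start).
#'
#' @param genome A [genome_annotation()].
#' @param roles A [role_set()].
#' @return Named list role -> tibble of matching gene records.
#' @export
find_role_hits <- function(genome, roles) {
  genes <- genome$genes
  sym <- tolower(genes$symbol)
  out <- lapply(roles$roles, function(r) {
    match_syn <- sym %in% roles$synonyms[[r]]
    for (pn in names(roles$fusion_pairs)) {
      if (r %in% roles$fusion_pairs[[pn]] && !is.null(roles$fusion_synonyms[[pn]]))
        match_syn <- match_syn | sym %in% roles$fusion_synonyms[[pn]]
    }
    hit <- genes[match_syn, , drop = FALSE]
    hit[order(hit$contig, hit$start), , drop = FALSE]
  })
  setNames(out, roles$roles)
}

#' Call fused records by sequence length
#'
#' A record is called fused for an adjacent role pair (X, Y) when it is
#' annotated to X or Y (or to a combined symbol), its protein length reaches
#' `fusion_frac` of the summed reference median lengths of X and Y, and no
#' separate record for the partner role lies within the neighborhood window.
#' A fused record fills both roles of its pair downstream.
#'
#' @param hits Output of [find_role_hits()].
#' @param roles A [role_set()] with reference median lengths.
#' @param params A [screen_params()].
#' @return Tibble of fusion calls: `pair`, `protein_id`, `symbol`, `contig`,
#'   `start`, `end`, `length_aa`.
#' @export
detect_fusions <- function(hits, roles, params = screen_params()) {
  calls <- list()
  for (pn in names(roles$fusion_pairs)) {
    pair <- roles$fusion_pairs[[pn]]
    X <- pair[1]; Y <- pair[2]
    cands <- dplyr::distinct(dplyr::bind_rows(hits[[X]], hits[[Y]]),
                             .data$protein_id, .keep_all = TRUE)
    if (nrow(cands) == 0) next
    thr <- params$fusion_frac * sum(roles$median_length[pair])
    combined <- roles$fusion_synonyms[[pn]] %||% character()
    for (i in seq_len(nrow(cands))) {
      r <- cands[i, ]
      if (nchar(r$protein) < thr) next
      annotated <- character()
      if (tolower(r$symbol) %in% combined) annotated <- pair
      if (tolower(r$symbol) %in% roles$synonyms[[X]]) annotated <- union(annotated, X)
      if (tolower(r$symbol) %in% roles$synonyms[[Y]]) annotated <- union(annotated, Y)
      if (length(annotated) == 0) next
      partners <- setdiff(pair, annotated)
      partner_near <- FALSE
      for (p in partners) {
        other <- hits[[p]][hits[[p]]$protein_id != r$protein_id, , drop = FALSE]
        if (nrow(other) > 0 &&
            any(record_gap(r$contig, r$start, r$end,
                           other$contig, other$start, other$end) <= params$window_bp))
          partner_near <- TRUE
      }
      if (partner_near) next
      calls[[length(calls) + 1L]] <- tibble(
        pair = pn, protein_id = r$protein_id, symbol = r$symbol,
        contig = r$contig, start = r$start, end = r$end,
        length_aa = nchar(r$protein))
    }
  }
  calls <- if (length(calls)) dplyr::bind_rows(calls) else
    tibble(pair = character(), protein_id = character(), symbol = character(),
           contig = character(), start = integer(), end = integer(),
           length_aa = integer())
  dup <- unique(calls$protein_id[duplicated(calls$protein_id)])
  assert_that(length(dup) == 0,
    paste0("record(s) satisfy the fusion length rule for more than one pair: ",
           paste(dup, collapse = ", ")))
  calls
}

# substitute fusion calls into the per-role hit lists: the fused record
# appears in both roles of its pair, flagged with the pair name
#' @noRd
substitute_fusions <- function(hits, fusions, roles) {
  hits <- lapply(hits, function(h) { h$fused_pair <- NA_character_; h })
  if (nrow(fusions) == 0) return(hits)
  all_genes <- dplyr::bind_rows(hits)
  for (i in seq_len(nrow(fusions))) {
    f <- fusions[i, ]
    rec <- all_genes[all_genes$protein_id == f$protein_id, , drop = FALSE][1, ]
    rec$fused_pair <- f$pair
    for (r in roles$fusion_pairs[[f$pair]]) {
      h <- hits[[r]]
      if (f$protein_id %in% h$protein_id) {
        h$fused_pair[h$protein_id == f$protein_id] <- f$pair
      } else {
        h <- dplyr::bind_rows(h, rec)
        h <- h[order(h$contig, h$start), , drop = FALSE]
      }
      hits[[r]] <- h
    }
  }
  hits
}

#' Resolve one complement per genome by neighborhood co-location
#'
#' Chooses one record per role so that the chosen set spans the smallest
#' genomic window (max end minus min start), restricted to a single contig by
#' default. When several annotated copies of a role exist, this formalises
#' picking the copy "in the same genomic neighborhood" as the rest of the
#' complement. Combinations are enumerated exhaustively up to
#' `combination_cap`; beyond it a greedy fallback anchors on the medoid of
#' the single-copy roles and picks the nearest copy per multi-copy role.
#' Ties are broken by the smallest (contig, start) vector.
#'
#' @param genome A [genome_annotation()].
#' @param hits Output of [find_role_hits()]; computed if `NULL`.
#' @param fusions Output of [detect_fusions()]; computed if `NULL`.
#' @param roles A [role_set()].
#' @param params A [screen_params()].
#' @return An object of class `nif_complement` with fields `genome_id`,
#'   `status` (`complete` / `incomplete`), `missing_roles`, `reason`,
#'   `fusion_flags`, `span_bp`, and `chosen` (tibble role -> record).
#' @export
resolve_complement <- function(genome, hits = NULL, fusions = NULL,
                               roles = nif_roles(), params = screen_params()) {
  if (is.null(hits)) hits <- find_role_hits(genome, roles)
  if (is.null(fusions)) fusions <- detect_fusions(hits, roles, params)
  cand <- substitute_fusions(hits, fusions, roles)

  n_cand <- vapply(cand, nrow, 0L)
  missing <- roles$roles[n_cand == 0]
  if (length(missing) > 0)
    return(new_complement(genome, "incomplete", missing_roles = missing))

  pick <- if (prod(n_cand) <= params$combination_cap)
    resolve_exhaustive(cand, roles, params)
  else resolve_greedy(cand, roles, params)

  if (is.null(pick))
    return(new_complement(genome, "incomplete", reason = "cross_contig"))

  chosen <- dplyr::bind_rows(lapply(seq_along(roles$roles), function(i) {
    row <- cand[[i]][pick[i], , drop = FALSE]
    row$role <- roles$roles[i]
    row
  }))
  chosen <- chosen[, c("role", setdiff(names(chosen), "role"))]
  flags <- sort(unique(chosen$fused_pair[!is.na(chosen$fused_pair)]))
  new_complement(genome, "complete", chosen = chosen, fusion_flags = flags,
                 span_bp = complement_span(chosen))
}

#' @noRd
new_complement <- function(genome, status, chosen = NULL, missing_roles = character(),
                           fusion_flags = character(), span_bp = NA_real_,
                           reason = NA_character_) {
  structure(list(genome_id = genome$genome_id, taxon = genome$taxon,
                 status = status, missing_roles = missing_roles,
                 reason = reason, fusion_flags = fusion_flags,
                 span_bp = span_bp, chosen = chosen),
            class = "nif_complement")
}

#' @export
print.nif_complement <- function(x, ...) {
  cat("<nif_complement> ", x$genome_id, ": ", x$status, sep = "")
  if (length(x$missing_roles)) cat(" (missing ", paste(x$missing_roles, collapse = ","), ")", sep = "")
  if (!is.na(x$reason)) cat(" [", x$reason, "]", sep = "")
  if (length(x$fusion_flags)) cat(" fused:", paste(x$fusion_flags, collapse = ","))
  if (!is.na(x$span_bp)) cat(" span:", x$span_bp, "bp")
  cat("\n")
  invisible(x)
}

# span of a chosen record set: window width on one contig, or summed
# per-contig widths when cross-contig complements are allowed
#' @noRd
complement_span <- function(chosen) {
  u <- dplyr::distinct(chosen, .data$protein_id, .keep_all = TRUE)
  sum(vapply(split(u, u$contig),
             function(g) max(g$end) - min(g$start), 0))
}

# exhaustive minimal-window search over per-role candidate combinations
#' @noRd
resolve_exhaustive <- function(cand, roles, params) {
  n_cand <- vapply(cand, nrow, 0L)
  grid <- as.matrix(do.call(expand.grid, lapply(n_cand, seq_len)))
  ng <- nrow(grid)
  colnum <- function(field) matrix(vapply(seq_along(cand),
    function(i) as.numeric(cand[[i]][[field]][grid[, i]]), numeric(ng)), nrow = ng)
  colchr <- function(field) matrix(vapply(seq_along(cand),
    function(i) as.character(cand[[i]][[field]][grid[, i]]), character(ng)), nrow = ng)
  starts <- colnum("start"); ends <- colnum("end")
  contigs <- colchr("contig"); pids <- colchr("protein_id")
  fused <- colchr("fused_pair")

  ok <- rep(TRUE, nrow(grid))
  # a fused record must fill exactly its two adjacent roles
  for (pn in names(roles$fusion_pairs)) {
    pr <- match(roles$fusion_pairs[[pn]], roles$roles)
    a_f <- !is.na(fused[, pr[1]]) & fused[, pr[1]] == pn
    b_f <- !is.na(fused[, pr[2]]) & fused[, pr[2]] == pn
    ok <- ok & ((a_f & b_f & pids[, pr[1]] == pids[, pr[2]]) | (!a_f & !b_f))
  }
  if (params$require_same_contig)
    ok <- ok & matrixStats_all_equal(contigs)
  if (!any(ok)) return(NULL)

  span <- do.call(pmax, as.data.frame(ends)) - do.call(pmin, as.data.frame(starts))
  if (!params$require_same_contig) {
    multi <- !matrixStats_all_equal(contigs)
    if (any(multi & ok)) {
      span[multi & ok] <- vapply(which(multi & ok), function(k) {
        complement_span(tibble(protein_id = pids[k, ], contig = contigs[k, ],
                               start = starts[k, ], end = ends[k, ]))
      }, 0)
    }
  }
  span[!ok] <- Inf
  best <- which(span == min(span))
  if (length(best) > 1) {
    key <- vapply(best, function(k)
      paste(contigs[k, ], sprintf("%012.0f", starts[k, ]), collapse = "|"), "")
    best <- best[order(key, method = "radix")][1]
  }
  grid[best[1], ]
}

#' @noRd
matrixStats_all_equal <- function(m) {
  res <- rep(TRUE, nrow(m))
  for (j in seq_len(ncol(m))[-1]) res <- res & m[, j] == m[, 1]
  res
}

# greedy fallback: fix single-copy roles, anchor on their medoid midpoint,
# take the nearest copy per multi-copy role
#' @noRd
resolve_greedy <- function(cand, roles, params) {
  n_cand <- vapply(cand, nrow, 0L)
  single <- which(n_cand == 1)
  greedy_from <- function(fixed_idx) {
    pick <- integer(length(cand))
    pick[fixed_idx] <- 1L
    fixed <- dplyr::bind_rows(lapply(fixed_idx, function(i) cand[[i]][1, ]))
    mids <- (fixed$start + fixed$end) / 2
    dmat <- outer(seq_len(nrow(fixed)), seq_len(nrow(fixed)), function(a, b)
      abs(mids[a] - mids[b]) + ifelse(fixed$contig[a] == fixed$contig[b], 0, 1e12))
    anchor <- fixed[which.min(rowSums(dmat)), , drop = FALSE]
    for (i in setdiff(seq_along(cand), fixed_idx)) {
      h <- cand[[i]]
      d <- record_gap(anchor$contig, anchor$start, anchor$end,
                      h$contig, h$start, h$end)
      if (params$require_same_contig && all(is.infinite(d))) return(NULL)
      j <- order(d, h$contig, h$start)[1]
      pick[i] <- j
    }
    pick
  }
  fixed_idx <- if (length(single) > 0) single else integer()
  if (length(fixed_idx) == 0) {
    # no single-copy anchor: try every candidate of the least-ambiguous role
    base <- which.min(n_cand)
    best_pick <- NULL; best_span <- Inf
    for (j in seq_len(n_cand[base])) {
      cand2 <- cand
      cand2[[base]] <- cand2[[base]][j, , drop = FALSE]
      p <- greedy_from_role(cand2, base, params)
      if (is.null(p)) next
      p[base] <- j
      sp <- pick_span(cand, p)
      if (sp < best_span) { best_span <- sp; best_pick <- p }
    }
    return(best_pick)
  }
  pick <- greedy_from(fixed_idx)
  if (is.null(pick)) return(NULL)
  if (params$require_same_contig) {
    ctg <- vapply(seq_along(cand), function(i) cand[[i]]$contig[pick[i]], "")
    if (length(unique(ctg)) > 1) return(NULL)
  }
  pick
}

#' @noRd
greedy_from_role <- function(cand2, base, params) {
  anchor <- cand2[[base]][1, , drop = FALSE]
  pick <- integer(length(cand2))
  pick[base] <- 1L
  for (i in setdiff(seq_along(cand2), base)) {
    h <- cand2[[i]]
    d <- record_gap(anchor$contig, anchor$start, anchor$end,
                    h$contig, h$start, h$end)
    if (params$require_same_contig && all(is.infinite(d))) return(NULL)
    pick[i] <- order(d, h$contig, h$start)[1]
  }
  pick
}

#' @noRd
pick_span <- function(cand, pick) {
  chosen <- dplyr::bind_rows(lapply(seq_along(cand), function(i)
    cand[[i]][pick[i], , drop = FALSE]))
  complement_span(chosen)
}

#' Screen a set of genomes for complete complements
#'
#' Runs hit finding, fusion calling and neighborhood resolution on every
#' genome and assembles a per-genome report plus completeness counts per
#' phylum and genus.
#'
#' @param genomes List of [genome_annotation()] objects (unique genome ids).
#' @param roles A [role_set()].
#' @param params A [screen_params()].
#' @return A tibble (class `complement_table`), one row per genome ordered by
#'   `genome_id`, with columns `genome_id`, `phylum`, `genus`, `status`,
#'   `missing_roles`, `reason`, `fusion_flags`, `span_bp` and one
#'   `pid_<role>` column per role. Attributes `complements` (the underlying
#'   `nif_complement` objects), `by_phylum` and `by_genus` (complete counts).
#' @export
screen_genomes <- function(genomes, roles = nif_roles(), params = screen_params()) {
  ids <- vapply(genomes, function(g) g$genome_id, "")
  dup <- unique(ids[duplicated(ids)])
  assert_that(length(dup) == 0,
              paste0("duplicate genome_id(s): ", paste(dup, collapse = ", ")))
  ord <- order(ids, method = "radix")
  genomes <- genomes[ord]
  comps <- lapply(genomes, resolve_complement, roles = roles, params = params)
  rows <- dplyr::bind_rows(lapply(comps, function(cp) {
    pid <- setNames(rep(NA_character_, length(roles$roles)),
                    paste0("pid_", roles$roles))
    if (!is.null(cp$chosen))
      pid[paste0("pid_", cp$chosen$role)] <- cp$chosen$protein_id
    dplyr::bind_cols(
      tibble(genome_id = cp$genome_id,
             phylum = unname(cp$taxon["phylum"] %||% NA_character_),
             genus = unname(cp$taxon["genus"] %||% NA_character_),
             status = cp$status,
             missing_roles = paste(cp$missing_roles, collapse = ","),
             reason = cp$reason,
             fusion_flags = paste(cp$fusion_flags, collapse = ","),
             span_bp = cp$span_bp),
      as_tibble(as.list(pid)))
  }))
  names(comps) <- vapply(comps, function(cp) cp$genome_id, "")
  count_complete <- function(key) {
    if (nrow(rows) == 0) return(tibble(!!key := character(), n_complete = integer()))
    dplyr::count(rows[rows$status == "complete", ], .data[[key]],
                 name = "n_complete")
  }
  structure(rows, complements = comps,
            by_phylum = count_complete("phylum"),
            by_genus = count_complete("genus"),
            class = c("complement_table", class(rows)))
}

#' Write a complement table to TSV
#'
#' @param tab Output of [screen_genomes()].
#' @param path Output TSV path.
#' @param header Optional comment lines (each prefixed `# `) written above
#'   the table.
#' @return `path`, invisibly.
#' @export
write_complements <- function(tab, path, header = character()) {
  write_tsv_commented(as_tibble(tab), path, header)
}
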