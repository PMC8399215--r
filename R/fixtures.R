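# Annotated-genome fixtures with planted operons, paralogs, fusions and
# incomplete complements; every planted fact is logged as ground truth.

#' Generate genome annotation fixtures with planted truth
#'
#' Builds `n_genomes` synthetic genome annotations on a single contig. Each
#' complete genome carries one gene per role co-located within
#' `operon_span_bp`; a fixed fraction of genomes is planted incomplete
#' (one or two roles deleted), a fraction carries a fused EN or NB record
#' (one record of summed length annotated with the first role's symbol),
#' and every genome receives decoy paralog copies of randomly chosen roles
#' at `decoy_distance_bp` from the operon. Counts are exact:
#' `round(fraction * n_genomes)` genomes per planted class, assigned by a
#' seeded permutation.
#'
#' @param n_genomes Number of genomes.
#' @param operon_span_bp Maximum genomic span of the planted operon.
#' @param decoy_distance_bp Distance from the operon to decoy paralogs
#'   (must exceed `operon_span_bp`).
#' @param fraction_incomplete Fraction of genomes with missing roles.
#' @param fraction_fused_en,fraction_fused_nb Fractions with fused EN / NB.
#' @param n_decoys Decoy paralog copies planted per genome.
#' @param roles A [role_set()]; planted protein lengths are its reference
#'   median lengths.
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @return List with `genomes` (list of [genome_annotation()]) and `truth`,
#'   a tibble with one row per genome: `genome_id`, `status`,
#'   `missing_roles`, `fused`, `span_bp`, per-role planted `pid_<role>`,
#'   and `decoy_ids`.
#' @export
generate_genome_fixtures <- function(n_genomes = 20L, operon_span_bp = 10000L,
                                     decoy_distance_bp = 500000L,
                                     fraction_incomplete = 0.3,
                                     fraction_fused_en = 0.1,
                                     fraction_fused_nb = 0.1,
                                     n_decoys = 2L,
                                     roles = nif_roles(), seed = 1L) {
  assert_that(decoy_distance_bp > operon_span_bp,
              "decoy_distance_bp must exceed operon_span_bp")
  n_inc <- round(fraction_incomplete * n_genomes)
  n_en <- round(fraction_fused_en * n_genomes)
  n_nb <- round(fraction_fused_nb * n_genomes)
  assert_that(n_inc + n_en + n_nb <= n_genomes, "planted fractions exceed 1")
  phyla <- c("Proteobacteria", "Cyanobacteria", "Firmicutes", "Actinobacteria",
             "Nitrospira")
  with_seed(seed, {
    ids <- sprintf("g%03d", seq_len(n_genomes))
    perm <- sample(ids)
    class_of <- setNames(rep("complete", n_genomes), ids)
    class_of[perm[seq_len(n_inc)]] <- "incomplete"
    if (n_en > 0) class_of[perm[n_inc + seq_len(n_en)]] <- "fused_EN"
    if (n_nb > 0) class_of[perm[n_inc + n_en + seq_len(n_nb)]] <- "fused_NB"

    genomes <- list()
    truth_rows <- list()
    for (g in ids) {
      cls <- class_of[[g]]
      lens <- roles$median_length
      plan <- tibble(role = roles$roles,
                     symbol = unname(vapply(roles$roles, function(r)
                       roles$synonyms[[r]][1], "")),
                     aa = as.integer(unname(lens)))
      fused <- ""
      missing <- character()
      if (cls == "fused_EN") {
        fused <- "EN"
        plan <- plan[plan$role != "N", ]
        plan$aa[plan$role == "E"] <- as.integer(lens["E"] + lens["N"])
      } else if (cls == "fused_NB") {
        fused <- "NB"
        plan <- plan[plan$role != "B", ]
        plan$aa[plan$role == "N"] <- as.integer(lens["N"] + lens["B"])
      } else if (cls == "incomplete") {
        n_miss <- sample(1:2, 1)
        missing <- sort(sample(roles$roles, n_miss))
        plan <- plan[!plan$role %in% missing, ]
      }

      # lay the operon genes left to right with even intergenic gaps
      gene_bp <- 3L * plan$aa
      gap <- max(50L, floor((operon_span_bp - sum(gene_bp)) /
                              max(1L, nrow(plan) - 1L)) - 50L)
      start0 <- sample(100000:1000000, 1)
      starts <- start0 + cumsum(c(0L, head(gene_bp + gap, -1)))
      ends <- starts + gene_bp - 1L
      strand <- sample(c("+", "-"), nrow(plan), replace = TRUE)
      pid <- sprintf("%s_p%02d", g, seq_len(nrow(plan)))
      prot <- vapply(plan$aa, function(a)
        paste(sample(AA20, a, replace = TRUE), collapse = ""), "")
      genes <- tibble(symbol = plan$symbol, contig = "c1",
                      start = as.integer(starts), end = as.integer(ends),
                      strand = strand, protein_id = pid, protein = prot)

      # decoy paralogs of random roles, far from the operon
      decoy_ids <- character()
      if (n_decoys > 0 && nrow(plan) > 0) {
        droles <- sample(plan$role, min(n_decoys, nrow(plan)))
        for (i in seq_along(droles)) {
          r <- droles[i]
          # decoys are ordinary-length distal paralogs, never fused copies
          aa <- as.integer(lens[[r]])
          dpid <- sprintf("%s_decoy%02d", g, i)
          dstart <- as.integer(start0 + decoy_distance_bp + (i - 1L) * 5000L)
          genes <- dplyr::bind_rows(genes, tibble(
            symbol = plan$symbol[plan$role == r], contig = "c1",
            start = dstart, end = dstart + 3L * aa - 1L,
            strand = "+", protein_id = dpid,
            protein = paste(sample(AA20, aa, replace = TRUE), collapse = "")))
          decoy_ids <- c(decoy_ids, dpid)
        }
      }

      taxon <- c(phylum = phyla[(match(g, ids) - 1L) %% length(phyla) + 1L],
                 genus = paste0("Genus_", substr(g, 2, 4)))
      genomes[[g]] <- genome_annotation(g, genes, taxon)

      pid_map <- setNames(rep(NA_character_, length(roles$roles)),
                          paste0("pid_", roles$roles))
      pid_map[paste0("pid_", plan$role)] <- pid
      if (fused == "EN") pid_map["pid_N"] <- pid_map["pid_E"]
      if (fused == "NB") pid_map["pid_B"] <- pid_map["pid_N"]
      truth_rows[[g]] <- dplyr::bind_cols(
        tibble(genome_id = g,
               status = if (cls == "incomplete") "incomplete" else "complete",
               missing_roles = paste(missing, collapse = ","),
               fused = fused,
               span_bp = max(ends) - min(starts)),
        as_tibble(as.list(pid_map)),
        tibble(decoy_ids = paste(decoy_ids, collapse = ",")))
    }
    list(genomes = unname(genomes),
         truth = dplyr::bind_rows(truth_rows),
         seed = as.integer(seed))
  })
}

#' Write genome fixtures to disk
#'
#' Emits, per genome, the TSV annotation dialect and a protein FASTA, plus
#' the truth table as TSV — the same formats the pipeline consumes.
#'
#' @param fixtures Output of [generate_genome_fixtures()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_fixtures <- function(fixtures, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in fixtures$genomes) {
    tab <- g$genes[, c("symbol", "contig", "start", "end", "strand", "protein_id")]
    readr::write_tsv(tab, file.path(dir, paste0(g$genome_id, ".tsv")),
                     col_names = FALSE)
    write_fasta(setNames(g$genes$protein, g$genes$protein_id),
                file.path(dir, paste0(g$genome_id, ".faa")))
  }
  readr::write_tsv(fixtures$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
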