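#' Construct a genome annotation
#'
#' Bundles one genome's gene records and protein sequences. Coordinates are
#' 1-based inclusive (GFF3 convention) at this layer and are only converted
#' inside algorithms, so no off-by-one can creep in at I/O.
#'
#' @param genome_id Genome identifier (unique per analysis).
#' @param genes Tibble with columns `symbol`, `contig`, `start`, `end`,
#'   `strand` (`+`/`-`), `protein_id`, `protein` (amino-acid sequence).
#' @param taxon Named character vector of rank -> name (e.g.
#'   `c(phylum = "Cyanobacteria", genus = "Nostoc")`).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, genes, taxon = c(phylum = "unknown", genus = "unknown")) {
  assert_that(is.character(genome_id) && length(genome_id) == 1 && nzchar(genome_id),
              "genome_id must be a non-empty string")
  genes <- as_tibble(genes)
  needed <- c("symbol", "contig", "start", "end", "strand", "protein_id", "protein")
  missing_cols <- setdiff(needed, names(genes))
  assert_that(length(missing_cols) == 0,
              paste0("genes table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (nrow(genes) > 0) {
    bad <- genes$start > genes$end
    assert_that(!any(bad),
      paste0("start > end for protein_id(s): ",
             paste(genes$protein_id[bad], collapse = ", ")))
    dup <- unique(genes$protein_id[duplicated(genes$protein_id)])
    assert_that(length(dup) == 0,
      paste0("duplicate protein_id(s) in genome ", genome_id, ": ",
             paste(dup, collapse = ", ")))
    assert_that(all(genes$strand %in% c("+", "-")), "strand must be '+' or '-'")
    assert_that(all(nzchar(genes$protein)),
                "every gene record needs a resolvable protein sequence")
  }
  structure(list(genome_id = genome_id, taxon = taxon, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", x$genome_id, " (",
      paste(names(x$taxon), x$taxon, sep = "=", collapse = ", "),
      "): ", nrow(x$genes), " gene record(s)\n", sep = "")
  invisible(x)
}

#' Read a gene annotation table plus its protein FASTA
#'
#' Two dialects are supported. `tsv`: six tab-separated columns
#' `symbol, contig, start, end, strand, protein_id` (a header line starting
#' with `symbol` is allowed and skipped). `gff3`: a GFF3 file whose CDS
#' features carry `gene=` and `protein_id=` attributes (parsed with
#' rtracklayer). In both cases the companion FASTA supplies the protein
#' sequence for every `protein_id`.
#'
#' @param path Annotation table path.
#' @param fasta_path Companion protein FASTA path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param genome_id Genome identifier; defaults to the annotation file stem.
#' @param taxon Named character vector of rank -> name.
#' @return A [genome_annotation()].
#' @export
read_annotation_table <- function(path, fasta_path, dialect = c("tsv", "gff3"),
                                  genome_id = sub("\\.[^.]*$", "", basename(path)),
                                  taxon = c(phylum = "unknown", genus = "unknown")) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), paste0("annotation file not found: ", path))
  prot <- read_fasta(fasta_path)
  tab <- if (dialect == "tsv") read_annotation_tsv(path) else read_annotation_gff3(path)
  miss <- setdiff(tab$protein_id, prot$id)
  assert_that(length(miss) == 0,
    paste0("protein_id(s) with no FASTA record: ", paste(miss, collapse = ", ")))
  tab$protein <- prot$seq[match(tab$protein_id, prot$id)]
  genome_annotation(genome_id, tab, taxon)
}

#' @noRd
read_annotation_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1], "symbol")) lines <- lines[-1]
  if (!length(lines))
    return(tibble(symbol = character(), contig = character(), start = integer(),
                  end = integer(), strand = character(), protein_id = character()))
  tab <- readr::read_tsv(I(paste(lines, collapse = "\n")),
    col_names = c("symbol", "contig", "start", "end", "strand", "protein_id"),
    col_types = "cciicc", progress = FALSE)
  as_tibble(tab)
}

#' @noRd
read_annotation_gff3 <- function(path) {
  assert_that(requireNamespace("rtracklayer", quietly = TRUE),
              "the gff3 dialect requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  sym <- as.character(gr$gene)
  pid <- as.character(gr$protein_id)
  assert_that(!any(is.na(sym)) && !any(is.na(pid)),
              "every CDS feature needs gene= and protein_id= attributes")
  df <- as.data.frame(gr)
  tibble(symbol = sym,
         contig = as.character(df$seqnames),
         start = as.integer(df$start),
         end = as.integer(df$end),
         strand = as.character(df$strand),
         protein_id = pid)
}
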