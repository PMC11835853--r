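#' Protein record
#'
#' Bundles a gene symbol with its amino-acid sequence and gene-level
#' metadata: the population frequency of the associated disease (used by
#' the benign-by-frequency supplementation rule) and optional OMIM /
#' UniProt identifiers.
#'
#' @param gene Gene symbol.
#' @param sequence Amino-acid sequence (1-letter codes, 20-letter standard
#'   alphabet).
#' @param disease_frequency Optional disease frequency in the population,
#'   a fraction strictly between 0 and 1.
#' @param omim_id,uniprot_id Optional identifier strings.
#' @return An object of class `protein_record`.
#' @export
#' @examples
#' p <- protein_record("ADA", "MAQTPAFDKPKVELHVHLDGSIK", disease_frequency = 5e-6)
#' p$gene
protein_record <- function(gene, sequence, disease_frequency = NULL,
                           omim_id = NULL, uniprot_id = NULL) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  check_sequence(sequence)
  if (!is.null(disease_frequency)) {
    if (!is.numeric(disease_frequency) || length(disease_frequency) != 1L ||
        is.na(disease_frequency) ||
        disease_frequency <= 0 || disease_frequency >= 1)
      stop("disease_frequency must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(
    list(gene = gene, sequence = sequence,
         disease_frequency = disease_frequency,
         omim_id = omim_id, uniprot_id = uniprot_id),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$gene, "-", nchar(x$sequence), "aa\n")
  if (!is.null(x$disease_frequency))
    cat("  disease frequency:", format(x$disease_frequency), "\n")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()]. The first
#' whitespace-delimited token of each FASTA header is taken as the gene
#' symbol.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param gene_config Optional data frame from [read_gene_config()]; when
#'   given, disease frequency and identifiers are attached to matching
#'   genes.
#' @return Named list of [protein_record()] objects.
#' @export
read_protein_fasta <- function(path, gene_config = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  genes <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
  recs <- lapply(seq_along(seqs), function(i) {
    gene <- genes[[i]]
    cfg <- if (!is.null(gene_config) && gene %in% gene_config$gene)
      gene_config[match(gene, gene_config$gene), ] else NULL
    protein_record(
      gene, as.character(seqs[[i]]),
      disease_frequency = if (!is.null(cfg) && is.finite(cfg$disease_frequency))
        cfg$disease_frequency,
      omim_id = if (!is.null(cfg) && nzchar(cfg$omim_id %||% "")) cfg$omim_id,
      uniprot_id = if (!is.null(cfg) && nzchar(cfg$uniprot_id %||% "")) cfg$uniprot_id
    )
  })
  stats::setNames(recs, genes)
}

#' Read a per-gene configuration table
#'
#' CSV with columns `gene`, `disease_frequency` and optional `omim_id`,
#' `uniprot_id`.
#'
#' @param path Path to the CSV file.
#' @return Data frame with one row per gene.
#' @export
read_gene_config <- function(path) {
  cfg <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("gene", "disease_frequency") %in% names(cfg)))
    stop("gene config needs columns 'gene' and 'disease_frequency'", call. = FALSE)
  for (col in c("omim_id", "uniprot_id"))
    if (is.null(cfg[[col]])) cfg[[col]] <- ""
  cfg$disease_frequency <- as.numeric(cfg$disease_frequency)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
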