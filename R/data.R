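# Variant-table ingestion and curation rules: missense-only validation,
# benign supplementation by population allele frequency, and the minimum
# dataset-size gate.

#' Load a variant table
#'
#' Reads a CSV with header `gene,position,ref,alt,label,allele_frequency`
#' (label one of `pathogenic`, `benign`, `unknown`; allele_frequency may
#' be empty) and validates each row against the protein sequences: the
#' reference residue must match the sequence at the 1-based position, ref
#' and alt must be standard residues, and ref must differ from alt
#' (missense only). Failing rows are dropped with a row-indexed warning;
#' duplicate `(gene, position, alt)` rows keep the first occurrence.
#'
#' @param path Path to the variant CSV.
#' @param proteins Named list of [protein_record()]s (names = gene).
#' @return Data frame of validated variants (class `variant_table`),
#'   columns as in the file, input order preserved.
#' @export
load_variants <- function(path, proteins) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(position = "integer"))
  required <- c("gene", "position", "ref", "alt", "label")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(tab$allele_frequency)) tab$allele_frequency <- NA_real_
  tab$allele_frequency <- suppressWarnings(as.numeric(tab$allele_frequency))
  validate_variants(tab, proteins)
}

validate_variants <- function(tab, proteins) {
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    problem <- NULL
    if (!row$gene %in% names(proteins)) {
      problem <- paste0("unknown gene '", row$gene, "'")
    } else if (!is_standard_residue(row$ref) || !is_standard_residue(row$alt)) {
      problem <- "non-standard residue code"
    } else if (identical(row$ref, row$alt)) {
      problem <- "not missense (ref equals alt)"
    } else if (!row$label %in% c("pathogenic", "benign", "unknown")) {
      problem <- paste0("unknown label '", row$label, "'")
    } else if (!is.na(row$allele_frequency) &&
               (row$allele_frequency < 0 || row$allele_frequency > 1)) {
      problem <- "allele_frequency outside [0, 1]"
    } else {
      seq <- proteins[[row$gene]]$sequence
      if (is.na(row$position) || row$position < 1L || row$position > nchar(seq)) {
        problem <- paste0("position ", row$position, " out of range")
      } else {
        actual <- substr(seq, row$position, row$position)
        if (actual != row$ref)
          problem <- paste0("reference mismatch: table says '", row$ref,
                            "' but sequence has '", actual, "'")
      }
    }
    if (!is.null(problem)) {
      warning("variant row ", i, " rejected: ", problem, call. = FALSE)
      keep[i] <- FALSE
    }
  }
  tab <- tab[keep, , drop = FALSE]
  dup <- duplicated(tab[, c("gene", "position", "alt")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (gene, position, alt) row(s) dropped; ",
            "first occurrence kept", call. = FALSE)
    tab <- tab[!dup, , drop = FALSE]
  }
  rownames(tab) <- NULL
  class(tab) <- c("variant_table", "data.frame")
  tab
}

#' Supplement benign variants by population allele frequency
#'
#' Variants with label `unknown` whose allele frequency strictly exceeds
#' the population frequency of the disease are relabeled `benign` (the
#' "B+" rule); all other unknowns stay unknown, and already-labeled
#' variants are never touched. Unknown variants lacking an allele
#' frequency trigger a warning and stay unknown.
#'
#' @param variants A `variant_table`.
#' @param disease_frequency Disease frequency in the population, in (0, 1).
#' @return The relabeled `variant_table`, with a logical column
#'   `supplemented` marking the promoted rows.
#' @export
supplement_benign <- function(variants, disease_frequency) {
  if (!is.numeric(disease_frequency) || length(disease_frequency) != 1L ||
      disease_frequency <= 0 || disease_frequency >= 1)
    stop("disease_frequency must lie strictly between 0 and 1", call. = FALSE)
  unknown <- variants$label == "unknown"
  no_freq <- unknown & is.na(variants$allele_frequency)
  if (any(no_freq))
    warning(sum(no_freq), " unknown-label variant(s) without allele ",
            "frequency left unlabeled", call. = FALSE)
  promote <- unknown & !is.na(variants$allele_frequency) &
    variants$allele_frequency > disease_frequency
  variants$supplemented <- promote
  variants$label[promote] <- "benign"
  variants
}

#' Minimum-dataset-size gate
#'
#' A training set passes the gate when it holds at least `min_n` labeled
#' (pathogenic + benign) missense variants. In the library the gate is
#' advisory; the command-line pipeline enforces it.
#'
#' @param variants A `variant_table`.
#' @param min_n Threshold, default 75.
#' @return Logical scalar; `FALSE` comes with a warning.
#' @export
gate_min_variants <- function(variants, min_n = 75L) {
  n <- sum(variants$label %in% c("pathogenic", "benign"))
  ok <- n >= min_n
  if (!ok)
    warning("only ", n, " labeled variants (< ", min_n, "): dataset below ",
            "the recommended minimum", call. = FALSE)
  ok
}

#' Assemble a training set of descriptor-set examples
#'
#' Runs the representation pipeline for every labeled variant: peptide
#' window extraction, molecular-graph construction and MNA descriptor-set
#' computation at the given configuration. Unknown-label variants are
#' excluded.
#'
#' @param protein A [protein_record()].
#' @param variants A `variant_table` for that protein.
#' @param pl Peptide length (odd, 5-31).
#' @param level MNA level.
#' @param form Descriptor representation, see [mna_descriptor_set()].
#' @return List of examples (`id`, `dset`, `label`) for [fit_sspr()] and
#'   the cross-validation functions.
#' @export
build_training_set <- function(protein, variants, pl, level, form = "key") {
  labeled <- variants[variants$label %in% c("pathogenic", "benign"), ,
                      drop = FALSE]
  lapply(seq_len(nrow(labeled)), function(i) {
    row <- labeled[i, ]
    w <- extract_peptide_window(protein, row$position, row$alt, pl)
    g <- build_molecular_graph(w)
    list(id = paste0(row$gene, ":", row$ref, row$position, row$alt),
         dset = mna_descriptor_set(g, level, form = form),
         label = row$label)
  })
}

#' Dataset provider for the model-selection grid
#'
#' Returns a `function(pl)` that builds the per-peptide-length dataset of
#' molecular graphs required by [grid_search()], caching nothing between
#' calls.
#'
#' @inheritParams build_training_set
#' @return Function of `pl`.
#' @export
grid_provider <- function(protein, variants) {
  labeled <- variants[variants$label %in% c("pathogenic", "benign"), ,
                      drop = FALSE]
  function(pl) {
    lapply(seq_len(nrow(labeled)), function(i) {
      row <- labeled[i, ]
      w <- extract_peptide_window(protein, row$position, row$alt, pl)
      list(id = paste0(row$gene, ":", row$ref, row$position, row$alt),
           graph = build_molecular_graph(w),
           label = row$label)
    })
  }
}
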