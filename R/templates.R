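# Residue templates: heavy atoms and Kekule bonds per standard amino acid,
# shipped as inst/extdata/residue_templates.json. Hydrogens are not stored;
# they are materialized at graph-build time from standard valences.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

STANDARD_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, H = 1L)

.mnapred_env <- new.env(parent = emptyenv())

#' Residue templates for the 20 standard amino acids
#'
#' Returns the parsed heavy-atom templates used to assemble peptide
#' molecular graphs: for each one-letter residue code, a list with `atoms`
#' (data frame: `name`, `element`) and `bonds` (data frame: `a`, `b`,
#' `order`, atom names). Templates describe the free amino acid (backbone
#' N, CA, C, carbonyl O and hydroxyl OXT plus the side chain); fixed
#' neutral protonation states are used (Asp/Glu as COOH, Lys as NH2, Arg as
#' neutral guanidine, His as the N-epsilon-H tautomer).
#'
#' @return Named list of residue templates, names being the 20 one-letter
#'   codes.
#' @export
#' @examples
#' tpl <- residue_templates()
#' nrow(tpl$G$atoms)  # glycine: 5 heavy atoms
residue_templates <- function() {
  if (!is.null(.mnapred_env$templates)) return(.mnapred_env$templates)
  path <- system.file("extdata", "residue_templates.json", package = "mnapred",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path)
  tpl <- lapply(raw, function(res) {
    atoms <- data.frame(
      name = vapply(res$atoms, `[[`, "", "name"),
      element = vapply(res$atoms, `[[`, "", "element"),
      stringsAsFactors = FALSE
    )
    bonds <- data.frame(
      a = vapply(res$bonds, `[[`, "", "a"),
      b = vapply(res$bonds, `[[`, "", "b"),
      order = vapply(res$bonds, function(x) as.integer(x$order), 0L),
      stringsAsFactors = FALSE
    )
    list(atoms = atoms, bonds = bonds)
  })
  stopifnot(setequal(names(tpl), AA_ALPHABET))
  .mnapred_env$templates <- tpl
  tpl
}

is_standard_residue <- function(x) {
  nchar(x) == 1L & x %in% AA_ALPHABET
}

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("protein sequence must be a non-empty string", call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stop("non-standard residue code(s) in sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(chars)
}
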