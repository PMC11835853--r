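# MDL SD file (V2000) writer and reader. Coordinates are zero-filled 2D
# placeholders: downstream MNA descriptors use topology only.

#' Write molecular graphs to an MDL SD file
#'
#' Each graph becomes one V2000 molfile block with all coordinates 0.0 and
#' bond order 1 (the graph stores connectivity only); the record tag is
#' written both as the molfile title and as an SD data field `<record>`.
#'
#' @param graphs List of `molgraph` objects.
#' @param tags Character vector of record tags, one per graph.
#' @param file Path or connection to write to.
#' @return Invisibly, the number of records written.
#' @export
write_sdf <- function(graphs, tags, file) {
  stopifnot(length(graphs) == length(tags))
  out <- character(0)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    stopifnot(inherits(g, "molgraph"))
    na <- length(g$elements)
    nb <- nrow(g$bonds)
    atom_lines <- sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, g$elements)
    bond_lines <- if (nb) sprintf("%3d%3d%3d  0", g$bonds[, 1], g$bonds[, 2], 1L)
    out <- c(out,
             tags[[i]], "  mnapred", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
             atom_lines, bond_lines,
             "M  END",
             "> <record>", tags[[i]], "",
             "$$$$")
  }
  writeLines(out, file)
  invisible(length(graphs))
}

#' Read an MDL SD file
#'
#' Parses V2000 molfile blocks written by [write_sdf()] (or compatible
#' files): element symbols from the atom block, connectivity from the bond
#' block, and SD data fields as tags. Bond orders and coordinates are
#' discarded.
#'
#' @param file Path or connection.
#' @return List of records, each a list with `graph` (a `molgraph`) and
#'   `tag` (the `<record>` data field, falling back to the molfile title).
#' @export
read_sdf <- function(file) {
  lines <- readLines(file)
  records <- list()
  pos <- 1L
  rec_i <- 1L
  n <- length(lines)
  bad <- function(msg) stop("SDF record ", rec_i, ": ", msg, call. = FALSE)
  while (pos <= n) {
    if (pos + 3L > n) bad("truncated header")
    title <- lines[[pos]]
    counts <- lines[[pos + 3L]]
    na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
    if (is.na(na) || is.na(nb)) bad("malformed counts line")
    atom_end <- pos + 3L + na
    bond_end <- atom_end + nb
    if (bond_end > n) bad("truncated atom/bond block")
    atom_lines <- lines[(pos + 4L):atom_end]
    elements <- trimws(substr(atom_lines, 32, 34))
    if (any(!nzchar(elements))) bad("missing element symbol")
    bonds <- matrix(integer(0), ncol = 2)
    if (nb > 0) {
      bond_lines <- lines[(atom_end + 1L):bond_end]
      b1 <- suppressWarnings(as.integer(substr(bond_lines, 1, 3)))
      b2 <- suppressWarnings(as.integer(substr(bond_lines, 4, 6)))
      if (anyNA(b1) || anyNA(b2)) bad("malformed bond line")
      if (any(b1 < 1 | b1 > na | b2 < 1 | b2 > na))
        bad("bond atom index out of range")
      bonds <- cbind(b1, b2)
      dimnames(bonds) <- NULL
    }
    # scan to M END then data fields until $$$$
    pos <- bond_end + 1L
    while (pos <= n && !startsWith(lines[[pos]], "M  END")) pos <- pos + 1L
    if (pos > n) bad("missing M  END")
    pos <- pos + 1L
    tag <- title
    while (pos <= n && lines[[pos]] != "$$$$") {
      if (startsWith(lines[[pos]], "> ") && grepl("<record>", lines[[pos]], fixed = TRUE)) {
        if (pos + 1L <= n) tag <- lines[[pos + 1L]]
      }
      pos <- pos + 1L
    }
    if (pos > n) bad("missing $$$$ terminator")
    pos <- pos + 1L
    records[[rec_i]] <- list(graph = new_molgraph(elements, bonds), tag = tag)
    rec_i <- rec_i + 1L
  }
  records
}
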