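# Peptide windows and molecular graph assembly.

#' Extract the peptide window around an amino-acid substitution
#'
#' Cuts the odd-length window of `pl` residues centred on the substituted
#' position and applies the substitution. Near a sequence edge the deficit
#' on the short side is compensated on the other side, so the window keeps
#' its full length whenever the protein is at least `pl` residues long;
#' only for proteins shorter than `pl` is the whole (substituted) sequence
#' returned.
#'
#' @param protein A [protein_record()].
#' @param pos 1-based substitution position.
#' @param alt Alternate residue (1-letter code); must differ from the
#'   reference residue at `pos` (synonymous changes are rejected).
#' @param pl Odd peptide length between 5 and 31.
#' @return A `peptide_window`: list with `residues` (substitution applied),
#'   `center_offset` (0-based index of the substituted residue),
#'   `source_span` (1-based inclusive protein coordinates) and
#'   `length_config`.
#' @export
#' @examples
#' p <- protein_record("X", "ACDEF")
#' extract_peptide_window(p, 3, "N", 5)$residues  # "ACNEF"
extract_peptide_window <- function(protein, pos, alt, pl) {
  stopifnot(inherits(protein, "protein_record"))
  if (!is.numeric(pl) || length(pl) != 1L || pl %% 2L != 1L || pl < 5L || pl > 31L)
    stop("pl must be an odd integer in [5, 31]", call. = FALSE)
  n <- nchar(protein$sequence)
  if (!is.numeric(pos) || length(pos) != 1L || pos < 1L || pos > n)
    stop("position ", pos, " out of range 1..", n, call. = FALSE)
  if (!is_standard_residue(alt))
    stop("alternate residue '", alt, "' is not a standard amino acid", call. = FALSE)
  ref <- substr(protein$sequence, pos, pos)
  if (alt == ref)
    stop("substitution at position ", pos, " is synonymous (", ref, "->", alt, ")",
         call. = FALSE)

  half <- (pl - 1L) %/% 2L
  start <- pos - half
  end <- pos + half
  if (start < 1L) {
    end <- min(n, end + (1L - start))
    start <- 1L
  }
  if (end > n) {
    start <- max(1L, start - (end - n))
    end <- n
  }
  residues <- substr(protein$sequence, start, end)
  offset <- pos - start
  substr(residues, offset + 1L, offset + 1L) <- alt
  structure(
    list(residues = residues, center_offset = offset,
         source_span = c(start, end), length_config = as.integer(pl)),
    class = "peptide_window"
  )
}

#' @export
print.peptide_window <- function(x, ...) {
  cat("<peptide_window>", x$residues, "\n  center:", x$center_offset,
      " span:", x$source_span[1], "-", x$source_span[2],
      " pl:", x$length_config, "\n")
  invisible(x)
}

new_molgraph <- function(elements, bonds) {
  structure(list(elements = elements, bonds = bonds), class = "molgraph")
}

#' Build the molecular graph of a peptide
#'
#' Assembles residue template graphs into a peptide: residues are chained
#' by peptide (C'-N) bonds, each bond condensing out the hydroxyl oxygen of
#' the upstream carboxyl group; termini are left as free neutral amine and
#' carboxylic acid. Explicit hydrogens are added to every heavy atom up to
#' its standard valence (C 4, N 3, O 2, S 2), counting Kekule bond orders
#' from the templates.
#'
#' @param window A `peptide_window` from [extract_peptide_window()], or a
#'   plain string of 1-letter residue codes.
#' @return A `molgraph`: list with `elements` (character vector of element
#'   symbols, hydrogens explicit) and `bonds` (2-column integer matrix of
#'   atom indices, each row an undirected bond).
#' @export
#' @examples
#' g <- build_molecular_graph("G")
#' table(g$elements)  # 2 C, 5 H, 1 N, 2 O
build_molecular_graph <- function(window) {
  residues <- if (inherits(window, "peptide_window")) window$residues else window
  chars <- check_sequence(residues)
  tpl <- residue_templates()
  n_res <- length(chars)

  elements <- character(0)
  bonds <- matrix(integer(0), ncol = 2)
  orders <- integer(0)
  prev_c <- NA_integer_   # index of previous residue's carbonyl C

  for (i in seq_len(n_res)) {
    res <- tpl[[chars[[i]]]]
    atoms <- res$atoms
    rbonds <- res$bonds
    if (i < n_res) {   # peptide bond condenses out the hydroxyl O
      keep <- atoms$name != "OXT"
      atoms <- atoms[keep, , drop = FALSE]
      rbonds <- rbonds[rbonds$a != "OXT" & rbonds$b != "OXT", , drop = FALSE]
    }
    idx <- stats::setNames(length(elements) + seq_len(nrow(atoms)), atoms$name)
    elements <- c(elements, atoms$element)
    if (nrow(rbonds)) {
      bonds <- rbind(bonds, cbind(idx[rbonds$a], idx[rbonds$b]))
      orders <- c(orders, rbonds$order)
    }
    if (!is.na(prev_c)) {
      bonds <- rbind(bonds, cbind(prev_c, idx[["N"]]))
      orders <- c(orders, 1L)
    }
    prev_c <- idx[["C"]]
  }

  # hydrogens to standard valence
  val_used <- integer(length(elements))
  for (k in seq_len(nrow(bonds))) {
    val_used[bonds[k, 1]] <- val_used[bonds[k, 1]] + orders[k]
    val_used[bonds[k, 2]] <- val_used[bonds[k, 2]] + orders[k]
  }
  n_h <- STANDARD_VALENCE[elements] - val_used
  if (any(n_h < 0))
    stop("internal: template valence exceeded", call. = FALSE)
  h_owner <- rep(seq_along(elements), n_h)
  h_idx <- length(elements) + seq_along(h_owner)
  elements <- c(elements, rep("H", length(h_owner)))
  bonds <- rbind(bonds, cbind(h_owner, h_idx))
  dimnames(bonds) <- NULL
  storage.mode(bonds) <- "integer"
  new_molgraph(elements, bonds)
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph>", length(x$elements), "atoms (",
      sum(x$elements != "H"), "heavy ),", nrow(x$bonds), "bonds\n")
  invisible(x)
}

# adjacency list: integer neighbor indices per atom
molgraph_adjacency <- function(graph) {
  n <- length(graph$elements)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  b <- graph$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
    adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
  }
  adj
}

#' Validate molecular-graph invariants
#'
#' Checks connectivity, absence of self-loops and duplicate bonds, and
#' that every hydrogen has degree exactly one.
#'
#' @param graph A `molgraph`.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
validate_molgraph <- function(graph) {
  stopifnot(inherits(graph, "molgraph"))
  n <- length(graph$elements)
  b <- graph$bonds
  if (any(b[, 1] == b[, 2])) stop("self-loop in molecular graph", call. = FALSE)
  key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  if (anyDuplicated(key)) stop("duplicate bond in molecular graph", call. = FALSE)
  adj <- molgraph_adjacency(graph)
  deg <- lengths(adj)
  if (any(deg[graph$elements == "H"] != 1L))
    stop("hydrogen atom with degree != 1", call. = FALSE)
  # connectivity by BFS
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    nxt <- unique(unlist(adj[queue]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    queue <- nxt
  }
  if (!all(seen)) stop("molecular graph is disconnected", call. = FALSE)
  invisible(TRUE)
}
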