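# Multilevel Neighborhoods of Atoms (MNA) descriptors.
#
# The level-0 descriptor of an atom is its element label; the level-k
# descriptor is `label(child1,child2,...)` where the children are the
# level-(k-1) descriptors of all bonded neighbours (hydrogens included),
# sorted lexicographically, duplicates kept. Hydrogen atoms are never
# descriptor centres. The descriptor set of a graph at level k collects the
# distinct level-k descriptors over all heavy-atom centres.

#' Canonical MNA descriptor string of one atom
#'
#' Computes the literal canonical descriptor text by recursion. The string
#' enumerates every backtracking walk of length at most `level` from the
#' centre, so its size grows exponentially with `level`; this text form is
#' intended for inspection and small-molecule work (see
#' [mna_descriptor_set()] for the representation used in models).
#'
#' @param graph A `molgraph`.
#' @param atom 1-based atom index; must not be a hydrogen.
#' @param level Neighborhood radius in covalent bonds (>= 0).
#' @return Character scalar, e.g. `"O(C(H,H,H,O),H(O))"`.
#' @export
#' @examples
#' water <- structure(list(elements = c("O", "H", "H"),
#'                         bonds = cbind(c(1L, 1L), c(2L, 3L))),
#'                    class = "molgraph")
#' mna_descriptor(water, 1, 1)  # "O(H,H)"
mna_descriptor <- function(graph, atom, level) {
  stopifnot(inherits(graph, "molgraph"))
  n <- length(graph$elements)
  if (!is.numeric(atom) || length(atom) != 1L || atom < 1L || atom > n)
    stop("unknown atom id: ", atom, call. = FALSE)
  if (graph$elements[[atom]] == "H")
    stop("hydrogen atoms cannot be descriptor centres", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || level < 0L)
    stop("level must be >= 0", call. = FALSE)
  adj <- molgraph_adjacency(graph)
  memo <- new.env(parent = emptyenv())
  rec <- function(a, k) {
    key <- paste0(a, ".", k)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- if (k == 0L) {
      graph$elements[[a]]
    } else {
      kids <- vapply(adj[[a]], rec, "", k = k - 1L)
      paste0(graph$elements[[a]], "(", paste(sort_c(kids), collapse = ","), ")")
    }
    memo[[key]] <- out
    out
  }
  rec(as.integer(atom), as.integer(level))
}

# locale-independent lexicographic sort (radix sorting uses C collation)
sort_c <- function(x) sort(x, method = "radix")

#' MNA descriptor set of a molecular graph
#'
#' The deduplicated canonical level-`level` descriptors over all heavy-atom
#' centres — the feature representation consumed by the classifier. By
#' default descriptors are carried as 128-bit canonical fingerprints
#' (`form = "key"`), which are equal exactly when the canonical descriptor
#' strings are equal but stay fixed-size at high levels; `form = "text"`
#' returns the literal strings (exponential in `level`; use on small
#' graphs).
#'
#' @param graph A `molgraph`.
#' @param level Descriptor level (>= 0; models use 5-15).
#' @param form `"key"` (default) or `"text"`.
#' @return A `descriptor_set`: list with `level`, `form` and `items`
#'   (sorted unique character vector).
#' @export
mna_descriptor_set <- function(graph, level, form = c("key", "text")) {
  stopifnot(inherits(graph, "molgraph"))
  form <- match.arg(form)
  if (length(graph$elements) == 0L) stop("empty graph", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || level < 0L)
    stop("level must be >= 0", call. = FALSE)
  heavy <- which(graph$elements != "H")
  items <- if (form == "key") {
    keys <- .mna_hash_levels(graph$elements, graph$bonds, as.integer(level))
    keys[[as.integer(level) + 1L]][heavy]
  } else {
    vapply(heavy, function(a) mna_descriptor(graph, a, level), "")
  }
  new_descriptor_set(sort_c(unique(items)), as.integer(level), form)
}

new_descriptor_set <- function(items, level, form) {
  structure(list(level = level, form = form, items = items),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat("<descriptor_set> level", x$level, "(", x$form, "):",
      length(x$items), "descriptors\n")
  invisible(x)
}

# Descriptor sets for every level 0..max_level in one pass (key form).
# Returns a list indexed by level+1 of sorted unique key vectors.
mna_key_level_sets <- function(graph, max_level) {
  heavy <- which(graph$elements != "H")
  keys <- .mna_hash_levels(graph$elements, graph$bonds, as.integer(max_level))
  lapply(keys, function(k) sort_c(unique(k[heavy])))
}

#' Dump the MNA descriptors of a graph as text
#'
#' One line per distinct descriptor and level:
#' `level<TAB>count<TAB>text`, where `count` is the number of heavy-atom
#' centres carrying that descriptor. Intended for debugging and golden-file
#' tests; uses the literal text form.
#'
#' @param graph A `molgraph`.
#' @param max_level Highest level to include (from 0).
#' @param file Optional path; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when written to `file`).
#' @export
descriptor_dump <- function(graph, max_level, file = NULL) {
  heavy <- which(graph$elements != "H")
  lines <- unlist(lapply(0:max_level, function(lv) {
    txt <- vapply(heavy, function(a) mna_descriptor(graph, a, lv), "")
    tab <- table(txt)
    tab <- tab[sort_c(names(tab))]
    sprintf("%d\t%d\t%s", lv, as.integer(tab), names(tab))
  }))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
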