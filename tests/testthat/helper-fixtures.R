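# Shared fixtures: tiny hand-built molecules, random graphs/datasets, and
# file writers for the command-line tests. Everything is generated in code.

make_molgraph <- function(elements, bonds) {
  structure(list(elements = elements,
                 bonds = matrix(as.integer(bonds), ncol = 2)),
            class = "molgraph")
}

water_graph <- function() {
  make_molgraph(c("O", "H", "H"), cbind(c(1, 1), c(2, 3)))
}

methanol_graph <- function() {
  # C(1)-H(2,3,4), C-O(5), O-H(6)
  make_molgraph(c("C", "H", "H", "H", "O", "H"),
                cbind(c(1, 1, 1, 1, 5), c(2, 3, 4, 5, 6)))
}

# relabel atoms by a permutation: atom i becomes perm[i]
permute_molgraph <- function(graph, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  make_molgraph(graph$elements[inv],
                cbind(perm[graph$bonds[, 1]], perm[graph$bonds[, 2]]))
}

random_peptide <- function(n, alphabet = mnapred:::AA_ALPHABET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random connected labeled graph without hydrogens (random tree + extras)
random_molgraph <- function(n_atoms, labels = c("C", "N", "O", "S"),
                            extra_edges = 1L) {
  elements <- sample(labels, n_atoms, replace = TRUE)
  bonds <- if (n_atoms > 1)
    cbind(2:n_atoms, vapply(2:n_atoms, function(i) sample.int(i - 1L, 1L), 0L))
  else matrix(integer(0), ncol = 2)
  for (dummy in seq_len(extra_edges)) {
    if (n_atoms < 3) break
    cand <- sample.int(n_atoms, 2L)
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (cand[1] != cand[2] &&
        !(paste(min(cand), max(cand)) %in% key))
      bonds <- rbind(bonds, cand)
  }
  make_molgraph(elements, bonds)
}

graph_diameter <- function(graph) {
  n <- length(graph$elements)
  adj <- mnapred:::molgraph_adjacency(graph)
  ecc <- vapply(seq_len(n), function(s) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      nxt <- unique(unlist(adj[queue]))
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- dist[queue[[1]]] + 1L  # BFS layers: all in queue share depth
      queue <- nxt
    }
    max(dist)
  }, 0L)
  max(ecc)
}

dset_of <- function(items, level = 5L) {
  mnapred:::new_descriptor_set(mnapred:::sort_c(unique(items)),
                               as.integer(level), "key")
}

# random descriptor-set datasets for the classifier/validation tests
random_examples <- function(n, vocab_size = 12L, level = 5L,
                            p_item = 0.4, frac_path = 0.5) {
  vocab <- sprintf("d%02d", seq_len(vocab_size))
  labels <- rep(c("pathogenic", "benign"),
                c(ceiling(n * frac_path), n - ceiling(n * frac_path)))
  lapply(seq_len(n), function(i) {
    items <- vocab[stats::runif(vocab_size) < p_item]
    if (!length(items)) items <- sample(vocab, 1L)
    list(id = sprintf("ex%03d", i), dset = dset_of(items, level),
         label = labels[[i]])
  })
}

# O(n^2) pairwise oracle for the tie-corrected AUC
iap_brute <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

write_variants_csv <- function(variants, path) {
  cols <- c("gene", "position", "ref", "alt", "label", "allele_frequency")
  utils::write.csv(as.data.frame(variants)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  path
}

write_fasta <- function(protein, path) {
  writeLines(c(paste0(">", protein$gene), protein$sequence), path)
  path
}

write_gene_config_csv <- function(protein, path) {
  writeLines(c("gene,disease_frequency,omim_id,uniprot_id",
               paste(protein$gene, protein$disease_frequency %||% 1e-4,
                     "000000", "P00000", sep = ",")),
             path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
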