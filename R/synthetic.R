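# Synthetic ClinVar/gnomAD-style data: a random protein, missense variants
# whose ground truth follows a plantable motif rule (pathogenic iff the
# position lies in a damaging span AND the alternate residue is in a
# damaging set), label noise, and allele frequencies that make the
# benign-by-frequency supplementation rule exercisable.

#' Specification for the synthetic variant generator
#'
#' Defaults describe the package's reference simulation conditions: a
#' 180-residue random protein with a 45-residue damaging span (positions
#' 61-105), eight chemically drastic damaging alternates, 200 variants
#' drawn with clinical-ascertainment-style enrichment (45% of draws from
#' the pathogenic rule region, mirroring the near-balanced
#' pathogenic/benign composition of curated clinical sets), no label
#' noise, and log-normal allele frequencies (benign around 1e-3,
#' pathogenic around 1e-6) against a disease frequency of 1e-4.
#'
#' @param seq_length Protein length.
#' @param motif_start,motif_end 1-based inclusive damaging span.
#' @param damaging Character vector of damaging alternate residues.
#' @param n_variants Number of distinct variants to draw (>= 2).
#' @param label_noise Probability of flipping a true label, in \[0, 0.5).
#' @param ascertainment Fraction of variants drawn from the pathogenic
#'   rule region (positions in span x damaging alternates); `NULL` for
#'   uniform sampling over all (position, alternate) pairs.
#' @param unknown_fraction Fraction of benign-labeled variants emitted
#'   with label `unknown` (they keep their allele frequency, so
#'   [supplement_benign()] can recover them).
#' @param disease_frequency Disease frequency the generated protein
#'   carries, in (0, 1).
#' @param benign_af_meanlog,benign_af_sdlog,path_af_meanlog,path_af_sdlog
#'   Log-normal allele-frequency parameters per true class.
#' @param seed Integer seed; the generator is fully reproducible.
#' @param gene Gene symbol given to the synthetic protein.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seq_length = 180L, motif_start = 61L,
                           motif_end = 105L,
                           damaging = c("P", "G", "W", "C", "R", "D", "K", "F"),
                           n_variants = 200L, label_noise = 0,
                           ascertainment = 0.45, unknown_fraction = 0,
                           disease_frequency = 1e-4,
                           benign_af_meanlog = log(1e-3), benign_af_sdlog = 1,
                           path_af_meanlog = log(1e-6), path_af_sdlog = 1,
                           seed = 1L, gene = "SYN1") {
  spec <- list(seq_length = as.integer(seq_length),
               motif_start = as.integer(motif_start),
               motif_end = as.integer(motif_end),
               damaging = damaging, n_variants = as.integer(n_variants),
               label_noise = label_noise, ascertainment = ascertainment,
               unknown_fraction = unknown_fraction,
               disease_frequency = disease_frequency,
               benign_af_meanlog = benign_af_meanlog,
               benign_af_sdlog = benign_af_sdlog,
               path_af_meanlog = path_af_meanlog,
               path_af_sdlog = path_af_sdlog,
               seed = as.integer(seed), gene = gene)
  if (spec$seq_length < 5L) stop("seq_length too small", call. = FALSE)
  if (spec$motif_start < 1L || spec$motif_end > spec$seq_length ||
      spec$motif_start > spec$motif_end)
    stop("motif span must lie within the sequence", call. = FALSE)
  if (!all(is_standard_residue(spec$damaging)) || !length(spec$damaging))
    stop("damaging set must be non-empty standard residues", call. = FALSE)
  if (spec$n_variants < 2L) stop("n_variants must be >= 2", call. = FALSE)
  if (spec$label_noise < 0 || spec$label_noise >= 0.5)
    stop("label_noise must lie in [0, 0.5)", call. = FALSE)
  if (!is.null(spec$ascertainment) &&
      (spec$ascertainment <= 0 || spec$ascertainment >= 1))
    stop("ascertainment must lie in (0, 1) or be NULL", call. = FALSE)
  if (spec$unknown_fraction < 0 || spec$unknown_fraction > 1)
    stop("unknown_fraction must lie in [0, 1]", call. = FALSE)
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic protein and variant table
#'
#' Draws a random sequence over the 20-letter alphabet and `n_variants`
#' distinct (position, alternate) pairs; the true label is pathogenic iff
#' the position falls in the damaging span and the alternate is in the
#' damaging set, then flipped with probability `label_noise`. Allele
#' frequencies follow the true class so that true-benign variants tend to
#' exceed the disease frequency. Identical specs give byte-identical
#' output.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `protein` (a [protein_record()]) and `variants` (a
#'   `variant_table` with an extra `true_label` column).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  seq_chars <- sample(AA_ALPHABET, spec$seq_length, replace = TRUE)
  sequence <- paste(seq_chars, collapse = "")

  # all missense (position, alt) pairs, split by the pathogenic rule
  pos_all <- rep(seq_len(spec$seq_length), each = length(AA_ALPHABET))
  alt_all <- rep(AA_ALPHABET, times = spec$seq_length)
  keep <- alt_all != seq_chars[pos_all]
  pos_all <- pos_all[keep]; alt_all <- alt_all[keep]
  in_rule <- pos_all >= spec$motif_start & pos_all <= spec$motif_end &
    alt_all %in% spec$damaging

  n <- spec$n_variants
  pick <- if (is.null(spec$ascertainment)) {
    sample(length(pos_all), n)
  } else {
    n_rule <- min(round(n * spec$ascertainment), sum(in_rule))
    c(sample(which(in_rule), n_rule),
      sample(which(!in_rule), n - n_rule))
  }
  pos <- pos_all[pick]; alt <- alt_all[pick]
  truth <- in_rule[pick]

  flip <- stats::runif(n) < spec$label_noise
  observed <- xor(truth, flip)
  label <- ifelse(observed, "pathogenic", "benign")

  af <- ifelse(truth,
               stats::rlnorm(n, spec$path_af_meanlog, spec$path_af_sdlog),
               stats::rlnorm(n, spec$benign_af_meanlog, spec$benign_af_sdlog))
  af <- pmin(af, 1)

  if (spec$unknown_fraction > 0) {
    benign_rows <- which(label == "benign")
    n_unk <- round(length(benign_rows) * spec$unknown_fraction)
    if (n_unk > 0)
      label[sample(benign_rows, n_unk)] <- "unknown"
  }

  variants <- data.frame(
    gene = spec$gene, position = pos, ref = seq_chars[pos], alt = alt,
    label = label, allele_frequency = af,
    true_label = ifelse(truth, "pathogenic", "benign"),
    stringsAsFactors = FALSE
  )
  class(variants) <- c("variant_table", "data.frame")
  protein <- protein_record(spec$gene, sequence,
                            disease_frequency = spec$disease_frequency)
  list(protein = protein, variants = variants)
}
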