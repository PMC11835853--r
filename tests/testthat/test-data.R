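# Variant ingestion, curation rules, and the synthetic generator.

make_protein_set <- function() {
  list(GENE1 = protein_record("GENE1", "ACDEFGHIKLMNPQRSTVWY",
                              disease_frequency = 1e-4))
}

write_rows <- function(rows) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("gene,position,ref,alt,label,allele_frequency", rows), path)
  path
}

test_that("well-formed variant rows load in order", {
  path <- write_rows(c("GENE1,1,A,G,pathogenic,",
                       "GENE1,2,C,W,benign,0.001",
                       "GENE1,3,D,N,unknown,0.01"))
  v <- load_variants(path, make_protein_set())
  expect_equal(nrow(v), 3L)
  expect_equal(v$position, 1:3)
  expect_equal(v$label, c("pathogenic", "benign", "unknown"))
  expect_true(is.na(v$allele_frequency[1]))
})

test_that("non-missense and mismatching rows are rejected with diagnostics", {
  path <- write_rows(c("GENE1,1,A,A,pathogenic,",    # ref == alt
                       "GENE1,2,C,W,benign,0.001"))
  expect_warning(v <- load_variants(path, make_protein_set()),
                 "row 1 rejected.*not missense")
  expect_equal(nrow(v), 1L)

  path2 <- write_rows("GENE1,2,G,W,benign,")         # sequence has C at 2
  expect_warning(v2 <- load_variants(path2, make_protein_set()),
                 "table says 'G'.*sequence has 'C'")
  expect_equal(nrow(v2), 0L)

  path3 <- write_rows(c("GENE1,99,A,G,benign,",      # out of range
                       "GENE1,1,A,B,benign,",        # non-standard alt
                       "NOPE,1,A,G,benign,"))        # unknown gene
  suppressWarnings(expect_warning(v3 <- load_variants(path3, make_protein_set())))
  expect_equal(nrow(v3), 0L)
})

test_that("duplicate (gene, position, alt) rows keep the first occurrence", {
  path <- write_rows(c("GENE1,2,C,W,benign,0.001",
                       "GENE1,2,C,W,pathogenic,"))
  expect_warning(v <- load_variants(path, make_protein_set()), "duplicate")
  expect_equal(nrow(v), 1L)
  expect_equal(v$label, "benign")
})

test_that("missing required columns fail loudly", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("gene,position,ref", "GENE1,1,A"), path)
  expect_error(load_variants(path, make_protein_set()), "missing column")
})

test_that("benign supplementation uses a strict frequency inequality", {
  path <- write_rows(c("GENE1,1,A,G,unknown,0.0001",   # above 0.0000313
                       "GENE1,2,C,W,unknown,0.0000313",# exactly equal
                       "GENE1,3,D,N,unknown,0",        # zero frequency
                       "GENE1,4,E,K,unknown,",         # missing frequency
                       "GENE1,5,F,L,pathogenic,0.9"))  # labeled: untouched
  suppressWarnings(v <- load_variants(path, make_protein_set()))
  expect_warning(out <- supplement_benign(v, 0.0000313), "without allele")
  expect_equal(out$label, c("benign", "unknown", "unknown", "unknown",
                            "pathogenic"))
  expect_equal(out$supplemented, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_error(supplement_benign(v, 0), "strictly between")
})

test_that("the dataset gate sits exactly at the minimum count", {
  v74 <- data.frame(label = rep(c("pathogenic", "benign"), c(40, 34)))
  v75 <- data.frame(label = rep(c("pathogenic", "benign"), c(40, 35)))
  v_unknown <- data.frame(label = c(rep("pathogenic", 75), rep("unknown", 10)))
  expect_warning(expect_false(gate_min_variants(v74)), "74 labeled")
  expect_silent(expect_true(gate_min_variants(v75)))
  expect_true(gate_min_variants(v_unknown))   # unknowns don't count
  expect_warning(expect_false(gate_min_variants(v74[0, , drop = FALSE])))
})

test_that("the generator is reproducible and validates its spec", {
  spec <- synthetic_spec(seed = 31, n_variants = 50)
  a <- generate_synthetic(spec)
  b <- generate_synthetic(spec)
  expect_identical(a$protein$sequence, b$protein$sequence)
  expect_identical(a$variants, b$variants)

  expect_error(synthetic_spec(label_noise = 0.5), "label_noise")
  expect_error(synthetic_spec(n_variants = 1), "n_variants")
  expect_error(synthetic_spec(motif_start = 0), "motif span")
  expect_error(synthetic_spec(motif_end = 999), "motif span")
  expect_error(synthetic_spec(damaging = "X"), "damaging")
})

test_that("every generated variant matches its sequence and the label rule", {
  spec <- synthetic_spec(seed = 77, label_noise = 0)
  out <- generate_synthetic(spec)
  chars <- strsplit(out$protein$sequence, "")[[1]]
  v <- out$variants
  expect_true(all(chars[v$position] == v$ref))
  expect_true(all(v$ref != v$alt))
  expect_false(anyDuplicated(v[, c("position", "alt")]) > 0)
  in_rule <- v$position >= spec$motif_start & v$position <= spec$motif_end &
    v$alt %in% spec$damaging
  expect_identical(v$true_label, ifelse(in_rule, "pathogenic", "benign"))
  # no noise, no unknowns: observed labels equal the truth
  expect_identical(v$label, v$true_label)
})

test_that("uniform sampling recovers the analytic pathogenic fraction", {
  # motif covering 30% of positions, 5 damaging alternates: expected
  # pathogenic fraction 0.3 * 5/19 under uniform (position, alt) draws
  spec <- synthetic_spec(seq_length = 300, motif_start = 101, motif_end = 190,
                         damaging = c("P", "G", "W", "C", "R"),
                         n_variants = 200, label_noise = 0,
                         ascertainment = NULL, seed = 12)
  out <- generate_synthetic(spec)
  frac <- mean(out$variants$true_label == "pathogenic")
  expect_lt(abs(frac - 0.3 * 5 / 19), 0.05)
})

test_that("unknown-fraction output is recoverable by supplementation", {
  spec <- synthetic_spec(seed = 41, unknown_fraction = 0.3)
  out <- generate_synthetic(spec)
  expect_gt(sum(out$variants$label == "unknown"), 0)
  sup <- supplement_benign(out$variants, out$protein$disease_frequency)
  # benign allele frequencies center on 1e-3 >> disease frequency 1e-4,
  # so most unknowns come back as benign
  expect_gt(sum(sup$supplemented), 0.5 * sum(out$variants$label == "unknown"))
  expect_true(all(sup$label[out$variants$label == "pathogenic"] == "pathogenic"))
})
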