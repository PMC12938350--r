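test_that("feature-table rows parse with markup, dash variants and separators", {
  txt <- paste(
    "Gene\tStrand\tLocation\tSize(bp)\tIntergenics Length\tAnticodon\tAminoAcids\tStartCodon\tStopCodon",
    "*tRNA^Leu^*\t+\t2773–2846\t74\t600\tTAA\t\t\t",
    "*tRNA^Phe^*\t+\t1–68\t68\t0\tGAA\t\t\t",
    "*ND4*\t+\t11,425–12,805\t1381\t0\t\t460\tATG\tT-",
    sep = "\n")
  rec <- parse_feature_table(txt, genome_length = 17485, species_id = "x")
  f <- rec$features
  leu <- f[f$base_name == "tRNA-Leu", ]
  expect_equal(leu$strand, "+")
  expect_equal(c(leu$start, leu$end), c(2773L, 2846L))
  phe <- f[f$base_name == "tRNA-Phe", ]
  expect_equal(c(phe$start, phe$end, phe$anticodon), c("1", "68", "GAA"))
  expect_equal(f[f$base_name == "ND4", "start"], 11425L)
  expect_equal(f[f$base_name == "ND4", "aa_count"], 460L)
  expect_equal(f[f$base_name == "tRNA-Phe", "amino_acid"], "F")
})

test_that("header-only input gives an empty record; bad rows name the row", {
  rec <- parse_feature_table("Gene\tStrand\tLocation\tSize(bp)",
                             genome_length = 100, species_id = "empty")
  expect_equal(nrow(rec$features), 0)
  expect_equal(unname(gene_counts(rec)["tRNA"]), 0L)

  bad_loc <- "Gene\tStrand\tLocation\nND1\t+\tnot-a-span"
  expect_error(parse_feature_table(bad_loc, 100, "x"), "row 1")
  bad_gene <- "Gene\tStrand\tLocation\nNOTAGENE\t+\t1-10"
  expect_error(parse_feature_table(bad_gene, 100, "x"), "accepted labels")
})

test_that("gene_size handles plain, single-base, and origin-wrapping features", {
  expect_equal(gene_size(2773, 2846, 17485), 74L)
  expect_equal(gene_size(5, 5, 100), 1L)
  expect_equal(gene_size(95, 4, 100, wraps_origin = TRUE),
               oracle_span_size(95, 4, 100, TRUE))
  expect_equal(gene_size(95, 4, 100, wraps_origin = TRUE), 10L)
})

test_that("intergenic_spacer reproduces gaps, overlaps, abutment and wrap", {
  expect_equal(intergenic_spacer(2846, 3447, 17485), 600L)
  expect_equal(intergenic_spacer(9185, 9176, 17485), -10L)
  expect_equal(intergenic_spacer(100, 101, 17485), 0L)
  expect_equal(intergenic_spacer(17480, 3, 17485, wrap = TRUE), 7L)
  expect_error(intergenic_spacer(90, 5, 100, circular = FALSE, wrap = TRUE),
               "non-circular")
})

test_that("sizes plus spacers telescope to the genome length on full annotations", {
  for (s in c(2, 11)) {
    sim <- generate_record(generator_spec(seed = s))
    tot <- sum(feature_sizes(sim$record)) + sum(intergenic_spacers(sim$record))
    expect_identical(as.integer(tot), sim$record$genome_length)
  }
})

test_that("duplicate labels get ordinal suffixes and keep anticodons", {
  fx <- liparis_fixtures()
  f <- fx$tanakae$features
  ala <- f[grepl("^tRNA-Ala", f$name), ]
  expect_equal(ala$name, c("tRNA-Ala-1", "tRNA-Ala-2"))
  expect_equal(ala$anticodon, c("TGC", "TGC"))
})

test_that("validator flags the published annotation inconsistencies as data", {
  fx <- liparis_fixtures()
  expect_s3_class(validate_record(fx$tanakae), "validation_report")
  expect_equal(nrow(validate_record(fx$tanakae)), 0)

  v <- validate_record(fx$chefuensis)
  expect_true(any(v$rule == "aa-mismatch" & v$feature == "ND4"))
  expect_true(any(v$rule == "spacer-mismatch" & v$feature == "ATPase8" &
                    v$expected == "-10" & v$observed == "-8"))
  expect_true(any(v$rule == "spacer-mismatch" & v$feature == "ND5" &
                    v$expected == "-4" & v$observed == "-2"))
  # the Tyr/Ala/Asn/Cys anticodons are permuted relative to the standard set
  nonstd <- v[v$rule == "anticodon-nonstandard", "feature"]
  expect_setequal(nonstd, c("tRNA-Tyr", "tRNA-Ala", "tRNA-Asn", "tRNA-Cys"))
})

test_that("generated records validate clean and round-trip through TSV and JSON", {
  sim <- generate_record(generator_spec(seed = 4))
  expect_equal(nrow(validate_record(sim$record)), 0)

  tsv <- write_feature_table(sim$record)
  rt <- parse_feature_table(tsv, sim$record$genome_length,
                            sim$record$species_id)
  expect_equal(rt$features, sim$record$features)

  p <- file.path(tempdir(), "rec.json")
  write_record(sim$record, p)
  back <- read_record(p)
  expect_equal(back$features, sim$record$features)
  expect_identical(back$sequence, sim$record$sequence)
  expect_identical(back$genome_length, sim$record$genome_length)
})

test_that("genbank flat files parse, round-trip, and support origin-spanning joins", {
  rec <- parse_genbank(tiny_genbank_text())
  expect_equal(nrow(rec$features), 2)
  expect_equal(rec$genome_length, 120L)
  expect_true(rec$circular)
  expect_equal(rec$features$strand, c("+", "-"))
  expect_equal(nchar(rec$sequence), 120L)

  p <- file.path(tempdir(), "roundtrip.gb")
  write_genbank(rec, p)
  back <- parse_genbank(p)
  expect_equal(back$features, rec$features)
  expect_identical(back$sequence, rec$sequence)

  wrap_txt <- sub("     tRNA            1..40",
                  "     tRNA            join(110..120,1..29)",
                  tiny_genbank_text(), fixed = TRUE)
  wrec <- parse_genbank(wrap_txt)
  tr <- wrec$features[wrec$features$category == "tRNA", ]
  expect_true(tr$wraps_origin)
  expect_equal(gene_size(tr$start, tr$end, 120, tr$wraps_origin),
               oracle_span_size(110, 29, 120, TRUE))

  noseq <- sub("(?s)ORIGIN.*//", "//", tiny_genbank_text(), perl = TRUE)
  expect_warning(r2 <- parse_genbank(noseq), "sequence-less")
  expect_null(r2$sequence)
})

test_that("strand orientation is applied only at sequence extraction", {
  feats <- data.frame(name = "ND1", base_name = "ND1", category = "PCG",
                      strand = "-", start = 3, end = 8,
                      stringsAsFactors = FALSE)
  rec <- mitogenome_record("t", 10, feats, sequence = "AACCCGGGTT")
  expect_equal(feature_sequence(rec, "ND1"), revcomp("CCCGGG"))
  expect_equal(feature_sequence(rec, "ND1"), "CCCGGG")
})
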