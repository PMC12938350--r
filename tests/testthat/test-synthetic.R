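test_that("generation is deterministic in the seed", {
  a <- generate_record(generator_spec(seed = 5))
  b <- generate_record(generator_spec(seed = 5))
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$record$features, b$record$features)
  c <- generate_record(generator_spec(seed = 6))
  expect_false(identical(a$record$sequence, c$record$sequence))
})

test_that("generated annotations are internally consistent", {
  sim <- generate_record(generator_spec(seed = 14))
  expect_equal(nrow(validate_record(sim$record)), 0)
  counts <- gene_counts(sim$record)
  expect_equal(unname(counts["PCG"]), 13L)
  expect_equal(unname(counts["rRNA"]), 2L)
})

test_that("requested cluster pattern appears by construction", {
  for (pat in c("WANCY", "WYANC", "WNCYAC", "WNCYAA")) {
    sim <- generate_record(generator_spec(seed = 30, pattern = pat))
    expect_identical(classify_pattern(extract_cluster(sim$record)),
                     pat, label = pat)
    expect_identical(sim$ledger$pattern, pat)
  }
})

test_that("duplicate-bearing patterns raise the tRNA count", {
  base <- gene_counts(generate_record(generator_spec(seed = 1))$record)
  dup <- gene_counts(generate_record(
    generator_spec(seed = 1, pattern = "WNCYAA"))$record)
  expect_identical(unname(dup["tRNA"] - base["tRNA"]), 1L)
})

test_that("composition targets and skews are recovered within tolerance", {
  for (s in c(3, 7, 21, 33, 40)) {
    spec <- generator_spec(seed = s)
    sim <- generate_record(spec)
    planted <- sim$ledger$realized_counts
    for (region in names(planted)) {
      tgt <- sim$ledger$composition_targets[[region]]
      real <- planted[[region]]
      fr <- real / sum(real)
      tg <- gc_skew(tgt[["G"]], tgt[["C"]])
      rg <- gc_skew(fr[["G"]], fr[["C"]])
      expect_lt(abs(tg - rg), 0.02,
                label = paste("gc_skew", region, "seed", s))
      ta <- at_skew(tgt[["A"]], tgt[["T"]])
      ra <- at_skew(fr[["A"]], fr[["T"]])
      expect_lt(abs(ta - ra), 0.02,
                label = paste("at_skew", region, "seed", s))
    }
  }
})

test_that("planted stop codons and lengths survive re-analysis", {
  sim <- generate_record(generator_spec(seed = 18))
  f <- sim$record$features
  pcg <- f[f$category == "PCG", ]
  for (i in seq_len(nrow(pcg))) {
    size <- gene_size(pcg$start[i], pcg$end[i], sim$record$genome_length,
                      pcg$wraps_origin[i])
    expect_equal(pcg$aa_count[i],
                 amino_acid_length(size, pcg$stop_codon[i]),
                 label = pcg$name[i])
  }
  # the ledger records exactly what was planted
  lp <- sim$ledger$pcg
  expect_setequal(names(lp), pcg$name)
  for (nm in names(lp)) {
    expect_equal(lp[[nm]]$aa_count,
                 pcg$aa_count[pcg$name == nm], label = nm)
  }
})

test_that("third-position A/T bias shows up in codon usage", {
  sim <- generate_record(generator_spec(seed = 25, codon_at_bias = 2))
  u <- compute_rscu(codon_counts(extract_cds(sim$record)))
  sense <- u[u$family_size > 1 & !u$zero_family, ]
  third <- substr(sense$codon, 3, 3)
  expect_gt(mean(sense$rscu[third %in% c("A", "T")]),
            mean(sense$rscu[third %in% c("G", "C")]))
})

test_that("infeasible specifications fail loudly", {
  expect_error(generate_record(generator_spec(seed = 1,
                                              genome_length = 12000)),
               "infeasible")
  expect_error(generator_spec(seed = 1,
                              composition = list(PCGs = c(T = 0.5, C = 0.5,
                                                          A = 0.5, G = 0.5))),
               "sum to 1")
  expect_error(generator_spec(seed = 1, pattern = "WXY"), "letters")
  expect_error(generator_spec(seed = 1, gu_per_trna = 15, ac_per_trna = 10),
               "21")
})

test_that("written synthetic bundles reload to the same record", {
  sim <- generate_record(generator_spec(seed = 28))
  d <- file.path(tempdir(), "synth_out")
  paths <- write_synthetic(sim, d)
  expect_true(all(file.exists(paths)))
  back <- parse_feature_table(paths[["table"]],
                              genome_length = sim$record$genome_length,
                              species_id = sim$record$species_id)
  expect_equal(back$features, sim$record$features)
  fa <- seqinr::read.fasta(paths[["fasta"]], as.string = TRUE,
                           seqonly = TRUE)
  expect_identical(toupper(fa[[1]]), sim$record$sequence)
})

test_that("analysis pipeline recovers planted truths across many seeds", {
  for (s in 101:120) {
    spec <- generator_spec(seed = s,
                           pattern = c("WANCY", "WYANC",
                                       "WNCYAC", "WNCYAA")[(s %% 4) + 1])
    sim <- generate_record(spec)
    expect_identical(classify_pattern(extract_cluster(sim$record)),
                     sim$ledger$pattern, label = paste("seed", s))
    expect_equal(nrow(validate_record(sim$record)), 0,
                 label = paste("seed", s))
    tot <- sum(feature_sizes(sim$record)) +
      sum(intergenic_spacers(sim$record))
    expect_identical(as.integer(tot), sim$record$genome_length)
  }
})
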