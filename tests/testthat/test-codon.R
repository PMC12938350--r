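test_that("amino_acid_length handles complete and incomplete stops", {
  expect_equal(amino_acid_length(1046, "TA-"), 348L)
  expect_equal(amino_acid_length(1141, "T-"), 380L)
  expect_equal(amino_acid_length(975, "TAA"), 324L)
  expect_equal(amino_acid_length(1545, "TAA"), 514L)
  expect_error(amino_acid_length(1382, "T-"), "frame")
})

test_that("the genetic code agrees with seqinr's vertebrate-mitochondrial table", {
  code <- mito_genetic_code()
  for (cdn in all_codons()) {
    ref <- seqinr::translate(strsplit(tolower(cdn), "")[[1]], numcode = 2)
    expect_identical(unname(code[cdn]), ref, label = paste("codon", cdn))
  }
  expect_setequal(mito_stop_codons(), c("TAA", "TAG", "AGA", "AGG"))
})

test_that("RSCU matches a direct per-family recomputation", {
  # uniform usage within every family gives RSCU 1 everywhere
  counts <- setNames(rep(3L, 64), all_codons())
  u <- compute_rscu(counts)
  expect_equal(nrow(u), 60)          # stop codons excluded
  expect_true(all(abs(u$rscu - 1) < 1e-12))

  # documented example: all usage on one codon of a 2-codon family
  ex <- compute_rscu(c(TTT = 10, TTC = 0))
  expect_equal(ex$rscu[ex$codon == "TTT"], 2)
  expect_equal(ex$rscu[ex$codon == "TTC"], 0)

  set.seed(19)
  counts <- setNames(sample(0:40, 64, replace = TRUE), all_codons())
  u <- compute_rscu(counts)
  code <- mito_genetic_code()
  for (r in seq_len(nrow(u))) {
    cdn <- u$codon[r]
    fam <- setdiff(names(code)[code == code[cdn]], mito_stop_codons())
    tot <- sum(counts[fam])
    expected <- if (tot == 0) 0 else counts[[cdn]] * length(fam) / tot
    expect_equal(u$rscu[r], expected, label = cdn)
    expect_equal(u$family_size[r], length(fam), label = cdn)
  }
})

test_that("zero-count families are flagged instead of dividing by zero", {
  # ATG and ATA form the 2-fold Met family under the vertebrate
  # mitochondrial code, so all usage on ATG gives it RSCU 2
  u <- compute_rscu(c(ATG = 5))
  met <- u$amino_acid == "M"
  expect_setequal(u$codon[met], c("ATG", "ATA"))
  expect_true(all(u$zero_family[!met]))
  expect_true(all(!u$zero_family[met]))
  expect_equal(u$rscu[u$codon == "ATG"], 2)
  expect_equal(u$rscu[u$codon == "ATA"], 0)
  expect_true(all(u$rscu[u$zero_family] == 0))
  expect_error(compute_rscu(c(ATG = -1)), "negative")
})

test_that("extract_cds completes incomplete stops and strips terminators", {
  sim <- generate_record(generator_spec(seed = 6))
  cds <- extract_cds(sim$record)
  sizes <- feature_sizes(sim$record)
  f <- sim$record$features
  code <- mito_genetic_code()
  for (g in names(cds)) {
    stop_tok <- f$stop_codon[f$name == g]
    expect_identical(length(cds[[g]]$codons),
                     as.integer(amino_acid_length(sizes[[g]], stop_tok)),
                     label = g)
    aa <- code[cds[[g]]$codons]
    expect_false(any(aa == "*"), label = g)
  }
})

test_that("a hand-built minus-strand CDS is read off the coding strand", {
  # coding strand: ATG GCC TAA (Met-Ala-stop), reverse-complemented on plus
  coding <- "ATGGCCTAA"
  plus <- revcomp(coding)
  seqn <- paste0("TT", plus, "GG")
  feats <- data.frame(name = "ND6", base_name = "ND6", category = "PCG",
                      strand = "-", start = 3, end = 11,
                      start_codon = "ATG", stop_codon = "TAA",
                      stringsAsFactors = FALSE)
  rec <- mitogenome_record("t", nchar(seqn), feats, sequence = seqn)
  cds <- extract_cds(rec)
  expect_identical(cds[["ND6"]]$codons, c("ATG", "GCC"))
  expect_identical(cds[["ND6"]]$start_codon, "ATG")
  cc <- codon_counts(cds)
  expect_equal(unname(cc["ATG"]), 1L)
  expect_equal(unname(cc["GCC"]), 1L)
  expect_equal(sum(cc), 2L)
})

test_that("internal stop codons trigger a warning naming the gene", {
  seqn <- paste0("ATG", "TAA", "GCC", "TAG")
  feats <- data.frame(name = "ND1", base_name = "ND1", category = "PCG",
                      strand = "+", start = 1, end = 12,
                      start_codon = "ATG", stop_codon = "TAG",
                      stringsAsFactors = FALSE)
  rec <- mitogenome_record("t", 12, feats, sequence = seqn)
  expect_warning(extract_cds(rec), "ND1")
})

test_that("PCG concatenation follows canonical order and sums trimmed lengths", {
  sims <- lapply(c(12, 13), function(s) generate_record(generator_spec(seed = s)))
  recs <- lapply(sims, `[[`, "record")
  cat1 <- concatenate_pcgs(recs[[1]])
  f <- recs[[1]]$features
  pcg <- f[f$category == "PCG", ]
  exp_len <- sum(sapply(seq_len(nrow(pcg)), function(i)
    3 * amino_acid_length(gene_size(pcg$start[i], pcg$end[i],
                                    recs[[1]]$genome_length,
                                    pcg$wraps_origin[i]),
                          pcg$stop_codon[i])))
  expect_equal(nchar(cat1[[1]]), exp_len)
  # the concatenation starts with ND1's start codon (canonical order)
  nd1 <- extract_cds(recs[[1]])[["ND1"]]
  expect_identical(substr(cat1[[1]], 1, 3), nd1$start_codon)

  both <- concatenate_pcgs(recs)
  expect_length(both, 2L)
  expect_identical(names(both),
                   vapply(recs, `[[`, character(1), "species_id"))

  # a record missing a PCG is an error naming the gene
  drop <- recs[[2]]
  drop$features <- drop$features[drop$features$base_name != "ND6", ]
  expect_error(concatenate_pcgs(list(drop)), "ND6")
})

test_that("codon usage tables round-trip through the writer", {
  sim <- generate_record(generator_spec(seed = 9))
  u <- compute_rscu(codon_counts(extract_cds(sim$record)))
  p <- file.path(tempdir(), "rscu.tsv")
  write_rscu(u, p)
  back <- utils::read.delim(p, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(u))
  expect_equal(back$codon, u$codon)
  expect_equal(back$rscu, u$rscu, tolerance = 1e-9)
})

test_that("amino-acid usage attribute sums to the codon total", {
  sim <- generate_record(generator_spec(seed = 10))
  counts <- codon_counts(extract_cds(sim$record))
  u <- compute_rscu(counts)
  aa <- attr(u, "aa_usage")
  expect_equal(sum(aa$count), sum(u$count))
  expect_equal(sum(aa$frequency), 1, tolerance = 1e-12)
})
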