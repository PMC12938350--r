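# Synthetic annotated mitogenome generator with known ground truth.
#
# Records are built gene by gene from per-region composition targets; PCG
# sequences are drawn codon-wise from the sense codons of the vertebrate
# mitochondrial code (so no internal stops arise), started and stopped with
# the requested codons; tRNAs are emitted as cloverleaf stems with planted
# G-U / A-C pair counts and an accompanying dot-bracket string. The returned
# ground-truth ledger stores realized (not target) quantities so pipeline
# recovery tests can be exact.

.CLUSTER_TRNA <- data.frame(
  letter = c("W", "A", "N", "C", "Y"),
  name = c("tRNA-Trp", "tRNA-Ala", "tRNA-Asn", "tRNA-Cys", "tRNA-Tyr"),
  strand = c("+", "-", "-", "-", "-"),
  stringsAsFactors = FALSE
)

.DEFAULT_STOPS <- c(
  ND1 = "TAA", ND2 = "TA-", COXI = "TAA", COXII = "T-", ATPase8 = "TAA",
  ATPase6 = "TA-", COXIII = "TA-", ND3 = "T-", ND4L = "TAA", ND4 = "T-",
  ND5 = "TAA", ND6 = "TAA", Cytb = "T-"
)

.PCG_SIZES <- c(
  ND1 = 975, ND2 = 1046, COXI = 1545, COXII = 691, ATPase8 = 168,
  ATPase6 = 683, COXIII = 785, ND3 = 349, ND4L = 297, ND4 = 1381,
  ND5 = 1839, ND6 = 522, Cytb = 1141
)

.PCG_STRAND <- c(
  ND1 = "+", ND2 = "+", COXI = "+", COXII = "+", ATPase8 = "+",
  ATPase6 = "+", COXIII = "+", ND3 = "+", ND4L = "+", ND4 = "+",
  ND5 = "+", ND6 = "-", Cytb = "+"
)

# default composition targets per region (proportions T, C, A, G), set to
# values typical of a snailfish mitogenome
.DEFAULT_COMPOSITION <- list(
  PCGs = c(T = 0.33, C = 0.27, A = 0.26, G = 0.14),
  rRNA = c(T = 0.23, C = 0.25, A = 0.33, G = 0.19),
  tRNA = c(T = 0.28, C = 0.20, A = 0.30, G = 0.22),
  control = c(T = 0.32, C = 0.14, A = 0.43, G = 0.11)
)

#' Specification for the synthetic mitogenome generator
#'
#' @param seed integer seed governing every random draw
#' @param genome_length target total length in bp; the control region absorbs
#'   the slack after all genes are placed
#' @param pattern cluster order between ND2 and COI: one of the named pattern
#'   labels or any custom string over the letters W, A, N, C, Y
#' @param composition list of per-region base-proportion targets (names
#'   PCGs, rRNA, tRNA, control; each a T/C/A/G vector summing to 1)
#' @param codon_at_bias multiplicative weight for A/T-ending sense codons,
#'   emulating the A/T third-position preference of fish mitogenomes
#' @param gu_per_trna,ac_per_trna number of G-U wobble and A-C pairs planted
#'   in each tRNA's 21 stem pairs
#' @param stop_codons named vector of stop tokens per PCG
#' @return list of class \code{generator_spec}
#' @export
generator_spec <- function(seed = 1, genome_length = 16800,
                           pattern = "WANCY",
                           composition = .DEFAULT_COMPOSITION,
                           codon_at_bias = 2,
                           gu_per_trna = 1, ac_per_trna = 0,
                           stop_codons = .DEFAULT_STOPS) {
  comp <- utils::modifyList(.DEFAULT_COMPOSITION, composition)
  for (r in names(comp)) {
    comp[[r]] <- comp[[r]][c("T", "C", "A", "G")]
    if (abs(sum(comp[[r]]) - 1) > 1e-6) {
      stop("composition proportions for region ", r, " must sum to 1")
    }
  }
  pat <- strsplit(toupper(pattern), "")[[1]]
  if (!all(pat %in% .CLUSTER_TRNA$letter)) {
    stop("cluster pattern letters must come from W, A, N, C, Y")
  }
  if (gu_per_trna + ac_per_trna > 21) {
    stop("requested G-U + A-C pairs exceed the 21 stem pairs of a tRNA")
  }
  stops <- utils::modifyList(as.list(.DEFAULT_STOPS), as.list(stop_codons))
  structure(list(seed = seed, genome_length = genome_length,
                 pattern = pat, composition = comp,
                 codon_at_bias = codon_at_bias,
                 gu_per_trna = gu_per_trna, ac_per_trna = ac_per_trna,
                 stop_codons = unlist(stops)),
            class = "generator_spec")
}

# Deterministic largest-remainder quantization of n draws over probs; the
# realized counts differ from n * probs by less than one per category, so
# region composition recovers its target up to rounding rather than up to
# multinomial sampling noise.
.quantize_counts <- function(n, probs) {
  probs <- probs / sum(probs)
  raw <- n * probs
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    up <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[up] <- counts[up] + 1
  }
  stats::setNames(as.integer(counts), names(probs))
}

# n bases with quantized composition in random order
.sample_bases <- function(n, probs) {
  if (n == 0) return("")
  counts <- .quantize_counts(n, probs)
  paste(sample(rep(names(counts), counts)), collapse = "")
}

# Codon weights over the 60 sense codons whose marginal base composition
# matches the target while keeping the third-position A/T preference.
# Excluding the four stop codons (and the bias itself) perturbs the base
# marginals, so a multiplicative per-base correction is fitted iteratively;
# failure to converge means the requested composition cannot be realized
# with sense codons.
.codon_weights <- function(probs, at_bias, tol = 1e-9, max_iter = 500) {
  code <- mito_genetic_code()
  sense <- names(code)[code != "*"]
  b <- do.call(rbind, strsplit(sense, ""))
  base_w <- vapply(seq_len(nrow(b)), function(i) prod(probs[b[i, ]]),
                   numeric(1))
  base_w <- base_w * ifelse(b[, 3] %in% c("A", "T"), at_bias, 1)
  corr <- c(T = 1, C = 1, A = 1, G = 1)
  for (it in seq_len(max_iter)) {
    w <- base_w * corr[b[, 1]] * corr[b[, 2]] * corr[b[, 3]]
    w <- w / sum(w)
    marg <- vapply(names(corr), function(bb)
      sum(w * rowSums(b == bb)) / 3, numeric(1))
    if (max(abs(marg - probs)) < tol) {
      return(stats::setNames(w, sense))
    }
    corr <- corr * (probs / pmax(marg, 1e-12))^0.5
  }
  stop("infeasible spec: composition targets incompatible with the sense ",
       "codons of the vertebrate mitochondrial code")
}

.count_bases <- function(strings) {
  chars <- strsplit(paste(strings, collapse = ""), "")[[1]]
  vapply(c(T = "T", C = "C", A = "A", G = "G"),
         function(b) sum(chars == b), integer(1))
}

# One pooled multiset of body codons for all PCGs: the region's base counts
# are quantized to the target, the fixed start/stop bases are subtracted,
# codon weights are refitted to the remaining composition, and the codon
# counts themselves are quantized. The shuffled pool is then dealt to the
# genes, so the realized aggregate PCG composition matches the target up to
# rounding while third-position A/T bias is retained.
.pcg_codon_pool <- function(sizes, starts, stop_tokens, probs, at_bias) {
  stop_seqs <- gsub("-", "", stop_tokens, fixed = TRUE)
  n_body <- (sizes - nchar(stop_seqs)) / 3 - 1
  if (any(n_body < 1)) stop("PCG size too small for a body codon")
  region_total <- sum(sizes)
  desired <- .quantize_counts(region_total, probs)
  fixed <- .count_bases(c(starts, stop_seqs))
  body_target <- pmax(desired - fixed, 0)
  codon_w <- .codon_weights(body_target / sum(body_target), at_bias)
  pool_counts <- .quantize_counts(sum(n_body), codon_w)
  pool <- sample(rep(names(pool_counts), pool_counts))
  out <- vector("list", length(sizes))
  at <- 1L
  for (g in seq_along(sizes)) {
    take <- pool[at:(at + n_body[g] - 1)]
    at <- at + as.integer(n_body[g])
    out[[g]] <- paste0(starts[g], paste(take, collapse = ""), stop_seqs[g])
  }
  stats::setNames(out, names(sizes))
}

# Cloverleaf tRNA generation is split in two phases so the loop bases can
# compensate the composition constraint the stems impose (a Watson-Crick
# pair always contributes one base and its complement, so stems alone can
# never realize a G/C- or A/T-skewed target): first the 21 stem pairs per
# tRNA are drawn with the planted G-U / A-C counts, then the loop bases of
# all tRNAs are allocated as one quantized pool topping the region up to its
# composition target.

# 21 stem pairs (acceptor 7, D 4, anticodon 5, T 5) with planted classes
.gen_trna_stems <- function(n_gu, n_ac, probs) {
  n_pairs <- 21
  cls <- sample(c(rep("GU", n_gu), rep("AC", n_ac),
                  rep("WC", n_pairs - n_gu - n_ac)))
  pair_of <- function(kind) {
    switch(kind,
           WC = {
             five <- sample(c("G", "C", "A", "T"), 1,
                            prob = probs[c("G", "C", "A", "T")])
             c(five, chartr("GCAT", "CGTA", five))
           },
           GU = if (stats::runif(1) < 0.5) c("G", "T") else c("T", "G"),
           AC = if (stats::runif(1) < 0.5) c("A", "C") else c("C", "A"))
  }
  lapply(cls, pair_of)
}

# assemble one tRNA from its stems, anticodon, and 24 allocated loop bases:
# D loop 8, anticodon loop 2+2 around the anticodon, variable arm 4,
# T loop 7, discriminator 1; returns sequence + dot-bracket (69 nt)
.assemble_trna <- function(pairs, anticodon, loop_bases) {
  take <- function(k) {
    out <- pairs[seq_len(k)]
    pairs <<- pairs[-seq_len(k)]
    out
  }
  acc <- take(7); dst <- take(4); ast <- take(5); tst <- take(5)
  five <- function(p) paste(vapply(p, `[`, character(1), 1), collapse = "")
  three <- function(p) paste(rev(vapply(p, `[`, character(1), 2)),
                             collapse = "")
  lb <- loop_bases
  grab <- function(n) {
    out <- paste(lb[seq_len(n)], collapse = "")
    lb <<- lb[-seq_len(n)]
    out
  }
  d_loop <- grab(8)
  ac_loop <- paste0(grab(2), anticodon, grab(2))
  var_arm <- grab(4)
  t_loop <- grab(7)
  disc <- grab(1)
  seqs <- c(five(acc), five(dst), d_loop, three(dst),
            five(ast), ac_loop, three(ast), var_arm,
            five(tst), t_loop, three(tst), three(acc), disc)
  db <- c(strrep("(", 7), strrep("(", 4), strrep(".", 8), strrep(")", 4),
          strrep("(", 5), strrep(".", 7), strrep(")", 5), strrep(".", 4),
          strrep("(", 5), strrep(".", 7), strrep(")", 5), strrep(")", 7),
          ".")
  list(sequence = paste(seqs, collapse = ""),
       dot_bracket = paste(db, collapse = ""))
}

# loop-base pool for all tRNAs: region target counts minus the bases already
# fixed by stems and anticodons, adjusted to the exact pool size
.trna_loop_pool <- function(n_trna, stem_ac_bases, probs) {
  pool_size <- 24L * n_trna
  desired <- .quantize_counts(69L * n_trna, probs)
  counts <- pmax(desired - stem_ac_bases, 0L)
  diff <- pool_size - sum(counts)
  while (diff != 0) {
    if (diff > 0) {
      i <- which.max(desired - stem_ac_bases - counts)
      counts[i] <- counts[i] + 1L
      diff <- diff - 1L
    } else {
      i <- which.max(counts)
      counts[i] <- counts[i] - 1L
      diff <- diff + 1L
    }
  }
  sample(rep(names(counts), counts))
}

.NONCLUSTER_TRNAS <- data.frame(
  name = c("tRNA-Phe", "tRNA-Val", "tRNA-Leu", "tRNA-Ile", "tRNA-Gln",
           "tRNA-Met", "tRNA-Ser", "tRNA-Asp", "tRNA-Lys", "tRNA-Gly",
           "tRNA-Arg", "tRNA-His", "tRNA-Ser", "tRNA-Leu", "tRNA-Glu",
           "tRNA-Thr", "tRNA-Pro"),
  anticodon = c("GAA", "TAC", "TAA", "GAT", "TTG", "CAT", "TGA", "GTC",
                "TTT", "TCC", "TCG", "GTG", "GCT", "TAG", "TTC", "TGT",
                "TGG"),
  strand = c("+", "+", "+", "+", "-", "+", "-", "+", "+", "+", "+", "+",
             "+", "+", "-", "+", "-"),
  stringsAsFactors = FALSE
)

.STD_TRNA_ANTICODON_BY_BASE <- c(
  "tRNA-Trp" = "TCA", "tRNA-Ala" = "TGC", "tRNA-Asn" = "GTT",
  "tRNA-Cys" = "GCA", "tRNA-Tyr" = "GTA"
)

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Builds a circular record with 13 PCGs, 2 rRNAs, 22 or 23 tRNAs (depending
#' on the requested ND2-COI cluster pattern), an origin of light-strand
#' replication inside the cluster, and a control region absorbing the slack
#' up to the target genome length. All features abut (zero spacers), so the
#' sizes and spacers telescope exactly to the genome length.
#'
#' @param spec a \code{generator_spec}
#' @return list of class \code{synthetic_mitogenome} with elements
#'   \code{record} (a \code{mitogenome_record} with sequence) and
#'   \code{ledger} (ground truth: pattern, per-region composition targets and
#'   realized strand-oriented counts, per-PCG start/stop/aa counts, per-tRNA
#'   structures and planted pair counts)
#' @export
generate_record <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  comp <- spec$composition
  plan <- list()  # each: name, category, strand, gene_seq (oriented), extras
  add <- function(name, category, strand, gene_seq, anticodon = NA,
                  start_codon = NA, stop_codon = NA, aa_count = NA,
                  dot_bracket = NULL) {
    plan[[length(plan) + 1]] <<- list(
      name = name, category = category, strand = strand, gene_seq = gene_seq,
      anticodon = anticodon, start_codon = start_codon,
      stop_codon = stop_codon, aa_count = aa_count, dot_bracket = dot_bracket)
  }
  # tRNA phase 1: stems now, loop bases allocated after all tRNAs are known
  trna_parts <- list()
  add_trna <- function(name, anticodon, strand) {
    trna_parts[[length(trna_parts) + 1]] <<- list(
      name = name, anticodon = anticodon,
      stems = .gen_trna_stems(spec$gu_per_trna, spec$ac_per_trna, comp$tRNA))
    add(name, "tRNA", strand, NA_character_, anticodon = anticodon)
  }
  pcg_starts <- stats::setNames(
    ifelse(names(.PCG_SIZES) == "COXI", "GTG", "ATG"), names(.PCG_SIZES))
  pcg_seqs <- .pcg_codon_pool(.PCG_SIZES, pcg_starts,
                              spec$stop_codons[names(.PCG_SIZES)],
                              comp$PCGs, spec$codon_at_bias)
  add_pcg <- function(name) {
    stop_tok <- spec$stop_codons[[name]]
    add(name, "PCG", .PCG_STRAND[[name]], pcg_seqs[[name]],
        start_codon = pcg_starts[[name]], stop_codon = stop_tok,
        aa_count = amino_acid_length(.PCG_SIZES[[name]], stop_tok))
  }

  nc <- .NONCLUSTER_TRNAS
  add_trna(nc$name[1], nc$anticodon[1], nc$strand[1])              # Phe
  add("12S-rRNA", "rRNA", "+", .sample_bases(950, comp$rRNA))
  add_trna(nc$name[2], nc$anticodon[2], nc$strand[2])              # Val
  add("16S-rRNA", "rRNA", "+", .sample_bases(1680, comp$rRNA))
  add_trna(nc$name[3], nc$anticodon[3], nc$strand[3])              # Leu(UUR)
  add_pcg("ND1")
  add_trna(nc$name[4], nc$anticodon[4], nc$strand[4])              # Ile
  add_trna(nc$name[5], nc$anticodon[5], nc$strand[5])              # Gln
  add_trna(nc$name[6], nc$anticodon[6], nc$strand[6])              # Met
  add_pcg("ND2")
  for (k in seq_along(spec$pattern)) {
    row <- .CLUSTER_TRNA[.CLUSTER_TRNA$letter == spec$pattern[k], ]
    add_trna(row$name, .STD_TRNA_ANTICODON_BY_BASE[[row$name]], row$strand)
    if (k == 1) add("OL", "OL", "+", .sample_bases(35, comp$tRNA))
  }
  add_pcg("COXI")
  for (k in 7:9) add_trna(nc$name[k], nc$anticodon[k], nc$strand[k])
  add_pcg("COXII")  # placed after Asp below in canonical order
  # reorder: canonical order is Ser, Asp, COXII, Lys -- adjust: we added
  # Ser(7), Asp(8), Lys(9) then COXII; swap last two plan entries
  n <- length(plan)
  plan[c(n - 1, n)] <- plan[c(n, n - 1)]
  add_pcg("ATPase8")
  add_pcg("ATPase6")
  add_pcg("COXIII")
  add_trna(nc$name[10], nc$anticodon[10], nc$strand[10])           # Gly
  add_pcg("ND3")
  add_trna(nc$name[11], nc$anticodon[11], nc$strand[11])           # Arg
  add_pcg("ND4L")
  add_pcg("ND4")
  for (k in 12:14) add_trna(nc$name[k], nc$anticodon[k], nc$strand[k])
  add_pcg("ND5")
  add_pcg("ND6")
  add_trna(nc$name[15], nc$anticodon[15], nc$strand[15])           # Glu
  add_pcg("Cytb")
  add_trna(nc$name[16], nc$anticodon[16], nc$strand[16])           # Thr
  add_trna(nc$name[17], nc$anticodon[17], nc$strand[17])           # Pro

  # tRNA phase 2: allocate the pooled loop bases and assemble each tRNA
  n_trna <- length(trna_parts)
  stem_ac_bases <- .count_bases(c(
    unlist(lapply(trna_parts, function(p) unlist(p$stems))),
    vapply(trna_parts, `[[`, character(1), "anticodon")))
  loop_pool <- .trna_loop_pool(n_trna, stem_ac_bases, comp$tRNA)
  trna_slots <- which(vapply(plan, function(p) p$category == "tRNA",
                             logical(1)))
  structures <- vector("list", n_trna)
  for (i in seq_len(n_trna)) {
    lb <- loop_pool[(24L * (i - 1L) + 1L):(24L * i)]
    asm <- .assemble_trna(trna_parts[[i]]$stems, trna_parts[[i]]$anticodon,
                          lb)
    plan[[trna_slots[i]]]$gene_seq <- asm$sequence
    plan[[trna_slots[i]]]$dot_bracket <- asm$dot_bracket
    structures[[i]] <- parse_structure(asm$dot_bracket, asm$sequence,
                                       name = trna_parts[[i]]$name)
  }

  placed <- sum(vapply(plan, function(p) nchar(p$gene_seq), integer(1)))
  dloop_len <- spec$genome_length - placed
  if (dloop_len < 50) {
    stop("infeasible spec: genome_length ", spec$genome_length,
         " leaves no room for a control region (genes occupy ", placed,
         " bp)")
  }
  add("D-loop", "control", "+", .sample_bases(dloop_len, comp$control))

  # lay out on the heavy strand, all features abutting
  pos <- 1L
  rows <- list()
  segs <- character(length(plan))
  for (i in seq_along(plan)) {
    p <- plan[[i]]
    len <- nchar(p$gene_seq)
    segs[i] <- if (p$strand == "-") revcomp(p$gene_seq) else p$gene_seq
    rows[[i]] <- data.frame(
      name = p$name, base_name = p$name, category = p$category,
      strand = p$strand, start = pos, end = pos + len - 1L,
      wraps_origin = FALSE, size_printed = len,
      spacer_printed = 0L,
      anticodon = p$anticodon, amino_acid = NA_character_,
      aa_count = p$aa_count, start_codon = p$start_codon,
      stop_codon = p$stop_codon, stringsAsFactors = FALSE)
    pos <- pos + len
  }
  features <- do.call(rbind, rows)
  features$name <- .disambiguate_names(features$base_name)
  is_trna <- features$category == "tRNA"
  features$amino_acid[is_trna] <-
    unname(.AA3_TO_1[sub("^tRNA-", "", features$base_name[is_trna])])
  names(structures) <- features$name[is_trna]
  for (i in seq_along(structures)) {
    structures[[i]]$name <- names(structures)[i]
  }

  record <- mitogenome_record(
    species_id = paste0("synthetic-", spec$seed),
    genome_length = spec$genome_length,
    features = features,
    sequence = paste(segs, collapse = ""),
    circular = TRUE,
    declared_counts = c(PCG = 13L,
                        tRNA = sum(is_trna),
                        rRNA = 2L))

  oriented <- vapply(plan, `[[`, character(1), "gene_seq")
  cats <- vapply(plan, `[[`, character(1), "category")
  realized <- list(
    PCGs = .count_bases(oriented[cats == "PCG"]),
    rRNA = .count_bases(oriented[cats == "rRNA"]),
    tRNA = .count_bases(oriented[cats == "tRNA"]),
    control = .count_bases(oriented[cats == "control"]))

  pcg_rows <- features[features$category == "PCG", ]
  ledger <- list(
    seed = spec$seed,
    pattern = paste(spec$pattern, collapse = ""),
    genome_length = spec$genome_length,
    composition_targets = comp,
    realized_counts = realized,
    pcg = stats::setNames(lapply(seq_len(nrow(pcg_rows)), function(i) list(
      start_codon = pcg_rows$start_codon[i],
      stop_codon = pcg_rows$stop_codon[i],
      aa_count = pcg_rows$aa_count[i])), pcg_rows$name),
    trna_pairs = list(per_trna = c(g_u = spec$gu_per_trna,
                                   a_c = spec$ac_per_trna,
                                   watson_crick = 21 - spec$gu_per_trna -
                                     spec$ac_per_trna),
                      n_trna = sum(is_trna)),
    structures = structures)
  structure(list(record = record, ledger = ledger),
            class = "synthetic_mitogenome")
}

#' Generate a random labeled tree with clustered or random tip states
#'
#' Clustered assignment builds one monophyletic clade per state (random
#' subtree shape inside each clade), so the Fitch parsimony cost is exactly
#' the number of states minus one. Random assignment draws states uniformly
#' per tip on a random topology.
#'
#' @param n_tips number of tips (>= 4)
#' @param states character vector of state labels (fewer than n_tips)
#' @param clustering "clustered" or "random"
#' @param seed integer seed
#' @return list: \code{tree} (ape phylo), \code{states} (named tip vector)
#' @export
generate_labeled_tree <- function(n_tips, states,
                                  clustering = c("clustered", "random"),
                                  seed = 1) {
  clustering <- match.arg(clustering)
  if (n_tips < 4) stop("n_tips must be at least 4")
  k <- length(states)
  if (k > n_tips) stop("more states than tips")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  if (clustering == "clustered") {
    sizes <- rep(n_tips %/% k, k)
    sizes[seq_len(n_tips %% k)] <- sizes[seq_len(n_tips %% k)] + 1
    offset <- 0
    subtrees <- character(k)
    tip_states <- character(0)
    for (i in seq_len(k)) {
      labs <- paste0("t", offset + seq_len(sizes[i]))
      sub <- if (sizes[i] == 1) labs else {
        tr <- ape::rtree(sizes[i], tip.label = labs, br = NULL)
        sub <- ape::write.tree(tr)
        sub <- sub(";$", "", sub)
        sub
      }
      subtrees[i] <- sub
      tip_states <- c(tip_states, stats::setNames(rep(states[i], sizes[i]),
                                                  labs))
      offset <- offset + sizes[i]
    }
    tree <- ape::read.tree(text = paste0("(", paste(subtrees, collapse = ","),
                                         ");"))
  } else {
    tree <- ape::rtree(n_tips, br = NULL)
    tip_states <- stats::setNames(sample(states, n_tips, replace = TRUE),
                                  tree$tip.label)
  }
  list(tree = tree, states = tip_states)
}

#' Write a synthetic mitogenome to disk
#'
#' Emits the full text bundle: FASTA genome sequence, annotation feature
#' table, per-tRNA dot-bracket structures, and the ground-truth ledger JSON.
#'
#' @param sim a \code{synthetic_mitogenome} from \code{\link{generate_record}}
#' @param dir output directory (created if needed)
#' @return named vector of written paths, invisibly
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- sim$record
  paths <- c(
    fasta = file.path(dir, "genome.fa"),
    table = file.path(dir, "features.tsv"),
    structures = file.path(dir, "trna_structures.txt"),
    ledger = file.path(dir, "ledger.json"))
  seqinr::write.fasta(list(strsplit(rec$sequence, "")[[1]]),
                      names = rec$species_id, file.out = paths[["fasta"]],
                      nbchar = 70)
  write_feature_table(rec, paths[["table"]])
  st_lines <- unlist(lapply(names(sim$ledger$structures), function(nm) {
    s <- sim$ledger$structures[[nm]]
    db <- db_from_pairing(s)
    c(paste0(">", nm), chartr("U", "T", s$sequence), db)
  }))
  writeLines(st_lines, paths[["structures"]])
  led <- sim$ledger
  led$structures <- NULL
  jsonlite::write_json(led, paths[["ledger"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Dot-bracket string from a structure's pairing
#' @param structure a \code{trna_structure}
#' @return dot-bracket string (pairs must be non-crossing)
#' @export
db_from_pairing <- function(structure) {
  n <- nchar(structure$sequence)
  db <- rep(".", n)
  pr <- structure$pairing
  for (r in seq_len(nrow(pr))) {
    db[pr[r, 1]] <- "("
    db[pr[r, 2]] <- ")"
  }
  paste(db, collapse = "")
}
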