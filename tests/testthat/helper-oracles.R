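# Independent brute-force oracles, deliberately implemented with different
# algorithms from the package code they check.

# --- TDRL oracle -----------------------------------------------------------
# Duplication of block [i,j] of `o`, as a plain index construction.
oracle_expand <- function(o, i, j) {
  n <- length(o)
  c(o[seq_len(j)], o[i:j], if (j < n) o[(j + 1):n])
}

# All distinct orders reachable in exactly one round by enumerating every
# loss subset of every expansion (letters must all be retained).
oracle_reach_one <- function(o) {
  letters_needed <- unique(o)
  seen <- new.env(parent = emptyenv())
  out <- list()
  n <- length(o)
  for (i in seq_len(n)) for (j in i:n) {
    e <- oracle_expand(o, i, j)
    m <- length(e)
    for (mask in 0:(2^m - 1)) {
      keep <- e[bitwAnd(bitwShiftR(mask, 0:(m - 1)), 1L) == 1L]
      if (!all(letters_needed %in% keep)) next
      key <- paste(keep, collapse = "")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1]] <- keep
      }
    }
  }
  out
}

# Recursive subsequence membership (distinct from the package's two-pointer).
oracle_is_subseq <- function(target, e) {
  if (length(target) == 0) return(TRUE)
  if (length(e) < length(target)) return(FALSE)
  hit <- which(e == target[1])
  for (p in hit) {
    rest_e <- if (p < length(e)) e[(p + 1):length(e)] else character(0)
    if (oracle_is_subseq(target[-1], rest_e)) return(TRUE)
  }
  FALSE
}

# Can `target` be reached from `o` in one round? (block enumeration + deletion
# = subsequence of the expansion, retaining all letters)
oracle_one_round_hits <- function(o, target) {
  if (!all(unique(o) %in% unique(target))) return(FALSE)
  n <- length(o)
  for (i in seq_len(n)) for (j in i:n) {
    if (oracle_is_subseq(target, oracle_expand(o, i, j))) return(TRUE)
  }
  FALSE
}

# Minimum TDRL rounds from src to tgt within max_rounds (0, 1, 2) or NA.
oracle_min_rounds <- function(src, tgt, max_rounds = 2,
                              reach1_cache = NULL) {
  src <- strsplit(src, "")[[1]]
  tgt <- strsplit(tgt, "")[[1]]
  if (identical(src, tgt)) return(0L)
  if (max_rounds >= 1 && oracle_one_round_hits(src, tgt)) return(1L)
  if (max_rounds >= 2) {
    reach1 <- if (is.null(reach1_cache)) oracle_reach_one(src) else
      reach1_cache
    for (o1 in reach1) {
      if (oracle_one_round_hits(o1, tgt)) return(2L)
    }
  }
  NA_integer_
}

# --- Fitch oracle ----------------------------------------------------------
# Exhaustive minimum over all internal-node labelings.
oracle_fitch <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  tipst <- as.character(states[tree$tip.label])
  st_levels <- sort(unique(tipst))
  k <- length(st_levels)
  edge <- tree$edge
  best <- Inf
  lab <- rep(1L, nnode)
  repeat {
    node_state <- c(tipst, st_levels[lab])
    cost <- sum(node_state[edge[, 1]] != node_state[edge[, 2]])
    if (cost < best) best <- cost
    p <- 1L
    while (p <= nnode && lab[p] == k) {
      lab[p] <- 1L
      p <- p + 1L
    }
    if (p > nnode) break
    lab[p] <- lab[p] + 1L
  }
  as.integer(best)
}

# --- misc ------------------------------------------------------------------
# size of a circular feature by explicit position enumeration
oracle_span_size <- function(start, end, L, wraps) {
  pos <- if (wraps) c(start:L, 1:end) else start:end
  length(pos)
}

# minimal 2-gene GenBank flat file used by io tests
tiny_genbank_text <- function() {
  paste(c(
    "LOCUS       testrec 120 bp    DNA     circular     VRT",
    "ACCESSION   TEST0001",
    "  ORGANISM  test_species",
    "FEATURES             Location/Qualifiers",
    "     tRNA            1..40",
    '                     /gene="tRNA-Phe"',
    "     CDS             complement(41..100)",
    '                     /gene="ND1"',
    '                     /note_stop="TAA"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//"), collapse = "\n")
}
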