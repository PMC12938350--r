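# Classification of tRNA secondary-structure base pairs into Watson-Crick,
# G-U wobble, A-C, and other non-canonical classes. Structures are consumed
# (dot-bracket + sequence), never predicted.

#' Build a tRNA structure from sequence and explicit pairing
#'
#' @param name tRNA name
#' @param sequence RNA or DNA string (T is transcribed to U)
#' @param pairing two-column integer matrix of paired positions (i, j),
#'   1-based; each position may appear in at most one pair
#' @return list of class \code{trna_structure}
#' @export
trna_structure <- function(name, sequence, pairing) {
  sequence <- chartr("Tt", "Uu", toupper(sequence))
  pairing <- matrix(as.integer(pairing), ncol = 2)
  if (nrow(pairing)) {
    if (any(pairing < 1 | pairing > nchar(sequence))) {
      stop("pair position out of sequence range in ", name)
    }
    if (any(pairing[, 1] == pairing[, 2])) {
      stop("pair referencing identical positions in ", name)
    }
    flat <- as.vector(pairing)
    if (anyDuplicated(flat)) {
      stop("position participating in more than one pair in ", name)
    }
    pairing <- t(apply(pairing, 1, sort))
  }
  structure(list(name = name, sequence = sequence, pairing = pairing),
            class = "trna_structure")
}

#' Parse a dot-bracket secondary structure
#'
#' Pairing is derived by matching '(' with ')' in nesting order; the
#' structure string must have the same length as the sequence and be
#' balanced.
#'
#' @param dot_bracket dot-bracket string
#' @param sequence nucleotide string of the same length
#' @param name optional structure name
#' @return a \code{trna_structure}
#' @export
#' @examples
#' parse_structure("((..))", "GGAACC")
parse_structure <- function(dot_bracket, sequence, name = "tRNA") {
  if (nchar(dot_bracket) != nchar(sequence)) {
    stop("dot-bracket and sequence lengths differ")
  }
  chars <- strsplit(dot_bracket, "")[[1]]
  stack <- integer(0)
  pairs <- list()
  for (p in seq_along(chars)) {
    if (chars[p] == "(") {
      stack <- c(stack, p)
    } else if (chars[p] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket: unmatched ')'")
      pairs[[length(pairs) + 1]] <- c(stack[length(stack)], p)
      stack <- stack[-length(stack)]
    } else if (chars[p] != ".") {
      stop("unexpected character '", chars[p], "' in dot-bracket")
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '('")
  pairing <- if (length(pairs)) do.call(rbind, pairs) else
    matrix(integer(0), ncol = 2)
  trna_structure(name, sequence, pairing)
}

.empty_pair_counts <- function() {
  structure(list(watson_crick = 0L, g_u = 0L, a_c = 0L, other = 0L),
            class = "pair_class_counts")
}

#' Classify the base pairs of one tRNA structure
#'
#' Each pair is classified by its unordered nucleotide set: \{A,U\} and
#' \{G,C\} are Watson-Crick; \{G,U\} is the wobble class; \{A,C\} its own
#' class; anything else is "other", so the four classes always partition the
#' pairs.
#'
#' @param structure a \code{trna_structure}
#' @return list of class \code{pair_class_counts} with integer fields
#'   watson_crick, g_u, a_c, other
#' @export
classify_pairs <- function(structure) {
  out <- .empty_pair_counts()
  s <- strsplit(structure$sequence, "")[[1]]
  for (r in seq_len(nrow(structure$pairing))) {
    duo <- sort(s[structure$pairing[r, ]])
    key <- paste(duo, collapse = "")
    cls <- switch(key, AU = "watson_crick", CG = "watson_crick",
                  GU = "g_u", AC = "a_c", "other")
    out[[cls]] <- out[[cls]] + 1L
  }
  out
}

#' Aggregate pair-class counts over a set of tRNA structures
#' @param structures list of \code{trna_structure}s
#' @return componentwise sum as a \code{pair_class_counts}
#' @export
aggregate_pairs <- function(structures) {
  out <- .empty_pair_counts()
  for (st in structures) {
    ct <- classify_pairs(st)
    for (k in names(out)) out[[k]] <- out[[k]] + ct[[k]]
  }
  out
}

#' @export
print.pair_class_counts <- function(x, ...) {
  cat(sprintf(
    "<pair_class_counts> WC %d, G-U %d, A-C %d, other %d (total %d)\n",
    x$watson_crick, x$g_u, x$a_c, x$other,
    x$watson_crick + x$g_u + x$a_c + x$other))
  invisible(x)
}

#' Pair-class table for a set of structures
#' @param structures list of \code{trna_structure}s
#' @return data.frame with one row per tRNA plus a "total" row
#' @export
pair_class_table <- function(structures) {
  rows <- lapply(structures, function(st) {
    ct <- classify_pairs(st)
    data.frame(trna = st$name, watson_crick = ct$watson_crick, g_u = ct$g_u,
               a_c = ct$a_c, other = ct$other, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tot <- aggregate_pairs(structures)
  rbind(tab, data.frame(trna = "total", watson_crick = tot$watson_crick,
                        g_u = tot$g_u, a_c = tot$a_c, other = tot$other,
                        stringsAsFactors = FALSE))
}
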