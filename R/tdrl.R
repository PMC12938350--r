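# WANCY tRNA-cluster extraction, rearrangement-pattern classification, and
# the tandem-duplication-random-loss (TDRL) scenario engine.
#
# A gene order is a character vector of single-letter tRNA codes (optionally
# carrying a "strand" attribute, which duplication copies unchanged and
# pattern matching ignores). A TDRL round duplicates a contiguous block of
# the current order, inserting the copy immediately after the block, and then
# deletes a set of copies (indices into the post-duplication order). Every
# distinct letter must retain at least one copy at all times.

.NAMED_PATTERNS <- c(WANCY = "WANCY", WYANC = "WYANC",
                     WNCYAC = "WNCYAC", WNCYAA = "WNCYAA")

#' Construct a gene order from a compact string or letter vector
#' @param x string like "WANCY" or character vector of single letters
#' @param strand optional strand vector (+/-), carried as an attribute
#' @return character vector of class \code{gene_order}
#' @export
gene_order <- function(x, strand = NULL) {
  letters <- if (length(x) == 1 && nchar(x) > 1) strsplit(x, "")[[1]] else
    as.character(x)
  letters <- toupper(letters)
  if (!is.null(strand)) {
    stopifnot(length(strand) == length(letters))
    attr(letters, "strand") <- strand
  }
  class(letters) <- "gene_order"
  letters
}

#' @export
print.gene_order <- function(x, ...) {
  cat("<gene_order> ", paste(unclass(x), collapse = ""), "\n", sep = "")
  invisible(x)
}

.order_string <- function(o) paste(unclass(o), collapse = "")

#' Extract the tRNA cluster between ND2 and COI
#'
#' Returns the single-letter order of all tRNA genes lying strictly between
#' the end of ND2 and the start of COI, in genomic order — the WANCY cluster
#' region of the vertebrate mitogenome.
#'
#' @param record a \code{mitogenome_record}
#' @return a \code{gene_order} (possibly empty), with strand attribute
#' @export
extract_cluster <- function(record) {
  f <- record$features
  nd2 <- which(f$base_name == "ND2")
  coi <- which(f$base_name == "COXI")
  if (length(nd2) != 1 || length(coi) != 1) {
    stop("record must contain exactly one ND2 and one COXI anchor")
  }
  sel <- which(f$category == "tRNA" &
               f$start > f$end[nd2] & f$end < f$start[coi])
  sel <- sel[order(f$start[sel])]
  gene_order(f$amino_acid[sel], strand = f$strand[sel])
}

#' Classify a tRNA-cluster gene order against the named rearrangement patterns
#'
#' Exact letter-sequence match against the canonical vertebrate order (WANCY)
#' and the rearranged orders WYANC, WNCYAC and WNCYAA observed in Liparis;
#' anything else is OTHER. Strand is ignored.
#'
#' @param order a \code{gene_order} (or string)
#' @return one of "WANCY", "WYANC", "WNCYAC", "WNCYAA", "OTHER"
#' @export
classify_pattern <- function(order) {
  s <- .order_string(gene_order(order))
  hit <- names(.NAMED_PATTERNS)[.NAMED_PATTERNS == s]
  if (length(hit)) hit else "OTHER"
}

.expand_block <- function(order, block) {
  n <- length(order)
  i <- block[1]; j <- block[2]
  if (i < 1 || j > n || i > j) {
    stop("duplication block [", i, ",", j, "] out of range for order of ",
         "length ", n)
  }
  idx <- c(seq_len(j), i:j, if (j < n) (j + 1):n)
  order[idx]
}

#' Replay a TDRL event history on a gene order
#'
#' Each round duplicates the contiguous block \code{[i, j]} of the current
#' order, inserting the copy immediately after position \code{j}, and then
#' deletes the listed copy indices (1-based positions in the
#' post-duplication order). Deleting the last copy of any letter is an error.
#'
#' @param source a \code{gene_order} (or string)
#' @param rounds list of rounds, each \code{list(block = c(i, j),
#'   losses = integer vector)}; an empty list is the identity
#' @return the derived \code{gene_order}
#' @export
#' @examples
#' apply_tdrl("WANCY",
#'   list(list(block = c(1, 5), losses = c(2, 3, 4, 6, 10))))  # WYANC
apply_tdrl <- function(source, rounds) {
  cur <- unclass(gene_order(source))
  strand <- attr(cur, "strand")
  for (r in seq_along(rounds)) {
    rd <- rounds[[r]]
    exp_idx <- local({
      n <- length(cur)
      i <- rd$block[1]; j <- rd$block[2]
      if (i < 1 || j > n || i > j) {
        stop("round ", r, ": duplication block [", i, ",", j,
             "] out of range (order length ", n, ")")
      }
      c(seq_len(j), i:j, if (j < n) (j + 1):n)
    })
    e <- cur[exp_idx]
    es <- if (!is.null(strand)) strand[exp_idx]
    losses <- unique(as.integer(rd$losses))
    if (length(losses)) {
      if (any(losses < 1 | losses > length(e))) {
        stop("round ", r, ": loss index out of range of the expanded order")
      }
      kept <- e[-losses]
      if (!is.null(es)) es <- es[-losses]
    } else {
      kept <- e
    }
    gone <- setdiff(unique(cur), unique(kept))
    if (length(gone)) {
      stop("round ", r, ": deletion leaves no copy of gene(s) ",
           paste(gone, collapse = ", "))
    }
    cur <- kept
    strand <- es
  }
  gene_order(cur, strand = strand)
}

#' Construct a TDRL scenario object
#' @param source,derived gene orders (or strings)
#' @param rounds event list as for \code{\link{apply_tdrl}}
#' @return list of class \code{tdrl_scenario}
#' @export
tdrl_scenario <- function(source, rounds, derived) {
  structure(list(source = gene_order(source), rounds = rounds,
                 derived = gene_order(derived)),
            class = "tdrl_scenario")
}

#' @export
print.tdrl_scenario <- function(x, ...) {
  cat("<tdrl_scenario> ", .order_string(x$source), " -> ",
      .order_string(x$derived), " in ", length(x$rounds), " round(s)\n",
      sep = "")
  for (r in seq_along(x$rounds)) {
    rd <- x$rounds[[r]]
    cat("  round ", r, ": duplicate [", rd$block[1], ",", rd$block[2],
        "], lose {", paste(rd$losses, collapse = ","), "}\n", sep = "")
  }
  invisible(x)
}

#' Verify that a TDRL scenario replays to its stated derived order
#'
#' TRUE iff replaying the rounds on the source yields exactly the derived
#' order and no round violates the copy-retention or index-range invariants.
#'
#' @param scenario a \code{tdrl_scenario}
#' @return logical
#' @export
verify_scenario <- function(scenario) {
  out <- tryCatch(apply_tdrl(scenario$source, scenario$rounds),
                  error = function(e) NULL)
  !is.null(out) && identical(.order_string(out),
                             .order_string(scenario$derived))
}

# all index embeddings of `target` as a subsequence of `e`
.embeddings <- function(e, target) {
  k <- length(target)
  n <- length(e)
  res <- list()
  rec <- function(ti, from, acc) {
    if (ti > k) { res[[length(res) + 1]] <<- acc; return(invisible()) }
    if (n - from + 1 < k - ti + 1) return(invisible())
    for (p in from:n) {
      if (e[p] == target[ti]) rec(ti + 1, p + 1, c(acc, p))
    }
  }
  if (k == 0 || k > n) return(res)
  rec(1, 1, integer(0))
  res
}

# is target a subsequence of e (two-pointer)
.is_subseq <- function(target, e) {
  ti <- 1
  for (p in seq_along(e)) {
    if (ti > length(target)) break
    if (e[p] == target[ti]) ti <- ti + 1
  }
  ti > length(target)
}

.all_blocks <- function(n) {
  out <- list()
  for (i in seq_len(n)) for (j in i:n) out[[length(out) + 1]] <- c(i, j)
  out
}

#' Exhaustive search for minimal TDRL scenarios
#'
#' Breadth-first over the number of duplication rounds: returns every
#' scenario that derives \code{target} from \code{source} in the minimum
#' number of rounds, in canonical latest-possible-deletion form (all copy
#' losses are attached to the final round; earlier rounds are pure
#' duplications). Any timing of losses can be rewritten into this form
#' without changing the round count or the derived order, so minimality is
#' assessed over the full event space. Scenarios are sorted by total number
#' of losses, then by a lexicographic encoding of their events.
#'
#' @param source,target gene orders (or strings) over the same letter set
#' @param max_rounds maximum rounds to try (default 3; keep small, the event
#'   space grows quickly)
#' @return list of \code{tdrl_scenario}s (empty if unreachable); attribute
#'   \code{min_rounds} gives the minimum round count, or NA when unreachable
#' @export
minimal_scenarios <- function(source, target, max_rounds = 3) {
  src <- unclass(gene_order(source))
  tgt <- unclass(gene_order(target))
  if (!setequal(unique(src), unique(tgt))) {
    stop("source and target use different letter alphabets")
  }
  if (identical(src, tgt)) {
    out <- list(tdrl_scenario(src, list(), tgt))
    attr(out, "min_rounds") <- 0L
    return(out)
  }
  # prefixes of pure duplications at the current depth
  prefixes <- list(list(blocks = list(), order = src))
  for (rounds in seq_len(max_rounds)) {
    found <- list()
    for (pf in prefixes) {
      for (blk in .all_blocks(length(pf$order))) {
        e <- .expand_block(pf$order, blk)
        if (!.is_subseq(tgt, e)) next
        for (emb in .embeddings(e, tgt)) {
          losses <- setdiff(seq_along(e), emb)
          evts <- c(lapply(pf$blocks,
                           function(b) list(block = b, losses = integer(0))),
                    list(list(block = blk, losses = losses)))
          found[[length(found) + 1]] <- tdrl_scenario(src, evts, tgt)
        }
      }
    }
    if (length(found)) {
      keys <- vapply(found, function(s) paste(
        vapply(s$rounds, function(rd) paste0(
          "[", rd$block[1], ",", rd$block[2], "|",
          paste(rd$losses, collapse = ","), "]"), character(1)),
        collapse = ""), character(1))
      found <- found[!duplicated(keys)]
      keys <- keys[!duplicated(keys)]
      tot <- vapply(found, function(s)
        sum(vapply(s$rounds, function(rd) length(rd$losses), integer(1))),
        integer(1))
      ord <- order(tot, keys)
      out <- found[ord]
      attr(out, "min_rounds") <- as.integer(rounds)
      return(out)
    }
    if (rounds < max_rounds) {
      nxt <- list()
      seen <- character(0)
      for (pf in prefixes) {
        for (blk in .all_blocks(length(pf$order))) {
          e <- .expand_block(pf$order, blk)
          key <- paste0(paste(vapply(c(pf$blocks, list(blk)), function(b)
            paste(b, collapse = "-"), character(1)), collapse = ";"))
          nxt[[length(nxt) + 1]] <- list(blocks = c(pf$blocks, list(blk)),
                                         order = e)
        }
      }
      prefixes <- nxt
    }
  }
  out <- list()
  attr(out, "min_rounds") <- NA_integer_
  out
}

#' Reference TDRL reconstructions for the Liparis WANCY rearrangements
#'
#' The event histories proposed for the three rearranged cluster patterns:
#' WYANC (one whole-cluster duplication, losing the first-copy ANC and the
#' second-copy W and Y), WNCYAC (one whole-cluster duplication, losing the
#' first-copy A and the second-copy W, N and Y, leaving a duplicated Cys),
#' and WNCYAA (two duplications: the first whole-cluster duplication loses
#' one A and one W copy, a second duplication of the leading WNCYA block then
#' loses the second WNCY block copy and the trailing NCY).
#'
#' @return named list of \code{tdrl_scenario}s (WYANC, WNCYAC, WNCYAA), each
#'   with source WANCY
#' @export
liparis_tdrl_scenarios <- function() {
  list(
    WYANC = tdrl_scenario(
      "WANCY",
      list(list(block = c(1, 5), losses = c(2, 3, 4, 6, 10))),
      "WYANC"),
    WNCYAC = tdrl_scenario(
      "WANCY",
      list(list(block = c(1, 5), losses = c(2, 6, 8, 10))),
      "WNCYAC"),
    WNCYAA = tdrl_scenario(
      "WANCY",
      list(list(block = c(1, 5), losses = c(2, 6)),
           list(block = c(1, 5), losses = c(6, 7, 8, 9, 11, 12, 13))),
      "WNCYAA")
  )
}

#' Write TDRL scenarios to the JSON exchange format
#' @param scenarios list of \code{tdrl_scenario}s
#' @param path output path
#' @return path, invisibly
#' @export
write_scenarios <- function(scenarios, path) {
  obj <- lapply(scenarios, function(s) list(
    source = .order_string(s$source),
    rounds = lapply(s$rounds, function(rd)
      list(block = rd$block, losses = rd$losses)),
    derived = .order_string(s$derived)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
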