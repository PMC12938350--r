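# Codon accounting under the vertebrate mitochondrial code: start/stop
# bookkeeping, incomplete-stop completion, codon counting, RSCU, and
# PCG concatenation.

#' Amino acids encoded by a gene of a given size and stop codon
#'
#' Mitochondrial PCGs may end in a complete stop (TAA/TAG/AGA/AGG, 3 nt) or
#' an incomplete stop ("TA-", 2 nt; "T-", 1 nt) completed to TAA by
#' polyadenylation. The coding length excluding the stop must be an exact
#' codon multiple.
#'
#' @param size gene length in bp
#' @param stop_codon stop token: TAA, TAG, AGA, AGG, "TA-" or "T-"
#' @return integer amino-acid count (size - stop length) / 3
#' @export
#' @examples
#' amino_acid_length(1046, "TA-")  # 348
#' amino_acid_length(1141, "T-")   # 380
amino_acid_length <- function(size, stop_codon) {
  sl <- stop_codon_length(stop_codon)
  if (size <= sl) stop("gene size ", size, " not larger than its stop")
  coding <- size - sl
  if (coding %% 3 != 0) {
    stop("frame inconsistency: size ", size, " minus ", sl,
         "-nt stop '", stop_codon, "' is not a codon multiple")
  }
  as.integer(coding / 3)
}

#' Extract per-PCG codon sequences from a record
#'
#' For each protein-coding gene: takes the strand-oriented sequence,
#' completes an incomplete terminal stop to TAA by appending A's, strips the
#' stop, and splits the remainder into codons. Internal stop codons trigger a
#' warning naming the gene and codon position.
#'
#' @param record a \code{mitogenome_record} with sequence; PCG features must
#'   carry a \code{stop_codon} token
#' @return named list (one element per PCG, genomic order) with components
#'   codons (character vector), start_codon, stop_codon, aa_count
#' @export
extract_cds <- function(record) {
  if (is.null(record$sequence)) stop("record carries no sequence")
  f <- record$features
  idx <- which(f$category == "PCG")
  if (length(idx) == 0) stop("record contains no protein-coding genes")
  code <- mito_genetic_code()
  out <- lapply(idx, function(i) {
    s <- feature_sequence(record, i)
    stop_tok <- f$stop_codon[i]
    if (is.na(stop_tok)) stop("PCG ", f$name[i], " has no stop_codon token")
    sl <- stop_codon_length(stop_tok)
    if ((nchar(s) - sl) %% 3 != 0) {
      stop("frame inconsistency in ", f$name[i], ": length ", nchar(s),
           " with ", sl, "-nt stop")
    }
    # polyadenylation completes T-/TA- to TAA; then the stop is stripped
    completed <- if (sl < 3) paste0(s, strrep("A", 3 - sl)) else s
    coding <- substr(completed, 1, nchar(completed) - 3)
    codons <- substring(coding, seq(1, nchar(coding), 3),
                        seq(3, nchar(coding), 3))
    aa <- unname(code[codons])
    internal <- which(!is.na(aa) & aa == "*")
    if (length(internal)) {
      warning("internal stop codon(s) in ", f$name[i], " at codon ",
              paste(internal, collapse = ", "))
    }
    list(codons = codons,
         start_codon = codons[1],
         stop_codon = stop_tok,
         aa_count = length(codons))
  })
  stats::setNames(out, f$name[idx])
}

#' Codon counts over the 64 codons
#' @param codons character vector of codons (DNA alphabet), or the list
#'   returned by \code{\link{extract_cds}}
#' @return named integer vector of length 64 in TCAG order
#' @export
codon_counts <- function(codons) {
  if (is.list(codons)) codons <- unlist(lapply(codons, `[[`, "codons"))
  tab <- table(factor(toupper(codons), levels = all_codons()))
  stats::setNames(as.integer(tab), all_codons())
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the mean count of its
#' synonymous family under the vertebrate mitochondrial code, i.e.
#' count * family_size / family_total. Stop codons are excluded. Families
#' with zero total get RSCU 0 for all members and are flagged.
#'
#' @param counts named numeric vector of per-codon counts (names are codons;
#'   missing codons count 0)
#' @return data.frame of class \code{codon_usage_table}: codon, amino_acid,
#'   count, family_size, rscu, zero_family; attribute \code{aa_usage} holds
#'   per-amino-acid totals and frequencies
#' @export
#' @examples
#' compute_rscu(c(TTT = 10, TTC = 0))[1:2, "rscu"]  # 2, 0
compute_rscu <- function(counts) {
  if (any(counts < 0)) stop("negative codon counts")
  code <- mito_genetic_code()
  sense <- names(code)[code != "*"]
  full <- stats::setNames(numeric(length(sense)), sense)
  hit <- intersect(names(counts), sense)
  full[hit] <- counts[hit]
  aa <- code[sense]
  fam_total <- tapply(full, aa, sum)
  fam_size <- table(aa)
  rscu <- ifelse(fam_total[aa] > 0,
                 full * as.numeric(fam_size[aa]) / fam_total[aa], 0)
  res <- data.frame(
    codon = sense, amino_acid = unname(aa), count = unname(full),
    family_size = as.integer(fam_size[aa]),
    rscu = unname(rscu),
    zero_family = unname(fam_total[aa] == 0),
    stringsAsFactors = FALSE)
  total <- sum(full)
  aa_usage <- data.frame(
    amino_acid = names(fam_total),
    count = as.numeric(fam_total),
    frequency = if (total > 0) as.numeric(fam_total) / total
                else rep(0, length(fam_total)),
    stringsAsFactors = FALSE)
  attr(res, "aa_usage") <- aa_usage
  class(res) <- c("codon_usage_table", "data.frame")
  res
}

#' Concatenate the 13 PCG coding sequences of each record
#'
#' Extracts every protein-coding gene, strips (completed) stop codons, and
#' concatenates in the canonical vertebrate gene order ND1..Cytb, the usual
#' preparation of a mitogenomic phylogenetic matrix.
#'
#' @param records list of \code{mitogenome_record}s with sequence
#' @param fasta optional path; when given, concatenations are written as FASTA
#' @return named character vector of concatenated coding sequences
#' @export
concatenate_pcgs <- function(records, fasta = NULL) {
  if (inherits(records, "mitogenome_record")) records <- list(records)
  out <- vapply(records, function(r) {
    cds <- extract_cds(r)
    base <- sub("-[0-9]+$", "", names(cds))
    missing <- setdiff(.PCG_ORDER, base)
    if (length(missing)) {
      stop("species ", r$species_id, " is missing PCG(s): ",
           paste(missing, collapse = ", "))
    }
    ord <- match(.PCG_ORDER, base)
    paste(vapply(cds[ord], function(g) paste(g$codons, collapse = ""),
                 character(1)), collapse = "")
  }, character(1))
  names(out) <- vapply(records, `[[`, character(1), "species_id")
  if (!is.null(fasta)) {
    seqinr::write.fasta(as.list(out), names = names(out), file.out = fasta,
                        nbchar = 70)
  }
  out
}

#' Write a codon usage table as TSV
#' @param cut a \code{codon_usage_table} from \code{\link{compute_rscu}}
#' @param path output path
#' @return path, invisibly
#' @export
write_rscu <- function(cut, path) {
  utils::write.table(as.data.frame(cut), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
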