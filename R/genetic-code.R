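# Vertebrate mitochondrial genetic code (NCBI translation table 2) and
# canonical gene nomenclature shared across the package.

.codon_bases <- c("T", "C", "A", "G")

#' All 64 codons in TCAG order
#' @return character vector of 64 codons
#' @keywords internal
all_codons <- function() {
  as.vector(t(outer(
    as.vector(t(outer(.codon_bases, .codon_bases, paste0))),
    .codon_bases, paste0
  )))
}

# Amino-acid string in TCAG codon order for translation table 2:
# TGA = Trp, ATA = Met, AGA/AGG = stop.
.MITO_CODE_STRING <-
  "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG"

#' Vertebrate mitochondrial genetic code
#'
#' Codon-to-amino-acid map for NCBI translation table 2 (vertebrate
#' mitochondrial): \code{TGA} encodes Trp, \code{ATA} encodes Met, and
#' \code{AGA}/\code{AGG} are stop codons in addition to \code{TAA}/\code{TAG}.
#'
#' @return Named character vector of length 64; names are DNA codons, values
#'   single-letter amino-acid codes with \code{"*"} for stops.
#' @export
#' @examples
#' mito_genetic_code()[["TGA"]]  # "W"
mito_genetic_code <- function() {
  stats::setNames(strsplit(.MITO_CODE_STRING, "")[[1]], all_codons())
}

#' Stop codons of the vertebrate mitochondrial code
#' @return character vector of the four complete stop codons
#' @export
mito_stop_codons <- function() {
  code <- mito_genetic_code()
  names(code)[code == "*"]
}

# three-letter -> one-letter amino-acid codes (tRNA naming)
.AA3_TO_1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)

# Standard vertebrate mitochondrial anticodons (DNA alphabet, as annotated
# on the gene), keyed by base tRNA label. The two serine/leucine isotypes
# are distinguished by their genomic position suffix.
.STD_ANTICODON <- c(
  "tRNA-Phe" = "GAA", "tRNA-Val" = "TAC", "tRNA-Leu-1" = "TAA",
  "tRNA-Ile" = "GAT", "tRNA-Gln" = "TTG", "tRNA-Met" = "CAT",
  "tRNA-Trp" = "TCA", "tRNA-Ala" = "TGC", "tRNA-Asn" = "GTT",
  "tRNA-Cys" = "GCA", "tRNA-Tyr" = "GTA", "tRNA-Ser-1" = "TGA",
  "tRNA-Asp" = "GTC", "tRNA-Lys" = "TTT", "tRNA-Gly" = "TCC",
  "tRNA-Arg" = "TCG", "tRNA-His" = "GTG", "tRNA-Ser-2" = "GCT",
  "tRNA-Leu-2" = "TAG", "tRNA-Glu" = "TTC", "tRNA-Thr" = "TGT",
  "tRNA-Pro" = "TGG"
)

# canonical 13 PCG labels in vertebrate genomic order
.PCG_ORDER <- c(
  "ND1", "ND2", "COXI", "COXII", "ATPase8", "ATPase6", "COXIII",
  "ND3", "ND4L", "ND4", "ND5", "ND6", "Cytb"
)

# accepted stop-codon tokens; "TA-" and "T-" are incomplete stops finished
# to TAA by polyadenylation of the mature transcript
.STOP_TOKENS <- c("TAA", "TAG", "AGA", "AGG", "TA-", "T-")

#' Length in nucleotides contributed by a stop-codon token
#' @param stop_codon one of TAA, TAG, AGA, AGG, "TA-", "T-"
#' @return 3 for complete stops, 2 for "TA-", 1 for "T-"
#' @export
stop_codon_length <- function(stop_codon) {
  stop_codon <- toupper(trimws(stop_codon))
  if (!stop_codon %in% .STOP_TOKENS) {
    stop("unknown stop-codon token '", stop_codon, "'; accepted: ",
         paste(.STOP_TOKENS, collapse = ", "))
  }
  nchar(gsub("-", "", stop_codon, fixed = TRUE))
}

#' Reverse complement of a DNA string
#' @param x single DNA string (IUPAC codes preserved where complementable)
#' @return reverse-complemented string, uppercase
#' @keywords internal
revcomp <- function(x) {
  chars <- rev(strsplit(toupper(x), "")[[1]])
  paste(chartr("ACGTN", "TGCAN", chars), collapse = "")
}
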