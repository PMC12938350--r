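# Minimal GenBank flat-file reader/writer for annotated mitogenomes.
# No installed R package parses GenBank flat files offline, so the subset of
# the format needed here (LOCUS, CDS/tRNA/rRNA/D-loop/rep_origin features
# with complement() and origin-spanning join(), /gene and /product
# qualifiers, ORIGIN block) is handled directly.

.gb_parse_span <- function(loc, genome_length) {
  loc <- gsub("[<>]", "", loc)
  comp <- grepl("^complement\\(", loc)
  if (comp) loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    spans <- lapply(parts, function(p) as.integer(strsplit(p, "..",
                                                           fixed = TRUE)[[1]]))
    if (length(spans) == 2 && spans[[1]][2] == genome_length &&
        spans[[2]][1] == 1) {
      return(list(start = spans[[1]][1], end = spans[[2]][2],
                  wraps = TRUE, comp = comp))
    }
    stop("unsupported join() location: ", loc)
  }
  se <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  if (length(se) == 1) se <- c(se, se)
  list(start = se[1], end = se[2], wraps = FALSE, comp = comp)
}

.gb_feature_name <- function(key, quals) {
  gene <- quals[["gene"]]
  prod <- quals[["product"]]
  raw <- if (!is.null(gene)) gene else prod
  if (key == "D-loop" || (is.null(raw) && key == "misc_feature")) {
    return("D-loop")
  }
  if (key == "rep_origin") return("OL")
  if (is.null(raw)) stop("feature without /gene or /product qualifier")
  # "tRNA-Leu" product form parses directly; map rRNA products
  if (grepl("12S", raw)) return("12S-rRNA")
  if (grepl("16S", raw)) return("16S-rRNA")
  normalize_gene_name(raw)
}

#' Parse a GenBank flat file into a mitogenome record
#'
#' Supports the feature keys CDS, tRNA, rRNA, D-loop and rep_origin, with
#' \code{complement()} locations and two-segment \code{join()} locations that
#' span the origin of a circular molecule. When the ORIGIN block is missing
#' the record is returned without sequence, with a warning.
#'
#' @param path path to a GenBank flat file (or its text with newlines)
#' @param species_id optional species id; defaults to the ORGANISM/DEFINITION
#' @return a \code{mitogenome_record}
#' @export
parse_genbank <- function(path, species_id = NULL) {
  lines <- if (length(path) == 1 && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else if (length(path) == 1) strsplit(path, "\n", fixed = TRUE)[[1]]
  else path
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) stop("not a GenBank flat file: no LOCUS line")
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  genome_length <- as.integer(toks[which(toks == "bp") - 1])
  circular <- any(grepl("circular", locus[1]))
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line)) strsplit(trimws(acc_line[1]),
                                              "\\s+")[[1]][2] else NULL
  if (is.null(species_id)) {
    org <- grep("^\\s+ORGANISM", lines, value = TRUE)
    species_id <- if (length(org)) trimws(sub("^\\s+ORGANISM\\s+", "", org[1]))
                  else if (!is.null(accession)) accession else "unknown"
  }

  fstart <- grep("^FEATURES", lines)
  oline <- grep("^ORIGIN", lines)
  fend <- if (length(oline)) oline[1] - 1 else length(lines)
  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1):fend]
    is_key <- grepl("^ {5}\\S", block)
    idx <- which(is_key)
    for (k in seq_along(idx)) {
      from <- idx[k]
      to <- if (k < length(idx)) idx[k + 1] - 1 else length(block)
      hdr <- strsplit(trimws(block[from]), "\\s+")[[1]]
      key <- hdr[1]
      if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "rep_origin",
                      "misc_feature")) next
      loc <- paste0(hdr[-1], collapse = "")
      qlines <- trimws(block[seq(from + 1, length.out = max(0, to - from))])
      quals <- list()
      for (q in qlines[grepl("^/", qlines)]) {
        m <- regmatches(q, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', q))[[1]]
        if (length(m) == 3) quals[[m[2]]] <- m[3]
      }
      span <- .gb_parse_span(loc, genome_length)
      name <- .gb_feature_name(key, quals)
      stop_cod <- quals[["note_stop"]]
      feats[[length(feats) + 1]] <- data.frame(
        name = name, base_name = name, category = feature_category(name),
        strand = if (span$comp) "-" else "+",
        start = span$start, end = span$end, wraps_origin = span$wraps,
        size_printed = NA_integer_, spacer_printed = NA_integer_,
        anticodon = if (!is.null(quals[["anticodon_seq"]]))
          toupper(quals[["anticodon_seq"]]) else NA_character_,
        amino_acid = NA_character_, aa_count = NA_integer_,
        start_codon = NA_character_,
        stop_codon = if (is.null(stop_cod)) NA_character_
                     else toupper(stop_cod),
        stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(matrix(nrow = 0, ncol = length(.FEATURE_COLS),
                      dimnames = list(NULL, .FEATURE_COLS)))
  if (nrow(features)) {
    features$name <- .disambiguate_names(features$base_name)
    is_trna <- features$category == "tRNA"
    features$amino_acid[is_trna] <-
      unname(.AA3_TO_1[sub("^tRNA-", "", features$base_name[is_trna])])
  }

  sequence <- NULL
  if (length(oline)) {
    seq_lines <- lines[(oline[1] + 1):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (!nzchar(sequence)) sequence <- NULL
  }
  if (is.null(sequence)) {
    warning("no ORIGIN block: returning a sequence-less record")
  }
  mitogenome_record(species_id, genome_length, features,
                    sequence = sequence, accession = accession,
                    circular = circular)
}

#' Write a mitogenome record as a GenBank flat file
#'
#' Emits the subset of the format that \code{\link{parse_genbank}} reads, so
#' write -> read round-trips the record.
#'
#' @param record a \code{mitogenome_record}
#' @param path output path
#' @return path, invisibly
#' @export
write_genbank <- function(record, path) {
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s     VRT",
                   record$species_id, record$genome_length,
                   if (record$circular) "circular" else "linear"))
  if (!is.null(record$accession)) {
    out <- c(out, paste0("ACCESSION   ", record$accession))
  }
  out <- c(out, paste0("  ORGANISM  ", record$species_id),
           "FEATURES             Location/Qualifiers")
  f <- record$features
  for (i in seq_len(nrow(f))) {
    key <- switch(f$category[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control = "D-loop", OL = "rep_origin")
    span <- if (f$wraps_origin[i]) {
      sprintf("join(%d..%d,1..%d)", f$start[i], record$genome_length, f$end[i])
    } else sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "-") span <- sprintf("complement(%s)", span)
    out <- c(out, sprintf("     %-16s%s", key, span),
             sprintf('                     /gene="%s"', f$base_name[i]))
    if (!is.na(f$anticodon[i])) {
      out <- c(out, sprintf('                     /anticodon_seq="%s"',
                            f$anticodon[i]))
    }
    if (!is.na(f$stop_codon[i])) {
      out <- c(out, sprintf('                     /note_stop="%s"',
                            f$stop_codon[i]))
    }
  }
  if (!is.null(record$sequence)) {
    out <- c(out, "ORIGIN")
    s <- tolower(record$sequence)
    for (pos in seq(1, nchar(s), by = 60)) {
      chunk <- substr(s, pos, min(pos + 59, nchar(s)))
      groups <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", pos, paste(groups, collapse = " ")))
    }
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
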