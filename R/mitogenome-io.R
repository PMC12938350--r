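# Reading, validating, and coordinate arithmetic on annotated circular
# mitogenome records.
#
# Conventions: coordinates are 1-based and fully inclusive ("1-68" has size
# 68); the intergenic spacer after a feature is next.start - prev.end - 1
# (negative = overlap); minus-strand features store heavy-strand coordinates
# as annotated, and orientation is applied only when sequence is extracted.

.FEATURE_COLS <- c(
  "name", "base_name", "category", "strand", "start", "end", "wraps_origin",
  "size_printed", "spacer_printed", "anticodon", "amino_acid", "aa_count",
  "start_codon", "stop_codon"
)

# Accepted canonical labels (after normalization); tRNAs are handled by
# pattern so every standard isotype is accepted.
.GENE_SYNONYMS <- c(
  "COI" = "COXI", "COX1" = "COXI", "CO1" = "COXI",
  "COII" = "COXII", "COX2" = "COXII", "CO2" = "COXII",
  "COIII" = "COXIII", "COX3" = "COXIII", "CO3" = "COXIII",
  "ATP8" = "ATPase8", "ATP6" = "ATPase6",
  "CYTB" = "Cytb", "COB" = "Cytb",
  "12S" = "12S-rRNA", "16S" = "16S-rRNA",
  "12S RRNA" = "12S-rRNA", "16S RRNA" = "16S-rRNA",
  "12S-RRNA" = "12S-rRNA", "16S-RRNA" = "16S-rRNA",
  "RRNS" = "12S-rRNA", "RRNL" = "16S-rRNA",
  "D-LOOP" = "D-loop", "DLOOP" = "D-loop", "CONTROL REGION" = "D-loop",
  "OL" = "OL", "O_L" = "OL", "REP_ORIGIN" = "OL",
  "ND1" = "ND1", "ND2" = "ND2", "ND3" = "ND3", "ND4" = "ND4",
  "ND4L" = "ND4L", "ND5" = "ND5", "ND6" = "ND6",
  "ATPASE8" = "ATPase8", "ATPASE6" = "ATPase6",
  "COXI" = "COXI", "COXII" = "COXII", "COXIII" = "COXIII"
)

#' Normalize a gene label from an annotation table
#'
#' Strips markup (asterisks, caret superscripts), maps synonyms
#' (COI/COX1 -> COXI, ATP8 -> ATPase8, ...) and returns the canonical label
#' used throughout the package (e.g. \code{tRNA-Leu}, \code{12S-rRNA}).
#'
#' @param raw gene label as printed in a feature table
#' @return canonical label
#' @export
normalize_gene_name <- function(raw) {
  x <- trimws(gsub("*", "", raw, fixed = TRUE))
  # tRNA^Leu^ / tRNA-Leu / trnL forms
  m <- regmatches(x, regexec("^tRNA[-^ ]?([A-Za-z]{3})\\^?$", x))[[1]]
  if (length(m) == 2) {
    aa3 <- paste0(toupper(substr(m[2], 1, 1)), tolower(substr(m[2], 2, 3)))
    if (!aa3 %in% names(.AA3_TO_1)) {
      stop("unknown tRNA amino acid '", m[2], "' in label '", raw, "'")
    }
    return(paste0("tRNA-", aa3))
  }
  key <- toupper(x)
  if (key %in% names(.GENE_SYNONYMS)) return(unname(.GENE_SYNONYMS[key]))
  stop("unknown gene label '", raw, "'; accepted labels: tRNA-Xxx, ",
       paste(sort(unique(.GENE_SYNONYMS)), collapse = ", "))
}

#' Feature category from a canonical gene label
#' @param name canonical label
#' @return one of "PCG", "tRNA", "rRNA", "control", "OL"
#' @export
feature_category <- function(name) {
  vapply(name, function(n) {
    base <- sub("-[0-9]+$", "", n)
    if (grepl("^tRNA-", base)) return("tRNA")
    if (grepl("rRNA$", base)) return("rRNA")
    if (base == "D-loop") return("control")
    if (base == "OL") return("OL")
    if (base %in% .PCG_ORDER) return("PCG")
    stop("cannot categorize gene label '", n, "'")
  }, character(1), USE.NAMES = FALSE)
}

# normalize unicode minus/dash variants, strip thousands separators
.norm_num_text <- function(x) {
  x <- gsub("−|–|—|‒", "-", x)
  gsub(",", "", x, fixed = TRUE)
}

.parse_int <- function(x) {
  x <- trimws(.norm_num_text(x))
  if (!nzchar(x)) return(NA_integer_)
  v <- suppressWarnings(as.integer(x))
  if (is.na(v)) stop("cannot parse integer from '", x, "'")
  v
}

.parse_location <- function(loc, row = NA) {
  s <- trimws(.norm_num_text(loc))
  parts <- strsplit(s, "-", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) != 2 || anyNA(suppressWarnings(as.integer(parts)))) {
    stop("malformed Location '", loc, "'",
         if (!is.na(row)) paste0(" in row ", row) else "")
  }
  as.integer(parts)
}

#' Construct an annotated mitogenome record
#'
#' @param species_id species identifier
#' @param genome_length genome length in bp
#' @param features data.frame of features (one row per gene); missing optional
#'   columns are filled with NA
#' @param sequence optional nucleotide string of length \code{genome_length}
#' @param accession optional GenBank accession
#' @param circular logical; circular molecule (default TRUE)
#' @param declared_counts optional named vector with elements PCG, tRNA, rRNA
#'   stating the annotation's claimed gene totals
#' @return object of class \code{mitogenome_record}
#' @export
mitogenome_record <- function(species_id, genome_length, features,
                              sequence = NULL, accession = NULL,
                              circular = TRUE, declared_counts = NULL) {
  stopifnot(is.data.frame(features))
  for (col in .FEATURE_COLS) {
    if (!col %in% names(features)) features[[col]] <- NA
  }
  features <- features[, .FEATURE_COLS]
  if (nrow(features) > 0) {
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    features$wraps_origin <- ifelse(is.na(features$wraps_origin), FALSE,
                                    as.logical(features$wraps_origin))
    if (any(features$start < 1)) stop("feature start < 1")
    bad <- !features$wraps_origin & features$end > genome_length
    if (any(bad)) {
      stop("feature end beyond genome length: ",
           paste(features$name[bad], collapse = ", "))
    }
    if (any(!features$wraps_origin & features$end < features$start)) {
      stop("feature end < start without wraps_origin")
    }
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
  }
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != genome_length) {
      stop("sequence length (", nchar(sequence),
           ") differs from genome_length (", genome_length, ")")
    }
  }
  structure(
    list(species_id = species_id,
         accession = accession,
         genome_length = as.integer(genome_length),
         circular = isTRUE(circular),
         features = features,
         sequence = sequence,
         declared_counts = declared_counts),
    class = "mitogenome_record"
  )
}

#' @export
print.mitogenome_record <- function(x, ...) {
  cat("<mitogenome_record> ", x$species_id,
      if (!is.null(x$accession)) paste0(" (", x$accession, ")"), "\n",
      "  length: ", x$genome_length, " bp",
      if (x$circular) " (circular)", "\n", sep = "")
  ct <- gene_counts(x)
  cat("  genes: ", sum(ct[c("PCG", "tRNA", "rRNA")]),
      " (", ct[["PCG"]], " PCG, ", ct[["tRNA"]], " tRNA, ",
      ct[["rRNA"]], " rRNA)\n", sep = "")
  cat("  sequence: ", if (is.null(x$sequence)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}

#' Gene counts by category
#' @param record a \code{mitogenome_record}
#' @return named integer vector over PCG, tRNA, rRNA, control, OL
#' @export
gene_counts <- function(record) {
  cats <- c("PCG", "tRNA", "rRNA", "control", "OL")
  tab <- table(factor(record$features$category, levels = cats))
  stats::setNames(as.integer(tab), cats)
}

# disambiguate duplicated labels with ordinal suffixes in genomic order
.disambiguate_names <- function(base_names) {
  out <- base_names
  dup <- unique(base_names[duplicated(base_names)])
  for (d in dup) {
    idx <- which(base_names == d)
    out[idx] <- paste0(d, "-", seq_along(idx))
  }
  out
}

#' Parse an annotation feature table
#'
#' Reads the tab-separated dialect used for mitogenome annotation summaries,
#' with columns Gene, Strand, Location, Size(bp), Intergenics Length,
#' Anticodon, AminoAcids, StartCodon, StopCodon. Gene labels may carry markup
#' (\code{*ND1*}, \code{tRNA^Leu^}); locations accept thousands separators
#' and hyphen/en-dash/minus variants. Duplicate gene labels are disambiguated
#' with ordinal suffixes in genomic order (\code{tRNA-Ala-1}, \code{tRNA-Ala-2}).
#'
#' @param text either a path to a TSV file or the TSV content as a character
#'   string (with embedded newlines) or vector of lines
#' @param genome_length total genome length in bp
#' @param species_id species identifier for the record
#' @param circular logical, default TRUE
#' @param accession optional accession string
#' @param declared_counts optional named vector (PCG, tRNA, rRNA)
#' @return a \code{mitogenome_record} (without sequence)
#' @export
parse_feature_table <- function(text, genome_length, species_id,
                                circular = TRUE, accession = NULL,
                                declared_counts = NULL) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE, encoding = "UTF-8")
  } else if (length(text) == 1) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty feature table: no header row")
  if (!grepl("^\\s*\\*?Gene\\*?\\t", lines[1], ignore.case = TRUE)) {
    stop("feature table must begin with a header row starting with 'Gene'")
  }
  body <- lines[-1]
  n <- length(body)
  feats <- lapply(seq_len(n), function(i) {
    cells <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    length(cells) <- 9  # pad trailing empties
    cells[is.na(cells)] <- ""
    name <- normalize_gene_name(cells[1])
    strand <- trimws(.norm_num_text(cells[2]))
    if (!strand %in% c("+", "-")) {
      stop("row ", i, " ('", cells[1], "'): strand must be + or -")
    }
    loc <- tryCatch(.parse_location(cells[3], row = i), error = function(e) {
      stop("row ", i, " ('", cells[1], "'): ", conditionMessage(e),
           call. = FALSE)
    })
    wraps <- loc[2] < loc[1]
    stop_cod <- toupper(trimws(.norm_num_text(cells[9])))
    data.frame(
      name = name, base_name = name, category = feature_category(name),
      strand = strand, start = loc[1], end = loc[2], wraps_origin = wraps,
      size_printed = .parse_int(cells[4]),
      spacer_printed = .parse_int(cells[5]),
      anticodon = ifelse(nzchar(trimws(cells[6])), toupper(trimws(cells[6])),
                         NA_character_),
      amino_acid = NA_character_,
      aa_count = .parse_int(cells[7]),
      start_codon = ifelse(nzchar(trimws(cells[8])),
                           toupper(trimws(cells[8])), NA_character_),
      stop_codon = ifelse(nzchar(stop_cod), stop_cod, NA_character_),
      stringsAsFactors = FALSE
    )
  })
  features <- do.call(rbind, feats)
  if (is.null(features)) {
    features <- data.frame(matrix(nrow = 0, ncol = length(.FEATURE_COLS),
                                  dimnames = list(NULL, .FEATURE_COLS)))
  } else {
    features$name <- .disambiguate_names(features$base_name)
    is_trna <- features$category == "tRNA"
    aa3 <- sub("^tRNA-", "", features$base_name[is_trna])
    features$amino_acid[is_trna] <- unname(.AA3_TO_1[aa3])
  }
  mitogenome_record(species_id, genome_length, features,
                    accession = accession, circular = circular,
                    declared_counts = declared_counts)
}

#' Size of a feature on a circular genome
#'
#' For an ordinary feature the size is \code{end - start + 1}; a feature
#' wrapping the origin covers \code{genome_length - start + 1 + end}
#' positions. Vectorized over features.
#'
#' @param start,end 1-based inclusive coordinates
#' @param genome_length genome length in bp
#' @param wraps_origin logical, feature spans the origin
#' @return integer size(s) in bp
#' @export
#' @examples
#' gene_size(2773, 2846, 17485)        # 74
#' gene_size(95, 4, 100, wraps_origin = TRUE)  # 10
gene_size <- function(start, end, genome_length, wraps_origin = FALSE) {
  wraps_origin <- rep_len(wraps_origin, length(start))
  out <- ifelse(wraps_origin,
                (genome_length - start + 1) + end,
                end - start + 1)
  as.integer(out)
}

#' Sizes of all features in a record
#' @param record a \code{mitogenome_record}
#' @return integer vector named by feature
#' @export
feature_sizes <- function(record) {
  f <- record$features
  stats::setNames(
    gene_size(f$start, f$end, record$genome_length, f$wraps_origin),
    f$name
  )
}

#' Intergenic spacer between two consecutive features
#'
#' The number of unannotated bases between the end of one feature and the
#' start of the next: \code{next_start - prev_end - 1}. Negative values
#' denote overlap. When \code{wrap = TRUE} on a circular record the spacer
#' runs across the origin: \code{genome_length - prev_end + next_start - 1}.
#'
#' @param prev_end end of the upstream feature
#' @param next_start start of the downstream feature
#' @param genome_length genome length in bp
#' @param circular logical; the record is circular
#' @param wrap logical; the gap spans the origin
#' @return signed integer spacer in bp
#' @export
#' @examples
#' intergenic_spacer(2846, 3447, 17485)   # 600
#' intergenic_spacer(9185, 9176, 17485)   # -10 (overlap)
intergenic_spacer <- function(prev_end, next_start, genome_length,
                              circular = TRUE, wrap = FALSE) {
  if (any(wrap & !circular)) {
    stop("cannot compute a spacer across the origin of a non-circular record")
  }
  wrap <- rep_len(wrap, length(prev_end))
  out <- ifelse(wrap,
                genome_length - prev_end + next_start - 1,
                next_start - prev_end - 1)
  as.integer(out)
}

#' Spacers between all consecutive features of a record
#'
#' Returns one spacer per consecutive feature pair in genomic order; for a
#' circular record a final wrap-around spacer (last feature back to the
#' first) is appended.
#'
#' @param record a \code{mitogenome_record}
#' @return named integer vector ("prev->next")
#' @export
intergenic_spacers <- function(record) {
  f <- record$features
  n <- nrow(f)
  if (n < 2) return(stats::setNames(integer(0), character(0)))
  sp <- intergenic_spacer(f$end[-n], f$start[-1], record$genome_length,
                          circular = record$circular)
  nm <- paste0(f$name[-n], "->", f$name[-1])
  if (record$circular) {
    wrap_prev_end <- if (f$wraps_origin[n]) f$end[n] - record$genome_length
                     else f$end[n]
    sp <- c(sp, intergenic_spacer(wrap_prev_end, f$start[1],
                                  record$genome_length,
                                  circular = TRUE, wrap = !f$wraps_origin[n]))
    nm <- c(nm, paste0(f$name[n], "->", f$name[1]))
  }
  stats::setNames(sp, nm)
}

#' Validate the internal consistency of an annotated record
#'
#' Checks, per feature: the printed size against the computed size; the
#' printed amino-acid count of PCGs against \code{amino_acid_length}; the
#' printed intergenic spacer against the computed spacer to the next listed
#' feature; tRNA anticodons against the standard vertebrate mitochondrial
#' assignments; and, when the record declares gene totals, the category
#' counts against them. Violations are returned as data, never raised.
#'
#' @param record a \code{mitogenome_record}
#' @return data.frame of class \code{validation_report} with columns
#'   feature, rule (size-mismatch, aa-mismatch, spacer-mismatch,
#'   anticodon-nonstandard, count-anomaly), expected, observed
#' @export
validate_record <- function(record) {
  f <- record$features
  v <- list()
  add <- function(feature, rule, expected, observed) {
    v[[length(v) + 1]] <<- data.frame(
      feature = feature, rule = rule,
      expected = as.character(expected), observed = as.character(observed),
      stringsAsFactors = FALSE)
  }
  n <- nrow(f)
  if (n > 0) {
    sizes <- feature_sizes(record)
    for (i in seq_len(n)) {
      if (!is.na(f$size_printed[i]) && f$size_printed[i] != sizes[i]) {
        add(f$name[i], "size-mismatch", sizes[i], f$size_printed[i])
      }
      if (f$category[i] == "PCG" && !is.na(f$aa_count[i]) &&
          !is.na(f$stop_codon[i])) {
        aa <- tryCatch(
          amino_acid_length(sizes[i], f$stop_codon[i]),
          error = function(e) NA_integer_)
        if (is.na(aa)) {
          add(f$name[i], "aa-mismatch",
              paste0("integral codon count for size ", sizes[i], " with stop ",
                     f$stop_codon[i]),
              f$aa_count[i])
        } else if (aa != f$aa_count[i]) {
          add(f$name[i], "aa-mismatch", aa, f$aa_count[i])
        }
      }
      if (i < n && !is.na(f$spacer_printed[i])) {
        sp <- intergenic_spacer(f$end[i], f$start[i + 1],
                                record$genome_length,
                                circular = record$circular)
        if (sp != f$spacer_printed[i]) {
          add(f$name[i], "spacer-mismatch", sp, f$spacer_printed[i])
        }
      }
      if (f$category[i] == "tRNA" && !is.na(f$anticodon[i])) {
        std <- .STD_ANTICODON[f$name[i]]
        if (is.na(std)) std <- .STD_ANTICODON[f$base_name[i]]
        if (is.na(std)) {
          # numbered isotype whose standard table keys the base name only
          std <- .STD_ANTICODON[paste0(f$base_name[i], "-1")]
        }
        if (!is.na(std) && f$anticodon[i] != std) {
          add(f$name[i], "anticodon-nonstandard", std, f$anticodon[i])
        }
      }
    }
  }
  if (!is.null(record$declared_counts)) {
    ct <- gene_counts(record)
    for (cat in intersect(names(record$declared_counts), names(ct))) {
      if (ct[[cat]] != record$declared_counts[[cat]]) {
        add(paste0("<", cat, ">"), "count-anomaly",
            record$declared_counts[[cat]], ct[[cat]])
      }
    }
  }
  rep <- if (length(v)) do.call(rbind, v) else
    data.frame(feature = character(0), rule = character(0),
               expected = character(0), observed = character(0),
               stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' Serialize a record's feature table
#'
#' Writes the tab-separated annotation dialect read by
#' \code{\link{parse_feature_table}}; \code{parse(write(x))} is the identity.
#'
#' @param record a \code{mitogenome_record}
#' @param path optional output path; if NULL the TSV text is returned
#' @return the TSV text, invisibly when written to a file
#' @export
write_feature_table <- function(record, path = NULL) {
  f <- record$features
  hdr <- paste("Gene", "Strand", "Location", "Size(bp)", "Intergenics Length",
               "Anticodon", "AminoAcids", "StartCodon", "StopCodon",
               sep = "\t")
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  rows <- if (nrow(f) == 0) character(0) else paste(
    f$base_name, f$strand, paste0(f$start, "-", f$end),
    fmt(f$size_printed), fmt(f$spacer_printed), fmt(f$anticodon),
    fmt(f$aa_count), fmt(f$start_codon), fmt(f$stop_codon),
    sep = "\t")
  txt <- paste(c(hdr, rows), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Write a record to JSON
#' @param record a \code{mitogenome_record}
#' @param path output path
#' @return path, invisibly
#' @export
write_record <- function(record, path) {
  obj <- unclass(record)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a record from JSON written by \code{write_record}
#' @param path input path
#' @return a \code{mitogenome_record}
#' @export
read_record <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- as.data.frame(obj$features, stringsAsFactors = FALSE)
  dc <- obj$declared_counts
  if (!is.null(dc)) dc <- unlist(dc)
  mitogenome_record(obj$species_id, obj$genome_length, feats,
                    sequence = if (is.null(obj$sequence)) NULL
                               else obj$sequence,
                    accession = obj$accession, circular = obj$circular,
                    declared_counts = dc)
}

#' Extract a feature's strand-oriented sequence
#'
#' Returns the coding/structural-strand sequence of the feature: the genomic
#' substring (wrapping the origin where flagged), reverse-complemented for
#' minus-strand features.
#'
#' @param record a \code{mitogenome_record} carrying sequence
#' @param feature feature name or row index
#' @return nucleotide string
#' @export
feature_sequence <- function(record, feature) {
  if (is.null(record$sequence)) stop("record carries no sequence")
  f <- record$features
  i <- if (is.character(feature)) match(feature, f$name) else as.integer(feature)
  if (is.na(i) || i < 1 || i > nrow(f)) stop("unknown feature: ", feature)
  s <- if (f$wraps_origin[i]) {
    paste0(substr(record$sequence, f$start[i], record$genome_length),
           substr(record$sequence, 1, f$end[i]))
  } else {
    substr(record$sequence, f$start[i], f$end[i])
  }
  if (f$strand[i] == "-") revcomp(s) else s
}
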