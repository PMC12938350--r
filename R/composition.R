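# Base composition and strand-skew statistics per region class.

#' GC skew
#'
#' Strand compositional asymmetry (G - C) / (G + C). Accepts raw counts or
#' percentages; the ratio is scale-invariant.
#'
#' @param g,c guanine and cytosine counts or percentages
#' @return ratio in [-1, 1]
#' @export
#' @examples
#' gc_skew(14.37, 26.61)   # -0.29868...
gc_skew <- function(g, c) {
  if (any(g + c <= 0)) stop("undefined skew: G + C must be positive")
  (g - c) / (g + c)
}

#' AT skew
#'
#' Strand compositional asymmetry (A - T) / (A + T).
#'
#' @param a,t adenine and thymine counts or percentages
#' @return ratio in [-1, 1]
#' @export
#' @examples
#' at_skew(29.64, 27.77)   # 0.03257...
at_skew <- function(a, t) {
  if (any(a + t <= 0)) stop("undefined skew: A + T must be positive")
  (a - t) / (a + t)
}

.REGIONS <- c("PCGs", "rRNA", "tRNA", "control", "genome")

.region_rows <- function(record, region) {
  f <- record$features
  switch(region,
         PCGs = which(f$category == "PCG"),
         rRNA = which(f$category == "rRNA"),
         tRNA = which(f$category == "tRNA"),
         control = which(f$category == "control"),
         genome = seq_len(nrow(f)),
         stop("unknown region '", region, "'; one of ",
              paste(.REGIONS, collapse = ", ")))
}

#' Base composition and skews of a genomic region class
#'
#' Concatenates the strand-oriented sequence of every feature in the region
#' (reverse complement for minus-strand features) and reports base
#' percentages, AT content, and both strand skews. \code{region = "genome"}
#' counts the whole heavy-strand sequence regardless of annotation.
#' Ambiguity codes are excluded from all counts and denominators.
#'
#' @param record a \code{mitogenome_record} carrying sequence
#' @param region one of "PCGs", "rRNA", "tRNA", "control", "genome"
#' @param heavy_strand_only if TRUE, count the annotated heavy-strand
#'   substring of every feature instead of its strand-oriented sequence
#' @return list of class \code{composition_profile}: region, counts (named
#'   T/C/A/G), percent (named, to full precision), at_percent, gc_skew,
#'   at_skew, n (bases counted)
#' @export
region_composition <- function(record, region = "genome",
                               heavy_strand_only = FALSE) {
  region <- match.arg(region, .REGIONS)
  if (is.null(record$sequence)) stop("record carries no sequence")
  if (region == "genome") {
    seqs <- record$sequence
  } else {
    idx <- .region_rows(record, region)
    if (length(idx) == 0) stop("region '", region, "' has no features")
    seqs <- vapply(idx, function(i) {
      if (heavy_strand_only) {
        f <- record$features
        s <- if (f$wraps_origin[i]) {
          paste0(substr(record$sequence, f$start[i], record$genome_length),
                 substr(record$sequence, 1, f$end[i]))
        } else substr(record$sequence, f$start[i], f$end[i])
        s
      } else {
        feature_sequence(record, i)
      }
    }, character(1))
  }
  chars <- strsplit(toupper(paste(seqs, collapse = "")), "")[[1]]
  counts <- vapply(c(T = "T", C = "C", A = "A", G = "G"),
                   function(b) sum(chars == b), integer(1))
  n <- sum(counts)
  if (n == 0) stop("region '", region, "' contains no unambiguous bases")
  pct <- 100 * counts / n
  structure(list(
    region = region,
    counts = counts,
    percent = pct,
    at_percent = unname(pct[["T"]] + pct[["A"]]),
    # a region devoid of one base class has an undefined skew: report NA
    # rather than raising, so the other statistics stay available
    gc_skew = if (counts[["G"]] + counts[["C"]] > 0)
      gc_skew(counts[["G"]], counts[["C"]]) else NA_real_,
    at_skew = if (counts[["A"]] + counts[["T"]] > 0)
      at_skew(counts[["A"]], counts[["T"]]) else NA_real_,
    n = n
  ), class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf(
    "<composition_profile> %s (%d bp)\n  T %.2f%%  C %.2f%%  A %.2f%%  G %.2f%%  AT %.2f%%\n  GC-skew %.5f  AT-skew %.5f\n",
    x$region, x$n, x$percent[["T"]], x$percent[["C"]], x$percent[["A"]],
    x$percent[["G"]], x$at_percent, x$gc_skew, x$at_skew))
  invisible(x)
}

#' Composition table over region classes
#'
#' One row per region, mirroring the standard mitogenome composition summary
#' layout (T%, C%, A%, G%, AT%, GC skew, AT skew). Percentages are rounded to
#' 2 decimals and skews to 5 in the returned table.
#'
#' @param record a \code{mitogenome_record} carrying sequence
#' @param regions character vector of regions to include
#' @param heavy_strand_only passed to \code{\link{region_composition}}
#' @return data.frame with columns Region, T, C, A, G, AT, GC_skew, AT_skew
#' @export
composition_table <- function(record, regions = .REGIONS,
                              heavy_strand_only = FALSE) {
  rows <- lapply(regions, function(r) {
    p <- region_composition(record, r, heavy_strand_only = heavy_strand_only)
    data.frame(Region = r,
               T = round(p$percent[["T"]], 2), C = round(p$percent[["C"]], 2),
               A = round(p$percent[["A"]], 2), G = round(p$percent[["G"]], 2),
               AT = round(p$at_percent, 2),
               GC_skew = round(p$gc_skew, 5), AT_skew = round(p$at_skew, 5),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
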