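# Packaged reference data: curated annotation tables for the two Yellow Sea
# snailfish mitogenomes (Liparis chefuensis, 18,870 bp; Liparis tanakae,
# 17,485 bp), their printed per-region base percentages, the 16-taxon
# Liparidae phylogeny used for character mapping, and the per-species
# WANCY-cluster pattern and habitat-depth assignments.
#
# The annotation tables are kept verbatim as published, including their
# internal inconsistencies (which validate_record is designed to surface);
# coordinates only, no sequence.

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "mitoarch")
  if (!nzchar(p)) stop("packaged fixture not found: ", file)
  p
}

#' Reference snailfish mitogenome fixtures
#'
#' Loads the packaged reference set: annotation records (coordinates only)
#' for Liparis chefuensis (18,870 bp, 37 genes: 13 PCGs + 22 tRNAs + 2 rRNAs)
#' and Liparis tanakae (17,485 bp, 38 genes: 13 PCGs + 23 tRNAs including a
#' duplicated tRNA-Ala + 2 rRNAs), the published per-region base percentages
#' of both genomes, the Liparidae tree topology (16 tips, Cottus dzungaricus
#' outgroup, unresolved nodes as multifurcations), and the tip character
#' maps: WANCY-cluster rearrangement pattern for all tips and habitat depth
#' class (shallow < 30 m, deep > 100 m) for the Liparis tips.
#'
#' @return list with elements \code{chefuensis} and \code{tanakae}
#'   (\code{mitogenome_record}s), \code{composition} (data.frame of printed
#'   T/C/A/G percentages per species and region), \code{tree} (ape phylo),
#'   \code{patterns} and \code{depth} (named tip-state vectors)
#' @export
liparis_fixtures <- function() {
  chef <- parse_feature_table(
    .fixture_path("liparis_chefuensis_features.tsv"),
    genome_length = 18870, species_id = "Liparis_chefuensis",
    accession = "PX718959",
    declared_counts = c(PCG = 13L, tRNA = 22L, rRNA = 2L))
  tana <- parse_feature_table(
    .fixture_path("liparis_tanakae_features.tsv"),
    genome_length = 17485, species_id = "Liparis_tanakae",
    accession = "PX718960",
    declared_counts = c(PCG = 13L, tRNA = 23L, rRNA = 2L))
  comp <- utils::read.delim(.fixture_path("liparis_composition.tsv"),
                            stringsAsFactors = FALSE)
  tree <- parse_newick(.fixture_path("liparidae_tree.nwk"))
  pat <- utils::read.delim(.fixture_path("liparis_patterns.tsv"),
                           stringsAsFactors = FALSE)
  dep <- utils::read.delim(.fixture_path("liparis_depth.tsv"),
                           stringsAsFactors = FALSE)
  list(chefuensis = chef,
       tanakae = tana,
       composition = comp,
       tree = tree,
       patterns = stats::setNames(pat$pattern, pat$tip),
       depth = stats::setNames(dep$depth_class, dep$tip))
}
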