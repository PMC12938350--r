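# End-to-end orchestration: parse -> validate -> composition -> codon ->
# cluster/TDRL -> phylogenetic character mapping, with a reproducible output
# manifest.

#' Assemble a pipeline configuration
#'
#' @param inputs list of input descriptors; each either an existing
#'   \code{mitogenome_record} or a list with \code{table} (feature-table
#'   path), \code{genome_length} and \code{species_id} (plus optional
#'   \code{fasta} with the genome sequence), or a list with \code{genbank}
#'   (flat-file path), or a list with \code{json} (record JSON path)
#' @param out_dir output directory
#' @param regions region classes for composition statistics
#' @param reference_order source gene order for TDRL search (default WANCY)
#' @param max_rounds TDRL search depth (default 2)
#' @param tree optional newick path or phylo for character mapping
#' @param characters optional two-column TSV (tip, state) or named vector
#' @param n_perm,seed permutation-test settings
#' @param verbose print stage progress
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(inputs, out_dir,
                            regions = c("PCGs", "rRNA", "tRNA", "control",
                                        "genome"),
                            reference_order = "WANCY", max_rounds = 2,
                            tree = NULL, characters = NULL,
                            n_perm = 999, seed = 42, verbose = FALSE) {
  structure(list(inputs = inputs, out_dir = out_dir, regions = regions,
                 reference_order = reference_order, max_rounds = max_rounds,
                 tree = tree, characters = characters, n_perm = n_perm,
                 seed = seed, verbose = verbose),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of \code{\link{pipeline_config}}
#' @return a \code{pipeline_config}
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.load_input <- function(x) {
  if (inherits(x, "mitogenome_record")) return(x)
  if (!is.null(x$json)) return(read_record(x$json))
  if (!is.null(x$genbank)) return(parse_genbank(x$genbank))
  if (!is.null(x$table)) {
    rec <- parse_feature_table(x$table, genome_length = x$genome_length,
                               species_id = x$species_id)
    if (!is.null(x$fasta)) {
      fa <- seqinr::read.fasta(x$fasta, as.string = TRUE, seqonly = TRUE)
      rec$sequence <- toupper(fa[[1]])
      if (nchar(rec$sequence) != rec$genome_length) {
        stop("FASTA length does not match genome_length for ", x$species_id)
      }
    }
    return(rec)
  }
  stop("input descriptor needs one of: a record, json, genbank, table")
}

#' Run the full mitogenome analysis pipeline
#'
#' Stages, in order: parse inputs; validate annotations; per-region
#' composition statistics and codon usage (sequence-bearing records only);
#' ND2-COI cluster extraction, pattern classification and minimal-TDRL
#' search from the reference order; Fitch character mapping with a
#' tip-permutation test when a tree and character map are configured (the
#' phylo stage is skipped with a logged notice otherwise). Output files are
#' deterministic given the configuration and seed; the returned manifest
#' lists every file with its MD5 hash.
#'
#' @param cfg a \code{pipeline_config}
#' @return the manifest (list), invisibly written to
#'   \code{out_dir/manifest.json}; element \code{patterns} maps species to
#'   pattern labels, \code{n_violations} counts validation violations
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (isTRUE(cfg$verbose)) message(msg)
  }
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)

  say("stage parse: ", length(cfg$inputs), " input(s)")
  records <- lapply(cfg$inputs, function(x) {
    tryCatch(.load_input(x), error = function(e) {
      stop("stage parse failed for input '",
           paste(unlist(x)[1], collapse = ""), "': ", conditionMessage(e),
           call. = FALSE)
    })
  })
  names(records) <- vapply(records, `[[`, character(1), "species_id")

  say("stage validate")
  n_viol <- 0L
  for (sp in names(records)) {
    rep <- validate_record(records[[sp]])
    n_viol <- n_viol + nrow(rep)
    p <- file.path(cfg$out_dir, paste0(sp, "_validation.tsv"))
    utils::write.table(as.data.frame(rep), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(p)
    say("  ", sp, ": ", nrow(rep), " violation(s)")
  }

  for (sp in names(records)) {
    rec <- records[[sp]]
    if (is.null(rec$sequence)) {
      say("stage stats: skipped for ", sp, " (no sequence)")
      next
    }
    say("stage stats: ", sp)
    tab <- composition_table(rec, regions = cfg$regions)
    p <- file.path(cfg$out_dir, paste0(sp, "_composition.tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
    say("stage codon: ", sp)
    cut <- compute_rscu(codon_counts(extract_cds(rec)))
    p <- file.path(cfg$out_dir, paste0(sp, "_rscu.tsv"))
    write_rscu(cut, p)
    emit(p)
  }

  say("stage cluster")
  patterns <- vapply(records, function(r)
    classify_pattern(extract_cluster(r)), character(1))
  for (sp in names(records)) say("  ", sp, ": ", patterns[[sp]])

  say("stage tdrl (reference ", cfg$reference_order, ", max_rounds ",
      cfg$max_rounds, ")")
  tdrl <- list()
  for (sp in names(records)) {
    obs <- extract_cluster(records[[sp]])
    if (identical(paste(unclass(obs), collapse = ""),
                  toupper(cfg$reference_order))) {
      tdrl[[sp]] <- list(min_rounds = 0L, n_scenarios = 1L)
      next
    }
    sc <- tryCatch(
      minimal_scenarios(cfg$reference_order, obs,
                        max_rounds = cfg$max_rounds),
      error = function(e) NULL)
    if (is.null(sc)) {
      say("  ", sp, ": TDRL search not applicable (",
          "alphabet differs from reference)")
      next
    }
    p <- file.path(cfg$out_dir, paste0(sp, "_tdrl_scenarios.json"))
    write_scenarios(sc, p)
    emit(p)
    tdrl[[sp]] <- list(min_rounds = attr(sc, "min_rounds"),
                       n_scenarios = length(sc))
    say("  ", sp, ": min rounds ", attr(sc, "min_rounds"), ", ",
        length(sc), " scenario(s)")
  }

  phylo_res <- NULL
  if (!is.null(cfg$tree) && !is.null(cfg$characters)) {
    say("stage phylo")
    tree <- if (inherits(cfg$tree, "phylo")) cfg$tree else
      parse_newick(cfg$tree)
    chars <- if (is.character(cfg$characters) &&
                 length(cfg$characters) == 1 &&
                 file.exists(cfg$characters)) {
      d <- utils::read.delim(cfg$characters, stringsAsFactors = FALSE)
      stats::setNames(d[[2]], d[[1]])
    } else cfg$characters
    fit <- fitch_parsimony(tree, chars)
    perm <- tip_permutation_test(tree, chars, n_perm = cfg$n_perm,
                                 seed = cfg$seed)
    phylo_res <- list(steps = fit$steps, p_value = perm$p_value,
                      n_perm = cfg$n_perm, seed = cfg$seed)
    say("  fitch steps ", fit$steps, ", permutation p = ",
        format(perm$p_value, digits = 4))
  } else {
    say("stage phylo: skipped (tree or character map not configured)")
  }

  log_path <- file.path(cfg$out_dir, "pipeline.log")
  writeLines(log_lines, log_path)
  emit(log_path)

  manifest <- list(
    seed = cfg$seed,
    patterns = as.list(patterns),
    tdrl = tdrl,
    phylo = phylo_res,
    n_violations = n_viol,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = basename(p),
                                      md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
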