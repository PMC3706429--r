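# Orchestration over the analysis stages. Each runner validates its
# inputs, writes its standard tables plus a manifest sufficient to
# reproduce the outputs byte-for-byte, and returns its results
# invisibly. These are the package's pipeline entry points.

validate_config <- function(config, known) {
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  config
}

write_manifest <- function(dir, stage, params) {
  jsonlite::write_json(
    c(list(stage = stage,
           package = "phageMosaic",
           version = as.character(utils::packageVersion("phageMosaic"))),
      params),
    file.path(dir, paste0(stage, ".manifest.json")),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
}

#' Simulate a synthetic cohort and write it to disk
#'
#' Wraps [makeCohort()]: writes one FASTA and feature TSV per genome
#' (host included), the truth log as JSON, and a manifest.
#'
#' @param out_dir Output directory.
#' @param scenario `"cluster_j_like"` or `"minimal"`.
#' @param seed Integer root seed.
#' @param genome_length,host_length Optional size overrides.
#' @return The cohort, invisibly.
#' @export
runSimulate <- function(out_dir, scenario = "cluster_j_like", seed = 1L,
                        genome_length = NULL, host_length = NULL) {
  cohort <- makeCohort(scenario, seed = seed, genome_length = genome_length,
                       host_length = host_length)
  writeCohort(cohort, out_dir)
  write_manifest(out_dir, "simulate",
                 list(scenario = scenario, seed = seed,
                      genome_length = genome_length, host_length = host_length))
  invisible(cohort)
}

#' Compare genomes: ANI matrix, pham shared-gene matrix, optional dotplot
#'
#' Writes `ani_matrix.tsv` (3 decimals), `shared_genes.tsv`,
#' `phams.tsv`, and optionally per-pair dotplot match TSVs.
#'
#' @param genomes List of at least two [PhageGenome-class] objects.
#' @param out_dir Output directory.
#' @param fragment ANI fragment size (bp).
#' @param dotplots Also write k-mer match tables for every pair.
#' @param dot_k Dotplot word size.
#' @return List with `ani`, `shared`, `phams`, invisibly.
#' @export
runCompare <- function(genomes, out_dir, fragment = 1000L, dotplots = FALSE,
                       dot_k = 15L) {
  if (length(genomes) < 2L) stop("need at least two genomes to compare")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ani_m <- aniMatrix(genomes, fragment)
  utils::write.table(format(round(ani_m, 3), nsmall = 3),
                     file.path(out_dir, "ani_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  prot <- cohortProteins(genomes)
  phams <- buildPhams(scoreEdges(prot), prot)
  shared <- sharedGeneMatrix(phams)
  utils::write.table(shared, file.path(out_dir, "shared_genes.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  writePhamTable(phams, file.path(out_dir, "phams.tsv"))
  if (dotplots) {
    for (i in seq_along(genomes)) {
      for (j in seq_along(genomes)) {
        if (i >= j) next
        dm <- dotplotMatches(genomeSeq(genomes[[i]]), genomeSeq(genomes[[j]]),
                             k = dot_k)
        utils::write.table(dm, file.path(out_dir, sprintf(
          "dotplot_%s_%s.tsv", genomeId(genomes[[i]]), genomeId(genomes[[j]]))),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  write_manifest(out_dir, "compare",
                 list(genomes = vapply(genomes, genomeId, character(1)),
                      fragment = fragment, dot_k = if (dotplots) dot_k else NULL))
  invisible(list(ani = ani_m, shared = shared, phams = phams))
}

calls_to_table <- function(calls) {
  if (!length(calls)) {
    return(data.frame(carrier = character(0), reference = character(0),
                      start = integer(0), end = integer(0), length = integer(0),
                      host_gene = character(0), type = character(0),
                      tsd_len = integer(0), tsd_seq = character(0),
                      deletion_bp = integer(0), restored_identity = numeric(0),
                      exon1_ends_T = logical(0), intron_ends_G = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(calls, function(cl) {
    ev <- cl@evidence
    data.frame(
      carrier = cl@carrier, reference = cl@reference,
      start = cl@start, end = cl@end, length = cl@length,
      host_gene = cl@host_gene, type = cl@type,
      tsd_len = if (!is.null(ev$tsd)) ev$tsd$tsd_len else NA_integer_,
      tsd_seq = if (!is.null(ev$tsd)) ev$tsd$tsd_seq else NA_character_,
      deletion_bp = if (!is.null(ev$deletion_bp)) ev$deletion_bp else NA_integer_,
      restored_identity = if (!is.null(ev$splice)) ev$splice$restored_identity else NA_real_,
      exon1_ends_T = if (!is.null(ev$splice)) unname(ev$splice$group_I_flags[1]) else NA,
      intron_ends_G = if (!is.null(ev$splice)) unname(ev$splice$group_I_flags[2]) else NA,
      stringsAsFactors = FALSE
    )
  }))
}

#' Write insertion calls as BED (0-based half-open, writer boundary only)
#'
#' @param calls List of [InsertionCall-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCallsBed <- function(calls, path) {
  tab <- calls_to_table(calls)
  bed <- data.frame(chrom = tab$carrier, chromStart = tab$start - 1L,
                    chromEnd = tab$end, name = tab$type)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Scan carrier/reference pairs for mobile elements and att sites
#'
#' For each designated pair, runs [findInsertions()] +
#' [classifyInsertion()]; for each phage with an annotated integrase,
#' runs [findAttCore()] against the host. Writes `insertions.tsv`, a
#' consolidated `scan.json` with full evidence, an optional BED, and the
#' capsid report for the supplied triangulation number.
#'
#' @param genomes Named list of [PhageGenome-class] objects.
#' @param pairs `data.frame` with `carrier`, `reference` genome ids.
#' @param out_dir Output directory.
#' @param host Optional host [PhageGenome-class] for att discovery.
#' @param capsid_T Optional triangulation number for the capsid report.
#' @return List with `calls`, `att`, `capsid`, invisibly.
#' @export
runScan <- function(genomes, pairs, out_dir, host = NULL, capsid_T = NULL) {
  missing <- setdiff(unique(c(pairs$carrier, pairs$reference)), names(genomes))
  if (length(missing)) stop("missing genomes: ", paste(missing, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  calls <- list()
  for (i in seq_len(nrow(pairs))) {
    calls <- c(calls, scanPair(genomes[[pairs$carrier[i]]],
                               genomes[[pairs$reference[i]]]))
  }
  tab <- calls_to_table(calls)
  utils::write.table(tab, file.path(out_dir, "insertions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeCallsBed(calls, file.path(out_dir, "insertions.bed"))
  att <- NULL
  if (!is.null(host)) {
    att <- lapply(genomes, function(g) {
      ft <- geneFeatures(g)
      ig <- ft[grepl("integrase", ft$product), , drop = FALSE]
      if (!nrow(ig)) return(NULL)
      findAttCore(g, host, ig[1, ])
    })
    att <- Filter(Negate(is.null), att)
    att_tab <- do.call(rbind, lapply(names(att), function(id) {
      a <- att[[id]]
      if (!a@found) return(NULL)
      data.frame(genome = id, core_len = nchar(a@core_seq),
                 phage_start = a@phage_interval[1], phage_end = a@phage_interval[2],
                 host_start = a@host_interval[1], host_end = a@host_interval[2],
                 strand = a@strand, trna = a@trna_overlap,
                 arm_sites = nrow(a@arm_sites), stringsAsFactors = FALSE)
    }))
    if (!is.null(att_tab)) {
      utils::write.table(att_tab, file.path(out_dir, "att_sites.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  capsid <- if (!is.null(capsid_T)) capsidReport(capsid_T, portal_present = TRUE)
  jsonlite::write_json(
    list(insertions = tab, capsid = capsid),
    file.path(out_dir, "scan.json"), auto_unbox = TRUE, digits = NA, na = "null"
  )
  write_manifest(out_dir, "scan",
                 list(pairs = pairs, capsid_T = capsid_T,
                      host = if (!is.null(host)) genomeId(host) else NULL))
  invisible(list(calls = calls, att = att, capsid = capsid))
}
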