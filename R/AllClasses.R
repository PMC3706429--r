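#' @import methods
NULL

# ---- PhageGenome -------------------------------------------------------

empty_features <- function() {
  data.frame(
    gene_number = character(0),
    start = integer(0),
    end = integer(0),
    strand = character(0),
    kind = character(0),
    product = character(0),
    translation = character(0),
    stringsAsFactors = FALSE
  )
}

#' PhageGenome: a named DNA sequence with ordered gene features
#'
#' The central container of the package. Holds one linear genome as a plain
#' DNA string over \{A,C,G,T,N\} together with an ordered feature table.
#' All coordinates are 1-based inclusive throughout the package, matching
#' GenBank convention.
#'
#' The feature table has columns `gene_number` (character label),
#' `start`, `end` (1-based inclusive), `strand` (`+`/`-`),
#' `kind` (`CDS`, `tRNA`, `other`), `product`, and optional `translation`.
#'
#' @slot id Genome label.
#' @slot seq DNA string (single character value), uppercase, `U` already
#'   normalized to `T` on input.
#' @slot features `data.frame` of gene features, sorted by `start`.
#' @slot source Provenance text: a file path or `"synthetic"`.
#'
#' @export
setClass("PhageGenome",
  representation(
    id = "character",
    seq = "character",
    features = "data.frame",
    source = "character"
  ),
  prototype(features = empty_features(), source = "memory")
)

setValidity("PhageGenome", function(object) {
  msgs <- character(0)
  if (length(object@seq) != 1L || nchar(object@seq) < 1L) {
    msgs <- c(msgs, "seq must be a single non-empty string")
  } else if (grepl("[^ACGTN]", object@seq)) {
    msgs <- c(msgs, "seq contains characters outside {A,C,G,T,N}")
  }
  ft <- object@features
  need <- c("gene_number", "start", "end", "strand", "kind", "product")
  if (!all(need %in% names(ft))) {
    msgs <- c(msgs, paste("features must have columns:", paste(need, collapse = ", ")))
  } else if (nrow(ft) > 0L) {
    if (any(ft$start < 1L) || any(ft$end > nchar(object@seq))) {
      msgs <- c(msgs, "feature interval outside [1, genome length]")
    }
    if (any(ft$end < ft$start)) msgs <- c(msgs, "feature with end < start")
    if (!all(ft$strand %in% c("+", "-"))) msgs <- c(msgs, "strand must be '+' or '-'")
    if (is.unsorted(ft$start)) msgs <- c(msgs, "features must be sorted by start")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PhageGenome
#'
#' @param id Genome label.
#' @param seq DNA string; lowercase and `U` are normalized.
#' @param features Feature `data.frame` (see [PhageGenome-class]); may omit
#'   the `translation` column.
#' @param source Provenance text.
#' @return A [PhageGenome-class] object.
#' @examples
#' g <- PhageGenome("toy", "ATGAAATAAACGT")
#' genomeLength(g)
#' @export
PhageGenome <- function(id, seq, features = empty_features(), source = "memory") {
  seq <- chartr("u", "t", toupper(seq))
  seq <- chartr("U", "T", seq)
  if (!"translation" %in% names(features)) features$translation <- NA_character_
  features$gene_number <- as.character(features$gene_number)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features) > 1L) features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  new("PhageGenome", id = id, seq = seq, features = features, source = source)
}

#' @describeIn PhageGenome-class genome label
#' @param x,object A `PhageGenome`.
#' @export
genomeId <- function(x) x@id

#' @describeIn PhageGenome-class genome sequence as a character string
#' @export
genomeSeq <- function(x) x@seq

#' @describeIn PhageGenome-class genome length in bp
#' @export
genomeLength <- function(x) nchar(x@seq)

#' @describeIn PhageGenome-class the feature table
#' @export
geneFeatures <- function(x) x@features

setMethod("show", "PhageGenome", function(object) {
  cat(sprintf(
    "PhageGenome '%s': %d bp, %d features (%d CDS, %d tRNA), GC %.1f%% [%s]\n",
    object@id, nchar(object@seq), nrow(object@features),
    sum(object@features$kind == "CDS"), sum(object@features$kind == "tRNA"),
    100 * gcContent(object), object@source
  ))
})

# ---- TruthLog ----------------------------------------------------------

#' TruthLog: ground truth for synthetic cohorts
#'
#' Records every event applied by the synthetic-genome generator: point
#' substitutions and indels from the evolution step (per genome, in ancestor
#' coordinates) and every planted mobile element with its exact final
#' coordinates. This is the oracle recovery tests compare against.
#'
#' @slot events `data.frame` with one row per planted element:
#'   `kind`, `genome`, `start`, `end` (final carrier coordinates, 1-based
#'   inclusive), `payload`, `host_gene`, `tsd_len`, `tsd_seq`,
#'   `deletion_bp`, `deleted_seq`, `replaced_seq`, `exon1_end`, `aa_pos`.
#' @slot subs Per-genome list of substitution tables
#'   (`pos`, `old`, `new` in ancestor coordinates).
#' @slot indels Per-genome list of indel tables.
#' @slot pre_plant Named character vector: each genome's sequence after
#'   evolution but before any planting (conservation oracle).
#' @slot seed Integer root seed.
#' @slot scenario Scenario name.
#' @export
setClass("TruthLog",
  representation(
    events = "data.frame",
    subs = "list",
    indels = "list",
    pre_plant = "character",
    seed = "integer",
    scenario = "character"
  )
)

setValidity("TruthLog", function(object) {
  ev <- object@events
  need <- c("kind", "genome", "start", "end")
  if (nrow(ev) > 0L && !all(need %in% names(ev))) {
    return("events must have columns kind, genome, start, end")
  }
  if (nrow(ev) > 0L && any(ev$end < ev$start)) return("event with end < start")
  TRUE
})

setMethod("show", "TruthLog", function(object) {
  cat(sprintf(
    "TruthLog: %d planted events across %d genomes (scenario '%s', seed %d)\n",
    nrow(object@events), length(object@subs), object@scenario, object@seed
  ))
  if (nrow(object@events)) print(table(object@events$kind))
})

#' @describeIn TruthLog-class the planted-event table
#' @param x A `TruthLog`.
#' @export
truthEvents <- function(x) x@events

# ---- InsertionCall -----------------------------------------------------

#' InsertionCall: an intervening segment present in one genome, absent in a relative
#'
#' @slot carrier,reference Genome ids.
#' @slot start,end 1-based inclusive coordinates of the inserted segment in
#'   the carrier, left-normalized (shifted to the smallest start compatible
#'   with the flanking repeat structure, as in VCF indel convention).
#' @slot length Segment length in bp (`end - start + 1`).
#' @slot host_gene Gene label of the annotated CDS containing the segment,
#'   or `NA` for intergenic insertions.
#' @slot flank_anchor_len Exact-match length on each side of the junction.
#' @slot type One of `intron`, `intein`, `transposon`, `endonuclease`,
#'   `unclassified`.
#' @slot evidence List of type-specific evidence (reference junction
#'   coordinates, reference bases lost at the target, splice/TSD/intein
#'   results once classified).
#' @export
setClass("InsertionCall",
  representation(
    carrier = "character",
    reference = "character",
    start = "integer",
    end = "integer",
    length = "integer",
    host_gene = "character",
    flank_anchor_len = "integer",
    type = "character",
    evidence = "list"
  ),
  prototype(type = "unclassified", host_gene = NA_character_, evidence = list())
)

setValidity("InsertionCall", function(object) {
  msgs <- character(0)
  if (object@length < 1L) msgs <- c(msgs, "length must be >= 1")
  if (object@length != object@end - object@start + 1L) {
    msgs <- c(msgs, "length inconsistent with coordinates")
  }
  if (object@flank_anchor_len < 1L) msgs <- c(msgs, "flank anchors must be >= 1 bp")
  if (!object@type %in% c("intron", "intein", "transposon", "endonuclease", "unclassified")) {
    msgs <- c(msgs, "unknown type")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "InsertionCall", function(object) {
  cat(sprintf(
    "InsertionCall: %s %d-%d (%d bp) vs %s; host gene %s; type %s\n",
    object@carrier, object@start, object@end, object@length,
    object@reference,
    ifelse(is.na(object@host_gene), "<intergenic>", object@host_gene),
    object@type
  ))
})

#' @describeIn InsertionCall-class carrier coordinates as `c(start, end)`
#' @param x An `InsertionCall`.
#' @export
callCoords <- function(x) c(start = x@start, end = x@end)

#' @describeIn InsertionCall-class assigned element type
#' @export
callType <- function(x) x@type

# ---- AttSite -----------------------------------------------------------

#' AttSite: an attP/attB common core shared between phage and host
#'
#' @slot core_seq The common-core DNA (identical in phage and host after
#'   strand normalization).
#' @slot phage_interval,host_interval 1-based inclusive intervals.
#' @slot strand `+` when the host carries the core on the same strand as
#'   the phage, `-` when on the reverse complement.
#' @slot trna_overlap Product label of the host tRNA overlapping the core,
#'   or `NA`.
#' @slot distance_from_int_3prime Gap in bp between the integrase 3' end
#'   and the core start.
#' @slot arm_sites `data.frame` of arm-type repeats (`name`, `start`,
#'   `end`, `orientation`, `mismatches`, `seq`).
#' @slot found `FALSE` for a no-site result (best shared length below the
#'   minimum core length; recorded in `core_seq` anyway).
#' @export
setClass("AttSite",
  representation(
    core_seq = "character",
    phage_interval = "integer",
    host_interval = "integer",
    strand = "character",
    trna_overlap = "character",
    distance_from_int_3prime = "integer",
    arm_sites = "data.frame",
    found = "logical"
  ),
  prototype(
    trna_overlap = NA_character_, found = TRUE,
    arm_sites = data.frame()
  )
)

setValidity("AttSite", function(object) {
  if (!object@found) return(TRUE)
  if (nchar(object@core_seq) != diff(object@phage_interval) + 1L) {
    return("core length inconsistent with phage interval")
  }
  if (nchar(object@core_seq) != diff(object@host_interval) + 1L) {
    return("core length inconsistent with host interval")
  }
  TRUE
})

setMethod("show", "AttSite", function(object) {
  if (!object@found) {
    cat(sprintf("AttSite: no core found (best shared length %d bp)\n",
                nchar(object@core_seq)))
    return(invisible(NULL))
  }
  cat(sprintf(
    "AttSite: %d bp core, phage %d-%d, host %d-%d (%s strand)%s; %d arm-type sites\n",
    nchar(object@core_seq),
    object@phage_interval[1], object@phage_interval[2],
    object@host_interval[1], object@host_interval[2], object@strand,
    ifelse(is.na(object@trna_overlap), "",
           paste0("; overlaps ", object@trna_overlap)),
    nrow(object@arm_sites)
  ))
})

#' @describeIn AttSite-class the common-core sequence
#' @param x An `AttSite`.
#' @export
coreSeq <- function(x) x@core_seq

# ---- CapsidGeometry ----------------------------------------------------

#' CapsidGeometry: icosahedral lattice stoichiometry
#'
#' @slot h,k Non-negative lattice indices (not both zero).
#' @slot T Triangulation number, `h^2 + h*k + k^2`.
#' @slot subunits_total `60 * T`.
#' @slot subunits_virion `60 * T - 5` when a portal replaces one pentameric
#'   vertex, else `60 * T`.
#' @slot portal_present Logical.
#' @export
setClass("CapsidGeometry",
  representation(
    h = "integer", k = "integer", T = "integer",
    subunits_total = "integer", subunits_virion = "integer",
    portal_present = "logical"
  )
)

setValidity("CapsidGeometry", function(object) {
  msgs <- character(0)
  if (object@h < 0L || object@k < 0L || (object@h == 0L && object@k == 0L)) {
    msgs <- c(msgs, "(h,k) must be non-negative and not both zero")
  }
  if (object@T != object@h^2 + object@h * object@k + object@k^2) {
    msgs <- c(msgs, "T != h^2 + hk + k^2")
  }
  if (object@subunits_total != 60L * object@T) msgs <- c(msgs, "subunits_total != 60T")
  expected <- 60L * object@T - if (object@portal_present) 5L else 0L
  if (object@subunits_virion != expected) msgs <- c(msgs, "subunits_virion inconsistent")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CapsidGeometry", function(object) {
  cat(sprintf(
    "CapsidGeometry: T=%d (h=%d,k=%d); %d subunits per shell, %d per virion%s\n",
    object@T, object@h, object@k, object@subunits_total, object@subunits_virion,
    if (object@portal_present) " (portal at one vertex)" else ""
  ))
})
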