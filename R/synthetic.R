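# Synthetic ancestor/descendant genome generation with planted mobile
# elements and a machine-readable truth log. The generator defines the
# study conditions recovery tests run under: ~110 kb, ~61% GC phage
# genomes diverged by point substitutions and rare small indels, carrying
# group I intron-like insertions (T|...G boundary hallmarks, optional
# reverse-strand LAGLIDADG ORF), in-frame protein inteins, a transposon
# with a direct target-site duplication, free-standing endonuclease genes
# (precise or deletion-associated), and a shared attP/attB core written
# into a host tRNA gene flanked by degenerate arm-type repeats.
#
# The substitution/indel process is a deliberately simple stand-in (no
# selection, no codon model, no recombination); it reproduces divergence
# LEVELS, not divergence mechanisms.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# stop-free coding DNA: n_codons codons at roughly the target GC,
# ATG start, random stop at the end
make_orf_dna <- function(n_codons, gc) {
  if (n_codons < 3L) stop("ORF needs at least 3 codons")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  inner <- n_codons - 2L
  m <- matrix(sample(DNA_BASES, 3L * inner, replace = TRUE, prob = p), nrow = 3L)
  codons <- paste0(m[1, ], m[2, ], m[3, ])
  repeat {
    bad <- which(codons %in% STOP_CODONS)
    if (!length(bad)) break
    repl <- matrix(sample(DNA_BASES, 3L * length(bad), replace = TRUE, prob = p), nrow = 3L)
    codons[bad] <- paste0(repl[1, ], repl[2, ], repl[3, ])
  }
  paste0("ATG", paste(codons, collapse = ""),
         sample(STOP_CODONS, 1L, prob = c(0.2, 0.3, 0.5)))
}

# codon table for reverse translation (code 11 shares codon assignments
# with the standard code)
aa_codon_table <- function() {
  gc <- Biostrings::getGeneticCode("11")
  split(names(gc), unname(gc))
}

# coding DNA for a given amino-acid string (random synonymous codons)
reverse_translate <- function(aa, codon_table = aa_codon_table()) {
  letters <- strsplit(aa, "", fixed = TRUE)[[1]]
  codons <- vapply(letters, function(x) {
    opts <- codon_table[[x]]
    if (is.null(opts)) stop("cannot reverse-translate residue ", x)
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

random_protein <- function(n_aa) {
  aas <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
  paste(sample(aas, n_aa, replace = TRUE), collapse = "")
}

#' Generate a synthetic ancestral phage genome
#'
#' Produces an i.i.d. background at the target GC with an alternating
#' grid of stop-free CDS genes (size ~ Normal(`gene_mean`, `gene_mean`/5),
#' floored to a multiple of 3, minimum 150 bp) separated by 1-100 bp
#' intergenic gaps. Genes run in alternating strand blocks to mimic the
#' leftwards/rightwards operon layout of temperate phage genomes.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc Target GC fraction in (0, 1).
#' @param gene_mean Mean CDS length in bp.
#' @param seed Integer seed; identical inputs give byte-identical output.
#' @param id Genome label.
#' @return A [PhageGenome-class] with `source = "synthetic"`.
#' @export
generateAncestor <- function(length, gc = 0.61, gene_mean = 900L, seed = 1L,
                             id = "ancestor") {
  if (length < 1000L) stop("genome length must be >= 1000")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (gene_mean < 150L) stop("gene_mean must be >= 150")
  with_seed(seed, {
    seq <- random_dna(length, gc)
    # gene grid
    feats <- list()
    pos <- 0L
    gene_no <- 0L
    strand <- "+"
    block_left <- sample(3:8, 1L)
    repeat {
      gap <- sample(1:100, 1L)
      glen <- max(150L, 3L * as.integer(round(
        stats::rnorm(1L, gene_mean, gene_mean / 5) / 3
      )))
      gstart <- pos + gap + 1L
      gend <- gstart + glen - 1L
      if (gend > length - 50L) break
      gene_no <- gene_no + 1L
      orf <- make_orf_dna(glen %/% 3L, gc)
      seq <- str_overwrite(seq, gstart, if (strand == "-") revComp(orf) else orf)
      feats[[gene_no]] <- data.frame(
        gene_number = as.character(gene_no),
        start = gstart, end = gend, strand = strand,
        kind = "CDS", product = "hypothetical protein",
        translation = NA_character_, stringsAsFactors = FALSE
      )
      pos <- gend
      block_left <- block_left - 1L
      if (block_left == 0L) {
        strand <- if (strand == "+") "-" else "+"
        block_left <- sample(3:8, 1L)
      }
    }
    if (gene_no < 2L) stop("parameters leave no room for genes")
    PhageGenome(id, seq, do.call(rbind, feats), source = "synthetic")
  })
}

#' Evolution parameters for [evolveGenome()]
#'
#' @param substitution_rate Expected substitutions per site, in `[0, 0.5]`.
#' @param indel_rate Expected indel events per site, in `[0, 0.5]`.
#' @param indel_size_geometric_p Geometric size parameter in (0, 1].
#' @param seed Integer seed.
#' @return A validated list of class `EvolutionConfig`.
#' @export
evolutionConfig <- function(substitution_rate = 0, indel_rate = 0,
                            indel_size_geometric_p = 0.5, seed = 1L) {
  if (substitution_rate < 0 || substitution_rate > 0.5) {
    stop("substitution_rate must be in [0, 0.5]")
  }
  if (indel_rate < 0 || indel_rate > 0.5) stop("indel_rate must be in [0, 0.5]")
  if (indel_size_geometric_p <= 0 || indel_size_geometric_p > 1) {
    stop("indel_size_geometric_p must be in (0, 1]")
  }
  structure(
    list(substitution_rate = substitution_rate, indel_rate = indel_rate,
         indel_size_geometric_p = indel_size_geometric_p,
         seed = as.integer(seed)),
    class = "EvolutionConfig"
  )
}

# shift feature coordinates for an insertion of `n` bases after `pos`
features_after_insertion <- function(ft, pos, n) {
  if (!nrow(ft)) return(ft)
  inside <- ft$start <= pos & ft$end > pos
  after <- ft$start > pos
  ft$end[inside] <- ft$end[inside] + n
  ft$start[after] <- ft$start[after] + n
  ft$end[after] <- ft$end[after] + n
  ft
}

# shift feature coordinates for a deletion of [s..e]
features_after_deletion <- function(ft, s, e) {
  if (!nrow(ft)) return(ft)
  # count deleted positions strictly before each coordinate
  del_before <- function(x) pmax(0L, pmin(e, x - 1L) - s + 1L)
  ns <- ft$start - del_before(ft$start)
  ne <- ft$end - del_before(ft$end) - (ft$end >= s & ft$end <= e)
  keep <- !(ft$start >= s & ft$end <= e)
  ft <- ft[keep, , drop = FALSE]
  ft$start <- ns[keep]
  ft$end <- pmax(ne[keep], ft$start)
  ft
}

#' Evolve a genome by point substitutions and small indels
#'
#' Substitutions are drawn per site; indel counts are Poisson with
#' geometric sizes. Indels never fall within 10 bp of a CDS boundary, and
#' indels inside a CDS are coerced to a multiple of 3 so reading frames
#' (and thus protein-level ground truth) stay well defined.
#'
#' @param genome A [PhageGenome-class].
#' @param config An [evolutionConfig()].
#' @param id Label for the evolved genome (default: keep).
#' @return A list with the evolved `genome` and a [TruthLog-class] `truth`
#'   holding the substitution and indel tables (ancestor coordinates).
#' @export
evolveGenome <- function(genome, config, id = genomeId(genome)) {
  stopifnot(inherits(config, "EvolutionConfig"))
  with_seed(config$seed, {
    seq <- genomeSeq(genome)
    ft <- geneFeatures(genome)
    L <- nchar(seq)
    # substitutions
    nsub <- stats::rbinom(1L, L, config$substitution_rate)
    subs <- data.frame(pos = integer(0), old = character(0), new = character(0),
                       stringsAsFactors = FALSE)
    if (nsub > 0L) {
      pos <- sort(sample.int(L, nsub))
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      old <- chars[pos]
      old_i <- match(old, DNA_BASES)
      old_i[is.na(old_i)] <- 1L  # N sites mutate like A; cosmetic
      new_i <- ((old_i - 1L + sample.int(3L, nsub, replace = TRUE)) %% 4L) + 1L
      chars[pos] <- DNA_BASES[new_i]
      # selection against nonsense: revert substitutions that create an
      # in-frame stop inside a CDS, so orthologous proteins stay
      # full-length and protein-level ground truth is well defined
      keep <- rep(TRUE, nsub)
      cds <- ft[ft$kind == "CDS", , drop = FALSE]
      for (rep_pass in 1:3) {
        reverted <- FALSE
        for (gi in seq_len(nrow(cds))) {
          gs <- cds$start[gi]; ge <- cds$end[gi]
          gene_chars <- chars[gs:ge]
          if (cds$strand[gi] == "-") {
            gene_chars <- rev(c(A = "T", C = "G", G = "C", T = "A",
                                N = "N")[gene_chars])
          }
          nc <- length(gene_chars) %/% 3L
          if (nc < 2L) next
          cod <- paste0(gene_chars[3L * seq_len(nc) - 2L],
                        gene_chars[3L * seq_len(nc) - 1L],
                        gene_chars[3L * seq_len(nc)])
          # premature stops, plus a destroyed terminal stop
          bad <- which(cod[-nc] %in% STOP_CODONS)
          if (!(cod[nc] %in% STOP_CODONS)) bad <- c(bad, nc)
          for (b in bad) {
            sense_pos <- (3L * b - 2L):(3L * b)
            gpos <- if (cds$strand[gi] == "+") gs + sense_pos - 1L else
              ge - sense_pos + 1L
            hit <- which(pos %in% gpos & keep)
            if (length(hit)) {
              chars[pos[hit]] <- old[hit]
              keep[hit] <- FALSE
              reverted <- TRUE
            }
          }
        }
        if (!reverted) break
      }
      seq <- paste(chars, collapse = "")
      subs <- data.frame(pos = pos[keep], old = old[keep],
                         new = DNA_BASES[new_i][keep],
                         stringsAsFactors = FALSE)
      nsub <- nrow(subs)
    }
    # indels
    n_indel <- stats::rpois(1L, L * config$indel_rate)
    indels <- data.frame(type = character(0), pos = integer(0), size = integer(0),
                         seq = character(0), stringsAsFactors = FALSE)
    if (n_indel > 0L) {
      cds <- ft[ft$kind == "CDS", , drop = FALSE]
      gc_here <- gcContent(seq)
      planned <- list()
      for (i in seq_len(n_indel)) {
        for (try in 1:200) {
          p <- sample.int(nchar(seq) - 30L, 1L)
          sz <- stats::rgeom(1L, config$indel_size_geometric_p) + 1L
          in_cds <- which(cds$start <= p & cds$end >= p)
          if (length(in_cds)) {
            # keep clear of CDS termini; force frame-preserving size
            if (p < cds$start[in_cds[1]] + 10L || p > cds$end[in_cds[1]] - 10L - sz) next
            sz <- max(3L, 3L * as.integer(round(sz / 3)))
          }
          planned[[i]] <- list(pos = p, size = sz,
                               type = sample(c("ins", "del"), 1L))
          break
        }
      }
      planned <- Filter(Negate(is.null), planned)
      if (length(planned)) {
        ord <- order(vapply(planned, `[[`, 0, "pos"), decreasing = TRUE)
        rows <- list()
        for (ev in planned[ord]) {
          if (ev$type == "ins") {
            ins <- random_dna(ev$size, gc_here)
            seq <- str_insert(seq, ev$pos, ins)
            ft <- features_after_insertion(ft, ev$pos, ev$size)
            rows[[length(rows) + 1L]] <- data.frame(
              type = "ins", pos = ev$pos, size = ev$size, seq = ins,
              stringsAsFactors = FALSE)
          } else {
            s <- ev$pos; e <- min(nchar(seq), ev$pos + ev$size - 1L)
            delseq <- subseq_str(seq, s, e)
            seq <- str_delete(seq, s, e)
            ft <- features_after_deletion(ft, s, e)
            rows[[length(rows) + 1L]] <- data.frame(
              type = "del", pos = s, size = e - s + 1L, seq = delseq,
              stringsAsFactors = FALSE)
          }
        }
        indels <- do.call(rbind, rows)
      }
    }
    g <- PhageGenome(id, seq, ft, source = "synthetic")
    truth <- new("TruthLog",
      events = empty_truth_events(),
      subs = stats::setNames(list(subs), id),
      indels = stats::setNames(list(indels), id),
      pre_plant = stats::setNames(genomeSeq(g), id),
      seed = config$seed, scenario = "evolve"
    )
    list(genome = g, truth = truth)
  })
}

empty_truth_events <- function() {
  data.frame(
    kind = character(0), genome = character(0),
    start = integer(0), end = integer(0),
    payload = character(0), host_gene = character(0),
    tsd_len = integer(0), tsd_seq = character(0),
    deletion_bp = integer(0), deleted_seq = character(0),
    replaced_seq = character(0), exon1_end = integer(0),
    aa_pos = integer(0), orientation = character(0),
    stringsAsFactors = FALSE
  )
}

truth_event <- function(kind, genome, start, end, payload = NA_character_,
                        host_gene = NA_character_, tsd_len = NA_integer_,
                        tsd_seq = NA_character_, deletion_bp = NA_integer_,
                        deleted_seq = NA_character_, replaced_seq = NA_character_,
                        exon1_end = NA_integer_, aa_pos = NA_integer_,
                        orientation = NA_character_) {
  data.frame(kind = kind, genome = genome, start = as.integer(start),
             end = as.integer(end), payload = payload, host_gene = host_gene,
             tsd_len = as.integer(tsd_len), tsd_seq = tsd_seq,
             deletion_bp = as.integer(deletion_bp), deleted_seq = deleted_seq,
             replaced_seq = replaced_seq, exon1_end = as.integer(exon1_end),
             aa_pos = as.integer(aa_pos), orientation = orientation,
             stringsAsFactors = FALSE)
}

#' Specification of one element to plant
#'
#' @param kind One of `"intron"`, `"intein"`, `"transposon"`,
#'   `"endonuclease"`, `"att_core"`.
#' @param target Gene label (intron/intein) or genome coordinate
#'   (transposon/endonuclease site; `NULL` picks an intergenic site).
#' @param payload Optional explicit DNA (or protein for inteins) payload.
#' @param options Kind-specific options, see [plantElement()].
#' @return A list of class `PlantSpec`.
#' @export
plantSpec <- function(kind, target = NULL, payload = NULL, options = list()) {
  kind <- match.arg(kind, c("intron", "intein", "transposon", "endonuclease", "att_core"))
  if (!is.null(options$tsd_len) && (options$tsd_len < 0L || options$tsd_len > 15L)) {
    stop("tsd_len must be in [0, 15]")
  }
  if (!is.null(options$deletion_at_target) && options$deletion_at_target < 0L) {
    stop("deletion_at_target must be >= 0")
  }
  structure(list(kind = kind, target = target, payload = payload,
                 options = options), class = "PlantSpec")
}

# Is the carrier window around an insertion point present verbatim in
# the designated reference? Planting only at locally clean junctions
# keeps the planted truth unambiguous (same rationale as keeping indels
# away from elements): a substitution right at a junction would make the
# element's exact boundary genuinely unidentifiable.
junction_is_clean <- function(genome, point, clean_against, flank = 8L) {
  if (is.null(clean_against)) return(TRUE)
  lo <- point - flank + 1L
  hi <- point + flank
  if (lo < 1L || hi > genomeLength(genome)) return(FALSE)
  grepl(subseq_str(genomeSeq(genome), lo, hi), genomeSeq(clean_against),
        fixed = TRUE)
}

# find an intergenic position with at least `margin` bp of clearance,
# avoiding any `exclude` intervals (e.g. the integrase/att cassette)
pick_intergenic_site <- function(genome, margin = 20L, exclude = NULL) {
  ft <- geneFeatures(genome)
  L <- genomeLength(genome)
  bounds <- rbind(c(0L, ft$start[1]),
                  cbind(ft$end, c(ft$start[-1], L + 1L)))
  gaps <- data.frame(lo = bounds[, 1] + 1L, hi = bounds[, 2] - 1L)
  gaps <- gaps[gaps$hi - gaps$lo + 1L >= 2L * margin & gaps$lo > margin, , drop = FALSE]
  if (!is.null(exclude)) {
    for (iv in exclude) {
      gaps <- gaps[gaps$hi < iv[1] | gaps$lo > iv[2], , drop = FALSE]
    }
  }
  if (!nrow(gaps)) stop("no intergenic site with enough clearance")
  g <- gaps[sample.int(nrow(gaps), 1L), ]
  sample(seq.int(g$lo + margin, g$hi - margin), 1L)
}

#' Plant a mobile element into a synthetic genome
#'
#' Kinds and their options:
#' * `intron`: DNA inserted inside the target CDS at a sense position
#'   whose exon-1 final base is `T`; the payload's final base is forced to
#'   `G` (the group I boundary hallmarks) and carries an in-frame stop so
#'   the interrupted gene cannot read through. Options: `length` (default
#'   819), `internal_orf` (embed a reverse-strand 150-codon ORF containing
#'   the literal motif `LAGLIDADG`), `gc`.
#' * `intein`: in-frame, stop-free coding DNA for a random protein of
#'   `aa_len` (default 340) residues inserted after codon `aa_pos`
#'   (default 104) of the target CDS.
#' * `transposon`: element of `length` (default 1500) bp carrying a
#'   transposase-sized ORF (`orf_aa`, default 420), inserted after
#'   coordinate `target` (or a random intergenic site) with the
#'   `tsd_len`-mer (default 5) ending at the site duplicated on both
#'   flanks. The empty allele keeps a single copy.
#' * `endonuclease`: free-standing ORF cassette (`length` default 1000,
#'   `orf_aa` default 300) at an intergenic site; `deletion_at_target`
#'   (default 0) reference bases are removed upon insertion.
#' * `att_core`: writes an identical common core (`core_len`, default 44)
#'   into the phage ~`offset` (default 100) bp downstream of the
#'   plus-strand gene `int_gene`, and into the anticodon-loop region of
#'   the host tRNA; four consensus-conformant arm-type 10-mers are placed
#'   as P1, P2 (left) and P3, P4 (right), plus an optional inverted pair
#'   near the integrase start (`inverted_at_int_start`). Pass the host
#'   genome as `options$host`; the returned list then also carries the
#'   modified `host`.
#'
#' Draws come from the current RNG state; wrap in a seeded context (or use
#' [makeCohort()]) for reproducibility.
#'
#' @param genome Carrier [PhageGenome-class].
#' @param spec A [plantSpec()].
#' @return A list with the modified `genome`, a one-or-more-row `event`
#'   truth table (final 1-based inclusive coordinates), and for
#'   `att_core` the modified `host`.
#' @export
plantElement <- function(genome, spec) {
  stopifnot(inherits(spec, "PlantSpec"))
  switch(spec$kind,
    intron = plant_intron(genome, spec),
    intein = plant_intein(genome, spec),
    transposon = plant_transposon(genome, spec),
    endonuclease = plant_endonuclease(genome, spec),
    att_core = plant_att_core(genome, spec)
  )
}

get_gene <- function(genome, gene_number) {
  ft <- geneFeatures(genome)
  i <- which(ft$gene_number == as.character(gene_number))
  if (!length(i)) stop("no gene '", gene_number, "' in ", genomeId(genome))
  ft[i[1], , drop = FALSE]
}

# genome coordinate of the insertion point (insert AFTER this position)
# for a sense-strand position q of a gene
sense_to_insert_point <- function(gene, q) {
  if (gene$strand == "+") gene$start + q - 1L else gene$end - q
}

plant_intron <- function(genome, spec) {
  gene <- get_gene(genome, spec$target)
  opt <- spec$options
  len <- if (!is.null(opt$length)) as.integer(opt$length) else 819L
  gc <- if (!is.null(opt$gc)) opt$gc else gcContent(genome)
  internal_orf <- isTRUE(opt$internal_orf)
  sense <- extractGeneDNA(genome, gene)
  glen <- nchar(sense)
  margin <- 45L
  cand <- which(strsplit(subseq_str(sense, margin, glen - margin), "")[[1]] == "T") +
    margin - 1L
  if (!length(cand)) stop("target CDS has no T at a legal insertion point")
  cand <- cand[sample.int(length(cand))]
  q <- NULL
  for (qq in cand) {
    if (junction_is_clean(genome, sense_to_insert_point(gene, qq),
                          opt$clean_against)) {
      q <- qq
      break
    }
  }
  if (is.null(q)) stop("target CDS has no T at a legal insertion point")

  payload <- if (!is.null(spec$payload)) spec$payload else random_dna(len, gc)
  len <- nchar(payload)
  # force the 3' G hallmark
  payload <- paste0(substring(payload, 1L, len - 1L), "G")
  # in-frame stop early in the element so the interrupted gene cannot
  # translate through (introns disrupt; inteins do not)
  stop_at <- 12L + ((1L - q - 12L) %% 3L)  # payload pos with (q+pos) %% 3 == 1
  payload <- str_overwrite(payload, stop_at, "TGA")
  if (internal_orf) {
    if (len < 520L) stop("intron too short for an internal 150-codon ORF")
    aa <- random_protein(150L)
    aa <- paste0("M", str_overwrite(substring(aa, 2L), 50L, "LAGLIDADG"))
    orf <- reverse_translate(aa)
    orf <- paste0("ATG", substring(orf, 4L), sample(STOP_CODONS, 1L))
    payload <- str_overwrite(payload, 40L, revComp(orf))
  }

  p0 <- sense_to_insert_point(gene, q)
  ins <- if (gene$strand == "+") payload else revComp(payload)
  seq2 <- str_insert(genomeSeq(genome), p0, ins)
  ft2 <- features_after_insertion(geneFeatures(genome), p0, len)
  g2 <- PhageGenome(genomeId(genome), seq2, ft2, source = "synthetic")
  exon1_end_coord <- if (gene$strand == "+") p0 else p0 + len + 1L
  list(
    genome = g2,
    event = truth_event("intron", genomeId(genome),
                        start = p0 + 1L, end = p0 + len,
                        payload = payload, host_gene = gene$gene_number,
                        exon1_end = exon1_end_coord,
                        orientation = gene$strand)
  )
}

plant_intein <- function(genome, spec) {
  gene <- get_gene(genome, spec$target)
  opt <- spec$options
  aa_len <- if (!is.null(opt$aa_len)) as.integer(opt$aa_len) else 340L
  if (aa_len < 50L) stop("intein must be >= 50 aa")
  aa_pos <- if (!is.null(opt$aa_pos)) as.integer(opt$aa_pos) else 104L
  sense <- extractGeneDNA(genome, gene)
  if (nchar(sense) < 3L * (aa_pos + 10L)) stop("target CDS too short for aa_pos")
  payload_aa <- if (!is.null(spec$payload)) spec$payload else random_protein(aa_len)
  payload <- reverse_translate(payload_aa)
  q <- 3L * aa_pos
  if (!junction_is_clean(genome, sense_to_insert_point(gene, q), opt$clean_against)) {
    # slide to the nearest clean codon boundary
    for (delta in rep(1:30, each = 2L) * c(1L, -1L)) {
      q2 <- 3L * (aa_pos + delta)
      if (q2 >= 30L && q2 <= nchar(sense) - 30L &&
          junction_is_clean(genome, sense_to_insert_point(gene, q2),
                            opt$clean_against)) {
        q <- q2
        aa_pos <- aa_pos + delta
        break
      }
    }
  }
  p0 <- sense_to_insert_point(gene, q)
  ins <- if (gene$strand == "+") payload else revComp(payload)
  seq2 <- str_insert(genomeSeq(genome), p0, ins)
  ft2 <- features_after_insertion(geneFeatures(genome), p0, nchar(payload))
  list(
    genome = PhageGenome(genomeId(genome), seq2, ft2, source = "synthetic"),
    event = truth_event("intein", genomeId(genome),
                        start = p0 + 1L, end = p0 + nchar(payload),
                        payload = payload_aa, host_gene = gene$gene_number,
                        aa_pos = aa_pos, orientation = gene$strand)
  )
}

# payload with an embedded plus-strand ORF of orf_aa codons
orf_cassette <- function(length, orf_aa, gc, offset = 50L) {
  orf <- make_orf_dna(orf_aa, gc)
  if (length < nchar(orf) + offset + 20L) {
    length <- nchar(orf) + offset + 20L
  }
  str_overwrite(random_dna(length, gc), offset, orf)
}

plant_transposon <- function(genome, spec) {
  opt <- spec$options
  d <- if (!is.null(opt$tsd_len)) as.integer(opt$tsd_len) else 5L
  len <- if (!is.null(opt$length)) as.integer(opt$length) else 1500L
  orf_aa <- if (!is.null(opt$orf_aa)) as.integer(opt$orf_aa) else 420L
  site <- if (!is.null(spec$target)) as.integer(spec$target) else {
    s <- NULL
    for (try in 1:400) {
      s <- pick_intergenic_site(genome, margin = 25L, exclude = opt$exclude)
      if (junction_is_clean(genome, s, opt$clean_against)) break
    }
    s
  }
  if (site < d + 1L) stop("target shorter than tsd_len")
  tsd <- if (d > 0L) subseq_str(genomeSeq(genome), site - d + 1L, site) else ""
  generated <- is.null(spec$payload)
  payload <- if (!generated) spec$payload else
    orf_cassette(len, orf_aa, gcContent(genome))
  len <- nchar(payload)
  if (generated && d > 0L) {
    # keep the duplication length unambiguous: the element's edge bases
    # must not extend the duplicated word into the element
    gseq <- genomeSeq(genome)
    alt <- function(b) setdiff(c("G", "C", "A", "T"), b)[1]
    after <- subseq_str(gseq, site + 1L, site + 1L)
    if (substring(payload, 1L, 1L) == after) {
      payload <- str_overwrite(payload, 1L, alt(after))
    }
    before <- subseq_str(gseq, site - d, site - d)
    if (substring(payload, len, len) == before) {
      payload <- str_overwrite(payload, len, alt(before))
    }
  }
  block <- paste0(payload, tsd)
  seq2 <- str_insert(genomeSeq(genome), site, block)
  ft2 <- features_after_insertion(geneFeatures(genome), site, nchar(block))
  list(
    genome = PhageGenome(genomeId(genome), seq2, ft2, source = "synthetic"),
    event = truth_event("transposon", genomeId(genome),
                        start = site + 1L, end = site + nchar(block),
                        payload = payload, tsd_len = d, tsd_seq = tsd)
  )
}

plant_endonuclease <- function(genome, spec) {
  opt <- spec$options
  del <- if (!is.null(opt$deletion_at_target)) as.integer(opt$deletion_at_target) else 0L
  len <- if (!is.null(opt$length)) as.integer(opt$length) else 1000L
  orf_aa <- if (!is.null(opt$orf_aa)) as.integer(opt$orf_aa) else 150L
  site <- if (!is.null(spec$target)) as.integer(spec$target) else {
    s <- NULL
    for (try in 1:400) {
      s <- pick_intergenic_site(genome, margin = max(25L, del + 10L),
                                exclude = opt$exclude)
      # for a deletion-associated insertion the whole lost stretch plus
      # both flanks must be clean, or the loss count is ambiguous
      if (junction_is_clean(genome, s, opt$clean_against) &&
          junction_is_clean(genome, s + del, opt$clean_against)) break
    }
    s
  }
  payload <- if (!is.null(spec$payload)) spec$payload else
    orf_cassette(len, orf_aa, gcContent(genome))
  len <- nchar(payload)
  seq <- genomeSeq(genome)
  ft <- geneFeatures(genome)
  deleted <- ""
  if (del > 0L) {
    deleted <- subseq_str(seq, site + 1L, site + del)
    # guard the payload edges against content coincidences with the lost
    # target: if edge bases of the element equal the corresponding lost
    # bases, the element/target split is string-ambiguous
    alt <- function(b) setdiff(c("G", "C", "A", "T"), b)[1]
    guard <- min(3L, del)
    for (g in seq_len(guard)) {
      if (substring(payload, g, g) == substring(deleted, g, g)) {
        payload <- str_overwrite(payload, g, alt(substring(deleted, g, g)))
      }
      pg <- len - g + 1L
      dg <- del - g + 1L
      if (substring(payload, pg, pg) == substring(deleted, dg, dg)) {
        payload <- str_overwrite(payload, pg, alt(substring(deleted, dg, dg)))
      }
    }
    seq <- str_delete(seq, site + 1L, site + del)
    ft <- features_after_deletion(ft, site + 1L, site + del)
  }
  seq <- str_insert(seq, site, payload)
  ft <- features_after_insertion(ft, site, len)
  list(
    genome = PhageGenome(genomeId(genome), seq, ft, source = "synthetic"),
    event = truth_event("endonuclease", genomeId(genome),
                        start = site + 1L, end = site + len,
                        payload = payload, deletion_bp = del,
                        deleted_seq = ifelse(del > 0L, deleted, NA_character_))
  )
}

# one consensus-conformant arm-type 10-mer: TGCATACg/tPuPy
sample_arm_site <- function() {
  paste0("TGCATAC",
         sample(c("G", "T"), 1L),
         sample(c("A", "G"), 1L),
         sample(c("C", "T"), 1L))
}

plant_att_core <- function(genome, spec) {
  opt <- spec$options
  host <- opt$host
  if (is.null(host)) stop("att_core planting needs options$host")
  core_len <- if (!is.null(opt$core_len)) as.integer(opt$core_len) else 44L
  core <- if (!is.null(spec$payload)) spec$payload else
    random_dna(core_len, gcContent(host))
  core_len <- nchar(core)
  offset <- if (!is.null(opt$offset)) as.integer(opt$offset) else 100L
  int_gene <- get_gene(genome, opt$int_gene)
  if (int_gene$strand != "+") stop("generator plants att cassettes at plus-strand integrases")

  # host target first: the core goes into the tRNA anticodon-loop region
  hft <- geneFeatures(host)
  tr <- hft[hft$kind == "tRNA", , drop = FALSE]
  if (!nrow(tr)) stop("host has no annotated tRNA")
  h_start <- tr$start[1] + 30L
  hseq0 <- genomeSeq(host)
  host_flanks <- c(subseq_str(hseq0, h_start - 1L, h_start - 1L),
                   subseq_str(hseq0, h_start + core_len, h_start + core_len))

  seq <- genomeSeq(genome)
  events <- list()
  put <- function(kind, start, piece, orientation = NA_character_) {
    old <- subseq_str(seq, start, start + nchar(piece) - 1L)
    seq <<- str_overwrite(seq, start, piece)
    events[[length(events) + 1L]] <<- truth_event(
      kind, genomeId(genome), start, start + nchar(piece) - 1L,
      payload = piece, replaced_seq = old, orientation = orientation)
  }
  core_start <- int_gene$end + offset + 1L
  put("att_core", core_start, core)
  # the shared substring must end exactly at the planted core: the phage
  # bases flanking the core must differ from the host bases flanking its
  # copy, or the common core is ambiguous by chance extension
  alt_base <- function(b) setdiff(c("G", "C", "A", "T"), b)[1]
  if (subseq_str(seq, core_start - 1L, core_start - 1L) == host_flanks[1]) {
    put("att_flank", core_start - 1L, alt_base(host_flanks[1]))
  }
  right_at <- core_start + core_len
  if (subseq_str(seq, right_at, right_at) == host_flanks[2]) {
    put("att_flank", right_at, alt_base(host_flanks[2]))
  }
  # arm-type sites: P1,P2 left of the core, P3,P4 right
  put("arm_site", core_start - 60L, sample_arm_site(), "direct")
  put("arm_site", core_start - 35L, sample_arm_site(), "direct")
  put("arm_site", core_start + core_len + 24L, sample_arm_site(), "direct")
  put("arm_site", core_start + core_len + 49L, sample_arm_site(), "direct")
  if (isTRUE(opt$inverted_at_int_start)) {
    put("arm_site", int_gene$start - 22L, revComp(sample_arm_site()), "inverted")
    put("arm_site", int_gene$start - 12L, revComp(sample_arm_site()), "inverted")
  }
  g2 <- PhageGenome(genomeId(genome), seq, geneFeatures(genome), source = "synthetic")

  # write the identical core into the host
  hseq <- hseq0
  h_old <- subseq_str(hseq, h_start, h_start + core_len - 1L)
  hseq <- str_overwrite(hseq, h_start, core)
  host2 <- PhageGenome(genomeId(host), hseq, hft, source = "synthetic")
  events[[length(events) + 1L]] <- truth_event(
    "att_core_host", genomeId(host), h_start, h_start + core_len - 1L,
    payload = core, replaced_seq = h_old)

  list(genome = g2, host = host2, event = do.call(rbind, events), core = core)
}

# deterministic pick of a CDS meeting constraints, counting from a
# fractional genome position
pick_cds <- function(genome, min_len, strand = "+", after_frac = 0) {
  ft <- geneFeatures(genome)
  ok <- ft$kind == "CDS" & ft$strand == strand &
    (ft$end - ft$start + 1L) >= min_len &
    ft$start >= after_frac * genomeLength(genome)
  if (!any(ok)) stop("no CDS matches the constraints")
  ft[which(ok)[1], , drop = FALSE]
}

#' Generate a full synthetic cohort with planted elements and ground truth
#'
#' `scenario = "cluster_j_like"` builds six ~110 kb descendants of one
#' ancestor on a star phylogeny (per-branch substitution rates 0.015,
#' 0.015, 0.05, 0.05, 0.105, 0.105, giving pairwise planted identities of
#' roughly 0.80-0.97), plus a 50 kb high-GC host carrying a tRNA gene.
#' Planted: one intron with an internal reverse-strand LAGLIDADG ORF, one
#' 340 aa intein at residue 104, one transposon with a 5 bp target-site
#' duplication, one precise and one deletion-associated (35 bp)
#' free-standing endonuclease, and one 44 bp att common core written
#' identically into every phage downstream of its integrase and into the
#' host tRNA anticodon loop, flanked by arm-type repeats. Elements are
#' planted into sister genomes so each has a close relative lacking it —
#' the configuration mobile-element detection exploits in real cohorts.
#'
#' `scenario = "minimal"` builds two 20 kb genomes plus a host, with one
#' intron and the att cassette.
#'
#' @param scenario `"cluster_j_like"` or `"minimal"`.
#' @param seed Integer root seed; all per-stage streams derive from it by
#'   fixed offsets.
#' @param genome_length,host_length Optional overrides of the scenario's
#'   genome sizes.
#' @return A list with `genomes` (named list of [PhageGenome-class]),
#'   `host`, `truth` ([TruthLog-class]), and `pairs` (the carrier/reference
#'   detection pairs the planting design supports).
#' @export
makeCohort <- function(scenario = c("cluster_j_like", "minimal"), seed = 1L,
                       genome_length = NULL, host_length = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "cluster_j_like") {
    make_cohort_cluster_j(seed,
      genome_length = if (is.null(genome_length)) 110000L else as.integer(genome_length),
      host_length = if (is.null(host_length)) 50000L else as.integer(host_length))
  } else {
    make_cohort_minimal(seed,
      genome_length = if (is.null(genome_length)) 20000L else as.integer(genome_length),
      host_length = if (is.null(host_length)) 20000L else as.integer(host_length))
  }
}

# host with an annotated tRNA-Leu in an intergenic gap
make_host <- function(length, seed) {
  host <- generateAncestor(length, gc = 0.67, gene_mean = 1000L,
                           seed = seed, id = "host")
  ft <- geneFeatures(host)
  gaps_after <- which(c(ft$start[-1], genomeLength(host)) - ft$end > 90L)
  if (!length(gaps_after)) stop("host has no gap for a tRNA")
  at <- ft$end[gaps_after[1]] + 8L
  trna <- data.frame(gene_number = "tRNA1", start = at, end = at + 75L,
                     strand = "+", kind = "tRNA", product = "tRNA-Leu",
                     translation = NA_character_, stringsAsFactors = FALSE)
  PhageGenome("host", genomeSeq(host), rbind(ft, trna), source = "synthetic")
}

merge_truth <- function(truths, events, pre_plant, seed, scenario, ancestor) {
  new("TruthLog",
    events = events,
    subs = do.call(c, lapply(truths, slot, "subs")),
    indels = do.call(c, lapply(truths, slot, "indels")),
    pre_plant = pre_plant,
    seed = as.integer(seed), scenario = scenario
  )
}

make_cohort_cluster_j <- function(seed, genome_length, host_length) {
  anc <- generateAncestor(genome_length, gc = 0.61, gene_mean = 900L,
                          seed = derive_seed(seed, 1L), id = "ancestor")
  # designate a plus-strand integrase in the right half of the genome
  int_gene <- pick_cds(anc, min_len = 900L, strand = "+", after_frac = 0.55)
  ft <- geneFeatures(anc)
  ft$product[ft$gene_number == int_gene$gene_number] <- "integrase (tyrosine family)"
  anc <- PhageGenome("ancestor", genomeSeq(anc), ft, source = "synthetic")

  host <- make_host(host_length, derive_seed(seed, 2L))
  ids <- paste0("synJ", 1:6)
  # star phylogeny; pairwise planted identities span ~0.80-0.97, with an
  # outlier lineage (synJ6) supplying the distant pairs and close
  # relatives available as detection references for every carrier
  rates <- c(0.0155, 0.0155, 0.04, 0.04, 0.04, 0.17)
  evolved <- lapply(1:6, function(i) {
    evolveGenome(anc, evolutionConfig(
      substitution_rate = rates[i], indel_rate = 2e-05,
      indel_size_geometric_p = 0.5, seed = derive_seed(seed, 10L + i)
    ), id = ids[i])
  })
  genomes <- lapply(evolved, `[[`, "genome")
  names(genomes) <- ids
  truths <- lapply(evolved, `[[`, "truth")
  pre_plant <- vapply(genomes, genomeSeq, character(1))

  events <- empty_truth_events()
  plant <- function(i, spec, off) {
    with_seed(derive_seed(seed, off), {
      res <- plantElement(genomes[[i]], spec)
      genomes[[i]] <<- res$genome
      events <<- rbind(events, res$event)
      res
    })
  }
  # keep mobile-element sites clear of the integrase/att cassette region,
  # where an identical core will later be written into every genome
  cassette <- function(i) {
    ig <- get_gene(genomes[[i]], int_gene$gene_number)
    list(c(ig$start - 200L, ig$end + 1600L))
  }
  # intron in synJ1 (sister synJ2 lacks it)
  intron_gene <- pick_cds(genomes[[1]], min_len = 650L, strand = "+", after_frac = 0.05)
  plant(1L, plantSpec("intron", target = intron_gene$gene_number,
                      options = list(length = 819L, internal_orf = TRUE,
                                     clean_against = genomes[[2]])), 31L)
  # precise endonuclease in synJ2 (reference synJ1)
  plant(2L, plantSpec("endonuclease",
                      options = list(length = 1000L, orf_aa = 150L,
                                     exclude = cassette(2L),
                                     clean_against = genomes[[1]])), 32L)
  # intein in synJ3's largest early CDS (reference synJ4)
  intein_gene <- pick_cds(genomes[[3]], min_len = 1100L, strand = "+", after_frac = 0)
  plant(3L, plantSpec("intein", target = intein_gene$gene_number,
                      options = list(aa_len = 340L, aa_pos = 104L,
                                     clean_against = genomes[[4]])), 33L)
  # deletion-associated endonuclease in synJ4 (reference synJ3)
  plant(4L, plantSpec("endonuclease",
                      options = list(length = 1000L, orf_aa = 150L,
                                     deletion_at_target = 35L,
                                     exclude = cassette(4L),
                                     clean_against = genomes[[3]])), 34L)
  # transposon with a 5 bp TSD in synJ5 (reference synJ4)
  plant(5L, plantSpec("transposon",
                      options = list(tsd_len = 5L, length = 1500L, orf_aa = 420L,
                                     exclude = cassette(5L),
                                     clean_against = genomes[[4]])), 35L)
  # identical att core in every genome + the host tRNA
  core <- with_seed(derive_seed(seed, 40L), random_dna(44L, gcContent(host)))
  for (i in 1:6) {
    res <- with_seed(derive_seed(seed, 40L + i), {
      plantElement(genomes[[i]], plantSpec("att_core", payload = core,
        options = list(host = host, int_gene = int_gene$gene_number,
                       inverted_at_int_start = TRUE)))
    })
    genomes[[i]] <- res$genome
    host <- res$host
    events <- rbind(events, res$event)
  }

  truth <- merge_truth(truths, events, pre_plant, seed, "cluster_j_like", anc)
  pairs <- data.frame(
    carrier = c("synJ1", "synJ2", "synJ3", "synJ4", "synJ5"),
    reference = c("synJ2", "synJ1", "synJ4", "synJ3", "synJ4"),
    stringsAsFactors = FALSE
  )
  list(genomes = genomes, host = host, truth = truth, pairs = pairs,
       ancestor = anc, int_gene = int_gene$gene_number)
}

make_cohort_minimal <- function(seed, genome_length, host_length) {
  anc <- generateAncestor(genome_length, gc = 0.61, gene_mean = 900L,
                          seed = derive_seed(seed, 1L), id = "ancestor")
  int_gene <- pick_cds(anc, min_len = 600L, strand = "+", after_frac = 0.5)
  ft <- geneFeatures(anc)
  ft$product[ft$gene_number == int_gene$gene_number] <- "integrase (tyrosine family)"
  anc <- PhageGenome("ancestor", genomeSeq(anc), ft, source = "synthetic")
  host <- make_host(host_length, derive_seed(seed, 2L))
  ids <- c("synA", "synB")
  evolved <- lapply(1:2, function(i) {
    evolveGenome(anc, evolutionConfig(substitution_rate = 0.01,
                                      seed = derive_seed(seed, 10L + i)),
                 id = ids[i])
  })
  genomes <- lapply(evolved, `[[`, "genome")
  names(genomes) <- ids
  pre_plant <- vapply(genomes, genomeSeq, character(1))
  events <- empty_truth_events()

  intron_gene <- pick_cds(genomes[[1]], min_len = 650L, strand = "+", after_frac = 0.05)
  res <- with_seed(derive_seed(seed, 31L), {
    plantElement(genomes[[1]], plantSpec("intron", target = intron_gene$gene_number,
                                         options = list(length = 600L)))
  })
  genomes[[1]] <- res$genome
  events <- rbind(events, res$event)

  core <- with_seed(derive_seed(seed, 40L), random_dna(44L, gcContent(host)))
  for (i in 1:2) {
    res <- with_seed(derive_seed(seed, 40L + i), {
      plantElement(genomes[[i]], plantSpec("att_core", payload = core,
        options = list(host = host, int_gene = int_gene$gene_number)))
    })
    genomes[[i]] <- res$genome
    host <- res$host
    events <- rbind(events, res$event)
  }
  truth <- merge_truth(lapply(evolved, `[[`, "truth"), events, pre_plant,
                       seed, "minimal", anc)
  list(genomes = genomes, host = host, truth = truth,
       pairs = data.frame(carrier = "synA", reference = "synB",
                          stringsAsFactors = FALSE),
       ancestor = anc, int_gene = int_gene$gene_number)
}

#' Planted per-site identity between two cohort genomes
#'
#' Computed from the truth log's substitution maps on ancestor
#' coordinates: two genomes differ at a site when exactly one lineage
#' substituted it, or both did but to different bases. Indels and planted
#' elements are excluded (they are logged separately and are rare by
#' design), so this is the per-site identity the fragment ANI estimate is
#' compared against.
#'
#' @param truth A [TruthLog-class] from [makeCohort()].
#' @param ancestor The cohort's ancestor genome (for its length).
#' @return Symmetric matrix of planted identities.
#' @export
plantedIdentityMatrix <- function(truth, ancestor) {
  ids <- names(truth@subs)
  L <- genomeLength(ancestor)
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- truth@subs[[i]]
      b <- truth@subs[[j]]
      both <- merge(a, b, by = "pos")
      ndiff <- (nrow(a) - nrow(both)) + (nrow(b) - nrow(both)) +
        sum(both$new.x != both$new.y)
      m[i, j] <- m[j, i] <- 1 - ndiff / L
    }
  }
  m
}

#' Write a cohort to disk (FASTA + feature TSVs + truth JSON)
#'
#' @param cohort A [makeCohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in c(cohort$genomes, list(cohort$host))) {
    writeFasta(g, file.path(dir, paste0(genomeId(g), ".fasta")))
    writeFeatures(geneFeatures(g), file.path(dir, paste0(genomeId(g), ".features.tsv")))
  }
  truth <- cohort$truth
  jsonlite::write_json(
    list(seed = truth@seed, scenario = truth@scenario,
         events = truth@events, pairs = cohort$pairs),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(dir)
}
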