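# Classification evidence for intervening segments: splice restoration
# (group I intron test), internal ORF scanning, intein detection at the
# protein level, the classification rule, and in-silico PCR product-size
# prediction.

# translate straight through internal stops (homolog-search probe)
translate_through <- function(dna) {
  code <- genetic_code_cached("11")
  n_codon <- nchar(dna) %/% 3L
  if (!n_codon) return("")
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  aa <- unname(code[substring(dna, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa[aa != "*"], collapse = "")
}

# Matches between a candidate restored protein and the reference under a
# single-gap-at-the-junction model: positions before the splice junction
# and positions counted back from the C-terminus compare positionally.
# Equals plain positional identity for equal lengths; approximates the
# global alignment (whose one indel sits at the junction) otherwise.
junction_matches <- function(a_chars, r_chars, junction_aa) {
  la <- length(a_chars); lr <- length(r_chars)
  j <- min(junction_aa, la, lr)
  m <- if (j > 0L) sum(a_chars[seq_len(j)] == r_chars[seq_len(j)]) else 0L
  k <- min(la, lr) - j
  if (k > 0L) {
    m <- m + sum(a_chars[(la - k + 1L):la] == r_chars[(lr - k + 1L):lr])
  }
  m
}

# map a genome coordinate to a sense-strand position of a gene
genome_to_sense <- function(gene, p) {
  if (gene$strand == "+") p - gene$start + 1L else gene$end - p + 1L
}
sense_to_genome <- function(gene, q) {
  if (gene$strand == "+") gene$start + q - 1L else gene$end - q + 1L
}

# translate all CDS features of a genome (sense strand, table 11)
genomeProteins <- function(genome) {
  ft <- geneFeatures(genome)
  cds <- ft[ft$kind == "CDS", , drop = FALSE]
  out <- vapply(seq_len(nrow(cds)), function(i) {
    translateCDS(extractGeneDNA(genome, cds[i, ]))
  }, character(1))
  names(out) <- cds$gene_number
  out
}

# crude shared 4-mer counts to rank homolog candidates before alignment
shared_kmer_counts <- function(probe, targets, k = 4L) {
  pk <- unique(kmer_vector(probe, k))
  vapply(targets, function(t) sum(!is.na(match(unique(kmer_vector(t, k)), pk))),
         numeric(1))
}

best_reference_protein <- function(probe, ref_proteins, min_identity = 0.4,
                                   top = 5L) {
  if (!length(ref_proteins)) return(NULL)
  ranks <- order(shared_kmer_counts(probe, ref_proteins), decreasing = TRUE)
  best <- NULL
  for (i in ranks[seq_len(min(top, length(ranks)))]) {
    al <- globalAlignAA(probe, ref_proteins[[i]])
    if (is.null(best) || al$identity > best$identity) {
      best <- list(gene = names(ref_proteins)[i], protein = ref_proteins[[i]],
                   identity = al$identity)
    }
  }
  if (best$identity < min_identity) NULL else best
}

#' Test whether excising an insertion restores the interrupted protein
#'
#' Enumerates candidate excisions with both boundaries shifted within
#' `window` bp of the call, keeping the fused CDS in frame; each candidate
#' is excised, the exons fused and translated, and compared to the best
#' reference homolog (global identity >= 0.4 required). The excision
#' maximizing restored identity wins; ties prefer candidates satisfying
#' both group I boundary hallmarks (exon 1 ending in T, intron ending in
#' G), then an exact protein-length match, then the leftmost excision.
#' A fusion with an internal stop codon is never scored.
#'
#' @param call An [InsertionCall-class] with `host_gene` set.
#' @param carrier,reference [PhageGenome-class] objects.
#' @param window Boundary search half-width in bp.
#' @return A list (`SpliceHypothesis`): genome coordinates `exon1_end`,
#'   `intron_start`, `intron_end`, `exon2_start`; `restored_protein_len`,
#'   `reference_protein_len`, `restored_identity`, `reference_gene`;
#'   boundary bases and `group_I_flags`; `viable` plus a
#'   `"no_viable_splice"` marker when no in-frame stop-free fusion exists.
#' @export
testSpliceRestoration <- function(call, carrier, reference, window = 10L) {
  if (is.na(call@host_gene)) stop("call has no host gene")
  gene <- get_gene(carrier, call@host_gene)
  sense <- extractGeneDNA(carrier, gene)
  glen <- nchar(sense)
  # element interval in sense coordinates
  q1 <- genome_to_sense(gene, call@start)
  q2 <- genome_to_sense(gene, call@end)
  s0 <- min(q1, q2); e0 <- max(q1, q2)

  no_splice <- function(ref = NULL) {
    list(exon1_end = NA_integer_, intron_start = NA_integer_,
         intron_end = NA_integer_, exon2_start = NA_integer_,
         restored_protein_len = NA_integer_,
         reference_protein_len = if (is.null(ref)) NA_integer_ else nchar(ref$protein),
         restored_identity = 0, reference_gene = if (is.null(ref)) NA_character_ else ref$gene,
         exon1_3prime_base = NA_character_, intron_3prime_base = NA_character_,
         group_I_flags = c(exon1_ends_T = FALSE, intron_ends_G = FALSE),
         viable = FALSE, marker = "no_viable_splice")
  }

  # homolog search probe: nominal excision, stops stripped
  probe_dna <- paste0(substring(sense, 1L, s0 - 1L), substring(sense, e0 + 1L, glen))
  probe <- translate_through(probe_dna)
  ref <- best_reference_protein(probe, as.list(genomeProteins(reference)))
  if (is.null(ref)) return(no_splice())

  best <- NULL
  ref_len <- nchar(ref$protein)
  ref_chars <- strsplit(ref$protein, "", fixed = TRUE)[[1]]
  for (i in seq.int(-window, window)) {
    s <- s0 + i
    if (s < 2L) next
    for (jshift in seq.int(-window, window)) {
      e <- e0 + jshift
      if (e >= glen || e < s) next
      if ((glen - (e - s + 1L)) %% 3L != 0L) next
      fused <- paste0(substring(sense, 1L, s - 1L), substring(sense, e + 1L, glen))
      aa <- translateCDS(fused)
      full_len <- nchar(fused) %/% 3L - 1L  # expected length with terminal stop
      if (nchar(aa) < full_len) next       # internal stop: not viable
      # selection score: junction-anchored matches over the LONGER
      # length, so an excision that truncates the product cannot outscore
      # one restoring the full-length protein
      matches <- junction_matches(strsplit(aa, "", fixed = TRUE)[[1]],
                                  ref_chars, (s - 1L) %/% 3L)
      flags <- c(
        exon1_ends_T = substring(sense, s - 1L, s - 1L) == "T",
        intron_ends_G = substring(sense, e, e) == "G"
      )
      cand <- list(s = s, e = e,
                   score = matches / max(nchar(aa), ref_len),
                   aa_len = nchar(aa), flags = flags)
      if (is.null(best) || better_splice(cand, best, ref_len)) best <- cand
    }
  }
  if (is.null(best)) return(no_splice(ref))
  # reported identity of the winner: the package-wide global-alignment
  # definition (identical pairs / shorter length)
  fused <- paste0(substring(sense, 1L, best$s - 1L),
                  substring(sense, best$e + 1L, glen))
  best$identity <- globalAlignAA(translateCDS(fused), ref$protein)$identity

  list(
    exon1_end = sense_to_genome(gene, best$s - 1L),
    intron_start = sense_to_genome(gene, if (gene$strand == "+") best$s else best$e),
    intron_end = sense_to_genome(gene, if (gene$strand == "+") best$e else best$s),
    exon2_start = sense_to_genome(gene, best$e + 1L),
    restored_protein_len = best$aa_len,
    reference_protein_len = nchar(ref$protein),
    restored_identity = best$identity,
    reference_gene = ref$gene,
    exon1_3prime_base = substring(sense, best$s - 1L, best$s - 1L),
    intron_3prime_base = substring(sense, best$e, best$e),
    group_I_flags = best$flags,
    viable = TRUE, marker = NA_character_
  )
}

better_splice <- function(a, b, ref_len) {
  if (a$score != b$score) return(a$score > b$score)
  fa <- all(a$flags); fb <- all(b$flags)
  if (fa != fb) return(fa)
  la <- a$aa_len == ref_len; lb <- b$aa_len == ref_len
  if (la != lb) return(la)
  if (a$s != b$s) return(a$s < b$s)
  a$e < b$e
}

#' All complete open reading frames inside a DNA segment
#'
#' Scans both strands for ORFs from an ATG/GTG/TTG start to the next
#' in-frame stop, at least `min_aa` residues long. Positions for
#' minus-strand ORFs are given on the reverse complement of the segment.
#' Each ORF is flagged for the literal motif `LAGLIDADG`, the hallmark
#' used to spot intron-encoded homing endonucleases.
#'
#' @param segment DNA string, at least `3 * min_aa` bp.
#' @param min_aa Minimum protein length.
#' @return `data.frame` with `strand`, `nt_start` (position of the start
#'   codon on the reported strand), `aa_len`, `protein`, `has_laglidadg`.
#' @export
findInternalORFs <- function(segment, min_aa = 50L) {
  scan_strand <- function(s, strand) {
    n <- nchar(s)
    out <- list()
    if (n < 3L * (min_aa + 1L)) return(out)
    codon_tab <- genetic_code_cached("11")
    for (off in 0:2) {
      starts <- seq.int(1L + off, n - 2L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      aa <- codon_tab[codons]
      aa[is.na(aa)] <- "X"
      is_stop <- aa == "*"
      is_start <- codons %in% c("ATG", "GTG", "TTG")
      stop_idx <- which(is_stop)
      for (st in which(is_start)) {
        nxt <- stop_idx[stop_idx > st]
        if (!length(nxt)) next
        len_aa <- nxt[1] - st
        if (len_aa < min_aa) next
        prot <- paste(c("M", aa[(st + 1L):(nxt[1] - 1L)]), collapse = "")
        out[[length(out) + 1L]] <- data.frame(
          strand = strand, nt_start = starts[st], aa_len = len_aa,
          protein = prot, has_laglidadg = grepl("LAGLIDADG", prot, fixed = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    out
  }
  res <- c(scan_strand(segment, "+"), scan_strand(revComp(segment), "-"))
  if (!length(res)) {
    return(data.frame(strand = character(0), nt_start = integer(0),
                      aa_len = integer(0), protein = character(0),
                      has_laglidadg = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$strand, out$nt_start), , drop = FALSE]
}

#' Detect a protein intein by alignment against an intein-less homolog
#'
#' Globally aligns the two proteins and reports the longest internal run
#' of at least `min_len` carrier residues aligned to gaps in the
#' reference. Extein identities are computed separately on the flanking
#' aligned blocks (matches over the shorter block).
#'
#' @param carrier_protein,reference_protein Amino-acid strings.
#' @param min_len Minimum intein length (aa).
#' @return `NULL` when no such run exists, else a list (`InteinCall`)
#'   with `insertion_aa_start`, `insertion_aa_end` (carrier residue
#'   coordinates), `intein_len`, `extein1_identity`, `extein2_identity`.
#' @export
detectIntein <- function(carrier_protein, reference_protein, min_len = 100L) {
  if (!nchar(carrier_protein) || !nchar(reference_protein)) {
    stop("empty protein sequence")
  }
  al <- globalAlignAA(carrier_protein, reference_protein)
  p <- strsplit(al$aligned[1], "")[[1]]
  s <- strsplit(al$aligned[2], "")[[1]]
  run <- rle(s == "-" & p != "-")
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  cand <- which(run$values & run$lengths >= min_len &
                  starts > 1L & ends < length(p))
  if (!length(cand)) return(NULL)
  best <- cand[which.max(run$lengths[cand])]
  cols <- starts[best]:ends[best]
  carrier_pos <- cumsum(p != "-")
  block_identity <- function(columns) {
    if (!length(columns)) return(NA_real_)
    np <- sum(p[columns] != "-")
    ns <- sum(s[columns] != "-")
    if (!np || !ns) return(NA_real_)
    sum(p[columns] == s[columns] & p[columns] != "-") / min(np, ns)
  }
  list(
    insertion_aa_start = carrier_pos[starts[best]],
    insertion_aa_end = carrier_pos[ends[best]],
    intein_len = run$lengths[best],
    extein1_identity = block_identity(seq_len(starts[best] - 1L)),
    extein2_identity = block_identity((ends[best] + 1L):length(p))
  )
}

#' Classify an insertion call as intron, intein, transposon, or endonuclease
#'
#' Applies the evidence in fixed precedence: *intron* when the segment
#' sits inside a CDS, disrupts its reading frame (length not a multiple
#' of 3, or an in-frame stop), and a splice hypothesis restores >= 0.8
#' identity at the reference protein length; *intein* when the segment is
#' an in-frame CDS insertion whose protein carries a >= 100 aa internal
#' block absent from the reference homolog (no DNA splice needed to
#' restore the protein); *transposon* when a >= 2 bp target-site
#' duplication flanks the element and it carries an ORF of >= 200 aa;
#' *endonuclease* when an intergenic (or gene-replacing) segment carries
#' an ORF of >= 100 aa without a TSD; otherwise *unclassified*.
#'
#' @param call An [InsertionCall-class].
#' @param carrier,reference [PhageGenome-class] objects.
#' @return The call with `type` assigned and the evidence bundle
#'   (`splice`, `intein`, `tsd`, `orfs`, `target`) attached.
#' @export
classifyInsertion <- function(call, carrier, reference) {
  seg <- subseq_str(genomeSeq(carrier), call@start, call@end)
  orfs <- findInternalORFs(seg, min_aa = 50L)
  tsd <- detectTSD(call, carrier, reference)
  target <- reconstructTarget(call, carrier, reference)

  splice <- NULL
  intein <- NULL
  disrupts <- TRUE
  if (!is.na(call@host_gene)) {
    gene <- get_gene(carrier, call@host_gene)
    disrupts <- element_disrupts_frame(call, carrier, gene)
    splice <- tryCatch(testSpliceRestoration(call, carrier, reference),
                       error = function(e) NULL)
    if (!disrupts) {
      carrier_prot <- translateCDS(extractGeneDNA(carrier, gene))
      ref <- best_reference_protein(carrier_prot,
                                    as.list(genomeProteins(reference)))
      if (!is.null(ref)) {
        intein <- detectIntein(carrier_prot, ref$protein)
      }
    }
  }

  max_orf <- if (nrow(orfs)) max(orfs$aa_len) else 0L
  type <- if (!is.na(call@host_gene) && disrupts && !is.null(splice) &&
              isTRUE(splice$viable) && splice$restored_identity >= 0.8 &&
              identical(splice$restored_protein_len, splice$reference_protein_len)) {
    "intron"
  } else if (!is.na(call@host_gene) && !disrupts && !is.null(intein)) {
    "intein"
  } else if (tsd$tsd_len >= 2L && max_orf >= 200L) {
    "transposon"
  } else if (max_orf >= 100L) {
    "endonuclease"
  } else {
    "unclassified"
  }
  call@type <- type
  call@evidence <- c(call@evidence, list(
    splice = splice, intein = intein, tsd = tsd, orfs = orfs, target = target
  ))
  call
}

# does the element interrupt the host gene's reading frame?
element_disrupts_frame <- function(call, carrier, gene) {
  if (call@length %% 3L != 0L) return(TRUE)
  # in-frame stop check: element read in the host CDS frame
  q1 <- genome_to_sense(gene, call@start)
  q2 <- genome_to_sense(gene, call@end)
  s <- min(q1, q2)
  sense <- extractGeneDNA(carrier, gene)
  frame_start <- s + ((1L - s) %% 3L)  # first in-frame codon start inside element
  codons_end <- min(max(q1, q2) - 2L, nchar(sense) - 2L)
  if (frame_start > codons_end) return(FALSE)
  starts <- seq.int(frame_start, codons_end, by = 3L)
  any(substring(sense, starts, starts + 2L) %in% STOP_CODONS)
}

#' Scan a carrier/reference genome pair for classified insertions
#'
#' Convenience wrapper: [findInsertions()] followed by
#' [classifyInsertion()] on every call.
#'
#' @param carrier,reference [PhageGenome-class] objects.
#' @param min_len Minimum insertion length (bp).
#' @return List of classified [InsertionCall-class] objects.
#' @export
scanPair <- function(carrier, reference, min_len = 50L) {
  calls <- findInsertions(carrier, reference, min_len = min_len)
  lapply(calls, classifyInsertion, carrier = carrier, reference = reference)
}

#' In-silico PCR product-size prediction
#'
#' Primer sites may carry up to 2 mismatches but the 3'-terminal 5 bases
#' must match exactly. The product length runs between the two primer 5'
#' ends inclusive. With `spliced_coords` the product of the spliced
#' template is also reported (shorter by the excised interval length when
#' the excision lies inside the product).
#'
#' @param genome A [PhageGenome-class].
#' @param primer_f,primer_r Primer sequences (>= 15 bp), forward on the
#'   plus strand and reverse given 5'→3' on the minus strand.
#' @param spliced_coords Optional `c(start, end)` of an excised segment.
#' @return A list with `status` (`"ok"`, `"no_product"`, `"ambiguous"`),
#'   `genomic` product length, and `spliced` length (or `NA`).
#' @export
insilicoPCR <- function(genome, primer_f, primer_r, spliced_coords = NULL) {
  if (nchar(primer_f) < 15L || nchar(primer_r) < 15L) {
    stop("primers must be at least 15 bp")
  }
  seq <- Biostrings::DNAString(genomeSeq(genome))
  find_sites <- function(primer, reverse) {
    pat <- if (reverse) revComp(primer) else primer
    m <- Biostrings::matchPattern(pat, seq, max.mismatch = 2L, with.indels = FALSE)
    st <- Biostrings::start(m); en <- Biostrings::end(m)
    keep <- vapply(seq_along(st), function(i) {
      site <- subseq_str(genomeSeq(genome), st[i], en[i])
      if (reverse) {
        # primer 3' end sits at the left edge of the site
        substring(site, 1L, 5L) == substring(pat, 1L, 5L)
      } else {
        substring(site, nchar(site) - 4L) == substring(pat, nchar(pat) - 4L)
      }
    }, logical(1))
    cbind(st, en)[keep, , drop = FALSE]
  }
  f <- find_sites(primer_f, reverse = FALSE)
  r <- find_sites(primer_r, reverse = TRUE)
  if (nrow(f) == 0L || nrow(r) == 0L) {
    return(list(status = "no_product", genomic = NA_integer_, spliced = NA_integer_))
  }
  if (nrow(f) > 1L || nrow(r) > 1L) {
    return(list(status = "ambiguous", genomic = NA_integer_, spliced = NA_integer_))
  }
  if (r[1, 2] <= f[1, 1]) {
    return(list(status = "no_product", genomic = NA_integer_, spliced = NA_integer_))
  }
  genomic <- as.integer(r[1, 2] - f[1, 1] + 1L)
  spliced <- NA_integer_
  if (!is.null(spliced_coords)) {
    sc <- as.integer(spliced_coords)
    if (sc[1] > f[1, 1] && sc[2] < r[1, 2]) {
      spliced <- genomic - intervalLength(sc[1], sc[2])
    } else {
      spliced <- genomic
    }
  }
  list(status = "ok", genomic = genomic, spliced = spliced)
}
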