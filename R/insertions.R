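# Detection of intervening segments between closely related genomes.
#
# Strategy: chain unique shared 15-mers into a collinear backbone
# (longest-increasing-subsequence on reference positions), then refine
# each anchor gap with a mismatch-tolerant global alignment of the local
# windows and extract insertion gaps, left-normalizing boundaries within
# flanking repeats (VCF-style indel convention).

#' Find insertions of one genome relative to a close relative
#'
#' Reports segments where the carrier advances by at least `min_len` while
#' the reference advances by at most `max_ref_gap` (the allowance > 0
#' admits deletion-associated acquisitions, where the incoming element
#' replaced a short stretch of the target; the lost reference bases are
#' recorded as evidence). Boundaries are refined by alignment and
#' left-normalized. `host_gene` is set when the segment lies inside an
#' annotated CDS.
#'
#' @param carrier,reference [PhageGenome-class] objects.
#' @param min_len Minimum insertion length to report (bp).
#' @param k Anchor word size.
#' @param max_ref_gap Maximum reference bases lost at the target.
#' @return List of [InsertionCall-class]; empty (with a warning) when the
#'   genomes share no anchor chain.
#' @export
findInsertions <- function(carrier, reference, min_len = 50L, k = 15L,
                           max_ref_gap = 50L) {
  sa <- genomeSeq(carrier)
  sb <- genomeSeq(reference)
  ka <- kmer_vector(sa, k)
  kb <- kmer_vector(sb, k)
  ua <- unique_kmer_positions(ka)
  ub <- unique_kmer_positions(kb)
  m <- match(ka[ua], kb[ub])
  ok <- !is.na(m)
  if (sum(ok) < 2L) {
    warning("no shared unique ", k, "-mers; genomes too diverged to compare")
    return(list())
  }
  ca <- ua[ok]
  ra <- ub[m[ok]]
  ord <- order(ca)
  ca <- ca[ord]; ra <- ra[ord]
  chain <- lis_indices(ra)
  ca <- ca[chain]; ra <- ra[chain]

  calls <- list()
  for (i in seq_len(length(ca) - 1L)) {
    dc <- ca[i + 1L] - ca[i]
    dr <- ra[i + 1L] - ra[i]
    # candidate: carrier advances >= min_len more than the reference does
    # (minus the 10 bp micro-indel allowance near the junction)
    if (dc - dr < min_len - 10L) next
    new_calls <- refine_gap(sa, sb, ca[i], ca[i + 1L] + k - 1L,
                            ra[i], ra[i + 1L] + k - 1L,
                            min_len, max_ref_gap)
    calls <- c(calls, new_calls)
  }
  lapply(calls, function(cl) {
    finalize_call(cl, sa, sb, genomeId(carrier), genomeId(reference),
                  geneFeatures(carrier))
  })
}

# Refine one anchor gap under a single-event model: the carrier window C
# equals prefix + element + suffix, the reference window R equals
# prefix' + lost-target (d bases) + suffix', with prefix/suffix pairs
# differing only by substitutions. The junction j (prefix length) and
# target loss d are chosen to minimize flank mismatches; ties prefer the
# smaller d (parsimony: precise insertion) and then the larger j (flank
# bases stay flank). Prefix and suffix mismatch arrays make the search
# O(|R| * max_ref_gap).
refine_gap <- function(sa, sb, c_lo, c_hi, r_lo, r_hi, min_len, max_ref_gap) {
  C <- strsplit(subseq_str(sa, c_lo, c_hi), "", fixed = TRUE)[[1]]
  R <- strsplit(subseq_str(sb, r_lo, r_hi), "", fixed = TRUE)[[1]]
  LC <- length(C); LR <- length(R)
  net <- LC - LR
  if (net + max_ref_gap < min_len) return(list())
  m <- min(LC, LR)
  pm <- c(0L, cumsum(C[seq_len(m)] != R[seq_len(m)]))          # prefix mism.
  sfx <- c(0L, cumsum(rev(C)[seq_len(m)] != rev(R)[seq_len(m)]))  # suffix mism.
  best <- NULL
  for (d in 0:min(max_ref_gap, LR - 1L)) {
    if (net + d < min_len) next
    jmax <- LR - d
    # half a mismatch per deleted target base: removing reference bases
    # from scoring must cost something, or d inflates to absorb ordinary
    # flank substitutions near the junction
    score <- pm[seq_len(jmax + 1L)] + sfx[seq.int(jmax + 1L, 1L)] + 0.5 * d
    jbest <- max(which(score == min(score))) - 1L  # largest j on ties
    # <=: on score ties prefer the larger d — a partial content match
    # between the element edge and the lost target can tie the score,
    # and the larger d is the one whose excision restores the reference
    if (is.null(best) || score[jbest + 1L] <= best$score) {
      best <- list(score = score[jbest + 1L], d = d, j = jbest)
    }
  }
  if (is.null(best)) return(list())
  j <- best$j; d <- best$d
  start <- c_lo + j
  end <- c_lo + (LC - (LR - d - j)) - 1L
  list(list(
    start = start, end = end,
    ref_junction = r_lo + j - 1L,
    deletion_bp = d,
    deleted_seq = if (d > 0L) subseq_str(sb, r_lo + j, r_lo + j + d - 1L) else ""
  ))
}

finalize_call <- function(cl, sa, sb, carrier_id, reference_id, features) {
  start <- cl$start; end <- cl$end
  shift <- 0L
  while (start > 1L &&
         substring(sa, start - 1L, start - 1L) == substring(sa, end, end)) {
    start <- start - 1L
    end <- end - 1L
    shift <- shift + 1L
  }
  ref_junction <- cl$ref_junction - shift
  # exact flank match lengths outward from the junction
  lext <- 0L
  while (start - 1L - lext >= 1L && ref_junction - lext >= 1L &&
         substring(sa, start - 1L - lext, start - 1L - lext) ==
         substring(sb, ref_junction - lext, ref_junction - lext) && lext < 200L) {
    lext <- lext + 1L
  }
  rext <- 0L
  r_right <- ref_junction + cl$deletion_bp + 1L
  while (end + 1L + rext <= nchar(sa) && r_right + rext <= nchar(sb) &&
         substring(sa, end + 1L + rext, end + 1L + rext) ==
         substring(sb, r_right + rext, r_right + rext) && rext < 200L) {
    rext <- rext + 1L
  }
  cds <- features[features$kind == "CDS", , drop = FALSE]
  hit <- which(cds$start <= start & cds$end >= end)
  host_gene <- if (length(hit)) cds$gene_number[hit[1]] else NA_character_
  new("InsertionCall",
    carrier = carrier_id, reference = reference_id,
    start = as.integer(start), end = as.integer(end),
    length = as.integer(end - start + 1L),
    host_gene = host_gene,
    flank_anchor_len = as.integer(max(1L, min(lext, rext))),
    type = "unclassified",
    evidence = list(
      ref_junction = as.integer(ref_junction),
      deletion_bp = as.integer(cl$deletion_bp),
      deleted_seq = cl$deleted_seq,
      flank_left = lext, flank_right = rext
    )
  )
}

#' Detect a target-site duplication at an insertion call
#'
#' Searches duplication lengths `d` from `max_tsd` down to 1 over element
#' placements shifted 0..`d` bases right of the left-normalized call
#' start (the placement family a length-`d` duplication generates within
#' its repeat). A placement is accepted when the `d`-mers immediately
#' flanking the element in the carrier are identical, excising the
#' element plus one duplicate copy is string-equivalent to excising the
#' called segment, and the reference holds exactly one copy of the
#' duplicated word at the target junction. All equally maximal
#' placements are reported; `d = 0` means a precise insertion (empty
#' `tsd_seq`).
#'
#' @param call An [InsertionCall-class] from [findInsertions()].
#' @param carrier,reference [PhageGenome-class] objects.
#' @param max_tsd Largest duplication length considered.
#' @return A list with `tsd_seq`, `tsd_len`, `element_start`,
#'   `element_end`, and `alternatives` (data.frame of equally maximal
#'   placements).
#' @export
detectTSD <- function(call, carrier, reference, max_tsd = 15L) {
  sa <- genomeSeq(carrier)
  sb <- genomeSeq(reference)
  start <- call@start; len <- call@length
  j0 <- call@evidence$ref_junction
  for (d in seq.int(max_tsd, 1L)) {
    if (d >= len) next
    hits <- list()
    for (s in seq.int(start, start + d)) {
      e <- s + (len - d) - 1L
      if (s - d < 1L || e + d > nchar(sa)) next
      flankL <- subseq_str(sa, s - d, s - 1L)
      if (flankL != subseq_str(sa, e + 1L, e + d)) next
      # excising [s .. e+d] must be equivalent to excising the call
      t <- s - start
      equiv <- if (t >= 0L) {
        t == 0L || subseq_str(sa, start, s - 1L) ==
          subseq_str(sa, start + len, s + len - 1L)
      } else {
        subseq_str(sa, s, start - 1L) == subseq_str(sa, s + len, start + len - 1L)
      }
      if (!equiv) next
      # reference single-copy condition at the shifted junction
      j <- j0 + t
      if (j - d + 1L < 1L || j + d > nchar(sb)) next
      c1 <- subseq_str(sb, j - d + 1L, j) == flankL
      c2 <- subseq_str(sb, j + 1L, j + d) == flankL
      if (xor(c1, c2)) {
        hits[[length(hits) + 1L]] <- data.frame(
          element_start = s, element_end = e, tsd_seq = flankL,
          stringsAsFactors = FALSE)
      }
    }
    if (length(hits)) {
      alt <- do.call(rbind, hits)
      alt <- alt[order(alt$element_start), , drop = FALSE]
      return(list(tsd_seq = alt$tsd_seq[1], tsd_len = d,
                  element_start = alt$element_start[1],
                  element_end = alt$element_end[1],
                  alternatives = alt))
    }
  }
  list(tsd_seq = "", tsd_len = 0L,
       element_start = start, element_end = call@end,
       alternatives = data.frame(element_start = start,
                                 element_end = call@end,
                                 tsd_seq = "", stringsAsFactors = FALSE))
}

#' Reconstruct the pre-insertion target from an insertion call
#'
#' The insertion is precise when the reference flanks are contiguous at
#' the target; otherwise the reference bases absent from the carrier are
#' reported (count and sequence). An ambiguous junction (the call can
#' shift rightward within a repeat) is flagged; the leftmost
#' reconstruction is reported.
#'
#' @param call An [InsertionCall-class].
#' @param carrier,reference [PhageGenome-class] objects.
#' @return A list with `status` (`"precise"` or `"deletion_associated"`),
#'   `deleted_bp`, `deleted_seq`, and `ambiguous`.
#' @export
reconstructTarget <- function(call, carrier, reference) {
  sa <- genomeSeq(carrier)
  ambiguous <- call@end + 1L <= nchar(sa) &&
    substring(sa, call@start, call@start) ==
    substring(sa, call@end + 1L, call@end + 1L)
  d <- call@evidence$deletion_bp
  if (is.null(d) || d == 0L) {
    list(status = "precise", deleted_bp = 0L, deleted_seq = "",
         ambiguous = ambiguous)
  } else {
    list(status = "deletion_associated", deleted_bp = d,
         deleted_seq = call@evidence$deleted_seq, ambiguous = ambiguous)
  }
}
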