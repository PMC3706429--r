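# Alignment primitives, fragment-based ANI, dotplot matrices, and exact
# longest-common-substring search. DP alignment itself is delegated to
# Biostrings::pairwiseAlignment; this module fixes the scoring dialects.

.align_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.align_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .align_cache$BLOSUM62 <- e$BLOSUM62
  }
  .align_cache$BLOSUM62
}

#' Global protein alignment (Needleman-Wunsch, BLOSUM62 11/1)
#'
#' Identity is defined as identical aligned pairs divided by the length of
#' the shorter sequence, which keeps identities of homologs stable when one
#' partner carries a terminal or internal extension (e.g. an intein).
#'
#' @param a,b Non-empty amino-acid strings.
#' @return A list with `identity`, `aligned_cols` (alignment columns
#'   including gaps), `score`, `evalue` (`NA` for global alignments),
#'   `coords`, and the two `aligned` strings.
#' @export
globalAlignAA <- function(a, b) {
  if (!nchar(a) || !nchar(b)) stop("empty protein sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1
  )
  ap <- as.character(Biostrings::alignedPattern(aln))
  list(
    identity = Biostrings::nmatch(aln) / min(nchar(a), nchar(b)),
    matches = Biostrings::nmatch(aln),
    aligned_cols = nchar(ap),
    score = Biostrings::score(aln),
    evalue = NA_real_,
    coords = list(a = c(1L, nchar(a)), b = c(1L, nchar(b))),
    aligned = c(ap, as.character(Biostrings::alignedSubject(aln)))
  )
}

# local protein alignment + BlastP-style E-value (BLOSUM62 11/1 gapped
# Karlin-Altschul constants lambda = 0.267, K = 0.041)
local_align_aa <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1
  )
  s <- Biostrings::score(aln)
  list(score = s, evalue = 0.041 * nchar(a) * nchar(b) * exp(-0.267 * s))
}

# scoring dialect for nucleotide local alignment
NT_MATCH <- 2
NT_MISMATCH <- -3
NT_GAP_OPEN <- 5
NT_GAP_EXT <- 2
KA_LAMBDA <- 1.28
KA_K <- 0.46

nt_submat <- function() {
  if (is.null(.align_cache$nt)) {
    .align_cache$nt <- Biostrings::nucleotideSubstitutionMatrix(
      match = NT_MATCH, mismatch = NT_MISMATCH, baseOnly = FALSE
    )
  }
  .align_cache$nt
}

#' Local nucleotide alignment (Smith-Waterman)
#'
#' Match +2, mismatch -3, gap open -5, gap extend -2. The expectation
#' value uses ungapped Karlin-Altschul statistics with fixed constants
#' (lambda = 1.28, K = 0.46) over the search space `|a| x |b|`.
#'
#' @param a,b Non-empty DNA strings.
#' @return A list with `identity` (matches / alignment columns),
#'   `aligned_cols`, `score`, `evalue`, and `coords` (inclusive intervals
#'   on both sequences). A best score of zero or less is reported as a
#'   no-hit sentinel (`aligned_cols = 0`).
#' @export
localAlignNT <- function(a, b) {
  if (!nchar(a) || !nchar(b)) stop("empty DNA sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local", substitutionMatrix = nt_submat(),
    gapOpening = NT_GAP_OPEN, gapExtension = NT_GAP_EXT
  )
  s <- Biostrings::score(aln)
  if (s <= 0) {
    return(list(identity = 0, aligned_cols = 0L, score = 0,
                evalue = KA_K * nchar(a) * nchar(b),
                coords = NULL))
  }
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  ncols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(
    identity = Biostrings::nmatch(aln) / ncols,
    aligned_cols = ncols,
    score = s,
    evalue = KA_K * nchar(a) * nchar(b) * exp(-KA_LAMBDA * s),
    coords = list(
      a = c(Biostrings::start(pat), Biostrings::end(pat)),
      b = c(Biostrings::start(sub), Biostrings::end(sub))
    )
  )
}

# Best local alignment of a short fragment against a long target,
# restricted to the window suggested by shared 13-mer anchors (exact for
# related genomes at these scales; a fragment with no anchor support is
# reported unaligned).
fragment_best_hit <- function(frag, target, target_kmers, k = 13L, slop = 300L) {
  fk <- kmer_vector(frag, k)
  take <- seq(1L, length(fk), by = 7L)
  hit <- match(fk[take], target_kmers)
  ok <- !is.na(hit)
  if (sum(ok) < 3L) return(NULL)
  diag <- stats::median(hit[ok] - take[ok])
  lo <- max(1L, as.integer(diag) + 1L - slop)
  hi <- min(nchar(target), as.integer(diag) + nchar(frag) + slop)
  if (hi - lo + 1L < 30L) return(NULL)
  localAlignNT(frag, subseq_str(target, lo, hi))
}

ani_direction <- function(a, b, fragment) {
  n_frag <- nchar(a) %/% fragment
  bk <- kmer_vector(b, 13L)
  idents <- rep(NA_real_, n_frag)
  for (i in seq_len(n_frag)) {
    frag <- subseq_str(a, (i - 1L) * fragment + 1L, i * fragment)
    hit <- fragment_best_hit(frag, b, bk)
    if (is.null(hit) || hit$aligned_cols == 0L) next
    if (hit$identity >= 0.7 && hit$aligned_cols >= 0.7 * fragment) {
      idents[i] <- hit$identity
    }
  }
  retained <- !is.na(idents)
  list(
    value = if (any(retained)) mean(idents[retained]) else NA_real_,
    fraction_aligned = mean(retained),
    n_fragments = n_frag
  )
}

#' Fragment-based average nucleotide identity
#'
#' Goris-style dialect: the query is cut into consecutive non-overlapping
#' fragments (default 1 kb); each fragment's best local alignment against
#' the other genome is retained when it reaches >= 70% identity over
#' >= 70% of the fragment length; the direction value is the mean identity
#' of retained fragments. Both directions are computed and averaged, so
#' `ani(a, b) == ani(b, a)` exactly.
#'
#' @param a,b [PhageGenome-class] objects (or DNA strings), each at least
#'   twice the fragment length.
#' @param fragment Fragment size in bp.
#' @return A list with `ani`, `per_direction` (named pair), and per
#'   direction `fraction_aligned` and `n_fragments`.
#' @export
ani <- function(a, b, fragment = 1000L) {
  sa <- if (is(a, "PhageGenome")) genomeSeq(a) else a
  sb <- if (is(b, "PhageGenome")) genomeSeq(b) else b
  if (nchar(sa) < 2L * fragment || nchar(sb) < 2L * fragment) {
    stop("genomes must be at least twice the fragment length")
  }
  ab <- ani_direction(sa, sb, fragment)
  ba <- ani_direction(sb, sa, fragment)
  dirs <- c(ab = ab$value, ba = ba$value)
  list(
    ani = mean(dirs),
    per_direction = dirs,
    fraction_aligned = c(ab = ab$fraction_aligned, ba = ba$fraction_aligned),
    n_fragments = c(ab = ab$n_fragments, ba = ba$n_fragments)
  )
}

#' ANI matrix over a set of genomes
#'
#' @param genomes List of [PhageGenome-class] objects.
#' @param fragment Fragment size in bp.
#' @return Symmetric numeric matrix with genome ids as dimnames.
#' @export
aniMatrix <- function(genomes, fragment = 1000L) {
  ids <- vapply(genomes, genomeId, character(1))
  n <- length(genomes)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- ani(genomes[[i]], genomes[[j]], fragment)$ani
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' All exact k-mer matches between two sequences (dotplot matrix)
#'
#' Forward and reverse-complement matches, 1-based positions. For a
#' reverse-strand match, `posB` is the start in `b` of the segment whose
#' reverse complement equals the `a` k-mer.
#'
#' @param a,b DNA strings.
#' @param k Word size, >= 8.
#' @return `data.frame` with `posA`, `posB`, `strand`.
#' @export
dotplotMatches <- function(a, b, k = 10L) {
  if (k < 8L) stop("word size k must be >= 8")
  ka <- kmer_vector(a, k)
  match_side <- function(kb, strand, map_pos) {
    idx <- split(seq_along(kb), kb)
    hits <- idx[ka]
    lens <- lengths(hits)
    if (!sum(lens)) return(NULL)
    data.frame(
      posA = rep(seq_along(ka), lens),
      posB = map_pos(unlist(hits, use.names = FALSE)),
      strand = strand,
      stringsAsFactors = FALSE
    )
  }
  fwd <- match_side(kmer_vector(b, k), "+", identity)
  nb <- nchar(b)
  rev <- match_side(kmer_vector(revComp(b), k), "-",
                    function(i) nb - (i + k - 1L) + 1L)
  out <- rbind(fwd, rev)
  if (is.null(out)) {
    out <- data.frame(posA = integer(0), posB = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  }
  out[order(out$posA, out$posB), , drop = FALSE]
}

# any common substring of length L? returns NULL or c(posA, posB)
lcs_probe <- function(a, b, L) {
  sa <- kmer_vector(a, L)
  sb <- kmer_vector(b, L)
  m <- match(sa, sb)
  hit <- which(!is.na(m))
  if (!length(hit)) return(NULL)
  c(hit[1], m[hit[1]])
}

lcs_one_strand <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  # fast path: containment
  if (na <= nb && grepl(a, b, fixed = TRUE)) {
    return(list(length = na, posA = 1L,
                posB = as.integer(regexpr(a, b, fixed = TRUE))))
  }
  if (nb < na && grepl(b, a, fixed = TRUE)) {
    return(list(length = nb, posA = as.integer(regexpr(b, a, fixed = TRUE)),
                posB = 1L))
  }
  # exponential then binary search on the length
  if (is.null(lcs_probe(a, b, 1L))) return(list(length = 0L, posA = NA_integer_, posB = NA_integer_))
  lo <- 1L
  hi <- 2L
  maxL <- min(na, nb)
  while (hi < maxL && !is.null(lcs_probe(a, b, hi))) {
    lo <- hi
    hi <- min(maxL, hi * 2L)
  }
  if (!is.null(lcs_probe(a, b, hi))) lo <- hi else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (is.null(lcs_probe(a, b, mid))) hi <- mid else lo <- mid
    }
  }
  p <- lcs_probe(a, b, lo)
  list(length = lo, posA = p[1], posB = p[2])
}

#' Longest exact common substring of two DNA sequences
#'
#' Ties are broken by smallest position in `a`, then smallest position in
#' `b`. With `search_revcomp = TRUE` the reverse complement of `b` is also
#' searched; a minus-strand result reports `posB` as the start in `b` of
#' the segment whose reverse complement matches (the plus strand wins
#' ties).
#'
#' @param a,b Non-empty DNA strings.
#' @param search_revcomp Also consider the reverse complement of `b`.
#' @return A list with `length`, `posA`, `posB`, `strand`, `seq` (the
#'   shared substring in `a` orientation); `length` 0 when no base is
#'   shared.
#' @export
longestCommonSubstring <- function(a, b, search_revcomp = FALSE) {
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  plus <- lcs_one_strand(a, b)
  best <- c(plus, strand = "+")
  if (search_revcomp) {
    rcb <- revComp(b)
    minus <- lcs_one_strand(a, rcb)
    if (minus$length > plus$length) {
      nb <- nchar(b)
      best <- list(
        length = minus$length, posA = minus$posA,
        posB = nb - (minus$posB + minus$length - 1L) + 1L,
        strand = "-"
      )
    }
  }
  best$seq <- if (best$length > 0L) {
    subseq_str(a, best$posA, best$posA + best$length - 1L)
  } else ""
  best[c("length", "posA", "posB", "strand", "seq")]
}
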