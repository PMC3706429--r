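# attP/attB discovery: the common core shared between a phage and its
# host, arm-type integrase-binding repeats, hybrid attL/attR junctions,
# and integration-vector fragment design.

ARM_LEN <- 10L
# consensus TGCATACg/tPuPy: positions 2,3,5,6,7 are mandatory; positions
# 1,4,8,9,10 are scored against T,A,{G,T},{A,G},{C,T}
ARM_MANDATORY <- c(`2` = "G", `3` = "C", `5` = "T", `6` = "A", `7` = "C")
ARM_SCORED <- list(`1` = "T", `4` = "A", `8` = c("G", "T"),
                   `9` = c("A", "G"), `10` = c("C", "T"))

#' Scan a region for arm-type integrase-binding repeats
#'
#' Evaluates every 10-mer in the region, on both orientations, against
#' the degenerate consensus `TGCATACg/tPuPy`: the five conserved
#' positions (2,3,5-7 = G,C,T,A,C) must match exactly, and at most
#' `max_mismatch` violations are allowed among the remaining scored
#' positions (1 = T, 4 = A, 8 in \{G,T\}, 9 in \{A,G\}, 10 in \{C,T\}).
#' When a core interval is supplied, the two hits nearest the core on
#' each side are named P1, P2 (left, in left-to-right order) and P3, P4
#' (right).
#'
#' @param seq DNA string to scan.
#' @param region `c(start, end)` within `seq` (default: whole sequence).
#' @param max_mismatch Allowed violations among scored positions.
#' @param core_interval Optional `c(start, end)` of the att core, for
#'   P1-P4 naming.
#' @return `data.frame` with `name`, `start`, `end`, `orientation`
#'   (`direct`/`inverted`), `mismatches`, `seq`.
#' @export
scanArmSites <- function(seq, region = NULL, max_mismatch = 1L,
                         core_interval = NULL) {
  n <- nchar(seq)
  if (is.null(region)) region <- c(1L, n)
  if (region[1] < 1L || region[2] > n) stop("region out of bounds")
  lo <- region[1]; hi <- region[2]
  if (hi - lo + 1L < ARM_LEN) {
    return(data.frame(name = character(0), start = integer(0), end = integer(0),
                      orientation = character(0), mismatches = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  starts <- seq.int(lo, hi - ARM_LEN + 1L)
  words <- substring(seq, starts, starts + ARM_LEN - 1L)
  # evaluate the rule vectorized over all window starts, per position
  pos_chars <- lapply(seq_len(ARM_LEN), function(p) {
    substring(seq, starts + p - 1L, starts + p - 1L)
  })
  rule_mismatches <- function(cc) {
    mand <- rep(TRUE, length(starts))
    for (p in names(ARM_MANDATORY)) {
      mand <- mand & cc[[as.integer(p)]] == ARM_MANDATORY[[p]]
    }
    viol <- integer(length(starts))
    for (p in names(ARM_SCORED)) {
      viol <- viol + !(cc[[as.integer(p)]] %in% ARM_SCORED[[p]])
    }
    ifelse(mand & viol <= max_mismatch, viol, NA_integer_)
  }
  m_direct <- rule_mismatches(pos_chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc_chars <- lapply(seq_len(ARM_LEN), function(p) {
    unname(comp[pos_chars[[ARM_LEN + 1L - p]]])
  })
  m_inv <- rule_mismatches(rc_chars)
  dd <- which(!is.na(m_direct))
  ii <- which(!is.na(m_inv))
  if (!length(dd) && !length(ii)) {
    return(data.frame(name = character(0), start = integer(0), end = integer(0),
                      orientation = character(0), mismatches = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  out <- rbind(
    data.frame(name = rep("other", length(dd)), start = starts[dd],
               end = starts[dd] + ARM_LEN - 1L,
               orientation = rep("direct", length(dd)),
               mismatches = m_direct[dd], seq = words[dd],
               stringsAsFactors = FALSE),
    data.frame(name = rep("other", length(ii)), start = starts[ii],
               end = starts[ii] + ARM_LEN - 1L,
               orientation = rep("inverted", length(ii)),
               mismatches = m_inv[ii], seq = words[ii],
               stringsAsFactors = FALSE)
  )
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(core_interval)) {
    left <- which(out$end < core_interval[1] & out$orientation == "direct")
    right <- which(out$start > core_interval[2] & out$orientation == "direct")
    if (length(left)) {
      pick <- utils::tail(left, 2L)
      out$name[pick] <- paste0("P", seq_along(pick))
    }
    if (length(right)) {
      pick <- utils::head(right, 2L)
      out$name[pick] <- paste0("P", 2L + seq_along(pick))
    }
  }
  out
}

#' Find the attP/attB common core shared between phage and host
#'
#' Takes the window downstream of the integrase 3' end and reports its
#' longest exact common substring with the full host chromosome (both
#' strands). Overlap with an annotated host tRNA is reported (never
#' required). Arm-type sites are scanned in the cassette region around
#' the core and named P1-P4.
#'
#' @param phage,host [PhageGenome-class] objects.
#' @param int_gene Integrase feature row of the phage (e.g. from its
#'   feature table).
#' @param window Search window downstream of the integrase 3' end (bp).
#' @param min_core Minimum core length to accept.
#' @return An [AttSite-class]; when the best shared substring is shorter
#'   than `min_core`, a no-site result with `found = FALSE` and the best
#'   length recorded.
#' @export
findAttCore <- function(phage, host, int_gene, window = 1000L, min_core = 25L) {
  pseq <- genomeSeq(phage)
  int_end3 <- if (int_gene$strand == "+") int_gene$end else int_gene$start
  if (int_gene$strand == "+") {
    w_lo <- int_end3 + 1L
    w_hi <- min(nchar(pseq), int_end3 + window)
  } else {
    w_lo <- max(1L, int_end3 - window)
    w_hi <- int_end3 - 1L
  }
  if (w_hi <= w_lo) stop("no room downstream of the integrase")
  win <- subseq_str(pseq, w_lo, w_hi)
  lcs <- longestCommonSubstring(win, genomeSeq(host), search_revcomp = TRUE)
  if (lcs$length < min_core) {
    return(new("AttSite", core_seq = if (lcs$length > 0L) lcs$seq else "",
               phage_interval = c(NA_integer_, NA_integer_),
               host_interval = c(NA_integer_, NA_integer_),
               strand = "+", found = FALSE,
               distance_from_int_3prime = NA_integer_,
               arm_sites = data.frame()))
  }
  phage_iv <- c(w_lo + lcs$posA - 1L, w_lo + lcs$posA + lcs$length - 2L)
  host_iv <- c(lcs$posB, lcs$posB + lcs$length - 1L)
  hft <- geneFeatures(host)
  tr <- hft[hft$kind == "tRNA" & hft$start <= host_iv[2] & hft$end >= host_iv[1], ,
            drop = FALSE]
  dist <- if (int_gene$strand == "+") phage_iv[1] - int_gene$end - 1L else
    int_gene$start - phage_iv[2] - 1L
  cassette <- c(max(1L, phage_iv[1] - 200L),
                min(nchar(pseq), phage_iv[2] + 200L))
  arms <- scanArmSites(pseq, region = cassette, core_interval = phage_iv)
  site <- new("AttSite",
    core_seq = lcs$seq,
    phage_interval = as.integer(phage_iv),
    host_interval = as.integer(host_iv),
    strand = lcs$strand,
    trna_overlap = if (nrow(tr)) tr$product[1] else NA_character_,
    distance_from_int_3prime = as.integer(dist),
    arm_sites = arms, found = TRUE
  )
  # core identity invariant: phage and host substrings byte-identical
  host_core <- subseq_str(genomeSeq(host), host_iv[1], host_iv[2])
  if (lcs$strand == "-") host_core <- revComp(host_core)
  stopifnot(identical(host_core, site@core_seq))
  site
}

#' Predict hybrid attL/attR junction sequences
#'
#' Integration of the phage circle at the core produces attL (host left
#' arm + core + phage sequence downstream of the core) and attR (phage
#' sequence upstream of the core + core + host right arm). 200 bp of
#' context flank each side; a core too close to a sequence end yields a
#' truncated junction with a flag.
#'
#' @param phage,host [PhageGenome-class] objects.
#' @param site An [AttSite-class] from [findAttCore()].
#' @param context Context length on each side (bp).
#' @return A list with `attL`, `attR` (character), and `truncated`.
#' @export
predictAttLR <- function(phage, host, site, context = 200L) {
  if (!site@found) stop("no att site")
  pseq <- genomeSeq(phage)
  hseq <- genomeSeq(host)
  # orient the host so its core reads like the phage core
  if (site@strand == "-") {
    hseq <- revComp(hseq)
    L <- nchar(hseq)
    site@host_interval <- as.integer(c(L - site@host_interval[2] + 1L,
                                       L - site@host_interval[1] + 1L))
  }
  p <- site@phage_interval
  h <- site@host_interval
  core <- site@core_seq
  h_up <- subseq_str(hseq, max(1L, h[1] - context), h[1] - 1L)
  h_dn <- subseq_str(hseq, h[2] + 1L, min(nchar(hseq), h[2] + context))
  p_up <- subseq_str(pseq, max(1L, p[1] - context), p[1] - 1L)
  p_dn <- subseq_str(pseq, p[2] + 1L, min(nchar(pseq), p[2] + context))
  truncated <- nchar(h_up) < context || nchar(h_dn) < context ||
    nchar(p_up) < context || nchar(p_dn) < context
  list(attL = paste0(h_up, core, p_dn),
       attR = paste0(p_up, core, h_dn),
       truncated = truncated)
}

#' Design an integration-vector fragment interval
#'
#' The interval spans from `margin` bp before the integrase start through
#' `margin` bp after the core end, clamped to the genome — the segment an
#' integration-proficient plasmid needs (integrase + attP).
#'
#' @param phage A [PhageGenome-class].
#' @param int_gene Integrase feature row.
#' @param site An [AttSite-class].
#' @param margin Margin in bp.
#' @return `c(start, end)`, 1-based inclusive.
#' @export
designIntegrationFragment <- function(phage, int_gene, site, margin = 300L) {
  if (!site@found) stop("no att site")
  lo <- min(int_gene$start, site@phage_interval[1])
  hi <- max(int_gene$end, site@phage_interval[2])
  c(start = max(1L, lo - margin),
    end = min(genomeLength(phage), hi + margin))
}
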