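# Independent reference implementations ("oracles") used to validate the
# package's algorithms. These deliberately use brute-force or
# enumeration strategies and share no code with the implementation.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

rand_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# character-by-character reverse complement
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# hand-written standard/bacterial codon table (codon assignments of the
# bacterial code match the standard code)
ORACLE_CODONS <- local({
  aa <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
  b1 <- rep(c("T", "C", "A", "G"), each = 16)
  b2 <- rep(rep(c("T", "C", "A", "G"), each = 4), 4)
  b3 <- rep(c("T", "C", "A", "G"), 16)
  stats::setNames(strsplit(aa, "")[[1]], paste0(b1, b2, b3))
})

oracle_translate <- function(dna, initiator = TRUE) {
  n <- nchar(dna) %/% 3L
  out <- character(0)
  for (i in seq_len(n)) {
    codon <- substring(dna, 3 * i - 2, 3 * i)
    aa <- if (grepl("N", codon)) "X" else ORACLE_CODONS[[codon]]
    if (is.null(aa) || is.na(aa)) aa <- "X"
    if (aa == "*") break
    out <- c(out, aa)
  }
  if (initiator && length(out) &&
      substring(dna, 1, 3) %in% c("ATG", "GTG", "TTG")) {
    out[1] <- "M"
  }
  paste(out, collapse = "")
}

# quadratic affine-gap DP; gap of length L costs open + L * ext
# (Biostrings convention). type: "global" (end gaps penalized) or "local".
oracle_align <- function(a, b, submat, open, ext, type = "global") {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  local <- type == "local"
  if (local) {
    M[, 1] <- 0  # a local alignment may start anywhere
    M[1, ] <- 0
  } else {
    for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      diag_best <- max(M[i, j], Ix[i, j], Iy[i, j])
      M[i + 1, j + 1] <- if (local) max(diag_best + s, 0) else diag_best + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
      if (local && M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
    }
  }
  if (local) best else max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

oracle_nt_submat <- function(match = 2, mismatch = -3) {
  m <- matrix(mismatch, 4, 4, dimnames = list(BASES, BASES))
  diag(m) <- match
  m
}

# brute-force longest common substring via full DP table; ties by
# smallest end-position in a, then in b (equivalent to smallest starts
# for fixed length)
oracle_lcs <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  prev <- integer(m)
  best_len <- 0L; best_i <- NA_integer_; best_j <- NA_integer_
  for (i in seq_len(n)) {
    cur <- integer(m)
    eq <- av[i] == bv
    cur[eq] <- c(0L, prev[-m])[eq] + 1L
    if (any(cur > best_len)) {
      j <- which.max(cur)
      best_len <- cur[j]
      best_i <- i; best_j <- j
    }
    prev <- cur
  }
  if (best_len == 0L) {
    list(length = 0L, posA = NA_integer_, posB = NA_integer_)
  } else {
    list(length = best_len, posA = best_i - best_len + 1L,
         posB = best_j - best_len + 1L)
  }
}

# six-frame ORF enumeration: every ATG/GTG/TTG with an in-frame stop,
# protein of at least min_aa residues; minus strand on revcomp coords
oracle_orfs <- function(segment, min_aa = 50) {
  scan <- function(s, strand) {
    rows <- list()
    n <- nchar(s)
    for (pos in seq_len(max(0, n - 2))) {
      codon <- substring(s, pos, pos + 2)
      if (!codon %in% c("ATG", "GTG", "TTG")) next
      p <- pos + 3
      prot <- "M"
      found <- FALSE
      while (p + 2 <= n) {
        cd <- substring(s, p, p + 2)
        aa <- if (grepl("N", cd)) "X" else ORACLE_CODONS[[cd]]
        if (aa == "*") {
          found <- TRUE
          break
        }
        prot <- paste0(prot, aa)
        p <- p + 3
      }
      if (found && nchar(prot) >= min_aa) {
        rows[[length(rows) + 1]] <- data.frame(
          strand = strand, nt_start = pos, aa_len = nchar(prot),
          protein = prot, has_laglidadg = grepl("LAGLIDADG", prot, fixed = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    rows
  }
  out <- c(scan(segment, "+"), scan(oracle_revcomp(segment), "-"))
  if (!length(out)) {
    return(data.frame(strand = character(0), nt_start = integer(0),
                      aa_len = integer(0), protein = character(0),
                      has_laglidadg = logical(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$strand, res$nt_start), , drop = FALSE]
}

# exhaustive TSD rule evaluation: same contract as detectTSD, checked by
# explicit string surgery rather than index arithmetic
oracle_tsd <- function(carrier, call_start, call_end, ref, ref_junction,
                       max_tsd = 15) {
  len <- call_end - call_start + 1
  excise <- function(s, e) {
    paste0(substring(carrier, 1, s - 1), substring(carrier, e + 1, nchar(carrier)))
  }
  canonical <- excise(call_start, call_end)
  for (d in rev(seq_len(max_tsd))) {
    if (d >= len) next
    for (s in call_start:(call_start + d)) {
      e <- s + (len - d) - 1
      if (s - d < 1 || e + d > nchar(carrier)) next
      fl <- substring(carrier, s - d, s - 1)
      fr <- substring(carrier, e + 1, e + d)
      if (fl != fr) next
      if (!identical(excise(s, e + d), canonical)) next
      j <- ref_junction + (s - call_start)
      if (j - d + 1 < 1 || j + d > nchar(ref)) next
      c1 <- substring(ref, j - d + 1, j) == fl
      c2 <- substring(ref, j + 1, j + d) == fl
      if (xor(c1, c2)) return(list(tsd_len = d, tsd_seq = fl, element_start = s))
    }
  }
  list(tsd_len = 0L, tsd_seq = "", element_start = call_start)
}

# transitive closure by boolean matrix powers -> component labels
oracle_components <- function(n, edges) {
  A <- diag(TRUE, n)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      A[edges$i[r], edges$j[r]] <- TRUE
      A[edges$j[r], edges$i[r]] <- TRUE
    }
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  labels <- integer(n)
  next_label <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      next_label <- next_label + 1L
      labels[A[i, ]] <- next_label
    }
  }
  labels
}

# position-by-position arm-type consensus evaluation, vectorized over
# all window starts
oracle_arm_scan <- function(seq, max_mismatch = 1) {
  n <- nchar(seq)
  if (n < 10) {
    return(data.frame(start = integer(0), orientation = character(0),
                      mismatches = integer(0)))
  }
  starts <- seq_len(n - 9)
  ch <- lapply(1:10, function(p) substring(seq, starts + p - 1, starts + p - 1))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  eval_rule <- function(cc) {
    mand <- cc[[2]] == "G" & cc[[3]] == "C" & cc[[5]] == "T" &
      cc[[6]] == "A" & cc[[7]] == "C"
    viol <- (cc[[1]] != "T") + (cc[[4]] != "A") +
      (!(cc[[8]] %in% c("G", "T"))) + (!(cc[[9]] %in% c("A", "G"))) +
      (!(cc[[10]] %in% c("C", "T")))
    ifelse(mand & viol <= max_mismatch, viol, NA_integer_)
  }
  direct <- eval_rule(ch)
  # reverse complement of each window: position p reads comp(base 11-p)
  rc <- lapply(1:10, function(p) unname(comp[ch[[11 - p]]]))
  inverted <- eval_rule(rc)
  dd <- which(!is.na(direct))
  ii <- which(!is.na(inverted))
  out <- rbind(
    data.frame(start = starts[dd], orientation = rep("direct", length(dd)),
               mismatches = direct[dd]),
    data.frame(start = starts[ii], orientation = rep("inverted", length(ii)),
               mismatches = inverted[ii])
  )
  out[order(out$start), , drop = FALSE]
}

# left-normalize an interval within its repeat context (for comparing
# detected boundaries against planted truth)
normalize_left <- function(seq, s, e) {
  while (s > 1 && substring(seq, s - 1, s - 1) == substring(seq, e, e)) {
    s <- s - 1
    e <- e - 1
  }
  c(s, e)
}

# small two-genome fixture: a base genome and a copy with an insertion
insertion_fixture <- function(seed, genome_len = 20000, insert_len = 300,
                              site = NULL, insert = NULL) {
  set.seed(seed)
  base <- generateAncestor(genome_len, gc = 0.61, seed = seed, id = "ref")
  if (is.null(site)) site <- floor(genome_len / 2)
  if (is.null(insert)) insert <- rand_dna(insert_len, 0.61)
  carrier_seq <- paste0(substring(genomeSeq(base), 1, site), insert,
                        substring(genomeSeq(base), site + 1, genome_len))
  carrier <- PhageGenome("car", carrier_seq)
  list(reference = base, carrier = carrier, site = site, insert = insert)
}
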