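# Internal string / RNG helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] operating on plain
#' character strings; `N` is preserved.
#'
#' @param x A DNA string over \{A,C,G,T,N\}.
#' @return The reverse complement as a character string.
#' @export
revComp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# substring shorthand; 1-based inclusive
subseq_str <- function(x, start, end) substring(x, start, end)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Streams for sub-operations are derived from the root seed by fixed small
# offsets so that adding an element class never perturbs earlier draws.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# derived stream seed; keeps result well below .Machine$integer.max
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

# i.i.d. random DNA at a target GC
random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# all k-mers of a string as a character vector (position i -> k-mer at i)
kmer_vector <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

# positions of k-mers occurring exactly once
unique_kmer_positions <- function(kmers) {
  which(!(duplicated(kmers) | duplicated(kmers, fromLast = TRUE)))
}

# splice `insert` into `x` after position `pos` (0 <= pos <= nchar(x))
str_insert <- function(x, pos, insert) {
  paste0(substring(x, 1L, pos), insert, substring(x, pos + 1L, nchar(x)))
}

# delete inclusive interval [start, end] from `x`
str_delete <- function(x, start, end) {
  paste0(substring(x, 1L, start - 1L), substring(x, end + 1L, nchar(x)))
}

# overwrite x[start..start+nchar(repl)-1] with repl
str_overwrite <- function(x, start, repl) {
  end <- start + nchar(repl) - 1L
  stopifnot(start >= 1L, end <= nchar(x))
  paste0(substring(x, 1L, start - 1L), repl, substring(x, end + 1L, nchar(x)))
}

# longest increasing subsequence (strictly increasing) -> indices kept.
# Patience-sorting; O(n log n). Used to extract a collinear anchor chain.
lis_indices <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  tails <- numeric(n)      # smallest tail value of an increasing run of length l
  tails_idx <- integer(n)  # index in v achieving it
  prev <- integer(n)       # back-pointers
  len <- 0L
  for (i in seq_len(n)) {
    x <- v[i]
    # binary search: first run length whose tail >= x
    lo <- 1L; hi <- len + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (tails[mid] < x) lo <- mid + 1L else hi <- mid
    }
    pos <- lo
    tails[pos] <- x
    tails_idx[pos] <- i
    prev[i] <- if (pos > 1L) tails_idx[pos - 1L] else 0L
    if (pos > len) len <- pos
  }
  out <- integer(len)
  j <- tails_idx[len]
  for (l in rev(seq_len(len))) {
    out[l] <- j
    j <- prev[j]
  }
  out
}
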