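# Genome and annotation I/O plus the coordinate/sequence primitives that
# every other module builds on. All coordinates are 1-based inclusive.

#' Read genomes from a FASTA file
#'
#' Sequences are uppercased and `U` is normalized to `T`, so rules stated
#' at the RNA level (e.g. the 3' U of a spliced exon) are tested as `T`
#' at the DNA level. Characters outside \{A,C,G,T,N,U\} are a format error
#' naming the offending line.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A list of [PhageGenome-class] objects, in file order, with no
#'   features attached.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a valid FASTA file: ", path, " (", conditionMessage(e), ")")
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACGTNU]", toupper(seqs))
  if (any(bad)) {
    # locate the offending line for the error message
    lines <- readLines(path, warn = FALSE)
    body <- which(!startsWith(lines, ">") & grepl("[^ACGTNUacgtnu[:space:]]", lines))
    where <- if (length(body)) paste0(" at line ", body[1]) else ""
    stop("illegal sequence character outside {A,C,G,T,N,U}", where,
         " in record '", ids[which(bad)[1]], "'")
  }
  mapply(function(id, s) PhageGenome(id, s, source = path),
         ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write genomes to a FASTA file
#'
#' @param genomes A [PhageGenome-class] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(genomes, path) {
  if (is(genomes, "PhageGenome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, genomeSeq, character(1)))
  names(set) <- vapply(genomes, genomeId, character(1))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read gene features from a TSV table or a GenBank flat file
#'
#' The TSV dialect has a required header line with columns
#' `gene_number`, `start`, `end`, `strand`, `kind`, `product` and an
#' optional `translation` column. Coordinates are preserved exactly
#' (1-based inclusive, no shift). The GenBank dialect consumes only
#' `CDS` and `tRNA` features with plain or `complement()` locations and
#' `/product` and `/translation` qualifiers; `join()` locations are
#' rejected with a clear message.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"genbank"`.
#' @param genome_length Optional; when given, coordinates beyond it are a
#'   validation error.
#' @return A feature `data.frame` sorted by `start`.
#' @export
readFeatures <- function(path, dialect = c("tsv", "genbank"), genome_length = NULL) {
  dialect <- match.arg(dialect)
  ft <- if (dialect == "tsv") read_features_tsv(path) else read_features_genbank(path)
  if (nrow(ft)) {
    bad <- ft$end < ft$start
    if (any(bad)) {
      stop("feature '", ft$gene_number[which(bad)[1]], "': end < start")
    }
    if (!is.null(genome_length) && any(ft$end > genome_length)) {
      bad <- which(ft$end > genome_length)[1]
      stop("feature '", ft$gene_number[bad], "': coordinate beyond genome length")
    }
    ft <- ft[order(ft$start), , drop = FALSE]
    rownames(ft) <- NULL
  }
  ft
}

read_features_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) return(empty_features())
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  need <- c("gene_number", "start", "end", "strand", "kind", "product")
  if (!all(need %in% names(tab))) {
    stop("TSV feature table must have header columns: ", paste(need, collapse = ", "))
  }
  if (nrow(tab) == 0L) return(empty_features())
  data.frame(
    gene_number = tab$gene_number,
    start = as.integer(tab$start),
    end = as.integer(tab$end),
    strand = tab$strand,
    kind = tab$kind,
    product = tab$product,
    translation = if ("translation" %in% names(tab)) {
      ifelse(tab$translation == "", NA_character_, tab$translation)
    } else NA_character_,
    stringsAsFactors = FALSE
  )
}

# Minimal GenBank flat-file reader: LOCUS/FEATURES with CDS and tRNA keys.
read_features_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) return(empty_features())
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L else length(lines)
  block <- lines[(fstart[1] + 1L):fend]

  # a new feature starts at column 6; qualifiers/continuations at column 22
  key_rows <- grep("^ {5}\\S", block)
  out <- list()
  n <- 0L
  for (i in seq_along(key_rows)) {
    r <- key_rows[i]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[r])
    if (!key %in% c("CDS", "tRNA")) next
    last <- if (i < length(key_rows)) key_rows[i + 1L] - 1L else length(block)
    body <- block[r:last]
    loc <- sub("^ {5}\\S+\\s+", "", body[1])
    # location may continue on following lines until the first qualifier
    qual_at <- grep("^ {21}/", body)
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(body)
    if (loc_end > 1L) {
      loc <- paste0(loc, paste(trimws(body[2:loc_end]), collapse = ""))
    }
    if (grepl("join", loc)) {
      stop("join() locations are not supported (feature at '", trimws(body[1]), "')")
    }
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
    if (length(nums) < 2L) stop("cannot parse location: ", loc)
    qual <- paste(trimws(body[seq_along(body) >= loc_end + 1L]), collapse = " ")
    get_q <- function(name) {
      m <- regmatches(qual, regexpr(sprintf('/%s="[^"]*"', name), qual))
      if (length(m)) gsub('^/[a-z]+="|"$', "", m) else NA_character_
    }
    gene_q <- get_q("gene")
    locus_q <- get_q("locus_tag")
    n <- n + 1L
    out[[n]] <- data.frame(
      gene_number = if (!is.na(gene_q)) gene_q else if (!is.na(locus_q)) locus_q else as.character(n),
      start = as.integer(nums[1]),
      end = as.integer(nums[2]),
      strand = strand,
      kind = key,
      product = ifelse(is.na(get_q("product")), "", get_q("product")),
      translation = gsub(" ", "", get_q("translation")),
      stringsAsFactors = FALSE
    )
  }
  if (!n) return(empty_features())
  do.call(rbind, out)
}

#' Write a feature table as TSV
#'
#' @param features Feature `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFeatures <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Length of a 1-based inclusive interval
#'
#' @param start,end Coordinates with `1 <= start <= end`.
#' @return `end - start + 1`.
#' @examples
#' intervalLength(28186, 28450) # 265
#' intervalLength(54667, 54710) # 44
#' @export
intervalLength <- function(start, end) {
  if (any(start < 1L)) stop("coordinates must be >= 1")
  if (any(start > end)) stop("start > end")
  as.integer(end - start + 1L)
}

#' Extract the sense-strand DNA of a gene feature
#'
#' Returns the substring `[start..end]`, reverse-complemented when the
#' feature is on the `-` strand.
#'
#' @param genome A [PhageGenome-class].
#' @param feature A one-row slice of the feature table (or a list with
#'   `start`, `end`, `strand`).
#' @return DNA string in the gene's reading orientation.
#' @export
extractGeneDNA <- function(genome, feature) {
  s <- as.integer(feature$start)
  e <- as.integer(feature$end)
  if (s < 1L || e > genomeLength(genome)) stop("feature out of genome bounds")
  dna <- subseq_str(genomeSeq(genome), s, e)
  if (feature$strand == "-") revComp(dna) else dna
}

#' Translate a CDS to protein
#'
#' Uses the bacterial/plastid genetic code (transl_table 11) and stops at
#' the first stop codon. Codons containing `N` translate to `X`.
#' Alternative initiators `GTG`/`TTG` are rendered as `M` only when
#' `initiator = TRUE` (annotated CDS starts); elsewhere they translate by
#' the code table, as mycobacterial genomes use alternative starts only at
#' annotated initiation sites.
#'
#' @param dna In-frame coding DNA, length >= 3.
#' @param table Genetic code id (default `"11"`).
#' @param initiator Treat the first codon as an initiation codon.
#' @return Amino-acid string without the stop.
#' @export
translateCDS <- function(dna, table = "11", initiator = TRUE) {
  if (nchar(dna) < 3L) stop("CDS shorter than one codon")
  code <- genetic_code_cached(table)
  n_codon <- nchar(dna) %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N (or other ambiguity)
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
  if (initiator && length(aa) >= 1L && codons[1] %in% c("ATG", "GTG", "TTG")) {
    aa[1] <- "M"
  }
  paste(aa, collapse = "")
}

.code_cache <- new.env(parent = emptyenv())
genetic_code_cached <- function(table) {
  key <- paste0("t", table)
  if (is.null(.code_cache[[key]])) {
    .code_cache[[key]] <- Biostrings::getGeneticCode(table)
  }
  .code_cache[[key]]
}

#' GC content of a genome or DNA string
#'
#' `(G + C) / (A + C + G + T)`; `N` is excluded from the denominator.
#'
#' @param x A [PhageGenome-class] or DNA string.
#' @return GC fraction in `[0, 1]`.
#' @export
gcContent <- function(x) {
  s <- if (is(x, "PhageGenome")) genomeSeq(x) else x
  counts <- table(strsplit(s, "", fixed = TRUE)[[1]])
  gc <- sum(counts[names(counts) %in% c("G", "C")])
  acgt <- sum(counts[names(counts) %in% DNA_BASES])
  if (acgt == 0L) stop("sequence contains no unambiguous bases")
  as.numeric(gc / acgt)
}
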