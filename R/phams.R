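# Protein phamily ("pham") clustering: single-linkage under the dual
# threshold of >= 32.5% global identity OR local-alignment E-value
# <= 1e-50 (both inclusive), and shared-gene counting between genomes.

#' Pham clustering thresholds
#'
#' @param identity_threshold Global identity threshold (inclusive).
#' @param evalue_threshold Local-alignment E-value threshold (inclusive).
#' @return A validated list of class `PhamConfig`.
#' @export
phamConfig <- function(identity_threshold = 0.325, evalue_threshold = 1e-50) {
  if (identity_threshold <= 0 || identity_threshold >= 1) {
    stop("identity_threshold must be in (0, 1)")
  }
  if (evalue_threshold <= 0) stop("evalue_threshold must be > 0")
  structure(list(identity_threshold = identity_threshold,
                 evalue_threshold = evalue_threshold),
            class = "PhamConfig")
}

#' Collect all CDS proteins of a genome set for pham clustering
#'
#' @param genomes List of [PhageGenome-class] objects.
#' @return `data.frame` with `genome`, `gene`, `seq`.
#' @export
cohortProteins <- function(genomes) {
  out <- lapply(genomes, function(g) {
    p <- genomeProteins(g)
    p <- p[nchar(p) > 0L]
    data.frame(genome = genomeId(g), gene = names(p), seq = unname(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Score pairwise similarity edges between proteins
#'
#' An undirected edge is present when global identity (identical pairs /
#' shorter length) is at least the identity threshold OR the local
#' BLOSUM62 E-value is at most the E-value threshold. Candidate pairs
#' must share at least one 4-residue word before alignment is attempted —
#' the seed heuristic of BLAST-style search; a borderline pair whose
#' matches are all isolated single residues would be skipped, which is
#' the usual trade of seeded homology search.
#'
#' @param proteins `data.frame` with `genome`, `gene`, `seq` (e.g. from
#'   [cohortProteins()]). Duplicate (genome, gene) pairs are an error.
#' @param config A [phamConfig()].
#' @return `data.frame` of edges with columns `i`, `j` (row indices into
#'   `proteins`), `identity`, `evalue`.
#' @export
scoreEdges <- function(proteins, config = phamConfig()) {
  stopifnot(inherits(config, "PhamConfig"), nrow(proteins) >= 1L)
  key <- paste(proteins$genome, proteins$gene, sep = ":")
  if (anyDuplicated(key)) stop("duplicate (genome, gene) protein ids")
  n <- nrow(proteins)
  edges <- list()
  if (n < 2L) {
    return(data.frame(i = integer(0), j = integer(0),
                      identity = numeric(0), evalue = numeric(0)))
  }
  kmer_sets <- lapply(proteins$seq, function(s) unique(kmer_vector(s, 4L)))
  for (i in seq_len(n - 1L)) {
    ki <- kmer_sets[[i]]
    for (j in (i + 1L):n) {
      if (!any(!is.na(match(kmer_sets[[j]], ki)))) next
      idy <- globalAlignAA(proteins$seq[i], proteins$seq[j])$identity
      ev <- NA_real_
      hit <- idy >= config$identity_threshold
      if (!hit) {
        ev <- local_align_aa(proteins$seq[i], proteins$seq[j])$evalue
        hit <- ev <= config$evalue_threshold
      }
      if (hit) {
        edges[[length(edges) + 1L]] <- data.frame(
          i = i, j = j, identity = idy, evalue = ev)
      }
    }
  }
  if (!length(edges)) {
    return(data.frame(i = integer(0), j = integer(0),
                      identity = numeric(0), evalue = numeric(0)))
  }
  do.call(rbind, edges)
}

#' Build phams as connected components of the similarity graph
#'
#' Single-linkage: components of the edge graph; isolated proteins become
#' single-member phams (orphams). Pham ids are assigned by each
#' component's lexicographically smallest (genome, gene) member, so
#' output is stable across runs.
#'
#' @param edges Edge `data.frame` from [scoreEdges()].
#' @param proteins The protein table the edges index into.
#' @return `data.frame` with `pham_id`, `genome`, `gene` — a partition of
#'   the protein universe.
#' @export
buildPhams <- function(edges, proteins) {
  n <- nrow(proteins)
  if (nrow(edges) && (max(edges$i, edges$j) > n || min(edges$i, edges$j) < 1L)) {
    stop("edges reference unknown proteins")
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  }
  comp <- igraph::components(g)$membership
  key <- paste(proteins$genome, proteins$gene, sep = ":")
  smallest <- tapply(key, comp, function(k) sort(k)[1])
  ord <- order(smallest)
  relabel <- integer(length(smallest))
  relabel[ord] <- seq_along(ord)
  data.frame(
    pham_id = relabel[comp],
    genome = proteins$genome,
    gene = proteins$gene,
    stringsAsFactors = FALSE
  )
}

#' Number of genes of one genome with a pham member in another
#'
#' Counts genes of `a` whose pham also contains at least one gene of `b`.
#' Not necessarily symmetric: two paralogs in `a` matching one gene of
#' `b` count twice from `a`'s side and once from `b`'s.
#'
#' @param a,b Genome ids.
#' @param phams Pham table from [buildPhams()].
#' @return Integer count.
#' @export
sharedGeneCount <- function(a, b, phams) {
  if (!a %in% phams$genome) stop("unknown genome id: ", a)
  if (!b %in% phams$genome) stop("unknown genome id: ", b)
  phams_b <- unique(phams$pham_id[phams$genome == b])
  sum(phams$genome == a & phams$pham_id %in% phams_b)
}

#' Shared-gene count matrix over all genomes in a pham table
#'
#' @param phams Pham table from [buildPhams()].
#' @return Integer matrix, rows = counting genome, columns = partner.
#' @export
sharedGeneMatrix <- function(phams) {
  ids <- sort(unique(phams$genome))
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in ids) for (b in ids) m[a, b] <- sharedGeneCount(a, b, phams)
  m
}

#' Write a pham table as TSV (pham_id, size, members)
#'
#' @param phams Pham table from [buildPhams()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePhamTable <- function(phams, path) {
  key <- paste(phams$genome, phams$gene, sep = ":")
  by_pham <- split(key, phams$pham_id)
  tab <- data.frame(
    pham_id = as.integer(names(by_pham)),
    size = lengths(by_pham),
    members = vapply(by_pham, function(k) paste(sort(k), collapse = ";"),
                     character(1))
  )
  utils::write.table(tab[order(tab$pham_id), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
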