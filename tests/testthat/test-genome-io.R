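test_that("FASTA round trip preserves ids and sequences, normalizes case and U", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">one", "ACGTacgtn", ">two desc", "uuUUACGT"), tmp)
  gs <- readFasta(tmp)
  expect_length(gs, 2)
  expect_equal(genomeId(gs[[1]]), "one")
  expect_equal(genomeSeq(gs[[1]]), "ACGTACGTN")
  expect_equal(genomeSeq(gs[[2]]), "TTTTACGT")

  out <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(gs, out)
  gs2 <- readFasta(out)
  expect_equal(lapply(gs2, genomeSeq), lapply(gs, genomeSeq))
  expect_equal(vapply(gs2, genomeId, ""), vapply(gs, genomeId, ""))
})

test_that("FASTA errors name the problem", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), tmp)
  expect_error(readFasta(tmp), "empty")
  writeLines(c(">x", "ACGTZZ"), tmp)
  expect_error(readFasta(tmp), "illegal")
  expect_error(readFasta(file.path(tempdir(), "no-such.fa")), "no such file")
})

test_that("TSV feature tables parse with exact coordinates and validate", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_number\tstart\tend\tstrand\tkind\tproduct",
               "13\t8000\t9500\t+\tCDS\tmajor capsid",
               "2\t100\t400\t-\ttRNA\ttRNA-Leu"), tmp)
  ft <- readFeatures(tmp, "tsv")
  expect_equal(nrow(ft), 2)
  expect_equal(ft$start, c(100L, 8000L))  # sorted by start
  expect_equal(ft[ft$gene_number == "13", "end"], 9500L)

  writeLines(c("gene_number\tstart\tend\tstrand\tkind\tproduct",
               "1\t500\t100\t+\tCDS\tx"), tmp)
  expect_error(readFeatures(tmp, "tsv"), "end < start")
  writeLines(character(0), tmp)
  expect_equal(nrow(readFeatures(tmp, "tsv")), 0)
})

test_that("minimal GenBank flat files parse CDS/tRNA and reject join()", {
  tmp <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       TEST 100 bp DNA",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..60",
    '                     /product="capsid"',
    '                     /translation="MKV"',
    "     tRNA            complement(70..90)",
    '                     /product="tRNA-Leu"',
    "ORIGIN",
    "//"), tmp)
  ft <- readFeatures(tmp, "genbank")
  expect_equal(nrow(ft), 2)
  expect_equal(ft$kind, c("CDS", "tRNA"))
  expect_equal(ft$start, c(10L, 70L))
  expect_equal(ft$strand, c("+", "-"))
  expect_equal(ft$translation[1], "MKV")

  writeLines(c(
    "FEATURES             Location/Qualifiers",
    "     CDS             join(10..60,80..90)",
    "//"), tmp)
  expect_error(readFeatures(tmp, "genbank"), "join")
})

test_that("interval arithmetic is inclusive and guards its preconditions", {
  expect_equal(intervalLength(5, 5), 1L)
  expect_error(intervalLength(10, 5), "start > end")
  expect_error(intervalLength(0, 5), ">= 1")
  # a random sample agrees with the definition
  set.seed(1)
  s <- sample.int(1000, 50)
  e <- s + sample.int(100, 50)
  expect_equal(intervalLength(s, e), as.integer(e - s + 1))
})

test_that("gene extraction honors strand; double reverse-complement is identity", {
  g <- PhageGenome("t", "AAACGTTT")
  plus <- list(start = 4, end = 6, strand = "+")
  minus <- list(start = 4, end = 6, strand = "-")
  expect_equal(extractGeneDNA(g, plus), "CGT")
  expect_equal(extractGeneDNA(g, minus), "ACG")
  set.seed(7)
  for (i in 1:20) {
    seq <- rand_dna(60)
    gg <- PhageGenome("r", seq)
    s <- sample.int(40, 1)
    f <- list(start = s, end = s + sample.int(15, 1), strand = "-")
    expect_equal(extractGeneDNA(gg, f),
                 oracle_revcomp(substring(seq, f$start, f$end)))
    expect_equal(revComp(revComp(substring(seq, f$start, f$end))),
                 substring(seq, f$start, f$end))
  }
  expect_error(extractGeneDNA(g, list(start = 5, end = 99, strand = "+")),
               "bounds")
})

test_that("translation matches a codon-table oracle, with alt starts and N", {
  expect_equal(translateCDS("ATGAAATAA"), "MK")
  expect_equal(translateCDS("GTGAAA", initiator = TRUE), "MK")
  expect_equal(translateCDS("GTGAAA", initiator = FALSE), "VK")
  expect_equal(translateCDS("ATGANAAAA"), "MXK")
  expect_error(translateCDS("AT"), "codon")
  set.seed(11)
  for (i in 1:30) {
    dna <- rand_dna(300)
    expect_equal(translateCDS(dna), oracle_translate(dna))
  }
})

test_that("GC content excludes N and is strand-invariant", {
  expect_equal(gcContent("GGCC"), 1)
  expect_equal(gcContent("ATAT"), 0)
  expect_equal(gcContent("GCATNN"), 0.5)
  expect_error(gcContent("NNN"), "no unambiguous")
  set.seed(3)
  for (i in 1:10) {
    s <- rand_dna(200, gc = runif(1, 0.2, 0.8))
    expect_equal(gcContent(s), gcContent(oracle_revcomp(s)))
    expect_gte(gcContent(s), 0)
    expect_lte(gcContent(s), 1)
  }
})

test_that("PhageGenome validity catches malformed objects", {
  expect_error(PhageGenome("x", ""), "non-empty")
  ft <- data.frame(gene_number = "1", start = 5L, end = 50L, strand = "+",
                   kind = "CDS", product = "p", stringsAsFactors = FALSE)
  expect_error(PhageGenome("x", "ACGT", ft), "outside")
  g <- PhageGenome("x", strrep("ACGT", 20), ft)
  expect_s4_class(g, "PhageGenome")
  expect_equal(genomeLength(g), 80L)
})
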