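test_that("identical genomes yield no insertion calls", {
  g <- generateAncestor(12000, gc = 0.61, seed = 21)
  expect_length(findInsertions(g, g), 0)
})

test_that("a planted insertion is found with exact left-normalized boundaries", {
  fx <- insertion_fixture(seed = 22, insert_len = 265)
  calls <- findInsertions(fx$carrier, fx$reference)
  expect_length(calls, 1)
  cl <- calls[[1]]
  tn <- normalize_left(genomeSeq(fx$carrier), fx$site + 1,
                       fx$site + nchar(fx$insert))
  expect_equal(cl@start, tn[1])
  expect_equal(cl@end, tn[2])
  expect_equal(cl@length, 265L)
  # excision restores the reference exactly
  car <- genomeSeq(fx$carrier)
  restored <- paste0(substring(car, 1, cl@start - 1),
                     substring(car, cl@end + 1, nchar(car)))
  expect_identical(restored, genomeSeq(fx$reference))
})

test_that("unrelated genomes give an empty result with a warning", {
  set.seed(23)
  a <- PhageGenome("a", rand_dna(5000, 0.3))
  b <- PhageGenome("b", rand_dna(5000, 0.8))
  expect_warning(calls <- findInsertions(a, b), "diverged")
  expect_length(calls, 0)
})

test_that("splice restoration recovers a planted intron and flags hallmarks", {
  co <- makeCohort("minimal", seed = 8)
  ev <- truthEvents(co$truth)
  tr <- ev[ev$kind == "intron", ][1, ]
  calls <- findInsertions(co$genomes$synA, co$genomes$synB)
  cl <- calls[[which(vapply(calls, function(x) x@host_gene, "") == tr$host_gene)]]
  sp <- testSpliceRestoration(cl, co$genomes$synA, co$genomes$synB)
  expect_true(sp$viable)
  expect_gte(sp$restored_identity, 0.95)
  expect_equal(sp$restored_protein_len, sp$reference_protein_len)
  expect_true(all(sp$group_I_flags))
  expect_equal(sp$exon1_3prime_base, "T")
  expect_equal(sp$intron_3prime_base, "G")
  # splice never reports identity > 0 through an internal stop: the
  # winning excision's fused CDS must be stop-free
  gene <- geneFeatures(co$genomes$synA)
  gene <- gene[gene$gene_number == tr$host_gene, ]
  sense <- extractGeneDNA(co$genomes$synA, gene)
  q1 <- sp$intron_start - gene$start + 1
  q2 <- sp$intron_end - gene$start + 1
  fused <- paste0(substring(sense, 1, q1 - 1), substring(sense, q2 + 1, nchar(sense)))
  expect_equal(nchar(translateCDS(fused)), nchar(fused) / 3 - 1)
})

test_that("a segment ending in A cannot satisfy the intron G hallmark", {
  fx <- insertion_fixture(seed = 24, insert = paste0(rand_dna(199, 0.6), "A"))
  calls <- findInsertions(fx$carrier, fx$reference, min_len = 50)
  cl <- calls[[1]]
  sa <- genomeSeq(fx$carrier)
  expect_equal(substring(sa, cl@end, cl@end), "A")
})

test_that("internal ORF scan agrees with six-frame enumeration on fixtures", {
  # no start codon -> empty
  seg <- paste(rep("CCC", 120), collapse = "")
  expect_equal(nrow(findInternalORFs(seg, min_aa = 50)), 0)
  set.seed(25)
  for (i in 1:15) {
    seg <- rand_dna(500, runif(1, 0.3, 0.7))
    got <- findInternalORFs(seg, min_aa = 30)
    want <- oracle_orfs(seg, min_aa = 30)
    expect_equal(got$nt_start, want$nt_start)
    expect_equal(got$protein, want$protein)
  }
})

test_that("intein detection reports length, position, and extein identities", {
  expect_null(detectIntein(rand_protein(300), rand_protein(300)))
  p <- rand_protein(300)
  expect_null(detectIntein(p, p))
  set.seed(26)
  intein <- rand_protein(340)
  carrier <- paste0(substring(p, 1, 104), intein, substring(p, 105, 300))
  call <- detectIntein(carrier, p)
  expect_equal(call$intein_len, 340L)
  expect_equal(call$insertion_aa_start, 105L)
  expect_equal(call$extein1_identity, 1)
  expect_equal(call$extein2_identity, 1)
  # diverged exteins: identities track the planted divergence
  mutate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    idx <- which(runif(length(ch)) < rate)
    for (i in idx) ch[i] <- setdiff(c("A", "G", "L", "S"), ch[i])[1]
    paste(ch, collapse = "")
  }
  ref2 <- paste0(mutate(substring(p, 1, 104), 0.02),
                 mutate(substring(p, 105, 300), 0.03))
  call2 <- detectIntein(carrier, ref2)
  expect_gt(call2$extein1_identity, 0.93)
  expect_gt(call2$extein2_identity, 0.92)
  expect_equal(call2$intein_len, 340L)
})

test_that("TSD detection: planted duplications and precise insertions", {
  # planted 5 bp TSD with the canonical motif
  set.seed(27)
  base <- generateAncestor(12000, gc = 0.61, seed = 27)
  site <- 6000L
  seq0 <- phageMosaic:::str_overwrite(genomeSeq(base), site - 4L, "CACTG")
  ref <- PhageGenome("ref", seq0, geneFeatures(base))
  res <- plantElement(ref, plantSpec("transposon", target = site,
                                     options = list(tsd_len = 5, length = 700)))
  carrier <- res$genome
  calls <- findInsertions(carrier, ref)
  expect_length(calls, 1)
  tsd <- detectTSD(calls[[1]], carrier, ref)
  expect_equal(tsd$tsd_len, 5L)
  expect_equal(tsd$tsd_seq, "CACTG")

  # precise insertion built so the junction carries no chance repeat
  ref2 <- PhageGenome("r2", paste0(rand_dna(600, 0.5), "TTTT", "GGGG",
                                   rand_dna(600, 0.5)))
  ins <- paste0("A", rand_dna(198, 0.5), "C")
  car2 <- PhageGenome("c2", paste0(substring(genomeSeq(ref2), 1, 604), ins,
                                   substring(genomeSeq(ref2), 605, 1208)))
  calls2 <- findInsertions(car2, ref2, min_len = 50)
  tsd2 <- detectTSD(calls2[[1]], car2, ref2)
  expect_equal(tsd2$tsd_len, 0L)
  expect_equal(tsd2$tsd_seq, "")
})

test_that("target reconstruction distinguishes precise from deletion-associated", {
  anc <- generateAncestor(15000, gc = 0.61, seed = 28)
  set.seed(28)
  res <- plantElement(anc, plantSpec("endonuclease",
                                     options = list(length = 600, orf_aa = 150)))
  calls <- findInsertions(res$genome, anc)
  expect_equal(reconstructTarget(calls[[1]], res$genome, anc)$status, "precise")

  set.seed(29)
  res2 <- plantElement(anc, plantSpec("endonuclease",
                                      options = list(length = 600, orf_aa = 150,
                                                     deletion_at_target = 35)))
  calls2 <- findInsertions(res2$genome, anc)
  rec <- reconstructTarget(calls2[[1]], res2$genome, anc)
  expect_equal(rec$status, "deletion_associated")
  expect_equal(rec$deleted_bp, 35L)
  expect_equal(rec$deleted_seq, res2$event$deleted_seq)
  # reconstructing the reference from the call restores it byte-for-byte
  car <- genomeSeq(res2$genome)
  cl <- calls2[[1]]
  rebuilt <- paste0(substring(car, 1, cl@start - 1), rec$deleted_seq,
                    substring(car, cl@end + 1, nchar(car)))
  expect_identical(rebuilt, genomeSeq(anc))
})

test_that("classification assigns each planted element its own type", {
  co <- makeCohort("cluster_j_like", seed = 31)
  ev <- truthEvents(co$truth)
  planted <- ev[ev$kind %in% c("intron", "intein", "transposon", "endonuclease"), ]
  got <- character(0)
  for (i in seq_len(nrow(co$pairs))) {
    calls <- scanPair(co$genomes[[co$pairs$carrier[i]]],
                      co$genomes[[co$pairs$reference[i]]])
    got <- c(got, vapply(calls, callType, ""))
  }
  expect_setequal(sort(got), sort(planted$kind))
})

test_that("in-silico PCR predicts genomic and spliced product sizes", {
  set.seed(30)
  g <- PhageGenome("g", paste0(rand_dna(400, 0.5), rand_dna(265, 0.5),
                               rand_dna(400, 0.5)))
  seq <- genomeSeq(g)
  primer_f <- substring(seq, 101, 120)
  primer_r <- revComp(substring(seq, 901, 920))
  res <- insilicoPCR(g, primer_f, primer_r)
  expect_equal(res$status, "ok")
  expect_equal(res$genomic, 820L)
  res2 <- insilicoPCR(g, primer_f, primer_r, spliced_coords = c(401, 665))
  expect_equal(res2$spliced, 820L - 265L)
  # absent primer
  none <- insilicoPCR(g, strrep("ACGT", 5), primer_r)
  expect_equal(none$status, "no_product")
  expect_error(insilicoPCR(g, "ACGT", primer_r), "15")
  # a primer with two perfect sites is reported ambiguous
  dup <- PhageGenome("d", paste0(seq, seq))
  amb <- insilicoPCR(dup, primer_f, primer_r)
  expect_equal(amb$status, "ambiguous")
})
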