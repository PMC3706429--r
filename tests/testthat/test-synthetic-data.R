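test_that("ancestor generation hits target length, GC, and gene density", {
  g <- generateAncestor(20000, gc = 0.61, seed = 7)
  expect_equal(genomeLength(g), 20000L)
  expect_gte(nrow(geneFeatures(g)), 10)
  expect_true(all(geneFeatures(g)$kind == "CDS"))
  # determinism
  g2 <- generateAncestor(20000, gc = 0.61, seed = 7)
  expect_identical(genomeSeq(g), genomeSeq(g2))
  g3 <- generateAncestor(20000, gc = 0.61, seed = 8)
  expect_false(identical(genomeSeq(g), genomeSeq(g3)))
  # realized GC at scale (stop-codon exclusion shifts it by < 0.01)
  big <- generateAncestor(100000, gc = 0.61, seed = 1)
  expect_lt(abs(gcContent(big) - 0.61), 0.02)
  expect_error(generateAncestor(500), ">= 1000")
})

test_that("ancestor CDSs translate cleanly to full-length proteins", {
  g <- generateAncestor(15000, gc = 0.61, seed = 4)
  ft <- geneFeatures(g)
  for (i in seq_len(nrow(ft))) {
    dna <- extractGeneDNA(g, ft[i, ])
    aa <- translateCDS(dna)
    expect_equal(nchar(aa), nchar(dna) / 3 - 1)
  }
})

test_that("evolution respects rates, preserves frames, and is deterministic", {
  anc <- generateAncestor(30000, gc = 0.61, seed = 2)
  expect_error(evolutionConfig(substitution_rate = 0.9), "0.5")
  zero <- evolveGenome(anc, evolutionConfig(0, 0, seed = 5))
  expect_identical(genomeSeq(zero$genome), genomeSeq(anc))

  cfg <- evolutionConfig(substitution_rate = 0.05, indel_rate = 1e-4, seed = 5)
  e1 <- evolveGenome(anc, cfg)
  e2 <- evolveGenome(anc, cfg)
  expect_identical(genomeSeq(e1$genome), genomeSeq(e2$genome))
  expect_identical(e1$truth@subs, e2$truth@subs)

  # realized substitution count near expectation
  nsub <- nrow(e1$truth@subs[[1]])
  expect_lt(abs(nsub - 0.05 * 30000) / (0.05 * 30000), 0.15)
  # all CDS still translate full length (nonsense suppressed)
  ft <- geneFeatures(e1$genome)
  for (i in seq_len(nrow(ft))) {
    dna <- extractGeneDNA(e1$genome, ft[i, ])
    expect_equal(nchar(translateCDS(dna)), nchar(dna) %/% 3 - 1)
  }
  validObject(e1$genome)
})

test_that("planted intron satisfies boundary hallmarks and round-trips", {
  anc <- generateAncestor(15000, gc = 0.61, seed = 9)
  gene <- geneFeatures(anc)[3, ]
  set.seed(1)
  res <- plantElement(anc, plantSpec("intron", target = gene$gene_number,
                                     options = list(length = 600)))
  ev <- res$event
  expect_equal(ev$kind, "intron")
  expect_equal(ev$end - ev$start + 1L, 600L)
  seq2 <- genomeSeq(res$genome)
  # round trip restores the ancestor byte-for-byte
  restored <- paste0(substring(seq2, 1, ev$start - 1),
                     substring(seq2, ev$end + 1, nchar(seq2)))
  expect_identical(restored, genomeSeq(anc))
  # hallmarks on the gene's sense strand
  g2 <- res$genome
  gene2 <- geneFeatures(g2)[geneFeatures(g2)$gene_number == gene$gene_number, ]
  sense <- extractGeneDNA(g2, gene2)
  q1 <- if (gene2$strand == "+") ev$start - gene2$start + 1 else gene2$end - ev$end + 1
  q2 <- q1 + 599
  expect_equal(substring(sense, q1 - 1, q1 - 1), "T")  # exon 1 3' base
  expect_equal(substring(sense, q2, q2), "G")          # intron 3' base
  # host gene feature grew by the intron length
  expect_equal(gene2$end - gene$end, 600L)
})

test_that("planted intron with internal ORF carries a reverse-strand LAGLIDADG frame", {
  anc <- generateAncestor(15000, gc = 0.61, seed = 10)
  gene <- geneFeatures(anc)[2, ]
  set.seed(2)
  res <- plantElement(anc, plantSpec("intron", target = gene$gene_number,
                                     options = list(length = 819, internal_orf = TRUE)))
  orfs <- findInternalORFs(res$event$payload, min_aa = 100)
  # the planted 150-codon frame is recovered on the bottom strand (upstream
  # in-frame starts also read through to the same stop and are reported too)
  hit <- orfs[orfs$has_laglidadg & orfs$strand == "-" & orfs$aa_len == 150, ]
  expect_equal(nrow(hit), 1)
  expect_false(any(orfs$has_laglidadg & orfs$strand == "+"))
})

test_that("planted intein lengthens the protein in place", {
  anc <- generateAncestor(15000, gc = 0.61, seed = 12)
  ft <- geneFeatures(anc)
  gene <- ft[which((ft$end - ft$start + 1) >= 900)[1], ]
  before <- translateCDS(extractGeneDNA(anc, gene))
  set.seed(3)
  res <- plantElement(anc, plantSpec("intein", target = gene$gene_number,
                                     options = list(aa_len = 120, aa_pos = 60)))
  g2 <- res$genome
  gene2 <- geneFeatures(g2)[geneFeatures(g2)$gene_number == gene$gene_number, ]
  after <- translateCDS(extractGeneDNA(g2, gene2))
  expect_equal(nchar(after), nchar(before) + 120L)
  # exteins unchanged
  expect_equal(substring(after, 1, 60), substring(before, 1, 60))
  expect_equal(substring(after, 181), substring(before, 61))
})

test_that("planted transposon duplicates the target motif around the element", {
  anc <- generateAncestor(15000, gc = 0.61, seed = 13)
  base <- PhageGenome("ref", genomeSeq(anc), geneFeatures(anc))
  set.seed(4)
  site <- phageMosaic:::pick_intergenic_site(base, margin = 25)
  res <- plantElement(base, plantSpec("transposon", target = site,
                                      options = list(tsd_len = 5, length = 800)))
  ev <- res$event
  tsd <- ev$tsd_seq
  expect_equal(nchar(tsd), 5L)
  carrier <- genomeSeq(res$genome)
  # carrier: TSD ... element ... TSD; empty allele holds one copy
  expect_equal(substring(carrier, site - 4, site), tsd)
  expect_equal(substring(carrier, ev$end - 4, ev$end), tsd)
  expect_equal(substring(genomeSeq(base), site - 4, site), tsd)
  # excising the logged block restores the base genome
  restored <- paste0(substring(carrier, 1, ev$start - 1),
                     substring(carrier, ev$end + 1, nchar(carrier)))
  expect_identical(restored, genomeSeq(base))
})

test_that("deletion-associated endonuclease logs the lost target bases", {
  anc <- generateAncestor(15000, gc = 0.61, seed = 14)
  set.seed(5)
  res <- plantElement(anc, plantSpec("endonuclease",
                                     options = list(length = 500, orf_aa = 120,
                                                    deletion_at_target = 35)))
  ev <- res$event
  expect_equal(ev$deletion_bp, 35L)
  expect_equal(nchar(ev$deleted_seq), 35L)
  # restoration requires re-inserting the logged deletion
  carrier <- genomeSeq(res$genome)
  restored <- paste0(substring(carrier, 1, ev$start - 1), ev$deleted_seq,
                     substring(carrier, ev$end + 1, nchar(carrier)))
  expect_identical(restored, genomeSeq(anc))
})

test_that("cohorts are deterministic, complete, and within the planted identity band", {
  co <- makeCohort("minimal", seed = 5)
  expect_length(co$genomes, 2)
  expect_gt(nrow(truthEvents(co$truth)), 0)
  co2 <- makeCohort("minimal", seed = 5)
  expect_identical(vapply(co$genomes, genomeSeq, ""),
                   vapply(co2$genomes, genomeSeq, ""))
  expect_identical(genomeSeq(co$host), genomeSeq(co2$host))
  expect_identical(truthEvents(co$truth), truthEvents(co2$truth))

  cj <- makeCohort("cluster_j_like", seed = 6, genome_length = 40000,
                   host_length = 20000)
  kinds <- truthEvents(cj$truth)$kind
  expect_true(all(c("intron", "intein", "transposon", "endonuclease",
                    "att_core", "att_core_host", "arm_site") %in% kinds))
  pim <- plantedIdentityMatrix(cj$truth, cj$ancestor)
  off <- pim[upper.tri(pim)]
  # the target band is 0.79-0.97; allow binomial sampling noise at this
  # reduced genome size
  expect_true(all(off >= 0.785 & off <= 0.975))
})

test_that("feature bookkeeping survives planting and evolution", {
  cj <- makeCohort("cluster_j_like", seed = 3, genome_length = 40000,
                   host_length = 20000)
  for (g in cj$genomes) expect_true(validObject(g))
  expect_true(validObject(cj$host))
  expect_true(validObject(cj$truth))
})
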