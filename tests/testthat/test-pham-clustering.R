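make_proteins <- function(...) {
  seqs <- c(...)
  data.frame(genome = sub(":.*", "", names(seqs)),
             gene = sub(".*:", "", names(seqs)),
             seq = unname(seqs), stringsAsFactors = FALSE)
}

test_that("edges fire on identity or E-value, inclusively, and reject duplicates", {
  p <- rand_protein(200)
  prot <- make_proteins("A:1" = p, "B:1" = p)
  e <- scoreEdges(prot)
  expect_equal(nrow(e), 1)

  set.seed(41)
  prot2 <- make_proteins("A:1" = rand_protein(100), "B:1" = rand_protein(100))
  expect_equal(nrow(scoreEdges(prot2)), 0)

  dup <- make_proteins("A:1" = p, "A:1" = p)
  expect_error(scoreEdges(dup), "duplicate")

  # inclusive identity threshold: a pair at exactly 13/40 = 0.325.
  # Kept positions are scattered every third residue; all other residues
  # become W (absent from the base alphabet), so no gapped alignment can
  # gain matches and the identity is exact.
  set.seed(42)
  base <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVY", "")[[1]], 40,
                       replace = TRUE), collapse = "")
  ch <- strsplit(base, "")[[1]]
  keep <- c(1:4, seq(7, 31, by = 3))  # 13 positions, incl. one seed word
  ch[-keep] <- "W"
  mutated <- paste(ch, collapse = "")
  idy <- globalAlignAA(base, mutated)$identity
  expect_equal(idy, 0.325)  # the fixture sits exactly on the boundary
  e2 <- scoreEdges(make_proteins("A:1" = base, "B:1" = mutated))
  expect_equal(nrow(e2), 1)
})

test_that("single-linkage chains merge and orphams stay singletons", {
  # A-B and B-C similar, A-C not: one pham by transitivity
  set.seed(43)
  a <- rand_protein(150)
  b <- paste0(substring(a, 1, 100), rand_protein(50))
  c_ <- paste0(rand_protein(50), substring(b, 51, 150))
  prot <- make_proteins("X:1" = a, "Y:1" = b, "Z:1" = c_,
                        "X:2" = rand_protein(90))
  phams <- buildPhams(scoreEdges(prot), prot)
  expect_equal(length(unique(phams$pham_id)), 2)
  expect_equal(sum(table(phams$pham_id) == 1), 1)  # one orpham
  # partition property
  expect_equal(nrow(phams), nrow(prot))
  expect_false(anyDuplicated(paste(phams$genome, phams$gene)) > 0)
})

test_that("pham ids are stable and assigned by smallest member", {
  prot <- make_proteins("B:2" = rand_protein(80), "A:9" = rand_protein(80))
  phams <- buildPhams(data.frame(i = integer(0), j = integer(0)), prot)
  # "A:9" sorts before "B:2", so its pham gets id 1
  expect_equal(phams$pham_id[phams$genome == "A"], 1)
  expect_equal(phams$pham_id[phams$genome == "B"], 2)
})

test_that("shared gene counts: self, disjoint, and asymmetric paralog cases", {
  p <- rand_protein(120)
  q <- rand_protein(120)
  prot <- make_proteins("A:1" = p, "A:2" = p, "A:3" = q, "B:1" = p)
  phams <- buildPhams(scoreEdges(prot), prot)
  expect_equal(sharedGeneCount("A", "A", phams), 3L)
  # two A paralogs match one B gene: asymmetric
  expect_equal(sharedGeneCount("A", "B", phams), 2L)
  expect_equal(sharedGeneCount("B", "A", phams), 1L)
  expect_error(sharedGeneCount("A", "Z", phams), "unknown")
  m <- sharedGeneMatrix(phams)
  expect_equal(m["A", "B"], 2L)
  expect_equal(m["B", "B"], 1L)
})

test_that("adding an unrelated protein never merges phams", {
  set.seed(44)
  p1 <- rand_protein(150)
  p2 <- rand_protein(150)
  prot <- make_proteins("A:1" = p1, "B:1" = p2)
  phams0 <- buildPhams(scoreEdges(prot), prot)
  n0 <- length(unique(phams0$pham_id))
  prot2 <- rbind(prot, data.frame(genome = "C", gene = "1",
                                  seq = rand_protein(150)))
  phams1 <- buildPhams(scoreEdges(prot2), prot2)
  expect_equal(length(unique(phams1$pham_id)), n0 + 1)
})
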