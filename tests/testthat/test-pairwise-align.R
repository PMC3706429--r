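test_that("global protein alignment identity follows its definition", {
  same <- globalAlignAA("MKVLPW", "MKVLPW")
  expect_equal(same$identity, 1)
  expect_equal(globalAlignAA("MKV", "MQV")$identity, 2 / 3)
  expect_error(globalAlignAA("", "MKV"), "empty")
  # shorter-sequence denominator: a terminal extension does not dilute it
  expect_equal(globalAlignAA("MKVLPW", "MKVLPWAAAA")$identity, 1)
})

test_that("local nucleotide alignment handles self and disjoint inputs", {
  s <- strrep("ACGT", 25)
  self <- localAlignNT(s, s)
  expect_equal(self$identity, 1)
  expect_equal(self$coords$a, c(1L, 100L))
  expect_gt(self$score, 0)
  expect_lt(self$evalue, 1e-10)
  none <- localAlignNT(strrep("A", 40), strrep("C", 40))
  expect_equal(none$aligned_cols, 0L)
  expect_error(localAlignNT("", "ACGT"), "empty")
})

test_that("ANI is symmetric, 1 on self, and errors on short input", {
  g <- generateAncestor(4000, gc = 0.6, seed = 3, id = "g")
  a <- ani(g, g)
  expect_equal(a$ani, 1)
  expect_equal(unname(a$per_direction), c(1, 1))
  expect_error(ani(g, PhageGenome("s", strrep("ACGT", 100))), "twice")
})

test_that("ANI decreases with substitution rate and tracks per-site identity", {
  anc <- generateAncestor(60000, gc = 0.61, seed = 5, id = "anc")
  prev <- 1.01
  for (r in c(0.01, 0.05, 0.1)) {
    ev <- evolveGenome(anc, evolutionConfig(substitution_rate = r, seed = 9),
                       id = "mut")
    a <- ani(anc, ev$genome)
    # a genome at rate r sits near 1 - r identity to its ancestor
    expect_lt(abs(a$ani - (1 - r)), 0.01)
    expect_lt(a$ani, prev + 0.005)
    prev <- a$ani
  }
})

test_that("dotplot matches are exact, stranded, and swap-symmetric", {
  expect_error(dotplotMatches("ACGT", "ACGT", k = 4), ">= 8")
  a <- "ACGTACGTACGTACG"
  d <- dotplotMatches(a, a, k = 10)
  diag_hits <- d[d$posA == d$posB & d$strand == "+", ]
  expect_equal(nrow(diag_hits), nchar(a) - 10 + 1)
  set.seed(20)
  x <- rand_dna(80, 0.5)
  rc <- dotplotMatches(x, revComp(x), k = 12)
  minus <- rc[rc$strand == "-", ]
  # the full antidiagonal: every position matches its mirror image
  n <- nchar(x); k <- 12
  anti <- paste(seq_len(n - k + 1), n - seq_len(n - k + 1) - k + 2)
  expect_true(all(anti %in% paste(minus$posA, minus$posB)))

  set.seed(21)
  for (i in 1:10) {
    x <- rand_dna(80); y <- rand_dna(80)
    fwd <- dotplotMatches(x, y, k = 8)
    swp <- dotplotMatches(y, x, k = 8)
    fwd_plus <- fwd[fwd$strand == "+", c("posA", "posB")]
    swp_plus <- swp[swp$strand == "+", c("posB", "posA")]
    names(swp_plus) <- c("posA", "posB")
    o1 <- fwd_plus[order(fwd_plus$posA, fwd_plus$posB), ]
    o2 <- swp_plus[order(swp_plus$posA, swp_plus$posB), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o1, o2)
  }
})

test_that("longest common substring: forced example, self case, strand report", {
  r <- longestCommonSubstring("AAACGTAA", "TTCGTTT")
  expect_equal(r$length, 3L)
  expect_equal(r$seq, "CGT")

  s <- rand_dna(500, 0.5)
  self <- longestCommonSubstring(s, s)
  expect_equal(self$length, nchar(s))
  expect_equal(c(self$posA, self$posB), c(1L, 1L))

  # planted 44-mer on the minus strand of the target; flanking bases are
  # chosen so the shared match cannot extend past the planted core
  set.seed(33)
  core <- paste0("A", rand_dna(42, 0.6), "A")
  a <- paste0(rand_dna(198, 0.4), "TT", core, "TT", rand_dna(198, 0.4))
  b <- paste0(rand_dna(298, 0.4), "GG", oracle_revcomp(core), "GG",
              rand_dna(98, 0.4))
  hit <- longestCommonSubstring(a, b, search_revcomp = TRUE)
  expect_equal(hit$length, 44L)
  expect_equal(hit$strand, "-")
  expect_equal(hit$posA, 201L)
  expect_equal(hit$posB, 301L)
  expect_equal(substring(b, hit$posB, hit$posB + 43), oracle_revcomp(core))
})
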