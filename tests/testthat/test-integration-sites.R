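test_that("arm-site rule: consensus instance, scored mismatches, orientations", {
  hits <- scanArmSites(paste0("CC", "TGCATACGAC", "CC"))
  expect_equal(nrow(hits[hits$orientation == "direct", ]), 1)
  expect_equal(hits$mismatches[hits$orientation == "direct"], 0L)
  # position 9 violation only -> 1 mismatch, still a hit at max_mismatch 1
  h2 <- scanArmSites(paste0("CC", "TGCATACTTT", "CC"))
  h2 <- h2[h2$orientation == "direct", ]
  expect_equal(nrow(h2), 1)
  expect_equal(h2$mismatches, 1L)
  # two violations -> rejected
  h3 <- scanArmSites(paste0("CC", "GGCATACTTA", "CC"))
  expect_equal(nrow(h3[h3$orientation == "direct", ]), 0)
  # inverted consensus is found with the inverted orientation
  h4 <- scanArmSites(paste0("CC", revComp("TGCATACGAC"), "CC"))
  expect_equal(nrow(h4[h4$orientation == "inverted", ]), 1)
})

test_that("att core discovery finds the planted core, tRNA overlap, arm sites", {
  co <- makeCohort("minimal", seed = 9)
  ev <- truthEvents(co$truth)
  for (id in names(co$genomes)) {
    g <- co$genomes[[id]]
    ft <- geneFeatures(g)
    ig <- ft[grepl("integrase", ft$product), , drop = FALSE][1, ]
    site <- findAttCore(g, co$host, ig)
    tr <- ev[ev$kind == "att_core" & ev$genome == id, ]
    trh <- ev[ev$kind == "att_core_host", ][1, ]
    expect_true(site@found)
    expect_equal(nchar(coreSeq(site)), 44L)
    expect_equal(site@phage_interval, c(tr$start, tr$end))
    expect_equal(site@host_interval, c(trh$start, trh$end))
    expect_equal(site@trna_overlap, "tRNA-Leu")
    arm_names <- site@arm_sites$name
    expect_true(all(c("P1", "P2", "P3", "P4") %in% arm_names))
  }
})

test_that("a host without the core gives a no-site result", {
  co <- makeCohort("minimal", seed = 10)
  g <- co$genomes[[1]]
  ft <- geneFeatures(g)
  ig <- ft[grepl("integrase", ft$product), , drop = FALSE][1, ]
  empty_host <- generateAncestor(20000, gc = 0.67, seed = 999, id = "h2")
  site <- findAttCore(g, empty_host, ig)
  expect_false(site@found)
  expect_lt(nchar(site@core_seq), 25)
})

test_that("a core on the host minus strand is reported with strand '-'", {
  co <- makeCohort("minimal", seed = 12)
  g <- co$genomes[[1]]
  ft <- geneFeatures(g)
  ig <- ft[grepl("integrase", ft$product), , drop = FALSE][1, ]
  flipped <- PhageGenome("hostrc", revComp(genomeSeq(co$host)))
  site <- findAttCore(g, flipped, ig)
  expect_true(site@found)
  expect_equal(site@strand, "-")
  expect_equal(nchar(coreSeq(site)), 44L)
  # host substring reverse-complements to the phage core
  hseq <- genomeSeq(flipped)
  expect_equal(revComp(substring(hseq, site@host_interval[1], site@host_interval[2])),
               coreSeq(site))
})

test_that("attL/attR junctions each contain the core once and rebuild a prophage", {
  co <- makeCohort("minimal", seed = 9)
  g <- co$genomes[[1]]
  ft <- geneFeatures(g)
  ig <- ft[grepl("integrase", ft$product), , drop = FALSE][1, ]
  site <- findAttCore(g, co$host, ig)
  jn <- predictAttLR(g, co$host, site, context = 200)
  count_core <- function(s) {
    length(gregexpr(coreSeq(site), s, fixed = TRUE)[[1]])
  }
  expect_equal(count_core(jn$attL), 1)
  expect_equal(count_core(jn$attR), 1)
  expect_false(jn$truncated)
  # the prophage built by the same junction arithmetic carries the whole
  # phage rotated around the core and both hybrid junctions
  p <- site@phage_interval
  h <- site@host_interval
  pseq <- genomeSeq(g); hseq <- genomeSeq(co$host)
  prophage <- paste0(substring(hseq, 1, h[1] - 1), coreSeq(site),
                     substring(pseq, p[2] + 1, nchar(pseq)),
                     substring(pseq, 1, p[1] - 1), coreSeq(site),
                     substring(hseq, h[2] + 1, nchar(hseq)))
  expect_equal(nchar(prophage), nchar(hseq) + nchar(pseq) - (p[2] - p[1] + 1) +
                 nchar(coreSeq(site)))
  expect_true(grepl(jn$attL, prophage, fixed = TRUE))
  expect_true(grepl(jn$attR, prophage, fixed = TRUE))
})

test_that("integration fragment covers integrase and core with margins", {
  co <- makeCohort("minimal", seed = 9)
  g <- co$genomes[[1]]
  ft <- geneFeatures(g)
  ig <- ft[grepl("integrase", ft$product), , drop = FALSE][1, ]
  site <- findAttCore(g, co$host, ig)
  iv <- designIntegrationFragment(g, ig, site, margin = 300)
  expect_lte(iv["start"], ig$start - 300)
  expect_gte(iv["end"], site@phage_interval[2] + 300)
  iv0 <- designIntegrationFragment(g, ig, site, margin = 0)
  expect_equal(unname(iv0["start"]), ig$start)
  expect_equal(unname(iv0["end"]), site@phage_interval[2])
  # typical cassette span: integrase plus ~100 bp spacer plus the core
  expect_lt(iv["end"] - iv["start"] + 1, 2000 + (ig$end - ig$start + 1))
})
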