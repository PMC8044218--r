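mkTx <- function(fc, p = 0.01) {
  gr <- grFromBed("chr1", seq(0, by = 10000, length.out = length(fc)),
                  seq(0, by = 10000, length.out = length(fc)) + 2000, "+")
  gr$foldChange <- fc
  gr$pValue <- p
  gr
}

test_that("fold-change classification is strict, with an optional p filter", {
  cls <- classifyTranscripts(mkTx(c(3, 0.4, 1, 2, 0.5, 2.0001, 0.4999)))
  expect_equal(as.character(cls),
               c("up", "down", "unchanged", "unchanged", "unchanged",
                 "up", "down"))
  ## p filter on: a non-significant fold change drops out of the DE set
  cfg <- analysisConfig(applyPFilter = TRUE)
  cls2 <- classifyTranscripts(mkTx(c(3, 3), p = c(0.2, 0.01)), cfg)
  expect_equal(as.character(cls2), c("unchanged", "up"))
})

test_that("TSS extraction is strand-aware, including 1-bp transcripts", {
  expect_equal(start(transcriptTss(grFromBed("chr1", 100, 500, "+"))) - 1, 100)
  expect_equal(start(transcriptTss(grFromBed("chr1", 100, 500, "-"))) - 1, 499)
  expect_equal(start(transcriptTss(grFromBed("chr1", 100, 101, "+"))) - 1, 100)
  expect_equal(start(transcriptTss(grFromBed("chr1", 100, 101, "-"))) - 1, 100)
  expect_error(transcriptTss(grFromBed("chr1", 100, 500, ".")), "strand")
})

test_that("TSS-in-element overlap is half-open and matches a brute-force loop", {
  els <- grFromBed("chr1", c(1000, 5000), c(2000, 6000))
  atStart <- grFromBed("chr1", 1000, 1001, "+")
  atEnd <- grFromBed("chr1", 2000, 2001, "+")
  expect_equal(tssElementOverlap(atStart, els)$count, 1)
  expect_equal(tssElementOverlap(atEnd, els)$count, 0)
  set.seed(14)
  pos <- sample(0:7000, 300, replace = TRUE)
  tss <- grFromBed("chr1", pos, pos + 1, "+")
  eldf <- data.frame(chrom = "chr1", start = c(1000, 5000),
                     end = c(2000, 6000))
  expect_equal(tssElementOverlap(tss, els)$count,
               oracleTssOverlap(rep("chr1", 300), pos, eldf))
})

test_that("proximity profiles are monotone and match hand counts", {
  els <- list(bound = grFromBed("chr1", c(0, 100000), c(6000, 106000)))
  tss <- list(up = grFromBed("chr1", 6500, 6501, "+"))   # 500 bp past el 1
  pp <- proximityProfile(els, tss, analysisConfig())
  expect_equal(nrow(pp), 20)
  ## within every ladder distance >= 1 kb for element 1 only
  expect_equal(pp$proportion, rep(0.5, 20))
  ## monotonicity on random data
  set.seed(3)
  rtss <- list(up = dfToGr(randIv(50, 2e5, "chr1", 2)))
  pp2 <- proximityProfile(list(g = els$bound), rtss, analysisConfig())
  expect_true(all(diff(pp2$proportion) >= 0))
  expect_warning(proximityProfile(list(e = els$bound[0]), tss,
                                  analysisConfig()), "empty")
})

test_that("rotation nulls recover analytic coverage fractions", {
  sizes <- c(c1 = 1000)
  el <- grFromBed("c1", 0, 100)
  tss <- grFromBed("c1", 500, 501, "+")
  ep <- rotationExpectedProbability(tss, el, sizes, nPerm = 10000, seed = 5)
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(ep - 0.1), 3 * se)
  ## determinism given the seed
  expect_identical(ep, rotationExpectedProbability(tss, el, sizes,
                                                   nPerm = 10000, seed = 5))
  ## elements covering a whole chromosome trap every rotation
  expect_equal(rotationExpectedProbability(tss, grFromBed("c1", 0, 1000),
                                           sizes, nPerm = 50, seed = 1), 1)
  ## no elements on the chromosome
  expect_equal(rotationExpectedProbability(tss, el[0], sizes,
                                           nPerm = 50, seed = 1), 0)
  expect_error(rotationExpectedProbability(
    grFromBed("c9", 1, 2, "+"), el, sizes, nPerm = 10, seed = 1), "c9")
  ## single-offset mode also recovers the coverage fraction
  ep1 <- rotationExpectedProbability(tss, el, sizes, nPerm = 10000,
                                     seed = 5, perChromosome = FALSE)
  expect_lt(abs(ep1 - 0.1), 3 * se)
})

test_that("binomial tails are exact and direction follows the mean", {
  r <- binomialEnrichment(5, 10, 0.1)
  ## frozen exact sum: sum_{i>=5} C(10,i) 0.1^i 0.9^(10-i)
  expect_equal(r@pValue, sum(choose(10, 5:10) * 0.1^(5:10) * 0.9^(5:0)),
               tolerance = 1e-12)
  expect_equal(r@direction, "enriched")
  rd <- binomialEnrichment(1, 100, 0.1)
  expect_equal(rd@direction, "depleted")
  expect_equal(rd@pValue, pbinom(1, 100, 0.1), tolerance = 1e-12)
  ## central case: p-value not small, tie counts as depleted
  rc <- binomialEnrichment(10, 100, 0.1)
  expect_equal(rc@direction, "depleted")
  expect_gt(rc@pValue, 0.4)
  expect_message(r0 <- binomialEnrichment(3, 10, 0), "degenerate")
  expect_equal(r0@pValue, 0)
})

test_that("a planted element-TSS excess is detected as strong enrichment", {
  b <- simulateAll(fixtureSpec(rngSeed = 7), components = c("transcripts"))
  tx <- b$transcripts
  up <- tx[tx$class_planted == "up", ]
  tss <- transcriptTss(grFromBed(up$chrom, up$start, up$end, up$strand))
  res <- tssEnrichmentTest(tss, b$elements, b$chromSizes,
                           nPerm = 1000, seed = 7)
  expect_equal(res@direction, "enriched")
  expect_lt(res@pValue, 1e-10)
  ## the rotation estimate sits near the true coverage fraction
  expect_lt(abs(res@expectedP - b$truth$elementCoverageFraction), 0.02)
})

test_that("exon-sharing association is strand-matched and ignores introns", {
  mk <- function(id, strand, exons) {
    gr <- grFromBed("chr1", exons[[1]][1], exons[[length(exons)]][2], strand)
    gr$transcriptId <- id
    gr$exons <- GenomicRanges::GRangesList(
      grFromBed("chr1", vapply(exons, `[`, 0, 1),
                vapply(exons, `[`, 0, 2), strand))
    gr
  }
  novel <- mk("n1", "+", list(c(1000, 1200), c(5000, 5300)))
  known <- mk("k1", "+", list(c(1100, 1250), c(8000, 8300)))
  sameIntron <- mk("k2", "+", list(c(2000, 2400)))   # inside n1's intron
  oppStrand <- mk("k3", "-", list(c(1000, 1200)))
  a <- associateWithKnown(novel, c(known, sameIntron, oppStrand))
  expect_equal(a$knownId, "k1")
  expect_equal(nrow(associateWithKnown(novel, sameIntron)), 0)
  expect_equal(nrow(associateWithKnown(novel, oppStrand)), 0)
})
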