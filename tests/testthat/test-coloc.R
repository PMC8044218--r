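test_that("same-TF sites merge to most distal coordinates, never across TFs", {
  sitesByTf <- list(A = c(grFromBed("chr1", 0, 100), grFromBed("chr1", 50, 150)),
                    B = grFromBed("chr1", 120, 220))
  m <- mergeTfSites(sitesByTf)
  expect_length(m$A, 1)
  expect_equal(c(start(m$A) - 1, end(m$A)), c(0, 150))
  expect_length(m$B, 1)
  ## merged per-TF base coverage preserved on random input
  set.seed(9)
  r <- randIv(80)
  mr <- mergeTfSites(list(X = dfToGr(r)))$X
  mdf <- data.frame(chrom = as.character(seqnames(mr)),
                    start = start(mr) - 1, end = end(mr))
  expect_setequal(oracleCoveredBases(mdf), oracleCoveredBases(r))
})

test_that("element split is an exact disjoint partition", {
  els <- grFromBed("chr1", c(1000, 20000), c(7000, 26000))
  set.seed(31)
  sites <- dfToGr(randIv(120, maxc = 30000, chroms = "chr1", maxLen = 150))
  sp <- splitByElements(sites, els, 0.5)
  expect_equal(length(sp$elementDerived) + length(sp$other), length(sites))
  hits <- intersectFraction(sp$other, els, 0.5)
  expect_length(hits, 0)                      # nothing element-like leaks out
  ## 60%-inside site is element-derived; no-overlap site is not
  expect_length(splitByElements(grFromBed("chr1", 6940, 7040), els,
                                0.5)$elementDerived, 1)
  expect_length(splitByElements(grFromBed("chr1", 50000, 50100), els,
                                0.5)$elementDerived, 0)
})

test_that("element pair counts match brute-force set intersection and stay symmetric", {
  els <- grFromBed("chr1", c(0, 10000, 20000), c(6000, 16000, 26000))
  sitesByTf <- list(A = c(grFromBed("chr1", 100, 200),
                          grFromBed("chr1", 10100, 10200)),
                    B = grFromBed("chr1", 10500, 10600))
  pc <- elementPairCounts(els, sitesByTf, 0.5)
  expect_equal(pc@counts["A", "B"], 1L)
  expect_equal(pc@counts["A", "A"], 2L)
  expect_equal(pc@counts["B", "B"], 1L)
  expect_equal(pc@counts, t(pc@counts))
  expect_equal(displayCounts(pc), pc@counts^0.25)
  ## random instance equals brute force over element TF sets
  set.seed(12)
  rTf <- list(A = dfToGr(randIv(60, 30000, "chr1", 200)),
              B = dfToGr(randIv(40, 30000, "chr1", 200)))
  pc2 <- elementPairCounts(els, rTf, 0.5)
  setA <- unique(S4Vectors::subjectHits(intersectFraction(rTf$A, els, 0.5)))
  setB <- unique(S4Vectors::subjectHits(intersectFraction(rTf$B, els, 0.5)))
  expect_equal(pc2@counts["A", "B"], length(intersect(setA, setB)))
})

test_that("pairwise co-localisation proportions are asymmetric by construction", {
  sitesByTf <- list(
    A = grFromBed("chr1", c(0, 10000, 20000, 30000),
                  c(100, 10100, 20100, 30100)),
    B = grFromBed("chr1", 550, 600))
  cc <- pairwiseColocCounts(sitesByTf, 500)
  expect_equal(cc$counts["A", "B"], 1L)
  expect_equal(cc$counts["B", "A"], 1L)
  expect_equal(cc$proportions["A", "B"], 0.25)
  expect_equal(cc$proportions["B", "A"], 1)
  ## identity proportions[i,j] * totals[i] = counts[i,j]
  expect_equal(cc$proportions * cc$totals, cc$counts + 0)
  ## w = 0 with disjoint sites gives zeros
  cc0 <- pairwiseColocCounts(sitesByTf, 0)
  expect_true(all(cc0$counts == 0))
  ## empty TF yields missing proportions
  ccNA <- pairwiseColocCounts(list(A = sitesByTf$A,
                                   B = sitesByTf$B[0]), 500)
  expect_true(all(is.na(ccNA$proportions["B", ])))
})

test_that("pooled z-test matches the textbook formula, with antisymmetry", {
  ## frozen from an independent evaluation of the pooled formula:
  ## p = 560/1100, z = 0.1 / sqrt(p(1-p)(1/100 + 1/1000))
  r <- twoProportionZTest(60, 100, 500, 1000)
  expect_equal(r$z, 1.907239, tolerance = 1e-6)
  expect_equal(r$p, 0.02824473, tolerance = 1e-6)
  ## cross-check against the chi-square identity z^2 = X^2 (no correction)
  suppressWarnings(pt <- prop.test(c(60, 500), c(100, 1000), correct = FALSE))
  expect_equal(r$z^2, unname(pt$statistic), tolerance = 1e-12)
  ## equal proportions: z = 0, p = 0.5; swapping groups negates z
  expect_equal(twoProportionZTest(5, 50, 20, 200), list(z = 0, p = 0.5))
  r2 <- twoProportionZTest(500, 1000, 60, 100)
  expect_equal(r2$z, -r$z)
  expect_equal(r2$p, 1 - r$p)
  ## degenerate pooled proportions
  expect_equal(twoProportionZTest(0, 10, 0, 20), list(z = 0, p = 0.5))
  expect_equal(twoProportionZTest(10, 10, 20, 20), list(z = 0, p = 0.5))
  ## p is monotone decreasing in z
  zs <- vapply(seq(10, 90, 10), function(k)
    twoProportionZTest(k, 100, 50, 100)$z, 0)
  ps <- vapply(seq(10, 90, 10), function(k)
    twoProportionZTest(k, 100, 50, 100)$p, 0)
  expect_true(all(diff(zs) > 0) && all(diff(ps) < 0))
})

test_that("enrichment matrices test ordered pairs at alpha over k-squared", {
  mk <- function(starts) grFromBed("chr1", starts, starts + 100)
  same <- list(A = mk(c(0, 5000)), B = mk(c(200, 9000)),
               C = mk(c(20000, 40000)))
  m <- colocEnrichmentMatrix(same, same, analysisConfig())
  expect_equal(m@perTestAlpha, 0.05 / 9)
  ## identical groups: all z = 0, nothing significant, diagonal untested
  expect_true(all(m@z[!is.na(m@z)] == 0))
  expect_false(any(m@significant))
  expect_true(all(is.na(diag(m@p))))
  expect_equal(unname(m@totalsElement), c(2, 2, 2))
  expect_error(colocEnrichmentMatrix(same[1], same[1], analysisConfig()),
               "at least 2")
  expect_error(colocEnrichmentMatrix(same, same[c(1, 2)], analysisConfig()))
})

test_that("a planted element-restricted coupling is the significant cell", {
  spec <- fixtureSpec(rngSeed = 19, fivePrimeEnrichment = 1,
                      backgroundRate = 200,
                      coupling = data.frame(tfA = "ESR1", tfB = "FOXA1",
                                            prob = 0.8))
  b <- simulateAll(spec, components = "sites")
  parts <- lapply(b$sitesByTf, splitByElements, b$elements, 0.5)
  m <- colocEnrichmentMatrix(
    mergeTfSites(lapply(parts, `[[`, "elementDerived")),
    mergeTfSites(lapply(parts, `[[`, "other")), analysisConfig())
  expect_true(m@significant["ESR1", "FOXA1"])
  expect_true(m@significant["FOXA1", "ESR1"])
  others <- m@significant
  others[c("ESR1", "FOXA1"), c("ESR1", "FOXA1")] <- FALSE
  expect_false(any(others))
  expect_equal(m@stars["ESR1", "FOXA1"], "***")
})
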