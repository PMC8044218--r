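test_that("element windows are centred, exact-width, and flag clamping", {
  w <- elementWindow(grFromBed("chr1", 10000, 16000), 20000)
  expect_equal(c(start(w) - 1, end(w)), c(3000, 23000))
  expect_false(w$clamped)
  expect_true(elementWindow(grFromBed("chr1", 0, 100), 20000)$clamped)
  expect_true(elementWindow(grFromBed("chr1", 999000, 999100), 20000,
                            c(chr1 = 1e6))$clamped)
  expect_error(elementWindow(grFromBed("chr1", 0, 30000), 20000), "longer")
  expect_error(elementWindow(grFromBed("chr1", 0, 100), 19999))
})

test_that("meta-profiles normalise per element, orient 5'->3', and average", {
  cfg <- analysisConfig()
  elPlus <- grFromBed("chr1", 100000, 106000, "+")
  # one site in the first bin of the window ([93000, 93100))
  site1 <- grFromBed("chr1", 93010, 93060)
  p <- tfbsMetaProfile(elPlus, site1, cfg)
  expect_equal(profileValues(p), c(1, rep(0, 199)))
  ## same site relative to a minus-strand element appears mirrored
  elMinus <- grFromBed("chr1", 100000, 106000, "-")
  pm <- tfbsMetaProfile(elMinus, site1, cfg)
  expect_equal(profileValues(pm), rev(profileValues(p)))
  ## ... but not when orientation is off
  pmu <- tfbsMetaProfile(elMinus, site1, cfg, oriented = FALSE)
  expect_equal(profileValues(pmu), profileValues(p))
  ## averaging two elements preserves mass 1
  el2 <- grFromBed("chr1", c(100000, 400000), c(106000, 406000), "+")
  sites <- grFromBed("chr1", c(93010, 400000, 405000),
                     c(93060, 400200, 405050))
  p2 <- tfbsMetaProfile(el2, sites, cfg)
  expect_equal(sum(profileValues(p2)), 1, tolerance = 1e-12)
  expect_equal(p2@nElements, 2)
  ## elements without any site in the window are excluded from averaging
  el3 <- grFromBed(c("chr1", "chr1", "chr2"), c(100000, 400000, 500000),
                   c(106000, 406000, 506000), "+")
  p3 <- tfbsMetaProfile(el3, sites, cfg)
  expect_equal(p3@nElements, 2)
  expect_equal(profileValues(p3), profileValues(p2))
  expect_error(suppressWarnings(
    tfbsMetaProfile(grFromBed("chr3", 1e5, 1e5 + 6000), sites, cfg)),
    "no element")
})

test_that("mirroring all strands and coordinates reverses unoriented profiles exactly", {
  cfg <- analysisConfig()
  L <- 1e6
  set.seed(77)
  el <- grFromBed("chr1", c(1e5, 4e5, 7e5), c(1e5, 4e5, 7e5) + 6000,
                  c("+", "-", "+"))
  s0 <- sort(sample(90000:710000, 60))
  sites <- grFromBed("chr1", s0, s0 + 120)
  mirror <- function(gr) {
    st <- L - (end(gr))
    en <- L - (start(gr) - 1)
    flip <- c("+" = "-", "-" = "+", "*" = "*")
    grFromBed(as.character(seqnames(gr)), st, en,
              flip[as.character(strand(gr))])
  }
  pu <- tfbsMetaProfile(el, sites, cfg, oriented = FALSE)
  pmu <- tfbsMetaProfile(mirror(el), mirror(sites), cfg, oriented = FALSE)
  expect_equal(profileValues(pmu), rev(profileValues(pu)), tolerance = 1e-12)
  ## oriented profiles are invariant under the mirror
  po <- tfbsMetaProfile(el, sites, cfg)
  pmo <- tfbsMetaProfile(mirror(el), mirror(sites), cfg)
  expect_equal(profileValues(pmo), profileValues(po), tolerance = 1e-12)
})

test_that("binding summaries count elements per TF with the fraction rule", {
  els <- grFromBed(c("chr1", "chr1", "chr2"), c(1000, 20000, 1000),
                   c(7000, 26000, 7000))
  els$id <- paste0("e", 1:3)
  sitesByTf <- list(
    A = c(grFromBed("chr1", 2000, 2100), grFromBed("chr1", 21000, 21100)),
    B = grFromBed("chr1", 20500, 20600))
  bs <- bindingSummary(els, sitesByTf, 0.5)
  expect_equal(bs@perTfElementCount, c(A = 2L, B = 1L))
  expect_equal(nBoundElements(bs), 2L)
  expect_equal(sort(bs@perElementTfs$e2), c("A", "B"))
  expect_equal(unname(pctOfBound(bs)), c(100, 50))
  ## 40% overlap with f = 0.5 is not assigned
  partial <- list(A = grFromBed("chr1", 6960, 7060))   # 40/100 inside e1
  expect_equal(nBoundElements(bindingSummary(els, partial, 0.5)), 0L)
  ## order and duplication invariance
  bs2 <- bindingSummary(els, lapply(sitesByTf, rev), 0.5)
  expect_equal(bs2@perTfElementCount, bs@perTfElementCount)
  ## no sites -> all zero
  expect_equal(nBoundElements(bindingSummary(els, list(A = els[0]), 0.5)), 0L)
})

test_that("consensus projection follows the 5'-distance formula on both strands", {
  el <- grFromBed("chr1", 10000, 16000, "+", consensusStart = 1L)
  expect_equal(projectToConsensus(grFromBed("chr1", 12000, 12100), el), 2051L)
  ## site midpoint at the 5' end maps to consensus_start
  expect_equal(projectToConsensus(grFromBed("chr1", 10000, 10001), el), 1L)
  elm <- grFromBed("chr1", 10000, 16000, "-", consensusStart = 1L)
  expect_equal(projectToConsensus(grFromBed("chr1", 12000, 12100), elm), 3950L)
  expect_equal(projectToConsensus(grFromBed("chr1", 15999, 16000), elm), 1L)
  ## truncated element: consensus offset shifts positions
  el2 <- grFromBed("chr1", 10000, 16000, "+", consensusStart = 500L)
  expect_equal(projectToConsensus(grFromBed("chr1", 10000, 10001), el2), 500L)
  expect_error(projectToConsensus(grFromBed("chr1", 20000, 20100), el),
               "outside")
})

test_that("projection round-trips through its inverse on both strands", {
  set.seed(11)
  for (st in c("+", "-")) {
    el <- grFromBed("chr5", 50000, 56000, st, consensusStart = 37L)
    m0 <- sample(50000:55999, 50)
    sites <- grFromBed("chr5", m0, m0 + 1)
    pos <- projectToConsensus(sites, el)
    expect_equal(consensusToGenomic(pos, el), m0)
  }
})

test_that("consensus histograms bin at 5 bp and drop out-of-range positions", {
  h <- consensusHistogram(c(3L, 4L), bin = 5, maxPos = 20)
  expect_equal(unname(h), c(2L, 0L, 0L, 0L))
  expect_equal(names(h), c("0", "5", "10", "15"))
  expect_equal(sum(consensusHistogram(integer(0), 5, 100)), 0L)
  expect_message(h2 <- consensusHistogram(c(2L, 999L), 5, 100), "dropped 1")
  expect_equal(sum(h2), 1L)
  ## uniform positions fill bins roughly evenly (Poisson-scale bounds)
  set.seed(5)
  pos <- sample(1:6500, 5000, replace = TRUE)
  h3 <- consensusHistogram(pos, 5, 6500)
  expect_equal(sum(h3), 5000L)
  expect_true(all(h3 <= qpois(1 - 1e-6, 5000 / 1300) + 1))
})
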