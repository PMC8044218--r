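## Pairwise TFBS co-localisation inside vs outside the repeat subfamily:
## same-TF merging, element/non-element partition, ordered-pair window
## counts with asymmetric proportions, and one-tailed pooled two-proportion
## z-tests under k^2 Bonferroni control.

#' Merge same-TF binding sites to most distal coordinates
#'
#' @param sitesByTf named list of GRanges per TF.
#' @return Named list with \code{\link{mergeIntervals}} applied per TF;
#'   labels are never merged across TFs.
#' @export
mergeTfSites <- function(sitesByTf) {
  lapply(sitesByTf, mergeIntervals)
}

#' Partition sites into element-derived and the rest
#'
#' A site is element-derived iff at least a fraction \code{f} of it
#' overlaps some single element; the outputs are an exact disjoint
#' partition of the input.
#'
#' @param sites GRanges.
#' @param elements GRanges.
#' @param f overlap fraction of the site (default 0.5).
#' @return list(elementDerived, other), both GRanges.
#' @export
splitByElements <- function(sites, elements, f = 0.5) {
  hits <- intersectFraction(sites, elements, f)
  inEl <- seq_along(sites) %in% queryHits(hits)
  list(elementDerived = sites[inEl], other = sites[!inEl])
}

#' Element co-binding counts for TF pairs
#'
#' Symmetric matrix of elements containing binding sites (under the
#' fractional-overlap rule) of both TFs; the diagonal is the per-TF
#' bound-element count. The n^0.25 transform conventionally used for
#' heatmap display is applied only by \code{\link{displayCounts}}.
#'
#' @param elements GRanges.
#' @param sitesByTf named list of GRanges per TF.
#' @param f overlap fraction (default 0.5).
#' @return An \linkS4class{ElementPairCounts}.
#' @export
elementPairCounts <- function(elements, sitesByTf, f = 0.5) {
  tfs <- names(sitesByTf)
  sets <- lapply(sitesByTf, function(s)
    unique(subjectHits(intersectFraction(s, elements, f))))
  k <- length(tfs)
  m <- matrix(0L, k, k, dimnames = list(tfs, tfs))
  for (i in seq_len(k)) for (j in seq_len(k))
    m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  new("ElementPairCounts", tfs = tfs, counts = m)
}

#' @describeIn elementPairCounts power-transformed counts for display.
#' @param x an \code{ElementPairCounts}.
#' @export
displayCounts <- function(x) x@counts^x@displayExponent

#' Ordered-pair co-localisation counts and proportions
#'
#' For each ordered TF pair (i, j), counts the TF i sites having at least
#' one TF j site within the window rule (gap strictly less than \code{w})
#' and divides by TF i's total site count, yielding asymmetric proportions.
#' Sites should be merged per TF first (\code{\link{mergeTfSites}}).
#' Self-pairs are counted against the other sites of the same TF.
#'
#' @param sitesByTf named list of merged GRanges per TF.
#' @param w co-localisation window in bp (default 500).
#' @return list(counts, totals, proportions); \code{proportions[i, j] =
#'   counts[i, j] / totals[i]}, NA when a TF has no sites.
#' @export
pairwiseColocCounts <- function(sitesByTf, w = 500) {
  tfs <- names(sitesByTf)
  k <- length(tfs)
  counts <- matrix(0L, k, k, dimnames = list(tfs, tfs))
  totals <- setNames(vapply(sitesByTf, length, 0L), tfs)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) {
      a <- sitesByTf[[i]]
      if (length(a)) {
        h <- findOverlaps(a, a, maxgap = max(w - 1L, -1L),
                          ignore.strand = TRUE)
        h <- h[queryHits(h) != subjectHits(h)]
        counts[i, j] <- length(unique(queryHits(h)))
      }
    } else {
      counts[i, j] <- sum(windowJoin(sitesByTf[[i]], sitesByTf[[j]], w))
    }
  }
  proportions <- counts / ifelse(totals == 0, NA_real_, totals)
  list(counts = counts, totals = totals, proportions = proportions)
}

#' One-tailed pooled two-proportion z-test
#'
#' Pooled-variance form: with \eqn{\hat p = (k_1 + k_2) / (n_1 + n_2)},
#' \deqn{z = \frac{k_1/n_1 - k_2/n_2}{\sqrt{\hat p (1 - \hat p)(1/n_1 + 1/n_2)}}}
#' and the one-tailed p-value \eqn{1 - \Phi(z)} tests enrichment of group
#' 1; z keeps its sign, so depletion gives z < 0 and p > 0.5. No
#' continuity correction. When the pooled proportion is degenerate (0 or
#' 1) the statistic is defined as z = 0, p = 0.5.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list(z, p).
#' @examples
#' twoProportionZTest(60, 100, 500, 1000)
#' @export
twoProportionZTest <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  pool <- (k1 + k2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) return(list(z = 0, p = 0.5))
  z <- (k1 / n1 - k2 / n2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  list(z = z, p = pnorm(z, lower.tail = FALSE))
}

.starTiers <- function(p, perTestAlpha) {
  if (is.na(p)) return("")
  if (p < 1e-5) return("***")
  if (p < 1e-4) return("**")
  if (p < perTestAlpha) return("*")
  ""
}

#' Co-localisation enrichment: element-derived vs the rest of the genome
#'
#' For every ordered pair of distinct TFs, compares the co-localisation
#' proportion among element-derived sites against non-element-derived
#' sites with the one-tailed pooled z-test (direction: more co-localisation
#' in elements). Significance is Bonferroni-controlled at
#' \code{alpha / k^2} — the denominator counts the full k x k grid
#' including the untested self-pairs, reproducing the conventional
#' 0.05 / 81 = 6.2e-4 threshold for k = 9. The diagonal reports totals
#' only.
#'
#' @param elementSitesByTf,otherSitesByTf named lists of merged GRanges per
#'   TF; the TF name sets must be identical, k >= 2.
#' @param config an \linkS4class{AnalysisConfig} (colocWindow, alpha).
#' @return A \linkS4class{ColocalisationMatrix}.
#' @export
colocEnrichmentMatrix <- function(elementSitesByTf, otherSitesByTf,
                                  config = analysisConfig()) {
  tfs <- names(elementSitesByTf)
  if (!identical(sort(tfs), sort(names(otherSitesByTf))))
    stop("the two groups must cover the same TFs")
  if (length(tfs) < 2) stop("need at least 2 TFs")
  otherSitesByTf <- otherSitesByTf[tfs]
  k <- length(tfs)
  perTest <- config@alpha / k^2
  el <- pairwiseColocCounts(elementSitesByTf, config@colocWindow)
  ot <- pairwiseColocCounts(otherSitesByTf, config@colocWindow)
  dn <- list(tfs, tfs)
  z <- p <- matrix(NA_real_, k, k, dimnames = dn)
  sig <- matrix(FALSE, k, k, dimnames = dn)
  stars <- matrix("", k, k, dimnames = dn)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    n1 <- el$totals[i]; n2 <- ot$totals[i]
    if (n1 == 0 || n2 == 0) next        # proportion undefined: left missing
    zt <- twoProportionZTest(el$counts[i, j], n1, ot$counts[i, j], n2)
    z[i, j] <- zt$z
    p[i, j] <- zt$p
    sig[i, j] <- zt$p < perTest
    stars[i, j] <- .starTiers(zt$p, perTest)
  }
  new("ColocalisationMatrix", tfs = tfs,
      totalsElement = el$totals, totalsOther = ot$totals,
      propElement = el$proportions, propOther = ot$proportions,
      z = z, p = p, significant = sig,
      alpha = config@alpha, perTestAlpha = perTest, stars = stars)
}
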