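## Element-centred TFBS meta-profiles, binding summaries and projection of
## binding sites to repeat consensus coordinates.

#' Fixed-width windows centred on elements
#'
#' Each window is exactly \code{width} bp centred on the element midpoint
#' (0-based midpoint = floor((start + end) / 2)). Windows running off a
#' chromosome edge are truncated and flagged \code{clamped}; downstream
#' averaging excludes flagged windows.
#'
#' @param elements GRanges; an element longer than \code{width} is an error.
#' @param width even window width in bp.
#' @param chromLengths optional named lengths to detect clamping at the
#'   right edge (the left edge is always detected).
#' @return GRanges of windows, same order and strand as \code{elements},
#'   with a logical \code{clamped} metadata column.
#' @examples
#' elementWindow(grFromBed("chr1", 10000, 16000), 20000)  # [3000,23000)
#' @export
elementWindow <- function(elements, width, chromLengths = NULL) {
  stopifnot(width > 0, width %% 2 == 0)
  if (any(GenomicRanges::width(elements) > width))
    stop("element longer than the window width")
  mid0 <- floor((start(elements) - 1 + end(elements)) / 2)
  half <- width / 2
  ws0 <- mid0 - half          # 0-based half-open window [ws0, ws0 + width)
  we0 <- mid0 + half
  clamped <- ws0 < 0
  if (!is.null(chromLengths)) {
    len <- chromLengths[as.character(seqnames(elements))]
    if (any(is.na(len))) stop("chromosome missing from chromLengths")
    clamped <- clamped | we0 > len
    we0 <- pmin(we0, len)
  }
  ws0 <- pmax(ws0, 0)
  out <- GRanges(seqnames(elements), IRanges(ws0 + 1, we0),
                 strand = strand(elements))
  out$clamped <- clamped
  names(out) <- names(elements)
  out
}

## counts matrix (elements x bins) of features per bin of each window,
## identical semantics to binFeatureCounts applied per window.
.windowBinCounts <- function(windows, features, binWidth) {
  nBins <- width(ranges(windows))[1] / binWidth
  stopifnot(all(width(ranges(windows)) == nBins * binWidth))
  mat <- matrix(0L, nrow = length(windows), ncol = nBins)
  if (length(features) == 0 || length(windows) == 0) return(mat)
  hits <- findOverlaps(windows, features, ignore.strand = TRUE)
  for (h in seq_along(hits)) {
    w <- queryHits(hits)[h]; s <- subjectHits(hits)[h]
    rs <- max(start(features)[s], start(windows)[w]) - start(windows)[w]
    re <- min(end(features)[s], end(windows)[w]) - start(windows)[w] + 1
    b1 <- rs %/% binWidth + 1
    b2 <- (re - 1) %/% binWidth + 1
    mat[w, b1:b2] <- mat[w, b1:b2] + 1L
  }
  mat
}

## reverse rows of minus-strand elements so bin 1 is 5'-most
.orientRows <- function(mat, strands) {
  neg <- strands == "-"
  if (any(neg)) mat[neg, ] <- mat[neg, ncol(mat):1, drop = FALSE]
  mat
}

#' TFBS meta-profile around elements
#'
#' For each element, counts binding sites per bin of the centred window,
#' normalises the bin counts to the window total so every contributing
#' element's profile sums to 1, optionally reverses minus-strand windows
#' so bin 1 is 5'-most, and averages across all elements harbouring at
#' least one site in their window (elements with an empty window, and
#' clamped windows, are excluded).
#'
#' @param elements GRanges (stranded).
#' @param sites GRanges of binding sites.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param oriented reverse minus-strand windows (default TRUE).
#' @param chromLengths optional, for clamp detection.
#' @return A \linkS4class{MetaProfile}; its values sum to 1.
#' @export
tfbsMetaProfile <- function(elements, sites, config = analysisConfig(),
                            oriented = TRUE, chromLengths = NULL) {
  win <- elementWindow(elements, config@windowWidth, chromLengths)
  keep <- !win$clamped
  win <- win[keep]
  mat <- .windowBinCounts(win, sites, config@profileBin)
  tot <- rowSums(mat)
  use <- tot > 0
  if (!any(use))
    stop("no element has a binding site in its window")
  prof <- mat[use, , drop = FALSE] / tot[use]
  if (oriented)
    prof <- .orientRows(prof, as.character(strand(win))[use])
  new("MetaProfile", values = colMeans(prof), binWidth = config@profileBin,
      nElements = sum(use), oriented = oriented, label = "TFBS")
}

#' Per-TF and per-element binding summary
#'
#' Assigns sites to elements when at least a fraction \code{f} of the site
#' overlaps the element, then counts elements bound per TF and the TF set
#' per element. Percentages are reported against the number of bound
#' elements, the conventional denominator for per-TF binding frequencies.
#'
#' @param elements GRanges with an \code{id} metadata column (falls back to
#'   indices).
#' @param sitesByTf named list (or GRangesList) of site GRanges per TF.
#' @param f overlap fraction of the site (default 0.5).
#' @return A \linkS4class{BindingSummary}.
#' @export
bindingSummary <- function(elements, sitesByTf, f = 0.5) {
  ids <- if (!is.null(elements$id)) elements$id else as.character(seq_along(elements))
  perElement <- setNames(vector("list", length(elements)), ids)
  for (i in seq_along(perElement)) perElement[[i]] <- character(0)
  perTf <- integer(0)
  for (tf in names(sitesByTf)) {
    sites <- sitesByTf[[tf]]
    hits <- intersectFraction(sites, elements, f)
    bound <- unique(subjectHits(hits))
    perTf[tf] <- length(bound)
    for (e in bound) perElement[[e]] <- c(perElement[[e]], tf)
  }
  new("BindingSummary",
      perTfElementCount = perTf, perElementTfs = perElement,
      nBoundElements = sum(lengths(perElement) > 0L),
      nElements = length(elements))
}

#' @describeIn bindingSummary per-TF percentage of bound elements.
#' @param summary a \code{BindingSummary}.
#' @export
pctOfBound <- function(summary) {
  100 * summary@perTfElementCount / max(1L, summary@nBoundElements)
}

#' Project genomic positions into repeat consensus coordinates
#'
#' The site midpoint (0-based, floor((start + end) / 2)) is expressed as a
#' distance from the element's 5' end and shifted by the element's
#' consensus start (the RepeatMasker RepStart), giving a 1-based position
#' in the subfamily consensus. For minus-strand elements the 5' end is the
#' right genomic edge. Positions are clipped at 1.
#'
#' @param sites GRanges of sites (or 1-bp positions).
#' @param elements GRanges with \code{consensusStart}, recycled or parallel
#'   to \code{sites}; each site's midpoint must lie within its element.
#' @return Integer 1-based consensus positions.
#' @examples
#' el <- grFromBed("chr1", 10000, 16000, "+", consensusStart = 1L)
#' projectToConsensus(grFromBed("chr1", 12000, 12100), el)  # 2051
#' @export
projectToConsensus <- function(sites, elements) {
  if (length(elements) == 1) elements <- rep(elements, length(sites))
  stopifnot(length(elements) == length(sites))
  m0 <- floor((start(sites) - 1 + end(sites)) / 2)
  es0 <- start(elements) - 1
  ee0 <- end(elements)
  if (any(m0 < es0 | m0 >= ee0))
    stop("site midpoint outside the element span")
  cs <- elements$consensusStart
  neg <- as.character(strand(elements)) == "-"
  pos <- ifelse(neg, cs + (ee0 - 1 - m0), cs + (m0 - es0))
  as.integer(pmax(1, pos))
}

#' Inverse consensus projection
#'
#' Maps a 1-based consensus position back to the 0-based genomic midpoint
#' on a given element; the inverse of \code{\link{projectToConsensus}}.
#'
#' @param positions integer consensus positions.
#' @param elements GRanges with \code{consensusStart}, recycled or parallel.
#' @return 0-based genomic positions.
#' @export
consensusToGenomic <- function(positions, elements) {
  if (length(elements) == 1) elements <- rep(elements, length(positions))
  cs <- elements$consensusStart
  es0 <- start(elements) - 1
  ee0 <- end(elements)
  neg <- as.character(strand(elements)) == "-"
  ifelse(neg, ee0 - 1 - (positions - cs), es0 + (positions - cs))
}

#' Histogram of consensus positions
#'
#' Fixed-width bins over [1, maxPos]; bin b (1-based) covers consensus
#' positions (b-1)*bin + 1 .. b*bin. Positions beyond \code{maxPos} are
#' dropped with a logged count.
#'
#' @param positions integer 1-based consensus positions.
#' @param bin bp per bin (default 5).
#' @param maxPos upper bound of the histogram (default 6500, the
#'   conventional plotting range for the L1PA2 consensus).
#' @return Integer counts named by 0-based bin start.
#' @export
consensusHistogram <- function(positions, bin = 5, maxPos = 6500) {
  stopifnot(bin > 0)
  nBins <- ceiling(maxPos / bin)
  drop <- positions > maxPos | positions < 1
  if (any(drop))
    message("consensusHistogram: dropped ", sum(drop),
            " position(s) outside [1, ", maxPos, "]")
  positions <- positions[!drop]
  idx <- pmin((positions - 1) %/% bin + 1, nBins)
  counts <- tabulate(idx, nbins = nBins)
  names(counts) <- (seq_len(nBins) - 1) * bin
  counts
}
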