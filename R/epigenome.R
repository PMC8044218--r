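## Binned RPKM meta-profiles of epigenetic marks around elements:
## read-midpoint bin counts, RPKM conversion, replicate averaging, input
## subtraction and bound/unbound group averaging. Alignment is upstream;
## inputs are read positions (BED) or precomputed per-bin counts.

#' Per-window per-bin read counts by read midpoint
#'
#' Each read is assigned to exactly one bin by its midpoint (reads are
#' point-like at 100 bp resolution; single-bin assignment avoids
#' double-counting, matching read-count semantics). Windows must share one
#' width divisible by \code{binWidth}.
#'
#' @param reads GRanges of read positions (intervals are reduced to their
#'   0-based midpoints).
#' @param windows GRanges, e.g. from \code{\link{elementWindow}}.
#' @param binWidth bp per bin.
#' @return Integer matrix, rows = windows, cols = bins (genomic left to
#'   right).
#' @export
binnedReadCounts <- function(reads, windows, binWidth) {
  nBins <- width(ranges(windows))[1] / binWidth
  stopifnot(all(width(ranges(windows)) == nBins * binWidth))
  mat <- matrix(0L, length(windows), nBins)
  if (length(reads) == 0) return(mat)
  mid0 <- floor((start(reads) - 1 + end(reads)) / 2)
  pts <- GRanges(seqnames(reads), IRanges(mid0 + 1, width = 1))
  hits <- findOverlaps(windows, pts, ignore.strand = TRUE)
  if (length(hits)) {
    w <- queryHits(hits)
    b <- (mid0[subjectHits(hits)] + 1 - start(windows)[w]) %/% binWidth + 1
    for (h in seq_along(w)) mat[w[h], b[h]] <- mat[w[h], b[h]] + 1L
  }
  mat
}

#' RPKM conversion of bin counts
#'
#' RPKM = count * 1e9 / (binWidth * totalMapped): reads per kilobase of
#' bin per million mapped reads.
#'
#' @param counts numeric counts (vector or matrix).
#' @param binWidth bp per bin.
#' @param totalMapped total mapped reads in the library; must be > 0.
#' @return Values on the RPKM scale.
#' @examples
#' rpkmNormalise(10, 100, 1e7)  # 10.0
#' @export
rpkmNormalise <- function(counts, binWidth, totalMapped) {
  stopifnot(binWidth > 0)
  if (totalMapped <= 0) stop("totalMapped must be > 0")
  counts * 1e9 / (binWidth * totalMapped)
}

#' Average replicate profiles element-wise
#'
#' @param tracks list of numeric matrices (or vectors) on the same grid.
#' @return Arithmetic mean with an \code{nReplicates} attribute.
#' @export
averageReplicates <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  d <- lapply(tracks, dim)
  if (length(unique(vapply(tracks, length, 0L))) != 1 ||
      length(unique(vapply(d, paste, "", collapse = "x"))) != 1)
    stop("replicate grids differ")
  out <- Reduce(`+`, tracks) / length(tracks)
  attr(out, "nReplicates") <- length(tracks)
  out
}

#' Subtract an input control track
#'
#' Normalised RPKM = mark RPKM - control RPKM; values may be negative.
#' Replicates are averaged before subtraction.
#'
#' @param mark,control numeric matrices/vectors on the same grid.
#' @return mark - control.
#' @export
subtractControl <- function(mark, control) {
  if (length(mark) != length(control) ||
      !identical(dim(mark), dim(control)))
    stop("mark and control grids differ")
  m <- mark - control
  attributes(m) <- attributes(mark)
  m
}

#' Group-averaged RPKM meta-profiles
#'
#' Averages per-element binned values within each group (e.g. TF-bound vs
#' unbound elements), reversing minus-strand rows so profiles read 5' to
#' 3' of the element. Empty groups are omitted with a warning.
#'
#' @param perElement numeric matrix, rows parallel to \code{elements}.
#' @param elements GRanges supplying strands.
#' @param groups character/factor along \code{elements} (e.g. "bound",
#'   "unbound").
#' @param binWidth bp per bin.
#' @param oriented reverse minus-strand rows (default TRUE).
#' @param label mark label carried into the profiles.
#' @return Named list of \linkS4class{MetaProfile}, one per group level.
#' @export
groupMetaProfile <- function(perElement, elements, groups, binWidth,
                             oriented = TRUE, label = "") {
  stopifnot(nrow(perElement) == length(elements),
            length(groups) == length(elements))
  if (oriented)
    perElement <- .orientRows(perElement, as.character(strand(elements)))
  out <- list()
  for (g in unique(as.character(groups))) {
    rows <- which(groups == g)
    if (!length(rows)) {
      warning("empty group: ", g)
      next
    }
    out[[g]] <- new("MetaProfile",
                    values = colMeans(perElement[rows, , drop = FALSE]),
                    binWidth = binWidth, nElements = length(rows),
                    oriented = oriented,
                    label = if (nzchar(label)) paste(label, g) else g)
  }
  out
}
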