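## Differential-transcript classification, strand-aware TSS extraction,
## element proximity profiles and the rotation-permutation + binomial
## TSS-in-element enrichment test.

#' Classify transcripts by fold change
#'
#' Strict thresholds: up iff fold change > \code{upFc}, down iff
#' < \code{downFc}, otherwise unchanged (a fold change of exactly 2 is
#' unchanged). When \code{config@applyPFilter} is TRUE, transcripts with
#' p-value >= \code{dePCut} are reclassified as unchanged, yielding the
#' filtered DE set.
#'
#' @param transcripts GRanges from \code{\link{readTranscriptTable}}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return Factor with levels up, down, unchanged.
#' @export
classifyTranscripts <- function(transcripts, config = analysisConfig()) {
  fc <- transcripts$foldChange
  stopifnot(all(fc > 0))
  cls <- ifelse(fc > config@upFc, "up",
                ifelse(fc < config@downFc, "down", "unchanged"))
  if (config@applyPFilter) {
    pv <- transcripts$pValue
    cls[!is.na(pv) & pv >= config@dePCut] <- "unchanged"
  }
  factor(cls, levels = c("up", "down", "unchanged"))
}

#' Strand-aware transcription start sites
#'
#' The TSS is the position at which the transcript begins: the leftmost
#' base for plus-strand transcripts, the rightmost for minus-strand.
#'
#' @param transcripts stranded GRanges (strand "*" is an error).
#' @return 1-bp GRanges of TSS positions carrying the transcript metadata.
#' @examples
#' transcriptTss(grFromBed("chr1", 100, 500, "-"))  # 0-based position 499
#' @export
transcriptTss <- function(transcripts) {
  st <- as.character(strand(transcripts))
  if (any(!st %in% c("+", "-")))
    stop("TSS extraction needs stranded transcripts")
  pos <- ifelse(st == "+", start(transcripts), end(transcripts))
  out <- GRanges(seqnames(transcripts), IRanges(pos, width = 1), strand = st)
  mcols(out) <- mcols(transcripts)
  out
}

#' Count TSSs falling inside elements
#'
#' A TSS (a point) overlaps an element iff its position lies within the
#' half-open element span; no fraction rule applies. A TSS at the element
#' start overlaps; one at the exclusive end does not.
#'
#' @param tss 1-bp GRanges of TSS positions.
#' @param elements GRanges.
#' @return list(count = TSSs inside any element, hits = Hits tss ->
#'   elements).
#' @export
tssElementOverlap <- function(tss, elements) {
  hits <- findOverlaps(tss, elements, ignore.strand = TRUE)
  list(count = length(unique(queryHits(hits))), hits = hits)
}

#' Proximity profile of elements to class TSSs
#'
#' For each distance d on the ladder (1 kb to 20 kb in 1 kb steps by
#' default), the fraction of each element group having at least one TSS of
#' each class within d bp (window-join semantics); non-decreasing in d.
#'
#' @param elementsByGroup named list of GRanges (e.g. bound/unbound).
#' @param tssByClass named list of 1-bp TSS GRanges per class.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame(distance, group, class, proportion).
#' @export
proximityProfile <- function(elementsByGroup, tssByClass,
                             config = analysisConfig()) {
  dists <- seq(config@proximityStep, config@proximityMax,
               by = config@proximityStep)
  out <- list()
  for (g in names(elementsByGroup)) {
    els <- elementsByGroup[[g]]
    if (length(els) == 0) {
      warning("empty element group: ", g)
      next
    }
    for (cl in names(tssByClass)) {
      prop <- vapply(dists, function(d)
        mean(windowJoin(els, tssByClass[[cl]], d)), 0)
      out[[length(out) + 1L]] <- data.frame(
        distance = dists, group = g, class = cl, proportion = prop)
    }
  }
  do.call(rbind, out)
}

#' Expected TSS-in-element probability under a rotation null
#'
#' Circularly rotates TSS positions along each chromosome (elements stay
#' fixed): per permutation one uniform offset is drawn per chromosome and
#' every TSS moves to (position + offset) mod L, preserving per-chromosome
#' TSS counts and all pairwise circular distances. The expected
#' probability is the mean overlap count across permutations divided by
#' the number of TSSs. With \code{perChromosome = FALSE} a single
#' genome-wide offset is applied to all chromosomes instead.
#'
#' @param tss 1-bp GRanges of TSS positions.
#' @param elements GRanges.
#' @param chromLengths named chromosome lengths covering every chromosome
#'   of \code{tss} and \code{elements}.
#' @param nPerm number of rotations (>= 1).
#' @param seed integer RNG seed; results are deterministic given it.
#' @param perChromosome independent offsets per chromosome (default TRUE).
#' @return Scalar expected probability in [0, 1].
#' @export
rotationExpectedProbability <- function(tss, elements, chromLengths,
                                        nPerm = 10000, seed = 1L,
                                        perChromosome = TRUE) {
  stopifnot(nPerm >= 1)
  chroms <- unique(c(as.character(seqnames(tss)),
                     as.character(seqnames(elements))))
  if (any(!chroms %in% names(chromLengths)))
    stop("chromosome missing from chromLengths: ",
         paste(setdiff(chroms, names(chromLengths)), collapse = ", "))
  nTss <- length(tss)
  if (nTss == 0) stop("no TSSs supplied")
  set.seed(seed)
  tssChrom <- as.character(seqnames(tss))
  totalHits <- numeric(nPerm)
  sharedOffsets <- if (!perChromosome)
    floor(runif(nPerm) * max(chromLengths))
  for (chrom in unique(tssChrom)) {
    L <- chromLengths[[chrom]]
    pos0 <- start(tss)[tssChrom == chrom] - 1          # 0-based positions
    el <- elements[as.character(seqnames(elements)) == chrom]
    if (length(el) == 0) next
    ## membership lookup over merged element spans: a 0-based position p is
    ## inside iff findInterval over interleaved boundaries lands on an odd
    ## index
    sp <- reduce(ranges(el))
    bounds <- as.numeric(rbind(start(sp) - 1, end(sp)))
    offsets <- if (perChromosome) floor(runif(nPerm) * L)
               else sharedOffsets %% L
    shifted <- (outer(pos0, offsets, `+`)) %% L        # nTss x nPerm
    inside <- findInterval(shifted, bounds) %% 2 == 1
    totalHits <- totalHits + colSums(matrix(inside, ncol = nPerm))
  }
  mean(totalHits) / nTss
}

#' Binomial enrichment/depletion test for TSS-in-element overlap
#'
#' Exact one-sided binomial tail in the observed direction:
#' enriched (observed > expectedP * nTss) tests P(X >= observed), depleted
#' tests P(X <= observed), X ~ Binomial(nTss, expectedP).
#'
#' @param observed TSSs overlapping elements with no rotation applied.
#' @param nTss total TSSs of the class.
#' @param expectedP null per-TSS overlap probability, e.g. from
#'   \code{\link{rotationExpectedProbability}}.
#' @param nPermutations,seed bookkeeping recorded in the result.
#' @return An \linkS4class{EnrichmentResult}.
#' @examples
#' binomialEnrichment(5, 10, 0.1)  # enriched tail ~ 1.6e-3
#' @export
binomialEnrichment <- function(observed, nTss, expectedP,
                               nPermutations = NA_real_, seed = NA_real_) {
  stopifnot(observed >= 0, observed <= nTss,
            expectedP >= 0, expectedP <= 1)
  enriched <- observed > expectedP * nTss
  p <- if (enriched)
    pbinom(observed - 1, nTss, expectedP, lower.tail = FALSE)
  else
    pbinom(observed, nTss, expectedP)
  if (expectedP %in% c(0, 1))
    message("binomialEnrichment: degenerate expected probability ",
            expectedP)
  new("EnrichmentResult", observed = observed, nTss = nTss,
      expectedP = expectedP, nPermutations = nPermutations,
      pValue = p, direction = if (enriched) "enriched" else "depleted",
      seed = seed)
}

#' Full TSS-in-element enrichment test
#'
#' Convenience wrapper: counts observed overlaps, estimates the rotation
#' null and applies the binomial tail.
#'
#' @inheritParams rotationExpectedProbability
#' @return An \linkS4class{EnrichmentResult}.
#' @export
tssEnrichmentTest <- function(tss, elements, chromLengths,
                              nPerm = 10000, seed = 1L,
                              perChromosome = TRUE) {
  obs <- tssElementOverlap(tss, elements)$count
  ep <- rotationExpectedProbability(tss, elements, chromLengths,
                                    nPerm = nPerm, seed = seed,
                                    perChromosome = perChromosome)
  binomialEnrichment(obs, length(tss), ep,
                     nPermutations = nPerm, seed = seed)
}

#' Associate novel transcripts with known transcripts by shared exons
#'
#' A novel transcript is associated with a known transcript iff at least
#' one exon of each overlap by >= 1 bp on the same chromosome and strand
#' (intron-only or opposite-strand overlap does not associate).
#'
#' @param novel,known GRanges with an \code{exons} GRangesList column and
#'   \code{transcriptId}.
#' @return data.frame(novelId, knownId), one row per association.
#' @export
associateWithKnown <- function(novel, known) {
  out <- data.frame(novelId = character(), knownId = character())
  if (length(novel) == 0 || length(known) == 0) return(out)
  for (i in seq_along(novel)) {
    nEx <- novel$exons[[i]]
    for (j in seq_along(known)) {
      kEx <- known$exons[[j]]
      if (as.character(strand(novel))[i] != as.character(strand(known))[j])
        next
      if (any(overlapsAny(nEx, kEx, ignore.strand = TRUE)))
        out <- rbind(out, data.frame(novelId = novel$transcriptId[i],
                                     knownId = known$transcriptId[j]))
    }
  }
  out
}
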