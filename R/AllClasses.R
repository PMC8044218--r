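#' Analysis configuration
#'
#' Holds every tunable constant of the pipeline in one auditable object.
#' Defaults reproduce the canonical settings: a 20 kb window in 100 bp bins
#' centred on each element, element assignment when at least half of a
#' binding site overlaps the element, a 500 bp co-localisation window,
#' fold-change cut-offs of 2 (up) and 0.5 (down), motif significance at
#' p < 1e-4 with 5 bp consensus histogram bins, a 1--20 kb proximity ladder
#' in 1 kb steps, and 10,000 rotation permutations at alpha = 0.05.
#'
#' @slot windowWidth bp width of the element-centred window.
#' @slot profileBin bp per profile bin; must divide \code{windowWidth}.
#' @slot overlapFraction minimum fraction of a binding site that must
#'   overlap an element for assignment (0 < f <= 1).
#' @slot colocWindow bp window for calling two sites co-localised.
#' @slot upFc,downFc strict fold-change thresholds for up/down classes.
#' @slot dePCut optional p-value cut-off for the filtered DE set.
#' @slot applyPFilter whether \code{dePCut} is applied.
#' @slot motifP motif hit p-value threshold.
#' @slot motifBin bp per consensus histogram bin.
#' @slot proximityMax,proximityStep bp ladder for the proximity profile;
#'   step must divide max.
#' @slot nPermutations rotation permutations for the enrichment null.
#' @slot alpha familywise significance level; per-test level is
#'   \code{alpha / k^2} for k TFs.
#' @slot rngSeed integer seed controlling all randomness.
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  slots = c(
    windowWidth = "numeric", profileBin = "numeric",
    overlapFraction = "numeric", colocWindow = "numeric",
    upFc = "numeric", downFc = "numeric",
    dePCut = "numeric", applyPFilter = "logical",
    motifP = "numeric", motifBin = "numeric",
    proximityMax = "numeric", proximityStep = "numeric",
    nPermutations = "numeric", alpha = "numeric", rngSeed = "numeric"),
  prototype = list(
    windowWidth = 20000, profileBin = 100,
    overlapFraction = 0.5, colocWindow = 500,
    upFc = 2, downFc = 0.5,
    dePCut = 0.05, applyPFilter = FALSE,
    motifP = 1e-4, motifBin = 5,
    proximityMax = 20000, proximityStep = 1000,
    nPermutations = 10000, alpha = 0.05, rngSeed = 1L))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  pos <- c(windowWidth = object@windowWidth, profileBin = object@profileBin,
           overlapFraction = object@overlapFraction,
           upFc = object@upFc, downFc = object@downFc,
           motifP = object@motifP, motifBin = object@motifBin,
           proximityMax = object@proximityMax,
           proximityStep = object@proximityStep,
           nPermutations = object@nPermutations, alpha = object@alpha)
  if (any(pos <= 0))
    msg <- c(msg, paste("non-positive:", paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@colocWindow < 0) msg <- c(msg, "colocWindow must be >= 0")
  if (object@windowWidth %% object@profileBin != 0)
    msg <- c(msg, "profileBin must divide windowWidth")
  if (object@proximityMax %% object@proximityStep != 0)
    msg <- c(msg, "proximityStep must divide proximityMax")
  if (object@overlapFraction > 1) msg <- c(msg, "overlapFraction must be <= 1")
  if (!(object@downFc < 1 && 1 < object@upFc))
    msg <- c(msg, "need downFc < 1 < upFc")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalysisConfig
#'
#' @param ... named slot overrides, e.g. \code{analysisConfig(colocWindow = 1000)}.
#' @return A validated \linkS4class{AnalysisConfig}.
#' @examples
#' cfg <- analysisConfig(nPermutations = 1000, rngSeed = 7)
#' @export
analysisConfig <- function(...) new("AnalysisConfig", ...)

#' Element-centred meta-profile
#'
#' Per-bin values over a fixed-width window centred on repeat elements:
#' normalised TFBS counts (each contributing element's profile sums to 1) or
#' RPKM coverage. When \code{oriented} is TRUE, bin 1 is the 5'-most bin of
#' the element, i.e. minus-strand windows were reversed before averaging.
#'
#' @slot values numeric per-bin values, length \code{nBins}.
#' @slot binWidth bp per bin.
#' @slot nElements number of elements averaged over.
#' @slot oriented logical; profiles read 5' to 3' of the element.
#' @slot label free-text label (TF, mark or group).
#' @exportClass MetaProfile
setClass("MetaProfile",
  slots = c(values = "numeric", binWidth = "numeric", nElements = "numeric",
            oriented = "logical", label = "character"),
  prototype = list(oriented = TRUE, label = ""))

setValidity("MetaProfile", function(object) {
  if (length(object@values) == 0) return("values must be non-empty")
  if (object@nElements < 0) return("nElements must be >= 0")
  TRUE
})

#' @describeIn MetaProfile per-bin values.
#' @param object,x a \code{MetaProfile}.
#' @export
profileValues <- function(x) x@values

#' @export
setMethod("show", "MetaProfile", function(object) {
  cat("MetaProfile", if (nzchar(object@label)) paste0("[", object@label, "]"),
      ":", length(object@values), "bins x", object@binWidth,
      "bp, averaged over", object@nElements, "elements,",
      if (object@oriented) "oriented 5'->3'" else "genomic orientation", "\n")
})

#' Per-TF / per-element binding summary
#'
#' @slot perTfElementCount named integer: elements bound per TF.
#' @slot perElementTfs named list: TF set per element id.
#' @slot nBoundElements elements with at least one assigned site.
#' @slot nElements total elements considered.
#' @exportClass BindingSummary
setClass("BindingSummary",
  slots = c(perTfElementCount = "integer", perElementTfs = "list",
            nBoundElements = "integer", nElements = "integer"))

setValidity("BindingSummary", function(object) {
  nb <- sum(lengths(object@perElementTfs) > 0)
  if (nb != object@nBoundElements)
    return("nBoundElements must equal the number of non-empty element TF sets")
  TRUE
})

#' @export
setMethod("show", "BindingSummary", function(object) {
  cat("BindingSummary:", object@nBoundElements, "of", object@nElements,
      sprintf("elements bound (%.1f%%) by %d TFs\n",
              100 * object@nBoundElements / max(1, object@nElements),
              length(object@perTfElementCount)))
})

#' @describeIn BindingSummary number of elements with >= 1 assigned site.
#' @export
nBoundElements <- function(x) x@nBoundElements

#' Element co-binding pair counts
#'
#' Symmetric k x k matrix of elements containing binding of both TFs; the
#' diagonal holds per-TF bound-element counts. \code{displayExponent}
#' (default 0.25) is the power transform applied only when exporting for
#' heatmap display.
#'
#' @slot tfs ordered TF labels.
#' @slot counts symmetric integer matrix.
#' @slot displayExponent exponent for display transform.
#' @exportClass ElementPairCounts
setClass("ElementPairCounts",
  slots = c(tfs = "character", counts = "matrix", displayExponent = "numeric"),
  prototype = list(displayExponent = 0.25))

setValidity("ElementPairCounts", function(object) {
  if (!isTRUE(all.equal(object@counts, t(object@counts))))
    return("counts must be symmetric")
  TRUE
})

#' Pairwise co-localisation enrichment matrix
#'
#' Ordered-pair statistics: cell (i, j) describes sites of row TF i having a
#' column TF j site within the co-localisation window, contrasted between
#' element-derived and non-element-derived site sets with a one-tailed
#' pooled two-proportion z-test. Significance is controlled at
#' \code{alpha / k^2} (Bonferroni over the k x k grid, self-pairs untested
#' but kept in the denominator). Star tiers follow the conventional
#' annotation: * below the Bonferroni threshold, ** below 1e-4, *** below
#' 1e-5.
#'
#' @slot tfs ordered TF labels (length k).
#' @slot counts,proportions,z,p,significant k x k matrices (row = anchor TF).
#' @slot totalsElement,totalsOther named per-TF merged site totals.
#' @slot propElement,propOther k x k proportion matrices per group.
#' @slot alpha familywise level; @slot perTestAlpha alpha / k^2.
#' @slot stars character matrix of significance tiers.
#' @exportClass ColocalisationMatrix
setClass("ColocalisationMatrix",
  slots = c(tfs = "character",
            totalsElement = "numeric", totalsOther = "numeric",
            propElement = "matrix", propOther = "matrix",
            z = "matrix", p = "matrix", significant = "matrix",
            alpha = "numeric", perTestAlpha = "numeric", stars = "matrix"))

setValidity("ColocalisationMatrix", function(object) {
  k <- length(object@tfs)
  for (nm in c("propElement", "propOther", "z", "p", "significant", "stars")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(k, k))) return(paste(nm, "must be k x k"))
  }
  pe <- object@propElement
  if (any(pe < -1e-12 | pe > 1 + 1e-12, na.rm = TRUE))
    return("proportions must lie in [0, 1]")
  sig <- object@significant & !is.na(object@p)
  if (any(object@p[sig] >= object@perTestAlpha))
    return("significant cells must have p < perTestAlpha")
  TRUE
})

#' @export
setMethod("show", "ColocalisationMatrix", function(object) {
  k <- length(object@tfs)
  cat("ColocalisationMatrix:", k, "TFs, per-test alpha =",
      format(object@perTestAlpha, digits = 3), "\n")
  nsig <- sum(object@significant, na.rm = TRUE)
  cat(" ", nsig, "of", k * k - k, "ordered pairs significant\n")
})

#' @describeIn ColocalisationMatrix signed z-score matrix.
#' @param x a \code{ColocalisationMatrix}.
#' @export
colocZ <- function(x) x@z

#' @describeIn ColocalisationMatrix one-tailed p-value matrix.
#' @export
colocP <- function(x) x@p

#' TSS-in-element enrichment result
#'
#' @slot observed TSSs overlapping elements (no rotation applied).
#' @slot nTss total TSSs of the class tested.
#' @slot expectedP rotation-permutation estimate of the per-TSS overlap
#'   probability under the null.
#' @slot nPermutations rotations used.
#' @slot pValue one-sided binomial tail in the observed direction.
#' @slot direction "enriched" iff observed > expectedP * nTss, else "depleted".
#' @slot seed RNG seed used for the rotations.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  slots = c(observed = "numeric", nTss = "numeric", expectedP = "numeric",
            nPermutations = "numeric", pValue = "numeric",
            direction = "character", seed = "numeric"))

setValidity("EnrichmentResult", function(object) {
  if (object@expectedP < 0 || object@expectedP > 1)
    return("expectedP must lie in [0, 1]")
  if (object@observed > object@nTss) return("observed must be <= nTss")
  want <- if (object@observed > object@expectedP * object@nTss)
    "enriched" else "depleted"
  if (object@direction != want)
    return("direction inconsistent with observed vs expected mean")
  TRUE
})

#' @export
setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult: %d / %d TSSs in elements; expected_p = %.4g (%d permutations)\n  %s, binomial p = %.3g\n",
    object@observed, object@nTss, object@expectedP, object@nPermutations,
    object@direction, object@pValue))
})

#' Position weight matrix with log-odds scoring
#'
#' Built from JASPAR-style count matrices: probabilities are
#' \code{(counts + pseudocount) / column total}, log-odds are base-2 against
#' the background.
#'
#' @slot id matrix identifier (e.g. a JASPAR accession).
#' @slot counts,probs,logOdds 4 x width matrices, rows A, C, G, T.
#' @slot background length-4 background probabilities.
#' @slot pseudocount per-cell pseudocount used.
#' @exportClass PWMatrix
setClass("PWMatrix",
  slots = c(id = "character", counts = "matrix", probs = "matrix",
            logOdds = "matrix", background = "numeric",
            pseudocount = "numeric"))

setValidity("PWMatrix", function(object) {
  if (nrow(object@probs) != 4) return("probs must have 4 rows (A,C,G,T)")
  if (any(abs(colSums(object@probs) - 1) > 1e-6))
    return("probability columns must sum to 1")
  if (abs(sum(object@background) - 1) > 1e-6)
    return("background must sum to 1")
  TRUE
})

#' @describeIn PWMatrix motif width in positions.
#' @param x a \code{PWMatrix}.
#' @export
pwmWidth <- function(x) ncol(x@probs)

#' @export
setMethod("show", "PWMatrix", function(object) {
  cat("PWMatrix", object@id, ":", ncol(object@probs), "positions,",
      "pseudocount", object@pseudocount, "\n")
})

#' Exact PWM score distribution
#'
#' Distribution of the discretised log-odds score of a random background
#' word, computed by dynamic-programming convolution over positions.
#' \code{tail[i] = P(score >= scores[i])}.
#'
#' @slot scores attainable discretised scores, increasing.
#' @slot probs probabilities per score.
#' @slot tail upper-tail probabilities Q aligned with \code{scores}.
#' @slot granularity log-odds discretisation step.
#' @exportClass ScoreDistribution
setClass("ScoreDistribution",
  slots = c(scores = "numeric", probs = "numeric", tail = "numeric",
            granularity = "numeric"))

setValidity("ScoreDistribution", function(object) {
  if (length(object@scores) != length(object@probs)) return("length mismatch")
  if (abs(sum(object@probs) - 1) > 1e-9) return("probs must sum to 1")
  if (is.unsorted(object@scores)) return("scores must be increasing")
  if (any(diff(object@tail) > 1e-12)) return("tail must be non-increasing")
  TRUE
})

#' Synthetic fixture specification
#'
#' Defines the toy-genome study conditions for the closed-loop tests: three
#' 1 Mb chromosomes carrying 40 non-overlapping full-length 6 kb elements
#' with a 900 bp 5' regulatory subregion (mirroring the ~900 bp LINE-1
#' 5' UTR), four TFs with Poisson background sites at 100 sites/Mb and a
#' ten-fold 5'-subregion enrichment, optional pairwise element-restricted
#' coupling, transcripts with a planted fraction of element-derived TSSs,
#' and coverage reads with planted active-mark signal on bound elements.
#'
#' @slot chromLengths named bp lengths.
#' @slot nElements,elementLength,fivePrimeLen element geometry.
#' @slot tfNames TF labels.
#' @slot backgroundRate background sites per Mb per TF.
#' @slot fivePrimeEnrichment density multiplier inside 5' subregions.
#' @slot tfbsWidth bp width of simulated sites.
#' @slot coupling data.frame(tfA, tfB, prob): element-internal tfB sites
#'   are relocated to within \code{couplingDistance} of element-internal
#'   tfA sites with this probability, planting pairwise co-localisation
#'   while preserving each TF's marginal site density.
#' @slot couplingDistance bp.
#' @slot nTranscripts named counts per class (up, down, unchanged).
#' @slot tssInElementFraction named planted fractions per class.
#' @slot coverageReadsPerMb background read density per track.
#' @slot coverageSignalFactor multiplier for reads in bound-element
#'   5' subregions of signal tracks.
#' @slot motifOffset 1-based consensus offset where motif words are planted.
#' @slot rngSeed integer seed.
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  slots = c(chromLengths = "numeric", nElements = "numeric",
            elementLength = "numeric", fivePrimeLen = "numeric",
            tfNames = "character", backgroundRate = "numeric",
            fivePrimeEnrichment = "numeric", tfbsWidth = "numeric",
            coupling = "data.frame", couplingDistance = "numeric",
            nTranscripts = "numeric", tssInElementFraction = "numeric",
            coverageReadsPerMb = "numeric", coverageSignalFactor = "numeric",
            motifOffset = "numeric", rngSeed = "numeric"),
  prototype = list(
    chromLengths = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
    nElements = 40, elementLength = 6000, fivePrimeLen = 900,
    tfNames = c("ESR1", "FOXA1", "MYC", "E2F1"),
    backgroundRate = 100, fivePrimeEnrichment = 10, tfbsWidth = 200,
    coupling = data.frame(tfA = character(), tfB = character(),
                          prob = numeric()),
    couplingDistance = 100,
    nTranscripts = c(up = 200, down = 200, unchanged = 400),
    tssInElementFraction = c(up = 0.30, down = 0.005, unchanged = 0.02),
    coverageReadsPerMb = 2000, coverageSignalFactor = 20,
    motifOffset = 201, rngSeed = 1L))

setValidity("FixtureSpec", function(object) {
  msg <- character()
  if (any(object@chromLengths <= 0)) msg <- c(msg, "chromLengths must be > 0")
  if (object@elementLength >= min(object@chromLengths))
    msg <- c(msg, "elementLength must be < min chrom length")
  if (object@fivePrimeLen > object@elementLength)
    msg <- c(msg, "fivePrimeLen must be <= elementLength")
  if (any(object@backgroundRate < 0, object@fivePrimeEnrichment < 0))
    msg <- c(msg, "rates must be >= 0")
  if (nrow(object@coupling) &&
      (any(object@coupling$prob < 0 | object@coupling$prob > 1)))
    msg <- c(msg, "coupling probabilities must lie in [0, 1]")
  if (any(object@tssInElementFraction < 0 | object@tssInElementFraction > 1))
    msg <- c(msg, "tssInElementFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a FixtureSpec
#'
#' @param ... named slot overrides.
#' @return A validated \linkS4class{FixtureSpec}.
#' @examples
#' spec <- fixtureSpec(rngSeed = 42, nElements = 10)
#' @export
fixtureSpec <- function(...) new("FixtureSpec", ...)
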