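## PWM scanning of element sequences on the given strand with exact
## p-value calibration by dynamic-programming convolution of the
## discretised log-odds score distribution, plus consensus-position
## histograms and logo count-matrix export.

.BASES <- c("A", "C", "G", "T")

#' Build a PWM from a count matrix
#'
#' Probabilities are (counts + pseudocount) / column total; log-odds are
#' log2(prob / background). Any zero-probability cell with a zero
#' pseudocount is an error (it would give an infinite log-odds and break
#' exact calibration), so matrices with zero cells need a positive
#' pseudocount.
#'
#' @param counts 4 x width non-negative matrix, rows A, C, G, T (e.g. from
#'   \code{\link{readJasparPfm}}).
#' @param pseudocount per-cell pseudocount (default 0.1).
#' @param background length-4 background probabilities (default uniform).
#' @param id matrix identifier; defaults to the \code{id} attribute of
#'   \code{counts}.
#' @return A \linkS4class{PWMatrix}.
#' @export
loadPwm <- function(counts, pseudocount = 0.1,
                    background = rep(0.25, 4),
                    id = attr(counts, "id")) {
  if (is.null(id)) id <- "PWM"
  stopifnot(nrow(counts) == 4, ncol(counts) >= 1)
  if (any(counts < 0)) stop("negative counts")
  if (any(colSums(counts) == 0) && pseudocount == 0)
    stop("zero column total with zero pseudocount")
  adj <- counts + pseudocount
  probs <- sweep(adj, 2, colSums(adj), "/")
  if (any(probs == 0))
    stop("zero-probability cell with zero pseudocount")
  background <- background / sum(background)
  logOdds <- log2(probs / background)
  dimnames(probs) <- dimnames(logOdds) <- list(.BASES, NULL)
  cm <- as.matrix(counts)
  attr(cm, "id") <- NULL
  rownames(cm) <- .BASES
  new("PWMatrix", id = id, counts = cm, probs = probs,
      logOdds = logOdds, background = background,
      pseudocount = pseudocount)
}

## discretised integer log-odds, shared by the DP and the scanner so hit
## p-values are exactly calibrated against the tail function
.intScores <- function(pwm, granularity) round(pwm@logOdds / granularity)

#' Exact score distribution of a random background word
#'
#' Discretises the log-odds to \code{granularity} units and convolves the
#' per-position score distributions under the background model across
#' positions, giving the exact distribution of the score of a random
#' background word of the motif's width and the upper-tail function
#' Q(s) = P(score >= s). The discretisation error on any word score is at
#' most width x granularity / 2 log-odds units.
#'
#' @param pwm a \linkS4class{PWMatrix}.
#' @param granularity log-odds discretisation step (default 1e-3).
#' @return A \linkS4class{ScoreDistribution}.
#' @export
scoreDistribution <- function(pwm, granularity = 1e-3) {
  ints <- .intScores(pwm, granularity)
  bg <- pwm@background
  probs <- 1
  offset <- 0
  for (j in seq_len(ncol(ints))) {
    col <- ints[, j]
    lo <- min(col)
    new <- numeric(length(probs) + max(col) - lo)
    for (b in 1:4) {
      sh <- col[b] - lo
      idx <- seq_along(probs) + sh
      new[idx] <- new[idx] + probs * bg[b]
    }
    probs <- new
    offset <- offset + lo
  }
  keep <- probs > 0
  scores <- (offset + which(keep) - 1) * granularity
  probs <- probs[keep]
  tail <- rev(cumsum(rev(probs)))
  new("ScoreDistribution", scores = scores, probs = probs,
      tail = pmin(tail, 1), granularity = granularity)
}

#' Upper-tail probability of a score
#'
#' @param dist a \linkS4class{ScoreDistribution}.
#' @param score score(s) on the discretised scale.
#' @return Q(score) = P(random background word scores >= score).
#' @export
scoreTailProbability <- function(dist, score) {
  idx <- findInterval(score - 1e-12, dist@scores) + 1L
  out <- ifelse(idx > length(dist@scores), 0, dist@tail[pmin(idx, length(dist@scores))])
  as.numeric(out)
}

#' Score cutoff for a p-value threshold
#'
#' The smallest attainable discretised score s with Q(s) <= p; hits
#' require score >= s. If even the maximum score has Q > p (p below the
#' smallest attainable tail), the cutoff is set just above the maximum so
#' no hit can pass, with a message.
#'
#' @param dist a \linkS4class{ScoreDistribution}.
#' @param p target p-value, 0 < p <= 1 (p = 1 admits the minimum score).
#' @return Scalar score cutoff.
#' @export
thresholdForPvalue <- function(dist, p) {
  stopifnot(p > 0, p <= 1)
  ok <- dist@tail <= p
  if (!any(ok)) {
    message("thresholdForPvalue: p = ", p,
            " below the smallest attainable tail; no hit can pass")
    return(max(dist@scores) + dist@granularity)
  }
  dist@scores[which(ok)[1]]
}

#' Scan sequences with a PWM on the given strand
#'
#' Scores every window of each sequence with the discretised log-odds
#' (same discretisation as \code{\link{scoreDistribution}}, so hit
#' p-values are exactly the tail probabilities) and reports windows with
#' score >= cutoff. Only the provided strand is scanned — no
#' reverse-complement — matching strand-aware extracted repeat sequences.
#' Windows containing N are skipped; sequences shorter than the motif give
#' no hits.
#'
#' @param pwm a \linkS4class{PWMatrix}.
#' @param sequences named character vector or
#'   \link[Biostrings]{DNAStringSet} over A, C, G, T, N.
#' @param cutoff score cutoff from \code{\link{thresholdForPvalue}}.
#' @param dist optional \linkS4class{ScoreDistribution} used to attach
#'   p-values (recomputed if NULL).
#' @param granularity log-odds discretisation step (default 1e-3).
#' @return data.frame(seqId, offset0, score, pValue, match): \code{offset0}
#'   is the 0-based window start; plus per-sequence summary attributes
#'   \code{hitsPerSequence} and \code{nSequencesWithHit}.
#' @export
scanSequences <- function(pwm, sequences, cutoff, dist = NULL,
                          granularity = 1e-3) {
  if (is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  if (is.null(dist)) dist <- scoreDistribution(pwm, granularity)
  ints <- .intScores(pwm, dist@granularity)
  w <- ncol(ints)
  res <- list()
  perSeq <- setNames(integer(length(sequences)), names(sequences))
  for (sid in names(sequences)) {
    chars <- strsplit(toupper(sequences[[sid]]), "")[[1]]
    L <- length(chars)
    if (L < w) next
    code <- match(chars, .BASES)              # NA for N or other letters
    nStart <- L - w + 1
    scores <- numeric(nStart)
    valid <- rep(TRUE, nStart)
    for (j in seq_len(w)) {
      cj <- code[j:(j + nStart - 1)]
      bad <- is.na(cj)
      valid <- valid & !bad
      cj[bad] <- 1L
      scores <- scores + ints[cbind(cj, j)]
    }
    scores <- scores * dist@granularity
    pass <- which(valid & scores >= cutoff - 1e-12)
    perSeq[sid] <- length(pass)
    if (length(pass))
      res[[sid]] <- data.frame(
        seqId = sid, offset0 = pass - 1L, score = scores[pass],
        pValue = scoreTailProbability(dist, scores[pass]),
        match = vapply(pass, function(s)
          paste(chars[s:(s + w - 1)], collapse = ""), ""),
        stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(seqId = character(), offset0 = integer(),
               score = numeric(), pValue = numeric(), match = character())
  rownames(out) <- NULL
  attr(out, "hitsPerSequence") <- perSeq
  attr(out, "nSequencesWithHit") <- sum(perSeq > 0)
  out
}

#' Project motif hits to consensus coordinates
#'
#' Converts hit offsets within strand-extracted element sequences to
#' 1-based consensus positions (offset within the sequence is a distance
#' from the element 5' end, shifted by the element's consensus start),
#' using the hit midpoint, and bins them into the standard 5 bp consensus
#' histogram. Per-bin logo count matrices are built from the matched
#' subsequences of each requested peak bin.
#'
#' @param hits data.frame from \code{\link{scanSequences}} whose
#'   \code{seqId}s name elements.
#' @param elements GRanges with \code{id} and \code{consensusStart}.
#' @param motifWidth motif width in bp.
#' @param bin histogram bin width (default 5).
#' @param maxPos consensus plotting bound (default 6500).
#' @param peakBins 0-based starts of bins for which to return logo counts;
#'   defaults to the highest-count bin.
#' @return list(positions, histogram, logoCounts): \code{logoCounts} is a
#'   named list of 4 x width matrices whose column sums equal the number
#'   of contributing hits.
#' @export
hitsToConsensus <- function(hits, elements, motifWidth, bin = 5,
                            maxPos = 6500, peakBins = NULL) {
  ids <- if (!is.null(elements$id)) elements$id else
    as.character(seq_along(elements))
  idx <- match(hits$seqId, ids)
  if (any(is.na(idx))) stop("hit seqId not found among element ids")
  cs <- elements$consensusStart[idx]
  mid <- hits$offset0 + floor(motifWidth / 2)    # 0-based within sequence
  positions <- as.integer(pmax(1, cs + mid))
  histogram <- consensusHistogram(positions, bin = bin, maxPos = maxPos)
  binStart <- (positions - 1) %/% bin * bin
  if (is.null(peakBins) && length(positions))
    peakBins <- as.numeric(names(histogram)[which.max(histogram)])
  logoCounts <- list()
  for (pb in peakBins) {
    sel <- which(binStart == pb)
    if (!length(sel)) next
    m <- matrix(0L, 4, motifWidth, dimnames = list(.BASES, NULL))
    for (s in sel) {
      chars <- strsplit(hits$match[s], "")[[1]]
      for (j in seq_len(motifWidth))
        m[chars[j], j] <- m[chars[j], j] + 1L
    }
    logoCounts[[as.character(pb)]] <- m
  }
  list(positions = positions, histogram = histogram,
       logoCounts = logoCounts)
}
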