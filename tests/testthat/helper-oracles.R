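## Brute-force per-base / per-pair oracles, written directly from the
## definitions on 0-based half-open data.frames, independent of the
## GRanges-backed implementation they pin down.

randIv <- function(n, maxc = 1000, chroms = c("cA", "cB"), maxLen = 60) {
  s <- sample(0:(maxc - maxLen - 1), n, replace = TRUE)
  len <- sample(seq_len(maxLen), n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + len, stringsAsFactors = FALSE)
}

dfToGr <- function(df, strand = ".") grFromBed(df$chrom, df$start, df$end, strand)

## shared bases of two 0-based half-open intervals on the same chrom
.ovBp <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

oracleIntersectPairs <- function(q, t, f) {
  pairs <- NULL
  for (i in seq_len(nrow(q))) for (j in seq_len(nrow(t))) {
    if (q$chrom[i] != t$chrom[j]) next
    ov <- .ovBp(q$start[i], q$end[i], t$start[j], t$end[j])
    if (ov >= f * (q$end[i] - q$start[i]))
      pairs <- rbind(pairs, c(i, j))
  }
  if (is.null(pairs)) matrix(integer(), ncol = 2) else
    pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

oracleWindowJoin <- function(a, b, w) {
  vapply(seq_len(nrow(a)), function(i) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- .ovBp(a$start[i], a$end[i], b$start[j], b$end[j])
      gap <- max(b$start[j] - a$end[i], a$start[i] - b$end[j], 0)
      if (ov > 0 || gap < w) return(TRUE)
    }
    FALSE
  }, TRUE)
}

## set of covered 0-based bases, as "chrom:pos" keys
oracleCoveredBases <- function(df) {
  out <- character(0)
  for (i in seq_len(nrow(df)))
    out <- c(out, paste0(df$chrom[i], ":", seq(df$start[i], df$end[i] - 1)))
  unique(out)
}

oracleBinCounts <- function(wChrom, wStart, wEnd, binWidth, feats) {
  nBins <- (wEnd - wStart) / binWidth
  vapply(seq_len(nBins), function(b) {
    bs <- wStart + (b - 1) * binWidth
    be <- bs + binWidth
    sum(vapply(seq_len(nrow(feats)), function(j)
      feats$chrom[j] == wChrom &&
        .ovBp(bs, be, feats$start[j], feats$end[j]) > 0, TRUE))
  }, 0)
}

oracleTssOverlap <- function(tssChrom, tssPos0, els) {
  sum(vapply(seq_along(tssPos0), function(i)
    any(els$chrom == tssChrom[i] & els$start <= tssPos0[i] &
          tssPos0[i] < els$end), TRUE))
}

## exact PWM score distribution by enumerating all 4^w words
oracleEnumerateScores <- function(pwm, granularity = 1e-3) {
  ints <- round(pwm@logOdds / granularity)
  w <- ncol(ints)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(words))
  probs <- numeric(nrow(words))
  for (k in seq_len(nrow(words))) {
    scores[k] <- sum(ints[cbind(words[k, ], seq_len(w))]) * granularity
    probs[k] <- prod(pwm@background[words[k, ]])
  }
  agg <- aggregate(probs, by = list(score = scores), FUN = sum)
  agg[order(agg$score), ]
}

randomCountsPwm <- function(width, maxCount = 30) {
  counts <- matrix(sample(0:maxCount, 4 * width, replace = TRUE), 4, width)
  rownames(counts) <- c("A", "C", "G", "T")
  loadPwm(counts, pseudocount = 0.1)
}
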