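## Seeded generator of toy genomes and all pipeline inputs with known
## planted structure: non-overlapping full-length elements with a 5'
## regulatory subregion, Poisson background TFBSs with optional 5'
## enrichment and element-restricted pairwise coupling, transcripts with a
## planted fraction of element-derived TSSs, coverage reads with planted
## active-mark signal, and element sequences with planted motif words.

.simChrom <- function(spec) {
  lens <- spec@chromLengths
  sample(names(lens), 1, prob = lens)
}

## strand-aware 5' subregion of each element, as GRanges
.fivePrimeRegions <- function(elements, len) {
  neg <- as.character(strand(elements)) == "-"
  st <- ifelse(neg, end(elements) - len + 1, start(elements))
  GRanges(seqnames(elements), IRanges(st, width = len),
          strand = strand(elements))
}

.placeElements <- function(spec) {
  lens <- spec@chromLengths
  el <- spec@elementLength
  placed <- vector("list", spec@nElements)
  occupied <- GRanges()
  for (i in seq_len(spec@nElements)) {
    ok <- FALSE
    for (try in 1:1000) {
      chrom <- .simChrom(spec)
      s0 <- floor(runif(1, 0, lens[[chrom]] - el))
      cand <- GRanges(factor(chrom, names(lens)),
                      IRanges(s0 + 1, s0 + el),
                      strand = sample(c("+", "-"), 1))
      if (!any(overlapsAny(cand, occupied))) {
        occupied <- c(occupied, cand)
        placed[[i]] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("infeasible element placement: space exhausted")
  }
  out <- do.call(c, placed)
  out$id <- paste0("L1sim_", seq_along(out))
  out$repName <- "L1sim"
  out$repClass <- "LINE"
  out$repFamily <- "L1"
  out$consensusStart <- 1L
  out$consensusEnd <- as.integer(spec@elementLength)
  out
}

## midpoints -> site intervals clamped to the chromosome
.midpointSites <- function(chrom, mid0, width, L, levels) {
  half <- floor(width / 2)
  s0 <- pmax(0, mid0 - half)
  e0 <- pmin(L, s0 + width)
  s0 <- pmax(0, pmin(s0, e0 - 1))
  GRanges(factor(chrom, levels), IRanges(s0 + 1, e0))
}

.simSites <- function(spec, elements) {
  lens <- spec@chromLengths
  fp <- .fivePrimeRegions(elements, spec@fivePrimeLen)
  sites <- setNames(vector("list", length(spec@tfNames)), spec@tfNames)
  for (tf in spec@tfNames) {
    per <- list()
    for (chrom in names(lens)) {
      n <- rpois(1, spec@backgroundRate * lens[[chrom]] / 1e6)
      if (n > 0) {
        mid0 <- floor(runif(n, 0, lens[[chrom]]))
        per[[chrom]] <- .midpointSites(chrom, mid0, spec@tfbsWidth,
                                       lens[[chrom]], names(lens))
      }
    }
    if (spec@fivePrimeEnrichment > 1) {
      extraRate <- (spec@fivePrimeEnrichment - 1) *
        spec@backgroundRate / 1e6 * spec@fivePrimeLen
      for (i in seq_along(fp)) {
        n <- rpois(1, extraRate)
        if (n > 0) {
          chrom <- as.character(seqnames(fp))[i]
          mid0 <- start(fp)[i] - 1 + floor(runif(n, 0, spec@fivePrimeLen))
          per[[length(per) + 1L]] <- .midpointSites(chrom, mid0,
                                                    spec@tfbsWidth,
                                                    lens[[chrom]],
                                                    names(lens))
        }
      }
    }
    sites[[tf]] <- if (length(per)) sort(do.call(c, unname(per))) else
      GRanges()
  }
  ## element-restricted pairwise coupling: existing element-internal tfB
  ## sites are RELOCATED next to element-internal tfA sites with the given
  ## probability. Relocation (rather than spawning extra sites) preserves
  ## every TF's marginal site density, so coupling is a pure dependence
  ## between the pair and all other TF pairs stay exactly null.
  cp <- spec@coupling
  elMid <- function(gr) {
    mid0 <- floor((start(gr) - 1 + end(gr)) / 2)
    pts <- GRanges(seqnames(gr), IRanges(mid0 + 1, width = 1))
    list(mid0 = mid0, inEl = overlapsAny(pts, elements,
                                         ignore.strand = TRUE))
  }
  for (r in seq_len(nrow(cp))) {
    a <- sites[[cp$tfA[r]]]
    b <- sites[[cp$tfB[r]]]
    if (length(a) == 0 || length(b) == 0) next
    am <- elMid(a)
    bm <- elMid(b)
    aIdx <- which(am$inEl)
    bIdx <- which(bm$inEl)
    n <- min(length(aIdx), length(bIdx))
    if (n == 0) next
    move <- runif(n) < cp$prob[r]
    src <- bIdx[seq_len(n)][move]           # tfB sites to relocate
    anchor <- aIdx[seq_len(n)][move]        # their tfA partners
    if (length(src)) {
      chrom <- as.character(seqnames(a))[anchor]
      d <- round(runif(length(src), -spec@couplingDistance,
                       spec@couplingDistance))
      L <- spec@chromLengths[chrom]
      newMid <- pmax(0, pmin(L - 1, am$mid0[anchor] + d))
      moved <- .midpointSites(chrom, newMid, spec@tfbsWidth, L,
                              names(spec@chromLengths))
      sites[[cp$tfB[r]]] <- sort(c(b[-src], moved))
    }
  }
  sites
}

.simTranscripts <- function(spec, elements) {
  lens <- spec@chromLengths
  rows <- list()
  for (cls in names(spec@nTranscripts)) {
    n <- spec@nTranscripts[[cls]]
    q <- spec@tssInElementFraction[[cls]]
    for (i in seq_len(n)) {
      inEl <- runif(1) < q
      if (inEl && length(elements)) {
        e <- sample(length(elements), 1)
        chrom <- as.character(seqnames(elements))[e]
        tss0 <- start(elements)[e] - 1 +
          floor(runif(1, 0, width(ranges(elements))[e]))
        strand <- as.character(strand(elements))[e]
      } else {
        chrom <- .simChrom(spec)
        tss0 <- floor(runif(1, 0, lens[[chrom]]))
        strand <- sample(c("+", "-"), 1)
      }
      len <- floor(runif(1, 1000, 5000))
      if (strand == "+") {
        s0 <- tss0
        e0 <- min(lens[[chrom]], tss0 + len)
      } else {
        e0 <- tss0 + 1
        s0 <- max(0, e0 - len)
      }
      ## two exons: one at the TSS end, one at the far end of the span
      ex1 <- c(s0, min(e0, s0 + 200))
      ex2 <- c(max(s0, e0 - 300), e0)
      fc <- switch(cls,
        up = 2^runif(1, 1.2, 3),
        down = 2^-runif(1, 1.2, 3),
        unchanged = 2^runif(1, -0.8, 0.8))
      pv <- if (cls == "unchanged") runif(1) else runif(1, 0, 0.04)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = paste0("tx_", cls, "_", i), chrom = chrom,
        start = s0, end = e0, strand = strand,
        exon_starts = paste(c(ex1[1], ex2[1]), collapse = ","),
        exon_ends = paste(c(ex1[2], ex2[2]), collapse = ","),
        fold_change = fc, p_value = pv, q_value = min(1, pv * 2),
        class_planted = cls, tss_in_element = inEl,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.simCoverage <- function(spec, elements, boundIdx) {
  lens <- spec@chromLengths
  fp <- .fivePrimeRegions(elements[boundIdx], spec@fivePrimeLen)
  oneTrack <- function(signal) {
    per <- list()
    for (chrom in names(lens)) {
      n <- rpois(1, spec@coverageReadsPerMb * lens[[chrom]] / 1e6)
      if (n > 0) {
        p0 <- floor(runif(n, 0, lens[[chrom]]))
        per[[chrom]] <- GRanges(factor(chrom, names(lens)),
                                IRanges(p0 + 1, width = 1))
      }
    }
    if (signal && length(fp)) {
      extraRate <- (spec@coverageSignalFactor - 1) *
        spec@coverageReadsPerMb / 1e6 * spec@fivePrimeLen
      for (i in seq_along(fp)) {
        n <- rpois(1, extraRate)
        if (n > 0) {
          p0 <- start(fp)[i] - 1 + floor(runif(n, 0, spec@fivePrimeLen))
          per[[length(per) + 1L]] <-
            GRanges(factor(as.character(seqnames(fp))[i], names(lens)),
                    IRanges(p0 + 1, width = 1))
        }
      }
    }
    sort(do.call(c, unname(per)))
  }
  tracks <- list(H3K27ac_rep1 = oneTrack(TRUE),
                 H3K27ac_rep2 = oneTrack(TRUE),
                 input_rep1 = oneTrack(FALSE))
  manifest <- data.frame(
    sample = names(tracks),
    mark = c("H3K27ac", "H3K27ac", "input"),
    role = c("signal", "signal", "control"),
    total_mapped = vapply(tracks, length, 0L),
    stringsAsFactors = FALSE)
  list(tracks = tracks, manifest = manifest)
}

.randomGenome <- function(spec) {          # named character vector
  lens <- spec@chromLengths
  vapply(names(lens), function(chrom)
    paste(sample(c("A", "C", "G", "T"), lens[[chrom]], replace = TRUE),
          collapse = ""), "")
}

.MOTIF_WORD <- "ACGGAAGTGACC"

.plantMotifs <- function(seqs, elements, offset) {
  word <- .MOTIF_WORD
  w <- nchar(word)
  rcWord <- as.character(reverseComplement(DNAStringSet(word)))
  for (i in seq_along(elements)) {
    chrom <- as.character(seqnames(elements))[i]
    if (as.character(strand(elements))[i] == "-") {
      ## plant the reverse complement so strand-aware extraction recovers
      ## the word at the same 5'-relative offset
      g0 <- end(elements)[i] - (offset - 1) - w        # 0-based start
      substr(seqs[[chrom]], g0 + 1, g0 + w) <- rcWord
    } else {
      g0 <- start(elements)[i] - 1 + (offset - 1)
      substr(seqs[[chrom]], g0 + 1, g0 + w) <- word
    }
  }
  seqs
}

#' Strand-aware element sequences
#'
#' Extracts each element's sequence from the genome, reverse-complementing
#' minus-strand elements so all sequences read 5' to 3' of the element.
#'
#' @param genome a named \link[Biostrings]{DNAStringSet}.
#' @param elements GRanges with \code{id}.
#' @return DNAStringSet named by element id.
#' @export
extractElementSequences <- function(genome, elements) {
  out <- vector("list", length(elements))
  for (i in seq_along(elements)) {
    chrom <- as.character(seqnames(elements))[i]
    s <- subseq(genome[[chrom]], start(elements)[i], end(elements)[i])
    if (as.character(strand(elements))[i] == "-")
      s <- reverseComplement(s)
    out[[i]] <- as.character(s)
  }
  DNAStringSet(setNames(unlist(out),
                        if (!is.null(elements$id)) elements$id
                        else as.character(seq_along(elements))))
}

#' Simulate a complete input bundle with planted structure
#'
#' Deterministic given the seed: generates the element annotation, per-TF
#' binding sites (background + 5' enrichment + element-restricted
#' coupling), a transcript table with planted element-derived TSS
#' fractions, coverage read tracks with planted active-mark signal on
#' bound elements, and a genome carrying a planted motif word at a fixed
#' consensus offset of every element. The \code{truth} entry records every
#' planted quantity for closed-loop assertions.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @param components subset of c("sites", "transcripts", "coverage",
#'   "genome") to generate (elements are always generated); skipping the
#'   genome makes repeated simulation cheap for statistical tests.
#' @param seed overrides \code{spec@rngSeed} when given.
#' @return list(spec, chromSizes, elements, sitesByTf, transcripts,
#'   coverage, genome, pwm, truth).
#' @export
simulateAll <- function(spec = fixtureSpec(),
                        components = c("sites", "transcripts", "coverage",
                                       "genome"),
                        seed = NULL) {
  validObject(spec)
  if (is.null(seed)) seed <- spec@rngSeed
  set.seed(seed)
  elements <- .placeElements(spec)
  bundle <- list(spec = spec, chromSizes = spec@chromLengths,
                 elements = elements)
  truth <- list(
    seed = seed,
    elementCoverageFraction =
      sum(width(ranges(elements))) / sum(spec@chromLengths),
    couplingPairs = spec@coupling,
    tssInElementFraction = as.list(spec@tssInElementFraction),
    motifWord = .MOTIF_WORD, motifOffset = spec@motifOffset)
  if ("sites" %in% components) {
    bundle$sitesByTf <- .simSites(spec, elements)
    pooled <- unname(bundle$sitesByTf)
    pooled <- pooled[vapply(pooled, length, 0L) > 0]
    allSites <- if (length(pooled)) do.call(c, pooled) else GRanges()
    boundIdx <- unique(subjectHits(intersectFraction(allSites, elements,
                                                     0.5)))
    truth$boundElementIds <- elements$id[sort(boundIdx)]
    truth$nSitesPerTf <- vapply(bundle$sitesByTf, length, 0L)
  } else boundIdx <- integer(0)
  if ("transcripts" %in% components)
    bundle$transcripts <- .simTranscripts(spec, elements)
  if ("coverage" %in% components)
    bundle$coverage <- .simCoverage(spec, elements, boundIdx)
  if ("genome" %in% components) {
    seqs <- .plantMotifs(.randomGenome(spec), elements, spec@motifOffset)
    bundle$genome <- DNAStringSet(seqs)
    counts <- matrix(0L, 4, nchar(.MOTIF_WORD),
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    chars <- strsplit(.MOTIF_WORD, "")[[1]]
    for (j in seq_along(chars)) counts[chars[j], j] <- 20L
    attr(counts, "id") <- "SIM0001.1"
    bundle$pfm <- counts
  }
  bundle$truth <- truth
  bundle
}

#' Write a simulated bundle to disk in the external formats
#'
#' Emits chrom.sizes, a simple-dialect repeat TSV, per-TF BED files under
#' tfbs/, read-position BEDs with a samples manifest under coverage/, the
#' transcript TSV, the genome FASTA, the JASPAR PFM and truth.json.
#'
#' @param bundle from \code{\link{simulateAll}}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
writeFixtureBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(names(bundle$chromSizes), bundle$chromSizes),
              file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  el <- bundle$elements
  df <- .bedFrame(el)
  write.table(data.frame(chrom = df$chrom, start = df$start, end = df$end,
                         strand = df$strand, rep_name = el$repName,
                         consensus_start = el$consensusStart,
                         consensus_end = el$consensusEnd),
              file.path(dir, "repeats.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(bundle$sitesByTf)) {
    tdir <- file.path(dir, "tfbs")
    dir.create(tdir, showWarnings = FALSE)
    for (tf in names(bundle$sitesByTf))
      writeBed(bundle$sitesByTf[[tf]], file.path(tdir, paste0(tf, ".bed")))
  }
  if (!is.null(bundle$transcripts))
    write.table(bundle$transcripts[, !names(bundle$transcripts) %in%
                                     c("class_planted", "tss_in_element")],
                file.path(dir, "transcripts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$coverage)) {
    cdir <- file.path(dir, "coverage")
    dir.create(cdir, showWarnings = FALSE)
    for (s in names(bundle$coverage$tracks))
      writeBed(bundle$coverage$tracks[[s]],
               file.path(cdir, paste0(s, ".bed")))
    write.table(bundle$coverage$manifest, file.path(cdir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$genome))
    writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  if (!is.null(bundle$pfm))
    writeJasparPfm(bundle$pfm, attr(bundle$pfm, "id"),
                   file.path(dir, "motif.pfm"))
  write_json(bundle$truth, file.path(dir, "truth.json"),
             auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
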