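## Readers and writers for the external formats the pipeline touches.
## Internal convention: GRanges, 1-based closed (Bioconductor native).
## BED and UCSC rmsk inputs are 0-based half-open and converted on ingest;
## RepeatMasker consensus positions stay 1-based inclusive as reported.

#' Build a GRanges from 0-based half-open (BED-style) coordinates
#'
#' Convenience constructor used throughout the examples and tests so that
#' interval boundaries can be written in the BED convention of the input
#' formats.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates (end exclusive).
#' @param strand "+", "-" or "." (recycled).
#' @param ... further metadata columns.
#' @return A \link[GenomicRanges]{GRanges} (1-based closed internally).
#' @examples
#' grFromBed("chr1", 100, 200)  # covers bases 100..199 (0-based)
#' @export
grFromBed <- function(chrom, start, end, strand = ".", ...) {
  if (any(end <= start)) stop("end must be > start")
  strand <- ifelse(strand == ".", "*", strand)
  GRanges(chrom, IRanges(start + 1L, end), strand = strand, ...)
}

## chrom, start0, end0 columns of a GRanges (0-based half-open view)
.bedFrame <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr),
             strand = as.character(strand(gr)),
             stringsAsFactors = FALSE)
}

.stopLine <- function(path, i, what) {
  stop(sprintf("%s: malformed row at line %d: %s", path, i, what),
       call. = FALSE)
}

#' Read a RepeatMasker-style repeat annotation table
#'
#' Supports the UCSC rmsk table dump (\code{dialect = "ucsc"}: columns
#' genoName, genoStart, genoEnd, strand, repName, repClass, repFamily,
#' repStart, repEnd, repLeft; genoStart is 0-based) and a simplified TSV
#' (\code{dialect = "simple"}: chrom, start, end, strand, rep_name,
#' consensus_start, consensus_end with 0-based half-open genomic
#' coordinates). Consensus positions are 1-based inclusive in both
#' dialects. For minus-strand rows of the UCSC dialect the consensus start
#' is taken from \code{repLeft}, following the UCSC storage convention for
#' reverse-strand alignments.
#'
#' @param path file path (plain or gzipped TSV with header).
#' @param repName optional exact subfamily filter (e.g. "L1PA2").
#' @param dialect "ucsc" or "simple".
#' @return GRanges with metadata columns \code{id}, \code{repName},
#'   \code{repClass}, \code{repFamily}, \code{consensusStart},
#'   \code{consensusEnd}.
#' @export
readRepeatMasker <- function(path, repName = NULL,
                             dialect = c("simple", "ucsc")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
  names(tab)[1] <- sub("^#", "", names(tab)[1])
  need <- switch(dialect,
    ucsc = c("genoName", "genoStart", "genoEnd", "strand", "repName",
             "repClass", "repFamily", "repStart", "repEnd", "repLeft"),
    simple = c("chrom", "start", "end", "strand", "rep_name",
               "consensus_start", "consensus_end"))
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("dialect '", dialect, "' requires columns: ",
         paste(miss, collapse = ", "))
  if (dialect == "ucsc") {
    tab <- data.frame(chrom = tab$genoName, start = tab$genoStart,
                      end = tab$genoEnd, strand = tab$strand,
                      rep_name = tab$repName, rep_class = tab$repClass,
                      rep_family = tab$repFamily,
                      consensus_start = ifelse(tab$strand == "-",
                                               tab$repLeft, tab$repStart),
                      consensus_end = tab$repEnd,
                      stringsAsFactors = FALSE)
  } else {
    if (!"rep_class" %in% names(tab))
      tab$rep_class <- rep(NA_character_, nrow(tab))
    if (!"rep_family" %in% names(tab))
      tab$rep_family <- rep(NA_character_, nrow(tab))
  }
  for (i in seq_len(nrow(tab))) {        # line i+1 in the file (header)
    row <- tab[i, ]
    if (is.na(row$start) || is.na(row$end) || !is.numeric(row$start) ||
        !is.numeric(row$end))
      .stopLine(path, i + 1L, "non-numeric coordinates")
    if (row$end <= row$start)
      .stopLine(path, i + 1L, "end <= start")
    if (is.na(row$consensus_start) || is.na(row$consensus_end) ||
        row$consensus_start < 1 || row$consensus_end < row$consensus_start)
      .stopLine(path, i + 1L,
                "need consensus_end >= consensus_start >= 1")
    if (!row$strand %in% c("+", "-", "."))
      .stopLine(path, i + 1L, paste("bad strand", row$strand))
  }
  if (!is.null(repName)) tab <- tab[tab$rep_name == repName, , drop = FALSE]
  if (nrow(tab) == 0)
    return(.emptyGR(id = character(), repName = character(),
                    repClass = character(), repFamily = character(),
                    consensusStart = integer(), consensusEnd = integer()))
  gr <- grFromBed(tab$chrom, tab$start, tab$end, tab$strand,
                  id = paste0(tab$rep_name, "_", seq_len(nrow(tab))),
                  repName = tab$rep_name, repClass = tab$rep_class,
                  repFamily = tab$rep_family,
                  consensusStart = as.integer(tab$consensus_start),
                  consensusEnd = as.integer(tab$consensus_end))
  gr
}

#' Drop records on alternate, random, fix-patch and unplaced chromosomes
#'
#' Entities mapped outside the primary assembly are excluded from all
#' analyses. Matching is by UCSC naming: suffixes \code{_alt},
#' \code{_random}, \code{_fix} and the \code{chrUn} prefix.
#'
#' @param gr a GRanges (or anything with seqnames).
#' @return The subset on primary chromosomes, order preserved.
#' @examples
#' gr <- GenomicRanges::GRanges(c("chr1", "chr1_KI270766v1_alt"),
#'                              IRanges::IRanges(1, 10))
#' filterPrimaryChromosomes(gr)
#' @export
filterPrimaryChromosomes <- function(gr) {
  chr <- as.character(seqnames(gr))
  keep <- !grepl("(_alt|_random|_fix)$|^chrUn", chr)
  out <- gr[keep]
  if (is(out, "GRanges"))
    out <- keepSeqlevels(out, unique(as.character(seqnames(out))))
  out
}

## Validated BED reader; label column optional.
.readBedValidated <- function(path, needName = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      strand = character()))
  parts <- strsplit(lines, "\t")
  n <- lengths(parts)
  if (any(n < 3)) .stopLine(path, which(n < 3)[1], "fewer than 3 columns")
  if (needName && any(n < 4))
    .stopLine(path, which(n < 4)[1], "missing label column")
  chrom <- vapply(parts, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) .stopLine(path, which(bad)[1], "non-numeric coordinates")
  bad <- end <= start
  if (any(bad)) .stopLine(path, which(bad)[1], "end <= start")
  name <- ifelse(n >= 4, vapply(parts, function(p) p[4], ""), ".")
  strand <- ifelse(n >= 6, vapply(parts, function(p) p[min(6, length(p))], ""),
                   ".")
  strand[!strand %in% c("+", "-")] <- "."
  data.frame(chrom = chrom, start = start, end = end, name = name,
             strand = strand, stringsAsFactors = FALSE)
}

#' Read a BED file into a GRanges
#'
#' @param path BED3/BED6 path.
#' @return GRanges with a \code{name} metadata column.
#' @export
readBed <- function(path) {
  df <- .readBedValidated(path)
  if (nrow(df) == 0)
    return(.emptyGR(name = character()))
  grFromBed(df$chrom, df$start, df$end, df$strand, name = df$name)
}

#' Write intervals as BED6
#'
#' Emits chrom, 0-based start, exclusive end, name, score 0 and strand
#' ("." for unstranded); round-trips through \code{\link{readBed}} without
#' loss of chrom/start/end/name/strand.
#'
#' @param gr a GRanges; names taken from the \code{name} metadata column,
#'   then \code{names(gr)}, else ".".
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path) {
  df <- .bedFrame(gr)
  nm <- if (!is.null(gr$name)) gr$name else names(gr)
  df$name <- if (is.null(nm)) rep(".", nrow(df)) else nm
  df$score <- rep(0L, nrow(df))
  df <- df[, c("chrom", "start", "end", "name", "score", "strand")]
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read TF binding sites from BED with a TF label
#'
#' Either one BED file whose 4th column carries the TF label
#' (\code{tfLabelSource = "column"}), or a directory of per-TF BED files
#' named \code{<TF>.bed} (\code{tfLabelSource = "filename"}).
#'
#' @param path BED file or directory.
#' @param tfLabelSource "column" or "filename".
#' @return GRanges with a \code{tf} metadata column.
#' @export
readTFSites <- function(path, tfLabelSource = c("column", "filename")) {
  tfLabelSource <- match.arg(tfLabelSource)
  if (tfLabelSource == "filename" || dir.exists(path)) {
    if (!dir.exists(path)) stop("filename labelling needs a directory: ", path)
    files <- list.files(path, pattern = "\\.bed$", full.names = TRUE)
    if (!length(files)) stop("no .bed files in ", path)
    dfs <- lapply(files, function(f) {
      df <- .readBedValidated(f)
      df$tf <- rep(sub("\\.bed$", "", basename(f)), nrow(df))
      df
    })
    df <- do.call(rbind, dfs)
    if (nrow(df) == 0) return(.emptyGR(tf = character()))
    return(sort(grFromBed(df$chrom, df$start, df$end, df$strand,
                          tf = df$tf)))
  }
  df <- .readBedValidated(path, needName = TRUE)
  if (any(df$name == "." | !nzchar(df$name)))
    .stopLine(path, which(df$name == "." | !nzchar(df$name))[1],
              "missing TF label")
  if (nrow(df) == 0) return(.emptyGR(tf = character()))
  grFromBed(df$chrom, df$start, df$end, df$strand, tf = df$name)
}

#' Read a differential-transcript table
#'
#' TSV with columns \code{transcript_id, chrom, start, end, strand,
#' exon_starts, exon_ends, fold_change, p_value, q_value}; genomic
#' coordinates 0-based half-open, exon lists comma-separated. Rows with a
#' missing or non-positive fold change are dropped with a logged count
#' (fold changes are case/reference ratios and must be positive).
#'
#' @param path TSV path.
#' @return GRanges (mandatory strand) with metadata \code{transcriptId},
#'   \code{foldChange}, \code{pValue}, \code{qValue} and an \code{exons}
#'   GRangesList column.
#' @export
readTranscriptTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "chrom", "start", "end", "strand",
            "exon_starts", "exon_ends", "fold_change", "p_value", "q_value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!tab$strand %in% c("+", "-")))
    stop("transcript strand must be '+' or '-' (line ",
         which(!tab$strand %in% c("+", "-"))[1] + 1L, ")")
  drop <- is.na(tab$fold_change) | tab$fold_change <= 0
  if (any(drop)) {
    message("readTranscriptTable: dropped ", sum(drop),
            " row(s) with missing or non-positive fold change")
    tab <- tab[!drop, , drop = FALSE]
  }
  if (nrow(tab) == 0)
    stop("no usable transcript rows in ", path)
  exons <- lapply(seq_len(nrow(tab)), function(i) {
    es <- as.numeric(strsplit(as.character(tab$exon_starts[i]), ",")[[1]])
    ee <- as.numeric(strsplit(as.character(tab$exon_ends[i]), ",")[[1]])
    if (length(es) != length(ee) || any(is.na(es)) || any(is.na(ee)))
      .stopLine(path, i + 1L, "unparsable exon lists")
    if (any(es < tab$start[i]) || any(ee > tab$end[i]) || any(ee <= es))
      .stopLine(path, i + 1L, "exon outside transcript span")
    grFromBed(tab$chrom[i], es, ee, tab$strand[i])
  })
  gr <- grFromBed(tab$chrom, tab$start, tab$end, tab$strand,
                  transcriptId = tab$transcript_id,
                  foldChange = tab$fold_change,
                  pValue = tab$p_value, qValue = tab$q_value)
  gr$exons <- GRangesList(exons)
  gr
}

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with chromosome name and length.
#' @return Named numeric vector of lengths.
#' @export
readChromSizes <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("chrom.sizes needs two columns")
  setNames(as.numeric(tab[[2]]), tab[[1]])
}

#' Read a JASPAR-style PFM text file
#'
#' Accepts the JASPAR format (a \code{>ID name} header followed by four
#' rows \code{A [ counts ]} ... \code{T [ counts ]}) or four bare
#' whitespace-separated count rows in A, C, G, T order.
#'
#' @param path PFM path.
#' @return 4 x width count matrix with rownames A,C,G,T and an \code{id}
#'   attribute.
#' @export
readJasparPfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  id <- "PFM"
  if (grepl("^>", lines[1])) {
    id <- strsplit(sub("^>", "", lines[1]), "[ \t]+")[[1]][1]
    lines <- lines[-1]
  }
  if (length(lines) < 4) stop("PFM needs 4 count rows")
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", trimws(l))
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  w <- unique(lengths(rows))
  if (length(w) != 1) stop("PFM rows have unequal widths")
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  attr(counts, "id") <- id
  counts
}

#' Write a count matrix in JASPAR PFM format
#'
#' @param counts 4 x width matrix, rows A,C,G,T.
#' @param id matrix identifier for the header.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeJasparPfm <- function(counts, id, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", id), con)
  for (b in c("A", "C", "G", "T"))
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(counts[b, ], trim = TRUE),
                             collapse = " ")), con)
  invisible(path)
}

#' Summarise a repeat subfamily universe
#'
#' Counts the annotated copies and those whose genomic span exceeds a
#' length cut-off (full-length elements; ~6 kb for LINE-1).
#'
#' @param elements GRanges from \code{\link{readRepeatMasker}}.
#' @param minSpan bp; elements with span strictly greater are counted.
#' @return list(nElements, nOverMinSpan).
#' @export
repeatUniverseSummary <- function(elements, minSpan = 6000) {
  list(nElements = length(elements),
       nOverMinSpan = sum(width(ranges(elements)) > minSpan))
}
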