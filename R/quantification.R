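#' @importFrom Rsamtools asBam scanBam ScanBamParam
NULL

## Reference-aligned bases of a CIGAR string: sum of M, = and X operations.
cigarAlignedLength <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    op <- substring(toks, nchar(toks))
    len <- as.integer(substring(toks, 1, nchar(toks) - 1L))
    sum(len[op %in% c("M", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read alignments from a SAM file
#'
#' Converts the SAM to BAM internally (via \pkg{Rsamtools}) and extracts the
#' fields the quantification functions need. Unmapped records (FLAG 0x4) are
#' skipped; secondary alignments are retained, because equal-split
#' allocation needs every placement of a multi-mapping read. Mismatch counts
#' come from the NM tag; if the tag is absent, mismatches are set to 0 with
#' a warning.
#'
#' @param path Path to a SAM file with a valid header (\code{@SQ} lines).
#' @return A data.frame with columns \code{read_id}, \code{reference},
#'   \code{ref_strand} (\code{"+"}/\code{"-"}, alignment orientation
#'   relative to the reference), \code{start} (0-based),
#'   \code{aligned_length}, \code{mismatches}.
#' @export
readSamAlignments <- function(path) {
  bam <- tryCatch(
    Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE),
    error = function(e) stop("failed to parse SAM file '", path, "': ",
                             conditionMessage(e)))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = "NM")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  ## the converter silently truncates at a bad record; detect that
  body <- readLines(path)
  nExpected <- sum(nzchar(body) & !startsWith(body, "@"))
  if (length(res$flag) != nExpected)
    stop("SAM parse error at record ", length(res$flag) + 1L,
         " of '", path, "'")
  mapped <- bitwAnd(res$flag, 4L) == 0L
  nm <- res$tag$NM
  if (is.null(nm)) {
    if (any(mapped)) warning("no NM tags found; mismatches set to 0")
    nm <- rep(0L, length(res$flag))
  } else if (anyNA(nm[mapped])) {
    warning("NM tag missing on some records; their mismatches set to 0")
    nm[is.na(nm)] <- 0L
  }
  data.frame(
    read_id = res$qname[mapped],
    reference = as.character(res$rname[mapped]),
    ref_strand = ifelse(bitwAnd(res$flag[mapped], 16L) > 0L, "-", "+"),
    start = res$pos[mapped] - 1L,
    aligned_length = cigarAlignedLength(res$cigar[mapped]),
    mismatches = nm[mapped],
    stringsAsFactors = FALSE)
}

#' Write alignments as a SAM file
#'
#' Minimal single-end SAM writer used by the simulator and tests. The first
#' alignment of each read is primary; further placements get the secondary
#' flag. Reads listed in \code{unmappedIds} are emitted as unmapped records.
#'
#' @param alignments Alignment data.frame (see
#'   \code{\link{readSamAlignments}}).
#' @param refLengths Named integer vector: reference name -> length, for
#'   \code{@SQ} header lines.
#' @param path Output path.
#' @param seqs,quals Optional named character vectors (by read id) of read
#'   sequence and Phred+33 quality strings; defaults to \code{"*"}.
#' @param unmappedIds Character vector of read ids to write as unmapped.
#' @return Invisibly, \code{path}.
#' @export
writeSam <- function(alignments, refLengths, path, seqs = NULL, quals = NULL,
                     unmappedIds = character()) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(refLengths), "\tLN:", refLengths))
  sq <- function(id) if (!is.null(seqs) && id %in% names(seqs)) seqs[[id]] else "*"
  ql <- function(id) if (!is.null(quals) && id %in% names(quals)) quals[[id]] else "*"
  recs <- character(0)
  if (nrow(alignments) > 0) {
    first <- !duplicated(alignments$read_id)
    flag <- ifelse(alignments$ref_strand == "-", 16L, 0L) +
      ifelse(first, 0L, 256L)
    recs <- paste(alignments$read_id, flag, alignments$reference,
                  alignments$start + 1L, 255L,
                  paste0(alignments$aligned_length, "M"),
                  "*", 0L, 0L,
                  vapply(alignments$read_id, sq, character(1)),
                  vapply(alignments$read_id, ql, character(1)),
                  paste0("NM:i:", alignments$mismatches),
                  sep = "\t")
  }
  un <- character(0)
  if (length(unmappedIds) > 0) {
    un <- paste(unmappedIds, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                vapply(unmappedIds, sq, character(1)),
                vapply(unmappedIds, ql, character(1)), sep = "\t")
  }
  writeLines(c(hdr, recs, un), path)
  invisible(path)
}

#' Strand-aware read counting with equal-split allocation
#'
#' Counts reads against transcript models under one of three strand modes.
#' \code{sense_only} keeps alignments in the transcript's orientation (the
#' strand-specific convention), \code{antisense_only} the reverse, and
#' \code{both} ignores orientation (the non-strand-specific convention). A
#' read assigned to k transcripts contributes weight 1/k to each, so every
#' counted read carries total weight exactly 1 -- the equal-split allocation
#' whose bias on antisense-overlapped genes this package quantifies.
#'
#' @param alignments Alignment data.frame (see
#'   \code{\link{readSamAlignments}}). In transcript space
#'   \code{reference} is a transcript accession and \code{ref_strand == "+"}
#'   means sense; in genome space \code{reference} is a chromosome and a
#'   read is sense to a transcript when its strand equals the transcript's.
#' @param models A \code{\linkS4class{TranscriptSet}}.
#' @param strandMode One of \code{"sense_only"}, \code{"antisense_only"},
#'   \code{"both"}.
#' @param maxMismatches Alignments with more mismatches are discarded
#'   (default 3).
#' @param space \code{"transcript"} (default) or \code{"genome"}. Genome
#'   space assigns a read to every transcript whose exons overlap the read
#'   interval by at least one base.
#' @return A list: \code{counts} (named numeric over all model accessions,
#'   zeros included), \code{libraryMappedReads} (distinct reads with at
#'   least one surviving assignment under this mode), \code{skipped}
#'   (alignments to references absent from \code{models}/their chromosomes).
#' @export
countReads <- function(alignments, models,
                       strandMode = c("sense_only", "antisense_only", "both"),
                       maxMismatches = 3, space = c("transcript", "genome")) {
  strandMode <- match.arg(strandMode)
  space <- match.arg(space)
  acc <- accessions(models)
  zero <- setNames(numeric(length(acc)), acc)
  aln <- alignments[alignments$mismatches <= maxMismatches, , drop = FALSE]
  if (nrow(aln) == 0)
    return(list(counts = zero, libraryMappedReads = 0L, skipped = 0L))
  if (space == "transcript") {
    known <- aln$reference %in% acc
    skipped <- sum(!known)
    if (skipped > 0)
      warning(skipped, " alignment(s) to unknown references skipped")
    aln <- aln[known, , drop = FALSE]
    sense <- aln$ref_strand == "+"
    assign <- data.frame(read_id = aln$read_id, tx = aln$reference,
                         sense = sense, stringsAsFactors = FALSE)
  } else {
    chroms <- unique(txChrom(models))
    known <- aln$reference %in% chroms
    skipped <- sum(!known)
    if (skipped > 0)
      warning(skipped, " alignment(s) to unknown chromosomes skipped")
    aln <- aln[known, , drop = FALSE]
    if (nrow(aln) == 0)
      return(list(counts = zero, libraryMappedReads = 0L, skipped = skipped))
    reads <- GenomicRanges::GRanges(
      aln$reference,
      IRanges::IRanges(start = aln$start + 1L,
                       width = pmax(aln$aligned_length, 1L)))
    gl <- exonRanges(models)
    ex <- unlist(gl, use.names = FALSE)
    txi <- rep(seq_along(gl), S4Vectors::elementNROWS(gl))
    hits <- GenomicRanges::findOverlaps(reads, ex, ignore.strand = TRUE)
    if (length(hits) == 0)
      return(list(counts = zero, libraryMappedReads = 0L, skipped = skipped))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    tstr <- txStrand(models)
    assign <- data.frame(
      read_id = aln$read_id[qh],
      tx = acc[txi[sh]],
      sense = aln$ref_strand[qh] == unname(tstr[txi[sh]]),
      stringsAsFactors = FALSE)
  }
  if (strandMode == "sense_only") assign <- assign[assign$sense, , drop = FALSE]
  if (strandMode == "antisense_only") assign <- assign[!assign$sense, , drop = FALSE]
  if (nrow(assign) == 0)
    return(list(counts = zero, libraryMappedReads = 0L, skipped = skipped))
  assign <- assign[!duplicated(paste(assign$read_id, assign$tx)), , drop = FALSE]
  rid <- match(assign$read_id, unique(assign$read_id))
  k <- tabulate(rid)
  w <- 1 / k[rid]
  cts <- rowsum(w, assign$tx)
  zero[rownames(cts)] <- cts[, 1]
  list(counts = zero,
       libraryMappedReads = length(k),
       skipped = skipped)
}

#' Compute RPKM expression records
#'
#' RPKM = read count / (exonic length / 1000) / (mapped library size / 1e6).
#'
#' @param counts Named numeric vector of (possibly fractional) read counts.
#' @param lengths Named numeric vector of exonic lengths (bases); must cover
#'   every accession in \code{counts}.
#' @param libraryMappedReads Positive count of mapped reads in the library.
#' @return A data.frame with columns \code{accession}, \code{read_count},
#'   \code{exonic_length}, \code{rpkm}; one row per accession in
#'   \code{counts}, zero counts included.
#' @export
computeRpkm <- function(counts, lengths, libraryMappedReads) {
  if (libraryMappedReads <= 0)
    stop("libraryMappedReads must be positive")
  if (any(!names(counts) %in% names(lengths)))
    stop("lengths missing for some accessions")
  len <- lengths[names(counts)]
  if (any(len <= 0)) stop("all lengths must be positive")
  data.frame(
    accession = names(counts),
    read_count = as.numeric(counts),
    exonic_length = as.numeric(len),
    rpkm = as.numeric(counts) / (len / 1000) / (libraryMappedReads / 1e6),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an expression table
#'
#' @param expr Data.frame from \code{\link{computeRpkm}}.
#' @param path Output path (TSV with header).
#' @return Invisibly, \code{path}.
#' @export
writeExpression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table written by \code{\link{writeExpression}}
#'
#' @param path Path to the TSV.
#' @return Expression data.frame.
#' @export
readExpression <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
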