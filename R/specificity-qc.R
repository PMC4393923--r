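#' Per-position base-quality profile of a FASTQ file
#'
#' Reads a Phred-scaled FASTQ (default Phred+33) and summarises the quality
#' score at each read position: count of reads covering the position, mean,
#' and quartiles. Variable-length reads are supported.
#'
#' @param path Path to a FASTQ file.
#' @param offset ASCII offset of the quality encoding (default 33).
#' @return Data.frame with columns \code{position} (1-based), \code{count},
#'   \code{mean}, \code{q1}, \code{median}, \code{q3}; zero rows for an
#'   empty file.
#' @export
qualityProfile <- function(path, offset = 33L) {
  lines <- readLines(path)
  empty <- data.frame(position = integer(), count = integer(),
                      mean = numeric(), q1 = numeric(), median = numeric(),
                      q3 = numeric())
  if (length(lines) == 0) return(empty)
  if (length(lines) %% 4 != 0)
    stop("FASTQ parse error: line count not a multiple of 4")
  nrec <- length(lines) / 4
  hdr <- lines[seq(1, by = 4, length.out = nrec)]
  seqs <- lines[seq(2, by = 4, length.out = nrec)]
  plus <- lines[seq(3, by = 4, length.out = nrec)]
  quals <- lines[seq(4, by = 4, length.out = nrec)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("FASTQ parse error at record ", bad[1])
  ql <- lapply(quals, function(q) utf8ToInt(q) - offset)
  L <- max(lengths(ql))
  qm <- matrix(NA_real_, nrow = nrec, ncol = L)
  for (i in seq_len(nrec)) qm[i, seq_along(ql[[i]])] <- ql[[i]]
  res <- lapply(seq_len(L), function(p) {
    v <- qm[, p]; v <- v[!is.na(v)]
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(position = p, count = length(v), mean = mean(v),
               q1 = qs[1], median = qs[2], q3 = qs[3])
  })
  do.call(rbind, res)
}

#' Normalized gene-body coverage profile
#'
#' Each aligned base at transcript position p (0-based, 5' to 3' in
#' transcript orientation) of a transcript of exonic length L falls into
#' bin \code{floor(100 * p / L)}. Bin counts are summed over all transcripts
#' and divided by the total number of mapped bases, so the profile sums to
#' the fraction of mapped bases falling inside the models (at most 1).
#'
#' @param alignments Transcript-space alignment data.frame.
#' @param models A \code{\linkS4class{TranscriptSet}}.
#' @return Numeric vector of 100 bin frequencies.
#' @export
coverageProfile <- function(alignments, models) {
  prof <- numeric(100)
  if (nrow(alignments) == 0) return(prof)
  totalBases <- sum(alignments$aligned_length)
  aln <- alignments[alignments$reference %in% accessions(models), ,
                    drop = FALSE]
  if (nrow(aln) == 0) return(prof)
  len <- exonicLength(models)
  L <- unname(len[aln$reference])
  pos <- sequence(aln$aligned_length, from = aln$start)
  Lrep <- rep(L, aln$aligned_length)
  keep <- pos >= 0 & pos < Lrep
  bin <- floor(100 * pos[keep] / Lrep[keep]) + 1L
  tb <- tabulate(bin, nbins = 100)
  tb / totalBases
}

#' Mappable-rate and strand-specificity summary
#'
#' Rates are fractions of all sequenced reads (mapped plus unmapped). The
#' sense:antisense mappable-rate ratio is near 1 for a non-strand-specific
#' library and far above 1 for a strand-specific one; the antisense
#' fraction (antisense-mapped over all mapped) estimates the strand-leakage
#' level of an SS library.
#'
#' @param totalReads Total sequenced reads (> 0).
#' @param mappedSense,mappedAntisense,mappedAny Read counts mapped in
#'   sense-only, antisense-only and either-strand mode.
#' @return A list: \code{rate_any}, \code{rate_sense},
#'   \code{rate_antisense}, \code{sense_to_antisense_ratio} (\code{Inf}
#'   with \code{infinite_ratio = TRUE} when no antisense reads),
#'   \code{antisense_fraction}, \code{infinite_ratio}.
#' @export
mappableRates <- function(totalReads, mappedSense, mappedAntisense,
                          mappedAny) {
  if (totalReads <= 0) stop("totalReads must be positive")
  if (any(c(mappedSense, mappedAntisense, mappedAny) > totalReads))
    stop("mapped counts cannot exceed totalReads")
  inf <- mappedAntisense == 0
  list(rate_any = mappedAny / totalReads,
       rate_sense = mappedSense / totalReads,
       rate_antisense = mappedAntisense / totalReads,
       sense_to_antisense_ratio = if (inf) Inf else mappedSense / mappedAntisense,
       antisense_fraction = if (mappedAny > 0) mappedAntisense / mappedAny else NA_real_,
       infinite_ratio = inf)
}

#' Per-transcript sense/antisense read-count ratios
#'
#' Emits one record per transcript whose weighted read count reaches
#' \code{minCount} on both strands (dropping transcripts with tiny counts
#' avoids dramatic ratios driven by sampling noise). Transcripts with
#' antisense excess (log2 ratio < 0) are candidate hosts of unannotated
#' antisense transcription.
#'
#' @param senseCounts,antisenseCounts Named numeric vectors of weighted
#'   counts over the same accessions.
#' @param minCount Both-strand threshold (default 10).
#' @return Data.frame with columns \code{accession}, \code{sense_count},
#'   \code{antisense_count}, \code{log2_ratio} (sense over antisense);
#'   attribute \code{n_antisense_excess}.
#' @export
strandRatioTable <- function(senseCounts, antisenseCounts, minCount = 10) {
  acc <- intersect(names(senseCounts), names(antisenseCounts))
  s <- senseCounts[acc]; a <- antisenseCounts[acc]
  keep <- s >= minCount & a >= minCount
  out <- data.frame(accession = acc[keep],
                    sense_count = unname(s[keep]),
                    antisense_count = unname(a[keep]),
                    log2_ratio = unname(log2(s[keep] / a[keep])),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_antisense_excess") <- sum(out$log2_ratio < 0)
  out
}
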