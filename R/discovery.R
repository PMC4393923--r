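#' Read a blat PSL alignment file
#'
#' Parses the 21-column PSL dialect (optionally with the 5-line psLayout
#' header). Alignment identity is computed with the standard mRNA
#' convention: matches / (matches + misMatches + qNumInsert).
#'
#' @param path Path to a PSL file.
#' @return Data.frame with one row per alignment: \code{isotig_id},
#'   \code{chrom}, \code{strand}, \code{matches}, \code{mismatches},
#'   \code{q_num_insert}, \code{query_size}, \code{identity},
#'   \code{block_count} and list-columns \code{block_starts},
#'   \code{block_ends} (genomic, 0-based half-open, sorted).
#' @export
readPsl <- function(path) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1], "psLayout"))
    lines <- lines[-seq_len(5)]
  lines <- lines[nzchar(lines)]
  cols <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(cols) != 21L)
  if (length(bad))
    stop("PSL parse error at record ", bad[1], ": expected 21 fields")
  if (length(cols) == 0)
    return(data.frame(isotig_id = character(), chrom = character(),
                      strand = character(), matches = integer(),
                      mismatches = integer(), q_num_insert = integer(),
                      query_size = integer(), identity = numeric(),
                      block_count = integer()))
  m <- do.call(rbind, cols)
  ints <- function(j) as.integer(m[, j])
  parseList <- function(s) as.integer(strsplit(sub(",+$", "", s), ",")[[1]])
  blockSizes <- lapply(m[, 19], parseList)
  tStarts <- lapply(m[, 21], parseList)
  out <- data.frame(
    isotig_id = m[, 10], chrom = m[, 14],
    strand = substring(m[, 9], 1, 1),
    matches = ints(1), mismatches = ints(2), q_num_insert = ints(5),
    query_size = ints(11), block_count = ints(18),
    stringsAsFactors = FALSE)
  out$identity <- out$matches /
    (out$matches + out$mismatches + out$q_num_insert)
  out$block_starts <- tStarts
  out$block_ends <- Map(`+`, tStarts, blockSizes)
  bc <- lengths(out$block_starts)
  if (any(bc != out$block_count))
    stop("PSL parse error at record ", which(bc != out$block_count)[1],
         ": blockCount does not match block lists")
  out
}

#' Filter contig alignments by identity and pick one locus per contig
#'
#' Keeps alignments with identity at least \code{minIdentity} (boundary
#' inclusive). When one contig passes at several genomic loci, only the
#' best-identity locus is kept; an exact tie makes the contig ambiguous and
#' drops it entirely.
#'
#' @param aln Data.frame from \code{\link{readPsl}}.
#' @param minIdentity Minimum identity fraction (default 0.95).
#' @return Filtered data.frame, at most one row per contig.
#' @export
filterIsotigAlignments <- function(aln, minIdentity = 0.95) {
  aln <- aln[aln$identity >= minIdentity, , drop = FALSE]
  if (nrow(aln) == 0) return(aln)
  keep <- unlist(lapply(split(seq_len(nrow(aln)), aln$isotig_id),
                        function(idx) {
    if (length(idx) == 1) return(idx)
    best <- max(aln$identity[idx])
    top <- idx[aln$identity[idx] == best]
    if (length(top) > 1) integer(0) else top
  }), use.names = FALSE)
  aln[sort(keep), , drop = FALSE]
}

#' Check the GT-AG splice rule for a contig alignment
#'
#' Every gap between consecutive blocks must begin with GT and end with AG
#' on the alignment's strand. For a minus-strand alignment the genomic
#' plus-strand sequence of the intron must therefore read CT...AC
#' (the reverse complement). Single-block alignments pass vacuously.
#'
#' @param aln One row of an alignment data.frame (see
#'   \code{\link{readPsl}}), or a data.frame (checked row-wise).
#' @param genome A named \code{DNAStringSet}.
#' @return Logical (vector when \code{aln} has several rows).
#' @export
checkGtAg <- function(aln, genome) {
  one <- function(chrom, strand, starts, ends) {
    if (!chrom %in% names(genome))
      stop("chromosome ", chrom, " absent from genome")
    chrlen <- Biostrings::width(genome[chrom])
    if (any(starts < 0) || any(ends > chrlen))
      stop("block coordinates outside chromosome ", chrom)
    nb <- length(starts)
    if (nb < 2) return(TRUE)
    for (i in seq_len(nb - 1)) {
      i0 <- ends[i]        # 0-based intron start
      i1 <- starts[i + 1]  # 0-based intron end (exclusive)
      if (i1 - i0 < 4) return(FALSE)
      don <- as.character(Biostrings::subseq(genome[[chrom]], i0 + 1, i0 + 2))
      acp <- as.character(Biostrings::subseq(genome[[chrom]], i1 - 1, i1))
      ok <- if (strand == "+") don == "GT" && acp == "AG"
            else don == "CT" && acp == "AC"
      if (!ok) return(FALSE)
    }
    TRUE
  }
  vapply(seq_len(nrow(aln)), function(i)
    one(aln$chrom[i], aln$strand[i],
        aln$block_starts[[i]], aln$block_ends[[i]]),
    logical(1))
}

#' Assign antisense host genes to contig alignments
#'
#' A contig qualifies as novel antisense when its blocks overlap the exons
#' of a known transcript on the opposite strand and overlap no known exon
#' on its own strand (sense-concordant contigs are fragments of known
#' genes, not novel). The host is the opposite-strand known transcript with
#' the largest exonic overlap. With \code{nonoverlappedOnly = TRUE}
#' (default) only known genes that are not themselves antisense-overlapped
#' by another known gene are eligible hosts.
#'
#' @param aln Alignment data.frame (after
#'   \code{\link{filterIsotigAlignments}} and GT-AG filtering).
#' @param known A \code{\linkS4class{TranscriptSet}} of known models
#'   (after \code{\link{filterSingleLocus}}).
#' @param nonoverlappedOnly Restrict hosts to known transcripts without an
#'   antisense-overlapping known partner (default \code{TRUE}).
#' @return The rows of \code{aln} that qualify, with an added \code{host}
#'   column (host transcript accession).
#' @export
assignAntisenseHosts <- function(aln, known, nonoverlappedOnly = TRUE) {
  if (nrow(aln) == 0) { aln$host <- character(0); return(aln) }
  gr <- GenomicRanges::GRanges(
    seqnames = rep(aln$chrom, lengths(aln$block_starts)),
    ranges = IRanges::IRanges(
      start = unlist(aln$block_starts) + 1L,
      end = unlist(aln$block_ends)),
    strand = rep(aln$strand, lengths(aln$block_starts)))
  alnIdx <- rep(seq_len(nrow(aln)), lengths(aln$block_starts))
  gl <- exonRanges(known)
  ex <- unlist(gl, use.names = FALSE)
  txi <- rep(seq_along(gl), S4Vectors::elementNROWS(gl))
  hits <- GenomicRanges::findOverlaps(gr, ex, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  sameStrand <- as.character(GenomicRanges::strand(gr))[qh] ==
    as.character(GenomicRanges::strand(ex))[sh]
  senseHit <- unique(alnIdx[qh[sameStrand]])
  eligible <- rep(TRUE, length(known))
  if (nonoverlappedOnly) {
    pr <- findAntisenseOverlaps(known)
    overlappedAcc <- unique(c(pr@pairs$acc_a, pr@pairs$acc_b))
    eligible <- !(accessions(known) %in% overlappedAcc)
  }
  anti <- !sameStrand & eligible[txi[sh]]
  if (!any(anti)) {
    out <- aln[integer(0), , drop = FALSE]; out$host <- character(0)
    return(out)
  }
  w <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(gr)[qh[anti]], GenomicRanges::ranges(ex)[sh[anti]]))
  key <- paste(alnIdx[qh[anti]], txi[sh[anti]], sep = "|")
  tot <- rowsum(w, key)
  ids <- do.call(rbind, strsplit(rownames(tot), "|", fixed = TRUE))
  cand <- data.frame(alnIdx = as.integer(ids[, 1]),
                     tx = as.integer(ids[, 2]), bases = tot[, 1])
  cand <- cand[!(cand$alnIdx %in% senseHit), , drop = FALSE]
  if (nrow(cand) == 0) {
    out <- aln[integer(0), , drop = FALSE]; out$host <- character(0)
    return(out)
  }
  best <- do.call(rbind, lapply(split(cand, cand$alnIdx), function(d)
    d[which.max(d$bases), , drop = FALSE]))
  out <- aln[best$alnIdx, , drop = FALSE]
  out$host <- accessions(known)[best$tx]
  rownames(out) <- NULL
  out
}

#' Convert contig alignments to transcript models
#'
#' @param aln Alignment data.frame (with or without a \code{host} column).
#' @param gene Gene symbols (default: the isotig ids).
#' @return A \code{\linkS4class{TranscriptSet}}.
#' @export
alignmentsToTranscripts <- function(aln, gene = aln$isotig_id) {
  TranscriptSet(accession = aln$isotig_id, gene = gene,
                chrom = aln$chrom, strand = aln$strand,
                exonStarts = aln$block_starts, exonEnds = aln$block_ends)
}

#' Group antisense transcripts into novel genes
#'
#' Transcripts on the same chromosome and strand are merged into one novel
#' gene exactly when their exons overlap, taking the transitive closure;
#' transcripts without exonic overlap stay separate genes however close
#' their spans are. Gene ids (NAG0001, NAG0002, ...) are assigned in
#' genomic order (chromosome, then start).
#'
#' @param ts A \code{\linkS4class{TranscriptSet}} of novel transcripts.
#' @param hosts Optional named character vector (by accession) of host
#'   gene accessions.
#' @param readCounts Optional named numeric vector of weighted read counts.
#' @return Data.frame with one row per novel gene: \code{nag_id},
#'   \code{chrom}, \code{strand}, \code{n_transcripts}, \code{host},
#'   \code{read_count} and a list-column \code{members}.
#' @export
groupIntoGenes <- function(ts, hosts = NULL, readCounts = NULL) {
  n <- length(ts)
  if (n == 0)
    return(data.frame(nag_id = character(), chrom = character(),
                      strand = character(), n_transcripts = integer(),
                      host = character(), read_count = numeric()))
  gl <- exonRanges(ts)
  ex <- unlist(gl, use.names = FALSE)
  txi <- rep(seq_along(gl), S4Vectors::elementNROWS(gl))
  hits <- GenomicRanges::findOverlaps(ex, ex, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ## union-find over transcripts linked by same-strand exonic overlap
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (h in seq_along(qh)) {
    a <- txi[qh[h]]; b <- txi[sh[h]]
    if (a != b) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  spans <- txSpan(ts)
  groups <- split(seq_len(n), comp)
  ord <- order(vapply(groups, function(g)
    as.character(GenomicRanges::seqnames(spans))[g[1]], character(1)),
    vapply(groups, function(g)
      min(GenomicRanges::start(spans)[g]), numeric(1)))
  groups <- groups[ord]
  acc <- accessions(ts)
  out <- data.frame(
    nag_id = sprintf("NAG%04d", seq_along(groups)),
    chrom = vapply(groups, function(g)
      as.character(GenomicRanges::seqnames(spans))[g[1]], character(1)),
    strand = vapply(groups, function(g) txStrand(ts)[g[1]], character(1)),
    n_transcripts = lengths(groups),
    stringsAsFactors = FALSE)
  out$host <- vapply(groups, function(g) {
    if (is.null(hosts)) return(NA_character_)
    h <- unique(stats::na.omit(hosts[acc[g]]))
    if (length(h) == 0) NA_character_ else h[1]
  }, character(1))
  out$read_count <- vapply(groups, function(g) {
    if (is.null(readCounts)) return(NA_real_)
    sum(readCounts[acc[g]], na.rm = TRUE)
  }, numeric(1))
  out$members <- lapply(groups, function(g) acc[g])
  out
}

#' Write novel genes as a refFlat-format table with read counts
#'
#' One line per member transcript: the 11 refFlat columns (the novel gene
#' id as geneName) plus a \code{read_count} column.
#'
#' @param genes Data.frame from \code{\link{groupIntoGenes}}.
#' @param ts The \code{\linkS4class{TranscriptSet}} the groups refer to.
#' @param path Output path.
#' @param readCounts Optional named numeric vector of per-transcript counts.
#' @return Invisibly, \code{path}.
#' @export
writeNovelGenes <- function(genes, ts, path, readCounts = NULL) {
  acc <- unlist(genes$members, use.names = FALSE)
  gene <- rep(genes$nag_id, genes$n_transcripts)
  sub <- ts[acc]
  tmp <- tempfile()
  writeRefFlat(TranscriptSet(
    accession = acc, gene = gene, chrom = txChrom(sub), strand = txStrand(sub),
    exonStarts = lapply(exonRanges(sub), function(g) GenomicRanges::start(g) - 1L),
    exonEnds = lapply(exonRanges(sub), function(g) GenomicRanges::end(g))), tmp)
  lines <- readLines(tmp)
  rc <- if (is.null(readCounts)) rep(NA, length(acc)) else readCounts[acc]
  writeLines(paste(lines, rc, sep = "\t"), path)
  invisible(path)
}

#' Read a novel-antisense-transcript table
#'
#' Reads the refFlat-like layout used for reporting novel antisense
#' transcripts: header line, then columns transcript, chrom, strand,
#' txStart, txEnd, exonStarts, exonEnds, read_count (0-based half-open
#' coordinates, comma-separated exon lists). A packaged example is
#' available via
#' \code{system.file("extdata", "novel_antisense_genes.tsv",
#' package = "strandcheck")}.
#'
#' @param path Path to the TSV.
#' @return A list: \code{transcripts}
#'   (\code{\linkS4class{TranscriptSet}}), \code{readCounts} (named
#'   numeric).
#' @export
readNovelGeneTable <- function(path) {
  tbl <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  parseList <- function(s) as.integer(strsplit(sub(",+$", "", gsub(" ", "", s)), ",")[[1]])
  ts <- TranscriptSet(accession = tbl$transcript,
                      gene = sub("-[0-9]+$", "", tbl$transcript),
                      chrom = tbl$chrom, strand = tbl$strand,
                      exonStarts = lapply(tbl$exonStarts, parseList),
                      exonEnds = lapply(tbl$exonEnds, parseList))
  list(transcripts = ts,
       readCounts = setNames(tbl$read_count, tbl$transcript))
}

#' Fold-change comparison of novel genes sharing vs not sharing a host
#'
#' For every pair of novel genes overlapped by the same known gene the RPKM
#' fold change max/min is collected into the FCsame set; pairs with
#' different hosts form the FCdiff set. A one-sided Welch t-test on log2
#' fold changes asks whether same-host pairs have systematically smaller
#' fold changes (i.e. more similar expression) than cross-host pairs.
#'
#' @param nagRpkm Data.frame with columns \code{nag_id}, \code{host},
#'   \code{rpkm}.
#' @return A list: \code{fc_same}, \code{fc_diff} (numeric vectors, all
#'   >= 1), \code{t_statistic}, \code{p_value}, \code{n_skipped} (pairs
#'   dropped for zero RPKM).
#' @export
fcSameDiff <- function(nagRpkm) {
  stopifnot(all(c("nag_id", "host", "rpkm") %in% names(nagRpkm)))
  n <- nrow(nagRpkm)
  if (length(unique(nagRpkm$host)) < 2)
    stop("need novel genes from at least two hosts")
  pairs <- utils::combn(n, 2)
  r1 <- nagRpkm$rpkm[pairs[1, ]]; r2 <- nagRpkm$rpkm[pairs[2, ]]
  same <- nagRpkm$host[pairs[1, ]] == nagRpkm$host[pairs[2, ]]
  zero <- r1 == 0 | r2 == 0
  if (any(zero))
    warning(sum(zero), " pair(s) skipped for zero RPKM")
  fc <- pmax(r1, r2) / pmin(r1, r2)
  fc_same <- fc[same & !zero]
  fc_diff <- fc[!same & !zero]
  if (length(fc_same) < 2 || length(fc_diff) < 2)
    stop("need at least two pairs in each of FCsame and FCdiff")
  tt <- stats::t.test(log2(fc_same), log2(fc_diff), alternative = "less",
                      var.equal = FALSE)
  list(fc_same = fc_same, fc_diff = fc_diff,
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       n_skipped = sum(zero))
}
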