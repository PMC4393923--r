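#' Construct a TranscriptSet from exon coordinates
#'
#' Coordinates follow the UCSC refFlat convention: 0-based half-open. They
#' are stored internally as 1-based closed \code{GRanges}.
#'
#' @param accession Character vector of transcript ids.
#' @param gene Character vector of gene symbols.
#' @param chrom Character vector of chromosome names.
#' @param strand Character vector, \code{"+"} or \code{"-"}.
#' @param exonStarts,exonEnds Lists of integer vectors (parallel per
#'   transcript), 0-based half-open.
#' @param cdsStart,cdsEnd Optional integer vectors (default: transcript
#'   bounds).
#' @return A \code{\linkS4class{TranscriptSet}}.
#' @export
TranscriptSet <- function(accession, gene, chrom, strand, exonStarts,
                          exonEnds, cdsStart = NULL, cdsEnd = NULL) {
  n <- length(accession)
  stopifnot(length(gene) == n, length(chrom) == n, length(strand) == n,
            length(exonStarts) == n, length(exonEnds) == n)
  if (n == 0) {
    gl <- GenomicRanges::GRangesList()
    return(new("TranscriptSet", exons = gl, gene = character(),
               cds = matrix(integer(), ncol = 2,
                            dimnames = list(NULL, c("cdsStart", "cdsEnd")))))
  }
  nex <- lengths(exonStarts)
  if (!all(nex == lengths(exonEnds)))
    stop("exonStarts and exonEnds must have equal lengths per transcript")
  gr <- GenomicRanges::GRanges(
    seqnames = rep(chrom, nex),
    ranges = IRanges::IRanges(start = unlist(exonStarts) + 1L,
                              end = unlist(exonEnds)),
    strand = rep(strand, nex)
  )
  gl <- S4Vectors::split(gr, factor(rep(seq_len(n), nex),
                                    levels = seq_len(n)))
  names(gl) <- accession
  if (is.null(cdsStart)) cdsStart <- vapply(exonStarts, function(s) s[[1]], numeric(1))
  if (is.null(cdsEnd)) cdsEnd <- vapply(exonEnds, function(e) e[[length(e)]], numeric(1))
  cds <- cbind(cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd))
  new("TranscriptSet", exons = gl, gene = as.character(gene), cds = cds)
}

#' @describeIn TranscriptSet Number of transcript models.
#' @param x A \code{TranscriptSet}.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' @export
setMethod("accessions", "TranscriptSet", function(x) names(x@exons))

#' @export
setMethod("geneSymbols", "TranscriptSet",
          function(x) setNames(x@gene, names(x@exons)))

#' @export
setMethod("exonRanges", "TranscriptSet", function(x) x@exons)

#' Exonic (mRNA) length of each transcript
#'
#' Sum of exon widths -- the "initial length" used as the denominator of the
#' overlap percentage.
#'
#' @param x A \code{TranscriptSet}.
#' @return Named numeric vector of base counts.
#' @export
setMethod("exonicLength", "TranscriptSet", function(x) {
  setNames(as.numeric(sum(GenomicRanges::width(x@exons))), names(x@exons))
})

#' @export
setMethod("txStrand", "TranscriptSet", function(x) {
  setNames(as.character(unlist(S4Vectors::runValue(
    GenomicRanges::strand(x@exons)), use.names = FALSE)), names(x@exons))
})

#' @export
setMethod("txChrom", "TranscriptSet", function(x) {
  setNames(as.character(unlist(S4Vectors::runValue(
    GenomicRanges::seqnames(x@exons)), use.names = FALSE)), names(x@exons))
})

#' @export
setMethod("txSpan", "TranscriptSet", function(x) {
  unlist(range(x@exons))
})

setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@exons))
  new("TranscriptSet", exons = x@exons[i], gene = x@gene[i],
      cds = x@cds[i, , drop = FALSE])
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object), "transcript model(s) from",
      length(unique(object@gene)), "gene(s)\n")
  if (length(object) > 0) {
    st <- table(txStrand(object))
    cat("  strands: ", paste(names(st), st, sep = ":", collapse = "  "), "\n")
    acc <- accessions(object)
    cat("  accessions:", paste(utils::head(acc, 5), collapse = ", "),
        if (length(acc) > 5) "..." else "", "\n")
  }
})

#' Read a refFlat gene-model table
#'
#' Parses the 11-column UCSC refFlat dialect (geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds) with
#' 0-based half-open coordinates and comma-terminated exon lists.
#'
#' @param path Path to a tab-separated refFlat file (no header).
#' @return A \code{\linkS4class{TranscriptSet}}.
#' @export
readRefFlat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(TranscriptSet(character(), character(), character(), character(),
                         list(), list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 11L)
  if (length(bad))
    stop("refFlat parse error at line ", bad[1], ": expected 11 fields, got ",
         length(fields[[bad[1]]]))
  m <- do.call(rbind, fields)
  parse_list <- function(s, line) {
    v <- suppressWarnings(as.integer(strsplit(sub(",+$", "", s), ",")[[1]]))
    if (anyNA(v))
      stop("refFlat parse error at line ", line, ": non-integer exon coordinate")
    v
  }
  n <- nrow(m)
  exonStarts <- vector("list", n); exonEnds <- vector("list", n)
  for (i in seq_len(n)) {
    exonStarts[[i]] <- parse_list(m[i, 10], i)
    exonEnds[[i]] <- parse_list(m[i, 11], i)
    cnt <- suppressWarnings(as.integer(m[i, 9]))
    if (is.na(cnt))
      stop("refFlat parse error at line ", i, ": non-integer exonCount")
    if (length(exonStarts[[i]]) != cnt || length(exonEnds[[i]]) != cnt)
      stop("refFlat parse error at line ", i, ": exonCount ", cnt,
           " does not match exon list lengths")
  }
  coord <- suppressWarnings(apply(m[, 5:8, drop = FALSE], 2, as.numeric))
  coord <- matrix(coord, nrow = n)
  if (anyNA(coord))
    stop("refFlat parse error at line ", which(is.na(coord))[1] %% n,
         ": non-integer coordinate")
  txStart <- coord[, 1]; txEnd <- coord[, 2]
  first <- vapply(exonStarts, function(s) s[[1]], numeric(1))
  last <- vapply(exonEnds, function(e) e[[length(e)]], numeric(1))
  bad <- which(first != txStart | last != txEnd)
  if (length(bad))
    stop("refFlat parse error at line ", bad[1],
         ": txStart/txEnd do not match exon bounds")
  TranscriptSet(accession = m[, 2], gene = m[, 1], chrom = m[, 3],
                strand = m[, 4], exonStarts = exonStarts,
                exonEnds = exonEnds,
                cdsStart = coord[, 3], cdsEnd = coord[, 4])
}

#' Write a TranscriptSet as a refFlat table
#'
#' @param x A \code{TranscriptSet}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeRefFlat <- function(x, path) {
  n <- length(x)
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- x@exons[[i]]
    s0 <- GenomicRanges::start(g) - 1L
    e0 <- GenomicRanges::end(g)
    lines[i] <- paste(
      x@gene[i], names(x@exons)[i],
      as.character(GenomicRanges::seqnames(g))[1],
      as.character(GenomicRanges::strand(g))[1],
      s0[1], e0[length(e0)], x@cds[i, 1], x@cds[i, 2], length(g),
      paste0(paste(s0, collapse = ","), ","),
      paste0(paste(e0, collapse = ","), ","),
      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Restrict to transcripts with a single genomic locus
#'
#' A transcript whose accession appears on more than one refFlat line maps
#' to multiple genomic loci; all its records are dropped. Input order is
#' preserved for the survivors.
#'
#' @param x A \code{TranscriptSet}.
#' @return A \code{TranscriptSet} of single-locus transcripts.
#' @export
filterSingleLocus <- function(x) {
  acc <- accessions(x)
  keep <- acc %in% names(which(table(acc) == 1L))
  x[which(keep)]
}

#' Detect mutually antisense-overlapped transcript pairs
#'
#' Finds every unordered pair of transcripts on the same chromosome and
#' opposite strands whose exons intersect in genomic space. The shared
#' exonic base count is exact (exon intersections within a pair are
#' disjoint, so per-exon widths sum without double counting). Each side's
#' overlap percentage divides by that transcript's exonic length.
#'
#' @param x A \code{TranscriptSet}, typically after
#'   \code{\link{filterSingleLocus}}.
#' @return An \code{\linkS4class{OverlapPairs}}.
#' @export
findAntisenseOverlaps <- function(x) {
  empty <- S4Vectors::DataFrame(acc_a = character(), acc_b = character(),
                                shared_exonic_bases = numeric(),
                                overlap_pct_a = numeric(),
                                overlap_pct_b = numeric())
  if (length(x) < 2) return(new("OverlapPairs", pairs = empty))
  gl <- x@exons
  gr <- unlist(gl, use.names = FALSE)
  txi <- rep(seq_along(gl), S4Vectors::elementNROWS(gl))
  plus <- as.logical(GenomicRanges::strand(gr) == "+")
  gp <- gr[plus]; gm <- gr[!plus]
  ip <- txi[plus]; im <- txi[!plus]
  hits <- GenomicRanges::findOverlaps(gp, gm, ignore.strand = TRUE)
  if (length(hits) == 0) return(new("OverlapPairs", pairs = empty))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  w <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(gp)[qh], GenomicRanges::ranges(gm)[sh]))
  key <- paste(ip[qh], im[sh], sep = "|")
  shared <- rowsum(w, key)
  ids <- do.call(rbind, strsplit(rownames(shared), "|", fixed = TRUE))
  ia <- as.integer(ids[, 1]); ib <- as.integer(ids[, 2])
  len <- exonicLength(x)
  acc <- accessions(x)
  ord <- order(ia, ib)
  ia <- ia[ord]; ib <- ib[ord]; shared <- shared[ord, 1]
  df <- S4Vectors::DataFrame(
    acc_a = acc[ia], acc_b = acc[ib],
    shared_exonic_bases = as.numeric(shared),
    overlap_pct_a = 100 * shared / len[ia],
    overlap_pct_b = 100 * shared / len[ib])
  new("OverlapPairs", pairs = df)
}

#' @export
setMethod("length", "OverlapPairs", function(x) nrow(x@pairs))

#' @export
setMethod("overlapTable", "OverlapPairs",
          function(x) as.data.frame(x@pairs))

setMethod("show", "OverlapPairs", function(object) {
  cat("OverlapPairs with", nrow(object@pairs), "antisense-overlapped pair(s)\n")
  if (nrow(object@pairs) > 0) {
    pct <- c(object@pairs$overlap_pct_a, object@pairs$overlap_pct_b)
    cat(sprintf("  overlap percentage: median %.2f%%, max %.2f%%\n",
                stats::median(pct), max(pct)))
  }
})

#' Per-transcript maximum overlap percentage
#'
#' A transcript may be overlapped by several antisense partners; for
#' stratifying analyses each transcript is assigned its maximum overlap
#' percentage over all its pairs.
#'
#' @param x An \code{OverlapPairs}.
#' @param accession Optional character vector restricting/ordering the
#'   output; transcripts absent from every pair get 0.
#' @return Named numeric vector of percentages.
#' @export
setMethod("maxOverlapPct", "OverlapPairs", function(x, accession = NULL) {
  df <- x@pairs
  acc <- c(df$acc_a, df$acc_b)
  pct <- c(df$overlap_pct_a, df$overlap_pct_b)
  res <- tapply(pct, acc, max)
  out <- setNames(as.numeric(res), names(res))
  if (!is.null(accession)) {
    out <- setNames(ifelse(accession %in% names(out),
                           out[accession], 0), accession)
  }
  out
})
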