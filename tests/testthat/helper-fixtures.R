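# Fixture builders shared across test files. Everything is constructed in
# code; no binary fixtures.

# A synthetic two-transcript geometry emulating the published KHNYN/SDR39U1
# antisense pair: an 8-exon plus-strand transcript of mRNA length 2500 whose
# last exon is overlapped by the first two genomic exons of a 6-exon
# minus-strand transcript of mRNA length 489, sharing 346 exonic bases --
# so the overlap percentages are 346/2500 = 13.84% and 346/489 = 70.76%.
khnynLikePair <- function() {
  aStarts <- 10000 + 750 * (0:7)
  aEnds <- c(aStarts[1:7] + 250, aStarts[8] + 750)
  bStarts <- c(15300, 15600, 16500, 17000, 17500, 18000)
  bEnds <- c(15500, 15746, 16540, 17040, 17540, 18023)
  TranscriptSet(
    accession = c("NM_015299", "NM_020195"),
    gene = c("KHNYN", "SDR39U1"),
    chrom = c("chr14", "chr14"),
    strand = c("+", "-"),
    exonStarts = list(aStarts, bStarts),
    exonEnds = list(aEnds, bEnds))
}

# Random small annotation on one chromosome; transcripts may overlap freely.
randomAnnotation <- function(nTx, chromLen = 5000, maxExons = 3) {
  strand <- sample(c("+", "-"), nTx, replace = TRUE)
  exS <- vector("list", nTx); exE <- vector("list", nTx)
  for (i in seq_len(nTx)) {
    ne <- sample.int(maxExons, 1)
    bounds <- sort(sample.int(chromLen - 1, 2 * ne))
    bounds <- bounds + 2L * (seq_along(bounds) - 1L)  # enforce exon gaps
    exS[[i]] <- bounds[seq(1, 2 * ne, 2)] - 1
    exE[[i]] <- bounds[seq(2, 2 * ne, 2)]
  }
  TranscriptSet(accession = sprintf("TX%03d", seq_len(nTx)),
                gene = sprintf("G%03d", seq_len(nTx)),
                chrom = rep("chr1", nTx), strand = strand,
                exonStarts = exS, exonEnds = exE)
}

# Per-base boolean-mask oracle for shared exonic bases between antisense
# transcripts; independent of the interval-tree path under test.
sharedBasesOracle <- function(ts, chromLen = 10000) {
  acc <- accessions(ts)
  str <- txStrand(ts)
  chr <- txChrom(ts)
  gl <- exonRanges(ts)
  masks <- lapply(seq_along(gl), function(i) {
    m <- logical(chromLen)
    g <- gl[[i]]
    for (j in seq_along(g))
      m[seq(GenomicRanges::start(g)[j], GenomicRanges::end(g)[j])] <- TRUE
    m
  })
  out <- list()
  for (i in seq_len(length(ts) - 1)) {
    for (j in seq(i + 1, length(ts))) {
      if (chr[i] != chr[j] || str[i] == str[j]) next
      s <- sum(masks[[i]] & masks[[j]])
      if (s > 0)
        out[[length(out) + 1]] <- data.frame(
          acc_a = acc[i], acc_b = acc[j], shared = s)
    }
  }
  if (length(out) == 0)
    return(data.frame(acc_a = character(), acc_b = character(),
                      shared = numeric()))
  do.call(rbind, out)
}

# Minimal single-pair annotation: plus-strand A and minus-strand B,
# single-exon each, sharing `shared` genomic bases.
simplePair <- function(lenA = 2000, lenB = 2000, shared = 1400,
                       offset = 1000) {
  TranscriptSet(c("A", "B"), c("GA", "GB"), c("chr1", "chr1"), c("+", "-"),
                exonStarts = list(offset, offset + lenA - shared),
                exonEnds = list(offset + lenA, offset + lenA - shared + lenB))
}

# Write a SAM file from scratch lines (header built from refLengths).
writeRawSam <- function(lines, refLengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(refLengths), "\tLN:", refLengths))
  writeLines(c(hdr, lines), path)
  path
}

# Expand a qPCR-style fixture path.
qpcrFixture <- function() {
  system.file("extdata", "qpcr_ags_12genes.tsv", package = "strandcheck")
}

novelGeneFixture <- function() {
  system.file("extdata", "novel_antisense_genes.tsv", package = "strandcheck")
}

# One simulated expression table pair (SS sense-only vs NSS both) from a
# shared abundance vector; used by the correlation tests.
simulatedExpressionPair <- function(cfg, ts, abundances, pairs,
                                    seedSS, seedNSS) {
  cfgSS <- cfg; cfgSS$protocol <- "SS"; cfgSS$leakageP <- 0; cfgSS$seed <- seedSS
  cfgNS <- cfg; cfgNS$protocol <- "NSS"; cfgNS$seed <- seedNSS
  simSS <- simulateReads(cfgSS, ts, abundances = abundances, pairs = pairs)
  simNS <- simulateReads(cfgNS, ts, abundances = abundances, pairs = pairs)
  crSS <- countReads(simSS$alignments, ts, "sense_only")
  crNS <- countReads(simNS$alignments, ts, "both")
  list(ss = computeRpkm(crSS$counts, exonicLength(ts), crSS$libraryMappedReads),
       nss = computeRpkm(crNS$counts, exonicLength(ts), crNS$libraryMappedReads))
}
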