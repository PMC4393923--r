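# helper: one PSL line from components
pslLine <- function(matches, mismatches, qNumInsert, strand, name, qSize,
                    chrom, tSize, starts, ends) {
  sizes <- ends - starts
  paste(matches, mismatches, 0, 0, qNumInsert, 0, length(starts) - 1,
        if (length(starts) > 1) sum(starts[-1] - ends[-length(ends)]) else 0,
        strand, name, qSize, 0, qSize, chrom, tSize,
        starts[1], ends[length(ends)], length(starts),
        paste0(paste(sizes, collapse = ","), ","),
        paste0(paste(cumsum(c(0, head(sizes, -1))), collapse = ","), ","),
        paste0(paste(starts, collapse = ","), ","),
        sep = "\t")
}

test_that("PSL parsing computes identity and block coordinates", {
  f <- tempfile(fileext = ".psl")
  writeLines(c(
    pslLine(95, 5, 0, "+", "iso1", 100, "chr1", 10000, c(100, 500), c(150, 550)),
    pslLine(9499, 501, 0, "-", "iso2", 10000, "chr2", 10000, 1000, 10499)), f)
  a <- readPsl(f)
  expect_equal(nrow(a), 2L)
  expect_equal(a$identity, c(0.95, 0.9499))
  expect_equal(a$block_starts[[1]], c(100L, 500L))
  expect_equal(a$block_ends[[1]], c(150L, 550L))
  expect_equal(a$strand, c("+", "-"))
  # malformed record
  writeLines("only\tthree\tfields", f)
  expect_error(readPsl(f), "21 fields")
})

test_that("identity filter is boundary-inclusive and keeps the best locus", {
  f <- tempfile(fileext = ".psl")
  writeLines(c(
    pslLine(95, 5, 0, "+", "edge", 100, "chr1", 1e4, 0, 100),
    pslLine(9499, 501, 0, "+", "below", 10000, "chr1", 1e4, 200, 10200),
    pslLine(99, 1, 0, "+", "multi", 100, "chr1", 1e4, 400, 500),
    pslLine(96, 4, 0, "+", "multi", 100, "chr2", 1e4, 400, 500),
    pslLine(98, 2, 0, "+", "tied", 100, "chr1", 1e4, 600, 700),
    pslLine(98, 2, 0, "+", "tied", 100, "chr2", 1e4, 600, 700)), f)
  out <- filterIsotigAlignments(readPsl(f), minIdentity = 0.95)
  expect_true("edge" %in% out$isotig_id)        # exactly 0.95 kept
  expect_false("below" %in% out$isotig_id)      # 0.9499 dropped
  expect_equal(sum(out$isotig_id == "multi"), 1L)
  expect_equal(out$chrom[out$isotig_id == "multi"], "chr1")  # best identity
  expect_false("tied" %in% out$isotig_id)       # ambiguous tie dropped
})

test_that("GT-AG rule is strand-aware and strict", {
  # chr1: intron [110,150) reads GT..AG on plus; chr2 intron reads CT..AC
  s1 <- paste0(strrep("A", 110), "GT", strrep("A", 36), "AG", strrep("A", 100))
  s2 <- paste0(strrep("A", 110), "CT", strrep("A", 36), "AC", strrep("A", 100))
  s3 <- paste0(strrep("A", 110), "GC", strrep("A", 36), "AG", strrep("A", 100))
  genome <- Biostrings::DNAStringSet(c(chr1 = s1, chr2 = s2, chr3 = s3))
  mk <- function(chrom, strand) data.frame(
    isotig_id = "i", chrom = chrom, strand = strand, matches = 100L,
    mismatches = 0L, q_num_insert = 0L, query_size = 100L,
    block_count = 2L, identity = 1,
    block_starts = I(list(c(50L, 150L))), block_ends = I(list(c(110L, 210L))),
    stringsAsFactors = FALSE)
  expect_true(checkGtAg(mk("chr1", "+"), genome))
  expect_false(checkGtAg(mk("chr1", "-"), genome))
  expect_true(checkGtAg(mk("chr2", "-"), genome))
  expect_false(checkGtAg(mk("chr2", "+"), genome))
  expect_false(checkGtAg(mk("chr3", "+"), genome))  # GC-AG rejected
  # single block passes vacuously
  one <- mk("chr3", "+"); one$block_starts <- I(list(50L)); one$block_ends <- I(list(110L)); one$block_count <- 1L
  expect_true(checkGtAg(one, genome))
  # reverse-complement construction agrees with the minus-strand check
  rc <- Biostrings::DNAStringSet(c(chr2rc = as.character(
    Biostrings::reverseComplement(genome[["chr2"]]))))
  L <- Biostrings::width(genome["chr2"])
  mkrc <- mk("chr2rc", "+")
  mkrc$block_starts <- I(list(L - c(210L, 110L)))
  mkrc$block_ends <- I(list(L - c(150L, 50L)))
  expect_identical(checkGtAg(mkrc, rc), checkGtAg(mk("chr2", "-"), genome))
  # coordinates beyond the chromosome raise
  far <- mk("chr1", "+"); far$block_ends <- I(list(c(110L, 10000L)))
  expect_error(checkGtAg(far, genome), "outside")
})

test_that("antisense host assignment discards sense-concordant and intergenic contigs", {
  known <- TranscriptSet(c("NM_host", "NM_other"), c("PTOV1L", "OTH"),
                         c("chr19", "chr19"), c("+", "+"),
                         exonStarts = list(c(1000, 3000), 9000),
                         exonEnds = list(c(2000, 4000), 9500))
  aln <- data.frame(
    isotig_id = c("anti1", "sense1", "inter1"),
    chrom = "chr19", strand = c("-", "+", "-"),
    matches = 100L, mismatches = 0L, q_num_insert = 0L, query_size = 100L,
    block_count = 1L, identity = 1,
    block_starts = I(list(1200L, 1300L, 6000L)),
    block_ends = I(list(1700L, 1800L, 6400L)),
    stringsAsFactors = FALSE)
  out <- assignAntisenseHosts(aln, known)
  expect_equal(out$isotig_id, "anti1")
  expect_equal(out$host, "NM_host")
})

test_that("host restriction to nonoverlapped genes can be relaxed", {
  # host itself is antisense-overlapped by another known gene
  known <- TranscriptSet(c("NM_A", "NM_B"), c("gA", "gB"),
                         c("chr1", "chr1"), c("+", "-"),
                         exonStarts = list(1000, 1500),
                         exonEnds = list(2000, 2600))
  aln <- data.frame(
    isotig_id = "iso", chrom = "chr1", strand = "-",
    matches = 50L, mismatches = 0L, q_num_insert = 0L, query_size = 50L,
    block_count = 1L, identity = 1,
    block_starts = I(list(1050L)), block_ends = I(list(1150L)),
    stringsAsFactors = FALSE)
  expect_equal(nrow(assignAntisenseHosts(aln, known)), 0L)
  rel <- assignAntisenseHosts(aln, known, nonoverlappedOnly = FALSE)
  expect_equal(rel$host, "NM_A")
})

test_that("published novel transcripts group into the published gene structure", {
  nt <- readNovelGeneTable(novelGeneFixture())
  g <- groupIntoGenes(nt$transcripts, readCounts = nt$readCounts)
  expect_equal(nrow(g), 5L)
  chr19 <- g[g$chrom == "chr19", ]
  expect_equal(nrow(chr19), 2L)   # two independent genes despite <500 b gap
  expect_setequal(chr19$members[[1]], c("NAG0001-1", "NAG0001-2"))
  expect_setequal(chr19$members[[2]], c("NAG0002-1", "NAG0002-2"))
  expect_equal(chr19$nag_id, c("NAG0001", "NAG0002"))  # genomic order
  expect_equal(chr19$read_count, c(180 + 34, 121 + 125.5))
  # grouping is a partition
  expect_setequal(unlist(g$members), accessions(nt$transcripts))
  expect_equal(sum(g$n_transcripts), length(nt$transcripts))
})

test_that("grouping takes the transitive closure and ignores input order", {
  # a-b overlap, b-c overlap, a-c do not: one gene of three
  mk <- function(perm) {
    ts <- TranscriptSet(c("a", "b", "c")[perm], c("x", "x", "x")[perm],
                        rep("chr1", 3), rep("-", 3),
                        exonStarts = list(0, 80, 160)[perm],
                        exonEnds = list(100, 180, 260)[perm])
    groupIntoGenes(ts)
  }
  g <- mk(1:3)
  expect_equal(nrow(g), 1L)
  expect_setequal(g$members[[1]], c("a", "b", "c"))
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    g2 <- mk(perm)
    expect_equal(nrow(g2), 1L)
    expect_setequal(g2$members[[1]], c("a", "b", "c"))
  }
  # single transcript forms its own gene
  single <- TranscriptSet("solo", "s", "chr1", "+", list(0), list(50))
  expect_equal(nrow(groupIntoGenes(single)), 1L)
})

test_that("novel genes serialize to a refFlat-style table with read counts", {
  nt <- readNovelGeneTable(novelGeneFixture())
  g <- groupIntoGenes(nt$transcripts, readCounts = nt$readCounts)
  f <- tempfile()
  writeNovelGenes(g, nt$transcripts, f, readCounts = nt$readCounts)
  lines <- strsplit(readLines(f), "\t")
  expect_true(all(lengths(lines) == 12L))
  rc <- as.numeric(vapply(lines, `[[`, character(1), 12))
  expect_equal(sum(rc), sum(nt$readCounts))
})

test_that("FCsame/FCdiff contrasts same-host against cross-host fold changes", {
  # schema: {a,b,c} share host A, {d,e} share host B
  nag <- data.frame(nag_id = letters[1:5],
                    host = c("A", "A", "A", "B", "B"),
                    rpkm = c(10, 12, 9, 200, 170))
  out <- fcSameDiff(nag)
  expect_equal(length(out$fc_same), choose(3, 2) + choose(2, 2))  # 4
  expect_equal(length(out$fc_diff), 3 * 2)                        # 6
  expect_true(all(out$fc_same >= 1) && all(out$fc_diff >= 1))
  expect_lt(out$p_value, 0.05)
  expect_equal(min(out$fc_same), 10 / 9, tolerance = 1e-12)
  # equal abundances give fold change exactly 1
  expect_equal(fcSameDiff(data.frame(
    nag_id = c("p", "q", "r", "s"), host = c("A", "A", "B", "B"),
    rpkm = c(7, 7, 50, 60)))$fc_same[1], 1)
  # zero RPKM pairs skipped with a warning
  nag0 <- rbind(nag, data.frame(nag_id = "f", host = "B", rpkm = 0))
  expect_warning(out0 <- fcSameDiff(nag0), "zero")
  expect_equal(out0$n_skipped, 5L)
  # synthetic separation: same-host within 10%, cross-host spans 100x
  set.seed(33)
  hosts <- rep(sprintf("H%d", 1:8), each = 2)
  base <- rep(10^runif(8, 0, 2), each = 2)
  nag2 <- data.frame(nag_id = sprintf("n%02d", 1:16), host = hosts,
                     rpkm = base * runif(16, 0.9, 1.1))
  out2 <- fcSameDiff(nag2)
  expect_lt(out2$p_value, 0.001)
})
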