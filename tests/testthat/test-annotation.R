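test_that("refFlat parsing round-trips coordinates and tolerates trailing commas", {
  lines <- c(
    "NAG0001\tNAG0001-1\tchr19\t-\t50361371\t50362420\t50361371\t50362420\t2\t50361371,50362099,\t50361883,50362420,",
    "GENEX\tNM_X\tchr1\t+\t100\t900\t100\t900\t2\t100,500,\t300,900,")
  f <- tempfile()
  writeLines(lines, f)
  ts <- readRefFlat(f)
  expect_s4_class(ts, "TranscriptSet")
  expect_equal(length(ts), 2L)
  expect_equal(accessions(ts), c("NAG0001-1", "NM_X"))
  expect_equal(unname(txChrom(ts)), c("chr19", "chr1"))
  expect_equal(unname(txStrand(ts)), c("-", "+"))
  g <- exonRanges(ts)[["NAG0001-1"]]
  expect_equal(GenomicRanges::start(g) - 1L, c(50361371L, 50362099L))
  expect_equal(GenomicRanges::end(g), c(50361883L, 50362420L))
  # write and re-read
  f2 <- tempfile()
  writeRefFlat(ts, f2)
  ts2 <- readRefFlat(f2)
  expect_equal(accessions(ts2), accessions(ts))
  expect_equal(exonicLength(ts2), exonicLength(ts))
})

test_that("refFlat parse errors name the offending line", {
  f <- tempfile()
  writeLines(c("G\tT1\tchr1\t+\t0\t10\t0\t10\t1\t0,\t10,",
               "G\tT2\tchr1\t+\t0\t10\t0\t10\t2\t0,5,8,\t3,10,12,"), f)
  expect_error(readRefFlat(f), "line 2")
  writeLines("G\tT1\tchr1\t+", f)
  expect_error(readRefFlat(f), "line 1")
  writeLines("G\tT1\tchr1\t+\t0\tten\t0\t10\t1\t0,\t10,", f)
  expect_error(readRefFlat(f), "coordinate")
  # empty file gives an empty set
  writeLines(character(0), f)
  expect_equal(length(readRefFlat(f)), 0L)
})

test_that("exonic length sums exon widths", {
  nt <- readNovelGeneTable(novelGeneFixture())
  len <- exonicLength(nt$transcripts)
  expect_equal(unname(len["NAG0002-1"]), 1276)
  expect_equal(unname(len["NAG0001-1"]), (50361883 - 50361371) + (50362420 - 50362099))
  toy <- TranscriptSet("T", "G", "chr1", "+", list(c(0, 20)), list(c(10, 30)))
  expect_equal(unname(exonicLength(toy)), 20)
})

test_that("multi-locus transcripts are removed, order preserved", {
  ts <- TranscriptSet(c("X", "X", "Y", "Z"), c("gX", "gX", "gY", "gZ"),
                      c("chr1", "chr2", "chr3", "chr1"), rep("+", 4),
                      exonStarts = list(0, 0, 0, 50),
                      exonEnds = list(10, 10, 10, 80))
  out <- filterSingleLocus(ts)
  expect_equal(accessions(out), c("Y", "Z"))
  # identity on all-unique input
  expect_equal(accessions(filterSingleLocus(out)), c("Y", "Z"))
  # brute-force count oracle on random duplication patterns
  set.seed(41)
  for (i in 1:5) {
    n <- 30
    acc <- sprintf("T%02d", sample.int(20, n, replace = TRUE))
    ts <- TranscriptSet(acc, acc, rep("chr1", n), rep("+", n),
                        exonStarts = as.list(seq_len(n) * 100),
                        exonEnds = as.list(seq_len(n) * 100 + 50))
    expected <- sum(table(acc) == 1)
    expect_equal(length(filterSingleLocus(ts)), expected)
  }
})

test_that("antisense overlap detection requires opposite strands and exonic intersection", {
  # same strand, overlapping: no pair
  ss <- TranscriptSet(c("A", "B"), c("gA", "gB"), c("chr1", "chr1"),
                      c("+", "+"), list(0, 50), list(100, 150))
  expect_equal(length(findAntisenseOverlaps(ss)), 0L)
  # opposite strands, exons interleaved (intron-only overlap): no pair
  io <- TranscriptSet(c("A", "B"), c("gA", "gB"), c("chr1", "chr1"),
                      c("+", "-"),
                      exonStarts = list(c(0, 200), c(110, 310)),
                      exonEnds = list(c(100, 300), c(190, 400)))
  expect_equal(length(findAntisenseOverlaps(io)), 0L)
  # different chromosomes: no pair
  dc <- TranscriptSet(c("A", "B"), c("gA", "gB"), c("chr1", "chr2"),
                      c("+", "-"), list(0, 0), list(100, 100))
  expect_equal(length(findAntisenseOverlaps(dc)), 0L)
  # a genuine pair
  pr <- findAntisenseOverlaps(simplePair(lenA = 1000, lenB = 500, shared = 200))
  tab <- overlapTable(pr)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$shared_exonic_bases, 200)
  expect_equal(tab$overlap_pct_a, 20)
  expect_equal(tab$overlap_pct_b, 40)
})

test_that("overlap percentages are symmetric through the shared base count", {
  set.seed(7)
  for (i in 1:10) {
    ts <- randomAnnotation(12)
    pr <- findAntisenseOverlaps(ts)
    tab <- overlapTable(pr)
    if (nrow(tab) == 0) next
    len <- exonicLength(ts)
    expect_equal(tab$overlap_pct_a / 100 * len[tab$acc_a],
                 tab$shared_exonic_bases, ignore_attr = TRUE)
    expect_equal(tab$overlap_pct_b / 100 * len[tab$acc_b],
                 tab$shared_exonic_bases, ignore_attr = TRUE)
  }
})

test_that("shared exonic bases match the per-base mask oracle", {
  set.seed(11)
  for (i in 1:20) {
    ts <- randomAnnotation(10)
    got <- overlapTable(findAntisenseOverlaps(ts))
    want <- sharedBasesOracle(ts)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    expect_equal(nrow(got), nrow(want))
    expect_equal(
      got$shared_exonic_bases[order(key(got$acc_a, got$acc_b))],
      want$shared[order(key(want$acc_a, want$acc_b))])
  }
})

test_that("extending an exon into the partner never decreases shared bases", {
  base <- simplePair(lenA = 1000, lenB = 1000, shared = 300)
  s0 <- overlapTable(findAntisenseOverlaps(base))$shared_exonic_bases
  for (ext in c(50, 200, 400)) {
    # extend B's exon further left into A
    ts <- TranscriptSet(c("A", "B"), c("GA", "GB"), c("chr1", "chr1"),
                        c("+", "-"),
                        exonStarts = list(1000, 1700 - ext),
                        exonEnds = list(2000, 2700))
    s1 <- overlapTable(findAntisenseOverlaps(ts))$shared_exonic_bases
    expect_gte(s1, s0)
    s0 <- s1
  }
})

test_that("a reconstructed KHNYN/SDR39U1-like geometry yields the published overlap values", {
  pr <- findAntisenseOverlaps(khnynLikePair())
  tab <- overlapTable(pr)
  expect_equal(nrow(tab), 1L)
  pct <- setNames(c(tab$overlap_pct_a, tab$overlap_pct_b),
                  c(tab$acc_a, tab$acc_b))
  expect_equal(round(unname(pct["NM_015299"]), 2), 13.84)
  expect_equal(round(unname(pct["NM_020195"]), 2), 70.76)
})

test_that("maximum overlap percentage aggregates over multiple partners", {
  # A overlapped by B (20%) and C (50%)
  ts <- TranscriptSet(c("A", "B", "C"), c("gA", "gB", "gC"),
                      rep("chr1", 3), c("+", "-", "-"),
                      exonStarts = list(0, 800, 300),
                      exonEnds = list(1000, 1200, 550))
  mo <- maxOverlapPct(findAntisenseOverlaps(ts), accession = accessions(ts))
  expect_equal(unname(mo["A"]), 25)  # C shares 250 of A's 1000
  expect_equal(unname(mo["C"]), 100) # C entirely inside A
  expect_equal(unname(mo["B"]), 50)  # B shares 200 of its 400
})
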