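#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with validated
#' defaults. The defaults describe a small desk-scale study: one 1 Mb
#' chromosome, 60 genes of which 40\% form antisense-overlapped pairs with
#' overlap fractions spread over (0.1, 0.9), 101-base single-end reads,
#' log-normal true abundances, Beta(1, 2) 5'-biased fragment starts, a
#' strand-leakage probability of 0.13 for SS libraries, and qPCR Ct noise
#' of 0.1 cycles.
#'
#' @param seed Integer seed; every generator is deterministic given
#'   (seed, config).
#' @param nChromosomes,chromLength Genome shape.
#' @param nGenes Number of known genes (pairs count as two).
#' @param fractionAntisensePairs Fraction of genes placed as antisense
#'   pairs.
#' @param overlapRange Range of target overlap fractions for pairs,
#'   within (0, 1].
#' @param exonCountRange,exonLengthRange,intronLengthRange Singleton gene
#'   architecture (bases).
#' @param pairLengthRange Exonic length range of pair members (bases).
#' @param abundanceMeanlog,abundanceSdlog Log-normal true-abundance
#'   parameters.
#' @param nReads Library size.
#' @param readLength Read length in bases (default 101).
#' @param protocol \code{"SS"} or \code{"NSS"}.
#' @param leakageP Probability a strand-specific read reports the wrong
#'   strand, in [0, 0.5].
#' @param positionalBias Beta shape parameters for the fragment start
#'   position along the transcript (default c(1, 2): 5'-biased).
#' @param ctNoiseSd qPCR Ct replicate noise SD in cycles.
#' @param ctBaseline Ct of a unit-abundance gene.
#' @param ctReplicates qPCR replicates per gene.
#' @param nPlantedNags Number of host genes that receive planted novel
#'   antisense transcripts.
#' @param nagsPerHost Planted transcripts per host (mutually
#'   exon-overlapping, hence one novel gene per host).
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L,
                             nChromosomes = 1L,
                             chromLength = 1e6,
                             nGenes = 60L,
                             fractionAntisensePairs = 0.4,
                             overlapRange = c(0.1, 0.9),
                             exonCountRange = c(1L, 6L),
                             exonLengthRange = c(150L, 400L),
                             intronLengthRange = c(200L, 800L),
                             pairLengthRange = c(800L, 2500L),
                             abundanceMeanlog = 0,
                             abundanceSdlog = 1.5,
                             nReads = 1e5,
                             readLength = 101L,
                             protocol = c("SS", "NSS"),
                             leakageP = 0.13,
                             positionalBias = c(1, 2),
                             ctNoiseSd = 0.1,
                             ctBaseline = 30,
                             ctReplicates = 3L,
                             nPlantedNags = 0L,
                             nagsPerHost = 2L) {
  protocol <- match.arg(protocol)
  if (leakageP < 0 || leakageP > 0.5)
    stop("leakageP must lie in [0, 0.5]")
  if (any(overlapRange <= 0) || any(overlapRange > 1))
    stop("overlapRange must lie in (0, 1]")
  if (fractionAntisensePairs < 0 || fractionAntisensePairs > 1)
    stop("fractionAntisensePairs must lie in [0, 1]")
  if (readLength < 1 || nReads < 1) stop("invalid read settings")
  cfg <- list(seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
              chromLength = chromLength, nGenes = as.integer(nGenes),
              fractionAntisensePairs = fractionAntisensePairs,
              overlapRange = overlapRange,
              exonCountRange = exonCountRange,
              exonLengthRange = exonLengthRange,
              intronLengthRange = intronLengthRange,
              pairLengthRange = pairLengthRange,
              abundanceMeanlog = abundanceMeanlog,
              abundanceSdlog = abundanceSdlog,
              nReads = nReads, readLength = as.integer(readLength),
              protocol = protocol, leakageP = leakageP,
              positionalBias = positionalBias,
              ctNoiseSd = ctNoiseSd, ctBaseline = ctBaseline,
              ctReplicates = as.integer(ctReplicates),
              nPlantedNags = as.integer(nPlantedNags),
              nagsPerHost = as.integer(nagsPerHost))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig: seed", x$seed, "|", x$nGenes, "genes on",
      x$nChromosomes, "chromosome(s) of", x$chromLength, "b |",
      x$nReads, "x", x$readLength, "b", x$protocol, "reads",
      if (x$protocol == "SS") paste0("(leakage ", x$leakageP, ")") else "",
      "\n")
  invisible(x)
}

#' Simulate a random genome
#'
#' I.i.d. uniform ACGT sequences, one per chromosome, named chr1, chr2, ...
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return A named \code{DNAStringSet}.
#' @export
simulateGenome <- function(config) {
  set.seed(config$seed)
  seqs <- vapply(seq_len(config$nChromosomes), function(i)
    paste(sample(c("A", "C", "G", "T"), config$chromLength, replace = TRUE),
          collapse = ""), character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- paste0("chr", seq_len(config$nChromosomes))
  g
}

## overwrite genome[[chrom]][at0, at0+nchar(what)) (0-based) with `what`
plantSequence <- function(genome, chrom, at0, what) {
  Biostrings::subseq(genome[chrom], start = at0 + 1L,
                     width = nchar(what)) <- Biostrings::DNAStringSet(what)
  genome
}

#' Simulate a gene annotation with controlled antisense overlap
#'
#' Lays out genes left to right along the chromosomes: antisense pairs
#' (two single-exon transcripts on opposite strands, positioned so both
#' sides realize a target overlap fraction drawn from
#' \code{config$overlapRange} to within rounding), then multi-exon
#' singleton genes. Optionally plants novel antisense transcripts inside
#' singleton hosts, writing canonical GT/AG (strand-appropriate)
#' dinucleotides into the genome at every planted splice site.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param genome \code{DNAStringSet} from \code{\link{simulateGenome}}.
#' @return A list: \code{transcripts} (\code{TranscriptSet} of known
#'   genes), \code{pairsTruth} (data.frame \code{acc_a}, \code{acc_b},
#'   \code{target_overlap}), \code{nags} (\code{TranscriptSet} of planted
#'   novel transcripts, empty when none), \code{nagHosts} (named character
#'   vector: planted accession -> host accession), \code{genome} (possibly
#'   modified copy).
#' @export
simulateAnnotation <- function(config, genome) {
  set.seed(config$seed + 1L)
  rl <- config$readLength
  nPairGenes <- 2L * round(config$nGenes * config$fractionAntisensePairs / 2)
  nPairs <- nPairGenes / 2L
  nSingles <- config$nGenes - nPairGenes
  gap <- function() round(runif(1, 500, 2000))
  chromCursor <- setNames(rep(1000, config$nChromosomes), names(genome))
  nextChrom <- function(need) {
    for (ch in names(genome)) {
      if (chromCursor[ch] + need < config$chromLength - 1000) return(ch)
    }
    stop("genes do not fit; increase chromLength")
  }
  acc <- character(); gene <- character(); chrom <- character()
  strand <- character(); exS <- list(); exE <- list()
  pairsTruth <- data.frame(acc_a = character(), acc_b = character(),
                           target_overlap = numeric())
  for (i in seq_len(nPairs)) {
    o <- runif(1, config$overlapRange[1], config$overlapRange[2])
    LA <- round(runif(1, config$pairLengthRange[1], config$pairLengthRange[2]))
    S <- max(rl, round(o * LA))  # shared region must hold a read
    LB <- round(S / o)
    ch <- nextChrom(LA + LB)
    c0 <- chromCursor[ch]
    aA <- sprintf("PAIRA%04d", i); aB <- sprintf("PAIRB%04d", i)
    acc <- c(acc, aA, aB); gene <- c(gene, paste0("G", aA), paste0("G", aB))
    chrom <- c(chrom, ch, ch); strand <- c(strand, "+", "-")
    exS <- c(exS, list(c0), list(c0 + LA - S))
    exE <- c(exE, list(c0 + LA), list(c0 + LA - S + LB))
    chromCursor[ch] <- max(c0 + LA, c0 + LA - S + LB) + gap()
    pairsTruth <- rbind(pairsTruth,
                        data.frame(acc_a = aA, acc_b = aB, target_overlap = o))
  }
  for (i in seq_len(nSingles)) {
    ne <- sample(seq(config$exonCountRange[1], config$exonCountRange[2]), 1)
    el <- round(runif(ne, config$exonLengthRange[1], config$exonLengthRange[2]))
    il <- if (ne > 1)
      round(runif(ne - 1, config$intronLengthRange[1],
                  config$intronLengthRange[2])) else integer(0)
    span <- sum(el) + sum(il)
    ch <- nextChrom(span)
    c0 <- chromCursor[ch]
    starts <- c0 + cumsum(c(0, utils::head(el, -1) + il))
    ends <- starts + el
    aS <- sprintf("SING%04d", i)
    acc <- c(acc, aS); gene <- c(gene, paste0("G", aS))
    chrom <- c(chrom, ch); strand <- c(strand, sample(c("+", "-"), 1))
    exS <- c(exS, list(starts)); exE <- c(exE, list(ends))
    chromCursor[ch] <- ends[length(ends)] + gap()
  }
  ts <- TranscriptSet(acc, gene, chrom, strand, exS, exE)
  ## plant novel antisense transcripts inside singleton hosts
  nagAcc <- character(); nagChrom <- character(); nagStrand <- character()
  nagS <- list(); nagE <- list(); nagHosts <- character()
  if (config$nPlantedNags > 0) {
    singles <- grep("^SING", acc)
    wide <- singles[(vapply(exE[singles], max, numeric(1)) -
                     vapply(exS[singles], min, numeric(1))) > 1200]
    if (length(wide) < config$nPlantedNags)
      stop("not enough wide singleton hosts; increase nGenes or exon sizes")
    hostsIdx <- sample(wide, config$nPlantedNags)
    k <- 0L
    for (h in hostsIdx) {
      hs <- min(exS[[h]]); he <- max(exE[[h]])
      opp <- if (strand[h] == "+") "-" else "+"
      ## anchor region shared by the host's planted transcripts
      a0 <- hs + 100L
      for (j in seq_len(config$nagsPerHost)) {
        k <- k + 1L
        nex <- sample(1:2, 1)
        if (nex == 1) {
          s <- a0; e <- a0 + round(runif(1, 250, 400))
          st <- s; en <- e
        } else {
          l1 <- round(runif(1, 120, 200)); l2 <- round(runif(1, 120, 200))
          il <- round(runif(1, 100, 250))
          st <- c(a0, a0 + l1 + il); en <- c(a0 + l1, a0 + l1 + il + l2)
        }
        if (max(en) > he - 50) { st <- st - (max(en) - (he - 50)); en <- en - (max(en) - (he - 50)) }
        nm <- sprintf("PLNT%04d-%d", match(h, hostsIdx), j)
        nagAcc <- c(nagAcc, nm); nagChrom <- c(nagChrom, chrom[h])
        nagStrand <- c(nagStrand, opp)
        nagS <- c(nagS, list(st)); nagE <- c(nagE, list(en))
        nagHosts[nm] <- acc[h]
        ## write splice-site dinucleotides into the genome (plus-strand
        ## letters: GT..AG for a + transcript, CT..AC for a - transcript)
        if (length(st) > 1) {
          for (q in seq_len(length(st) - 1)) {
            don <- if (opp == "+") "GT" else "CT"
            acp <- if (opp == "+") "AG" else "AC"
            genome <- plantSequence(genome, chrom[h], en[q], don)
            genome <- plantSequence(genome, chrom[h], st[q + 1] - 2L, acp)
          }
        }
      }
    }
  }
  nags <- TranscriptSet(nagAcc,
                        gene = sub("-[0-9]+$", "", nagAcc),
                        chrom = nagChrom, strand = nagStrand,
                        exonStarts = nagS, exonEnds = nagE)
  list(transcripts = ts, pairsTruth = pairsTruth, nags = nags,
       nagHosts = nagHosts, genome = genome)
}

## cumulative exon offsets in genomic order; returns list(starts0, cum)
.exonOffsets <- function(gr) {
  w <- GenomicRanges::width(gr)
  list(gstart0 = GenomicRanges::start(gr) - 1L,
       gend0 = GenomicRanges::end(gr),
       cum = cumsum(c(0L, utils::head(w, -1))),
       width = w)
}

## genomic 0-based start of a read at transcript position p (length rl),
## or NA when the read spans an exon junction
.txToGenomicStart <- function(off, L, strand, p, rl) {
  q <- if (strand == "+") p else L - p - rl  # genomic-order offset
  ei <- pmax(findInterval(q, off$cum), 1L)
  inside <- (q + rl) <= (off$cum[ei] + off$width[ei]) & q >= off$cum[ei]
  ifelse(inside, off$gstart0[ei] + (q - off$cum[ei]), NA_real_)
}

## transcript position of a read occupying genomic [g0, g0+rl) fully inside
## one exon
.genomicToTxStart <- function(off, L, strand, g0, rl) {
  ei <- pmax(findInterval(g0, off$gstart0), 1L)
  inside <- g0 >= off$gstart0[ei] & (g0 + rl) <= off$gend0[ei]
  q <- off$cum[ei] + (g0 - off$gstart0[ei])
  ifelse(inside, if (strand == "+") q else L - q - rl, NA_real_)
}

#' Simulate a stranded read library with ground truth
#'
#' Reads are drawn per transcript from a multinomial with weights
#' abundance x exonic length (so RPKM recovers abundance); fragment starts
#' follow the configured Beta positional bias scaled to the transcript; a
#' strand-specific library reports the wrong strand with probability
#' \code{leakageP}, a non-strand-specific one reports a uniform strand.
#' For antisense-overlapped transcripts, a read lying entirely within a
#' shared exonic segment additionally receives a secondary alignment on
#' the partner (opposite orientation), which is what makes equal-split
#' allocation ambiguous downstream.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param transcripts A \code{\linkS4class{TranscriptSet}}.
#' @param abundances Optional named numeric vector of true abundances
#'   (default: drawn log-normal from the config).
#' @param pairs Optional \code{\linkS4class{OverlapPairs}} (default:
#'   computed from \code{transcripts}).
#' @return A list: \code{alignments} (transcript-space alignment
#'   data.frame, secondary placements included), \code{truth} (list with
#'   \code{reads}: read_id, transcript, start, reported_strand;
#'   \code{transcripts}: accession, abundance, true_count),
#'   \code{excluded} (accessions shorter than the read length).
#' @export
simulateReads <- function(config, transcripts, abundances = NULL,
                          pairs = NULL) {
  set.seed(config$seed + 2L)
  rl <- config$readLength
  L <- exonicLength(transcripts)
  acc <- accessions(transcripts)
  if (is.null(abundances)) {
    abundances <- setNames(
      rlnorm(length(acc), config$abundanceMeanlog, config$abundanceSdlog),
      acc)
  }
  if (any(!acc %in% names(abundances)))
    stop("abundances missing for some transcripts")
  eligible <- L >= rl
  if (any(!eligible))
    warning(sum(!eligible), " transcript(s) shorter than the read length excluded")
  useAcc <- acc[eligible]
  w <- abundances[useAcc] * L[useAcc]
  cnt <- as.vector(rmultinom(1, config$nReads, w / sum(w)))
  names(cnt) <- useAcc
  tx <- rep(useAcc, cnt)
  n <- length(tx)
  Ltx <- L[tx]
  u <- rbeta(n, config$positionalBias[1], config$positionalBias[2])
  start <- unname(pmin(floor(u * (Ltx - rl + 1)), Ltx - rl))
  reported_sense <- if (config$protocol == "SS")
    runif(n) >= config$leakageP else runif(n) < 0.5
  read_id <- sprintf("read%07d", seq_len(n))
  strandOf <- txStrand(transcripts)
  aln <- data.frame(read_id = read_id, reference = tx,
                    ref_strand = ifelse(reported_sense, "+", "-"),
                    start = as.numeric(start), aligned_length = rl,
                    mismatches = 0L, stringsAsFactors = FALSE)
  ## secondary alignments on antisense partners over shared exonic segments
  if (is.null(pairs)) pairs <- findAntisenseOverlaps(transcripts)
  pdf <- as.data.frame(pairs@pairs)
  sec <- list()
  if (nrow(pdf) > 0) {
    gl <- exonRanges(transcripts)
    ## plain-R exon tables (S4 extraction is too slow inside the pair loop)
    sL <- as.list(GenomicRanges::start(gl))
    eL <- as.list(GenomicRanges::end(gl))
    offs <- Map(function(s1, e1) {
      s0 <- s1 - 1L; w <- e1 - s0
      list(gstart0 = s0, gend0 = e1,
           cum = cumsum(c(0L, utils::head(w, -1))), width = w)
    }, sL, eL)
    names(offs) <- acc
    ## 0-based half-open intersection of two small sorted exon lists
    isect0 <- function(a, b) {
      os <- numeric(0); oe <- numeric(0)
      for (i in seq_along(offs[[a]]$gstart0)) {
        s <- pmax(offs[[a]]$gstart0[i], offs[[b]]$gstart0)
        e <- pmin(offs[[a]]$gend0[i], offs[[b]]$gend0)
        hit <- e > s
        os <- c(os, s[hit]); oe <- c(oe, e[hit])
      }
      o <- order(os)
      list(s = os[o], e = oe[o])
    }
    byTx <- split(seq_len(n), tx)
    addSide <- function(src, dst, shared) {
      idx <- byTx[[src]]
      if (is.null(idx) || length(shared$s) == 0) return(NULL)
      g0 <- .txToGenomicStart(offs[[src]], L[[src]], strandOf[[src]],
                              start[idx], rl)
      ok <- !is.na(g0)
      if (!any(ok)) return(NULL)
      gi <- g0[ok]
      si <- pmax(findInterval(gi, shared$s), 1L)
      inShared <- gi >= shared$s[si] & (gi + rl) <= shared$e[si]
      if (!any(inShared)) return(NULL)
      sel <- idx[ok][inShared]
      g2 <- gi[inShared]
      p2 <- .genomicToTxStart(offs[[dst]], L[[dst]], strandOf[[dst]], g2, rl)
      keep <- !is.na(p2)
      if (!any(keep)) return(NULL)
      data.frame(read_id = read_id[sel][keep], reference = dst,
                 ref_strand = ifelse(reported_sense[sel][keep], "-", "+"),
                 start = p2[keep], aligned_length = rl, mismatches = 0L,
                 stringsAsFactors = FALSE)
    }
    for (r in seq_len(nrow(pdf))) {
      shared <- isect0(pdf$acc_a[r], pdf$acc_b[r])
      sec[[length(sec) + 1L]] <- addSide(pdf$acc_a[r], pdf$acc_b[r], shared)
      sec[[length(sec) + 1L]] <- addSide(pdf$acc_b[r], pdf$acc_a[r], shared)
    }
  }
  alignments <- rbind(aln, do.call(rbind, sec))
  alignments <- alignments[order(match(alignments$read_id, read_id)), ]
  rownames(alignments) <- NULL
  truthTx <- data.frame(accession = useAcc,
                        abundance = unname(abundances[useAcc]),
                        true_count = as.numeric(cnt),
                        stringsAsFactors = FALSE)
  list(alignments = alignments,
       truth = list(reads = data.frame(read_id = read_id, transcript = tx,
                                       start = as.numeric(start),
                                       reported_strand = aln$ref_strand,
                                       stringsAsFactors = FALSE),
                    transcripts = truthTx),
       excluded = acc[!eligible])
}

#' Extract transcript (mRNA) sequences from a genome
#'
#' Concatenates exon sequences in genomic order and reverse-complements
#' minus-strand transcripts.
#'
#' @param transcripts A \code{\linkS4class{TranscriptSet}}.
#' @param genome A named \code{DNAStringSet}.
#' @return A \code{DNAStringSet} named by accession.
#' @export
transcriptSeqs <- function(transcripts, genome) {
  gl <- exonRanges(transcripts)
  seqs <- vapply(seq_along(gl), function(i) {
    g <- gl[[i]]
    ch <- as.character(GenomicRanges::seqnames(g))[1]
    parts <- vapply(seq_along(g), function(j)
      as.character(Biostrings::subseq(genome[[ch]],
                                      GenomicRanges::start(g)[j],
                                      GenomicRanges::end(g)[j])),
      character(1))
    paste(parts, collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  minus <- txStrand(transcripts) == "-"
  out[minus] <- Biostrings::reverseComplement(out[minus])
  names(out) <- accessions(transcripts)
  out
}

#' Write simulated reads as FASTQ
#'
#' Read sequences are taken from the source transcript (reverse-complemented
#' when the read reports the antisense strand); base qualities decay
#' linearly along the read (Q = 40 - 0.2 x position + N(0, 1), clamped to
#' [2, 40]), Phred+33.
#'
#' @param sim Result of \code{\link{simulateReads}}.
#' @param transcripts The \code{\linkS4class{TranscriptSet}} used.
#' @param genome The genome the transcripts live on.
#' @param path Output FASTQ path.
#' @param config The \code{\link{simulationConfig}} (for the seed and read
#'   length).
#' @return Invisibly, \code{path}.
#' @export
writeSimulatedFastq <- function(sim, transcripts, genome, path, config) {
  set.seed(config$seed + 3L)
  rd <- sim$truth$reads
  txs <- transcriptSeqs(transcripts, genome)
  rl <- config$readLength
  frag <- Biostrings::DNAStringSet(txs[rd$transcript],
                                   start = as.integer(rd$start) + 1L,
                                   width = rl)
  anti <- rd$reported_strand == "-"
  frag[anti] <- Biostrings::reverseComplement(frag[anti])
  n <- nrow(rd)
  q <- matrix(pmin(pmax(round(40 - 0.2 * (col(matrix(0, n, rl)) - 1) +
                                rnorm(n * rl, 0, 1)), 2), 40),
              nrow = n)
  qstr <- apply(q, 1, function(v) intToUtf8(v + 33L))
  out <- character(4 * n)
  out[seq(1, by = 4, length.out = n)] <- paste0("@", rd$read_id)
  out[seq(2, by = 4, length.out = n)] <- as.character(frag)
  out[seq(3, by = 4, length.out = n)] <- "+"
  out[seq(4, by = 4, length.out = n)] <- qstr
  writeLines(out, path)
  invisible(path)
}

#' Project transcript-space alignments to genome space
#'
#' Keeps alignments whose read footprint lies inside one exon (a spliced
#' footprint cannot be represented by the contiguous alignment records the
#' counters consume); junction-spanning alignments are dropped and counted
#' in the \code{n_dropped} attribute. The genomic strand is the read's
#' transcript-relative strand composed with the transcript's strand.
#'
#' @param alignments Transcript-space alignment data.frame.
#' @param transcripts A \code{\linkS4class{TranscriptSet}}.
#' @return A genome-space alignment data.frame.
#' @export
alignmentsToGenomeSpace <- function(alignments, transcripts) {
  acc <- accessions(transcripts)
  aln <- alignments[alignments$reference %in% acc, , drop = FALSE]
  gl <- exonRanges(transcripts)
  offs <- lapply(seq_along(gl), function(i) .exonOffsets(gl[[i]]))
  names(offs) <- acc
  L <- exonicLength(transcripts)
  strandOf <- txStrand(transcripts)
  chromOf <- txChrom(transcripts)
  g0 <- vapply(seq_len(nrow(aln)), function(i)
    .txToGenomicStart(offs[[aln$reference[i]]], L[aln$reference[i]],
                      strandOf[aln$reference[i]], aln$start[i],
                      aln$aligned_length[i]), numeric(1))
  keep <- !is.na(g0)
  txPlus <- strandOf[aln$reference] == "+"
  readPlus <- aln$ref_strand == "+"
  out <- data.frame(read_id = aln$read_id[keep],
                    reference = unname(chromOf[aln$reference[keep]]),
                    ref_strand = ifelse(txPlus[keep] == readPlus[keep],
                                        "+", "-"),
                    start = g0[keep],
                    aligned_length = aln$aligned_length[keep],
                    mismatches = aln$mismatches[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Write exact-match PSL records for transcript models
#'
#' A minimal contig "placer" for building discovery-pipeline fixtures: each
#' transcript becomes one perfect blat-style alignment (matches = exonic
#' length, no mismatches or gaps).
#'
#' @param ts A \code{\linkS4class{TranscriptSet}}.
#' @param path Output PSL path.
#' @param chromLengths Optional named vector of chromosome lengths for the
#'   tSize column (default 0).
#' @return Invisibly, \code{path}.
#' @export
transcriptsToPsl <- function(ts, path, chromLengths = NULL) {
  gl <- exonRanges(ts)
  L <- exonicLength(ts)
  lines <- vapply(seq_along(gl), function(i) {
    g <- gl[[i]]
    ch <- as.character(GenomicRanges::seqnames(g))[1]
    s0 <- GenomicRanges::start(g) - 1L
    e0 <- GenomicRanges::end(g)
    sizes <- e0 - s0
    tsize <- if (!is.null(chromLengths) && ch %in% names(chromLengths))
      chromLengths[[ch]] else 0L
    intronBases <- if (length(g) > 1) sum(s0[-1] - e0[-length(e0)]) else 0L
    paste(L[i], 0L, 0L, 0L, 0L, 0L, length(g) - 1L, intronBases,
          txStrand(ts)[i], accessions(ts)[i], L[i], 0L, L[i],
          ch, tsize, s0[1], e0[length(e0)], length(g),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(cumsum(c(0L, utils::head(sizes, -1))), collapse = ","), ","),
          paste0(paste(s0, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a replicate qPCR Ct table
#'
#' Ct = baseline - log2(abundance) + N(0, ctNoiseSd^2), independent per
#' replicate, so the delta-Ct fold change between two genes recovers their
#' true abundance ratio in expectation.
#'
#' @param abundances Named positive numeric vector of true abundances.
#' @param targets,controls Gene names (present in \code{abundances}).
#' @param config A \code{\link{simulationConfig}}.
#' @return A qPCR table data.frame (see \code{\link{readQpcrTable}}).
#' @export
simulateQpcr <- function(abundances, targets, controls, config) {
  stopifnot(all(abundances > 0),
            all(c(targets, controls) %in% names(abundances)))
  set.seed(config$seed + 4L)
  genes <- c(targets, controls)
  K <- config$ctReplicates
  ct <- matrix(config$ctBaseline - log2(abundances[genes]) +
                 rnorm(length(genes) * K, 0, config$ctNoiseSd),
               nrow = length(genes), ncol = K)
  tbl <- data.frame(gene = genes,
                    role = c(rep("target", length(targets)),
                             rep("internal_control", length(controls))),
                    stringsAsFactors = FALSE)
  for (k in seq_len(K)) tbl[[paste0("Ct", k)]] <- ct[, k]
  tbl
}
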