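#' TranscriptSet: a collection of refFlat transcript models
#'
#' Holds one gene model per transcript: accession, gene symbol, and exon
#' structure as a \link[GenomicRanges]{GRangesList} (one \code{GRanges} of
#' exons per transcript, 0-based half-open coordinates converted to the
#' 1-based closed convention of \pkg{IRanges} internally). Accessions may be
#' duplicated when a transcript maps to several genomic loci; see
#' \code{\link{filterSingleLocus}}.
#'
#' @slot exons A \code{GRangesList}, one element per transcript, named by
#'   accession. Exons within a transcript are sorted and disjoint, all on
#'   one chromosome and strand.
#' @slot gene Character vector of gene symbols, parallel to \code{exons}.
#' @slot cds Two-column integer matrix of cdsStart/cdsEnd (0-based
#'   half-open, as in refFlat); parsed but not otherwise used.
#'
#' @aliases TranscriptSet-class
#' @exportClass TranscriptSet
setClass("TranscriptSet",
  representation(
    exons = "CompressedGRangesList",
    gene = "character",
    cds = "matrix"
  )
)

setValidity("TranscriptSet", function(object) {
  msg <- character()
  n <- length(object@exons)
  if (length(object@gene) != n)
    msg <- c(msg, "gene must be parallel to exons")
  if (is.null(names(object@exons)) && n > 0)
    msg <- c(msg, "exons must be named by accession")
  if (n > 0) {
    nex <- S4Vectors::elementNROWS(object@exons)
    if (any(nex < 1))
      msg <- c(msg, "every transcript needs at least one exon")
    chr_per_tx <- lengths(unique(GenomicRanges::seqnames(object@exons)))
    str_per_tx <- lengths(unique(GenomicRanges::strand(object@exons)))
    if (any(chr_per_tx != 1) || any(str_per_tx != 1))
      msg <- c(msg, "exons of one transcript must share chromosome and strand")
    ok_sorted <- vapply(seq_len(n), function(i) {
      g <- object@exons[[i]]
      s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
      all(diff(s) > 0) && all(utils::head(e, -1) < utils::tail(s, -1)) &&
        all(e >= s)
    }, logical(1))
    if (!all(ok_sorted))
      msg <- c(msg, "exons must be sorted, non-empty and pairwise disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' OverlapPairs: antisense-overlapped transcript pairs
#'
#' One row per unordered pair of transcripts on the same chromosome and
#' opposite strands whose exons share at least one genomic base. The overlap
#' percentage of each side is the shared exonic base count divided by that
#' transcript's exonic (mRNA) length, times 100 -- so the two percentages of
#' a pair differ whenever the transcripts differ in length.
#'
#' @slot pairs A \code{DataFrame} with columns \code{acc_a}, \code{acc_b},
#'   \code{shared_exonic_bases}, \code{overlap_pct_a}, \code{overlap_pct_b}.
#'
#' @aliases OverlapPairs-class
#' @exportClass OverlapPairs
setClass("OverlapPairs", representation(pairs = "DFrame"))

setValidity("OverlapPairs", function(object) {
  df <- object@pairs
  need <- c("acc_a", "acc_b", "shared_exonic_bases",
            "overlap_pct_a", "overlap_pct_b")
  if (!all(need %in% colnames(df)))
    return(paste("missing columns:", paste(setdiff(need, colnames(df)), collapse = ", ")))
  if (nrow(df) == 0) return(TRUE)
  msg <- character()
  if (any(df$acc_a == df$acc_b)) msg <- c(msg, "acc_a must differ from acc_b")
  if (any(df$shared_exonic_bases <= 0))
    msg <- c(msg, "shared_exonic_bases must be positive")
  if (any(df$overlap_pct_a <= 0 | df$overlap_pct_a > 100) ||
      any(df$overlap_pct_b <= 0 | df$overlap_pct_b > 100))
    msg <- c(msg, "overlap percentages must lie in (0, 100]")
  if (length(msg)) msg else TRUE
})
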