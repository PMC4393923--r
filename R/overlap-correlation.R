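#' Stratify transcripts into overlap-percentage bins
#'
#' Overlapped transcripts are assigned to exactly one bin by their maximum
#' overlap percentage over all antisense partners, using half-open
#' (lower, upper] intervals; nonoverlapped transcripts form the O = 0 set.
#'
#' @param pairs An \code{\linkS4class{OverlapPairs}}.
#' @param models The full \code{\linkS4class{TranscriptSet}} (defines the
#'   universe of transcripts, hence the O = 0 set).
#' @param edges Strictly increasing numeric vector of bin edges starting at
#'   0 (default deciles \code{seq(0, 100, 10)}).
#' @return A list with elements \code{zero} (character vector, the O = 0
#'   set) and \code{bins}: a data.frame with columns \code{label},
#'   \code{lower}, \code{upper}, \code{size} and a list-column
#'   \code{members}.
#' @export
binByOverlap <- function(pairs, models, edges = seq(0, 100, 10)) {
  if (length(edges) < 2) stop("need at least two bin edges")
  if (any(diff(edges) <= 0) || edges[1] != 0)
    stop("edges must be strictly increasing and start at 0")
  acc <- accessions(models)
  mo <- maxOverlapPct(pairs, accession = acc)
  overlapped <- names(mo)[mo > 0]
  zero <- setdiff(acc, overlapped)
  idx <- cut(mo[overlapped], breaks = edges, right = TRUE,
             include.lowest = FALSE)
  labs <- levels(idx)
  members <- lapply(labs, function(l) overlapped[which(idx == l)])
  bins <- data.frame(label = labs,
                     lower = utils::head(edges, -1),
                     upper = utils::tail(edges, -1),
                     size = lengths(members))
  bins$members <- members
  list(zero = zero, bins = bins)
}

#' SS/NSS expression correlation within a transcript set
#'
#' Pearson correlation of log2 RPKM between two libraries over the given
#' members. Transcripts are used only if their read count exceeds
#' \code{minCount} in both libraries (guards against log of zero and
#' extreme low-count values).
#'
#' @param exprSS,exprNSS Expression data.frames from
#'   \code{\link{computeRpkm}}.
#' @param members Character vector of accessions.
#' @param minCount Read-count threshold applied in both libraries
#'   (default 1e-4).
#' @return A list: \code{r} (Pearson correlation, \code{NA} when fewer than
#'   3 transcripts survive), \code{n} (transcripts used), \code{ok}
#'   (logical, \code{FALSE} when r is undefined).
#' @export
correlationInSet <- function(exprSS, exprNSS, members, minCount = 1e-4) {
  ss <- exprSS[match(members, exprSS$accession), ]
  ns <- exprNSS[match(members, exprNSS$accession), ]
  keep <- !is.na(ss$accession) & !is.na(ns$accession) &
    ss$read_count > minCount & ns$read_count > minCount
  n <- sum(keep)
  if (n < 3)
    return(list(r = NA_real_, n = n, ok = FALSE))
  r <- stats::cor(log2(ss$rpkm[keep]), log2(ns$rpkm[keep]))
  list(r = r, n = n, ok = TRUE)
}

#' Size-matched mimic resampling from the nonoverlapped set
#'
#' For each requested bin size, repeatedly draws that many transcripts
#' without replacement from the O = 0 (nonoverlapped) set and computes the
#' SS/NSS correlation, returning the mean and SD over replicates. A flat
#' mimic curve shows that correlation differences between overlap bins are
#' not explained by set size.
#'
#' @param zeroSet Character vector: the O = 0 transcript set.
#' @param binSizes Integer vector of set sizes to mimic.
#' @param exprSS,exprNSS Expression data.frames.
#' @param reps Replicates per bin size (default 100).
#' @param seed Mandatory integer seed.
#' @param minCount Passed to \code{\link{correlationInSet}}.
#' @return Data.frame with columns \code{size}, \code{r_mimic_mean},
#'   \code{r_mimic_sd}, \code{reps_used}.
#' @export
mimicResample <- function(zeroSet, binSizes, exprSS, exprNSS, reps = 100,
                          seed, minCount = 1e-4) {
  if (missing(seed)) stop("seed is required for reproducibility")
  if (any(binSizes > length(zeroSet)))
    stop("bin size exceeds the O = 0 pool (", length(zeroSet), ")")
  set.seed(seed)
  out <- lapply(binSizes, function(sz) {
    rs <- vapply(seq_len(reps), function(i) {
      draw <- sample(zeroSet, sz, replace = FALSE)
      correlationInSet(exprSS, exprNSS, draw, minCount = minCount)$r
    }, numeric(1))
    rs_ok <- rs[!is.na(rs)]
    data.frame(size = sz,
               r_mimic_mean = mean(rs_ok),
               r_mimic_sd = stats::sd(rs_ok),
               reps_used = length(rs_ok))
  })
  do.call(rbind, out)
}

#' Overlap-stratified SS/NSS concordance report
#'
#' Convenience wrapper: bins transcripts by overlap percentage, computes the
#' real per-bin SS/NSS correlation and the size-matched mimic control.
#'
#' @inheritParams binByOverlap
#' @inheritParams mimicResample
#' @return Data.frame with one row per bin: \code{label}, \code{size},
#'   \code{n_used}, \code{r_real}, \code{r_mimic_mean}, \code{r_mimic_sd}.
#' @export
overlapCorrelationReport <- function(pairs, models, exprSS, exprNSS,
                                     edges = seq(0, 100, 10), reps = 100,
                                     seed, minCount = 1e-4) {
  strat <- binByOverlap(pairs, models, edges)
  real <- lapply(strat$bins$members, function(m)
    correlationInSet(exprSS, exprNSS, m, minCount = minCount))
  mim <- mimicResample(strat$zero, strat$bins$size, exprSS, exprNSS,
                       reps = reps, seed = seed, minCount = minCount)
  data.frame(label = strat$bins$label,
             size = strat$bins$size,
             n_used = vapply(real, `[[`, numeric(1), "n"),
             r_real = vapply(real, `[[`, numeric(1), "r"),
             r_mimic_mean = mim$r_mimic_mean,
             r_mimic_sd = mim$r_mimic_sd)
}
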