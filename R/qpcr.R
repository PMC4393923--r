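#' Read a qPCR Ct table
#'
#' Expected TSV layout: header line, then one row per gene with columns
#' \code{gene}, \code{role} (\code{target} or \code{internal_control}) and
#' \code{Ct1..CtK} (equal replicate count for every gene). RPKM columns, if
#' present, are carried through.
#'
#' @param path Path to the TSV.
#' @return A data.frame validated for the invariants above.
#' @export
readQpcrTable <- function(path) {
  tbl <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validateQpcrTable(tbl)
  tbl
}

validateQpcrTable <- function(tbl) {
  if (!all(c("gene", "role") %in% names(tbl)))
    stop("qPCR table needs 'gene' and 'role' columns")
  ctc <- grep("^Ct[0-9]+$", names(tbl), value = TRUE)
  if (length(ctc) == 0) stop("qPCR table has no Ct columns")
  if (!all(tbl$role %in% c("target", "internal_control")))
    stop("role must be 'target' or 'internal_control'")
  if (sum(tbl$role == "target") < 1 || sum(tbl$role == "internal_control") < 1)
    stop("need at least one target and one internal control")
  for (cc in ctc) {
    bad <- which(is.na(tbl[[cc]]) | tbl[[cc]] <= 0)
    if (length(bad))
      stop("missing or non-positive Ct for gene ", tbl$gene[bad[1]],
           " replicate ", sub("Ct", "", cc))
  }
  invisible(ctc)
}

#' Fold changes from qPCR Ct values
#'
#' Uses the delta-Ct model with amplification efficiency 2:
#' FC = 2^(Ct_control - Ct_target), computed within each replicate for
#' every (target, control) combination. A table of T targets, C controls
#' and K replicates yields T x C x K fold changes.
#'
#' @param tbl A qPCR table (see \code{\link{readQpcrTable}}).
#' @return Data.frame with columns \code{target}, \code{control},
#'   \code{replicate}, \code{fc}; attribute \code{source = "ct"}.
#' @export
ctFoldChanges <- function(tbl) {
  ctc <- validateQpcrTable(tbl)
  targets <- tbl$gene[tbl$role == "target"]
  controls <- tbl$gene[tbl$role == "internal_control"]
  ct <- as.matrix(tbl[, ctc, drop = FALSE])
  rownames(ct) <- tbl$gene
  grid <- expand.grid(target = targets, control = controls,
                      replicate = seq_along(ctc),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$fc <- 2 ^ (ct[cbind(match(grid$control, rownames(ct)), grid$replicate)] -
                  ct[cbind(match(grid$target, rownames(ct)), grid$replicate)])
  attr(grid, "source") <- "ct"
  grid
}

#' Fold changes from RPKM values
#'
#' FC = RPKM_target / RPKM_control for every (target, control) combination.
#'
#' @param rpkm Named numeric vector of RPKM values covering all genes.
#' @param targets,controls Character vectors of gene names.
#' @param source Label stored as an attribute (e.g. \code{"rpkm_ss"}).
#' @return Data.frame with columns \code{target}, \code{control}, \code{fc}.
#' @export
rpkmFoldChanges <- function(rpkm, targets, controls, source = "rpkm") {
  miss <- setdiff(c(targets, controls), names(rpkm))
  if (length(miss))
    stop("RPKM missing for gene(s): ", paste(miss, collapse = ", "))
  if (any(rpkm[controls] == 0))
    stop("control gene(s) with zero RPKM: ",
         paste(controls[rpkm[controls] == 0], collapse = ", "))
  grid <- expand.grid(target = targets, control = controls,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$fc <- unname(rpkm[grid$target] / rpkm[grid$control])
  attr(grid, "source") <- source
  grid
}

#' Bootstrap comparison of qPCR vs RNA-seq fold-change concordance
#'
#' Aligns Ct fold changes with SS and NSS RPKM fold changes on
#' (target, control, replicate) tuples (RPKM fold changes are expanded
#' across replicates), then bootstraps: each replicate resamples target
#' genes with replacement and recomputes the Pearson correlation of log2
#' fold changes, Ct vs SS and Ct vs NSS, over the resampled genes'
#' expansions. Reports the paired two-sided t-test comparing the two
#' correlation distributions and the fraction of replicates in which the SS
#' correlation exceeds the NSS one.
#'
#' @param ctFc Data.frame from \code{\link{ctFoldChanges}}.
#' @param ssFc,nssFc Data.frames from \code{\link{rpkmFoldChanges}}.
#' @param reps Bootstrap replicates (default 100).
#' @param seed Mandatory integer seed.
#' @param unit Resampling unit: \code{"gene"} (default) resamples target
#'   genes, \code{"tuple"} resamples individual fold-change tuples.
#' @param maxRetry Replicates drawing fewer than 3 distinct genes are
#'   redrawn, at most this many times each (default 100).
#' @return A list: \code{perRep} (data.frame \code{r_ss}, \code{r_nss}),
#'   \code{meanRss}, \code{meanRnss}, \code{pValue},
#'   \code{fracSsGreater}.
#' @export
bootstrapCompare <- function(ctFc, ssFc, nssFc, reps = 100, seed,
                             unit = c("gene", "tuple"), maxRetry = 100) {
  if (missing(seed)) stop("seed is required for reproducibility")
  unit <- match.arg(unit)
  key <- paste(ctFc$target, ctFc$control)
  ss <- ssFc$fc[match(key, paste(ssFc$target, ssFc$control))]
  ns <- nssFc$fc[match(key, paste(nssFc$target, nssFc$control))]
  if (anyNA(ss) || anyNA(ns))
    stop("fold-change sets are not aligned on (target, control) keys")
  lct <- log2(ctFc$fc); lss <- log2(ss); lns <- log2(ns)
  genes <- unique(ctFc$target)
  byGene <- split(seq_along(lct), ctFc$target)
  set.seed(seed)
  oneRep <- function() {
    for (i in seq_len(maxRetry)) {
      if (unit == "gene") {
        g <- sample(genes, length(genes), replace = TRUE)
        if (length(unique(g)) < 3) next
        idx <- unlist(byGene[g], use.names = FALSE)
      } else {
        idx <- sample(length(lct), replace = TRUE)
        if (length(unique(ctFc$target[idx])) < 3) next
      }
      return(c(stats::cor(lct[idx], lss[idx]), stats::cor(lct[idx], lns[idx])))
    }
    stop("could not draw a bootstrap replicate with >=3 distinct genes")
  }
  rs <- t(vapply(seq_len(reps), function(i) oneRep(), numeric(2)))
  perRep <- data.frame(r_ss = rs[, 1], r_nss = rs[, 2])
  pv <- if (reps >= 2)
    stats::t.test(perRep$r_ss, perRep$r_nss, paired = TRUE)$p.value
  else NA_real_
  list(perRep = perRep,
       meanRss = mean(perRep$r_ss),
       meanRnss = mean(perRep$r_nss),
       pValue = pv,
       fracSsGreater = mean(perRep$r_ss > perRep$r_nss))
}
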