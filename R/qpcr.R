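## Relative transcript abundance across silk-gland tissue panels by the
## 2^-ddCt method: per tissue, dCt = Ct(target) - Ct(reference gene);
## ddCt = dCt(tissue) - dCt(calibrator tissue); relative quantity
## RQ = 2^(-ddCt). Defaults follow the standard silk-gland panel design:
## the housekeeping gene RPL13a as reference and leg tissue as calibrator.
## Censored ("Undetermined") wells never impute a numeric RQ.

#' Aggregate replicate Ct values
#'
#' Collapses replicate wells to one mean Ct per (sample, tissue, target)
#' group, using only non-censored replicates; a group whose replicates are
#' all censored stays censored. No-reverse-transcriptase (NRT) control wells
#' are aggregated separately and reported, never mixed into sample means --
#' a group containing both NRT and sample wells is an error.
#'
#' @param ct Ct data.frame (see \link{readCtTable}): sample, tissue, target,
#'   replicate, ct, and optionally censored / is_nrt.
#' @return data.frame: sample, tissue, target, is_nrt, mean_ct, sd_ct,
#'   n_replicates (non-censored count), censored.
#' @export
aggregateReplicates <- function(ct) {
  need <- c("sample", "tissue", "target", "ct")
  missing <- setdiff(need, names(ct))
  if (length(missing) > 0) {
    stop(sprintf("Ct table is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (!"censored" %in% names(ct)) ct$censored <- FALSE
  if (!"is_nrt" %in% names(ct)) ct$is_nrt <- FALSE
  key <- paste(ct$sample, ct$tissue, ct$target, sep = "\r")
  mixed <- tapply(ct$is_nrt, key, function(z) any(z) && !all(z))
  if (any(mixed)) {
    bad <- strsplit(names(mixed)[which(mixed)[1L]], "\r")[[1L]]
    stop(sprintf("group (%s, %s, %s) mixes NRT control and sample wells",
                 bad[1L], bad[2L], bad[3L]))
  }
  rows <- lapply(split(seq_len(nrow(ct)), key), function(ix) {
    g <- ct[ix, , drop = FALSE]
    ok <- !g$censored
    data.frame(sample = g$sample[1L], tissue = g$tissue[1L],
               target = g$target[1L], is_nrt = g$is_nrt[1L],
               mean_ct = if (any(ok)) mean(g$ct[ok]) else NA_real_,
               sd_ct = if (sum(ok) > 1L) stats::sd(g$ct[ok]) else NA_real_,
               n_replicates = sum(ok), censored = !any(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[orderStrings(out$sample, out$tissue, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' 2^-ddCt for one target/tissue against reference and calibrator
#'
#' @param targetCt,referenceCt mean Ct of target and reference gene in the
#'   tissue of interest (cycles).
#' @param calibratorTargetCt,calibratorReferenceCt mean Ct of target and
#'   reference gene in the calibrator tissue.
#' @return list with \code{delta_ct}, \code{delta_delta_ct}, \code{rq}, and
#'   \code{quantifiable}; any censored (NA) input yields a not-quantifiable
#'   result with no numeric rq.
#' @examples
#' ddct(20, 18, 21, 18)$rq  # one cycle lower than calibrator: rq = 2
#' @export
ddct <- function(targetCt, referenceCt, calibratorTargetCt,
                 calibratorReferenceCt) {
  inputs <- c(targetCt, referenceCt, calibratorTargetCt, calibratorReferenceCt)
  if (anyNA(inputs)) {
    return(list(delta_ct = NA_real_, delta_delta_ct = NA_real_,
                rq = NA_real_, quantifiable = FALSE))
  }
  dct <- targetCt - referenceCt
  dctCal <- calibratorTargetCt - calibratorReferenceCt
  ddctVal <- dct - dctCal
  list(delta_ct = dct, delta_delta_ct = ddctVal, rq = 2^(-ddctVal),
       quantifiable = TRUE)
}

#' Relative quantities across a tissue panel
#'
#' Computes, per sample and target, the 2^-ddCt relative quantity of every
#' tissue against the calibrator tissue, normalized to the reference gene.
#' The calibrator tissue's rq is exactly 1 for every quantifiable target (by
#' construction). Replicate variability is propagated in quadrature over the
#' four standard errors entering ddCt and reported as \code{sd_ddct}; no
#' significance testing is performed.
#'
#' @param ct Ct data.frame (see \link{readCtTable}); NRT control wells are
#'   excluded.
#' @param reference reference (housekeeping) target name.
#' @param calibrator calibrator tissue name.
#' @return data.frame: sample, tissue, target, delta_ct, delta_delta_ct,
#'   sd_ddct, rq, quantifiable.
#' @export
relativeQuantities <- function(ct, reference = "RPL13a", calibrator = "legs") {
  agg <- aggregateReplicates(ct)
  agg <- agg[!agg$is_nrt, , drop = FALSE]
  if (!reference %in% agg$target)
    stop(sprintf("reference target '%s' not present in the Ct table", reference))
  if (!calibrator %in% agg$tissue)
    stop(sprintf("calibrator tissue '%s' not present in the Ct table", calibrator))
  se2 <- function(sd, n) ifelse(is.na(sd) | n <= 0L, 0, sd^2 / n)
  rows <- list()
  for (s in unique(agg$sample)) {
    a <- agg[agg$sample == s, , drop = FALSE]
    refRows <- a[a$target == reference, , drop = FALSE]
    refCt <- stats::setNames(refRows$mean_ct, refRows$tissue)
    refSe2 <- stats::setNames(se2(refRows$sd_ct, refRows$n_replicates),
                              refRows$tissue)
    for (tg in setdiff(unique(a$target), reference)) {
      t <- a[a$target == tg, , drop = FALSE]
      cal <- t[t$tissue == calibrator, , drop = FALSE]
      calCt <- if (nrow(cal) == 1L && !cal$censored) cal$mean_ct else NA_real_
      calSe2 <- if (nrow(cal) == 1L) se2(cal$sd_ct, cal$n_replicates) else 0
      for (i in seq_len(nrow(t))) {
        tissue <- t$tissue[i]
        d <- ddct(if (t$censored[i]) NA_real_ else t$mean_ct[i],
                  refCt[tissue][[1L]], calCt, refCt[calibrator][[1L]])
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, tissue = tissue, target = tg,
          delta_ct = d$delta_ct, delta_delta_ct = d$delta_delta_ct,
          sd_ddct = sqrt(se2(t$sd_ct[i], t$n_replicates[i]) +
                           refSe2[tissue][[1L]] + calSe2 +
                           refSe2[calibrator][[1L]]),
          rq = d$rq, quantifiable = d$quantifiable,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[orderStrings(out$sample, out$target, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank silk glands by relative expression for one target
#'
#' Orders the quantifiable tissues of one target by decreasing relative
#' quantity (ties keep their input order); the top gland can feed class
#' assignment as expression evidence.
#'
#' @param rq data.frame from \link{relativeQuantities}, already restricted to
#'   one target (and typically to silk-gland tissues).
#' @param tissues optional tissue subset to rank (e.g. the silk glands only).
#' @return data.frame of ranked tissues (tissue, rq) with the top gland in
#'   attribute \code{"top"}; an error if no tissue is quantifiable.
#' @export
rankGlands <- function(rq, tissues = NULL) {
  if (length(unique(rq$target)) > 1L)
    stop("rankGlands expects quantities for a single target")
  if (!is.null(tissues)) rq <- rq[rq$tissue %in% tissues, , drop = FALSE]
  rq <- rq[rq$quantifiable & !is.na(rq$rq), , drop = FALSE]
  if (nrow(rq) == 0) stop("no quantifiable tissue for this target")
  ord <- order(-rq$rq)   # stable: ties keep input order
  out <- data.frame(tissue = rq$tissue[ord], rq = rq$rq[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "top") <- out$tissue[1L]
  out
}
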