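## Targeted-MS (internal-standard-triggered) quantitation.
##
## Transition-level reports carry, per target peptide, the per-sample area
## under the curve of each monitored product ion in a heavy (spiked
## internal standard) and light (endogenous) channel.  A peptide is
## quantifiable in a sample when its heavy channel shows nonzero AUC for
## at least five of the six monitored ions; the light/heavy abundance
## ratio is the summed light AUC over the summed heavy AUC of the three
## most intense fragments (ranked by the heavy channel, which is spiked at
## a fixed amount and immune to biology); age groups are compared to the
## 3-month reference by an unpaired one-sided t-test in the direction of
## the observed mean difference.

#' Filter peptides by internal-standard ion detectability
#'
#' Per (peptide, sample): quantifiable iff the heavy-channel AUC is nonzero
#' for at least `minIons` of `nIons` monitored product ions.  Peptides with
#' a different monitored-ion count are evaluated against their own count
#' with a warning.
#'
#' @param records long data.frame with `peptide_id`, `fragment`, `channel`,
#'   `sample`, `auc`.
#' @param nIons expected monitored ions per peptide (default 6).
#' @param minIons minimum nonzero heavy ions (default 5).
#' @return data.frame (`peptide_id`, `sample`, `n_ions`, `n_nonzero`,
#'   `quantifiable`).
#' @export
filterQuantifiablePeptides <- function(records, nIons = 6L, minIons = 5L) {
  heavy <- records[records$channel == "heavy", ]
  key <- interaction(heavy$peptide_id, heavy$sample, drop = TRUE)
  spl <- split(heavy, key)
  out <- do.call(rbind, lapply(spl, function(d) {
    data.frame(peptide_id = d$peptide_id[1], sample = d$sample[1],
               n_ions = nrow(d), n_nonzero = sum(d$auc > 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  odd <- unique(out$peptide_id[out$n_ions != nIons])
  if (length(odd))
    warning(length(odd), " peptide(s) monitored with != ", nIons,
            " ions; filtered against their own ion count")
  ## threshold scales with the actual ion count (5-of-6 rule)
  out$quantifiable <- out$n_nonzero >= pmin(out$n_ions, minIons) &
    (out$n_ions - out$n_nonzero) <= (nIons - minIons)
  out
}

#' Light/heavy ratios from the top-3 fragment ions
#'
#' For each quantifiable (peptide, sample): rank fragments by the chosen
#' channel's AUC (heavy by default), take the top `nTop`, and set
#' `ratio = sum(light AUC) / sum(heavy AUC)` over those fragments.
#'
#' @param records long transition data.frame (see
#'   [filterQuantifiablePeptides()]).
#' @param quantifiable output of [filterQuantifiablePeptides()]; computed
#'   when `NULL`.
#' @param nTop fragments to sum (default 3).
#' @param rankBy channel defining "most intense": `heavy`, `light`, `sum`.
#' @return data.frame (`peptide_id`, `sample`, `ratio`, `light_sum`,
#'   `heavy_sum`, `fragments`); non-quantifiable or zero-heavy entries have
#'   `NA` ratio.
#' @export
quantifyRatios <- function(records, quantifiable = NULL, nTop = 3L,
                           rankBy = c("heavy", "light", "sum")) {
  rankBy <- match.arg(rankBy)
  if (is.null(quantifiable))
    quantifiable <- filterQuantifiablePeptides(records)
  key <- interaction(records$peptide_id, records$sample, drop = TRUE)
  spl <- split(records, key)
  out <- do.call(rbind, lapply(spl, function(d) {
    pid <- d$peptide_id[1]; smp <- d$sample[1]
    q <- quantifiable$quantifiable[quantifiable$peptide_id == pid &
                                     quantifiable$sample == smp]
    heavy <- d[d$channel == "heavy", ]
    light <- d[d$channel == "light", ]
    light <- light[match(heavy$fragment, light$fragment), ]
    rank <- switch(rankBy, heavy = heavy$auc, light = light$auc,
                   sum = heavy$auc + light$auc)
    top <- order(-rank)[seq_len(min(nTop, nrow(heavy)))]
    hs <- sum(heavy$auc[top]); ls <- sum(light$auc[top])
    ratio <- if (!length(q) || !q[1] || hs <= 0) NA_real_ else ls / hs
    data.frame(peptide_id = pid, sample = smp, ratio = ratio,
               light_sum = ls, heavy_sum = hs,
               fragments = paste(heavy$fragment[top], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare age groups to the reference by one-sided t-tests
#'
#' Per peptide and non-reference age group: unpaired t-test of the
#' per-sample light/heavy ratios against the reference age (3 months), with
#' the one-sided p-value taken in the direction of the observed mean
#' difference (recorded in `direction`).  Equal group distributions give
#' p = 0.5 under this convention.
#'
#' @param quants data.frame from [quantifyRatios()].
#' @param metadata data.frame with `sample_id` and `age_months`.
#' @param referenceAge reference group (default 3).
#' @param logRatios test log-transformed ratios instead of the natural
#'   scale.
#' @return data.frame (`peptide_id`, `age_months`, `n`, `n_ref`,
#'   `mean_ratio`, `mean_ref`, `t`, `direction`, `p`, and `p_greater`, the
#'   fixed-direction one-sided p of an increase over the reference);
#'   degenerate comparisons are flagged with `NA` p.
#' @export
compareToReference <- function(quants, metadata, referenceAge = 3,
                               logRatios = FALSE) {
  age <- metadata$age_months[match(quants$sample, metadata$sample_id)]
  quants$age <- age
  vals <- if (logRatios) log(quants$ratio) else quants$ratio
  quants$val <- vals
  out <- list()
  for (pid in unique(quants$peptide_id)) {
    d <- quants[quants$peptide_id == pid & !is.na(quants$val), ]
    ref <- d$val[d$age == referenceAge]
    for (a in setdiff(sort(unique(d$age)), referenceAge)) {
      x <- d$val[d$age == a]
      if (length(x) < 2 || length(ref) < 2) next
      if (stats::sd(x) == 0 && stats::sd(ref) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          peptide_id = pid, age_months = a, n = length(x),
          n_ref = length(ref), mean_ratio = mean(x), mean_ref = mean(ref),
          t = NA_real_, direction = "none", p = NA_real_,
          p_greater = NA_real_)
        next
      }
      tt <- stats::t.test(x, ref)
      dir <- if (tt$statistic >= 0) "up" else "down"
      pOne <- stats::pt(abs(tt$statistic), tt$parameter,
                        lower.tail = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        peptide_id = pid, age_months = a, n = length(x),
        n_ref = length(ref), mean_ratio = mean(x), mean_ref = mean(ref),
        t = unname(tt$statistic), direction = dir, p = unname(pOne),
        p_greater = unname(stats::pt(tt$statistic, tt$parameter,
                                     lower.tail = FALSE)))
    }
  }
  do.call(rbind, out)
}
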