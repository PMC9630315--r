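## Quantitative qPCR statistics used to validate triplex association.

#' Delta-delta Ct fold change
#'
#' \code{2^-ddCt} with \code{ddCt = (target - reference) - (target_ctrl -
#' reference_ctrl)}. The amplification efficiency per cycle is configurable
#' (default 2, i.e. perfect doubling).
#'
#' @param targetCt,refCt Treated-condition Ct values (target and reference
#'   gene).
#' @param targetCtCtrl,refCtCtrl Control-condition Ct values.
#' @param efficiency Fold amplification per cycle (default 2).
#' @return Fold change (vectorized).
#' @examples
#' ddctFold(24, 18, 25.5, 18.5)  # 2^-((24-18) - (25.5-18.5)) = 2
#' @export
ddctFold <- function(targetCt, refCt, targetCtCtrl, refCtCtrl,
                     efficiency = 2) {
  stopifnot(is.finite(targetCt), is.finite(refCt), is.finite(targetCtCtrl),
            is.finite(refCtCtrl))
  ddct <- (targetCt - refCt) - (targetCtCtrl - refCtCtrl)
  efficiency^(-ddct)
}

#' Percent-input recovery for RIP/ChIP qPCR
#'
#' Expresses immunoprecipitated material relative to the measured input
#' aliquot. With dilution adjustment (default), the input Ct is first
#' shifted by \code{log2(1/inputFraction)} cycles to represent 100% input:
#' \code{100 * 2^((ctInput - log2(1/inputFraction)) - ctIP)}.
#'
#' @param ctIP Ct of the immunoprecipitated sample.
#' @param ctInput Ct of the input aliquot.
#' @param inputFraction Fraction of sample used as input, in (0, 1]
#'   (e.g. 0.10 or 0.05).
#' @param adjustDilution Apply the input-dilution adjustment (default
#'   \code{TRUE}).
#' @return Percent input (vectorized).
#' @examples
#' percentInput(25 - log2(1 / 0.1), 25, 0.1)  # 100
#' @export
percentInput <- function(ctIP, ctInput, inputFraction,
                         adjustDilution = TRUE) {
  if (any(inputFraction <= 0 | inputFraction > 1))
    stop("'inputFraction' must be in (0, 1]")
  adj <- if (adjustDilution) log2(1 / inputFraction) else 0
  100 * 2^((ctInput - adj) - ctIP)
}

#' RNase-H resistance ratio of percent-input recoveries
#'
#' Ratio of percent-input recovery with versus without RNase H treatment.
#' RNase H digests the RNA of DNA-RNA heteroduplexes but not triplex-held
#' RNA, so a ratio near 1 indicates RNase-H-resistant (triplex-like)
#' association and a ratio well below 1 indicates heteroduplex-like
#' sensitivity.
#'
#' @param pctPlus Percent input with RNase H treatment.
#' @param pctMinus Percent input without RNase H treatment (must be > 0).
#' @param analyteId Optional identifier column.
#' @return A \code{data.frame} with columns \code{analyte_id},
#'   \code{pct_input_plus_rnaseh}, \code{pct_input_minus_rnaseh},
#'   \code{ratio}.
#' @examples
#' rnasehRatio(2.5, 5.0)$ratio  # 0.5
#' @export
rnasehRatio <- function(pctPlus, pctMinus, analyteId = NA_character_) {
  if (any(pctMinus <= 0))
    stop("undefined ratio: 'pctMinus' must be positive")
  if (any(pctPlus < 0)) stop("'pctPlus' must be non-negative")
  data.frame(analyte_id = analyteId,
             pct_input_plus_rnaseh = pctPlus,
             pct_input_minus_rnaseh = pctMinus,
             ratio = pctPlus / pctMinus)
}

#' Summarize a replicated Ct table into per-analyte fold changes
#'
#' Computes the delta-delta Ct fold change per analyte from a tidy Ct table
#' (as produced by \code{\link{makeCtTable}}). Replicates are aggregated as
#' the arithmetic mean of delta-delta Ct (i.e. the geometric mean of
#' per-replicate folds), keeping the averaging in the log domain.
#'
#' @param ct A \code{data.frame} with columns \code{analyte_id},
#'   \code{condition} (\code{"treated"}/\code{"control"}),
#'   \code{replicate}, \code{target_ct}, \code{reference_ct}.
#' @param efficiency Fold amplification per cycle (default 2).
#' @return A \code{data.frame} with columns \code{analyte_id} and
#'   \code{fold_change}.
#' @export
summarizeCtTable <- function(ct, efficiency = 2) {
  needed <- c("analyte_id", "condition", "replicate", "target_ct",
              "reference_ct")
  missing_cols <- setdiff(needed, names(ct))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  folds <- vapply(split(ct, ct$analyte_id), function(d) {
    tr <- d[d$condition == "treated", ]
    co <- d[d$condition == "control", ]
    dct_tr <- mean(tr$target_ct - tr$reference_ct)
    dct_co <- mean(co$target_ct - co$reference_ct)
    efficiency^(-(dct_tr - dct_co))
  }, numeric(1))
  data.frame(analyte_id = names(folds), fold_change = unname(folds),
             row.names = NULL)
}
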