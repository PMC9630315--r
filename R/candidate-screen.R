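## Triplex sequencing candidate prioritization: Poisson peak enrichment and
## the high-stringency filter cascade.

#' Poisson peak enrichment
#'
#' Given the observed read count in a peak and the expected count under the
#' background model (the Poisson rate lambda), returns the fold enrichment
#' \code{observed / expected} and the upper-tail Poisson probability
#' \code{P(X >= observed | lambda = expected)}. The negative log10 p-value
#' is capped (default 300) to stay finite.
#'
#' @param observed Non-negative integer vector of observed read counts.
#' @param expected Positive numeric vector of expected counts (lambda).
#' @param cap Cap applied to \code{-log10(p)} (default 300).
#' @return A \code{data.frame} with columns \code{observed},
#'   \code{expected}, \code{fold_enrichment}, \code{p_enrich},
#'   \code{neg_log10_p}.
#' @examples
#' poissonEnrichment(0, 5)$p_enrich    # 1: P(X >= 0) = 1
#' poissonEnrichment(5, 5)$fold_enrichment  # 1
#' @export
poissonEnrichment <- function(observed, expected, cap = 300) {
  if (any(expected <= 0)) stop("'expected' must be positive")
  if (any(observed < 0)) stop("'observed' must be non-negative")
  p <- stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE)
  ## log-scale tail for counts where p underflows
  logp <- stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE,
                       log.p = TRUE) / log(10)
  data.frame(observed = observed, expected = expected,
             fold_enrichment = observed / expected,
             p_enrich = p,
             neg_log10_p = pmin(-logp, cap))
}

#' Intersect candidate lncRNA identifier sets from two cell lines
#'
#' @param setA,setB Character vectors of lncRNA identifiers.
#' @return Sorted character vector of identifiers present in both.
#' @examples
#' intersectCellLines(c("b", "a"), c("a", "c"))
#' @export
intersectCellLines <- function(setA, setB) {
  sort(intersect(unique(as.character(setA)), unique(as.character(setB))))
}

#' Screening thresholds for the candidate cascade
#'
#' Defaults mirror a high-stringency triplex sequencing screen: fold
#' enrichment strictly greater than 10, \code{-log10(p)} strictly greater
#' than 20, nuclear expression and every tissue signal strictly positive,
#' and a coding probability below the published human CPAT cutoff 0.364.
#'
#' @param foldCut Strict lower cut on best fold enrichment (default 10).
#' @param logpCut Strict lower cut on best \code{-log10(p)} (default 20).
#' @param nuclearMin Nuclear expression must exceed this (default 0).
#' @param tissueMin Every tissue signal must exceed this (default 0).
#' @param codingCut Coding probability must be strictly below this
#'   (default 0.364).
#' @return A named list of thresholds for \code{\link{applyScreen}}.
#' @export
screenThresholds <- function(foldCut = 10, logpCut = 20, nuclearMin = 0,
                             tissueMin = 0, codingCut = 0.364) {
  list(foldCut = foldCut, logpCut = logpCut, nuclearMin = nuclearMin,
       tissueMin = tissueMin, codingCut = codingCut)
}

.SCREEN_FILTERS <- c("both_cell_lines", "fold_enrichment", "neg_log10_p",
                     "nuclear_signal", "tissue_signals",
                     "coding_probability", "overlapping_gene_conflict")

#' Apply the candidate screening cascade
#'
#' Filters a per-lncRNA candidate table through the full cascade: presence
#' in both cell lines, strict fold-enrichment and \code{-log10(p)} cuts on
#' the best peak, strictly positive nuclear signal, strictly positive
#' signal in every tissue column, coding probability below the non-coding
#' cut, and absence of an overlapping-gene conflict (the manual
#' genome-browser exclusion, supplied as a flag). Each row's pass/fail per
#' filter is a pure function of the row and the thresholds, so the result
#' is independent of row order; the attrition report attributes each
#' removed row to the first filter (in cascade order) that rejects it.
#'
#' @param rows A \code{data.frame} with columns \code{lncrna_id},
#'   \code{best_fold_enrichment}, \code{best_neg_log10_p},
#'   \code{present_in_both_cell_lines} (logical), \code{nuclear_signal},
#'   one or more \code{tissue_*} columns, \code{coding_probability}, and
#'   \code{overlapping_gene_conflict} (logical).
#' @param thresholds Output of \code{\link{screenThresholds}}.
#' @return A list with \code{retained} (the surviving rows, with a
#'   \code{pass_flags} attribute-free logical matrix bound as
#'   \code{attr(, "passFlags")}), and \code{attrition} (a \code{data.frame}
#'   of per-filter removal counts summing to
#'   \code{nrow(rows) - nrow(retained)}).
#' @examples
#' tab <- data.frame(lncrna_id = "x", best_fold_enrichment = 50,
#'                   best_neg_log10_p = 30,
#'                   present_in_both_cell_lines = TRUE,
#'                   nuclear_signal = 1, tissue_aorta = 1,
#'                   coding_probability = 0.01,
#'                   overlapping_gene_conflict = FALSE)
#' applyScreen(tab)$retained$lncrna_id
#' @export
applyScreen <- function(rows, thresholds = screenThresholds()) {
  needed <- c("lncrna_id", "best_fold_enrichment", "best_neg_log10_p",
              "present_in_both_cell_lines", "nuclear_signal",
              "coding_probability", "overlapping_gene_conflict")
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  tissueCols <- grep("^tissue_", names(rows), value = TRUE)
  if (!length(tissueCols))
    stop("missing column(s): at least one 'tissue_*' column is required")

  th <- thresholds
  tissueOK <- rowSums(as.matrix(rows[, tissueCols, drop = FALSE]) >
                        th$tissueMin) == length(tissueCols)
  flags <- cbind(
    both_cell_lines = as.logical(rows$present_in_both_cell_lines),
    fold_enrichment = rows$best_fold_enrichment > th$foldCut,
    neg_log10_p = rows$best_neg_log10_p > th$logpCut,
    nuclear_signal = rows$nuclear_signal > th$nuclearMin,
    tissue_signals = tissueOK,
    coding_probability = rows$coding_probability < th$codingCut,
    overlapping_gene_conflict = !as.logical(rows$overlapping_gene_conflict))
  flags <- flags[, .SCREEN_FILTERS, drop = FALSE]

  pass <- rowSums(flags) == ncol(flags)
  firstFail <- apply(flags, 1L, function(f)
    if (all(f)) NA_character_ else .SCREEN_FILTERS[which(!f)[1L]])
  attrition <- data.frame(
    filter = .SCREEN_FILTERS,
    removed = vapply(.SCREEN_FILTERS, function(f)
      sum(firstFail == f, na.rm = TRUE), integer(1)),
    row.names = NULL)

  retained <- rows[pass, , drop = FALSE]
  attr(retained, "passFlags") <- flags
  list(retained = retained, attrition = attrition)
}
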