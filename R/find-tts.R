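#' Search duplex DNA for triplex target sites of a triplex-forming oligo
#'
#' Finds all maximal, gapless (collinear) matches between windows of a
#' third-strand sequence (TFO; RNA or DNA) and the purine strand of a DNA
#' duplex, under the Hoogsteen pairing code of one or more binding motifs.
#' Both duplex strands are examined as potential purine tracts; hits on the
#' minus strand are reported in plus-strand coordinates with strand
#' \code{"-"}. In the antiparallel (reverse-Hoogsteen purine) motif the TFO
#' runs antiparallel to the purine strand; in the parallel (Hoogsteen
#' pyrimidine) motif it runs parallel.
#'
#' A window is a valid hit when its length is at least \code{minLen} and its
#' mismatch fraction (positions where the pairing code disallows the base
#' pair) is at most \code{maxErrorRate}; only maximal windows -- those whose
#' one-base extensions violate the error constraint or the sequence bounds
#' -- are kept, and windows with no matched position are dropped. Overlapping
#' hits of the same motif and strand whose RNA- and DNA-side intervals both
#' overlap are collapsed to the highest-scoring hit (score = matched
#' positions), ties broken by leftmost DNA then leftmost RNA coordinate.
#'
#' @param tfo The third-strand sequence (\code{RNAString}, \code{DNAString},
#'   single-sequence \code{XStringSet}, or character). U and T are
#'   equivalent at comparison time.
#' @param duplex The duplex DNA plus strand: \code{DNAString}, character, or
#'   a (possibly multi-sequence) \code{DNAStringSet} scanned per sequence.
#' @param minLen Minimum hit length in nt (default 12).
#' @param maxErrorRate Maximum mismatch fraction per hit (default 0.2).
#' @param motifs Motifs to search, a subset of
#'   \code{c("antiparallel_purine", "parallel_pyrimidine")}.
#' @param tfoId Identifier recorded for the TFO (defaults to the name of
#'   \code{tfo} if available, else \code{"tfo"}).
#' @param merge Collapse overlapping same-motif, same-strand hits to the
#'   best-scoring one (default \code{TRUE}); with \code{FALSE} all maximal
#'   valid windows are returned.
#' @return A \code{GRanges} of TTS hits sorted by (seqname, start,
#'   tfoStart), strand = purine strand, with metadata columns \code{tfoId},
#'   \code{tfoStart}, \code{tfoEnd} (1-based closed on the TFO),
#'   \code{motif}, \code{orientation}, \code{mismatches} and \code{score}.
#' @examples
#' findTTS(strrep("A", 15), strrep("A", 15), minLen = 12)
#' @export
findTTS <- function(tfo, duplex, minLen = 12L, maxErrorRate = 0.2,
                    motifs = c("antiparallel_purine", "parallel_pyrimidine"),
                    tfoId = NULL, merge = TRUE) {
  motifs <- match.arg(motifs, .TRIPLEX_MOTIFS, several.ok = TRUE)
  minLen <- as.integer(minLen)
  if (minLen < 1L) stop("'minLen' must be >= 1")
  if (maxErrorRate < 0 || maxErrorRate >= 1)
    stop("'maxErrorRate' must be in [0, 1)")

  if (is.null(tfoId))
    tfoId <- if (!is.null(names(tfo)) && length(names(tfo)) == 1L)
      names(tfo) else "tfo"
  tchar <- .asDNAChar(if (is(tfo, "XStringSet")) tfo[[1L]] else tfo)
  tvec <- .encodeBases(tchar, "tfo")
  nT <- length(tvec)

  if (minLen > nT) {
    warning("'minLen' exceeds the TFO length; returning no hits")
    return(.emptyHits())
  }

  duplex <- if (is(duplex, "DNAStringSet")) duplex
    else Biostrings::DNAStringSet(setNames(.asDNAChar(duplex), "duplex"))
  if (is.null(names(duplex)))
    names(duplex) <- paste0("seq", seq_along(duplex))

  rows <- list()
  for (si in seq_along(duplex)) {
    sname <- names(duplex)[si]
    plus <- toupper(as.character(duplex[[si]]))
    pvec_plus <- .encodeBases(plus, "duplex")
    nD <- length(pvec_plus)
    pvec_minus <- .encodeBases(
      as.character(Biostrings::reverseComplement(duplex[[si]])), "duplex")

    for (str in c("+", "-")) {
      pvec <- if (str == "+") pvec_plus else pvec_minus
      for (motif in motifs) {
        anti <- .MOTIF_ORIENTATION[[motif]] == "antiparallel"
        tq <- if (anti) rev(tvec) else tvec
        m <- scan_maximal_windows(tq, pvec, triplexCode(motif),
                                  minLen, maxErrorRate)
        if (!nrow(m)) next
        len <- m[, "len"]
        mm <- m[, "mismatches"]
        keep <- len - mm >= 1L          # require >= 1 matched position
        if (!any(keep)) next
        m <- m[keep, , drop = FALSE]
        len <- len[keep]; mm <- mm[keep]
        t0 <- if (anti) nT - (m[, "tfo_start"] + len) else m[, "tfo_start"]
        d0 <- if (str == "+") m[, "pur_start"] else
          nD - (m[, "pur_start"] + len)
        rows[[length(rows) + 1L]] <- data.frame(
          seqname = sname, dstart = d0 + 1L, dend = d0 + len, strand = str,
          tstart = t0 + 1L, tend = t0 + len, motif = motif,
          orientation = unname(.MOTIF_ORIENTATION[motif]),
          mismatches = mm, score = len - mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(.emptyHits())
  hits <- do.call(rbind, rows)
  if (merge) hits <- .mergeHits(hits)
  gr <- GenomicRanges::GRanges(
    seqnames = hits$seqname,
    ranges = IRanges::IRanges(hits$dstart, hits$dend),
    strand = hits$strand,
    tfoId = tfoId, tfoStart = hits$tstart, tfoEnd = hits$tend,
    motif = hits$motif, orientation = hits$orientation,
    mismatches = hits$mismatches, score = hits$score)
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), gr$tfoStart)
  gr[ord]
}

.emptyHits <- function() {
  GenomicRanges::GRanges(
    tfoId = character(0), tfoStart = integer(0), tfoEnd = integer(0),
    motif = character(0), orientation = character(0),
    mismatches = integer(0), score = integer(0))
}

## Greedy merge: within each (seqname, strand, motif) group, visit hits by
## decreasing score, then leftmost DNA, then leftmost RNA coordinate; keep a
## hit unless a kept hit overlaps it on both the DNA and the RNA side.
.mergeHits <- function(df) {
  ord <- order(df$seqname, df$strand, df$motif, -df$score, df$dstart,
               df$tstart)
  df <- df[ord, , drop = FALSE]
  key <- paste(df$seqname, df$strand, df$motif)
  keep <- logical(nrow(df))
  for (g in split(seq_len(nrow(df)), key)) {
    kept <- integer(0)
    for (i in g) {
      clash <- FALSE
      for (j in kept) {
        if (df$dstart[i] <= df$dend[j] && df$dend[i] >= df$dstart[j] &&
            df$tstart[i] <= df$tend[j] && df$tend[i] >= df$tstart[j]) {
          clash <- TRUE
          break
        }
      }
      if (!clash) {
        kept <- c(kept, i)
        keep[i] <- TRUE
      }
    }
  }
  df[keep, , drop = FALSE]
}
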