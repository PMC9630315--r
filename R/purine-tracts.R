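#' Candidate triplex target tracts: purine-rich runs on either duplex strand
#'
#' Scans a duplex (given as its plus strand; the complementary strand is
#' implied) for maximal intervals in which one strand is purine-rich, i.e.
#' carries at most \code{maxInterruptions} pyrimidines. Such GA-rich tracts
#' are the canonical triplex target sites read by a third strand in the
#' major groove. Minus-strand tracts are reported in plus-strand coordinates
#' with strand \code{"-"}.
#'
#' An interval is reported when (i) its length is at least \code{minLen},
#' (ii) the number of pyrimidines on the tract strand is at most
#' \code{maxInterruptions}, and (iii) it is maximal: no extension by one
#' base on either side still satisfies the interruption budget.
#'
#' @param duplex A \code{DNAString}, single-sequence \code{DNAStringSet}, or
#'   character scalar: the plus strand of the duplex.
#' @param minLen Minimum tract length in nt (default 12).
#' @param maxInterruptions Maximum number of pyrimidine interruptions on the
#'   tract strand (default 1).
#' @param seqname Sequence name used in the returned \code{GRanges}.
#' @return A \code{GRanges} (plus-strand coordinates, 1-based closed) with
#'   strand set to the purine-carrying strand and a metadata column
#'   \code{interruptions}.
#' @examples
#' purineTracts("AAAAAAAAAAAAAA", minLen = 12)          # one "+" tract
#' purineTracts(strrep("C", 14), minLen = 12)           # one "-" tract
#' @export
purineTracts <- function(duplex, minLen = 12L, maxInterruptions = 1L,
                         seqname = "duplex") {
  sq <- .asDNAChar(duplex)
  code <- .encodeBases(sq, "duplex")
  n <- length(code)
  minLen <- as.integer(minLen)
  k <- as.integer(maxInterruptions)
  if (minLen < 1L) stop("'minLen' must be >= 1")
  if (k < 0L) stop("'maxInterruptions' must be >= 0")

  res <- list()
  for (str in c("+", "-")) {
    ## pyrimidine indicator on the tract strand: plus strand counts C/T;
    ## minus strand purines sit opposite plus-strand C/T's complement,
    ## i.e. plus-strand A/G are the minus-strand pyrimidine positions.
    pyr <- if (str == "+") code %in% c(2L, 4L) else code %in% c(1L, 3L)
    iv <- .maximalBudgetRuns(pyr, k, minLen)
    if (nrow(iv))
      res[[str]] <- GenomicRanges::GRanges(
        seqnames = seqname,
        ranges = IRanges::IRanges(start = iv[, 1L], end = iv[, 2L]),
        strand = str,
        interruptions = iv[, 3L])
  }
  if (!length(res))
    return(GenomicRanges::GRanges(interruptions = integer(0)))
  out <- do.call(c, unname(res))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

## Maximal windows [l, r] (1-based closed) with sum(flag[l:r]) <= k and
## width >= minLen. Uses the monotone two-pointer bound r(l); a candidate is
## maximal iff it is not contained in the candidate starting one base left.
.maximalBudgetRuns <- function(flag, k, minLen) {
  n <- length(flag)
  out <- matrix(integer(0), ncol = 3L)
  if (n < minLen) return(out)
  pre <- c(0L, cumsum(as.integer(flag)))
  r <- integer(n)
  j <- 0L
  for (l in seq_len(n)) {
    if (j < l - 1L) j <- l - 1L
    while (j < n && pre[j + 2L] - pre[l] <= k) j <- j + 1L
    r[l] <- j
  }
  keep <- which(r - seq_len(n) + 1L >= minLen &
                  (seq_len(n) == 1L | c(0L, r[-n]) < r))
  if (!length(keep)) return(out)
  cbind(keep, r[keep], pre[r[keep] + 1L] - pre[keep])
}

## Coerce sequence input to a plain uppercase character scalar.
.asDNAChar <- function(x) {
  if (is(x, "XStringSet")) {
    if (length(x) != 1L)
      stop("expected a single sequence")
    x <- x[[1L]]
  }
  toupper(as.character(x))
}
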