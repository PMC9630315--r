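## TFR discovery against a genomic region set with a shuffle-based
## empirical null, plus cross-TFR target-site overlap.

#' Evaluate code with a transient RNG seed
#'
#' Runs \code{expr} with the RNG seeded at \code{seed}, restoring the
#' caller's RNG state afterwards; with \code{seed = NULL} the expression
#' runs under the current RNG state.
#' @noRd
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Shuffle genomic regions preserving lengths and chromosomes
#'
#' Places the input regions uniformly at random, mutually non-overlapping,
#' on their own chromosomes (chromosome-preserving null). Region lengths are
#' conserved as a multiset per chromosome.
#'
#' @param regions A \code{GRanges} of target regions.
#' @param genomeBounds Named integer vector of chromosome lengths covering
#'   every chromosome used by \code{regions}.
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @return A \code{GRanges} with the same number of regions and the same
#'   per-chromosome length multiset, uniformly re-placed without overlap.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50))
#' shuffleRegions(gr, c(chr1 = 1000), seed = 1)
#' @export
shuffleRegions <- function(regions, genomeBounds, seed = NULL) {
  chroms <- as.character(GenomicRanges::seqnames(regions))
  if (!all(chroms %in% names(genomeBounds)))
    stop("'genomeBounds' must name every chromosome in 'regions'")
  .withSeed(seed, {
    starts <- integer(length(regions))
    for (ch in unique(chroms)) {
      idx <- which(chroms == ch)
      lens <- GenomicRanges::width(regions)[idx]
      L <- as.integer(genomeBounds[[ch]])
      free <- L - sum(lens)
      if (free < 0L)
        stop("regions do not fit on chromosome '", ch,
             "' without overlap (capacity error)")
      perm <- sample.int(length(idx))
      offs <- sort(sample.int(free + 1L, length(idx), replace = TRUE) - 1L)
      st <- offs + cumsum(c(0L, lens[perm][-length(idx)])) + 1L
      starts[idx[perm]] <- st
    }
    out <- regions
    GenomicRanges::ranges(out) <- IRanges::IRanges(
      start = starts, width = GenomicRanges::width(regions))
    out
  })
}

#' Count target regions carrying at least one triplex hit
#'
#' Extracts the duplex sequence of each region from \code{genome}, scans it
#' with \code{\link{findTTS}} against \code{rna}, and counts regions with at
#' least one hit. This is the test statistic of the randomization
#' enrichment test.
#'
#' @param rna The RNA sequence (TFO source).
#' @param regions \code{GRanges} of target regions.
#' @param genome Named \code{DNAStringSet} with one entry per chromosome.
#' @inheritParams findTTS
#' @param detail If \code{TRUE}, also return the per-region RNA-side hit
#'   intervals.
#' @return The count (integer), or with \code{detail = TRUE} a list with
#'   \code{count}, logical \code{hitRegion}, and \code{rnaIntervals} (a
#'   list of \code{IRanges} on the RNA, one per region).
#' @export
regionHitCount <- function(rna, regions, genome, minLen = 12L,
                           maxErrorRate = 0.2,
                           motifs = c("antiparallel_purine",
                                      "parallel_pyrimidine"),
                           detail = FALSE) {
  motifs <- match.arg(motifs, .TRIPLEX_MOTIFS, several.ok = TRUE)
  tvec <- .encodeBases(.asDNAChar(
    if (is(rna, "XStringSet")) rna[[1L]] else rna), "rna")
  scanner <- .rnaScanner(tvec, motifs, minLen, maxErrorRate)
  res <- .scanRegions(scanner, .encodeGenome(genome), regions)
  if (!detail) return(res$count)
  list(count = res$count, hitRegion = res$hitRegion,
       rnaIntervals = lapply(res$raw, function(w) {
         if (is.null(w) || !nrow(w)) return(IRanges::IRanges())
         IRanges::reduce(IRanges::IRanges(w[, 1L] + 1L, w[, 1L] + w[, 2L]))
       }))
}

.encodeGenome <- function(genome) {
  lapply(setNames(names(genome), names(genome)), function(ch)
    .encodeBases(as.character(genome[[ch]]), ch))
}

## Scans every region; `raw` holds per-region matrices of RNA-side windows
## (0-based start, length) straight from the C++ scan (no S4 on this path).
.scanRegions <- function(scanner, chromChars, regions) {
  chroms <- as.character(GenomicRanges::seqnames(regions))
  starts <- GenomicRanges::start(regions)
  ends <- GenomicRanges::end(regions)
  if (!all(chroms %in% names(chromChars)))
    stop("region chromosome(s) absent from the genome")
  if (any(starts < 1L) ||
      any(ends > lengths(chromChars)[chroms]))
    stop("region(s) extend beyond the chromosome bounds")
  raw <- vector("list", length(regions))
  hit <- logical(length(regions))
  for (i in seq_along(regions)) {
    w <- scanner(chromChars[[chroms[i]]][starts[i]:ends[i]])
    raw[[i]] <- w
    hit[i] <- nrow(w) > 0L
  }
  list(count = sum(hit), hitRegion = hit, raw = raw)
}

## Lean scanning closure used by the randomization machinery: precomputes
## the encoded RNA (both orientations) and pairing tables, and returns the
## reduced RNA-side hit intervals for one encoded duplex plus strand.
## Hit semantics match findTTS(..., merge = FALSE): interval reduction of
## maximal valid windows is unaffected by merging.
.rnaScanner <- function(tvec, motifs, minLen, maxErrorRate) {
  usePar <- "parallel_pyrimidine" %in% motifs
  useAnti <- "antiparallel_purine" %in% motifs
  codePar <- triplexCode("parallel_pyrimidine")
  codeAnti <- triplexCode("antiparallel_purine")
  function(pvecPlus)
    scan_region_hits(tvec, pvecPlus, codePar, codeAnti, usePar, useAnti,
                     minLen, maxErrorRate)
}

#' Empirical p-value with plus-one correction
#'
#' \code{(1 + #\{null >= observed\}) / (1 + n)}: the rank-based estimator
#' that can never return zero and is bounded below by \code{1/(n + 1)}.
#'
#' @param observed Observed test statistic.
#' @param nullCounts Numeric vector of the statistic under the null.
#' @return The empirical p-value.
#' @examples
#' empiricalP(10, rep(0, 50))  # 1/51
#' @export
empiricalP <- function(observed, nullCounts) {
  (1 + sum(nullCounts >= observed)) / (1 + length(nullCounts))
}

#' Discover triplex-forming regions within an RNA
#'
#' Candidate TFR windows are the maximal runs of RNA positions covered by at
#' least one triplex hit against the observed region set. Each window is
#' scored by the number of regions containing a hit overlapping it; its null
#' distribution is obtained by re-scoring against \code{nRandomizations}
#' position-shuffled region sets (\code{\link{shuffleRegions}}), and its
#' empirical p-value uses the plus-one estimator
#' \code{(1 + #\{null >= obs\}) / (1 + n)}. Windows with \code{p < alpha}
#' are merged (overlapping or abutting) into maximal TFR intervals.
#'
#' @inheritParams regionHitCount
#' @param nRandomizations Number of region shuffles for the null
#'   (default 200).
#' @param alpha Significance level on the raw empirical p-value
#'   (default 0.05); no multiple-testing correction across windows is
#'   applied.
#' @param seed Optional integer seed controlling the shuffles.
#' @param rnaId Identifier recorded for the RNA.
#' @return A \code{DataFrame} of TFRs with columns \code{rnaId},
#'   \code{start}, \code{end} (1-based closed on the RNA),
#'   \code{nTargetRegionsHit}, \code{empiricalP}, \code{nRandomizations}.
#'   \code{metadata()$windows} holds every candidate window with its
#'   observed count, null counts and p-value.
#' @export
discoverTFRs <- function(rna, regions, genome, minLen = 12L,
                         maxErrorRate = 0.2,
                         motifs = c("antiparallel_purine",
                                    "parallel_pyrimidine"),
                         nRandomizations = 200L, alpha = 0.05, seed = NULL,
                         rnaId = "rna") {
  if (nRandomizations < 1L) stop("'nRandomizations' must be >= 1")
  empty <- S4Vectors::DataFrame(
    rnaId = character(0), start = integer(0), end = integer(0),
    nTargetRegionsHit = integer(0), empiricalP = numeric(0),
    nRandomizations = integer(0))
  if (!length(regions)) {
    warning("empty region set; no TFRs to report")
    return(empty)
  }
  bounds <- setNames(Biostrings::width(genome), names(genome))

  motifs <- match.arg(motifs, .TRIPLEX_MOTIFS, several.ok = TRUE)
  tvec <- .encodeBases(.asDNAChar(
    if (is(rna, "XStringSet")) rna[[1L]] else rna), "rna")
  scanner <- .rnaScanner(tvec, motifs, minLen, maxErrorRate)
  chromChars <- .encodeGenome(genome)

  obs <- .scanRegions(scanner, chromChars, regions)
  allRaw <- do.call(rbind, obs$raw)
  if (is.null(allRaw) || !nrow(allRaw)) {
    warning("no triplex hits against the observed region set")
    return(empty)
  }
  windows <- IRanges::reduce(IRanges::IRanges(allRaw[, 1L] + 1L,
                                              allRaw[, 1L] + allRaw[, 2L]))
  winSt <- IRanges::start(windows)
  winEn <- IRanges::end(windows)

  ## regions containing >= 1 hit whose RNA interval overlaps each window
  countPerWindow <- function(raw) {
    out <- integer(length(winSt))
    for (w in raw) {
      if (!nrow(w)) next
      st <- w[, 1L] + 1L
      en <- w[, 1L] + w[, 2L]
      for (k in seq_along(winSt))
        if (any(st <= winEn[k] & en >= winSt[k]))
          out[k] <- out[k] + 1L
    }
    out
  }
  observed <- countPerWindow(obs$raw)

  nulls <- .withSeed(seed, {
    m <- matrix(0L, nRandomizations, length(windows))
    for (b in seq_len(nRandomizations)) {
      shuf <- shuffleRegions(regions, bounds)
      m[b, ] <- countPerWindow(.scanRegions(scanner, chromChars, shuf)$raw)
    }
    m
  })

  pvals <- vapply(seq_along(windows), function(w)
    empiricalP(observed[w], nulls[, w]), numeric(1))

  winDF <- S4Vectors::DataFrame(
    start = IRanges::start(windows), end = IRanges::end(windows),
    nTargetRegionsHit = observed, empiricalP = pvals,
    nullCounts = I(asplit(nulls, 2)))

  sig <- pvals < alpha
  if (!any(sig)) {
    S4Vectors::metadata(empty)$windows <- winDF
    return(empty)
  }
  tfrIv <- IRanges::reduce(windows[sig])
  hitmax <- vapply(seq_along(tfrIv), function(i) {
    inside <- IRanges::overlapsAny(windows, tfrIv[i])
    max(observed[inside & sig])
  }, integer(1))
  pmin_ <- vapply(seq_along(tfrIv), function(i) {
    inside <- IRanges::overlapsAny(windows, tfrIv[i])
    min(pvals[inside & sig])
  }, numeric(1))
  out <- S4Vectors::DataFrame(
    rnaId = rnaId, start = IRanges::start(tfrIv), end = IRanges::end(tfrIv),
    nTargetRegionsHit = hitmax, empiricalP = pmin_,
    nRandomizations = as.integer(nRandomizations))
  S4Vectors::metadata(out)$windows <- winDF
  out
}

#' Genomic target-site intervals shared by several TFR hit sets
#'
#' Reduces each hit set to its genomic intervals (strand-blind) and
#' intersects them across all sets; an interval is shared when every set
#' overlaps it by at least one base pair.
#'
#' @param hitSets A list of at least two \code{GRanges} (e.g. outputs of
#'   \code{\link{findTTS}} for different TFRs).
#' @return A list with \code{intervals} (the shared \code{GRanges}) and
#'   \code{count}.
#' @export
overlapTTS <- function(hitSets) {
  if (!is.list(hitSets) || length(hitSets) < 2L)
    stop("'hitSets' must be a list of at least two hit sets")
  red <- lapply(hitSets, function(g)
    IRanges::reduce(GenomicRanges::granges(g), ignore.strand = TRUE))
  shared <- Reduce(function(a, b)
    GenomicRanges::intersect(a, b, ignore.strand = TRUE), red)
  list(intervals = shared, count = length(shared))
}
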