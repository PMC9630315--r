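## Seeded synthetic-data generators. Every generator is deterministic under
## a seed and returns its ground truth alongside the data, so each
## downstream stage can be tested without external downloads.

#' Generate a random genome
#'
#' Chromosomes of i.i.d. bases at a requested GC fraction (no dinucleotide
#' structure; a documented simplification sufficient for testing pattern
#' searches).
#'
#' @param nChroms Number of chromosomes.
#' @param chromLen Chromosome length in nt (>= 100).
#' @param gcFraction Fraction of G+C in [0, 1]; G and C (and A and T) are
#'   equiprobable within their class.
#' @param seed Optional integer seed.
#' @return A named \code{DNAStringSet} (\code{chr1}, \code{chr2}, ...) with
#'   a \code{metadata()} manifest recording the generator settings.
#' @examples
#' makeGenome(1, 1000, 0.5, seed = 7)
#' @export
makeGenome <- function(nChroms = 1L, chromLen, gcFraction = 0.5,
                       seed = NULL) {
  if (nChroms < 1L) stop("'nChroms' must be positive")
  if (chromLen < 100L) stop("'chromLen' must be at least 100 nt")
  if (gcFraction < 0 || gcFraction > 1)
    stop("'gcFraction' must be in [0, 1]")
  prob <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
            G = gcFraction / 2, T = (1 - gcFraction) / 2)
  .withSeed(seed, {
    seqs <- vapply(seq_len(nChroms), function(i)
      paste(sample(names(prob), chromLen, replace = TRUE, prob = prob),
            collapse = ""), character(1))
    genome <- Biostrings::DNAStringSet(setNames(
      seqs, paste0("chr", seq_len(nChroms))))
    S4Vectors::metadata(genome) <- list(
      generator = "makeGenome", nChroms = nChroms, chromLen = chromLen,
      gcFraction = gcFraction, seed = seed)
    genome
  })
}

## Purine-strand sequence Hoogsteen-matched to a TFO under a motif code.
## Positions whose third-strand base has no allowed purine partner (e.g. C
## in the purine motif) are forced mismatches, filled with a pyrimidine so
## they stay mismatches under the motif.
.matchedPurineStrand <- function(tfoChars, motif) {
  anti <- .MOTIF_ORIENTATION[[motif]] == "antiparallel"
  third <- if (anti) rev(tfoChars) else tfoChars
  code <- triplexCode(motif)
  out <- character(length(third))
  forced <- logical(length(third))
  for (i in seq_along(third)) {
    partners <- .BASES[code[third[i], ]]
    if (length(partners)) {
      out[i] <- partners[1L]
    } else {
      forced[i] <- TRUE
      out[i] <- sample(c("C", "T"), 1L)
    }
  }
  list(strand = out, forced = forced)
}

#' Plant triplex target sites into a genome
#'
#' Writes duplex target sequences at random non-overlapping positions such
#' that the purine strand Hoogsteen-matches \code{tfo} under the chosen
#' motif with a mismatch fraction of at most \code{mismatchRate}
#' (third-strand bases with no purine partner under the motif, such as C in
#' the purine motif, are unavoidable mismatches and count against the
#' budget). Each site's purine strand is placed on a randomly chosen
#' genomic strand, recorded in the truth.
#'
#' @param genome A named \code{DNAStringSet}.
#' @param tfo The third-strand sequence (>= \code{minLen} nt).
#' @param nSites Number of sites to plant (0 leaves the genome unchanged).
#' @param mismatchRate Maximum tolerated mismatch fraction per site.
#' @param motif Binding motif of the planted sites.
#' @param seed Optional integer seed.
#' @param minLen Minimum TFO length accepted (default 12).
#' @return A list with \code{genome} (modified \code{DNAStringSet}) and
#'   \code{truth}: a \code{GRanges} of planted intervals (1-based closed)
#'   with strand = purine strand and a \code{mismatches} column.
#' @examples
#' g <- makeGenome(1, 1000, 0.5, seed = 1)
#' plantTTS(g, strrep("GA", 8), nSites = 3, seed = 2)$truth
#' @export
plantTTS <- function(genome, tfo, nSites, mismatchRate = 0,
                     motif = c("antiparallel_purine",
                               "parallel_pyrimidine"),
                     seed = NULL, minLen = 12L) {
  motif <- match.arg(motif)
  tchar <- .BASES[.encodeBases(.asDNAChar(
    if (is(tfo, "XStringSet")) tfo[[1L]] else tfo), "tfo")]
  len <- length(tchar)
  if (len < minLen)
    stop("'tfo' must be at least ", minLen, " nt")
  if (nSites == 0L)
    return(list(genome = genome, truth = GenomicRanges::GRanges()))

  .withSeed(seed, {
    ms <- .matchedPurineStrand(tchar, motif)
    if (sum(ms$forced) / len > mismatchRate + 1e-9)
      stop("tfo contains ", sum(ms$forced), " base(s) with no partner ",
           "under the '", motif, "' code; mismatchRate must be at least ",
           signif(sum(ms$forced) / len, 3))
    purineStrand <- paste(ms$strand, collapse = "")

    lens <- Biostrings::width(genome)
    if (nSites * len > sum(lens))
      stop("genome too small to place ", nSites,
           " non-overlapping sites (capacity error)")
    placed <- GenomicRanges::GRanges()
    tries <- 0L
    while (length(placed) < nSites) {
      if ((tries <- tries + 1L) > 1000L * nSites)
        stop("could not place ", nSites,
             " non-overlapping sites (capacity error)")
      ci <- sample.int(length(genome), 1L)
      if (lens[ci] < len) next
      st <- sample.int(lens[ci] - len + 1L, 1L)
      cand <- GenomicRanges::GRanges(names(genome)[ci],
                                     IRanges::IRanges(st, st + len - 1L),
                                     strand = sample(c("+", "-"), 1L))
      if (length(placed) &&
          any(IRanges::overlapsAny(cand, placed, ignore.strand = TRUE)))
        next
      placed <- c(placed, cand)
    }
    placed$mismatches <- sum(ms$forced)

    for (i in seq_along(placed)) {
      ch <- as.character(GenomicRanges::seqnames(placed))[i]
      ins <- if (as.character(GenomicRanges::strand(placed))[i] == "+")
        purineStrand
      else as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(purineStrand)))
      Biostrings::subseq(genome[[ch]],
                         GenomicRanges::start(placed)[i],
                         GenomicRanges::end(placed)[i]) <-
        Biostrings::DNAString(ins)
    }
    list(genome = genome,
         truth = GenomicRanges::sort(placed, ignore.strand = TRUE))
  })
}

#' Generate an RNA with a planted triplex-forming region
#'
#' A random-background RNA in which \code{tfo} is embedded at
#' \code{tfrStart}; the embedded interval is the ground-truth TFR for
#' recovery tests.
#'
#' @param rnaLen Total RNA length in nt.
#' @param tfo The sequence to embed (stored with RNA alphabet, U for T).
#' @param tfrStart 1-based start of the embedded TFR.
#' @param gcFraction Background GC fraction.
#' @param seed Optional integer seed.
#' @return A list with \code{rna} (a named \code{RNAStringSet} of length 1)
#'   and \code{truth} (an \code{IRanges} of the planted TFR).
#' @export
makeLncRNA <- function(rnaLen, tfo, tfrStart, gcFraction = 0.5,
                       seed = NULL) {
  tchar <- .BASES[.encodeBases(.asDNAChar(
    if (is(tfo, "XStringSet")) tfo[[1L]] else tfo), "tfo")]
  len <- length(tchar)
  if (tfrStart < 1L || tfrStart + len - 1L > rnaLen)
    stop("planted TFR does not fit in the RNA")
  prob <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
            G = gcFraction / 2, T = (1 - gcFraction) / 2)
  .withSeed(seed, {
    bg <- sample(names(prob), rnaLen, replace = TRUE, prob = prob)
    bg[tfrStart:(tfrStart + len - 1L)] <- tchar
    rna <- Biostrings::RNAStringSet(setNames(
      chartr("T", "U", paste(bg, collapse = "")), "synthetic_rna"))
    list(rna = rna, truth = IRanges::IRanges(tfrStart, tfrStart + len - 1L))
  })
}

#' Generate a synthetic per-lncRNA peak table
#'
#' Observed counts are Poisson(\code{backgroundLambda}) for background rows
#' and Poisson(\code{backgroundLambda * enrichedFold}) for the first
#' \code{nEnriched} rows; the expected column is the background rate, so
#' fold enrichment and the Poisson tail p-value are computed exactly as the
#' screen would on real peak summaries.
#'
#' @param nLncrnas Number of rows (lncRNAs).
#' @param nEnriched Number of truly enriched rows (<= \code{nLncrnas}).
#' @param backgroundLambda Background expected read count (> 0).
#' @param enrichedFold True fold enrichment of enriched rows.
#' @param seed Optional integer seed.
#' @return A list with \code{peaks} (a \code{data.frame} with
#'   \code{lncrna_id}, interval columns, \code{observed_reads},
#'   \code{expected_reads}, \code{fold_enrichment}, \code{p_enrich},
#'   \code{neg_log10_p}) and \code{truth} (\code{lncrna_id},
#'   \code{true_lambda}, \code{is_enriched}).
#' @examples
#' makePeakTable(5, 1, 5, 20, seed = 1)$truth
#' @export
makePeakTable <- function(nLncrnas, nEnriched = 0L, backgroundLambda,
                          enrichedFold = 1, seed = NULL) {
  if (nEnriched > nLncrnas)
    stop("'nEnriched' must not exceed 'nLncrnas'")
  if (backgroundLambda <= 0) stop("'backgroundLambda' must be positive")
  if (enrichedFold <= 0) stop("'enrichedFold' must be positive")
  .withSeed(seed, {
    enriched <- seq_len(nLncrnas) <= nEnriched
    lam <- ifelse(enriched, backgroundLambda * enrichedFold,
                  backgroundLambda)
    obs <- stats::rpois(nLncrnas, lam)
    enr <- poissonEnrichment(obs, rep(backgroundLambda, nLncrnas))
    ids <- sprintf("lnc%04d", seq_len(nLncrnas))
    peaks <- data.frame(
      lncrna_id = ids, chrom = "chr1",
      start = (seq_len(nLncrnas) - 1L) * 1000L + 1L,
      end = (seq_len(nLncrnas) - 1L) * 1000L + 500L,
      observed_reads = obs, expected_reads = backgroundLambda,
      fold_enrichment = enr$fold_enrichment, p_enrich = enr$p_enrich,
      neg_log10_p = enr$neg_log10_p)
    truth <- data.frame(lncrna_id = ids, true_lambda = lam,
                        is_enriched = enriched)
    list(peaks = peaks, truth = truth)
  })
}

#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' Builds a tidy replicated Ct table in which the delta-delta Ct statistic
#' recovers the requested fold changes in expectation: control target and
#' reference Cts sit at \code{baseCt}, and the treated target Ct is lowered
#' by \code{log2(fold)} cycles. Gaussian noise of sd \code{noiseSd} cycles
#' is added independently to every measured Ct.
#'
#' @param trueFoldChanges Named (or unnamed) positive numeric vector of
#'   fold changes, one per analyte.
#' @param baseCt Baseline Ct in cycles (default 25).
#' @param noiseSd Gaussian noise sd in cycles (default 0).
#' @param nReplicates Replicates per condition (default 3).
#' @param seed Optional integer seed.
#' @return A list with \code{ct} (columns \code{analyte_id},
#'   \code{condition}, \code{replicate}, \code{target_ct},
#'   \code{reference_ct}) and \code{truth} (\code{analyte_id},
#'   \code{true_fold}).
#' @examples
#' tab <- makeCtTable(c(geneA = 4), noiseSd = 0)
#' summarizeCtTable(tab$ct)  # recovers 4 exactly
#' @export
makeCtTable <- function(trueFoldChanges, baseCt = 25, noiseSd = 0,
                        nReplicates = 3L, seed = NULL) {
  if (any(trueFoldChanges <= 0)) stop("fold changes must be positive")
  ids <- names(trueFoldChanges)
  if (is.null(ids)) ids <- sprintf("analyte%02d", seq_along(trueFoldChanges))
  .withSeed(seed, {
    rows <- do.call(rbind, lapply(seq_along(trueFoldChanges), function(i) {
      fold <- trueFoldChanges[[i]]
      expand.grid(analyte_id = ids[i],
                  condition = c("control", "treated"),
                  replicate = seq_len(nReplicates),
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }))
    shift <- ifelse(rows$condition == "treated",
                    log2(trueFoldChanges[match(rows$analyte_id, ids)]), 0)
    rows$target_ct <- baseCt - shift + stats::rnorm(nrow(rows), 0, noiseSd)
    rows$reference_ct <- baseCt + stats::rnorm(nrow(rows), 0, noiseSd)
    list(ct = rows,
         truth = data.frame(analyte_id = ids,
                            true_fold = unname(trueFoldChanges)))
  })
}

#' Simulate a melting curve from the double-sigmoid model
#'
#' Evaluates the melting model on a temperature grid and adds
#' homoscedastic Gaussian noise.
#'
#' @param a,x0,b,c,x2,d Model parameters (amplitudes \code{a}, \code{c};
#'   midpoints \code{x0}, \code{x2} in degrees C; slopes \code{b},
#'   \code{d} > 0).
#' @param tMin,tMax,step Temperature grid in degrees C (default 5 to 95
#'   every 0.25 degC, a typical read density for a 1 degC/min CD melt).
#' @param noiseSd Gaussian noise sd (default 0).
#' @param seed Optional integer seed.
#' @param curveId Identifier for the curve.
#' @return A \code{\linkS4class{MeltingCurve}}.
#' @examples
#' makeMeltingCurve(0.5, 49.52, 3, 0.5, 79.90, 3)
#' @export
makeMeltingCurve <- function(a, x0, b, c, x2, d, tMin = 5, tMax = 95,
                             step = 0.25, noiseSd = 0, seed = NULL,
                             curveId = "curve") {
  if (tMin >= tMax) stop("'tMin' must be below 'tMax'")
  if (b <= 0 || d <= 0) stop("slope parameters b, d must be positive")
  temps <- seq(tMin, tMax, by = step)
  vals <- evalMeltingModel(c(a = a, x0 = x0, b = b, c = c, x2 = x2, d = d),
                           temps)
  .withSeed(seed, {
    if (noiseSd > 0) vals <- vals + stats::rnorm(length(vals), 0, noiseSd)
    MeltingCurve(temps, vals, curveId)
  })
}
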