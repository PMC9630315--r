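# Synthetic-data generators: composition, determinism, planted-truth
# recoverability, and manifest round-trips.

tfo23 <- function() subset(referenceOligos(), name == "TFO2-23")$sequence

test_that("makeGenome honors composition and is byte-deterministic", {
  g <- makeGenome(1, 10000, 0.5, seed = 7)
  gc <- sum(Biostrings::letterFrequency(g, c("G", "C"))) / 10000
  expect_lt(abs(gc - 0.5), 0.02)

  at <- makeGenome(1, 100, 0, seed = 1)
  expect_equal(sum(Biostrings::letterFrequency(at, c("G", "C"))), 0)

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(makeGenome(2, 500, 0.4, seed = 3), f1)
  Biostrings::writeXStringSet(makeGenome(2, 500, 0.4, seed = 3), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(makeGenome(1, 50, 0.5), "at least 100")
  expect_error(makeGenome(1, 1000, 1.2), "gcFraction")
})

test_that("plantTTS writes recoverable non-overlapping target sites", {
  g <- makeGenome(1, 10000, 0.5, seed = 21)
  ## a TFO with full purine-code coverage plants at zero mismatches
  cleanTfo <- "GAGGAAGGAAGGAGAG"
  pl <- plantTTS(g, cleanTfo, 5, 0, seed = 22)
  expect_equal(length(pl$truth), 5L)
  expect_true(all(GenomicRanges::width(pl$truth) == nchar(cleanTfo)))
  red <- IRanges::reduce(pl$truth, ignore.strand = TRUE)
  expect_equal(length(red), 5L)   # disjoint
  ## every planted site is found exactly, with zero mismatches
  hits <- findTTS(cleanTfo, pl$genome, minLen = nchar(cleanTfo),
                  maxErrorRate = 0)
  perfect <- hits[hits$mismatches == 0]
  ov <- GenomicRanges::findOverlaps(pl$truth, perfect, type = "equal",
                                    ignore.strand = TRUE)
  expect_equal(length(unique(S4Vectors::queryHits(ov))), 5L)

  ## the in-study TFO carries two cytosines: 2/23 forced mismatches
  pl2 <- plantTTS(g, tfo23(), 5, 0.1, seed = 23)
  expect_equal(length(pl2$truth), 5L)
  expect_true(all(GenomicRanges::width(pl2$truth) == 23L))
  expect_error(plantTTS(g, tfo23(), 2, 0, seed = 1), "mismatchRate")

  ## no sites requested leaves the genome untouched
  un <- plantTTS(g, cleanTfo, 0, 0, seed = 1)
  expect_identical(as.character(un$genome), as.character(g))

  ## capacity errors on an impossible request
  tiny <- makeGenome(1, 100, 0.5, seed = 2)
  expect_error(plantTTS(tiny, cleanTfo, 10, 0, seed = 1), "capacity")

  ## deterministic under a fixed seed
  again <- plantTTS(g, cleanTfo, 5, 0, seed = 22)
  expect_identical(as.character(again$genome), as.character(pl$genome))
  expect_equal(as.data.frame(again$truth), as.data.frame(pl$truth))
})

test_that("planted sites are recorded on the strand carrying the purine tract", {
  g <- makeGenome(1, 5000, 0.5, seed = 24)
  pl <- plantTTS(g, "GAGGAAGGAAGGAGAG", 6, 0, seed = 25)
  for (i in seq_along(pl$truth)) {
    sq <- Biostrings::subseq(pl$genome[[1]],
                             GenomicRanges::start(pl$truth)[i],
                             GenomicRanges::end(pl$truth)[i])
    if (as.character(GenomicRanges::strand(pl$truth))[i] == "-")
      sq <- Biostrings::reverseComplement(sq)
    pur <- sum(Biostrings::letterFrequency(
      Biostrings::DNAStringSet(sq), c("A", "G")))
    expect_equal(pur, 16L)  # the planted purine strand is all-purine
  }
})

test_that("null peak tables center on fold 1 and seeds reproduce them", {
  tab <- makePeakTable(2000, 0, 5, seed = 31)
  expect_lt(abs(mean(tab$peaks$fold_enrichment) - 1), 0.05)
  expect_false(any(tab$truth$is_enriched))
  again <- makePeakTable(2000, 0, 5, seed = 31)
  expect_identical(tab$peaks, again$peaks)
  expect_error(makePeakTable(10, 20, 5), "nEnriched")
})

test_that("enriched peak rows carry their planted signal", {
  tab <- makePeakTable(200, 3, 5, 20, seed = 32)
  enr <- tab$peaks[tab$truth$is_enriched, ]
  expect_true(all(enr$fold_enrichment > 10))
  expect_true(all(enr$neg_log10_p > 20))
})

test_that("ground truth round-trips through the manifest", {
  g <- makeGenome(1, 2000, 0.5, seed = 41)
  pl <- plantTTS(g, "GAGGAAGGAAGGAGAG", 3, 0, seed = 42)
  truth <- list(genome_id = "toy", seed = 42L,
                planted_tts = pl$truth,
                planted_tfr = IRanges::IRanges(30, 52),
                peak_truth = makePeakTable(5, 1, 5, 20, seed = 1)$truth)
  path <- tempfile(fileext = ".json")
  writeTruthManifest(truth, path)
  back <- readTruthManifest(path)
  expect_equal(back$genome_id, "toy")
  expect_equal(back$seed, 42L)
  expect_equal(back$planted_tts$start, GenomicRanges::start(pl$truth))
  expect_equal(back$planted_tts$end, GenomicRanges::end(pl$truth))
  expect_equal(back$planted_tts$strand,
               as.character(GenomicRanges::strand(pl$truth)))
  expect_equal(back$planted_tfr$start, 30L)
  expect_equal(back$peak_truth$is_enriched, c(TRUE, rep(FALSE, 4)))
})

test_that("strong planted signals are fully recoverable downstream", {
  ## mismatch 0 TTS -> found by the scan; fold 20 peaks -> retained by the
  ## screen; noiseless Ct -> exact folds; noiseless curves -> biphasic call
  g <- makeGenome(1, 8000, 0.5, seed = 51)
  pl <- plantTTS(g, "GAGGAAGGAAGGAGAG", 4, 0, seed = 52)
  hits <- findTTS("GAGGAAGGAAGGAGAG", pl$genome, maxErrorRate = 0)
  expect_true(all(IRanges::overlapsAny(pl$truth, hits,
                                       ignore.strand = TRUE)))

  tab <- makePeakTable(100, 5, 5, 20, seed = 53)
  cand <- data.frame(lncrna_id = tab$peaks$lncrna_id,
                     best_fold_enrichment = tab$peaks$fold_enrichment,
                     best_neg_log10_p = tab$peaks$neg_log10_p,
                     present_in_both_cell_lines = TRUE, nuclear_signal = 1,
                     tissue_aorta = 1, coding_probability = 0.01,
                     overlapping_gene_conflict = FALSE)
  kept <- applyScreen(cand)$retained$lncrna_id
  expect_setequal(kept, tab$truth$lncrna_id[tab$truth$is_enriched])

  ct <- makeCtTable(c(x = 12), noiseSd = 0, seed = 54)
  expect_equal(summarizeCtTable(ct$ct)$fold_change, 12, tolerance = 1e-12)

  cv <- makeMeltingCurve(0.5, 45, 3, 0.5, 80, 3)
  expect_equal(classifyTransition(cv)$model, "biphasic")
})
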