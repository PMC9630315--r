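# Randomization-null TFR discovery and target-site overlap.

tfo23 <- function() subset(referenceOligos(), name == "TFO2-23")$sequence

test_that("shuffleRegions conserves lengths, chromosomes and disjointness", {
  set.seed(501)
  gr <- GenomicRanges::GRanges(
    rep(c("chr1", "chr2"), c(4, 3)),
    IRanges::IRanges(start = c(1, 300, 700, 900, 10, 200, 450),
                     width = c(50, 80, 120, 40, 60, 90, 30)))
  bounds <- c(chr1 = 2000L, chr2 = 1000L)
  sh <- shuffleRegions(gr, bounds, seed = 9)
  expect_equal(as.character(GenomicRanges::seqnames(sh)),
               as.character(GenomicRanges::seqnames(gr)))
  for (ch in names(bounds)) {
    a <- sort(GenomicRanges::width(gr[GenomicRanges::seqnames(gr) == ch]))
    b <- sort(GenomicRanges::width(sh[GenomicRanges::seqnames(sh) == ch]))
    expect_equal(a, b)
  }
  expect_true(all(GenomicRanges::start(sh) >= 1))
  expect_true(all(GenomicRanges::end(sh) <=
                    bounds[as.character(GenomicRanges::seqnames(sh))]))
  red <- IRanges::reduce(sh, ignore.strand = TRUE)
  expect_equal(sum(GenomicRanges::width(red)), sum(GenomicRanges::width(sh)))
  ## determinism
  expect_identical(shuffleRegions(gr, bounds, seed = 9), sh)
})

test_that("a region filling its chromosome is returned unchanged", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500))
  sh <- shuffleRegions(gr, c(chr1 = 500L), seed = 1)
  expect_equal(GenomicRanges::start(sh), 1L)
  expect_equal(GenomicRanges::end(sh), 500L)
  ## and over-full chromosomes raise a capacity error
  gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 1), width = 300))
  expect_error(shuffleRegions(gr2, c(chr1 = 500L), seed = 1), "capacity")
})

test_that("empirical p-values use the plus-one estimator and never reach 0", {
  expect_equal(empiricalP(10, rep(0, 50)), 1 / 51)
  expect_equal(empiricalP(0, rep(5, 50)), 1)
  set.seed(502)
  for (i in 1:20) {
    nulls <- rpois(sample(10:200, 1), 3)
    p <- empiricalP(rpois(1, 3), nulls)
    expect_gt(p, 0)
    expect_gte(p, 1 / (length(nulls) + 1))
    expect_lte(p, 1)
  }
})

test_that("a planted TFR is recovered at the minimum attainable p-value", {
  tfo <- tfo23()
  g <- makeGenome(1, 10000, 0.5, seed = 31)
  pl <- plantTTS(g, tfo, 10, 0.1, seed = 32)
  st <- pmin(pmax(1L, GenomicRanges::start(pl$truth) - 38L), 10000L - 99L)
  regs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, width = 100))
  rna <- makeLncRNA(80, tfo, 30, seed = 33)
  tfr <- discoverTFRs(rna$rna, regs, pl$genome, nRandomizations = 50,
                      seed = 34)
  expect_gte(nrow(tfr), 1L)
  hit <- tfr$start <= IRanges::end(rna$truth) &
    tfr$end >= IRanges::start(rna$truth)
  expect_true(any(hit))
  ## all 10 regions carry the planted site; no shuffle should match that
  expect_equal(max(tfr$nTargetRegionsHit[hit]), 10L)
  expect_equal(min(tfr$empiricalP[hit]), 1 / 51)
  ## determinism of the full output
  tfr2 <- discoverTFRs(rna$rna, regs, pl$genome, nRandomizations = 50,
                       seed = 34)
  expect_equal(as.data.frame(tfr), as.data.frame(tfr2))
})

test_that("region sets without any hit give an empty result with a warning", {
  g <- makeGenome(1, 5000, 0.5, seed = 35)
  regs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 2000), width = 50))
  ## a pyrimidine-only RNA cannot seed any purine-motif window at 0 error
  expect_warning(
    tfr <- discoverTFRs(Biostrings::RNAString(strrep("C", 30)), regs, g,
                        maxErrorRate = 0, nRandomizations = 5, seed = 1),
    "no triplex hits")
  expect_equal(nrow(tfr), 0L)
  expect_warning(
    discoverTFRs(tfo23(), GenomicRanges::GRanges(), g,
                 nRandomizations = 5, seed = 1),
    "empty region set")
})

test_that("overlapTTS intersects interval sets and counts shared loci", {
  one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 40))
  expect_equal(overlapTTS(list(one, one, one))$count, 1L)
  shared <- overlapTTS(list(one, one, one))$intervals
  expect_equal(GenomicRanges::start(shared), 10L)

  disjoint <- list(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(20, 30)))
  expect_equal(overlapTTS(disjoint)$count, 0L)

  ## three sets sharing one 5-nt core
  s1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 51), c(20, 70)))
  s2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 101), c(30, 120)))
  s3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(16, 25))
  ov <- overlapTTS(list(s1, s2, s3))
  expect_equal(ov$count, 1L)
  expect_equal(GenomicRanges::start(ov$intervals), 16L)
  expect_equal(GenomicRanges::end(ov$intervals), 20L)
  ## order-invariance
  perm <- overlapTTS(list(s3, s1, s2))
  expect_equal(as.data.frame(perm$intervals), as.data.frame(ov$intervals))
  expect_error(overlapTTS(list(s1)), "at least two")
})
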