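# The search for triplex target sites: worked sequence examples, oracle
# equivalence, and the structural properties of the hit set.

epha2Duplex <- function()
  subset(referenceOligos(), name == "EPHA2_pyrimidine")$sequence
tfo23 <- function() subset(referenceOligos(), name == "TFO2-23")$sequence

test_that("the core TFR RNA hits the EPHA2 target duplex antiparallel", {
  hits <- findTTS(tfo23(), epha2Duplex(), minLen = 12, maxErrorRate = 0.2)
  anti <- hits[hits$motif == "antiparallel_purine"]
  expect_gte(length(anti), 1L)
  expect_true(any(GenomicRanges::width(anti) >= 12))
  ## exact coordinates from the independent brute-force oracle
  want <- oracleFindTTS(tfo23(), epha2Duplex())
  expect_true(sameHits(hitsToDF(hits), want))
  ## the purine tract lies on the minus strand of the pyrimidine-rich
  ## strand as written
  expect_true(all(as.character(GenomicRanges::strand(anti)) == "-"))
})

test_that("constructed duplexes give the forced hits", {
  ## poly-A TFO on poly-A duplex: one perfect antiparallel purine hit
  h <- findTTS(strrep("A", 15), strrep("A", 15), minLen = 12)
  expect_equal(length(h), 1L)
  expect_equal(h$mismatches, 0L)
  expect_equal(GenomicRanges::width(h), 15L)
  expect_equal(h$score, 15L)

  ## a duplex with no purine run: poly-G TFO against an AC-alternating
  ## duplex has no 12-mer window at zero error
  h2 <- findTTS(strrep("G", 12), strrep("AC", 100), minLen = 12,
                maxErrorRate = 0)
  expect_equal(length(h2), 0L)

  ## minLen beyond the TFO length warns and returns empty
  expect_warning(h3 <- findTTS("GAGGA", strrep("A", 30), minLen = 12),
                 "minLen")
  expect_equal(length(h3), 0L)
})

test_that("RNA and DNA alphabets give identical hits (U == T)", {
  dna <- "GCGGTGGAGGAAAGAGAAAGGAG"
  rna <- chartr("T", "U", dna)
  d <- randomSeq(60, 0.4)
  expect_true(sameHits(hitsToDF(findTTS(dna, d)),
                       hitsToDF(findTTS(rna, d))))
})

test_that("findTTS equals the brute-force oracle on random cases", {
  set.seed(402)
  for (i in 1:120) {
    tfo <- randomSeq(sample(12:25, 1), purineBias = runif(1, 0.25, 0.5))
    dup <- randomSeq(sample(15:40, 1), purineBias = runif(1, 0.25, 0.5))
    minLen <- sample(c(8L, 10L, 12L), 1)
    err <- sample(c(0, 0.1, 0.2), 1)
    for (mg in c(TRUE, FALSE)) {
      got <- hitsToDF(findTTS(tfo, dup, minLen = minLen,
                              maxErrorRate = err, merge = mg))
      want <- oracleFindTTS(tfo, dup, minLen = minLen, maxErrorRate = err,
                            merge = mg)
      expect_true(sameHits(got, want),
                  label = sprintf("case %d (tfo=%s dup=%s minLen=%d err=%g merge=%s)",
                                  i, tfo, dup, minLen, err, mg))
    }
  }
})

test_that("the fast oracle agrees with naive per-window scoring", {
  ## anchors the oracle itself on tiny cases before it is trusted above
  set.seed(403)
  for (i in 1:5) {
    tfo <- randomSeq(8, 0.4)
    dup <- randomSeq(10, 0.4)
    raw <- oracleFindTTS(tfo, dup, minLen = 5, maxErrorRate = 0.2,
                         merge = FALSE)
    if (is.null(raw)) next
    tchars <- strsplit(toupper(tfo), "")[[1]]
    dchars <- strsplit(toupper(dup), "")[[1]]
    for (r in seq_len(nrow(raw))) {
      row <- raw[r, ]
      pb <- if (row$strand == "+") dchars else
        unname(c(A = "T", C = "G", G = "C", T = "A")[dchars])
      samedir <- (row$strand == "+") == (row$motif == "parallel_pyrimidine")
      mm <- naiveWindowMismatches(tchars, pb, row$tstart, row$dstart,
                                  row$tend - row$tstart + 1L, row$motif,
                                  samedir)
      expect_equal(mm, row$mismatches)
    }
  }
})

test_that("reverse-complementing the duplex mirrors the raw hit set", {
  ## on the pre-merge maximal set the symmetry is exact; the merged set
  ## additionally depends on the (deliberately) leftmost tie-break
  set.seed(404)
  for (i in 1:30) {
    tfo <- randomSeq(sample(12:20, 1), 0.4)
    dup <- randomSeq(sample(20:40, 1), 0.4)
    n <- nchar(dup)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(dup)))
    a <- hitsToDF(findTTS(tfo, dup, merge = FALSE))
    b <- hitsToDF(findTTS(tfo, rc, merge = FALSE))
    if (is.null(a) || is.null(b)) {
      expect_true(is.null(a) && is.null(b))
      next
    }
    ## mirror b into a's coordinates
    b2 <- b
    b2$dstart <- n - b$dend + 1L
    b2$dend <- n - b$dstart + 1L
    b2$strand <- ifelse(b$strand == "+", "-", "+")
    expect_true(sameHits(a, b2))
  }
})

test_that("loosening the constraints never loses a matched region", {
  ## every maximal hit at strict settings is contained (both sides, same
  ## motif and strand) in a maximal hit at looser settings
  set.seed(405)
  contained <- function(strict, loose) {
    if (is.null(strict)) return(TRUE)
    if (is.null(loose)) return(FALSE)
    all(vapply(seq_len(nrow(strict)), function(i) {
      s <- strict[i, ]
      any(loose$motif == s$motif & loose$strand == s$strand &
            loose$dstart <= s$dstart & loose$dend >= s$dend &
            loose$tstart <= s$tstart & loose$tend >= s$tend)
    }, logical(1)))
  }
  for (i in 1:30) {
    tfo <- randomSeq(sample(14:25, 1), 0.45)
    dup <- randomSeq(sample(25:40, 1), 0.45)
    h12 <- hitsToDF(findTTS(tfo, dup, minLen = 14, maxErrorRate = 0.1,
                            merge = FALSE))
    hErr <- hitsToDF(findTTS(tfo, dup, minLen = 14, maxErrorRate = 0.2,
                             merge = FALSE))
    hLen <- hitsToDF(findTTS(tfo, dup, minLen = 10, maxErrorRate = 0.1,
                             merge = FALSE))
    expect_true(contained(h12, hErr))
    expect_true(contained(h12, hLen))
  }
})

test_that("every reported hit satisfies its own constraints", {
  set.seed(406)
  for (i in 1:40) {
    minLen <- sample(c(10L, 12L), 1)
    err <- sample(c(0.1, 0.2), 1)
    h <- findTTS(randomSeq(sample(12:25, 1), 0.45),
                 randomSeq(sample(20:40, 1), 0.45),
                 minLen = minLen, maxErrorRate = err)
    if (!length(h)) next
    expect_true(all(GenomicRanges::width(h) >= minLen))
    expect_true(all(h$mismatches / GenomicRanges::width(h) <= err + 1e-9))
    expect_true(all(h$tfoEnd - h$tfoStart + 1L == GenomicRanges::width(h)))
    expect_true(all(h$score == GenomicRanges::width(h) - h$mismatches))
    expect_true(all(h$score >= 1L))
  }
})
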