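# Independent brute-force oracles for the triplex search, built directly in
# plus-strand coordinates from the pairing predicate hoogsteenAllowed().
# They share no code with the package's diagonal scanner: orientation
# frames, maximality conditions and coordinate mapping are derived from
# first principles here.

.oracleComp <- c(A = "T", C = "G", G = "C", T = "A")

# Naive mismatch count of one window, summing hoogsteenAllowed calls.
# Used to validate the faster oracle on tiny cases.
naiveWindowMismatches <- function(tchars, pb, ts, ds, L, motif, samedir) {
  te <- ts + L - 1
  de <- ds + L - 1
  idx <- if (samedir) ds:de else de:ds
  sum(!hoogsteenAllowed(tchars[ts:te], pb[idx], motif))
}

# All maximal valid windows for one (strand, motif) configuration.
# pb: the purine-strand base at each plus-strand position.
# samedir: TRUE when t[ts+k] pairs pb[ds+k] (strand "+" parallel motif,
# strand "-" antiparallel motif); FALSE when t[ts+k] pairs pb[de-k].
.oracleConfigHits <- function(tchars, pb, motif, samedir, minLen, maxErr) {
  nT <- length(tchars)
  nD <- length(pb)
  A <- outer(seq_len(nT), seq_len(nD), function(i, j)
    hoogsteenAllowed(tchars[i], pb[j], motif))
  rows <- list()
  emit <- function(ts, ds, L, mm) {
    rows[[length(rows) + 1L]] <<- data.frame(
      tstart = ts, tend = ts + L - 1L, dstart = ds, dend = ds + L - 1L,
      mismatches = mm, score = L - mm)
  }
  scanDiag <- function(iIdx, jIdx) {
    M <- length(iIdx)
    if (M < minLen) return()
    mis <- !A[cbind(iIdx, jIdx)]
    cum <- c(0L, cumsum(mis))
    for (s in 1:(M - minLen + 1L)) {
      for (e in (s + minLen - 1L):M) {
        L <- e - s + 1L
        mm <- cum[e + 1L] - cum[s]
        if (mm > maxErr * L + 1e-9) next
        if (L - mm < 1L) next
        if (s > 1L && cum[e + 1L] - cum[s - 1L] <= maxErr * (L + 1L) + 1e-9)
          next
        if (e < M && cum[e + 2L] - cum[s] <= maxErr * (L + 1L) + 1e-9)
          next
        if (samedir) {
          emit(iIdx[s], jIdx[s], L, mm)
        } else {
          emit(iIdx[s], jIdx[e], L, mm)
        }
      }
    }
  }
  if (samedir) {
    for (cc in (1L - nT):(nD - 1L)) {
      ts <- max(1L, 1L - cc):min(nT, nD - cc)
      scanDiag(ts, ts + cc)
    }
  } else {
    for (cc in 2L:(nT + nD)) {
      i <- max(1L, cc - nD):min(nT, cc - 1L)
      scanDiag(i, cc - i)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# The oracle's own greedy merge: within (strand, motif), visit by score
# desc, then leftmost DNA, then leftmost RNA; drop hits overlapping a kept
# hit on both sides.
.oracleMerge <- function(df) {
  df <- df[order(-df$score, df$dstart, df$tstart), , drop = FALSE]
  kept <- df[0, ]
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    same <- kept$strand == r$strand & kept$motif == r$motif
    clash <- any(same & kept$dstart <= r$dend & kept$dend >= r$dstart &
                   kept$tstart <= r$tend & kept$tend >= r$tstart)
    if (!clash) kept <- rbind(kept, r)
  }
  kept
}

oracleFindTTS <- function(tfo, duplex, minLen = 12, maxErrorRate = 0.2,
                          motifs = c("antiparallel_purine",
                                     "parallel_pyrimidine"),
                          merge = TRUE) {
  tchars <- strsplit(chartr("Uu", "Tt", toupper(tfo)), "")[[1L]]
  dchars <- strsplit(toupper(duplex), "")[[1L]]
  if (minLen > length(tchars)) return(NULL)
  out <- list()
  for (strand in c("+", "-")) {
    pb <- if (strand == "+") dchars else unname(.oracleComp[dchars])
    for (motif in motifs) {
      samedir <- (strand == "+") ==
        (motif == "parallel_pyrimidine")
      h <- .oracleConfigHits(tchars, pb, motif, samedir, minLen,
                             maxErrorRate)
      if (!is.null(h)) {
        h$strand <- strand
        h$motif <- motif
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (!length(out)) return(NULL)
  df <- do.call(rbind, out)
  if (merge) df <- .oracleMerge(df)
  df[order(df$dstart, df$tstart, df$strand, df$motif), , drop = FALSE]
}

# Canonical data.frame view of findTTS output for comparison.
hitsToDF <- function(gr) {
  if (!length(gr)) return(NULL)
  df <- data.frame(
    tstart = gr$tfoStart, tend = gr$tfoEnd,
    dstart = GenomicRanges::start(gr), dend = GenomicRanges::end(gr),
    mismatches = gr$mismatches, score = gr$score,
    strand = as.character(GenomicRanges::strand(gr)),
    motif = gr$motif)
  df[order(df$dstart, df$tstart, df$strand, df$motif), , drop = FALSE]
}

sameHits <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  if (nrow(a) != nrow(b)) return(FALSE)
  rownames(a) <- rownames(b) <- NULL
  isTRUE(all.equal(a[order(a$dstart, a$tstart, a$strand, a$motif), ],
                   b[order(b$dstart, b$tstart, b$strand, b$motif), ],
                   check.attributes = FALSE))
}

# Random sequence with adjustable purine bias (keeps triplex hits frequent
# enough for the properties to bite).
randomSeq <- function(n, purineBias = 0.35) {
  p <- c(A = purineBias, G = purineBias,
         C = (1 - 2 * purineBias) / 2, T = (1 - 2 * purineBias) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Brute-force purine tract oracle: all substrings satisfying the budget,
# kept only when not strictly contained in another valid substring of the
# same strand.
oraclePurineTracts <- function(seq, minLen, maxInterruptions) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  n <- length(chars)
  res <- list()
  for (strand in c("+", "-")) {
    base <- if (strand == "+") chars else unname(.oracleComp[chars])
    pyr <- base %in% c("C", "T")
    valid <- list()
    for (s in seq_len(n)) for (e in s:n) {
      if (sum(pyr[s:e]) <= maxInterruptions)
        valid[[length(valid) + 1L]] <- c(s, e)
      else break
    }
    if (!length(valid)) next
    v <- do.call(rbind, valid)
    keep <- vapply(seq_len(nrow(v)), function(i) {
      inside <- v[, 1L] <= v[i, 1L] & v[, 2L] >= v[i, 2L]
      sum(inside) == 1L
    }, logical(1))
    v <- v[keep & (v[, 2L] - v[, 1L] + 1L) >= minLen, , drop = FALSE]
    if (nrow(v))
      res[[strand]] <- data.frame(start = v[, 1L], end = v[, 2L],
                                  strand = strand)
  }
  if (!length(res)) return(NULL)
  df <- do.call(rbind, res)
  rownames(df) <- NULL
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}
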