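## Hoogsteen / reverse-Hoogsteen pairing code.
##
## The third strand reads the purine-rich strand of the duplex in the major
## groove. Two canonical motifs are supported:
##   * antiparallel purine motif:      G.G:C, A.A:T, T.A:T
##   * parallel pyrimidine motif:      C.G:C, T.A:T (U = T)
## Rules are stored as a 4x4 logical matrix indexed (third-strand base,
## duplex purine-strand base) over the DNA alphabet; U is normalized to T at
## comparison time only.

.BASES <- c("A", "C", "G", "T")

.TRIPLEX_MOTIFS <- c("antiparallel_purine", "parallel_pyrimidine")

.MOTIF_ORIENTATION <- c(antiparallel_purine = "antiparallel",
                        parallel_pyrimidine = "parallel")

#' Hoogsteen pairing-rule table for a triplex motif
#'
#' Returns the pairing-rule matrix of a binding motif: a 4x4 logical matrix
#' whose rows are third-strand bases and whose columns are the base on the
#' purine strand of the duplex (the strand read in the major groove).
#'
#' @param motif One of \code{"antiparallel_purine"} (reverse-Hoogsteen
#'   purine motif: G.G:C, A.A:T, T.A:T) or \code{"parallel_pyrimidine"}
#'   (Hoogsteen pyrimidine motif: C.G:C, T/U.A:T).
#' @return A 4x4 logical matrix with dimnames over \code{A,C,G,T}.
#' @examples
#' triplexCode("antiparallel_purine")["G", "G"]  # TRUE
#' @export
triplexCode <- function(motif = c("antiparallel_purine",
                                  "parallel_pyrimidine")) {
  motif <- match.arg(motif)
  m <- matrix(FALSE, 4, 4, dimnames = list(third = .BASES, purine = .BASES))
  if (motif == "antiparallel_purine") {
    m["G", "G"] <- TRUE   # G . G:C
    m["A", "A"] <- TRUE   # A . A:T
    m["T", "A"] <- TRUE   # T . A:T
  } else {
    m["C", "G"] <- TRUE   # C+ . G:C
    m["T", "A"] <- TRUE   # T/U . A:T
  }
  m
}

## Encode a nucleotide string as integer codes 1..4 (A,C,G,T), with U -> T.
## IUPAC ambiguity codes are rejected so that hit sets are deterministic.
.encodeBases <- function(x, what = "sequence") {
  s <- chartr("Uu", "Tt", toupper(as.character(x)))
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  code <- match(v, .BASES)
  if (anyNA(code))
    stop("invalid base(s) in ", what, ": ",
         paste(unique(v[is.na(code)]), collapse = ", "),
         " (only A/C/G/T/U are accepted; IUPAC ambiguity codes are rejected)")
  code
}

#' Is a third-strand base allowed opposite a duplex purine base?
#'
#' Looks up the Hoogsteen pairing-rule table entry for one or more
#' (third-strand base, purine-strand base) pairs. U is treated as T; the
#' lookup is total over \code{A,C,G,T,U} and errors on any other symbol.
#'
#' @param third Character vector of third-strand (RNA/DNA) bases.
#' @param purine Character vector of duplex purine-strand bases.
#' @param motif Binding motif, see \code{\link{triplexCode}}.
#' @return Logical vector.
#' @examples
#' hoogsteenAllowed("G", "G", "antiparallel_purine")  # TRUE
#' hoogsteenAllowed("C", "A", "antiparallel_purine")  # FALSE
#' hoogsteenAllowed("U", "A", "parallel_pyrimidine")  # TRUE
#' @export
hoogsteenAllowed <- function(third, purine,
                             motif = c("antiparallel_purine",
                                       "parallel_pyrimidine")) {
  motif <- match.arg(motif)
  code <- triplexCode(motif)
  t_idx <- match(chartr("Uu", "Tt", toupper(third)), .BASES)
  p_idx <- match(chartr("Uu", "Tt", toupper(purine)), .BASES)
  if (anyNA(t_idx) || anyNA(p_idx))
    stop("unknown base symbol; only A/C/G/T/U are accepted")
  code[cbind(t_idx, p_idx)]
}
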