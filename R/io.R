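## Format I/O: FASTA via Biostrings, BED via rtracklayer (which handles the
## BED 0-based half-open convention; internally everything is 1-based
## closed GRanges/IRanges), plain TSV/CSV tables, JSON truth manifests.

#' Read a BED file of genomic regions
#'
#' @param path BED file path.
#' @return A \code{GRanges} (1-based closed internally; the file follows
#'   the BED 0-based half-open standard).
#' @export
readRegionsBED <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tryCatch(rtracklayer::import(path, format = "BED"),
           error = function(e)
             stop("malformed BED file '", path, "': ",
                  conditionMessage(e)))
}

#' Write genomic regions to a BED file
#'
#' @param gr A \code{GRanges}.
#' @param path Output path.
#' @export
writeRegionsBED <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write triplex target-site hits to BED
#'
#' The BED name field encodes the RNA-side interval and motif as
#' \code{tfoId:tfoStart-tfoEnd:motif}; the score field is the number of
#' matched positions.
#'
#' @param hits A \code{GRanges} from \code{\link{findTTS}}.
#' @param path Output path.
#' @export
writeTTSBed <- function(hits, path) {
  out <- GenomicRanges::granges(hits)
  out$name <- paste0(hits$tfoId, ":", hits$tfoStart, "-", hits$tfoEnd,
                     ":", hits$motif)
  out$score <- hits$score
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read melting curves from CSV
#'
#' Expects columns \code{temperature}, \code{value} and optionally
#' \code{curve_id} (one curve per id). Non-numeric or non-finite entries
#' are reported with their row numbers.
#'
#' @param path CSV file path.
#' @return A named list of \code{\linkS4class{MeltingCurve}} objects.
#' @export
readMeltingCurves <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("temperature", "value") %in% names(df)))
    stop("malformed melting-curve CSV '", path,
         "': need columns 'temperature' and 'value'")
  if (is.null(df$curve_id)) df$curve_id <- "curve"
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$temperature))) |
                 !is.finite(suppressWarnings(as.numeric(df$value))))
  if (length(bad))
    stop("malformed melting-curve CSV '", path, "': non-numeric data at ",
         "line(s) ", paste(bad + 1L, collapse = ", "))
  lapply(split(df, df$curve_id), function(d) {
    o <- order(d$temperature)
    MeltingCurve(d$temperature[o], d$value[o], d$curve_id[1L])
  })
}

#' Write melting curves to CSV
#'
#' @param curves A \code{MeltingCurve} or list thereof.
#' @param path Output path.
#' @export
writeMeltingCurves <- function(curves, path) {
  if (is(curves, "MeltingCurve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(curve_id = curveId(cv), temperature = temperatures(cv),
               value = ellipticities(cv))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write plain TSV tables
#'
#' Thin wrappers with column validation for the package's tabular formats.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @return \code{readTSV}: a \code{data.frame}.
#' @export
readTSV <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("malformed table '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  df
}

#' @rdname readTSV
#' @param df A \code{data.frame}.
#' @export
writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parse a 1-based inclusive genomic span string
#'
#' Converts browser-style spans such as \code{"chr1:16,478,543-16,478,567"}
#' (1-based, both ends included) into a \code{GRanges}; the example spans
#' 25 nt.
#'
#' @param x Character vector of span strings.
#' @return A \code{GRanges}.
#' @examples
#' GenomicRanges::width(parseGenomicSpan("chr1:16,478,543-16,478,567"))
#' @export
parseGenomicSpan <- function(x) {
  x <- gsub(",", "", x, fixed = TRUE)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
  bad <- which(vapply(m, length, integer(1)) != 4L)
  if (length(bad))
    stop("malformed genomic span: ", paste(x[bad], collapse = ", "))
  chrom <- vapply(m, `[`, character(1), 2L)
  start <- as.integer(vapply(m, `[`, character(1), 3L))
  end <- as.integer(vapply(m, `[`, character(1), 4L))
  if (any(start > end)) stop("genomic span start exceeds end")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

#' Write / read a ground-truth manifest
#'
#' Serializes a generator ground-truth list (intervals as \code{GRanges}
#' or \code{IRanges} are converted to plain tables) to JSON and back.
#' Round-tripping preserves all coordinates and values.
#'
#' @param truth A named list of ground-truth components.
#' @param path Output path.
#' @export
writeTruthManifest <- function(truth, path) {
  enc <- function(x) {
    if (is(x, "GRanges"))
      data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                 start = GenomicRanges::start(x),
                 end = GenomicRanges::end(x),
                 strand = as.character(GenomicRanges::strand(x)),
                 as.data.frame(S4Vectors::mcols(x)))
    else if (is(x, "IRanges"))
      data.frame(start = IRanges::start(x), end = IRanges::end(x))
    else if (is.list(x) && !is.data.frame(x)) lapply(x, enc)
    else x
  }
  jsonlite::write_json(lapply(truth, enc), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeTruthManifest
#' @return \code{readTruthManifest}: the manifest as nested lists /
#'   \code{data.frame}s.
#' @export
readTruthManifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Oligonucleotide fixtures used in the biophysical validation
#'
#' The third-strand RNA (TFO2-23, the core triplex-forming region of the
#' lncRNA), the two complementary 25-nt target strands in intron 1 of
#' EPHA2, the 15-nt ADM target strands, and the hairpin constructs in which
#' the two target strands are joined by a 5-thymidine linker so duplex
#' formation is intramolecular. Strand names reflect computed base
#' composition (purine vs pyrimidine rich). Note: the GC content computed
#' from the printed TFO2-23 sequence is 13/23 = 56.5%.
#'
#' @return A \code{data.frame} with columns \code{name}, \code{alphabet},
#'   \code{sequence}, \code{length_nt}, \code{genomic_span_hg19},
#'   \code{description}.
#' @examples
#' subset(referenceOligos(), name == "TFO2-23")$sequence
#' @export
referenceOligos <- function() {
  readTSV(system.file("extdata", "oligos.tsv", package = "TriplexKit",
                      mustWork = TRUE),
          required = c("name", "alphabet", "sequence", "length_nt"))
}

#' Published melting temperatures of the validated triplex constructs
#'
#' Fitted melting midpoints (degrees C, with fit standard errors where
#' reported) of the EPHA2 and ADM duplexes, the RNA-DNA heteroduplex, the
#' intermolecular triplex, and the hairpin-stabilized (CTGA) constructs.
#' Used to parameterize simulated curves for fit-recovery checks.
#'
#' @return A \code{data.frame} with columns \code{construct},
#'   \code{transition}, \code{tm_c}, \code{se_c}.
#' @export
meltingReference <- function() {
  readTSV(system.file("extdata", "melting_reference.tsv",
                      package = "TriplexKit", mustWork = TRUE),
          required = c("construct", "transition", "tm_c"))
}
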