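#' Construct a peak set
#'
#' A peak set holds the genomic intervals that define the feature (column)
#' axis of a cell-by-peak matrix. Coordinates are BED-style: 0-based,
#' half-open, unstranded.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors of 0-based half-open interval bounds.
#' @param peak_id Optional character vector of unique identifiers. Defaults
#'   to the canonical `chrom:start-end` form.
#' @return A `data.frame` of class `peak_set` with columns `peak_id`,
#'   `chrom`, `start`, `end`, in input order.
#' @examples
#' peak_set("chr1", 100L, 600L)
#' @export
peak_set <- function(chrom, start, end, peak_id = NULL) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  n <- length(chrom)
  if (length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (n > 0 && any(is.na(start) | is.na(end)))
    stop("start/end must be integer-valued")
  if (any(start < 0)) stop("start coordinates must be non-negative")
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("invalid interval (start >= end) for peak(s): %s",
                 paste(utils::head(chrom[bad], 5), utils::head(start[bad], 5),
                       sep = ":", collapse = ", ")))
  if (is.null(peak_id)) peak_id <- sprintf("%s:%d-%d", chrom, start, end)
  peak_id <- as.character(peak_id)
  if (anyDuplicated(peak_id))
    stop(sprintf("duplicated peak_id: %s",
                 paste(utils::head(unique(peak_id[duplicated(peak_id)]), 5),
                       collapse = ", ")))
  out <- data.frame(peak_id = peak_id, chrom = chrom, start = start,
                    end = end, stringsAsFactors = FALSE)
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Read peaks from a BED file
#'
#' Parses BED3/BED4 into a [peak_set()]. Intervals are kept 0-based
#' half-open exactly as stored on disk; when the name column is absent the
#' peak identifier is synthesised as `chrom:start-end`.
#'
#' @param path Path to a tab-separated BED file.
#' @return A `peak_set`; empty input yields an empty peak set.
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(peak_set(character(), integer(), integer()))
  lineno <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("BED parse error at line %d: expected >= 3 tab-separated columns, found %d",
                 lineno[which(nf < 3)[1]], nf[which(nf < 3)[1]][1]))
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("BED parse error at line %d: non-integer start/end", lineno[bad[1]]))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("BED validation error at line %d: start (%d) >= end (%d)",
                 lineno[bad[1]], start[bad[1]], end[bad[1]]))
  peak_id <- ifelse(nf >= 4, vapply(fields, function(f) f[[min(4, length(f))]], ""),
                    sprintf("%s:%d-%d", chrom, start, end))
  peak_set(chrom, start, end, peak_id)
}

#' Write peaks to a BED file
#'
#' Emits BED3 when every identifier equals the canonical `chrom:start-end`
#' form (so a canonical 3-column file round-trips byte-identically through
#' [read_peaks_bed()]), BED4 otherwise.
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  canonical <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  if (nrow(peaks) == 0) {
    writeLines(character(), path)
  } else if (all(peaks$peak_id == canonical)) {
    writeLines(sprintf("%s\t%d\t%d", peaks$chrom, peaks$start, peaks$end), path)
  } else {
    writeLines(sprintf("%s\t%d\t%d\t%s", peaks$chrom, peaks$start, peaks$end,
                       peaks$peak_id), path)
  }
  invisible(path)
}

#' Extract peak DNA sequences from a genome FASTA
#'
#' Returns one uppercase forward-strand sequence per peak, in peak order.
#' Sequence length equals `end - start`. Ambiguous bases (N) are retained;
#' downstream embedders decide how to treat them.
#'
#' @param peaks A `peak_set`.
#' @param genome Path to a FASTA file, or a [Biostrings::DNAStringSet].
#'   FASTA record names are truncated at the first whitespace.
#' @return Named character vector of sequences (names are peak identifiers).
#' @export
extract_peak_sequences <- function(peaks, genome) {
  stopifnot(inherits(peaks, "peak_set"))
  if (is.character(genome)) {
    if (!file.exists(genome)) stop(sprintf("FASTA file not found: %s", genome))
    genome <- Biostrings::readDNAStringSet(genome)
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (nrow(peaks) == 0) return(stats::setNames(character(), character()))
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing))
    stop(sprintf("chromosome(s) absent from FASTA: %s",
                 paste(utils::head(missing, 10), collapse = ", ")))
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  over <- which(peaks$end > chrom_len[peaks$chrom])
  if (length(over))
    stop(sprintf("peak %s extends beyond chromosome %s (length %d)",
                 peaks$peak_id[over[1]], peaks$chrom[over[1]],
                 chrom_len[[peaks$chrom[over[1]]]]))
  seqs <- vapply(seq_len(nrow(peaks)), function(i) {
    toupper(as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                            start = peaks$start[i] + 1L,
                                            end = peaks$end[i])))
  }, character(1))
  stats::setNames(seqs, peaks$peak_id)
}
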