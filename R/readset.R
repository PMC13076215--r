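#' Aligned-read interval set for one ChIP-seq sample
#'
#' A `ReadSet` holds a sample's aligned-read intervals (0-based half-open)
#' together with its library size (total mapped reads). BED intervals are
#' the canonical read representation; BAM alignments can be converted with
#' `bedtools bamtobed` upstream of this package.
#'
#' @param sample_id Sample identifier.
#' @param mark One of `"PolII"`, `"Ser2p"`, `"H3K4me3"`, `"H3K27me3"`,
#'   `"other"`.
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param library_size Total mapped reads; defaults to the number of
#'   intervals. Must be at least the number of intervals.
#' @return An object of class `ReadSet`.
#' @export
ReadSet <- function(sample_id, mark, intervals, library_size = NULL) {
  mark <- match.arg(mark, c("PolII", "Ser2p", "H3K4me3", "H3K27me3", "other"))
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) {
    bad <- which(intervals$start >= intervals$end)[1]
    stop("read interval ", bad, " has start >= end")
  }
  library_size <- library_size %||% nrow(intervals)
  if (library_size < nrow(intervals)) {
    stop("library_size (", library_size, ") is smaller than the number of intervals (",
         nrow(intervals), ")")
  }
  structure(list(sample_id = sample_id, mark = mark,
                 intervals = as.data.frame(intervals[c("chrom", "start", "end")]),
                 library_size = as.numeric(library_size)),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat("ReadSet '", x$sample_id, "' (", x$mark, "): ",
      nrow(x$intervals), " intervals, library size ",
      format(x$library_size, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Read aligned-read intervals from a BED file
#'
#' Loads the first three columns of a BED3+ file as read intervals. The
#' library size defaults to the number of intervals in the file when not
#' supplied explicitly (e.g. when the BED holds only a chromosome's worth
#' of a larger library).
#'
#' @param path Path to a BED3+ file (tab-separated, 0-based half-open).
#' @param sample_id Sample identifier.
#' @param mark Mark name, see [ReadSet()].
#' @param library_size Optional total mapped reads.
#' @return A [ReadSet].
#' @export
read_bed_reads <- function(path, sample_id, mark, library_size = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.info(path)$size == 0) {
    intervals <- data.frame(chrom = character(), start = integer(),
                            end = integer())
    return(ReadSet(sample_id, mark, intervals, library_size))
  }
  raw <- fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(raw) < 3) stop("malformed BED: fewer than 3 columns in ", path)
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], " in ", path,
         ": start must be < end")
  }
  intervals <- data.frame(chrom = as.character(raw[[1]]), start = start,
                          end = end)
  ReadSet(sample_id, mark, intervals, library_size)
}

#' Write a read set as BED3
#'
#' Intervals are written sorted by chromosome then start, giving
#' byte-stable output for identical inputs.
#'
#' @param reads A [ReadSet].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed_reads <- function(reads, path) {
  iv <- reads$intervals
  iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
  fwrite(iv, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
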