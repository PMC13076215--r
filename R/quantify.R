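#' RPKM over genomic windows
#'
#' Counts the read intervals overlapping each window by at least 1 bp (each
#' read counted at most once per window) and converts to reads per kilobase
#' per million mapped reads:
#' `RPKM = C / ((L / 1000) * (library_size / 1e6))`.
#' Zero-width windows (fully clipped background windows) get RPKM 0.
#'
#' @param reads A [ReadSet] with positive `library_size`.
#' @param windows data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [promoter_windows()].
#' @return Numeric vector of RPKM values, one per window row; named by
#'   `windows$gene_id` when present.
#' @export
compute_rpkm <- function(reads, windows) {
  stopifnot(inherits(reads, "ReadSet"), is.data.frame(windows))
  if (reads$library_size <= 0) stop("library_size must be positive")
  n <- nrow(windows)
  rpkm <- numeric(n)
  live <- windows$start < windows$end
  if (any(live) && nrow(reads$intervals) > 0) {
    iv <- reads$intervals
    w <- windows[live, , drop = FALSE]
    read_gr <- GRanges(iv$chrom, IRanges(iv$start + 1, iv$end))
    win_gr <- GRanges(w$chrom, IRanges(w$start + 1, w$end))
    counts <- countOverlaps(win_gr, read_gr)
    len_kb <- (w$end - w$start) / 1000
    rpkm[live] <- counts / (len_kb * (reads$library_size / 1e6))
  }
  if ("gene_id" %in% names(windows)) names(rpkm) <- windows$gene_id
  rpkm
}

#' Background coefficient from per-gene background RPKMs
#'
#' The background coefficient of a sample is the arithmetic mean of the
#' per-gene upstream-background RPKMs across all genes, floored at a small
#' epsilon so that sparse simulations with an all-zero background never
#' divide by zero.
#'
#' @param bg_rpkm Numeric vector of per-gene background RPKMs (at least one
#'   gene).
#' @param epsilon Lower floor for the coefficient.
#' @return A positive scalar.
#' @export
background_coefficient <- function(bg_rpkm, epsilon = 1e-6) {
  if (length(bg_rpkm) == 0) stop("background RPKM mapping is empty")
  max(mean(bg_rpkm), epsilon)
}

#' Background-corrected normalized RPKM for one sample
#'
#' Computes raw RPKM over each gene's signal window (promoter for Pol II
#' and histone marks, gene body for Ser2p) and over its upstream -4/-3 kb
#' background window, derives the sample's background coefficient as the
#' mean background RPKM across all genes, and divides the signal RPKM by
#' that coefficient. The resulting normalized RPKM is a dimensionless
#' fold-over-background that is invariant to sequencing depth.
#'
#' @param reads A [ReadSet].
#' @param ann A collapsed [Annotation].
#' @param region `"promoter"` (1-kb TSS window) or `"genebody"`.
#' @param half_width Promoter half-width in bp.
#' @param epsilon Floor for the background coefficient.
#' @return A `NormalizedSignal`: data.frame with columns `gene_id`,
#'   `raw_rpkm`, `raw_background_rpkm`, `normalized_rpkm`, and attributes
#'   `sample_id`, `mark`, `region`, `background_coefficient`.
#' @export
normalize_signal <- function(reads, ann, region = c("promoter", "genebody"),
                             half_width = 500, epsilon = 1e-6) {
  region <- match.arg(region)
  win <- switch(region,
                promoter = promoter_windows(ann, half_width),
                genebody = genebody_windows(ann))
  bg_win <- background_windows(ann)
  raw <- compute_rpkm(reads, win)
  bg <- compute_rpkm(reads, bg_win)
  coef <- background_coefficient(bg, epsilon)
  out <- data.frame(gene_id = win$gene_id, raw_rpkm = as.numeric(raw),
                    raw_background_rpkm = as.numeric(bg),
                    normalized_rpkm = as.numeric(raw) / coef)
  structure(out, sample_id = reads$sample_id, mark = reads$mark,
            region = region, background_coefficient = coef,
            class = c("NormalizedSignal", "data.frame"))
}

#' Extract normalized values from a signal table
#'
#' Accepts a `NormalizedSignal` (or any data.frame with `gene_id` and
#' `normalized_rpkm` columns) and returns the normalized values as a named
#' vector, the common currency of the classifiers.
#'
#' @param x Signal table.
#' @return Named numeric vector of normalized RPKM keyed by gene.
#' @export
normalized_values <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stopifnot(is.data.frame(x), all(c("gene_id", "normalized_rpkm") %in% names(x)))
  setNames(x$normalized_rpkm, x$gene_id)
}

#' Write / read a normalized-signal table as TSV
#'
#' @param signal A `NormalizedSignal` from [normalize_signal()].
#' @param path TSV path.
#' @return `write_signal_table` returns `path` invisibly;
#'   `read_signal_table` returns the table as a data.frame.
#' @export
write_signal_table <- function(signal, path) {
  fwrite(as.data.frame(signal), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_signal_table
#' @export
read_signal_table <- function(path) {
  if (!file.exists(path)) stop("signal table not found: ", path)
  fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}
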