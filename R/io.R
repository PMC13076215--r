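#' Write / read a gene-state table
#'
#' The gene-state table holds one row per gene with its classification
#' labels (bivalency, activity partition, Pol II status, decoupled flag,
#' germ-layer assignment) and the normalized signals they were derived
#' from. Written as plain TSV with a header; `read_state_table` re-reads
#' it with types preserved (logicals as TRUE/FALSE, missing lineage as
#' NA), so a write-then-read round-trips the table.
#'
#' @param states data.frame, e.g. from [classify_activity()] augmented
#'   with further label columns.
#' @param path TSV path.
#' @return `write_state_table`: invisibly, `path`. `read_state_table`: the
#'   table.
#' @export
write_state_table <- function(states, path) {
  stopifnot(is.data.frame(states))
  fwrite(states, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_state_table
#' @export
read_state_table <- function(path) {
  if (!file.exists(path)) stop("state table not found: ", path)
  out <- fread(path, sep = "\t", header = TRUE, data.table = FALSE,
               na.strings = "NA")
  if (nrow(out) == 0 && "gene_id" %in% names(out)) {
    out$gene_id <- as.character(out$gene_id)
  }
  out
}

#' Export per-gene values as a bedGraph promoter track
#'
#' Writes one bedGraph line per gene over its promoter window, sorted by
#' chromosome then start -- a browser-track export of, e.g., normalized
#' Pol II RPKM.
#'
#' @param values Named numeric vector keyed by gene id.
#' @param ann An [Annotation] containing every named gene.
#' @param path Output path.
#' @param half_width Promoter half-width in bp.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(values, ann, path, half_width = 500) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  unknown <- setdiff(names(values), ann$genes$gene_id)
  if (length(unknown) > 0) {
    stop("gene '", unknown[1], "' not present in the annotation")
  }
  keep <- ann$genes$gene_id %in% names(values)
  sub <- Annotation(ann$genes[keep, , drop = FALSE], ann$genome)
  win <- promoter_windows(sub, half_width)
  out <- data.frame(chrom = win$chrom, start = win$start, end = win$end,
                    value = unname(values[win$gene_id]))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
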