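#' Gene annotation container
#'
#' An `Annotation` bundles a table of gene models with the lengths of the
#' chromosomes they live on. Coordinates are 0-based half-open throughout,
#' the native convention of refFlat and BED.
#'
#' @param genes data.frame with columns `gene_id`, `tx_name`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `tx_start`, `tx_end` (0-based half-open).
#' @param genome named numeric vector of chromosome lengths in bp.
#' @return An object of class `Annotation`: a list with elements `genes`
#'   and `genome`.
#' @export
Annotation <- function(genes, genome) {
  stopifnot(is.data.frame(genes))
  required <- c("gene_id", "tx_name", "chrom", "strand", "tx_start", "tx_end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("annotation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(genes$tx_start >= genes$tx_end)) {
    bad <- genes$gene_id[genes$tx_start >= genes$tx_end][1]
    stop("gene '", bad, "' has tx_start >= tx_end")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (is.null(names(genome)) || !is.numeric(genome)) {
    stop("genome must be a named numeric vector of chromosome lengths")
  }
  unknown <- setdiff(unique(genes$chrom), names(genome))
  if (length(unknown) > 0) {
    stop("chromosome(s) absent from genome: ", paste(unknown, collapse = ", "))
  }
  over <- genes$tx_end > genome[genes$chrom]
  if (any(over)) {
    stop("gene '", genes$gene_id[over][1], "' extends beyond its chromosome")
  }
  genes <- as.data.frame(genes)
  genes$tx_start <- as.numeric(genes$tx_start)
  genes$tx_end <- as.numeric(genes$tx_end)
  structure(list(genes = genes, genome = genome), class = "Annotation")
}

#' @export
print.Annotation <- function(x, ...) {
  cat("Annotation:", nrow(x$genes), "gene model(s) on",
      length(x$genome), "chromosome(s)\n")
  invisible(x)
}

#' Number of gene models in an annotation
#' @param x An `Annotation`.
#' @return Integer count of gene models.
#' @export
n_genes <- function(x) nrow(x$genes)

#' Read a refFlat gene annotation
#'
#' Parses the 11-column UCSC refFlat format (geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds). One
#' record is produced per row, i.e. per transcript; use
#' [collapse_isoforms()] to reduce to one model per gene. Coordinates are
#' kept 0-based half-open as stored in the file.
#'
#' @param path Path to a tab-separated refFlat file.
#' @param genome Optional named numeric vector of chromosome lengths. When
#'   absent, each chromosome's length is inferred as the largest `txEnd`
#'   observed on it; supply real lengths when window clipping near
#'   chromosome ends matters.
#' @return An [Annotation].
#' @export
read_refflat <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("refFlat file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) {
    genes <- data.frame(gene_id = character(), tx_name = character(),
                        chrom = character(), strand = character(),
                        tx_start = integer(), tx_end = integer())
    return(Annotation(genes, genome %||% setNames(numeric(0), character(0))))
  }
  raw <- fread(path, sep = "\t", header = FALSE, data.table = FALSE,
               colClasses = "character", fill = TRUE)
  if (ncol(raw) != 11) {
    stop("malformed refFlat: expected 11 tab-separated columns, found ",
         ncol(raw))
  }
  tx_start <- suppressWarnings(as.integer(raw[[5]]))
  tx_end <- suppressWarnings(as.integer(raw[[6]]))
  bad <- which(is.na(tx_start) | is.na(tx_end) | tx_start >= tx_end)
  if (length(bad) > 0) {
    stop("malformed refFlat line ", bad[1], ": txStart must be < txEnd")
  }
  bad_strand <- which(!(raw[[4]] %in% c("+", "-")))
  if (length(bad_strand) > 0) {
    stop("malformed refFlat line ", bad_strand[1], ": unknown strand '",
         raw[[4]][bad_strand[1]], "'")
  }
  genes <- data.frame(gene_id = raw[[1]], tx_name = raw[[2]],
                      chrom = raw[[3]], strand = raw[[4]],
                      tx_start = tx_start, tx_end = tx_end)
  if (is.null(genome)) {
    genome <- tapply(genes$tx_end, genes$chrom, max)
    genome <- setNames(as.numeric(genome), names(genome))
  }
  Annotation(genes, genome)
}

#' Collapse transcript isoforms to one model per gene
#'
#' For every gene name, keeps the single longest transcript; ties are broken
#' by smallest `tx_start`, then lexicographically smallest transcript name.
#' The result has unique `gene_id`s, ordered by chromosome then start. The
#' operation is idempotent.
#'
#' @param ann An [Annotation] as parsed from refFlat.
#' @return An [Annotation] with one gene model per gene name.
#' @export
collapse_isoforms <- function(ann) {
  stopifnot(inherits(ann, "Annotation"))
  g <- ann$genes
  if (nrow(g) == 0) return(ann)
  len <- g$tx_end - g$tx_start
  ord <- order(g$gene_id, -len, g$tx_start, g$tx_name)
  g <- g[ord, , drop = FALSE]
  g <- g[!duplicated(g$gene_id), , drop = FALSE]
  g <- g[order(g$chrom, g$tx_start, g$gene_id), , drop = FALSE]
  rownames(g) <- NULL
  Annotation(g, ann$genome)
}

#' Write an annotation as refFlat
#'
#' One row per gene model; cds bounds are set to the transcript bounds and
#' each model is written as a single exon (exon structure is not used by the
#' pipeline).
#'
#' @param ann An [Annotation].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_refflat <- function(ann, path) {
  g <- ann$genes
  out <- data.frame(g$gene_id, g$tx_name, g$chrom, g$strand,
                    g$tx_start, g$tx_end, g$tx_start, g$tx_end, 1L,
                    paste0(g$tx_start, ","), paste0(g$tx_end, ","))
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
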