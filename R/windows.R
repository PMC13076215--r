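#' Promoter windows around the TSS
#'
#' The promoter window is a fixed-width window centered on the transcription
#' start site: `[TSS - half_width, TSS + half_width)`, clipped to chromosome
#' bounds. The TSS is `tx_start` for `+` strand genes and `tx_end - 1` (the
#' last base of the span, 0-based) for `-` strand genes. The default
#' `half_width` of 500 bp gives the 1-kb TSS-centered window used for Pol II
#' and histone-mark promoter signal.
#'
#' @param ann An [Annotation] (typically isoform-collapsed).
#' @param half_width Half-width of the window in bp.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), one row per gene in `ann`.
#' @export
promoter_windows <- function(ann, half_width = 500) {
  stopifnot(inherits(ann, "Annotation"), half_width > 0)
  g <- ann$genes
  tss <- tss_positions(ann)
  start <- tss - half_width
  end <- tss + half_width
  clip_windows(g$gene_id, g$chrom, start, end, ann$genome,
               allow_empty = FALSE, what = "promoter window")
}

#' Background windows upstream of the TSS
#'
#' The background window spans the region from -4 kb to -3 kb relative to
#' the TSS, on the gene's upstream side: `[TSS - far, TSS - near)` for `+`
#' strand genes and the strand-mirrored `[TSS + near + 1, TSS + far + 1)`
#' for `-` strand genes (the +1 mirrors the `TSS = tx_end - 1` convention).
#' Windows are clipped to chromosome bounds; a window clipped away entirely
#' is returned with zero width and its background RPKM is defined as 0.
#'
#' @param ann An [Annotation].
#' @param near,far Distances in bp bounding the upstream background region.
#' @return data.frame as in [promoter_windows()]; zero-width rows mark
#'   fully-clipped windows.
#' @export
background_windows <- function(ann, near = 3000, far = 4000) {
  stopifnot(inherits(ann, "Annotation"), near < far)
  g <- ann$genes
  tss <- tss_positions(ann)
  plus <- g$strand == "+"
  start <- ifelse(plus, tss - far, tss + near + 1)
  end <- ifelse(plus, tss - near, tss + far + 1)
  clip_windows(g$gene_id, g$chrom, start, end, ann$genome,
               allow_empty = TRUE, what = "background window")
}

#' Gene-body windows
#'
#' The gene-body window is the transcript span itself, used for Ser2p
#' (elongating Pol II) signal.
#'
#' @param ann An [Annotation].
#' @return data.frame as in [promoter_windows()].
#' @export
genebody_windows <- function(ann) {
  stopifnot(inherits(ann, "Annotation"))
  g <- ann$genes
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = g$tx_start, end = g$tx_end)
}

#' Strand-aware TSS positions
#'
#' @param ann An [Annotation].
#' @return Named numeric vector of 0-based TSS positions.
#' @export
tss_positions <- function(ann) {
  g <- ann$genes
  setNames(ifelse(g$strand == "+", g$tx_start, g$tx_end - 1), g$gene_id)
}

clip_windows <- function(gene_id, chrom, start, end, genome, allow_empty,
                         what) {
  len <- as.numeric(genome[chrom])
  cs <- pmax(start, 0)
  ce <- pmin(end, len)
  empty <- cs >= ce
  if (any(empty)) {
    if (!allow_empty) {
      stop(what, " for gene '", gene_id[empty][1],
           "' lies entirely off its chromosome")
    }
    cs[empty] <- 0
    ce[empty] <- 0
  }
  data.frame(gene_id = gene_id, chrom = chrom, start = cs, end = ce)
}
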