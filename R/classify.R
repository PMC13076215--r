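#' Classification thresholds
#'
#' All cutoffs used by the promoter-state classifiers, defaulting to the
#' values the analysis framework fixes: bivalent if both H3K4me3 and
#' H3K27me3 normalized RPKM > 2; Pol II(+) / activated if normalized Pol II
#' RPKM > 3; germ-layer-specific Ser2p rule > 3 in the home layer and < 2
#' elsewhere (one additional > 3 layer tolerated); RNA lineage rule FPKM
#' > 5 in one layer and < 5 in the others; transcriptionally decoupled if
#' gene-body Ser2p > 2 with FPKM < 1 and no other annotated gene within
#' 10 kb. Every comparison is strict: values exactly at a threshold fail.
#'
#' @param bivalent_min,pol2_pos_min,activated_min,ser2p_specific_hi,ser2p_specific_lo,rna_specific,decoupled_ser2p_min,decoupled_fpkm_max,neighbor_exclusion_bp
#'   Numeric cutoffs, see Description.
#' @return A named list of thresholds of class `chromstate_thresholds`.
#' @export
default_thresholds <- function(bivalent_min = 2, pol2_pos_min = 3,
                               activated_min = 3, ser2p_specific_hi = 3,
                               ser2p_specific_lo = 2, rna_specific = 5,
                               decoupled_ser2p_min = 2,
                               decoupled_fpkm_max = 1,
                               neighbor_exclusion_bp = 10000) {
  th <- list(bivalent_min = bivalent_min, pol2_pos_min = pol2_pos_min,
             activated_min = activated_min,
             ser2p_specific_hi = ser2p_specific_hi,
             ser2p_specific_lo = ser2p_specific_lo,
             rna_specific = rna_specific,
             decoupled_ser2p_min = decoupled_ser2p_min,
             decoupled_fpkm_max = decoupled_fpkm_max,
             neighbor_exclusion_bp = neighbor_exclusion_bp)
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive")
  if (th$ser2p_specific_lo >= th$ser2p_specific_hi) {
    stop("ser2p_specific_lo must be below ser2p_specific_hi")
  }
  structure(th, class = "chromstate_thresholds")
}

## align b's values onto a's gene order; error if the gene sets differ
align_genes <- function(a, b, what = "signal") {
  va <- normalized_values_any(a)
  vb <- normalized_values_any(b)
  only_a <- setdiff(names(va), names(vb))
  only_b <- setdiff(names(vb), names(va))
  if (length(only_a) > 0) {
    stop("gene '", only_a[1], "' present in one ", what, " table only")
  }
  if (length(only_b) > 0) {
    stop("gene '", only_b[1], "' present in one ", what, " table only")
  }
  list(a = va, b = vb[names(va)])
}

normalized_values_any <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (is.data.frame(x)) {
    if (all(c("gene_id", "normalized_rpkm") %in% names(x))) {
      return(setNames(x$normalized_rpkm, x$gene_id))
    }
    if (all(c("gene_id", "fpkm") %in% names(x))) {
      return(setNames(x$fpkm, x$gene_id))
    }
  }
  stop("expected a named numeric vector or a data.frame with gene_id and ",
       "normalized_rpkm (or fpkm) columns")
}

#' Call bivalent promoters
#'
#' A promoter is bivalent when its normalized RPKM exceeds the threshold
#' for both H3K4me3 and H3K27me3 (strictly; a value exactly at the cutoff
#' fails).
#'
#' @param h3k4me3,h3k27me3 Normalized-signal tables (see
#'   [normalized_values()]) covering the same genes.
#' @param th Thresholds from [default_thresholds()].
#' @return Named logical vector keyed by gene.
#' @export
classify_bivalent <- function(h3k4me3, h3k27me3, th = default_thresholds()) {
  v <- align_genes(h3k4me3, h3k27me3, "histone-mark")
  v$a > th$bivalent_min & v$b > th$bivalent_min
}

#' Partition genes into bivalent / activated / silenced with Pol II status
#'
#' Bivalent genes are subdivided by promoter Pol II occupancy into
#' Pol II(+) (normalized RPKM above the cutoff) and Pol II(-). Among the
#' remaining genes the same Pol II cutoff separates activated from
#' silenced. Every gene receives exactly one activity label; Pol II status
#' is `not_applicable` outside the bivalent set.
#'
#' @param pol2 Normalized Pol II promoter signal.
#' @param bivalent Named logical vector from [classify_bivalent()] over the
#'   same genes.
#' @param th Thresholds.
#' @return data.frame with columns `gene_id`, `bivalent`, `activity`
#'   (`bivalent`/`activated`/`silenced`), `pol2_status`
#'   (`pol2_plus`/`pol2_minus`/`not_applicable`).
#' @export
classify_activity <- function(pol2, bivalent, th = default_thresholds()) {
  v <- align_genes(pol2, bivalent * 1, "Pol II / bivalency")
  pol2v <- v$a
  biv <- as.logical(v$b)
  high <- pol2v > th$pol2_pos_min
  activity <- ifelse(biv, "bivalent", ifelse(high, "activated", "silenced"))
  pol2_status <- ifelse(biv, ifelse(high, "pol2_plus", "pol2_minus"),
                        "not_applicable")
  data.frame(gene_id = names(pol2v), bivalent = biv, activity = activity,
             pol2_status = pol2_status, row.names = NULL)
}

#' Which genes have no other gene within a given gap
#'
#' Isolation is measured between collapsed transcript spans, ignoring
#' strand: a gene is isolated when the gap between its span and every other
#' gene's span is at least `max_gap` bp (overlapping spans count as a gap
#' of 0). The only gene on a chromosome is always isolated.
#'
#' @param ann A collapsed [Annotation].
#' @param max_gap Exclusion distance in bp.
#' @return Named logical vector keyed by gene.
#' @export
gene_isolation <- function(ann, max_gap = 10000) {
  g <- ann$genes
  iso <- setNames(rep(TRUE, nrow(g)), g$gene_id)
  if (nrow(g) < 2) return(iso)
  gr <- GRanges(g$chrom, IRanges(g$tx_start + 1, g$tx_end))
  hits <- distanceToNearest(gr, ignore.strand = TRUE)
  d <- mcols(hits)$distance
  iso[queryHits(hits)] <- d >= max_gap
  iso
}

#' Identify transcriptionally decoupled genes
#'
#' Transcriptionally decoupled genes carry elongating-Pol II signal over
#' their body without mRNA output: gene-body Ser2p normalized RPKM above
#' the cutoff, FPKM below 1, and no other annotated gene within 10 kb of
#' the gene's span (close neighbors are excluded to avoid ambiguous signal
#' assignment).
#'
#' @param ser2p_genebody Gene-body Ser2p normalized signal.
#' @param expr FPKM for the matching sample: data.frame with `gene_id` and
#'   `fpkm` columns, or a named numeric vector.
#' @param ann A collapsed [Annotation] (used for the neighbor-exclusion
#'   test).
#' @param th Thresholds.
#' @param missing_as_zero Treat genes absent from `expr` as FPKM 0 instead
#'   of raising an error. Off by default: silent zeros hide joins gone
#'   wrong.
#' @return Named logical vector keyed by gene.
#' @export
identify_decoupled <- function(ser2p_genebody, expr, ann,
                               th = default_thresholds(),
                               missing_as_zero = FALSE) {
  ser2p <- normalized_values_any(ser2p_genebody)
  fpkm <- normalized_values_any(expr)
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  missing <- setdiff(names(ser2p), names(fpkm))
  if (length(missing) > 0) {
    if (!missing_as_zero) {
      stop("no FPKM for gene '", missing[1],
           "' (set missing_as_zero = TRUE to treat absent genes as 0)")
    }
    fpkm[missing] <- 0
  }
  fpkm <- fpkm[names(ser2p)]
  iso <- gene_isolation(ann, th$neighbor_exclusion_bp)
  unknown <- setdiff(names(ser2p), names(iso))
  if (length(unknown) > 0) {
    stop("gene '", unknown[1], "' absent from the annotation")
  }
  ser2p > th$decoupled_ser2p_min & fpkm < th$decoupled_fpkm_max &
    iso[names(ser2p)]
}

## rows = genes, cols = layers; input is a named list of signal tables
layer_matrix <- function(by_layer) {
  if (length(by_layer) < 2) stop("at least two germ layers are required")
  if (is.null(names(by_layer))) stop("layer list must be named")
  vals <- lapply(by_layer, normalized_values_any)
  genes <- names(vals[[1]])
  for (l in names(vals)[-1]) {
    v <- align_genes(vals[[1]], vals[[l]], "layer")
    vals[[l]] <- v$b
  }
  do.call(cbind, lapply(vals, function(v) v[genes]))
}

#' Assign germ-layer-specific genes from Ser2p signal
#'
#' A gene is assigned to the germ layer holding its maximum normalized
#' Ser2p signal when that maximum exceeds the high cutoff, every other
#' layer stays below the low cutoff -- except that one additional layer is
#' tolerated above the high cutoff (developmentally similar layers), in
#' which case it must be the second-highest and the remaining layers must
#' still be below the low cutoff. Ties at the maximum leave the gene
#' unassigned.
#'
#' @param ser2p_by_layer Named list, one normalized Ser2p signal table per
#'   germ layer (at least two layers, common gene set).
#' @param th Thresholds.
#' @return Named character vector: the assigned layer, or `NA` when
#'   unassigned.
#' @export
lineage_specific_ser2p <- function(ser2p_by_layer, th = default_thresholds()) {
  m <- layer_matrix(ser2p_by_layer)
  layers <- colnames(m)
  hi <- th$ser2p_specific_hi
  lo <- th$ser2p_specific_lo
  out <- rep(NA_character_, nrow(m))
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    top <- max(v)
    if (top <= hi || sum(v == top) > 1) next
    j <- which.max(v)
    others <- v[-j]
    n_hi <- sum(others > hi)
    ok <- if (n_hi == 0) {
      all(others < lo)
    } else if (n_hi == 1) {
      all(others[-which.max(others)] < lo)
    } else {
      FALSE
    }
    if (ok) out[i] <- layers[j]
  }
  setNames(out, rownames(m))
}

#' Assign germ-layer-specific genes from RNA expression
#'
#' A gene is layer-specific when its FPKM exceeds the cutoff in exactly one
#' germ layer and stays below it in every other; a value exactly at the
#' cutoff satisfies neither clause.
#'
#' @param expr_by_layer Named list, one expression table (`gene_id`,
#'   `fpkm`) or named numeric vector per layer.
#' @param th Thresholds.
#' @return Named character vector as in [lineage_specific_ser2p()].
#' @export
lineage_specific_rna <- function(expr_by_layer, th = default_thresholds()) {
  m <- layer_matrix(expr_by_layer)
  cutoff <- th$rna_specific
  above <- m > cutoff
  below <- m < cutoff
  n_above <- rowSums(above)
  ok <- n_above == 1 & rowSums(below) == ncol(m) - 1
  out <- rep(NA_character_, nrow(m))
  out[ok] <- colnames(m)[apply(above[ok, , drop = FALSE], 1, which)]
  setNames(out, rownames(m))
}
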