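#' Ordered multi-stage, multi-mark signal series
#'
#' Bundles normalized signal for several marks across an explicitly ordered
#' sequence of developmental stages (e.g. ICM, E5.5 epiblast, E6.5
#' epiblast, E7.5 ectoderm) over a common gene set.
#'
#' @param stages Character vector of stage ids in developmental order.
#' @param signals Named list: one entry per mark, each itself a named list
#'   mapping every stage id to a normalized signal table.
#' @return Object of class `StageSeries` with elements `stages`, `marks`,
#'   `genes` and per-mark gene-by-stage matrices in `m`.
#' @export
stage_series <- function(stages, signals) {
  if (length(stages) < 2) stop("a stage series needs at least two stages")
  if (is.null(names(signals))) stop("signals must be a named list of marks")
  m <- list()
  genes <- NULL
  for (mark in names(signals)) {
    per_stage <- signals[[mark]]
    missing <- setdiff(stages, names(per_stage))
    if (length(missing) > 0) {
      stop("mark '", mark, "' lacks stage '", missing[1], "'")
    }
    cols <- lapply(stages, function(s) normalized_values_any(per_stage[[s]]))
    genes <- genes %||% names(cols[[1]])
    for (col in cols) {
      if (!setequal(names(col), genes)) {
        stop("stage series does not cover a common gene set for mark '",
             mark, "'")
      }
    }
    m[[mark]] <- do.call(cbind, lapply(cols, function(col) col[genes]))
    colnames(m[[mark]]) <- stages
  }
  structure(list(stages = stages, marks = names(signals), genes = genes,
                 m = m), class = "StageSeries")
}

#' @export
print.StageSeries <- function(x, ...) {
  cat("StageSeries:", length(x$genes), "genes x", length(x$stages),
      "stages (", paste(x$stages, collapse = " -> "), ") for marks:",
      paste(x$marks, collapse = ", "), "\n")
  invisible(x)
}

#' Pol II(+) bivalent promoters at one stage
#'
#' Convenience wrapper applying the classification cutoffs: the genes that
#' are bivalent and whose normalized Pol II signal exceeds the Pol II(+)
#' threshold.
#'
#' @param pol2 Normalized Pol II promoter signal.
#' @param bivalent Named logical from [classify_bivalent()].
#' @param th Thresholds.
#' @return Character vector of gene ids.
#' @export
pol2_positive_genes <- function(pol2, bivalent, th = default_thresholds()) {
  states <- classify_activity(pol2, bivalent, th)
  states$gene_id[states$pol2_status == "pol2_plus"]
}

#' Gained / lost / retained promoters across a transition
#'
#' Set algebra over Pol II(+) promoter sets at two stages of a lineage
#' transition: `gained = to \ from`, `lost = from \ to`,
#' `retained = from ∩ to`.
#'
#' @param pol2_plus_from,pol2_plus_to Character vectors of Pol II(+) gene
#'   ids at the earlier and later stage (same gene universe).
#' @return List of class `TransitionReport` with elements `gained`, `lost`,
#'   `retained`.
#' @export
transition_sets <- function(pol2_plus_from, pol2_plus_to) {
  from <- unique(as.character(pol2_plus_from))
  to <- unique(as.character(pol2_plus_to))
  structure(list(gained = setdiff(to, from), lost = setdiff(from, to),
                 retained = intersect(from, to)),
            class = "TransitionReport")
}

#' @export
print.TransitionReport <- function(x, ...) {
  cat("TransitionReport: gained", length(x$gained), "| lost",
      length(x$lost), "| retained", length(x$retained), "\n")
  invisible(x)
}

#' Stage of first threshold crossing for a mark
#'
#' The onset of a mark at a gene is the earliest stage (in the declared
#' order) at which its normalized signal rises strictly above the
#' threshold; no persistence at later stages is required. Genes never
#' crossing get `NA`.
#'
#' @param series A [stage_series()].
#' @param mark Mark name present in the series.
#' @param threshold Normalized-signal cutoff.
#' @param genes Optional character vector restricting the genes (default:
#'   all genes in the series).
#' @return Named character vector of stage ids (`NA` = never crosses).
#' @export
onset_stage <- function(series, mark, threshold, genes = NULL) {
  stopifnot(inherits(series, "StageSeries"))
  if (!mark %in% series$marks) stop("unknown mark '", mark, "'")
  genes <- genes %||% series$genes
  unknown <- setdiff(genes, series$genes)
  if (length(unknown) > 0) stop("unknown gene '", unknown[1], "'")
  m <- series$m[[mark]][genes, , drop = FALSE]
  idx <- apply(m > threshold, 1, function(hit) {
    w <- which(hit)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  setNames(ifelse(is.na(idx), NA_character_, series$stages[idx]), genes)
}

#' Mark-onset cascade ordering per gene
#'
#' For each gene, orders the onset stages of H3K27me3, H3K4me3 and Pol II
#' into a pattern string such as `"K27<K4<PolII"` (simultaneous onsets
#' joined with `"="`). Genes for which any of the three marks never
#' crosses its threshold fall into the `"incomplete"` bucket. The cascade
#' of interest -- initial H3K27me3 deposition, then H3K4me3 acquisition,
#' then Pol II engagement -- corresponds to the `"K27<K4<PolII"` pattern.
#'
#' @param series A [stage_series()] containing the three marks.
#' @param genes Optional gene subset.
#' @param thresholds Named numeric vector of per-mark onset thresholds; by
#'   default the classification cutoffs (2 for the histone marks, 3 for
#'   Pol II).
#' @return List with `per_gene` (data.frame: gene_id, one onset column per
#'   mark, `pattern`) and `counts` (data.frame: `pattern`, `n`, decreasing).
#' @export
cascade_order <- function(series, genes = NULL,
                          thresholds = c(H3K27me3 = 2, H3K4me3 = 2,
                                         PolII = 3)) {
  stopifnot(inherits(series, "StageSeries"))
  marks <- names(thresholds)
  missing <- setdiff(marks, series$marks)
  if (length(missing) > 0) stop("series lacks mark '", missing[1], "'")
  genes <- genes %||% series$genes
  short <- c(H3K27me3 = "K27", H3K4me3 = "K4", PolII = "PolII",
             Ser2p = "Ser2p")
  onset_idx <- vapply(marks, function(mk) {
    stage <- onset_stage(series, mk, thresholds[[mk]], genes)
    match(stage, series$stages)
  }, integer(length(genes)))
  if (length(genes) == 1) onset_idx <- matrix(onset_idx, nrow = 1)
  colnames(onset_idx) <- marks
  pattern <- apply(onset_idx, 1, function(ix) {
    if (anyNA(ix)) return("incomplete")
    ord <- order(ix)
    lab <- short[marks][ord]
    sep <- ifelse(diff(ix[ord]) == 0, "=", "<")
    paste0(lab[1], paste0(sep, lab[-1], collapse = ""))
  })
  per_gene <- data.frame(gene_id = genes, row.names = NULL)
  for (mk in marks) {
    per_gene[[paste0("onset_", mk)]] <-
      ifelse(is.na(onset_idx[, mk]), NA_character_,
             series$stages[onset_idx[, mk]])
  }
  per_gene$pattern <- pattern
  tab <- sort(table(pattern), decreasing = TRUE)
  counts <- data.frame(pattern = names(tab), n = as.integer(tab),
                       row.names = NULL)
  list(per_gene = per_gene, counts = counts)
}
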