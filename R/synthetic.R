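#' Configuration for a synthetic ChIP-seq study
#'
#' Parameters of the seeded generator that emulates a multi-mark,
#' multi-lineage, multi-stage ChIP-seq + RNA-seq study with planted gene
#' classes. Reads are Poisson-distributed: a uniform background of `depth`
#' expected reads per kb genome-wide, plus window-targeted enrichment so
#' that an enriched window's total expected coverage is `multiplier` times
#' background (promoter windows for Pol II and histone marks, gene bodies
#' for Ser2p). Defaults define the reference study conditions: 500 genes,
#' depth 50 reads/kb, 8-fold enrichment for active signal with 10x/3x
#' strong/weak histone strata, three germ layers and a four-stage
#' trajectory.
#'
#' @param seed Integer master seed; every output is a pure function of the
#'   configuration and this seed.
#' @param n_genes Number of genes.
#' @param chrom Chromosome name of the single simulated chromosome.
#' @param chrom_length Chromosome length in bp; `NULL` = sized
#'   automatically to fit the gene packing.
#' @param gene_length_range Min/max gene length in bp.
#' @param min_gene_gap Minimum gap between consecutive genes (except
#'   deliberate close pairs), bp.
#' @param close_pair_fraction Fraction of genes placed in deliberately
#'   close pairs (gap `close_pair_gap` < 10 kb) to exercise the
#'   neighbor-exclusion rule.
#' @param close_pair_gap Gap inside a close pair, bp (< 10000).
#' @param layers Germ-layer names.
#' @param stages Developmental stages in order; the last stage is the one
#'   classified and perturbed.
#' @param depth Expected background reads per kb.
#' @param read_length Read length in bp.
#' @param enrichment Fold-over-background for active Pol II / Ser2p /
#'   H3K4me3 signal.
#' @param strong_enrichment,weak_enrichment Histone-mark fold-changes for
#'   the strong and weak strata of bivalent promoters (both above the
#'   bivalency cutoff).
#' @param class_fractions Named fractions of genes per planted class
#'   (`housekeeping_activated`, `bivalent_pol2_plus`,
#'   `bivalent_pol2_minus`, `decoupled`); the remainder is `silenced`.
#' @param lineage_fraction Fraction of genes (taken from the housekeeping
#'   pool) planted as germ-layer-specific.
#' @param fpkm_means Named FPKM class means.
#' @param fpkm_sigma Lognormal noise sigma on FPKM.
#' @param cascade_onsets Stage index (1-based) at which each mark switches
#'   on for cascade genes (the Pol II(+) bivalent class).
#' @param ko_k27_mult Knockout multiplier on H3K27me3 at bivalent
#'   promoters (PRC2-loss-like).
#' @param ko_pol2_gain Knockout multiplier on Pol II at bivalent promoters
#'   of the clusters in `ko_gain_clusters`.
#' @param ko_gain_clusters Chromatin clusters whose Pol II responds to the
#'   knockout.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 500L, chrom = "chrS",
                              chrom_length = NULL,
                              gene_length_range = c(2000L, 8000L),
                              min_gene_gap = 15000L,
                              close_pair_fraction = 0.05,
                              close_pair_gap = 5000L,
                              layers = c("Ect", "Mes", "End"),
                              stages = c("ICM", "E5.5Epi", "E6.5Epi",
                                         "E7.5Ect"),
                              depth = 50, read_length = 50L,
                              enrichment = 8, strong_enrichment = 10,
                              weak_enrichment = 3,
                              class_fractions = c(
                                housekeeping_activated = 0.20,
                                bivalent_pol2_plus = 0.15,
                                bivalent_pol2_minus = 0.15,
                                decoupled = 0.10),
                              lineage_fraction = 0.15,
                              fpkm_means = c(housekeeping = 20,
                                             lineage_home = 10,
                                             lineage_away = 0.5,
                                             bivalent_pol2_plus = 0.5,
                                             bivalent_pol2_minus = 0.2,
                                             decoupled = 0.2,
                                             silenced = 0.2),
                              fpkm_sigma = 0.3,
                              cascade_onsets = c(H3K27me3 = 2L,
                                                 H3K4me3 = 3L, PolII = 4L),
                              ko_k27_mult = 0.05, ko_pol2_gain = 2,
                              ko_gain_clusters = c("C2", "C3")) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              chrom = chrom, chrom_length = chrom_length,
              gene_length_range = as.integer(gene_length_range),
              min_gene_gap = as.integer(min_gene_gap),
              close_pair_fraction = close_pair_fraction,
              close_pair_gap = as.integer(close_pair_gap),
              layers = layers, stages = stages, depth = depth,
              read_length = as.integer(read_length),
              enrichment = enrichment,
              strong_enrichment = strong_enrichment,
              weak_enrichment = weak_enrichment,
              class_fractions = class_fractions,
              lineage_fraction = lineage_fraction,
              fpkm_means = fpkm_means, fpkm_sigma = fpkm_sigma,
              cascade_onsets = cascade_onsets,
              ko_k27_mult = ko_k27_mult, ko_pol2_gain = ko_pol2_gain,
              ko_gain_clusters = ko_gain_clusters)
  if (sum(class_fractions) > 1) stop("class fractions must sum to at most 1")
  if (any(c(enrichment, strong_enrichment, weak_enrichment, depth,
            ko_k27_mult, ko_pol2_gain) <= 0)) {
    stop("depth and all multipliers must be positive")
  }
  if (min_gene_gap < 0) stop("min_gene_gap must be non-negative")
  if (close_pair_gap >= 10000) {
    stop("close_pair_gap must be below the 10 kb exclusion distance")
  }
  if (lineage_fraction > class_fractions[["housekeeping_activated"]]) {
    stop("lineage_fraction cannot exceed the housekeeping fraction")
  }
  if (length(stages) < max(cascade_onsets)) {
    stop("cascade onsets exceed the number of stages")
  }
  structure(cfg, class = "SimulationConfig")
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping genes along one chromosome with inter-gene gaps
#' of at least `min_gene_gap` bp, except for a configurable fraction of
#' deliberately close pairs (gap `close_pair_gap`, below the 10-kb
#' exclusion distance) that exercise the decoupled-gene neighbor rule.
#' Strands are assigned by a seeded coin flip. Deterministic given the
#' configuration.
#'
#' @param cfg A [simulation_config()].
#' @return An [Annotation].
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  n <- cfg$n_genes
  with_seed(derive_seed(cfg$seed, "annotation"), function() {
    lens <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                   n, replace = TRUE)
    n_pairs <- round(cfg$close_pair_fraction * n / 2)
    close_before <- rep(FALSE, n)  # TRUE: gap before gene i is the close gap
    if (n_pairs > 0) {
      candidates <- seq(2, n, by = 3)
      if (length(candidates) < n_pairs) {
        stop("close_pair_fraction too high for n_genes")
      }
      close_before[sample(candidates, n_pairs)] <- TRUE
    }
    gaps <- cfg$min_gene_gap +
      round(runif(n, 0, cfg$min_gene_gap / 2))
    gaps[close_before] <- cfg$close_pair_gap
    starts <- cumsum(gaps + c(0, lens[-n]))
    ends <- starts + lens
    needed <- ends[n] + cfg$min_gene_gap
    chrom_length <- cfg$chrom_length %||% needed
    if (chrom_length < needed) {
      stop("infeasible packing: ", n, " genes need ", needed,
           " bp but chrom_length is ", chrom_length)
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("g%04d", seq_len(n))
    genes <- data.frame(gene_id = ids, tx_name = paste0(ids, ".1"),
                        chrom = cfg$chrom, strand = strand,
                        tx_start = starts, tx_end = ends)
    Annotation(genes, setNames(chrom_length, cfg$chrom))
  })
}

#' Plant ground-truth labels for a synthetic study
#'
#' Assigns every gene a class (housekeeping_activated, bivalent_pol2_plus,
#' bivalent_pol2_minus, decoupled, or silenced as remainder), a germ-layer
#' assignment for a subset of the housekeeping genes, a chromatin cluster
#' C1-C4 for bivalent genes, a cascade flag for Pol II(+) bivalent genes
#' and per-gene knockout multipliers. Decoupled genes are only planted on
#' genes isolated by at least 10 kb, keeping the planted label consistent
#' with the classifier's exclusion rule.
#'
#' @param cfg A [simulation_config()].
#' @param ann The matching [generate_annotation()] output.
#' @return data.frame of class `SyntheticTruth`: `gene_id`, `class`,
#'   `lineage`, `cluster`, `cascade`, `ko_pol2_mult`, `ko_k27_mult`.
#' @export
generate_truth <- function(cfg, ann) {
  stopifnot(inherits(cfg, "SimulationConfig"), inherits(ann, "Annotation"))
  n <- n_genes(ann)
  ids <- ann$genes$gene_id
  with_seed(derive_seed(cfg$seed, "truth"), function() {
    counts <- round(cfg$class_fractions * n)
    class <- setNames(rep("silenced", n), ids)
    iso <- gene_isolation(ann, 10000)
    isolated_pool <- ids[iso]
    if (length(isolated_pool) < counts[["decoupled"]]) {
      stop("not enough isolated genes to plant the decoupled class")
    }
    dec <- sample(isolated_pool, counts[["decoupled"]])
    class[dec] <- "decoupled"
    pool <- setdiff(ids, dec)
    for (cl in c("housekeeping_activated", "bivalent_pol2_plus",
                 "bivalent_pol2_minus")) {
      pick <- sample(pool, counts[[cl]])
      class[pick] <- cl
      pool <- setdiff(pool, pick)
    }
    lineage <- setNames(rep(NA_character_, n), ids)
    hk <- ids[class == "housekeeping_activated"]
    n_lin <- round(cfg$lineage_fraction * n)
    lin_genes <- sample(hk, n_lin)
    lineage[lin_genes] <- sample(cfg$layers, n_lin, replace = TRUE)
    cluster <- setNames(rep(NA_character_, n), ids)
    biv <- ids[class %in% c("bivalent_pol2_plus", "bivalent_pol2_minus")]
    # balanced strata: per-mark strong/weak fractions stay at one half, so
    # the planted labels coincide with the median-split definition
    cluster[biv] <- sample(rep_len(c("C1", "C2", "C3", "C4"), length(biv)))
    cascade <- class == "bivalent_pol2_plus"
    ko_pol2 <- ifelse(!is.na(cluster) & cluster %in% cfg$ko_gain_clusters,
                      cfg$ko_pol2_gain, 1)
    ko_k27 <- ifelse(class %in% c("bivalent_pol2_plus",
                                  "bivalent_pol2_minus"),
                     cfg$ko_k27_mult, 1)
    structure(data.frame(gene_id = ids, class = unname(class),
                         lineage = unname(lineage),
                         cluster = unname(cluster),
                         cascade = unname(cascade),
                         ko_pol2_mult = unname(ko_pol2),
                         ko_k27_mult = unname(ko_k27), row.names = NULL),
              class = c("SyntheticTruth", "data.frame"))
  })
}

## total expected fold-over-background per gene for one sample
mark_multipliers <- function(cfg, truth, mark, layer, stage_index,
                             condition) {
  E <- cfg$enrichment
  S <- cfg$strong_enrichment
  W <- cfg$weak_enrichment
  cl <- truth$class
  clus <- truth$cluster
  mult <- rep(1, nrow(truth))
  if (mark == "PolII") {
    mult[cl %in% c("housekeeping_activated", "bivalent_pol2_plus",
                   "decoupled")] <- E
  } else if (mark == "Ser2p") {
    active <- cl %in% c("housekeeping_activated", "decoupled")
    lin <- !is.na(truth$lineage)
    mult[active & !lin] <- E
    mult[active & lin & truth$lineage == layer] <- E
  } else if (mark == "H3K4me3") {
    mult[cl %in% c("housekeeping_activated", "decoupled")] <- E
    biv <- !is.na(clus)
    mult[biv & clus %in% c("C1", "C2")] <- S
    mult[biv & clus %in% c("C3", "C4")] <- W
  } else if (mark == "H3K27me3") {
    biv <- !is.na(clus)
    mult[biv & clus %in% c("C2", "C3")] <- S
    mult[biv & clus %in% c("C1", "C4")] <- W
  }
  if (mark %in% names(cfg$cascade_onsets)) {
    off <- truth$cascade & stage_index < cfg$cascade_onsets[[mark]]
    mult[off] <- 1
  }
  if (condition == "ko") {
    if (mark == "PolII") mult <- mult * truth$ko_pol2_mult
    if (mark == "H3K27me3") mult <- mult * truth$ko_k27_mult
  }
  mult
}

#' Simulate aligned reads for one sample
#'
#' Background reads are Poisson with expectation `depth` per kb, placed
#' uniformly along the chromosome. Each gene's target window (promoter for
#' Pol II and histone marks, gene body for Ser2p) receives additional
#' Poisson reads so that the window's total expected coverage is
#' `multiplier` times background, where the multiplier depends on the
#' gene's planted class, cluster, lineage, the stage (cascade genes switch
#' marks on at their planted onset stage) and the condition (knockout
#' multipliers). Multipliers below 1 saturate at background level. Reads
#' have fixed length and the library size is the total number of reads
#' emitted. Deterministic given the configuration seed and the sample
#' coordinates.
#'
#' @param cfg A [simulation_config()].
#' @param truth Matching [generate_truth()] output.
#' @param ann Matching [generate_annotation()] output.
#' @param mark One of `"PolII"`, `"Ser2p"`, `"H3K4me3"`, `"H3K27me3"`.
#' @param layer Germ layer (relevant to Ser2p lineage structure).
#' @param stage Stage id from `cfg$stages`.
#' @param condition `"control"` or `"ko"`.
#' @return A [ReadSet] with `sample_id` `<mark>_<layer>_<stage>_<condition>`.
#' @export
simulate_reads <- function(cfg, truth, ann, mark, layer, stage,
                           condition = c("control", "ko")) {
  condition <- match.arg(condition)
  stopifnot(inherits(cfg, "SimulationConfig"))
  stage_index <- match(stage, cfg$stages)
  if (is.na(stage_index)) stop("unknown stage '", stage, "'")
  if (!layer %in% cfg$layers) stop("unknown layer '", layer, "'")
  sample_id <- paste(mark, layer, stage, condition, sep = "_")
  chrom_len <- as.numeric(ann$genome[[cfg$chrom]])
  rl <- cfg$read_length
  win <- if (mark == "Ser2p") genebody_windows(ann) else
    promoter_windows(ann)
  mult <- mark_multipliers(cfg, truth, mark, layer, stage_index, condition)
  with_seed(derive_seed(cfg$seed, paste("reads", sample_id)), function() {
    n_bg <- rpois(1, cfg$depth * chrom_len / 1000)
    bg_start <- floor(runif(n_bg, 0, chrom_len - rl))
    lambda <- cfg$depth * (win$end - win$start) / 1000 * pmax(mult - 1, 0)
    n_enr <- rpois(length(lambda), lambda)
    w_idx <- rep.int(seq_along(n_enr), n_enr)
    lo <- win$start[w_idx]
    hi <- pmax(win$end[w_idx] - rl, lo + 1)
    enr_start <- floor(runif(length(w_idx), lo, hi))
    start <- c(bg_start, enr_start)
    start <- sort(start)
    intervals <- data.frame(chrom = cfg$chrom, start = start,
                            end = start + rl)
    ReadSet(sample_id, mark, intervals)
  })
}

#' Simulate an FPKM expression table
#'
#' FPKM per gene and germ layer equals the planted class mean (housekeeping
#' high in every layer; lineage genes high in their home layer only;
#' decoupled, silenced and Pol II(-) bivalent genes near zero) times
#' seeded lognormal noise `exp(N(0, sigma))`; with `sigma = 0` the class
#' means are returned exactly.
#'
#' @param cfg A [simulation_config()].
#' @param truth Matching [generate_truth()] output.
#' @return data.frame with `gene_id` and one FPKM column per germ layer.
#' @export
simulate_expression <- function(cfg, truth) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  fm <- cfg$fpkm_means
  base_mean <- function(layer) {
    mean <- numeric(nrow(truth))
    cl <- truth$class
    mean[cl == "housekeeping_activated"] <- fm[["housekeeping"]]
    mean[cl == "bivalent_pol2_plus"] <- fm[["bivalent_pol2_plus"]]
    mean[cl == "bivalent_pol2_minus"] <- fm[["bivalent_pol2_minus"]]
    mean[cl == "decoupled"] <- fm[["decoupled"]]
    mean[cl == "silenced"] <- fm[["silenced"]]
    lin <- !is.na(truth$lineage)
    mean[lin] <- ifelse(truth$lineage[lin] == layer, fm[["lineage_home"]],
                        fm[["lineage_away"]])
    mean
  }
  out <- data.frame(gene_id = truth$gene_id)
  for (layer in cfg$layers) {
    mu <- base_mean(layer)
    noise <- with_seed(derive_seed(cfg$seed, paste("expr", layer)),
                       function() exp(rnorm(nrow(truth), 0, cfg$fpkm_sigma)))
    out[[layer]] <- mu * noise
  }
  out
}

#' Generate a complete synthetic study on disk
#'
#' Writes a self-contained bundle: refFlat annotation, chromosome sizes,
#' BED read files with a sample manifest, a per-layer FPKM table, the
#' ground-truth manifest and the flattened configuration. The sample grid
#' covers Pol II / H3K4me3 / H3K27me3 at every stage (first layer), Ser2p
#' in every germ layer at the terminal stage, and knockout Pol II /
#' H3K27me3 at the terminal stage. Every file is re-generable
#' bit-identically from the configuration.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `cfg`, `ann`, `truth` and the
#'   sample `manifest` data.frame.
#' @export
generate_study <- function(cfg, dir) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(cfg, ann)
  write_refflat(ann, file.path(dir, "annotation.refflat"))
  fwrite(data.frame(chrom = names(ann$genome),
                    length = as.numeric(ann$genome)),
         file.path(dir, "genome.tsv"), sep = "\t", quote = FALSE)
  fwrite(as.data.frame(truth), file.path(dir, "truth.tsv"), sep = "\t",
         quote = FALSE)
  fwrite(simulate_expression(cfg, truth), file.path(dir, "expression.tsv"),
         sep = "\t", quote = FALSE)

  terminal <- cfg$stages[length(cfg$stages)]
  first_layer <- cfg$layers[1]
  grid <- rbind(
    expand.grid(mark = c("PolII", "H3K4me3", "H3K27me3"),
                layer = first_layer, stage = cfg$stages,
                condition = "control", stringsAsFactors = FALSE),
    expand.grid(mark = "Ser2p", layer = cfg$layers, stage = terminal,
                condition = "control", stringsAsFactors = FALSE),
    expand.grid(mark = c("PolII", "H3K27me3"), layer = first_layer,
                stage = terminal, condition = "ko",
                stringsAsFactors = FALSE))
  manifest <- data.frame(sample_id = character(), mark = character(),
                         layer = character(), stage = character(),
                         condition = character(), file = character(),
                         library_size = numeric())
  for (i in seq_len(nrow(grid))) {
    rs <- simulate_reads(cfg, truth, ann, grid$mark[i], grid$layer[i],
                         grid$stage[i], grid$condition[i])
    rel <- file.path("reads", paste0(rs$sample_id, ".bed"))
    write_bed_reads(rs, file.path(dir, rel))
    manifest[i, ] <- list(rs$sample_id, grid$mark[i], grid$layer[i],
                          grid$stage[i], grid$condition[i], rel,
                          rs$library_size)
  }
  fwrite(manifest, file.path(dir, "reads_manifest.tsv"), sep = "\t",
         quote = FALSE)
  flat <- vapply(cfg, function(v) paste(
    if (is.null(v)) "auto" else v, collapse = ","), character(1))
  fwrite(data.frame(key = names(flat), value = unname(flat)),
         file.path(dir, "config.tsv"), sep = "\t", quote = FALSE)
  invisible(list(dir = dir, cfg = cfg, ann = ann, truth = truth,
                 manifest = manifest))
}
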