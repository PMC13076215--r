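#' Load a study bundle from disk
#'
#' Reads the files a study bundle is made of (as written by
#' [generate_study()], or assembled by hand in the same layout): a refFlat
#' annotation, a `genome.tsv` chromosome-size table, a
#' `reads_manifest.tsv` indexing the BED read files (columns `sample_id`,
#' `mark`, `layer`, `stage`, `condition`, `file`, `library_size`), an
#' `expression.tsv` FPKM table with one column per germ layer, and a
#' `config.tsv` key-value file carrying at least `layers` and `stages`
#' (comma-separated).
#'
#' @param dir Bundle directory.
#' @return List with `dir`, `ann` (collapsed [Annotation]), `manifest`,
#'   `expression`, `layers`, `stages`.
#' @export
read_study <- function(dir) {
  need <- function(p) {
    path <- file.path(dir, p)
    if (!file.exists(path)) stop("missing input: ", path)
    path
  }
  genome_tab <- fread(need("genome.tsv"), sep = "\t", data.table = FALSE)
  genome <- setNames(as.numeric(genome_tab$length), genome_tab$chrom)
  ann <- collapse_isoforms(read_refflat(need("annotation.refflat"), genome))
  manifest <- fread(need("reads_manifest.tsv"), sep = "\t",
                    data.table = FALSE)
  expression <- fread(need("expression.tsv"), sep = "\t",
                      data.table = FALSE)
  config <- fread(need("config.tsv"), sep = "\t", data.table = FALSE)
  getcfg <- function(key) {
    row <- config$value[config$key == key]
    if (length(row) == 0) stop("config.tsv lacks key '", key, "'")
    strsplit(row, ",", fixed = TRUE)[[1]]
  }
  list(dir = dir, ann = ann, manifest = manifest, expression = expression,
       layers = getcfg("layers"), stages = getcfg("stages"))
}

manifest_sample <- function(study, mark, layer, stage, condition) {
  m <- study$manifest
  hit <- m$mark == mark & m$layer == layer & m$stage == stage &
    m$condition == condition
  if (sum(hit) == 0) {
    stop("no sample in manifest for mark=", mark, " layer=", layer,
         " stage=", stage, " condition=", condition)
  }
  m[which(hit)[1], ]
}

load_signal <- function(study, out_dir, sample_id) {
  path <- file.path(out_dir, "signals", paste0(sample_id, ".tsv"))
  if (!file.exists(path)) stop("missing input: ", path)
  read_signal_table(path)
}

#' Run the analysis pipeline on a study bundle
#'
#' Orchestrates the stages behind subcommands. `quantify` normalizes every
#' sample in the manifest (promoter windows for Pol II and histone marks,
#' gene-body windows for Ser2p) and writes one signal TSV per sample plus
#' a background-coefficient table. `classify` builds the gene-state table
#' (bivalency, activity partition, Pol II status, decoupled flag,
#' germ-layer assignment) for the terminal stage and writes BED6 tracks of
#' Pol II(+) and Pol II(-) promoters. `clusters` stratifies bivalent
#' promoters into C1-C4 and, when knockout samples are present, computes
#' fold-change quadrant fractions per cluster. `dynamics` derives
#' stage-to-stage Pol II(+) transition sets and the mark-onset cascade
#' summary. `all` runs everything in order; `simulate` generates a bundle
#' into `bundle_dir` first. Later stages load earlier stages' outputs,
#' recomputing them when absent. All outputs are plain TSV/BED under
#' `out_dir`, plus a deterministic `run_manifest.tsv` (package version,
#' seed, thresholds, input checksums); rerunning on identical inputs
#' reproduces every output byte for byte.
#'
#' @param bundle_dir Study bundle directory.
#' @param subcommand One of `"simulate"`, `"quantify"`, `"classify"`,
#'   `"clusters"`, `"dynamics"`, `"all"`.
#' @param out_dir Output directory (default `<bundle_dir>/results`).
#' @param config [simulation_config()] for `simulate` (default: one built
#'   from `seed`).
#' @param thresholds Classification thresholds.
#' @param cluster_method `"median_split"` or `"kmeans"` for the C1-C4
#'   stratification.
#' @param seed Seed (simulation and k-means initialization).
#' @return Invisibly, a list of computed objects and output paths.
#' @export
run_pipeline <- function(bundle_dir,
                         subcommand = c("all", "simulate", "quantify",
                                        "classify", "clusters", "dynamics"),
                         out_dir = file.path(bundle_dir, "results"),
                         config = NULL,
                         thresholds = default_thresholds(),
                         cluster_method = "median_split", seed = 1L) {
  subcommand <- match.arg(subcommand)
  if (any(unlist(thresholds) <= 0)) stop("config error: thresholds must be positive")
  if (subcommand == "simulate") {
    cfg <- config %||% simulation_config(seed = seed)
    res <- generate_study(cfg, bundle_dir)
    return(invisible(res))
  }
  study <- read_study(bundle_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  result <- list(out_dir = out_dir)

  if (subcommand %in% c("quantify", "all")) {
    result$backgrounds <- pipeline_quantify(study, out_dir)
  }
  if (subcommand %in% c("classify", "all")) {
    result$states <- pipeline_classify(study, out_dir, thresholds)
  }
  if (subcommand %in% c("clusters", "all")) {
    result$clusters <- pipeline_clusters(study, out_dir, thresholds,
                                         cluster_method, seed)
  }
  if (subcommand %in% c("dynamics", "all")) {
    result$dynamics <- pipeline_dynamics(study, out_dir, thresholds)
  }
  write_run_manifest(study, out_dir, subcommand, thresholds, seed)
  invisible(result)
}

pipeline_quantify <- function(study, out_dir) {
  dir.create(file.path(out_dir, "signals"), showWarnings = FALSE)
  m <- study$manifest
  coefs <- data.frame(sample_id = m$sample_id,
                      background_coefficient = NA_real_)
  for (i in seq_len(nrow(m))) {
    path <- file.path(study$dir, m$file[i])
    if (!file.exists(path)) stop("missing input: ", path)
    reads <- read_bed_reads(path, m$sample_id[i], m$mark[i],
                            m$library_size[i])
    region <- if (m$mark[i] == "Ser2p") "genebody" else "promoter"
    sig <- normalize_signal(reads, study$ann, region)
    coefs$background_coefficient[i] <- attr(sig, "background_coefficient")
    message("sample ", m$sample_id[i], ": background coefficient ",
            format(coefs$background_coefficient[i], digits = 6))
    write_signal_table(sig, file.path(out_dir, "signals",
                                      paste0(m$sample_id[i], ".tsv")))
  }
  fwrite(coefs, file.path(out_dir, "background_coefficients.tsv"),
         sep = "\t", quote = FALSE)
  coefs
}

ensure_signals <- function(study, out_dir) {
  if (!dir.exists(file.path(out_dir, "signals"))) {
    pipeline_quantify(study, out_dir)
  }
}

classification_signals <- function(study, out_dir) {
  terminal <- study$stages[length(study$stages)]
  first_layer <- study$layers[1]
  sig <- function(mark, layer = first_layer, condition = "control") {
    s <- manifest_sample(study, mark, layer, terminal, condition)
    load_signal(study, out_dir, s$sample_id)
  }
  list(terminal = terminal, first_layer = first_layer,
       pol2 = sig("PolII"), k4 = sig("H3K4me3"), k27 = sig("H3K27me3"),
       ser2p_by_layer = setNames(lapply(study$layers,
                                        function(l) sig("Ser2p", l)),
                                 study$layers))
}

pipeline_classify <- function(study, out_dir, th) {
  ensure_signals(study, out_dir)
  cs <- classification_signals(study, out_dir)
  if (!cs$first_layer %in% names(study$expression)) {
    stop("missing input: expression column '", cs$first_layer, "'")
  }
  expr <- setNames(study$expression[[cs$first_layer]],
                   study$expression$gene_id)
  bivalent <- classify_bivalent(cs$k4, cs$k27, th)
  states <- classify_activity(cs$pol2, bivalent, th)
  states$decoupled <- unname(
    identify_decoupled(cs$ser2p_by_layer[[cs$first_layer]], expr,
                       study$ann, th)[states$gene_id])
  states$lineage <- unname(
    lineage_specific_ser2p(cs$ser2p_by_layer, th)[states$gene_id])
  for (col in c("pol2", "k4", "k27")) {
    v <- normalized_values(cs[[col]])
    states[[paste0("normalized_", col)]] <- unname(v[states$gene_id])
  }
  ser2p <- normalized_values(cs$ser2p_by_layer[[cs$first_layer]])
  states$normalized_ser2p <- unname(ser2p[states$gene_id])
  write_state_table(states, file.path(out_dir, "state_table.tsv"))
  write_pol2_beds(states, study$ann, out_dir)
  states
}

write_pol2_beds <- function(states, ann, out_dir) {
  prom <- promoter_windows(ann)
  rownames(prom) <- prom$gene_id
  strand <- setNames(ann$genes$strand, ann$genes$gene_id)
  for (status in c("pol2_plus", "pol2_minus")) {
    sel <- states[states$pol2_status == status, , drop = FALSE]
    w <- prom[sel$gene_id, , drop = FALSE]
    bed <- data.frame(chrom = w$chrom, start = w$start, end = w$end,
                      name = sel$gene_id,
                      score = round(sel$normalized_pol2 * 100),
                      strand = unname(strand[sel$gene_id]))
    bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
    fwrite(bed, file.path(out_dir, paste0(status, "_promoters.bed")),
           sep = "\t", col.names = FALSE, quote = FALSE)
  }
}

pipeline_clusters <- function(study, out_dir, th, cluster_method, seed) {
  ensure_signals(study, out_dir)
  cs <- classification_signals(study, out_dir)
  bivalent <- classify_bivalent(cs$k4, cs$k27, th)
  strat <- stratify_c1c4(cs$k4, cs$k27, bivalent, method = cluster_method,
                         seed = seed)
  fwrite(strat, file.path(out_dir, "clusters.tsv"), sep = "\t",
         quote = FALSE)
  out <- list(clusters = strat)

  ko_rows <- study$manifest[study$manifest$condition == "ko", , drop = FALSE]
  if (nrow(ko_rows) > 0) {
    ko_sig <- function(mark) {
      s <- manifest_sample(study, mark, cs$first_layer, cs$terminal, "ko")
      load_signal(study, out_dir, s$sample_id)
    }
    fc_pol2 <- fold_change(ko_sig("PolII"), cs$pol2)
    fc_k27 <- fold_change(ko_sig("H3K27me3"), cs$k27)
    groups <- c(list(all_bivalent = strat$gene_id),
                split(strat$gene_id, strat$cluster))
    quad <- do.call(rbind, lapply(names(groups), function(g) {
      q <- quadrant_fractions(fc_pol2, fc_k27, groups[[g]])
      data.frame(cluster = g, n = length(groups[[g]]),
                 frac_UL = q[["upper_left"]], frac_UR = q[["upper_right"]],
                 frac_LL = q[["lower_left"]], frac_LR = q[["lower_right"]])
    }))
    fwrite(quad, file.path(out_dir, "quadrants.tsv"), sep = "\t",
           quote = FALSE)
    out$quadrants <- quad
    out$fc_pol2 <- fc_pol2
    out$fc_k27 <- fc_k27
  }
  out
}

pipeline_dynamics <- function(study, out_dir, th) {
  ensure_signals(study, out_dir)
  first_layer <- study$layers[1]
  per_mark <- function(mark) {
    setNames(lapply(study$stages, function(st) {
      s <- manifest_sample(study, mark, first_layer, st, "control")
      load_signal(study, out_dir, s$sample_id)
    }), study$stages)
  }
  series <- stage_series(study$stages,
                         list(PolII = per_mark("PolII"),
                              H3K4me3 = per_mark("H3K4me3"),
                              H3K27me3 = per_mark("H3K27me3")))
  pol2_plus <- lapply(study$stages, function(st) {
    k4 <- series$m$H3K4me3[, st]
    k27 <- series$m$H3K27me3[, st]
    biv <- classify_bivalent(k4, k27, th)
    pol2_positive_genes(series$m$PolII[, st], biv, th)
  })
  names(pol2_plus) <- study$stages
  transitions <- do.call(rbind, lapply(seq_len(length(study$stages) - 1),
                                       function(i) {
    tr <- transition_sets(pol2_plus[[i]], pol2_plus[[i + 1]])
    status <- c(rep("gained", length(tr$gained)),
                rep("lost", length(tr$lost)),
                rep("retained", length(tr$retained)))
    gene <- c(tr$gained, tr$lost, tr$retained)
    if (length(gene) == 0) return(NULL)
    df <- data.frame(from_stage = study$stages[i],
                     to_stage = study$stages[i + 1],
                     gene_id = gene, status = status)
    df[order(df$gene_id, df$status), , drop = FALSE]
  }))
  if (is.null(transitions)) {
    transitions <- data.frame(from_stage = character(),
                              to_stage = character(),
                              gene_id = character(), status = character())
  }
  fwrite(transitions, file.path(out_dir, "transitions.tsv"), sep = "\t",
         quote = FALSE)
  cascade <- cascade_order(series,
                           thresholds = c(H3K27me3 = th$bivalent_min,
                                          H3K4me3 = th$bivalent_min,
                                          PolII = th$pol2_pos_min))
  fwrite(cascade$per_gene, file.path(out_dir, "cascade.tsv"), sep = "\t",
         quote = FALSE)
  fwrite(cascade$counts, file.path(out_dir, "cascade_summary.tsv"),
         sep = "\t", quote = FALSE)
  list(series = series, pol2_plus = pol2_plus, transitions = transitions,
       cascade = cascade)
}

write_run_manifest <- function(study, out_dir, subcommand, th, seed) {
  inputs <- c(file.path(study$dir, "annotation.refflat"),
              file.path(study$dir, "reads_manifest.tsv"),
              file.path(study$dir, "expression.tsv"))
  sums <- md5sum(inputs[file.exists(inputs)])
  rows <- data.frame(
    key = c("package_version", "subcommand", "seed",
            paste0("threshold_", names(th)),
            paste0("md5_", basename(names(sums)))),
    value = c(as.character(packageVersion("chromstate")), subcommand,
              as.character(seed), as.character(unlist(th)),
              unname(sums)))
  fwrite(rows, file.path(out_dir, "run_manifest.tsv"), sep = "\t",
         quote = FALSE)
}
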