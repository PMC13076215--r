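# Shared fixtures and independent oracles, all built in code.

.fixtures <- new.env()

# The reference study conditions: 500 genes, depth 50 reads/kb, >= 5x
# enrichment. Generated once per test run and shared.
default_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    dir <- file.path(tempdir(), "chromstate-default-bundle")
    cfg <- simulation_config(seed = 20260901)
    res <- generate_study(cfg, dir)
    .fixtures$bundle <- res
  }
  .fixtures$bundle
}

# `all` pipeline output on the default bundle, computed once.
default_pipeline <- function() {
  if (is.null(.fixtures$pipeline)) {
    b <- default_bundle()
    out_dir <- file.path(b$dir, "results")
    .fixtures$pipeline <- suppressMessages(
      run_pipeline(b$dir, "all", out_dir = out_dir, seed = 11))
  }
  .fixtures$pipeline
}

# Small annotation built by hand: three genes on one 100-kb chromosome.
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    tx_name = c("gA.1", "gB.1", "gC.1"),
    chrom = "chr1",
    strand = c("+", "-", "+"),
    tx_start = c(10000, 40000, 70000),
    tx_end = c(14000, 46000, 72000))
  Annotation(genes, c(chr1 = 100000))
}

# Independent O(reads x windows) overlap scan (>= 1 bp overlap).
brute_force_counts <- function(intervals, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sum(intervals$chrom == w$chrom & intervals$start < w$end &
          intervals$end > w$start)
  }, numeric(1))
}

# Independent all-pairs gap scan for the 10-kb isolation rule.
brute_force_isolated <- function(genes, max_gap) {
  n <- nrow(genes)
  iso <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || genes$chrom[i] != genes$chrom[j]) next
      gap <- max(genes$tx_start[j] - genes$tx_end[i],
                 genes$tx_start[i] - genes$tx_end[j], 0)
      if (gap < max_gap) iso[i] <- FALSE
    }
  }
  setNames(iso, genes$gene_id)
}

# Well-separated positive Gaussian blobs with known membership.
make_blobs <- function(k = 3, per = 40, sep = 12, sd = 0.4, dims = 4,
                       seed = 60) {
  set.seed(seed)
  centers <- matrix(runif(k * dims, 1, 2), k, dims)
  for (j in seq_len(k)) centers[j, 1 + (j - 1) %% dims] <-
    centers[j, 1 + (j - 1) %% dims] + sep * j
  x <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(rnorm(per * dims, rep(centers[j, ], each = per), sd), per)
  }))
  list(x = abs(x), truth = rep(seq_len(k), each = per))
}

# Named-vector signal shorthand for classifier tests.
sig <- function(...) {
  v <- c(...)
  stopifnot(!is.null(names(v)))
  v
}

# Fraction of genes whose called label matches the planted one, NA == NA.
label_accuracy <- function(called, planted) {
  mean(mapply(function(a, b) {
    (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
  }, called, planted))
}
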