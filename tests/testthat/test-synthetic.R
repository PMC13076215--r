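small_cfg <- function(...) {
  simulation_config(seed = 101, n_genes = 60, depth = 25, ...)
}

test_that("annotation generation is deterministic with controlled gaps", {
  cfg <- simulation_config(seed = 3, n_genes = 100,
                           close_pair_fraction = 0.1,
                           close_pair_gap = 6000, min_gene_gap = 20000)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1$genes, a2$genes)
  g <- a1$genes
  gaps <- g$tx_start[-1] - g$tx_end[-nrow(g)]
  # exactly 10 genes (5 pairs) have a neighbor within 10 kb
  expect_equal(sum(gaps < 10000), 5)
  expect_equal(sum(!gene_isolation(a1, 10000)), 10)
  expect_true(all(gaps[gaps >= 10000] >= 20000))
  expect_true(all(g$tx_end <= a1$genome[["chrS"]]))
})

test_that("no close pairs means every gap is at least the minimum", {
  cfg <- simulation_config(seed = 4, n_genes = 40, close_pair_fraction = 0,
                           min_gene_gap = 20000)
  g <- generate_annotation(cfg)$genes
  gaps <- g$tx_start[-1] - g$tx_end[-nrow(g)]
  expect_true(all(gaps >= 20000))
})

test_that("an explicit chromosome length too small for the packing errors", {
  cfg <- simulation_config(seed = 5, n_genes = 50, chrom_length = 1e5)
  expect_error(generate_annotation(cfg), "infeasible packing")
})

test_that("planted truth respects class fractions and label consistency", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg)
  truth <- generate_truth(cfg, ann)
  expect_equal(nrow(truth), 60)
  counts <- table(truth$class)
  expect_equal(counts[["decoupled"]], round(0.10 * 60))
  expect_equal(counts[["bivalent_pol2_plus"]], round(0.15 * 60))
  # decoupled genes are planted only on isolated genes
  iso <- gene_isolation(ann, 10000)
  expect_true(all(iso[truth$gene_id[truth$class == "decoupled"]]))
  # clusters exactly on bivalent genes, lineage only on housekeeping
  biv <- truth$class %in% c("bivalent_pol2_plus", "bivalent_pol2_minus")
  expect_identical(!is.na(truth$cluster), biv)
  expect_true(all(truth$class[!is.na(truth$lineage)] ==
                    "housekeeping_activated"))
  expect_identical(truth$cascade, truth$class == "bivalent_pol2_plus")
})

test_that("read simulation is seed-deterministic with the library size as total reads", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg)
  truth <- generate_truth(cfg, ann)
  r1 <- simulate_reads(cfg, truth, ann, "PolII", "Ect", "E7.5Ect")
  r2 <- simulate_reads(cfg, truth, ann, "PolII", "Ect", "E7.5Ect")
  expect_identical(r1$intervals, r2$intervals)
  expect_equal(r1$library_size, nrow(r1$intervals))
  r3 <- simulate_reads(cfg, truth, ann, "PolII", "Ect", "ICM")
  expect_false(identical(r1$intervals, r3$intervals))
  expect_true(all(r1$intervals$end - r1$intervals$start == 50))
})

test_that("window read counts match their Poisson expectation", {
  b <- default_bundle()
  cfg <- b$cfg
  rs <- simulate_reads(cfg, b$truth, b$ann, "H3K4me3", cfg$layers[1],
                       cfg$stages[4])
  win <- promoter_windows(b$ann)
  counts <- compute_rpkm(rs, win) *
    (win$end - win$start) / 1000 * rs$library_size / 1e6
  mult <- rep(1, nrow(b$truth))
  cl <- b$truth$class
  mult[cl %in% c("housekeeping_activated", "decoupled")] <- cfg$enrichment
  mult[!is.na(b$truth$cluster) & b$truth$cluster %in% c("C1", "C2")] <-
    cfg$strong_enrichment
  mult[!is.na(b$truth$cluster) & b$truth$cluster %in% c("C3", "C4")] <-
    cfg$weak_enrichment
  # expected count: background over an L+49 bp catch plus planted extra
  lam <- cfg$depth * (1000 + 49) / 1000 + cfg$depth * (mult - 1)
  z <- (counts - lam) / sqrt(lam)
  expect_gte(mean(abs(z) <= 3), 0.99)
})

test_that("mean normalized signal sits near the planted multiplier", {
  b <- default_bundle()
  cfg <- b$cfg
  rs <- simulate_reads(cfg, b$truth, b$ann, "PolII", cfg$layers[1],
                       cfg$stages[4])
  s <- normalize_signal(rs, b$ann)
  v <- setNames(s$normalized_rpkm, s$gene_id)
  silenced <- b$truth$gene_id[b$truth$class == "silenced"]
  enriched <- b$truth$gene_id[b$truth$class == "housekeeping_activated"]
  expect_equal(mean(v[silenced]), 1, tolerance = 0.2)
  expect_equal(mean(v[enriched]), cfg$enrichment, tolerance = 0.2 * cfg$enrichment)
})

test_that("expression tables honor class means, noise and determinism", {
  cfg0 <- small_cfg(fpkm_sigma = 0)
  ann <- generate_annotation(cfg0)
  truth <- generate_truth(cfg0, ann)
  e0 <- simulate_expression(cfg0, truth)
  hk <- truth$class == "housekeeping_activated" & is.na(truth$lineage)
  expect_true(all(e0$Ect[hk] == 20))  # sigma 0: exact class means
  expect_true(all(e0$Ect[truth$class == "silenced"] == 0.2))
  lin_home <- !is.na(truth$lineage) & truth$lineage == "Ect"
  expect_true(all(e0$Ect[lin_home] == 10))
  expect_true(all(e0$Mes[lin_home] == 0.5))

  cfg <- small_cfg(fpkm_sigma = 0.3)
  truth2 <- generate_truth(cfg, generate_annotation(cfg))
  e1 <- simulate_expression(cfg, truth2)
  e2 <- simulate_expression(cfg, truth2)
  expect_identical(e1, e2)
  dec <- e1$Ect[truth2$class == "decoupled"]
  expect_gte(mean(dec < 1), 0.95)
})

test_that("a generated study bundle is complete and bit-reproducible", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res1 <- generate_study(cfg, d1)
  res2 <- generate_study(cfg, d2)
  for (f in c("annotation.refflat", "genome.tsv", "truth.tsv",
              "expression.tsv", "reads_manifest.tsv", "config.tsv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  for (f in res1$manifest$file) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_equal(nrow(res1$truth), cfg$n_genes)
  # different seed: same schema, different reads
  res3 <- generate_study(simulation_config(seed = 999, n_genes = 60,
                                           depth = 25),
                         withr::local_tempdir())
  expect_identical(names(res3$manifest), names(res1$manifest))
  expect_false(identical(
    readLines(file.path(d1, res1$manifest$file[1])),
    readLines(file.path(res3$dir, res3$manifest$file[1]))))
})
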