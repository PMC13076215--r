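test_that("bivalency requires both marks strictly above the cutoff", {
  k4 <- sig(a = 2.5, b = 2.5, c = 2.0, d = 1.0)
  k27 <- sig(a = 2.5, b = 1.0, c = 5.0, d = 5.0)
  biv <- classify_bivalent(k4, k27)
  expect_true(biv[["a"]])
  expect_false(biv[["b"]])   # one mark below
  expect_false(biv[["c"]])   # exactly at the boundary fails
  expect_false(biv[["d"]])
  expect_error(classify_bivalent(k4, sig(a = 1, b = 1, c = 1, e = 1)), "gene")
})

test_that("activity partition and Pol II status follow the strict Pol II cutoff", {
  pol2 <- sig(bp = 3.5, bm = 3.0, act = 3.5, sil = 2.9)
  biv <- sig(bp = TRUE, bm = TRUE, act = FALSE, sil = FALSE)
  st <- classify_activity(pol2, biv)
  rownames(st) <- st$gene_id
  expect_equal(st["bp", "pol2_status"], "pol2_plus")
  expect_equal(st["bm", "pol2_status"], "pol2_minus")  # 3.0 is not > 3
  expect_equal(st["act", "activity"], "activated")
  expect_equal(st["sil", "activity"], "silenced")
  expect_equal(st[c("bp", "bm"), "activity"], rep("bivalent", 2))
  expect_equal(st[c("act", "sil"), "pol2_status"], rep("not_applicable", 2))
})

test_that("activity labels tile the gene set and Pol II status tiles the bivalent set", {
  set.seed(21)
  for (rep in 1:200) {
    n <- sample(3:40, 1)
    ids <- paste0("g", seq_len(n))
    pol2 <- setNames(runif(n, 0, 6), ids)
    biv <- setNames(runif(n) < 0.4, ids)
    st <- classify_activity(pol2, biv)
    counts <- table(factor(st$activity,
                           c("bivalent", "activated", "silenced")))
    expect_equal(sum(counts), n)  # every gene exactly one activity label
    expect_equal(nrow(st), n)
    expect_setequal(st$gene_id[st$activity == "bivalent"], ids[biv])
    in_pm <- st$pol2_status %in% c("pol2_plus", "pol2_minus")
    expect_identical(in_pm, unname(biv[st$gene_id]))
  }
})

test_that("raising Pol II signal never demotes a gene", {
  set.seed(7)
  for (rep in 1:50) {
    pol2 <- setNames(runif(10, 0, 6), paste0("g", 1:10))
    biv <- setNames(runif(10) < 0.5, paste0("g", 1:10))
    st1 <- classify_activity(pol2, biv)
    st2 <- classify_activity(pol2 + runif(10, 0, 3), biv)
    demoted <- (st1$pol2_status == "pol2_plus" &
                  st2$pol2_status == "pol2_minus") |
      (st1$activity == "activated" & st2$activity == "silenced")
    expect_false(any(demoted))
  }
})

test_that("decoupled calls need Ser2p, low FPKM and 10-kb isolation", {
  # gA--gB gap 8 kb (excluded), gC isolated by >= 15 kb
  genes <- data.frame(gene_id = c("gA", "gB", "gC"),
                      tx_name = c("gA.1", "gB.1", "gC.1"),
                      chrom = "chr1", strand = "+",
                      tx_start = c(10000, 22000, 60000),
                      tx_end = c(14000, 26000, 64000))
  ann <- Annotation(genes, c(chr1 = 2e5))
  ser2p <- sig(gA = 2.5, gB = 2.5, gC = 2.5)
  fpkm <- sig(gA = 0.5, gB = 0.5, gC = 0.5)
  dec <- identify_decoupled(ser2p, fpkm, ann)
  expect_false(dec[["gA"]])  # neighbor gap 8 kb < 10 kb
  expect_false(dec[["gB"]])
  expect_true(dec[["gC"]])   # isolated, Ser2p > 2, FPKM < 1
  # FPKM rule
  dec2 <- identify_decoupled(ser2p, sig(gA = 0.5, gB = 0.5, gC = 1.5), ann)
  expect_false(dec2[["gC"]])
  # Ser2p rule, strict boundary
  dec3 <- identify_decoupled(sig(gA = 2.5, gB = 2.5, gC = 2.0), fpkm, ann)
  expect_false(dec3[["gC"]])
  # missing FPKM errors unless missing_as_zero
  expect_error(identify_decoupled(ser2p, sig(gA = 0.5, gB = 0.5), ann),
               "gC")
  dec4 <- identify_decoupled(ser2p, sig(gA = 0.5, gB = 0.5), ann,
                             missing_as_zero = TRUE)
  expect_true(dec4[["gC"]])
})

test_that("a 15-kb gap passes and overlapping spans fail the isolation test", {
  genes <- data.frame(gene_id = c("far1", "far2", "ov1", "ov2"),
                      tx_name = paste0(c("far1", "far2", "ov1", "ov2"), ".1"),
                      chrom = c("chr1", "chr1", "chr2", "chr2"),
                      strand = "+",
                      tx_start = c(10000, 29000, 1000, 3000),
                      tx_end = c(14000, 33000, 5000, 8000))
  ann <- Annotation(genes, c(chr1 = 1e5, chr2 = 1e5))
  iso <- gene_isolation(ann, 10000)
  expect_true(iso[["far1"]])   # gap 15 kb
  expect_true(iso[["far2"]])
  expect_false(iso[["ov1"]])   # overlap counts as within
  expect_false(iso[["ov2"]])
})

test_that("isolation matches a brute-force all-pairs gap scan", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    starts <- sort(sample.int(5e5, n)) * 2
    lens <- sample(500:5000, n, replace = TRUE)
    genes <- data.frame(gene_id = paste0("g", seq_len(n)),
                        tx_name = paste0("g", seq_len(n), ".1"),
                        chrom = sample(c("c1", "c2"), n, replace = TRUE),
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        tx_start = starts, tx_end = starts + lens)
    # drop genes overlapping a same-chromosome predecessor is unnecessary:
    # overlapping spans are legal input for the isolation test
    ann <- Annotation(genes, c(c1 = 2e6, c2 = 2e6))
    expect_identical(gene_isolation(ann, 10000),
                     brute_force_isolated(genes, 10000))
  }
})

test_that("Ser2p lineage rule assigns the argmax layer with one tolerated extra", {
  by_layer <- list(
    Ect = sig(g1 = 4.0, g2 = 4.0, g3 = 4.0, g4 = 1.0, g5 = 3.0),
    Mes = sig(g1 = 1.0, g2 = 3.5, g3 = 2.5, g4 = 1.0, g5 = 1.0),
    End = sig(g1 = 1.5, g2 = 1.0, g3 = 1.0, g4 = 1.0, g5 = 1.0))
  lin <- lineage_specific_ser2p(by_layer)
  expect_equal(lin[["g1"]], "Ect")            # > 3 in one, < 2 elsewhere
  expect_equal(lin[["g2"]], "Ect")            # one extra > 3 tolerated
  expect_true(is.na(lin[["g3"]]))             # 2.5 is neither < 2 nor > 3
  expect_true(is.na(lin[["g4"]]))             # never above the high cutoff
  expect_true(is.na(lin[["g5"]]))             # exactly 3 fails the > 3 rule
  expect_error(lineage_specific_ser2p(by_layer[1]), "two")
})

test_that("lineage assignment is invariant under layer permutation and unique", {
  set.seed(5)
  for (rep in 1:40) {
    n <- 15
    ids <- paste0("g", seq_len(n))
    by_layer <- list(Ect = setNames(runif(n, 0, 6), ids),
                     Mes = setNames(runif(n, 0, 6), ids),
                     End = setNames(runif(n, 0, 6), ids))
    a <- lineage_specific_ser2p(by_layer)
    b <- lineage_specific_ser2p(by_layer[c("End", "Ect", "Mes")])
    expect_identical(a, b[names(a)])
  }
})

test_that("RNA lineage rule needs > 5 in exactly one layer and < 5 elsewhere", {
  by_layer <- list(L1 = sig(g1 = 7.0, g2 = 7.0, g3 = 5.0),
                   L2 = sig(g1 = 2.0, g2 = 6.0, g3 = 1.0),
                   L3 = sig(g1 = 1.0, g2 = 1.0, g3 = 1.0))
  lin <- lineage_specific_rna(by_layer)
  expect_equal(lin[["g1"]], "L1")
  expect_true(is.na(lin[["g2"]]))   # second layer >= 5
  expect_true(is.na(lin[["g3"]]))   # exactly 5 satisfies neither clause
})
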