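test_that("promoter windows are 1-kb TSS-centered, strand-aware, clipped", {
  genes <- data.frame(gene_id = c("plus", "minus", "edge"),
                      tx_name = c("p.1", "m.1", "e.1"),
                      chrom = "chr1", strand = c("+", "-", "+"),
                      tx_start = c(10000, 5000, 100),
                      tx_end = c(14000, 10000, 2100))
  ann <- Annotation(genes, c(chr1 = 1e6))
  w <- promoter_windows(ann)
  expect_equal(unlist(w[w$gene_id == "plus", c("start", "end")],
                      use.names = FALSE), c(9500, 10500))
  # minus-strand TSS = tx_end - 1 = 9999
  expect_equal(unlist(w[w$gene_id == "minus", c("start", "end")],
                      use.names = FALSE), c(9499, 10499))
  # clipped at the chromosome start
  expect_equal(unlist(w[w$gene_id == "edge", c("start", "end")],
                      use.names = FALSE), c(0, 600))
})

test_that("background windows mirror -4/-3 kb across strands and clip to zero", {
  genes <- data.frame(gene_id = c("plus", "minus", "near_start"),
                      tx_name = c("p.1", "m.1", "n.1"),
                      chrom = "chr1", strand = c("+", "-", "+"),
                      tx_start = c(10000, 5000, 2000),
                      tx_end = c(14000, 10000, 4000))
  ann <- Annotation(genes, c(chr1 = 1e6))
  b <- background_windows(ann)
  expect_equal(unlist(b[b$gene_id == "plus", c("start", "end")],
                      use.names = FALSE), c(6000, 7000))
  # minus strand, TSS = 9999: [TSS + 3001, TSS + 4001) = [13000, 14000)
  expect_equal(unlist(b[b$gene_id == "minus", c("start", "end")],
                      use.names = FALSE), c(13000, 14000))
  # + strand TSS at 2000: [-2000, -1000) clipped away entirely
  nw <- b[b$gene_id == "near_start", ]
  expect_equal(nw$end - nw$start, 0)
})

test_that("plus and minus genes with mirrored reads get identical background RPKM", {
  # symmetry check for the +1 bp mirror convention
  L <- 100000
  genes <- data.frame(gene_id = c("p", "m"), tx_name = c("p.1", "m.1"),
                      chrom = c("cp", "cm"), strand = c("+", "-"),
                      tx_start = c(50000, L - 54000),
                      tx_end = c(54000, 50000 + 1))
  # minus TSS = tx_end - 1 = 50000 mirrored at position x -> L - 1 - x
  genes$tx_start[2] <- L - 54000
  genes$tx_end[2] <- L - 50000
  ann <- Annotation(genes, c(cp = L, cm = L))
  b <- background_windows(ann)
  wp <- b[b$gene_id == "p", ]
  wm <- b[b$gene_id == "m", ]
  # mirrored interval: [L - end, L - start)
  expect_equal(wm$start, L - wp$end)
  expect_equal(wm$end, L - wp$start)
})

test_that("gene-body windows are the transcript span", {
  ann <- toy_annotation()
  w <- genebody_windows(ann)
  expect_equal(w$start, ann$genes$tx_start)
  expect_equal(w$end, ann$genes$tx_end)
  expect_true(all(w$end - w$start == ann$genes$tx_end - ann$genes$tx_start))
})

test_that("RPKM follows C / (L_kb * M) with >= 1 bp overlap counting", {
  starts <- seq(10100, by = 20, length.out = 10)
  reads <- ReadSet("s", "PolII",
                   data.frame(chrom = "chr1", start = starts,
                              end = starts + 50),
                   library_size = 1e6)
  w1 <- data.frame(chrom = "chr1", start = 10000, end = 11000)
  expect_equal(compute_rpkm(reads, w1), 10.0)
  # no overlap -> 0
  w0 <- data.frame(chrom = "chr1", start = 50000, end = 51000)
  expect_equal(compute_rpkm(reads, w0), 0)
  # doubling window length with same overlap count halves RPKM
  w2 <- data.frame(chrom = "chr1", start = 10000, end = 12000)
  expect_equal(compute_rpkm(reads, w2), 5.0)
  # zero library size errors
  empty <- ReadSet("s", "PolII",
                   data.frame(chrom = character(), start = numeric(),
                              end = numeric()), library_size = 0)
  expect_error(compute_rpkm(empty, w1), "positive")
})

test_that("single-bp overlaps at window edges are counted", {
  reads <- ReadSet("s", "PolII",
                   data.frame(chrom = "chr1",
                              start = c(951, 1999, 900, 2000),
                              end = c(1001, 2049, 1000, 2050)),
                   library_size = 1000)
  w <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  # first two overlap by exactly 1 bp; last two touch without overlap
  expect_equal(compute_rpkm(reads, w), 2 / (1 * (1000 / 1e6)))
})

test_that("background coefficient is the floored mean over genes", {
  expect_equal(background_coefficient(c(1, 2, 3)), 2)
  expect_equal(background_coefficient(c(0, 0, 0)), 1e-6)
  expect_equal(background_coefficient(5), 5)
  expect_error(background_coefficient(numeric(0)), "empty")
})

test_that("normalized signal equals region RPKM over the background coefficient", {
  b <- default_bundle()
  rs <- simulate_reads(b$cfg, b$truth, b$ann, "PolII", b$cfg$layers[1],
                       b$cfg$stages[4])
  ann <- b$ann
  signal <- normalize_signal(rs, ann, "promoter")
  coef <- attr(signal, "background_coefficient")
  expect_equal(coef, background_coefficient(signal$raw_background_rpkm))
  expect_equal(signal$normalized_rpkm, signal$raw_rpkm / coef)
  expect_true(all(signal$normalized_rpkm >= 0))
  expect_identical(signal$normalized_rpkm == 0, signal$raw_rpkm == 0)
})

test_that("depth invariance: duplicating every read leaves normalization unchanged", {
  ann <- toy_annotation()
  set.seed(4)
  starts <- sort(round(runif(4000, 0, 99000)))
  iv <- data.frame(chrom = "chr1", start = starts, end = starts + 50)
  rs1 <- ReadSet("s", "PolII", iv)
  rs2 <- ReadSet("s", "PolII", rbind(iv, iv))
  s1 <- normalize_signal(rs1, ann)
  s2 <- normalize_signal(rs2, ann)
  expect_equal(s1$raw_rpkm, s2$raw_rpkm, tolerance = 1e-12)
  expect_equal(s1$normalized_rpkm, s2$normalized_rpkm, tolerance = 1e-12)
})

test_that("scaling all backgrounds by c scales normalized values by 1/c", {
  raw <- c(6, 3, 9)
  bg <- c(1, 2, 3)
  for (c_scale in c(0.5, 2, 10)) {
    coef1 <- background_coefficient(bg)
    coef2 <- background_coefficient(bg * c_scale)
    expect_identical(coef2, coef1 * c_scale)
    expect_identical(raw / coef2, (raw / coef1) / c_scale)
  }
})

test_that("uniform reads give promoter RPKM close to background RPKM", {
  ann <- toy_annotation()
  set.seed(99)
  n <- 60000
  starts <- floor(runif(n, 0, 99950))
  rs <- ReadSet("u", "PolII",
                data.frame(chrom = "chr1", start = starts,
                           end = starts + 50))
  s <- normalize_signal(rs, ann)
  expect_equal(mean(s$normalized_rpkm), 1, tolerance = 0.2)
})
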