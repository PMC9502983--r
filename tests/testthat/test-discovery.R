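# Enhancer discovery: TSS distances, summits, window quantification,
# peak-overlap annotation.

test_that("distance to nearest TSS matches exhaustive pairwise scan", {
  expect_equal(distance_to_nearest_tss(11600, 10000), 1600)
  expect_equal(distance_to_nearest_tss(10000, c(10000, 99)), 0)
  expect_error(distance_to_nearest_tss(5, numeric(0)), "empty")

  set.seed(1)
  tss <- sort(sample.int(1e6, 50))
  pos <- sample.int(1e6, 1000, replace = TRUE)
  got <- vapply(pos, distance_to_nearest_tss, numeric(1), tss = tss)
  brute <- vapply(pos, function(p) min(abs(outer(p, tss, "-"))), numeric(1))
  expect_equal(got, brute)
})

test_that("the distal filter is strict and matches a brute-force oracle", {
  genes <- gene_models("g1", "chr1", "+", 10000, 12000)
  qp <- quant_params()
  # no track: summit is the interval midpoint
  at_1500 <- genomic_intervals("chr1", 11400, 11600)   # summit 11500
  at_1501 <- genomic_intervals("chr1", 11401, 11601)   # summit 11501
  expect_equal(nrow(identify_enhancers(at_1500, genes, qp)), 0)
  expect_equal(nrow(identify_enhancers(at_1501, genes, qp)), 1)

  set.seed(2)
  gstart <- sort(sample.int(9e5, 20))
  genes <- gene_models(sprintf("g%d", 1:20), "chr1", "+", gstart, gstart + 1000)
  starts <- sample.int(950000, 200)
  peaks <- genomic_intervals("chr1", starts, starts + 800)
  got <- identify_enhancers(peaks, genes, qp)
  mid <- floor((peaks$start + peaks$end) / 2)
  keep <- vapply(mid, function(m) all(abs(m - genes$tss) > 1500), logical(1))
  expect_equal(nrow(got), sum(keep))
  expect_equal(sort(got$summit), sort(mid[keep]))
})

test_that("summits take the maximal bin midpoint with leftmost ties", {
  # no track -> midpoint fallback
  expect_equal(enhancer_summit("chr1", 100, 200), 150)
  # single maximal bin [140,150) -> 145
  v <- numeric(30); v[15] <- 9; v[10] <- 2
  expect_equal(enhancer_summit("chr1", 100, 200, tiny_track(v)), 145)
  # two equal maxima -> leftmost midpoint
  v2 <- numeric(30); v2[13] <- 5; v2[18] <- 5
  expect_equal(enhancer_summit("chr1", 100, 200, tiny_track(v2)), 125)
  # all-zero signal in the peak -> midpoint fallback
  expect_equal(enhancer_summit("chr1", 100, 200, tiny_track(numeric(30))), 150)
})

test_that("window signal is the floored RPM ratio", {
  qp <- quant_params()
  # 300 chip reads vs 100 input reads, both libraries 1e6 -> ratio 3.0
  chip <- tiny_track(rep(2, 150), library_size = 1e6)
  input <- tiny_track(rep(100 / 150, 150), library_size = 1e6)
  expect_equal(quantify_window_signal(chip, input, "chr1", 750, qp), 3.0)
  # zero chip reads -> 0
  zero <- tiny_track(numeric(150), library_size = 1e6)
  expect_equal(quantify_window_signal(zero, input, "chr1", 750, qp), 0)
  # zero input engages the floor: 3000 RPM / 0.5
  chip2 <- tiny_track(rep(20, 150), library_size = 1e6)
  expect_equal(quantify_window_signal(chip2, zero, "chr1", 750, qp), 6000)
})

test_that("window quantification matches the per-base oracle and is scale-free", {
  set.seed(3)
  qp <- quant_params()
  chip <- tiny_track(stats::rpois(2000, 3), library_size = NULL)
  input <- tiny_track(stats::rpois(2000, 2) + 1, library_size = NULL)
  summits <- sample(800:19000, 50)
  for (s in summits[1:10]) {
    expect_equal(quantify_window_signal(chip, input, "chr1", s, qp),
                 brute_window_signal(chip, input, "chr1", s, qp),
                 tolerance = 1e-9)
  }
  # scaling track values and library together changes nothing
  chip10 <- signal_track(lapply(chip$values, `*`, 10), chip$bin_size,
                         chip$library_size * 10)
  for (s in summits[1:10])
    expect_equal(quantify_window_signal(chip10, input, "chr1", s, qp),
                 quantify_window_signal(chip, input, "chr1", s, qp),
                 tolerance = 1e-12)
})

test_that("windows partitioning a chromosome conserve total read mass", {
  set.seed(4)
  tr <- tiny_track(stats::runif(1500, 0, 4))  # 15 kb
  starts <- seq(0, 14000, by = 1000)
  total <- sum(vapply(starts, function(s)
    window_reads(tr, "chr1", s, s + 1000), numeric(1)))
  expect_equal(total, sum(tr$values$chr1), tolerance = 1e-9)
})

test_that("H3K27ac overlap annotation is half-open and matches brute force", {
  qp <- quant_params()
  enh <- identify_enhancers(
    genomic_intervals("chr1", c(0, 0), c(1500, 1500)),
    gene_models("g", "chr1", "+", 900000, 901000), qp)
  enh$summit <- c(750, 750)  # windows [0,1500)
  # 1 bp overlap counts; half-open abutment does not
  a <- annotate_h3k27ac_overlap(enh[1, ], genomic_intervals("chr1", 1499, 1600),
                                genomic_intervals("chr2", 1, 2), qp)
  expect_true(a$overlaps_h3k27ac_peak)
  b <- annotate_h3k27ac_overlap(enh[1, ], genomic_intervals("chr1", 1500, 1600),
                                genomic_intervals("chr2", 1, 2), qp)
  expect_false(b$overlaps_h3k27ac_peak)

  set.seed(5)
  n <- 80
  es <- sample.int(50000, n)
  enh <- identify_enhancers(genomic_intervals("chr1", es, es + 1000),
                            gene_models("g", "chr1", "+", 900000, 901000), qp)
  ps <- sample.int(50000, 40)
  pk_u <- genomic_intervals("chr1", ps, ps + sample.int(300, 40))
  pk_s <- genomic_intervals("chr1", ps + 7, ps + 7 + sample.int(200, 40))
  got <- annotate_h3k27ac_overlap(enh, pk_u, pk_s, qp)
  pk <- rbind(as.data.frame(pk_u), as.data.frame(pk_s))
  brute <- vapply(seq_len(nrow(enh)), function(i) {
    ws <- max(enh$summit[i] - 750, 0); we <- enh$summit[i] + 750
    any(ws < pk$end & we > pk$start)
  }, logical(1))
  expect_equal(got$overlaps_h3k27ac_peak, brute)
})
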