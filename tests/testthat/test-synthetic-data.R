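# The seeded data generator: determinism, track rendering, motif planting,
# structural guarantees of the bundle.

test_that("identical seeds give byte-identical written bundles", {
  cfg <- small_sim_config(seed = 77, n = 40)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("render_track puts bump mass at the planted position", {
  set.seed(61)
  tr <- render_track(data.frame(chrom = "chr1", position = 5005,
                                amplitude = 2000),
                     sigma = 150, background_rate = 0.2, bin_size = 10,
                     chrom_lengths = c(chr1 = 20000))
  peak_bin <- which.max(tr$values$chr1)
  expect_lte(abs((peak_bin - 1) * 10 + 5 - 5005), 10)
  # library size is the realised total
  expect_equal(tr$library_size, sum(tr$values$chr1))
})

test_that("pure background has the configured Poisson mean", {
  set.seed(62)
  empty <- data.frame(chrom = character(), position = numeric(),
                      amplitude = numeric())
  tr <- render_track(empty, 150, background_rate = 2, bin_size = 10,
                     chrom_lengths = c(chr1 = 1e5))
  m <- mean(tr$values$chr1)   # 10,000 bins
  expect_lt(abs(m - 2), 4 * sqrt(2 / 1e4))
})

test_that("windowed signal is linear in bump amplitude", {
  base <- data.frame(chrom = "chr1", position = 10005, amplitude = 500)
  w <- function(a) {
    set.seed(63)  # same background realisation for both amplitudes
    tr <- render_track(transform(base, amplitude = a), 150, 0.5, 10,
                       c(chr1 = 2e4))
    window_reads(tr, "chr1", 10005 - 750, 10005 + 750)
  }
  r1 <- w(500); r2 <- w(1000)
  bg <- 150 * 0.5
  expect_equal((r2 - bg) / (r1 - bg), 2, tolerance = 0.1)
})

test_that("plant_motif writes the consensus and bounds-checks", {
  motifs <- builtin_motifs()
  s <- strrep("T", 200)
  planted <- plant_motif(s, motifs$EcR_syn, 100)
  expect_equal(substr(planted, 101, 113), "AGGTCAATGACCT")
  hits <- scan_pwm(planted, motifs$EcR_syn)
  expect_true(100 %in% hits$offset)
  # disrupting the planted window removes the hit
  disrupted <- plant_motif(planted, "GATCGATCGATCG", 100)
  expect_false(100 %in% scan_pwm(disrupted, motifs$EcR_syn)$offset)
  expect_error(plant_motif(s, motifs$EcR_syn, 195), "out of bounds")
  expect_error(plant_motif(s, motifs$EcR_syn, -1), "out of bounds")
})

test_that("motif planting rates recover the configured probability", {
  b <- default_bundle()
  gt <- b$ground_truth
  inc <- gt$category == "increasing"
  planted_rate <- mean(grepl("EcR_syn", gt$motifs_planted[inc]))
  # binomial CI around 0.6 at n = 136
  expect_lt(abs(planted_rate - 0.6), 3 * sqrt(0.6 * 0.4 / sum(inc)))
  # scanning the planted sequences finds the motif at the planted rate
  seqs <- b$enhancer_sequences[gt$name[inc]]
  hit <- vapply(seqs, function(s)
    nrow(scan_pwm(s, b$motifs$EcR_syn)) > 0, logical(1))
  expect_gte(mean(hit[grepl("EcR_syn", gt$motifs_planted[inc])]), 0.99)
})

test_that("bundle structure matches the planted design", {
  cfg <- small_sim_config(seed = 78, n = 60, make_genome = TRUE)
  b <- generate_dataset(cfg)
  gt <- b$ground_truth
  expect_equal(nrow(gt), 60)
  # planted counts follow largest-remainder apportionment of the fractions
  expect_equal(sum(gt$category == "increasing"),
               round(0.136 * 60))
  # no-response enhancers have no H3K27ac peak near their summit
  nr <- gt[gt$category == "no_response", ]
  pk <- as.data.frame(b$h3k27ac_peaks_stim)
  for (i in seq_len(nrow(nr))) {
    same <- pk[pk$chrom == nr$chrom[i], ]
    expect_false(any(same$start < nr$summit[i] + 750 &
                       same$end > nr$summit[i] - 750))
  }
  # decoy H3K4me1 peaks are TSS-proximal and must be rejected by discovery
  decoys <- b$h3k4me1_peaks[grepl("decoy", b$h3k4me1_peaks$name), ]
  expect_equal(nrow(decoys), round(0.05 * 60))
  enh <- identify_enhancers(b$h3k4me1_peaks, b$genes, quant_params(),
                            b$chip_stim)
  expect_equal(nrow(enh), 60)
  expect_false(any(grepl("decoy", enh$name)))
  # enhancer sequences are the 1.5 kb summit windows of the genome
  expect_equal(unname(nchar(b$enhancer_sequences[1])), 1500)
})

test_that("generated Ct tables invert to the planted expression folds", {
  b <- default_bundle()
  ct <- b$ct_table
  for (g in unique(ct$gene)) {
    gg <- ct[ct$gene == g, ]
    trt <- ct_measurement("t", g, "ref",
                          gg$ct_target[gg$sample == "treated"],
                          gg$ct_reference[gg$sample == "treated"])
    ctl <- ct_measurement("c", g, "ref",
                          gg$ct_target[gg$sample == "control"],
                          gg$ct_reference[gg$sample == "control"])
    est <- ddct_relative_expression(trt, ctl)$fold
    # Ct noise is 0.15 cycles/well; the ddCt of triplicate means has
    # SD ~ 0.17 cycles, i.e. ~0.17 on the log2 fold
    expect_lt(abs(log2(est) - log2(gg$true_fold[1])), 0.75)
  }
})

test_that("a saturated increasing plant is recovered wherever the quartile gate allows", {
  cfg <- small_sim_config(
    seed = 79, n = 80,
    category_fractions = c(increasing = 1, constant = 0, decreasing = 0,
                           no_response = 0, unclassified = 0))
  b <- generate_dataset(cfg)
  cl <- run_classification(b)
  e <- cl$enhancers
  # every enhancer above the stimulated bottom-quartile gate is called
  # increasing; the gate itself excludes (at most) the bottom quartile, and
  # nothing is ever called decreasing or constant
  gated <- e$signal_stim > cl$summary$quartiles$q25_stim
  expect_true(all(e$category[gated] == "increasing"))
  expect_equal(sum(e$category %in% c("decreasing", "constant")), 0)
  expect_gte(mean(e$category == "increasing"), 0.7)
})
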