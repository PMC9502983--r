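# Differential-expression calls, gene-level H3K27ac changes, and the pooled
# t machinery.

test_that("fold-change DE calls are inclusive at the boundary and involutive", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    expr_unstim = c(10, 15, 10),
                    expr_stim = c(15, 10, 12))
  rec <- classify_de_genes(tab)
  expect_equal(rec$de_class, c("up", "down", "unchanged"))
  expect_equal(rec$log2fc, log2(c(1.5, 2 / 3, 1.2)))

  # swapping conditions swaps up and down exactly
  set.seed(31)
  tab2 <- data.frame(gene_id = sprintf("g%d", 1:300),
                     expr_unstim = stats::rlnorm(300, 2, 1),
                     expr_stim = stats::rlnorm(300, 2, 1))
  fwd <- classify_de_genes(tab2)$de_class
  swapped <- tab2
  names(swapped)[2:3] <- names(tab2)[3:2]
  bwd <- classify_de_genes(swapped)$de_class
  expect_equal(bwd[fwd == "up"], rep("down", sum(fwd == "up")))
  expect_equal(bwd[fwd == "down"], rep("up", sum(fwd == "down")))
  expect_equal(bwd[fwd == "unchanged"], rep("unchanged", sum(fwd == "unchanged")))
})

test_that("gene-level H3K27ac change is the log2 ratio over the extended body", {
  genes <- gene_models("g1", "chr1", "+", 2000, 4000)
  # region [0, 4000): chip doubles between conditions at fixed library
  chip_u <- tiny_track(rep(4, 400), library_size = 1600)
  chip_s <- tiny_track(rep(8, 400), library_size = 1600)
  input <- tiny_track(rep(1, 400), library_size = 4e4)
  ch <- gene_ac_change(genes, chip_u, input, chip_s, input)
  expect_equal(ch$ac_unstim, 100)
  expect_equal(ch$ac_stim, 200)
  expect_equal(ch$log2_change, log2(200.5 / 100.5))
  # unchanged signal -> exactly 0
  same <- gene_ac_change(genes, chip_u, input, chip_u, input)
  expect_equal(same$log2_change, 0)
})

test_that("gene regions are strand-aware and match the per-base oracle", {
  set.seed(32)
  chip_u <- tiny_track(stats::rpois(1200, 3))
  chip_s <- tiny_track(stats::rpois(1200, 3))
  input <- tiny_track(stats::rpois(1200, 2) + 1)
  genes <- gene_models(c("p", "m"), "chr1", c("+", "-"),
                       c(4000, 4000), c(7000, 7000))
  ch <- gene_ac_change(genes, chip_u, input, chip_s, input)
  brute_region <- function(chip, s, e) {
    cr <- brute_window_reads(chip, "chr1", s, e) * 1e6 / chip$library_size
    ir <- brute_window_reads(input, "chr1", s, e) * 1e6 / input$library_size
    cr / max(ir, 0.5)
  }
  # + strand: [start - 2000, end); - strand: [start, end + 2000)
  expect_equal(ch$ac_unstim[1], brute_region(chip_u, 2000, 7000),
               tolerance = 1e-9)
  expect_equal(ch$ac_unstim[2], brute_region(chip_u, 4000, 9000),
               tolerance = 1e-9)
  expect_equal(ch$log2_change[1],
               log2((brute_region(chip_s, 2000, 7000) + 0.5) /
                      (brute_region(chip_u, 2000, 7000) + 0.5)),
               tolerance = 1e-9)
})

test_that("pooled t statistic matches hand computation and stats::t.test", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(round(r$t, 4), -3.6742)

  # antisymmetry is exact
  set.seed(33)
  x <- stats::rnorm(8); y <- stats::rnorm(11, 0.5)
  expect_identical(two_sample_t(x, y)$t, -two_sample_t(y, x)$t)

  # independent route: stats::t.test with pooled variance
  tt <- stats::t.test(x, y, var.equal = TRUE)
  r2 <- two_sample_t(x, y)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-12)

  # degenerate conventions
  same <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_warning(zv <- two_sample_t(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_equal(zv$p, 0)
})

test_that("the t tail probability agrees with numerical integration", {
  tdens <- function(u, df) gamma((df + 1) / 2) / (sqrt(df * pi) *
    gamma(df / 2)) * (1 + u^2 / df)^(-(df + 1) / 2)
  for (df in c(2, 4, 10)) {
    for (tval in c(0.3, 1.7, 4.2, 9.5)) {
      p_impl <- 2 * stats::pt(-tval, df)   # the tail the implementation uses
      p_num <- 2 * stats::integrate(tdens, tval, Inf, df = df,
                                    rel.tol = 1e-12)$value
      expect_equal(p_impl, p_num, tolerance = 1e-8)
    }
  }
})

test_that("coupled H3K27ac effects separate up- from down-regulated genes", {
  set.seed(34)
  ch <- data.frame(gene_id = sprintf("g%d", 1:120),
                   ac_unstim = 1, ac_stim = 1,
                   log2_change = c(stats::rnorm(50, 1, 0.4),
                                   stats::rnorm(50, -1, 0.4),
                                   stats::rnorm(20, 0, 0.4)))
  rec <- data.frame(gene_id = sprintf("g%d", 1:120),
                    expr_unstim = 1, expr_stim = 1, log2fc = 0,
                    de_class = rep(c("up", "down", "unchanged"),
                                   c(50, 50, 20)))
  cmp <- compare_ac_by_de_class(ch, rec)
  expect_gt(cmp$group_means[["up"]], 0)
  expect_lt(cmp$group_means[["down"]], 0)
  expect_true(cmp$ttest$significant)

  # all-zero changes: means 0, not significant
  ch$log2_change <- 0
  cmp0 <- compare_ac_by_de_class(ch, rec)
  expect_equal(unname(cmp0$group_means), c(0, 0, 0))
  expect_false(cmp0$ttest$significant)
  expect_error(compare_ac_by_de_class(ch[1:3, ], rec[1:3, ]), ">= 2 genes")
})
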