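# PWM scanning, consensus matching, hypergeometric enrichment.

perfect_pwm <- function(cons, id = "m", pc = 0) {
  bases <- strsplit(cons, "")[[1]]
  mat <- matrix(0, 4, length(bases), dimnames = list(c("A", "C", "G", "T")))
  for (j in seq_along(bases)) mat[bases[j], j] <- 1
  pwm(id, mat, pseudocount = pc)
}

test_that("a perfect match scores L * log2(4) bits and mismatches score -Inf", {
  p <- perfect_pwm("ACGT")
  expect_equal(pwm_max_score(p), 8)
  hits <- scan_pwm("TTACGTTT", p, score_min = 8)
  expect_equal(hits$offset[hits$strand == "+"], 2)
  expect_equal(hits$score[hits$strand == "+"], 8)
  # the reverse complement ACGT is ACGT: palindrome hits both strands
  expect_setequal(hits$strand, c("+", "-"))
  # zero-pseudocount mismatch is -Inf: no hit anywhere above any threshold
  expect_equal(nrow(scan_pwm("TTTTTTTT", p, score_min = -100)), 0)
  # threshold above the maximum attainable score: empty, not an error
  expect_equal(nrow(scan_pwm("TTACGTTT", p, score_min = 9)), 0)
})

test_that("scanning is reverse-complement symmetric", {
  set.seed(41)
  p <- builtin_motifs()$EcR_syn
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    s <- plant_motif(s, p, 37)
    h1 <- scan_pwm(s, p, score_min = 0.7 * pwm_max_score(p))
    h2 <- scan_pwm(reverse_complement(s), p,
                   score_min = 0.7 * pwm_max_score(p))
    # mirrored offsets, swapped strands, identical score multiset
    L <- ncol(p$matrix)
    expect_setequal(h2$offset, nchar(s) - L - h1$offset)
    expect_equal(sort(h1$score), sort(h2$score))
  }
})

test_that("hits equal brute-force scoring of every offset and strand", {
  set.seed(42)
  mat <- matrix(stats::rgamma(4 * 6, 1), 4, 6)
  mat <- sweep(mat, 2, colSums(mat), "/")
  p <- pwm("rand", mat, pseudocount = 0.01)
  for (i in 1:3) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 120, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    thr <- 0.3 * pwm_max_score(p)
    got <- scan_pwm(s, p, score_min = thr)
    want <- brute_scan_pwm(s, p, thr)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("IUPAC consensus matching honours degeneracy, budget and strand", {
  h <- match_ecre_consensus("TTAGGTCATT", "RGGTCA", 0)
  expect_equal(h$offset[h$strand == "+"], 2)
  expect_equal(h$mismatches[h$strand == "+"], 0)
  expect_equal(nrow(match_ecre_consensus("TTTGGTCATT", "RGGTCA", 0)), 0)
  h1 <- match_ecre_consensus("TTTGGTCATT", "RGGTCA", 1)
  expect_equal(h1$offset, 2)
  expect_equal(h1$mismatches, 1)
  expect_error(match_ecre_consensus("ACGT", "AXGT", 0), "IUPAC")
  # palindromic consensus: equal hit counts on a sequence and its rc
  set.seed(43)
  s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  pal <- "RGGTCATGACCY"   # its reverse complement is itself
  expect_equal(nrow(match_ecre_consensus(s, pal, 2)),
               nrow(match_ecre_consensus(reverse_complement(s), pal, 2)))
})

test_that("enrichment p-values are the exact hypergeometric upper tail", {
  seqs <- stats::setNames(rep("AAAA", 20), sprintf("e%02d", 1:20))
  # engineer k = 6 of n = 10 foreground, K = 8 of N = 20 with hits
  p <- perfect_pwm("ACGT", pc = 0.01)
  hit_ids <- c(sprintf("e%02d", 1:6), sprintf("e%02d", 11:12))
  seqs[hit_ids] <- "TTACGTTT"
  cats <- stats::setNames(rep(c("increasing", "other"), each = 10),
                          names(seqs))
  res <- enrich_by_category(seqs, cats, list(p), "increasing")
  expect_equal(res$k, 6); expect_equal(res$K, 8)
  expect_equal(res$p, 15686 / 184756, tolerance = 1e-12)
  expect_equal(res$fold, (6 / 10) / (8 / 20))
  # k = 0 -> upper tail includes X >= 0 -> p = 1 exactly
  seqs[] <- "AAAA"; seqs[sprintf("e%02d", 11:14)] <- "TTACGTTT"
  res0 <- enrich_by_category(seqs, cats, list(p), "increasing")
  expect_equal(res0$k, 0)
  expect_equal(res0$p, 1)
  expect_error(enrich_by_category(seqs, cats, list(), "increasing"), "empty")
})

test_that("hypergeometric p equals exact enumeration on a parameter sweep", {
  for (N in c(5, 12, 25)) {
    for (K in 0:N) {
      for (n in c(1, floor(N / 2), N)) {
        for (k in unique(c(0, 1, floor(min(n, K) / 2), min(n, K)))) {
          expect_equal(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                       exact_hyper_upper(k, K, N, n), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH adjustment preserves the p-value ordering", {
  set.seed(44)
  seqs <- stats::setNames(vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""),
    character(1)), sprintf("e%02d", 1:60))
  motifs <- builtin_motifs()
  for (i in 1:20)
    seqs[i] <- plant_motif(seqs[i], motifs$EcR_syn, 50)
  cats <- stats::setNames(rep(c("increasing", "other", "third"), each = 20),
                          names(seqs))
  res <- enrich_by_category(seqs, cats, motifs, "increasing")
  expect_equal(order(res$p), order(res$q))
  expect_true(all(res$q >= res$p))
  expect_equal(res$motif_id[1], "EcR_syn")
})

test_that("JASPAR-style motif files round-trip through write and read", {
  motifs <- builtin_motifs()
  f <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(motifs, f)
  back <- read_jaspar(f)
  expect_equal(length(back), length(motifs))
  expect_equal(back[[1]]$motif_id, motifs[[1]]$motif_id)
  expect_equal(back[[1]]$matrix, motifs[[1]]$matrix, tolerance = 1e-6)
  expect_equal(pwm_consensus(back[[2]]), pwm_consensus(motifs[[2]]))
})
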