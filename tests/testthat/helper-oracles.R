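# Independent oracles and small fixture builders used across the suite.
# Each oracle re-derives the quantity by the most naive route available
# (per-base expansion, exhaustive loops, exact combinatorics) and shares no
# code with the implementation it checks.

# Per-base brute-force read count over [start, end): expand the track to a
# per-base density vector and sum.
brute_window_reads <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) return(0)
  bs <- track$bin_size
  per_base <- rep(v / bs, each = bs)
  lo <- max(start, 0) + 1
  hi <- min(end, length(per_base))
  if (hi < lo) return(0)
  sum(per_base[lo:hi])
}

brute_window_signal <- function(chip, input_ctrl, chrom, summit, params) {
  s <- max(summit - params$window / 2, 0)
  e <- summit + params$window / 2
  c_rpm <- brute_window_reads(chip, chrom, s, e) * 1e6 / chip$library_size
  i_rpm <- brute_window_reads(input_ctrl, chrom, s, e) * 1e6 /
    input_ctrl$library_size
  c_rpm / max(i_rpm, params$input_floor)
}

# Per-base brute-force profile row (mean RPM/bp per column).
brute_profile_row <- function(track, chrom, summit, flank, profile_bin) {
  v <- track$values[[chrom]]
  bs <- track$bin_size
  per_base <- rep(v / bs, each = bs)
  pos <- (summit - flank):(summit + flank - 1)
  d <- numeric(length(pos))
  ok <- pos >= 0 & pos < length(per_base)
  d[ok] <- per_base[pos[ok] + 1]
  ncol <- 2 * flank / profile_bin
  out <- numeric(ncol)
  for (j in seq_len(ncol))
    out[j] <- mean(d[((j - 1) * profile_bin + 1):(j * profile_bin)])
  out * 1e6 / track$library_size
}

# Naive re-implementation of the classification rules: plain scalar if/else
# in the documented precedence order.
naive_classify <- function(u, s, overlaps, params, q25u, q25s, q75u, q75s) {
  out <- character(length(u))
  for (i in seq_along(u)) {
    eps <- params$signal_floor
    ratio <- s[i] / max(u[i], eps)
    if (!overlaps[i]) {
      out[i] <- "no_response"
    } else if (ratio >= params$fold_increase_min && s[i] > q25s) {
      out[i] <- "increasing"
    } else if ((1 - ratio) >= params$reduction_min && u[i] > q25u) {
      out[i] <- "decreasing"
    } else if (u[i] >= q75u && s[i] >= q75s &&
               abs(s[i] - u[i]) / max(u[i], eps) <= params$constant_max_change) {
      out[i] <- "constant"
    } else {
      out[i] <- "unclassified"
    }
  }
  out
}

# Exact hypergeometric upper tail by choose() enumeration.
exact_hyper_upper <- function(k, K, N, n) {
  if (k <= 0) return(1)
  if (k > min(n, K)) return(0)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Exhaustive PWM scan: loop over every offset and strand, summing column
# log-odds scores one base at a time.
brute_scan_pwm <- function(seq, p, score_min) {
  pc <- p$pseudocount
  probs <- (p$matrix + pc) / (1 + 4 * pc)
  smat <- log2(probs / p$background)
  L <- ncol(smat)
  score_at <- function(chars, off) {
    sc <- 0
    for (j in 1:L) {
      b <- chars[off + j]
      sc <- sc + if (b %in% rownames(smat)) smat[b, j] else 0
    }
    sc
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  rc <- strsplit(reverse_complement(seq), "")[[1]]
  m <- length(chars) - L + 1
  hits <- data.frame(offset = integer(), strand = character(),
                     score = numeric(), stringsAsFactors = FALSE)
  for (off in 0:(m - 1)) {
    sf <- score_at(chars, off)
    if (sf >= score_min)
      hits <- rbind(hits, data.frame(offset = off, strand = "+", score = sf))
    sr <- score_at(rc, off)
    if (sr >= score_min)
      hits <- rbind(hits, data.frame(offset = m - 1 - off, strand = "-",
                                     score = sr))
  }
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}

# Small track fixture: one chromosome from a bin-value vector.
tiny_track <- function(values, bin_size = 10, library_size = NULL,
                       chrom = "chr1") {
  if (is.null(library_size) && sum(values) == 0) library_size <- 1
  signal_track(stats::setNames(list(values), chrom), bin_size = bin_size,
               library_size = library_size)
}

# Reduced-size generator configuration for fast tests.
small_sim_config <- function(seed = 11, n = 200, make_genome = FALSE, ...) {
  simulation_config(seed = seed, n_chroms = 2, chrom_length = 1.6e6,
                    n_enhancers = n, locus_spacing = 13000,
                    make_genome = make_genome, ...)
}

# Memoised default-condition bundle shared by the acceptance checks.
.bundle_cache <- new.env(parent = emptyenv())
default_bundle <- function(seed = 20260926) {
  key <- sprintf("s%d", seed)
  if (is.null(.bundle_cache[[key]]))
    .bundle_cache[[key]] <- generate_dataset(simulation_config(seed = seed))
  .bundle_cache[[key]]
}

# Run discovery -> quantification -> overlap annotation -> classification on
# a generated bundle.
run_classification <- function(b, params = classification_params()) {
  enh <- identify_enhancers(b$h3k4me1_peaks, b$genes, quant_params(),
                            b$chip_stim)
  enh <- quantify_enhancers(enh, b$chip_unstim, b$input_unstim,
                            b$chip_stim, b$input_stim)
  enh <- annotate_h3k27ac_overlap(enh, b$h3k27ac_peaks_unstim,
                                  b$h3k27ac_peaks_stim)
  classify_all(enh, params)
}
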