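# Enhancer discovery and window quantification.
#
# Candidate enhancers are H3K4me1 peaks whose summit lies strictly more than
# `min_tss_distance` bp from every annotated TSS on the same chromosome. The
# per-enhancer H3K27ac signal is the input-normalised read count in a fixed
# window centred on the summit: an RPM ratio chip/input with a floor on the
# input denominator.

#' Quantification parameters
#'
#' @param window width in bp of the summit-centred quantification window
#'   (default 1500).
#' @param min_tss_distance minimum summit-to-TSS distance in bp for a peak to
#'   count as distal (default 1500; the filter is strict, `> min_tss_distance`).
#' @param input_floor minimal input density (RPM units) used as denominator
#'   floor in input normalisation (default 0.5).
#' @param bin_size track bin width in bp the windows must be compatible with
#'   (default 10).
#' @return A validated list of class `quant_params`.
#' @export
quant_params <- function(window = 1500, min_tss_distance = 1500,
                         input_floor = 0.5, bin_size = 10) {
  if (!is_number(window) || window <= 0 || window %% bin_size != 0)
    stopf("window must be positive and divisible by bin_size")
  if (!is_number(min_tss_distance) || min_tss_distance < 0)
    stopf("min_tss_distance must be >= 0")
  if (!is_number(input_floor) || input_floor <= 0)
    stopf("input_floor must be > 0")
  structure(list(window = window, min_tss_distance = min_tss_distance,
                 input_floor = input_floor, bin_size = bin_size),
            class = "quant_params")
}

#' Distance to the nearest TSS
#'
#' Strand-independent minimum of `|position - tss|` over the supplied TSS
#' positions (1-D; callers are expected to pass the TSSs of the relevant
#' chromosome).
#'
#' @param position genomic position (bp).
#' @param tss numeric vector of TSS positions.
#' @return Distance in bp.
#' @export
distance_to_nearest_tss <- function(position, tss) {
  if (!length(tss)) stopf("distance_to_nearest_tss: empty TSS list")
  min(abs(position - tss))
}

#' Locate the summit of a peak
#'
#' The summit is the midpoint of the maximum-signal bin of `track` within the
#' peak (ties resolved to the smallest coordinate); only bins whose midpoint
#' lies inside the peak are candidates. With no track, or an all-zero signal
#' in the peak, the floor of the interval midpoint is returned.
#'
#' @param start,end peak, 0-based half-open.
#' @param chrom chromosome name.
#' @param track optional [signal_track()] (typically stimulated H3K27ac).
#' @return Summit position (bp).
#' @export
enhancer_summit <- function(chrom, start, end, track = NULL) {
  fallback <- floor((start + end) / 2)
  if (is.null(track)) return(fallback)
  v <- track$values[[chrom]]
  if (is.null(v)) {
    missing_chrom_warning(chrom)
    return(fallback)
  }
  bs <- track$bin_size
  # bins whose midpoint i*bs + bs/2 lies in [start, end)
  lo <- ceiling((start - bs / 2) / bs)
  hi <- ceiling((end - bs / 2) / bs) - 1
  lo <- max(lo, 0)
  hi <- min(hi, length(v) - 1)
  if (hi < lo) return(fallback)
  vv <- v[(lo:hi) + 1]
  if (all(vv == 0)) return(fallback)
  (lo + which.max(vv) - 1) * bs + bs / 2
}

#' Identify candidate enhancers from distal H3K4me1 peaks
#'
#' Keeps exactly those peaks whose summit lies strictly more than
#' `params$min_tss_distance` bp from every TSS on the same chromosome
#' (peaks on chromosomes without any annotated gene are kept). Summits are
#' located with [enhancer_summit()] on the stimulated H3K27ac track when
#' given.
#'
#' @param h3k4me1_peaks a [genomic_intervals()] data frame of H3K4me1 peaks.
#' @param genes a [gene_models()] data frame (non-empty).
#' @param params a [quant_params()] object.
#' @param h3k27ac_stim_track optional [signal_track()] for summit calling.
#' @return A data.frame of class `c("enhancers", "data.frame")`, ordered by
#'   coordinate, with columns `chrom`, `start`, `end`, `name`, `strand`,
#'   `summit`, `tss_distance` and placeholder columns `signal_unstim`,
#'   `signal_stim`, `overlaps_h3k27ac_peak`, `category`.
#' @export
identify_enhancers <- function(h3k4me1_peaks, genes, params = quant_params(),
                               h3k27ac_stim_track = NULL) {
  validate_intervals(h3k4me1_peaks)
  if (!nrow(genes)) stopf("identify_enhancers: empty gene list")
  pk <- as.data.frame(h3k4me1_peaks)
  n <- nrow(pk)
  summit <- numeric(n)
  dist <- numeric(n)
  tss_by_chrom <- split(genes$tss, genes$chrom)
  for (i in seq_len(n)) {
    summit[i] <- enhancer_summit(pk$chrom[i], pk$start[i], pk$end[i],
                                 h3k27ac_stim_track)
    tss <- tss_by_chrom[[pk$chrom[i]]]
    dist[i] <- if (is.null(tss)) Inf else distance_to_nearest_tss(summit[i], tss)
  }
  keep <- dist > params$min_tss_distance
  out <- pk[keep, , drop = FALSE]
  out$summit <- summit[keep]
  out$tss_distance <- dist[keep]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  if (any(is.na(out$name)) || anyDuplicated(out$name))
    out$name <- sprintf("enh_%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out$signal_unstim <- rep(NA_real_, nrow(out))
  out$signal_stim <- rep(NA_real_, nrow(out))
  out$overlaps_h3k27ac_peak <- rep(NA, nrow(out))
  out$category <- rep(NA_character_, nrow(out))
  class(out) <- c("enhancers", "data.frame")
  out
}

#' Input-normalised signal in a summit-centred window
#'
#' The window is `[summit - window/2, summit + window/2)`, clipped (with a
#' warning) at the chromosome start. The signal is the ratio of
#' reads-per-million densities,
#' `chip_RPM / max(input_RPM, input_floor)`, dimensionless and non-negative.
#'
#' @param chip,input_ctrl [signal_track()] objects sharing `bin_size`.
#' @param chrom chromosome name.
#' @param summit window centre (bp).
#' @param params a [quant_params()] object.
#' @return Dimensionless input-normalised signal.
#' @export
quantify_window_signal <- function(chip, input_ctrl, chrom, summit,
                                   params = quant_params()) {
  if (chip$bin_size != input_ctrl$bin_size)
    stopf("chip and input tracks must share bin_size")
  half <- params$window / 2
  start <- summit - half
  if (start < 0) {
    warnf("window at %s:%g clipped at chromosome start", chrom, summit)
    start <- 0
  }
  end <- summit + half
  chip_rpm <- window_rpm(chip, chrom, start, end)
  input_rpm <- window_rpm(input_ctrl, chrom, start, end)
  chip_rpm / max(input_rpm, params$input_floor)
}

#' Quantify H3K27ac signal for all enhancers in both conditions
#'
#' Vectorised wrapper around [quantify_window_signal()] filling the
#' `signal_unstim` / `signal_stim` columns.
#'
#' @param enhancers output of [identify_enhancers()].
#' @param chip_unstim,input_unstim,chip_stim,input_stim [signal_track()]s.
#' @param params a [quant_params()] object.
#' @return `enhancers` with signal columns set.
#' @export
quantify_enhancers <- function(enhancers, chip_unstim, input_unstim,
                               chip_stim, input_stim,
                               params = quant_params()) {
  for (i in seq_len(nrow(enhancers))) {
    enhancers$signal_unstim[i] <- quantify_window_signal(
      chip_unstim, input_unstim, enhancers$chrom[i], enhancers$summit[i], params)
    enhancers$signal_stim[i] <- quantify_window_signal(
      chip_stim, input_stim, enhancers$chrom[i], enhancers$summit[i], params)
  }
  enhancers
}

#' Flag enhancers whose window overlaps an H3K27ac peak
#'
#' `overlaps_h3k27ac_peak` is set `TRUE` iff the summit-centred
#' quantification window shares at least 1 bp with any H3K27ac peak from
#' either condition (half-open: abutting windows do not overlap).
#'
#' @param enhancers output of [identify_enhancers()].
#' @param h3k27ac_peaks_unstim,h3k27ac_peaks_stim [genomic_intervals()] peak
#'   sets.
#' @param params a [quant_params()] object (for the window width).
#' @return `enhancers` with `overlaps_h3k27ac_peak` set.
#' @export
annotate_h3k27ac_overlap <- function(enhancers, h3k27ac_peaks_unstim,
                                     h3k27ac_peaks_stim,
                                     params = quant_params()) {
  validate_intervals(h3k27ac_peaks_unstim)
  validate_intervals(h3k27ac_peaks_stim)
  pk <- rbind(as.data.frame(h3k27ac_peaks_unstim)[, c("chrom", "start", "end")],
              as.data.frame(h3k27ac_peaks_stim)[, c("chrom", "start", "end")])
  pk_by_chrom <- split(pk[, c("start", "end")], pk$chrom)
  half <- params$window / 2
  hit <- logical(nrow(enhancers))
  for (i in seq_len(nrow(enhancers))) {
    p <- pk_by_chrom[[enhancers$chrom[i]]]
    if (is.null(p)) next
    ws <- max(enhancers$summit[i] - half, 0)
    we <- enhancers$summit[i] + half
    hit[i] <- overlaps_any(ws, we, p$start, p$end)
  }
  enhancers$overlaps_h3k27ac_peak <- hit
  enhancers
}

#' Write enhancers as BED6 plus a signal sidecar TSV
#'
#' @param enhancers enhancer data frame.
#' @param bed_path BED6 output path.
#' @param tsv_path optional sidecar path for summit/signal/category columns.
#' @return `bed_path`, invisibly.
#' @export
write_enhancers <- function(enhancers, bed_path, tsv_path = NULL) {
  iv <- genomic_intervals(enhancers$chrom, enhancers$start, enhancers$end,
                          name = enhancers$name, score = 0,
                          strand = enhancers$strand)
  write_bed(iv, bed_path)
  if (!is.null(tsv_path)) {
    x <- enhancers[order(enhancers$chrom, enhancers$start), , drop = FALSE]
    utils::write.table(as.data.frame(x), tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(bed_path)
}

#' Read an enhancer sidecar TSV written by [write_enhancers()]
#' @param path sidecar TSV path.
#' @return An enhancer data frame.
#' @export
read_enhancers <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  class(x) <- c("enhancers", "data.frame")
  x
}
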