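# Binned signal tracks.
#
# A signal track stores per-chromosome read counts in fixed-width bins
# (reads per bin, not per base) together with the library size used for
# reads-per-million scaling. It is the substrate for all window
# quantification, meta-profiles and accessibility calls.

#' Construct a binned signal track
#'
#' @param values named list mapping chromosome name to a numeric vector of
#'   non-negative read counts per bin.
#' @param bin_size bin width in bp (default 10).
#' @param library_size total read count used for RPM scaling; defaults to the
#'   sum over all bins.
#' @return An object of class `signal_track`: a list with elements
#'   `bin_size`, `values`, `library_size`.
#' @examples
#' tr <- signal_track(list(chr1 = c(5, 3, 0, 2)), bin_size = 10)
#' tr$library_size
#' @export
signal_track <- function(values, bin_size = 10, library_size = NULL) {
  if (!is.list(values) || is.null(names(values)) || !all(nzchar(names(values))))
    stopf("signal_track: 'values' must be a named list of per-chromosome vectors")
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (!is.numeric(v))
      stopf("signal_track: values for '%s' are not numeric", chrom)
    if (any(!is.finite(v)))
      stopf("signal_track: non-finite value on '%s'", chrom)
    if (any(v < 0))
      stopf("signal_track: negative value on '%s'", chrom)
    values[[chrom]] <- as.numeric(v)
  }
  if (!is_count(bin_size) || bin_size < 1)
    stopf("signal_track: bin_size must be a positive integer")
  if (is.null(library_size))
    library_size <- sum(vapply(values, sum, numeric(1)))
  if (!is_number(library_size) || library_size <= 0)
    stopf("signal_track: library_size must be > 0")
  structure(
    list(bin_size = as.numeric(bin_size), values = values,
         library_size = as.numeric(library_size)),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  nb <- vapply(x$values, length, integer(1))
  cat(sprintf("signal_track: %d chromosome(s), bin_size %g bp, library %.4g reads\n",
              length(x$values), x$bin_size, x$library_size))
  for (chrom in names(x$values))
    cat(sprintf("  %s: %d bins (%.4g reads)\n", chrom, nb[[chrom]],
                sum(x$values[[chrom]])))
  invisible(x)
}

# Warn once per missing chromosome, then treat it as all-zero signal.
missing_chrom_warning <- function(chrom) {
  warnf("chromosome '%s' absent from track; treating as zero signal", chrom)
}

#' Read count in a genomic window
#'
#' Sums track reads over `[start, end)` on `chrom`, length-weighting bins that
#' only partially overlap the window. Windows extending beyond the covered
#' extent are clipped; a chromosome absent from the track counts as zero
#' signal (with a warning).
#'
#' @param track a [signal_track()].
#' @param chrom chromosome name.
#' @param start,end window, 0-based half-open.
#' @return Read count (non-negative numeric scalar).
#' @export
window_reads <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "signal_track"))
  if (end <= start) stopf("window_reads: end must exceed start")
  v <- track$values[[chrom]]
  if (is.null(v)) {
    missing_chrom_warning(chrom)
    return(0)
  }
  bs <- track$bin_size
  start <- max(start, 0)
  end <- min(end, length(v) * bs)
  if (end <= start) return(0)
  first <- floor(start / bs)
  last <- floor((end - 1) / bs)
  idx <- seq.int(first, last)
  # bp overlap of the window with each covered bin
  ov <- pmin(end, (idx + 1) * bs) - pmax(start, idx * bs)
  sum(v[idx + 1] * ov / bs)
}

#' Reads-per-million in a genomic window
#'
#' @inheritParams window_reads
#' @return `window_reads()` scaled by `1e6 / library_size`.
#' @export
window_rpm <- function(track, chrom, start, end) {
  window_reads(track, chrom, start, end) * 1e6 / track$library_size
}

# Total covered extent (bp) of a chromosome, 0 if absent.
chrom_extent <- function(track, chrom) {
  v <- track$values[[chrom]]
  if (is.null(v)) 0 else length(v) * track$bin_size
}
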