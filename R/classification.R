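# Enhancer response classification.
#
# Each enhancer is assigned exactly one of five categories from its
# input-normalised H3K27ac signals before/after stimulation:
#
#   no_response  - quantification window overlaps no H3K27ac peak in either
#                  condition (evaluated first; such signals are background);
#   increasing   - >= `fold_increase_min`-fold gain and stimulated signal
#                  strictly above the bottom quartile of stimulated signals;
#   decreasing   - >= `reduction_min` relative loss and unstimulated signal
#                  strictly above the bottom quartile of unstimulated signals;
#   constant     - both signals at or above their top quartiles and relative
#                  change <= `constant_max_change`;
#   unclassified - none of the above (e.g. 1.2-fold changes).
#
# Quartiles are computed over peak-overlapping enhancers only. Under the
# floored ratios the increasing/decreasing/constant rule bodies are mutually
# exclusive, so the fixed evaluation order only resolves degenerate ties.

CATEGORY_LEVELS <- c("increasing", "constant", "decreasing", "no_response",
                     "unclassified")

#' Classification parameters
#'
#' @param fold_increase_min minimum stimulated/unstimulated ratio to call
#'   "increasing" (default 1.5, inclusive).
#' @param reduction_min minimum relative reduction to call "decreasing"
#'   (default 0.33, inclusive).
#' @param constant_max_change maximum relative change (vs the unstimulated
#'   signal) to call "constant" (default 0.10).
#' @param signal_floor denominator floor for the ratios (default 0.5).
#' @return A validated list of class `classification_params`.
#' @export
classification_params <- function(fold_increase_min = 1.5,
                                  reduction_min = 0.33,
                                  constant_max_change = 0.10,
                                  signal_floor = 0.5) {
  if (!is_number(fold_increase_min) || fold_increase_min <= 1)
    stopf("fold_increase_min must be > 1")
  if (!is_number(reduction_min) || reduction_min <= 0 || reduction_min >= 1)
    stopf("reduction_min must be in (0, 1)")
  if (!is_number(constant_max_change) || constant_max_change < 0 ||
      constant_max_change >= reduction_min)
    stopf("constant_max_change must satisfy 0 <= value < reduction_min")
  if (!is_number(signal_floor) || signal_floor <= 0)
    stopf("signal_floor must be > 0")
  structure(list(fold_increase_min = fold_increase_min,
                 reduction_min = reduction_min,
                 constant_max_change = constant_max_change,
                 signal_floor = signal_floor),
            class = "classification_params")
}

#' Linear-interpolation quantile
#'
#' The convention where the quantile of sorted `x` at fraction `q` is
#' `x[1 + h]` linearly interpolated with `h = (n - 1) * q`
#' (`stats::quantile` type 7).
#'
#' @param values non-empty numeric vector.
#' @param q fraction in `[0, 1]`.
#' @return The quantile value.
#' @examples
#' signal_quantile(c(1, 2, 3, 4), 0.25)  # 1.75
#' @export
signal_quantile <- function(values, q) {
  if (!length(values)) stopf("signal_quantile: empty input")
  if (anyNA(values)) stopf("signal_quantile: NA values")
  unname(stats::quantile(values, q, type = 7))
}

#' Classify a single enhancer
#'
#' Applies the category rules in fixed order (no_response, increasing,
#' decreasing, constant, unclassified). Vectorised over enhancers.
#'
#' @param signal_unstim,signal_stim input-normalised H3K27ac signals
#'   (non-negative).
#' @param overlaps_h3k27ac_peak logical; does the window overlap an H3K27ac
#'   peak in either condition?
#' @param params a [classification_params()] object.
#' @param q25_unstim,q25_stim,q75_unstim,q75_stim quartile thresholds
#'   computed over the classified population (see [classify_all()]).
#' @return Character vector of categories.
#' @export
classify_enhancer <- function(signal_unstim, signal_stim,
                              overlaps_h3k27ac_peak, params,
                              q25_unstim, q25_stim, q75_unstim, q75_stim) {
  if (any(signal_unstim < 0) || any(signal_stim < 0))
    stopf("classify_enhancer: negative signals")
  eps <- params$signal_floor
  denom <- pmax(signal_unstim, eps)
  ratio <- signal_stim / denom
  rel_change <- abs(signal_stim - signal_unstim) / denom
  n <- length(signal_unstim)
  out <- rep("unclassified", n)
  inc <- ratio >= params$fold_increase_min & signal_stim > q25_stim
  dec <- (1 - ratio) >= params$reduction_min & signal_unstim > q25_unstim
  con <- signal_unstim >= q75_unstim & signal_stim >= q75_stim &
    rel_change <= params$constant_max_change
  out[con] <- "constant"
  out[dec] <- "decreasing"
  out[inc] <- "increasing"
  out[!overlaps_h3k27ac_peak] <- "no_response"
  out
}

#' Classify all enhancers and summarise category counts
#'
#' Quartile thresholds are computed over the signals of enhancers with
#' `overlaps_h3k27ac_peak = TRUE` (the classifiable population; no-response
#' signals are definitionally background). Every enhancer receives exactly
#' one category.
#'
#' @param enhancers quantified, overlap-annotated enhancer data frame
#'   (see [quantify_enhancers()], [annotate_h3k27ac_overlap()]).
#' @param params a [classification_params()] object.
#' @return An object of class `enhancer_classification`: a list with
#'   `enhancers` (the input with `category` filled) and `summary` (list with
#'   `total`, per-category `counts` and `fractions`, and the `quartiles`
#'   used).
#' @export
classify_all <- function(enhancers, params = classification_params()) {
  if (anyNA(enhancers$signal_unstim) || anyNA(enhancers$signal_stim))
    stopf("classify_all: enhancers must be quantified first")
  if (anyNA(enhancers$overlaps_h3k27ac_peak))
    stopf("classify_all: enhancers must be overlap-annotated first")
  cls <- enhancers$overlaps_h3k27ac_peak
  if (sum(cls) < 4)
    stopf("classify_all: fewer than 4 classifiable enhancers; quartiles undefined")
  q <- list(
    q25_unstim = signal_quantile(enhancers$signal_unstim[cls], 0.25),
    q25_stim = signal_quantile(enhancers$signal_stim[cls], 0.25),
    q75_unstim = signal_quantile(enhancers$signal_unstim[cls], 0.75),
    q75_stim = signal_quantile(enhancers$signal_stim[cls], 0.75)
  )
  enhancers$category <- classify_enhancer(
    enhancers$signal_unstim, enhancers$signal_stim, cls, params,
    q$q25_unstim, q$q25_stim, q$q75_unstim, q$q75_stim)
  counts <- vapply(CATEGORY_LEVELS,
                   function(k) sum(enhancers$category == k), numeric(1))
  total <- nrow(enhancers)
  structure(
    list(enhancers = enhancers,
         summary = list(total = total, counts = as.list(counts),
                        fractions = as.list(counts / total),
                        quartiles = q),
         params = params),
    class = "enhancer_classification"
  )
}

#' @export
print.enhancer_classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Enhancer H3K27ac response classification: %d enhancers\n", s$total))
  for (k in CATEGORY_LEVELS)
    cat(sprintf("  %-13s %5d  (%.1f%%)\n", k, s$counts[[k]],
                100 * s$fractions[[k]]))
  cat(sprintf("  quartile gates: q25 %.3g/%.3g (unstim/stim), q75 %.3g/%.3g\n",
              s$quartiles$q25_unstim, s$quartiles$q25_stim,
              s$quartiles$q75_unstim, s$quartiles$q75_stim))
  invisible(x)
}

#' @export
summary.enhancer_classification <- function(object, ...) {
  object$summary
}

#' Scatter plot of enhancer signals coloured by category
#'
#' Log-log scatter of unstimulated vs stimulated input-normalised H3K27ac
#' signal, one point per enhancer.
#'
#' @param x an `enhancer_classification` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.enhancer_classification <- function(x, ...) {
  e <- x$enhancers
  cols <- c(increasing = "#d62728", constant = "#7f7f7f",
            decreasing = "#1f77b4", no_response = "#c7c7c7",
            unclassified = "#bcbd22")
  eps <- x$params$signal_floor
  graphics::plot(pmax(e$signal_unstim, eps), pmax(e$signal_stim, eps),
                 log = "xy", col = cols[e$category], pch = 16, cex = 0.5,
                 xlab = "H3K27ac signal (unstimulated)",
                 ylab = "H3K27ac signal (stimulated)", ...)
  graphics::abline(0, 1, untf = TRUE, lty = 2)
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   cex = 0.8, bty = "n")
  invisible(x)
}

#' Write a classification summary as JSON
#' @param x an `enhancer_classification` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification_summary <- function(x, path) {
  jsonlite::write_json(x$summary, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
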