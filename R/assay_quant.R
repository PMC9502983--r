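# Bench-side quantification formulas: delta-delta Ct relative expression,
# ChIP-qPCR percent input, dual-luciferase fold change and FAIRE-qPCR
# recovery ratio, with triplicate summarisation (means before differencing)
# and delta-method error propagation for the fold change.

#' Construct a qPCR Ct measurement
#'
#' @param sample sample label.
#' @param target target gene name.
#' @param reference normalisation reference gene name.
#' @param ct_target replicate cycle thresholds for the target (length >= 1,
#'   each in (0, 45)).
#' @param ct_reference replicate cycle thresholds for the reference.
#' @return Object of class `ct_measurement`.
#' @export
ct_measurement <- function(sample, target, reference, ct_target,
                           ct_reference) {
  for (ct in list(ct_target, ct_reference)) {
    if (!length(ct)) stopf("ct_measurement: need >= 1 replicate")
    if (any(ct <= 0 | ct >= 45))
      stopf("ct_measurement: Ct values must lie in (0, 45)")
  }
  structure(list(sample = sample, target = target, reference = reference,
                 ct_target = as.numeric(ct_target),
                 ct_reference = as.numeric(ct_reference)),
            class = "ct_measurement")
}

#' Delta-delta Ct relative expression
#'
#' Replicate means are taken first: `dCt = mean(ct_target) -
#' mean(ct_reference)` per sample, `ddCt = dCt_treated - dCt_control`, fold
#' change `2^(-ddCt)` (amplification efficiency 2 assumed). The standard
#' error of the fold is propagated from the replicate scatter by the delta
#' method.
#'
#' @param treated,control [ct_measurement()] objects for the same
#'   target/reference pair.
#' @return Object of class `relquant`: list with `fold`, `se`, `ddct`,
#'   `dct_treated`, `dct_control`.
#' @examples
#' tr <- ct_measurement("20E", "E75B", "RP49", c(22, 22, 22), c(20, 20, 20))
#' ct <- ct_measurement("DMSO", "E75B", "RP49", c(24, 24, 24), c(20, 20, 20))
#' ddct_relative_expression(tr, ct)$fold  # 4
#' @export
ddct_relative_expression <- function(treated, control) {
  stopifnot(inherits(treated, "ct_measurement"),
            inherits(control, "ct_measurement"))
  if (treated$target != control$target ||
      treated$reference != control$reference)
    stopf("ddct: treated and control must share target and reference genes")
  dct_t <- mean(treated$ct_target) - mean(treated$ct_reference)
  dct_c <- mean(control$ct_target) - mean(control$ct_reference)
  ddct <- dct_t - dct_c
  fold <- 2^(-ddct)
  var_mean <- function(x) if (length(x) > 1) stats::var(x) / length(x) else 0
  v <- var_mean(treated$ct_target) + var_mean(treated$ct_reference) +
    var_mean(control$ct_target) + var_mean(control$ct_reference)
  structure(list(fold = fold, se = log(2) * fold * sqrt(v), ddct = ddct,
                 dct_treated = dct_t, dct_control = dct_c),
            class = "relquant")
}

#' @export
print.relquant <- function(x, ...) {
  cat(sprintf("relative expression (ddCt): fold = %.4g (SE %.3g), ddCt = %.4g\n",
              x$fold, x$se, x$ddct))
  invisible(x)
}

#' ChIP-qPCR percent input
#'
#' `100 * input_fraction * 2^(ct_input - ct_ip)`, assuming amplification
#' efficiency 2. Vectorised over Ct values.
#'
#' @param ct_ip immunoprecipitate Ct.
#' @param ct_input input-chromatin Ct.
#' @param input_fraction fraction of chromatin used as input, in (0, 1]
#'   (e.g. 0.01 for a 1% input).
#' @return Percent of input recovered.
#' @examples
#' percent_input(20, 20, 0.01)  # 1
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction) {
  if (!is_number(input_fraction) || input_fraction <= 0 || input_fraction > 1)
    stopf("input_fraction must be in (0, 1]")
  100 * input_fraction * 2^(ct_input - ct_ip)
}

#' Dual-luciferase fold change
#'
#' Firefly/renilla ratio of the construct divided by that of the reporter
#' backbone.
#'
#' @param measure,backbone lists (or [luciferase_measurement()] objects) with
#'   elements `firefly` and `renilla` (`renilla > 0`).
#' @return Fold change over the backbone.
#' @export
luciferase_fold <- function(measure, backbone) {
  for (m in list(measure, backbone))
    if (!is_number(m$renilla) || m$renilla <= 0)
      stopf("luciferase_fold: renilla must be > 0")
  br <- backbone$firefly / backbone$renilla
  if (br == 0) stopf("luciferase_fold: backbone ratio is 0")
  (measure$firefly / measure$renilla) / br
}

#' Construct a luciferase measurement
#' @param construct construct label.
#' @param condition condition label.
#' @param firefly firefly luminescence.
#' @param renilla renilla luminescence (> 0, transfection control).
#' @return Object of class `luciferase_measurement` (a list).
#' @export
luciferase_measurement <- function(construct, condition, firefly, renilla) {
  if (!is_number(renilla) || renilla <= 0)
    stopf("luciferase_measurement: renilla must be > 0")
  structure(list(construct = construct, condition = condition,
                 firefly = as.numeric(firefly), renilla = as.numeric(renilla)),
            class = "luciferase_measurement")
}

#' FAIRE-qPCR recovery ratio
#'
#' Free-over-total DNA recovery. Either pre-linearised quantities
#' (`free_dna / total_dna`) or Ct values (`ct = TRUE`:
#' `2^(ct_total - ct_free)`, efficiency 2).
#'
#' @param free_dna free (protein-depleted) DNA quantity, or its Ct.
#' @param total_dna total DNA quantity, or its Ct.
#' @param ct interpret inputs as Ct values (default `FALSE`).
#' @return Recovery ratio.
#' @examples
#' faire_recovery_ratio(10, 100)        # 0.1
#' faire_recovery_ratio(25, 25, ct = TRUE)  # 1
#' @export
faire_recovery_ratio <- function(free_dna, total_dna, ct = FALSE) {
  if (ct) return(2^(total_dna - free_dna))
  if (any(total_dna <= 0)) stopf("faire_recovery_ratio: total DNA must be > 0")
  free_dna / total_dna
}
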