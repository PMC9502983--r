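# Gene expression dynamics and gene-level H3K27ac changes.
#
# Genes are called up-/down-regulated by a plain fold-change rule (the
# stated definition for the differential classes), gene-level H3K27ac
# signal is quantified over the gene body extended upstream of the TSS, and
# the two classes are compared with a pooled-variance Student's t test.

#' Classify differentially expressed genes by fold change
#'
#' `up` if `expr_stim / max(expr_unstim, floor) >= fold`, `down` if
#' `expr_unstim / max(expr_stim, floor) >= fold` (both inclusive), else
#' `unchanged`.
#'
#' @param table data.frame with columns `gene_id`, `expr_unstim`,
#'   `expr_stim` (abundances >= 0).
#' @param fold fold-change threshold (default 1.5).
#' @param floor abundance floor applied to denominators (default 0.01).
#' @return The table with added columns `log2fc` and `de_class`.
#' @export
classify_de_genes <- function(table, fold = 1.5, floor = 0.01) {
  need <- c("gene_id", "expr_unstim", "expr_stim")
  if (!all(need %in% names(table)))
    stopf("expression table must have columns %s", paste(need, collapse = ", "))
  if (any(table$expr_unstim < 0) || any(table$expr_stim < 0))
    stopf("abundances must be >= 0")
  u <- pmax(table$expr_unstim, floor)
  s <- pmax(table$expr_stim, floor)
  table$log2fc <- log2(s / u)
  table$de_class <- "unchanged"
  table$de_class[table$expr_stim / u >= fold] <- "up"
  table$de_class[table$expr_unstim / s >= fold] <- "down"
  table
}

#' Gene-level H3K27ac change
#'
#' Quantifies input-normalised H3K27ac signal per condition over the gene
#' region and returns the log2 change with a pseudocount. The default region
#' rule is the gene body extended `upstream` bp upstream of the TSS
#' (strand-aware); `region_rule = "promoter"` uses TSS +/- 1 kb instead.
#'
#' @param genes a [gene_models()] data frame.
#' @param chip_unstim,input_unstim,chip_stim,input_stim [signal_track()]s.
#' @param region_rule `"body_upstream"` (default) or `"promoter"`.
#' @param upstream upstream extension in bp (default 2000).
#' @param pseudocount pseudocount `c` in `log2((ac_stim + c)/(ac_unstim + c))`
#'   (default 0.5).
#' @param input_floor input RPM denominator floor (default 0.5).
#' @return data.frame with columns `gene_id`, `ac_unstim`, `ac_stim`,
#'   `log2_change`.
#' @export
gene_ac_change <- function(genes, chip_unstim, input_unstim, chip_stim,
                           input_stim, region_rule = c("body_upstream",
                                                       "promoter"),
                           upstream = 2000, pseudocount = 0.5,
                           input_floor = 0.5) {
  region_rule <- match.arg(region_rule)
  n <- nrow(genes)
  ac_u <- numeric(n); ac_s <- numeric(n)
  for (i in seq_len(n)) {
    if (region_rule == "promoter") {
      rs <- genes$tss[i] - 1000
      re <- genes$tss[i] + 1000
    } else if (genes$strand[i] == "+") {
      rs <- genes$start[i] - upstream
      re <- genes$end[i]
    } else {
      rs <- genes$start[i]
      re <- genes$end[i] + upstream
    }
    rs <- max(rs, 0)
    if (re <= rs)
      stopf("gene_ac_change: degenerate region for gene '%s'", genes$gene_id[i])
    ac_u[i] <- region_signal(chip_unstim, input_unstim, genes$chrom[i], rs, re,
                             input_floor)
    ac_s[i] <- region_signal(chip_stim, input_stim, genes$chrom[i], rs, re,
                             input_floor)
  }
  data.frame(gene_id = genes$gene_id, ac_unstim = ac_u, ac_stim = ac_s,
             log2_change = log2((ac_s + pseudocount) / (ac_u + pseudocount)),
             stringsAsFactors = FALSE)
}

# Input-normalised RPM ratio over an arbitrary region (the window
# quantification generalised away from summit-centred windows).
region_signal <- function(chip, input_ctrl, chrom, start, end, input_floor) {
  chip_rpm <- window_rpm(chip, chrom, start, end)
  input_rpm <- window_rpm(input_ctrl, chrom, start, end)
  chip_rpm / max(input_rpm, input_floor)
}

#' Pooled-variance two-sample Student's t test
#'
#' `t = (mean(x) - mean(y)) / sqrt(sp2 * (1/nx + 1/ny))` with the pooled
#' variance `sp2`, `df = nx + ny - 2`, two-sided p. Degenerate inputs follow
#' fixed conventions: zero pooled variance with equal means gives `t = 0`,
#' `p = 1`; zero pooled variance with unequal means gives `p = 0` (with a
#' warning).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param alpha significance level (default 0.05).
#' @return Object of class `t_test_result`: list with `t`, `df`, `p`,
#'   `significant`, `mean_x`, `mean_y`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))
#' @export
two_sample_t <- function(x, y, alpha = 0.05) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stopf("two_sample_t: need >= 2 observations per group")
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  dmean <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (dmean == 0) {
      t <- 0; p <- 1
    } else {
      warnf("two_sample_t: zero pooled variance with unequal means; p = 0")
      t <- sign(dmean) * Inf; p <- 0
    }
  } else {
    t <- dmean / sqrt(sp2 * (1 / nx + 1 / ny))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p = p, significant = p < alpha,
                 mean_x = mean(x), mean_y = mean(y), alpha = alpha),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("Student's t-test (pooled variance): t = %.4g, df = %d, p = %.4g%s\n",
              x$t, x$df, x$p, if (x$significant) " *" else ""))
  invisible(x)
}

#' Compare H3K27ac changes between up- and down-regulated genes
#'
#' Mean `log2_change` per differential-expression class and the up-vs-down
#' pooled t test.
#'
#' @param changes output of [gene_ac_change()].
#' @param records output of [classify_de_genes()].
#' @param alpha significance level (default 0.05).
#' @return List with `group_means` (named numeric over the classes present)
#'   and `ttest` (up vs down, a `t_test_result`).
#' @export
compare_ac_by_de_class <- function(changes, records, alpha = 0.05) {
  merged <- merge(changes, records[, c("gene_id", "de_class")], by = "gene_id")
  up <- merged$log2_change[merged$de_class == "up"]
  down <- merged$log2_change[merged$de_class == "down"]
  if (length(up) < 2 || length(down) < 2)
    stopf("compare_ac_by_de_class: need >= 2 genes in each of up/down")
  gm <- tapply(merged$log2_change, merged$de_class, mean)
  group_means <- stats::setNames(as.numeric(gm), names(gm))
  list(group_means = group_means,
       ttest = two_sample_t(up, down, alpha = alpha))
}
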