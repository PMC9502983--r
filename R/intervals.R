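# Genomic interval and gene-model containers.
#
# All coordinates in the package are BED-style: 0-based, half-open [start, end).
# GFF input (1-based, closed) is converted on read and never stored.

#' Construct a set of genomic intervals
#'
#' Builds the package's standard interval container: a `data.frame` with
#' columns `chrom`, `start`, `end`, `name`, `score`, `strand`, validated
#' against the half-open coordinate convention (`0 <= start < end`).
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector of 0-based inclusive start positions.
#' @param end integer vector of exclusive end positions.
#' @param name optional identifiers (recycled `NA` if missing).
#' @param score optional numeric scores.
#' @param strand strand symbols, each one of `"+"`, `"-"`, `"."`.
#' @return A `data.frame` of class `c("genomic_intervals", "data.frame")`.
#' @examples
#' genomic_intervals("chr1", 100, 600, name = "e1", strand = "+")
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = ".") {
  n <- length(chrom)
  out <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(out)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

validate_intervals <- function(x) {
  if (any(is.na(x$chrom) | !nzchar(x$chrom)))
    stopf("interval validation: empty chromosome name")
  if (any(!is.finite(x$start) | !is.finite(x$end)))
    stopf("interval validation: non-finite coordinates")
  if (any(x$start < 0))
    stopf("interval validation: negative start coordinate")
  bad <- which(x$start >= x$end)
  if (length(bad))
    stopf("interval validation: start >= end for %d record(s), first at row %d",
          length(bad), bad[1L])
  ok <- x$strand %in% c("+", "-", ".")
  if (!all(ok))
    stopf("interval validation: invalid strand symbol '%s'",
          x$strand[which(!ok)[1L]])
  invisible(x)
}

#' Construct gene models
#'
#' A gene model carries a strand-aware transcription start site (TSS): the TSS
#' equals `start` on the plus strand and `end - 1` on the minus strand, with
#' `[start, end)` the gene body in 0-based half-open coordinates.
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"` per gene.
#' @param start,end gene body, 0-based half-open.
#' @return A `data.frame` of class `c("gene_models", "data.frame")` with
#'   columns `gene_id`, `chrom`, `strand`, `tss`, `start`, `end`.
#' @examples
#' gene_models("g1", "chr1", "+", 1000, 2000)$tss  # 1000
#' gene_models("g2", "chr1", "-", 1000, 2000)$tss  # 1999
#' @export
gene_models <- function(gene_id, chrom, strand, start, end) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stopf("duplicate gene_id '%s'", gene_id[duplicated(gene_id)][1L])
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-")))
    stopf("unknown strand symbol '%s' (gene strands must be '+' or '-')",
          setdiff(strand, c("+", "-"))[1L])
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0) || any(start >= end))
    stopf("gene body must satisfy 0 <= start < end")
  out <- data.frame(
    gene_id = gene_id,
    chrom = as.character(chrom),
    strand = strand,
    tss = ifelse(strand == "+", start, end - 1),
    start = start,
    end = end,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_models", "data.frame")
  out
}

# 1 bp (or more) overlap between [s1,e1) and each interval in (s2,e2) vectors.
overlaps_any <- function(s1, e1, s2, e2) {
  any(s1 < e2 & e1 > s2)
}
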