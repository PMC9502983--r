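# Readers and writers for the standard plain-text formats the pipeline
# touches: BED3-6, bedGraph, GFF3/TSV gene tables, FASTA, expression TSV.
# All writers emit deterministic ordering (chromosome lexicographic, then
# start) so identical inputs give byte-identical outputs.

#' Read a BED3-BED6 file
#'
#' Coordinates are parsed as 0-based half-open; input record order is
#' preserved. Malformed lines and records with `start >= end` raise errors
#' naming the offending line.
#'
#' @param path path to a BED file.
#' @return A [genomic_intervals()] data frame (empty for an empty file).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   !startsWith(lines, "browser")]
  if (!length(lines))
    return(genomic_intervals(character(), numeric(), numeric())[0, ])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stopf("BED parse error at line %d: fewer than 3 fields", which(nf < 3)[1L])
  get_col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.numeric(get_col(2L, NA)))
  end <- suppressWarnings(as.numeric(get_col(3L, NA)))
  if (anyNA(start) || anyNA(end))
    stopf("BED parse error at line %d: non-numeric coordinate",
          which(is.na(start) | is.na(end))[1L])
  bad <- which(start >= end)
  if (length(bad))
    stopf("BED validation error at line %d: start >= end", bad[1L])
  name <- get_col(4L, NA_character_)
  score <- suppressWarnings(as.numeric(get_col(5L, NA_character_)))
  strand <- get_col(6L, ".")
  genomic_intervals(get_col(1L, NA_character_), start, end,
                    name = name, score = score, strand = strand)
}

#' Write intervals as BED
#'
#' Emits BED6 (or BED3 when no name/score/strand is set), sorted by
#' chromosome then start, so that `read_bed(write_bed(x))` reproduces the
#' records.
#'
#' @param intervals a [genomic_intervals()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  x <- intervals[order(intervals$chrom, intervals$start, intervals$end), ,
                 drop = FALSE]
  bed6 <- !(all(is.na(x$name)) && all(is.na(x$score)) && all(x$strand == "."))
  if (bed6) {
    out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end),
                   ifelse(is.na(x$name), ".", x$name),
                   ifelse(is.na(x$score), "0", format(x$score, trim = TRUE)),
                   x$strand)
  } else {
    out <- sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a bedGraph file into a binned signal track
#'
#' bedGraph values are interpreted as per-base read densities. Each record's
#' mass (`value * length`) is length-weighted into fixed bins, so rasterizing
#' conserves total mass exactly. Records must be sorted and non-overlapping
#' within each chromosome, and non-negative.
#'
#' @param path path to a bedGraph file.
#' @param bin_size bin width in bp for the resulting track (default 10).
#' @return A [signal_track()]; `library_size` is the total mass
#'   `sum(value * length)`.
#' @export
read_bedgraph <- function(path, bin_size = 10) {
  if (!file.exists(path)) stopf("bedGraph file not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = list(character = 1, numeric = 2:4))
  if (nrow(dt) == 0)
    stopf("bedGraph '%s' is empty", path)
  if (any(dt$start < 0) || any(dt$start >= dt$end))
    stopf("bedGraph validation error: start >= end or negative start")
  if (any(dt$value < 0))
    stopf("bedGraph validation error: negative value")
  values <- list()
  for (chrom in unique(dt$chrom)) {
    s <- dt$start[dt$chrom == chrom]
    e <- dt$end[dt$chrom == chrom]
    v <- dt$value[dt$chrom == chrom]
    if (is.unsorted(s, strictly = FALSE))
      stopf("bedGraph records not sorted on chromosome '%s'", chrom)
    if (any(s[-1] < e[-length(e)]))
      stopf("overlapping bedGraph records on chromosome '%s'", chrom)
    values[[chrom]] <- rasterize_records(s, e, v, bin_size)
  }
  signal_track(values, bin_size = bin_size,
               library_size = sum(dt$value * (dt$end - dt$start)))
}

# Length-weight sorted non-overlapping records into bins of 'bin_size' bp.
# Returns reads per bin. Vectorised: each record is split into a first
# partial piece, whole middle bins, and a last partial piece.
rasterize_records <- function(start, end, value, bin_size) {
  nbins <- ceiling(max(end) / bin_size)
  first <- floor(start / bin_size)
  last <- floor((end - 1) / bin_size)
  one <- first == last
  idx <- first[one]
  mass <- value[one] * (end[one] - start[one])
  multi <- which(!one)
  if (length(multi)) {
    # leading partial piece up to the first bin boundary
    idx <- c(idx, first[multi])
    mass <- c(mass, value[multi] * ((first[multi] + 1) * bin_size - start[multi]))
    # trailing partial (or full) piece from the last bin boundary
    idx <- c(idx, last[multi])
    mass <- c(mass, value[multi] * (end[multi] - last[multi] * bin_size))
    # whole bins strictly between
    nmid <- last[multi] - first[multi] - 1L
    has_mid <- which(nmid > 0)
    if (length(has_mid)) {
      rec <- multi[has_mid]
      mid_idx <- unlist(lapply(seq_along(rec), function(i)
        seq.int(first[rec[i]] + 1L, last[rec[i]] - 1L)))
      idx <- c(idx, mid_idx)
      mass <- c(mass, rep.int(value[rec] * bin_size, nmid[has_mid]))
    }
  }
  out <- numeric(nbins)
  agg <- rowsum(mass, idx)
  out[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  out
}

#' Write a signal track as bedGraph
#'
#' Emits per-base densities (reads per bin divided by bin size) over bin
#' spans, merging runs of equal values; chromosomes in lexicographic order.
#' Zero-valued runs are skipped. `read_bedgraph()` of the output reproduces
#' the track.
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  bs <- track$bin_size
  pieces <- lapply(sort(names(track$values)), function(chrom) {
    v <- track$values[[chrom]]
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- c(0, e[-length(e)])
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.table::data.table(chrom = chrom, start = s[keep] * bs,
                           end = e[keep] * bs, value = r$values[keep] / bs)
  })
  dt <- data.table::rbindlist(pieces)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3/GTF file or a TSS table
#'
#' Accepts either a tab-separated table with header columns
#' `gene_id, chrom, strand, tss` (0-based TSS; optional `start`, `end` body
#' columns) or a GFF3/GTF file, from which `gene`-typed records are taken and
#' converted from 1-based closed to 0-based half-open coordinates.
#'
#' @param path input path; format chosen by extension (`.gff`, `.gff3`,
#'   `.gtf` vs anything else) unless `format` is given.
#' @param format `"auto"`, `"gff"` or `"tsv"`.
#' @return A [gene_models()] data frame.
#' @export
read_tss_table <- function(path, format = c("auto", "gff", "tsv")) {
  if (!file.exists(path)) stopf("gene file not found: %s", path)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE)) "gff" else "tsv"
  }
  if (format == "gff") {
    g <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           quote = "", stringsAsFactors = FALSE,
                           col.names = c("seqid", "source", "type", "start",
                                         "end", "score", "strand", "phase",
                                         "attributes"))
    g <- g[g$type == "gene", , drop = FALSE]
    if (!nrow(g)) stopf("no gene records in '%s'", path)
    ids <- sub('.*(?:ID=|gene_id[= ]"?)([^;"]+)"?.*', "\\1", g$attributes)
    gene_models(ids, g$seqid, g$strand, g$start - 1, g$end)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss")
    if (!all(need %in% names(tab)))
      stopf("TSS table must have columns %s", paste(need, collapse = ", "))
    if (!all(c("start", "end") %in% names(tab))) {
      # body unknown: use a 1 bp body anchored at the TSS
      tab$start <- ifelse(tab$strand == "+", tab$tss, tab$tss)
      tab$end <- tab$start + 1
    }
    gm <- gene_models(tab$gene_id, tab$chrom, tab$strand, tab$start, tab$end)
    if (any(gm$tss != tab$tss))
      stopf("TSS table inconsistent: tss does not match strand-aware body end")
    gm
  }
}

#' Write gene models as a TSS table
#' @param genes a [gene_models()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tss_table <- function(genes, path) {
  x <- genes[order(genes$chrom, genes$tss), , drop = FALSE]
  utils::write.table(x[, c("gene_id", "chrom", "strand", "tss", "start", "end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file
#'
#' Sequences are upper-cased; characters outside the IUPAC nucleotide
#' alphabet raise an error.
#'
#' @param path path to a FASTA file.
#' @return Named character vector mapping sequence name to sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stopf("FASTA parse error: %s",
                                           conditionMessage(e)),
                 warning = function(w) stopf("FASTA parse error: %s",
                                             conditionMessage(w)))
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTRYSWKMBDHVN]", out)
  if (any(bad))
    stopf("FASTA parse error: non-IUPAC character in sequence '%s'",
          names(out)[bad][1L])
  out
}

#' Write sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a two-condition expression table
#'
#' @param path TSV with header columns `gene_id`, `expr_unstim`, `expr_stim`.
#' @return A data frame with those columns.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "expr_unstim", "expr_stim")
  if (!all(need %in% names(tab)))
    stopf("expression table must have columns %s", paste(need, collapse = ", "))
  if (any(tab$expr_unstim < 0) || any(tab$expr_stim < 0))
    stopf("expression abundances must be >= 0")
  tab[, need]
}
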