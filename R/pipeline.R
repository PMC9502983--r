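# End-to-end orchestration: identify -> quantify -> classify -> profile ->
# enrich -> gene dynamics, driven by a single (YAML or list) configuration,
# with deterministic outputs and a run report echoing every parameter.

#' Run the full enhancer-dynamics pipeline
#'
#' Executes the stages in order, writing each stage's outputs before the
#' next stage runs. Stages whose inputs are not configured (FAIRE tracks,
#' genome + motifs, expression table) are skipped with an explicit report
#' flag; failures abort with the failing stage named.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{inputs}{named paths: `h3k4me1_peaks`, `genes`, `chip_unstim`,
#'       `chip_stim`, `input_unstim`, `input_stim`, `h3k27ac_peaks_unstim`,
#'       `h3k27ac_peaks_stim`; optional `faire_unstim`, `faire_stim`,
#'       `genome`, `motifs`, `expression`.}
#'     \item{outdir}{output directory.}
#'     \item{quant}{arguments for [quant_params()].}
#'     \item{classification}{arguments for [classification_params()].}
#'     \item{accessibility}{`flank`, `profile_bin`, `faire_increase_fold`.}
#'     \item{motif}{`score_min` (bits; `NULL` for per-motif default).}
#'     \item{gene}{`de_fold`, `upstream`, `pseudocount`, `region_rule`.}
#'   }
#' @return An object of class `run_report`: stage status, output paths and
#'   checksums, the category summary, per-category accessibility fractions,
#'   top enrichment hits and a full parameter echo.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inp <- config$inputs
  need <- c("h3k4me1_peaks", "genes", "chip_unstim", "chip_stim",
            "input_unstim", "input_stim", "h3k27ac_peaks_unstim",
            "h3k27ac_peaks_stim")
  missing <- setdiff(need, names(inp))
  if (length(missing))
    stopf("pipeline config missing required inputs: %s",
          paste(missing, collapse = ", "))
  for (f in unlist(inp))
    if (!file.exists(f)) stopf("pipeline input does not exist: %s", f)
  outdir <- config$outdir
  if (is.null(outdir)) stopf("pipeline config needs 'outdir'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  qp <- do.call(quant_params, config$quant %||% list())
  cp <- do.call(classification_params, config$classification %||% list())
  acc <- config$accessibility %||% list()
  flank <- acc$flank %||% 3000
  profile_bin <- acc$profile_bin %||% 50
  faire_fold <- acc$faire_increase_fold %||% 1.2
  gene_cfg <- config$gene %||% list()

  report <- list(stages = list(), parameters = list(
    quant = unclass(qp), classification = unclass(cp),
    accessibility = list(flank = flank, profile_bin = profile_bin,
                         faire_increase_fold = faire_fold),
    motif = config$motif %||% list(), gene = gene_cfg),
    version = as.character(utils::packageVersion("enhancerdyn")))

  stage <- function(name, code) {
    res <- tryCatch(code, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    outs <- unlist(res$outputs)
    report$stages[[name]] <<- list(
      status = "completed", outputs = as.list(outs),
      checksums = as.list(tools::md5sum(outs)))
    res
  }
  skip <- function(name, why) {
    report$stages[[name]] <<- list(status = "skipped", reason = why)
    NULL
  }

  # identify + quantify --------------------------------------------------
  id <- stage("identify", {
    peaks <- read_bed(inp$h3k4me1_peaks)
    genes <- read_tss_table(inp$genes)
    chip_s <- read_bedgraph(inp$chip_stim, qp$bin_size)
    enh <- identify_enhancers(peaks, genes, qp, chip_s)
    chip_u <- read_bedgraph(inp$chip_unstim, qp$bin_size)
    in_u <- read_bedgraph(inp$input_unstim, qp$bin_size)
    in_s <- read_bedgraph(inp$input_stim, qp$bin_size)
    enh <- quantify_enhancers(enh, chip_u, in_u, chip_s, in_s, qp)
    enh <- annotate_h3k27ac_overlap(enh,
                                    read_bed(inp$h3k27ac_peaks_unstim),
                                    read_bed(inp$h3k27ac_peaks_stim), qp)
    bed <- file.path(outdir, "enhancers.bed")
    tsv <- file.path(outdir, "enhancers.tsv")
    write_enhancers(enh, bed, tsv)
    list(enh = enh, genes = genes, chip_u = chip_u, chip_s = chip_s,
         in_u = in_u, in_s = in_s, outputs = c(bed, tsv))
  })

  # classify --------------------------------------------------------------
  cls <- stage("classify", {
    cl <- classify_all(id$enh, cp)
    tsv <- file.path(outdir, "categories.tsv")
    utils::write.table(as.data.frame(cl$enhancers), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    js <- file.path(outdir, "summary.json")
    write_classification_summary(cl, js)
    list(cl = cl, outputs = c(tsv, js))
  })
  categories <- stats::setNames(cls$cl$enhancers$category,
                                cls$cl$enhancers$name)
  report$category_summary <- cls$cl$summary

  # accessibility ---------------------------------------------------------
  if (!is.null(inp$faire_unstim) && !is.null(inp$faire_stim)) {
    prof <- stage("profile", {
      fu <- read_bedgraph(inp$faire_unstim, qp$bin_size)
      fs <- read_bedgraph(inp$faire_stim, qp$bin_size)
      enh <- cls$cl$enhancers
      keep <- enh$category %in% c("increasing", "constant", "decreasing")
      mu <- profile_matrix(fu, enh[keep, ], flank, profile_bin, "unstim")
      ms <- profile_matrix(fs, enh[keep, ], flank, profile_bin, "stim")
      prof_cats <- categories[enh$name[keep]]
      agg <- list(unstim = aggregate_profile(mu, prof_cats),
                  stim = aggregate_profile(ms, prof_cats))
      ptsv <- file.path(outdir, "profiles.tsv")
      write_profiles(agg, ptsv)
      ch <- accessibility_change(fu, fs, enh, qp$window, faire_fold)
      atsv <- file.path(outdir, "accessibility.tsv")
      utils::write.table(ch, atsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      fr <- vapply(c("increasing", "constant", "decreasing"), function(k)
        if (any(categories == k)) fraction_increased(ch, categories, k)
        else NA_real_, numeric(1))
      list(profiles = agg, changes = ch, fraction_increased = fr,
           outputs = c(ptsv, atsv))
    })
    report$fraction_increased <- as.list(prof$fraction_increased)
  } else {
    skip("profile", "FAIRE tracks not configured")
  }

  # motif enrichment -------------------------------------------------------
  if (!is.null(inp$genome) && !is.null(inp$motifs)) {
    enr <- stage("enrich", {
      genome <- read_fasta(inp$genome)
      motifs <- read_jaspar(inp$motifs)
      enh <- cls$cl$enhancers
      half <- qp$window / 2
      seqs <- stats::setNames(substring(genome[enh$chrom],
                                        pmax(enh$summit - half + 1, 1),
                                        enh$summit + half), enh$name)
      score_min <- config$motif$score_min %||% NULL
      outs <- character(0)
      top <- list()
      for (k in c("increasing", "decreasing", "constant")) {
        if (!any(categories == k)) next
        res <- enrich_by_category(seqs, categories, motifs, k, score_min)
        f <- file.path(outdir, sprintf("enrichment_%s.tsv", k))
        utils::write.table(res, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outs <- c(outs, f)
        top[[k]] <- res$motif_id[1]
      }
      list(top = top, outputs = outs)
    })
    report$top_motifs <- enr$top
  } else {
    skip("enrich", "genome FASTA and/or motif file not configured")
  }

  # gene dynamics ----------------------------------------------------------
  if (!is.null(inp$expression)) {
    gd <- stage("gene_dynamics", {
      expr <- read_expression_table(inp$expression)
      rec <- classify_de_genes(expr, fold = gene_cfg$de_fold %||% 1.5)
      ch <- gene_ac_change(id$genes, id$chip_u, id$in_u, id$chip_s, id$in_s,
                           region_rule = gene_cfg$region_rule %||%
                             "body_upstream",
                           upstream = gene_cfg$upstream %||% 2000,
                           pseudocount = gene_cfg$pseudocount %||% 0.5)
      cmp <- compare_ac_by_de_class(ch, rec)
      tsv <- file.path(outdir, "gene_changes.tsv")
      utils::write.table(merge(ch, rec, by = "gene_id"), tsv, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(records = rec, changes = ch, comparison = cmp, outputs = tsv)
    })
    report$gene_dynamics <- list(
      group_means = as.list(gd$comparison$group_means),
      t = gd$comparison$ttest$t, p = gd$comparison$ttest$p)
  } else {
    skip("gene_dynamics", "expression table not configured")
  }

  json <- file.path(outdir, "report.json")
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("enhancerdyn run report\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-14s %s%s\n", nm, st$status,
                if (st$status == "skipped") paste0(" (", st$reason, ")")
                else ""))
  }
  if (!is.null(x$category_summary)) {
    s <- x$category_summary
    cat(sprintf("  enhancers: %d (%s)\n", s$total,
                paste(sprintf("%s %.1f%%", names(s$fractions),
                              100 * unlist(s$fractions)), collapse = ", ")))
  }
  invisible(x)
}
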