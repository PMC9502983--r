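# Seeded synthetic-data generator.
#
# Produces a complete toy dataset with the statistical structure the
# analysis assumes: a random genome laid out as regularly spaced gene/
# enhancer loci, planted enhancer response categories at chosen fractions,
# Gaussian-bump coverage tracks over Poisson background for H3K27ac (both
# conditions), matched inputs and FAIRE, accessibility gains coupled to a
# configured fraction of increasing enhancers, motifs planted by category,
# expression responses of the locus gene, and qPCR/luciferase tables
# generated from the planted fold changes through the inverse of the bench
# formulas. A ground-truth table makes every planting auditable.
#
# Signal realism is deliberately minimal (bumps + Poisson background, no
# read-level artefacts); the generator's job is statistical structure.

#' Simulation configuration
#'
#' Defaults describe a well-separated hormone-response experiment:
#' 1,000 enhancers with 13.6% increasing / 8.2% decreasing (the proportions
#' a genome-scale experiment of this kind reports), 55% accessibility
#' coupling among increasing enhancers, and fold models that clear the
#' classification thresholds by a wide margin relative to the Poisson
#' counting noise.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical bundles.
#' @param n_chroms,chrom_length genome shape (default 4 x 5 Mb).
#' @param n_enhancers number of enhancer loci (default 1000); one gene per
#'   locus.
#' @param category_fractions named fractions over
#'   increasing/constant/decreasing/no_response/unclassified, summing to 1.
#'   Planted counts use largest-remainder rounding, so configured fractions
#'   are met exactly up to integer resolution.
#' @param signal_meanlog,signal_sdlog log-normal location (per category) and
#'   scale for the unstimulated signal, in dimensionless signal units.
#' @param fold_ranges per-category fold ranges (uniform draws); unclassified
#'   folds are drawn from the two-sided range `c(0.75, 0.88)` /
#'   `c(1.15, 1.33)` so no classification rule can fire.
#' @param reads_per_signal_unit ChIP bump amplitude (reads) per signal unit
#'   (default 100).
#' @param peak_sigma Gaussian bump standard deviation in bp (default 150).
#' @param background_rate ChIP Poisson background, reads per bin
#'   (default 1.5).
#' @param input_rate input-track Poisson rate, reads per bin (default 5).
#' @param faire_background,faire_amp,faire_fold,faire_coupling FAIRE track
#'   model: Poisson background per bin, bump amplitude in reads, fold gain
#'   at coupled enhancers, and the fraction of increasing enhancers given
#'   the gain (default 0.55, planted as an exact count).
#' @param motif_rates named list: category -> named vector of per-motif
#'   planting probabilities (motif names refer to [builtin_motifs()]).
#' @param baseline_motif_rate planting probability for every motif in
#'   categories not listed in `motif_rates` (default 0.05).
#' @param expr_meanlog,expr_sdlog log-normal model of unstimulated gene
#'   expression.
#' @param expr_up_fold,expr_down_fold expression fold change of genes whose
#'   locus enhancer is increasing/decreasing (defaults 2.0 / 0.5).
#' @param expr_noise_sdlog log-scale expression noise (default 0.1).
#' @param gene_ac_base,gene_ac_sigma gene-body H3K27ac bump amplitude
#'   (reads) and width (bp); the bump fold follows the expression coupling.
#' @param decoy_fraction fraction (of `n_enhancers`) of extra TSS-proximal
#'   decoy H3K4me1 peaks that enhancer discovery must reject (default 0.05).
#' @param ct_sd Gaussian Ct noise standard deviation for qPCR tables
#'   (default 0.15 cycles).
#' @param bin_size track bin width in bp (default 10).
#' @param locus_spacing distance between consecutive gene loci (default
#'   20 kb).
#' @param make_genome generate sequence and plant motifs (default `TRUE`).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_chroms = 4, chrom_length = 5e6,
                              n_enhancers = 1000,
                              category_fractions = c(increasing = 0.136,
                                                     constant = 0.10,
                                                     decreasing = 0.082,
                                                     no_response = 0.10,
                                                     unclassified = 0.582),
                              signal_meanlog = c(increasing = 1.6,
                                                 constant = 3.0,
                                                 decreasing = 1.8,
                                                 no_response = 1.1,
                                                 unclassified = 1.1),
                              signal_sdlog = 0.3,
                              fold_ranges = list(increasing = c(2.2, 5.0),
                                                 constant = c(0.98, 1.02),
                                                 decreasing = c(0.2, 0.4),
                                                 no_response = c(1, 1),
                                                 unclassified = c(0.75, 0.88,
                                                                  1.15, 1.33)),
                              reads_per_signal_unit = 100,
                              peak_sigma = 150,
                              background_rate = 1.5,
                              input_rate = 5,
                              faire_background = 1.0,
                              faire_amp = 300,
                              faire_fold = 2.0,
                              faire_coupling = 0.55,
                              motif_rates = list(
                                increasing = c(EcR_syn = 0.6),
                                decreasing = c(Eip74_syn = 0.6)),
                              baseline_motif_rate = 0.05,
                              expr_meanlog = 3, expr_sdlog = 0.6,
                              expr_up_fold = 2.0, expr_down_fold = 0.5,
                              expr_noise_sdlog = 0.1,
                              gene_ac_base = 400, gene_ac_sigma = 400,
                              decoy_fraction = 0.05,
                              ct_sd = 0.15,
                              bin_size = 10,
                              locus_spacing = 20000,
                              make_genome = TRUE) {
  cfg <- as.list(environment())
  if (abs(sum(category_fractions) - 1) > 1e-9)
    stopf("category_fractions must sum to 1")
  if (!all(CATEGORY_LEVELS %in% names(category_fractions)))
    stopf("category_fractions must name all of: %s",
          paste(CATEGORY_LEVELS, collapse = ", "))
  if (any(category_fractions < 0)) stopf("category fractions must be >= 0")
  if (locus_spacing %% bin_size != 0 || locus_spacing < 13000)
    stopf("locus_spacing must be a multiple of bin_size and >= 13000 bp")
  cap <- loci_capacity(chrom_length, locus_spacing)
  if (cap * n_chroms < n_enhancers)
    stopf("genome too small for %d enhancer loci (capacity %d)",
          n_enhancers, cap * n_chroms)
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("simulation_config: %d enhancers on %d x %.2g bp ",
                     "chromosomes (seed %d)\n"),
              x$n_enhancers, x$n_chroms, x$chrom_length, x$seed))
  fr <- x$category_fractions
  cat("  planted fractions:",
      paste(sprintf("%s %.1f%%", names(fr), 100 * fr), collapse = ", "), "\n")
  invisible(x)
}

# Loci per chromosome: first TSS at 10 kb, each locus needs its enhancer
# summit (TSS + 5005) plus a 3 kb profile flank inside the chromosome.
loci_capacity <- function(chrom_length, locus_spacing) {
  if (chrom_length <= 18010) return(0L)
  floor((chrom_length - 18010) / locus_spacing) + 1L
}

# Largest-remainder integer apportionment of n among fractions.
apportion <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

#' Render a coverage track from positioned elements
#'
#' Each element contributes a Gaussian-shaped read-density bump
#' (`amplitude` total reads, standard deviation `sigma` bp, discretised by
#' bin via the normal CDF) on top of a Poisson background drawn per bin.
#'
#' @param elements data.frame with columns `chrom`, `position`, `amplitude`
#'   (amplitudes >= 0); may have zero rows.
#' @param sigma bump standard deviation in bp.
#' @param background_rate Poisson rate per bin.
#' @param bin_size bin width in bp.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param library_target optional total read count to rescale the track to;
#'   by default `library_size` is the realised total.
#' @return A [signal_track()].
#' @export
render_track <- function(elements, sigma, background_rate, bin_size,
                         chrom_lengths, library_target = NULL) {
  if (nrow(elements) && any(elements$amplitude < 0))
    stopf("render_track: amplitudes must be >= 0")
  values <- lapply(chrom_lengths, function(len) {
    nb <- ceiling(len / bin_size)
    if (background_rate > 0) as.numeric(stats::rpois(nb, background_rate))
    else numeric(nb)
  })
  names(values) <- names(chrom_lengths)
  for (i in seq_len(nrow(elements))) {
    chrom <- elements$chrom[i]
    v <- values[[chrom]]
    mu <- elements$position[i]
    # truncate at +/- 5 sigma with bin edges placed symmetrically around mu,
    # so a bump centred on a bin midpoint discretises to an exact mirror
    lo <- max(floor((mu - 5 * sigma) / bin_size), 0)
    hi <- min(ceiling((mu + 5 * sigma) / bin_size) - 1, length(v) - 1)
    if (hi < lo) next
    edges <- seq.int(lo, hi + 1) * bin_size
    mass <- diff(stats::pnorm(edges, mean = mu, sd = sigma))
    values[[chrom]][(lo:hi) + 1] <- v[(lo:hi) + 1] + elements$amplitude[i] * mass
  }
  tr <- signal_track(values, bin_size = bin_size)
  if (!is.null(library_target)) {
    scale <- library_target / tr$library_size
    tr$values <- lapply(tr$values, function(v) v * scale)
    tr$library_size <- library_target
  }
  tr
}

#' Plant a motif into a sequence
#'
#' Writes the motif's consensus letters at the given 0-based position,
#' leaving the rest of the sequence unchanged.
#'
#' @param seq nucleotide string.
#' @param motif a [pwm()] (its consensus is planted) or a character string.
#' @param position 0-based position of the first planted base.
#' @return The modified sequence.
#' @export
plant_motif <- function(seq, motif, position) {
  cons <- if (inherits(motif, "pwm")) pwm_consensus(motif) else toupper(motif)
  if (position < 0 || position + nchar(cons) > nchar(seq))
    stopf("plant_motif: position out of bounds")
  substr(seq, position + 1, position + nchar(cons)) <- cons
  seq
}

#' Generate a complete synthetic dataset
#'
#' Builds the in-memory bundle (tracks, peaks, genes, sequences, tables,
#' ground truth) and, when `outdir` is given, writes it in the standard
#' plain-text formats (FASTA, GFF3 + TSV, BED, bedGraph, TSV, JASPAR).
#' Identical seeds give byte-identical bundles.
#'
#' @param config a [simulation_config()].
#' @param outdir optional output directory (created if missing).
#' @return Invisibly, a list with elements `genes`, `h3k4me1_peaks`,
#'   `h3k27ac_peaks_unstim`, `h3k27ac_peaks_stim`, `chip_unstim`,
#'   `chip_stim`, `input_unstim`, `input_stim`, `faire_unstim`,
#'   `faire_stim`, `expression`, `ground_truth`, `motifs`,
#'   `enhancer_sequences`, `genome` (if generated), `ct_table`,
#'   `luciferase`, `faire_qpcr`, and `paths` (if written).
#' @export
generate_dataset <- function(config = simulation_config(), outdir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  bundle <- with_seed(config$seed, build_bundle(config))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    bundle$paths <- write_bundle(bundle, config, outdir)
  }
  invisible(bundle)
}

build_bundle <- function(cfg) {
  bs <- cfg$bin_size
  chrom_lengths <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                   sprintf("chr%d", seq_len(cfg$n_chroms)))
  cap <- loci_capacity(cfg$chrom_length, cfg$locus_spacing)

  # --- locus layout: one gene + one enhancer per locus -------------------
  n <- cfg$n_enhancers
  locus <- seq_len(n) - 1L
  chrom <- names(chrom_lengths)[locus %/% cap + 1L]
  tss <- 10000 + (locus %% cap) * cfg$locus_spacing
  strand <- ifelse(locus %% 2L == 0L, "+", "-")
  gene_id <- sprintf("gene_%05d", seq_len(n))
  genes <- gene_models(gene_id, chrom, strand,
                       ifelse(strand == "+", tss, tss - 1999),
                       ifelse(strand == "+", tss + 2000, tss + 1))
  # summits sit at track-bin midpoints so bump discretisation is symmetric
  summit <- tss + 5005
  enh_name <- sprintf("enh_%05d", seq_len(n))

  # --- planted categories, signals and folds -----------------------------
  counts <- apportion(cfg$category_fractions[CATEGORY_LEVELS], n)
  category <- sample(rep(CATEGORY_LEVELS, counts))
  signal_u <- stats::rlnorm(n, cfg$signal_meanlog[category], cfg$signal_sdlog)
  fold <- numeric(n)
  for (k in CATEGORY_LEVELS) {
    sel <- category == k
    if (!any(sel)) next
    r <- cfg$fold_ranges[[k]]
    if (k == "unclassified") {
      side <- sample(c(TRUE, FALSE), sum(sel), replace = TRUE)
      fold[sel] <- ifelse(side, stats::runif(sum(sel), r[3], r[4]),
                          stats::runif(sum(sel), r[1], r[2]))
    } else {
      fold[sel] <- stats::runif(sum(sel), r[1], r[2])
    }
  }
  classifiable <- category != "no_response"

  # --- peaks -------------------------------------------------------------
  n_decoy <- round(cfg$decoy_fraction * n)
  decoy_locus <- if (n_decoy > 0) sort(sample.int(n, n_decoy)) else integer(0)
  h3k4me1 <- genomic_intervals(
    c(chrom, chrom[decoy_locus]),
    c(summit - 400, tss[decoy_locus] + 100),
    c(summit + 400, tss[decoy_locus] + 900),
    name = c(enh_name, sprintf("decoy_%04d", seq_along(decoy_locus))))
  ac_peaks <- genomic_intervals(chrom[classifiable],
                                summit[classifiable] - 500,
                                summit[classifiable] + 500,
                                name = enh_name[classifiable])

  # --- expression coupling ----------------------------------------------
  noise <- function(m) exp(stats::rnorm(m, 0, cfg$expr_noise_sdlog))
  expr_fold <- noise(n)
  expr_fold[category == "increasing"] <-
    cfg$expr_up_fold * noise(sum(category == "increasing"))
  expr_fold[category == "decreasing"] <-
    cfg$expr_down_fold * noise(sum(category == "decreasing"))
  expr_u <- stats::rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
  expression <- data.frame(gene_id = gene_id, expr_unstim = expr_u,
                           expr_stim = expr_u * expr_fold,
                           stringsAsFactors = FALSE)

  # --- ChIP, input and FAIRE tracks --------------------------------------
  scale <- cfg$reads_per_signal_unit
  gene_center <- floor((genes$start + genes$end) / 2 / bs) * bs + bs / 2
  gene_amp_u <- cfg$gene_ac_base * exp(stats::rnorm(n, 0, 0.05))
  gene_ac_fold <- rep(1, n)
  gene_ac_fold[category == "increasing"] <- cfg$expr_up_fold
  gene_ac_fold[category == "decreasing"] <- cfg$expr_down_fold

  enh_el <- function(amp) data.frame(chrom = chrom[classifiable],
                                     position = summit[classifiable],
                                     amplitude = amp[classifiable])
  gene_el <- function(amp) data.frame(chrom = chrom, position = gene_center,
                                      amplitude = amp)
  chip_u <- render_two_sigma(
    enh_el(signal_u * scale), cfg$peak_sigma,
    gene_el(gene_amp_u), cfg$gene_ac_sigma,
    cfg$background_rate, bs, chrom_lengths)
  chip_s <- render_two_sigma(
    enh_el(signal_u * fold * scale), cfg$peak_sigma,
    gene_el(gene_amp_u * gene_ac_fold), cfg$gene_ac_sigma,
    cfg$background_rate, bs, chrom_lengths)
  empty <- data.frame(chrom = character(), position = numeric(),
                      amplitude = numeric())
  input_u <- render_track(empty, cfg$peak_sigma, cfg$input_rate, bs,
                          chrom_lengths)
  input_s <- render_track(empty, cfg$peak_sigma, cfg$input_rate, bs,
                          chrom_lengths)

  inc_idx <- which(category == "increasing")
  n_coupled <- round(cfg$faire_coupling * length(inc_idx))
  coupled <- rep(FALSE, n)
  if (n_coupled > 0)
    coupled[sample(inc_idx, n_coupled)] <- TRUE
  faire_amp_u <- rep(cfg$faire_amp, n)
  faire_amp_s <- ifelse(coupled, cfg$faire_amp * cfg$faire_fold, cfg$faire_amp)
  faire_u <- render_track(data.frame(chrom = chrom, position = summit,
                                     amplitude = faire_amp_u),
                          cfg$peak_sigma, cfg$faire_background, bs,
                          chrom_lengths)
  faire_s <- render_track(data.frame(chrom = chrom, position = summit,
                                     amplitude = faire_amp_s),
                          cfg$peak_sigma, cfg$faire_background, bs,
                          chrom_lengths)

  # --- genome sequence and motif planting --------------------------------
  motifs <- builtin_motifs()
  planted <- matrix(FALSE, n, length(motifs),
                    dimnames = list(enh_name, names(motifs)))
  genome <- NULL
  enh_seqs <- NULL
  if (cfg$make_genome) {
    bases <- charToRaw("ACGT")
    raw_genome <- lapply(chrom_lengths, function(len)
      bases[sample.int(4L, len, replace = TRUE)])
    for (j in seq_along(motifs)) {
      mname <- names(motifs)[j]
      cons <- pwm_consensus(motifs[[j]])
      rate <- vapply(category, function(k) {
        r <- cfg$motif_rates[[k]]
        if (!is.null(r) && mname %in% names(r)) r[[mname]]
        else cfg$baseline_motif_rate
      }, numeric(1))
      hit <- stats::runif(n) < rate
      offs <- round(stats::runif(n, -600, 600 - nchar(cons)))
      planted[, j] <- hit
      for (i in which(hit)) {
        pos <- summit[i] + offs[i]
        raw_genome[[chrom[i]]][(pos + 1):(pos + nchar(cons))] <-
          charToRaw(cons)
      }
    }
    genome <- vapply(raw_genome, rawToChar, character(1))
    enh_seqs <- stats::setNames(substring(genome[chrom], summit - 749,
                                          summit + 750), enh_name)
  }

  # --- qPCR / luciferase tables from planted folds -----------------------
  up_genes <- which(category == "increasing")
  up_genes <- up_genes[seq_len(min(3, length(up_genes)))]
  down_genes <- which(category == "decreasing")
  down_genes <- down_genes[seq_len(min(3, length(down_genes)))]
  qpcr_idx <- c(up_genes, down_genes)
  ct_rows <- lapply(qpcr_idx, function(i) {
    f <- expr_fold[i]
    data.frame(
      gene = gene_id[i], reference = "ref_gene",
      sample = rep(c("control", "treated"), each = 3),
      replicate = rep(1:3, 2),
      ct_target = c(24 + stats::rnorm(3, 0, cfg$ct_sd),
                    24 - log2(f) + stats::rnorm(3, 0, cfg$ct_sd)),
      ct_reference = 20 + stats::rnorm(6, 0, cfg$ct_sd),
      true_fold = f, stringsAsFactors = FALSE)
  })
  ct_table <- do.call(rbind, ct_rows)
  luc_folds <- c(backbone = 1, enh_a = 8, enh_b = 10, enh_c = 3)
  luciferase <- data.frame(
    construct = names(luc_folds), condition = "stimulated",
    firefly = 0.5 * luc_folds * 1000 * exp(stats::rnorm(4, 0, 0.05)),
    renilla = 1000 * exp(stats::rnorm(4, 0, 0.05)),
    true_fold = as.numeric(luc_folds), stringsAsFactors = FALSE)
  faire_qpcr <- data.frame(
    region = c("enh_a", "enh_a", "ctrl", "ctrl"),
    condition = rep(c("unstim", "stim"), 2),
    ct_free = c(26, 25, 27, 27) + stats::rnorm(4, 0, cfg$ct_sd),
    ct_total = 24 + stats::rnorm(4, 0, cfg$ct_sd),
    stringsAsFactors = FALSE)

  ground_truth <- data.frame(
    name = enh_name, chrom = chrom, summit = summit, category = category,
    signal_unstim_true = signal_u, fold_true = fold,
    faire_coupled = coupled, gene_id = gene_id, expr_fold_true = expr_fold,
    motifs_planted = apply(planted, 1, function(z)
      paste(colnames(planted)[z], collapse = ",")),
    stringsAsFactors = FALSE)

  list(genes = genes, h3k4me1_peaks = h3k4me1,
       h3k27ac_peaks_unstim = ac_peaks, h3k27ac_peaks_stim = ac_peaks,
       chip_unstim = chip_u, chip_stim = chip_s,
       input_unstim = input_u, input_stim = input_s,
       faire_unstim = faire_u, faire_stim = faire_s,
       expression = expression, ground_truth = ground_truth,
       motifs = motifs, enhancer_sequences = enh_seqs, genome = genome,
       ct_table = ct_table, luciferase = luciferase,
       faire_qpcr = faire_qpcr, chrom_lengths = chrom_lengths)
}

# Two element sets with different bump widths over one shared background.
render_two_sigma <- function(el1, sigma1, el2, sigma2, background_rate,
                             bin_size, chrom_lengths) {
  t1 <- render_track(el1, sigma1, background_rate, bin_size, chrom_lengths)
  t2 <- render_track(el2, sigma2, 0, bin_size, chrom_lengths)
  values <- stats::setNames(lapply(names(chrom_lengths), function(ch)
    t1$values[[ch]] + t2$values[[ch]]), names(chrom_lengths))
  signal_track(values, bin_size = bin_size)
}

write_bundle <- function(bundle, cfg, outdir) {
  p <- function(f) file.path(outdir, f)
  paths <- list(
    genes_gff = p("genes.gff3"), genes_tsv = p("genes.tsv"),
    h3k4me1_peaks = p("h3k4me1_peaks.bed"),
    h3k27ac_peaks_unstim = p("h3k27ac_peaks_unstim.bed"),
    h3k27ac_peaks_stim = p("h3k27ac_peaks_stim.bed"),
    chip_unstim = p("h3k27ac_unstim.bedgraph"),
    chip_stim = p("h3k27ac_stim.bedgraph"),
    input_unstim = p("input_unstim.bedgraph"),
    input_stim = p("input_stim.bedgraph"),
    faire_unstim = p("faire_unstim.bedgraph"),
    faire_stim = p("faire_stim.bedgraph"),
    expression = p("expression.tsv"),
    ct_table = p("ct_table.tsv"), luciferase = p("luciferase.tsv"),
    faire_qpcr = p("faire_qpcr.tsv"),
    motifs = p("motifs.jaspar"),
    ground_truth = p("ground_truth.tsv"))
  g <- bundle$genes
  writeLines(c("##gff-version 3",
               sprintf("%s\tenhancerdyn\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, as.integer(g$start + 1), as.integer(g$end),
                       g$strand, g$gene_id)), paths$genes_gff)
  write_tss_table(g, paths$genes_tsv)
  write_bed(bundle$h3k4me1_peaks, paths$h3k4me1_peaks)
  write_bed(bundle$h3k27ac_peaks_unstim, paths$h3k27ac_peaks_unstim)
  write_bed(bundle$h3k27ac_peaks_stim, paths$h3k27ac_peaks_stim)
  for (tr in c("chip_unstim", "chip_stim", "input_unstim", "input_stim",
               "faire_unstim", "faire_stim"))
    write_bedgraph(bundle[[tr]], paths[[tr]])
  wt <- function(x, f) utils::write.table(x, f, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(bundle$expression, paths$expression)
  wt(bundle$ct_table, paths$ct_table)
  wt(bundle$luciferase, paths$luciferase)
  wt(bundle$faire_qpcr, paths$faire_qpcr)
  write_jaspar(bundle$motifs, paths$motifs)
  wt(bundle$ground_truth, paths$ground_truth)
  if (!is.null(bundle$genome)) {
    paths$genome <- p("genome.fa")
    write_fasta(bundle$genome, paths$genome)
  }
  paths
}
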