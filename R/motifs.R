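# Known-motif scanning and per-category enrichment.
#
# Motifs are position weight matrices (base-probability columns) scored in
# log2-odds bits against a background distribution, or degenerate IUPAC
# consensus strings matched with a mismatch budget. Enrichment per enhancer
# category is presence/absence (>= 1 hit per sequence) tested with the
# hypergeometric upper tail against the full enhancer set, BH-adjusted
# across motifs.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Canonical nuclear-receptor inverted-repeat consensus
#'
#' Documented synthetic placeholder for a hormone-response element consensus
#' (an AGGTCA-style inverted repeat with 1 bp spacer, written in IUPAC
#' code). Real analyses should supply the organism's experimentally derived
#' consensus instead.
#' @export
ECRE_IR1_CONSENSUS <- "RGGTCANTGACCY"

#' Construct a position weight matrix
#'
#' @param motif_id motif identifier.
#' @param matrix 4 x L numeric matrix of base probabilities, rows in
#'   A, C, G, T order; every column must sum to 1 (within 1e-9). L >= 4.
#' @param background background base probabilities (default uniform).
#' @param pseudocount fraction added to each probability before log-odds
#'   scoring, renormalised (default 0.01).
#' @return An object of class `pwm`.
#' @export
pwm <- function(motif_id, matrix, background = rep(0.25, 4),
                pseudocount = 0.01) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stopf("pwm: matrix must have 4 rows (A, C, G, T)")
  if (ncol(matrix) < 4) stopf("pwm: motif length must be >= 4")
  if (any(abs(colSums(matrix) - 1) > 1e-9))
    stopf("pwm '%s': columns must sum to 1", motif_id)
  if (any(matrix < 0)) stopf("pwm: negative probabilities")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9)
    stopf("pwm: background must be 4 probabilities summing to 1")
  if (pseudocount < 0) stopf("pwm: pseudocount must be >= 0")
  rownames(matrix) <- c("A", "C", "G", "T")
  structure(list(motif_id = as.character(motif_id), matrix = matrix,
                 background = as.numeric(background),
                 pseudocount = as.numeric(pseudocount)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d, consensus %s, max score %.2f bits\n",
              x$motif_id, ncol(x$matrix), pwm_consensus(x),
              pwm_max_score(x)))
  invisible(x)
}

# log2-odds score matrix with pseudocount applied and a 5th row of zeros so
# that N (and other ambiguity codes) contribute 0 bits.
pwm_score_matrix <- function(p) {
  pc <- p$pseudocount
  probs <- (p$matrix + pc) / (1 + 4 * pc)
  s <- log2(probs / p$background)
  rbind(s, 0)
}

#' Maximum attainable PWM score (bits)
#' @param p a [pwm()].
#' @export
pwm_max_score <- function(p) {
  s <- pwm_score_matrix(p)
  sum(apply(s[1:4, , drop = FALSE], 2, max))
}

#' Consensus string of a PWM (argmax base per column)
#' @param p a [pwm()].
#' @export
pwm_consensus <- function(p) {
  paste(rownames(p$matrix)[apply(p$matrix, 2, which.max)], collapse = "")
}

#' Reverse complement of a nucleotide string
#' @param seq character string over the IUPAC alphabet.
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(seq))
  vapply(comp, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# Encode a sequence as integers 1..4 (A,C,G,T), 5 for anything else (N etc.).
encode_seq <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  code <- match(x, c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

# Scores at every offset of a single strand. Returns numeric(0) if the
# sequence is shorter than the motif.
scan_one_strand <- function(codes, smat) {
  L <- ncol(smat)
  m <- length(codes) - L + 1L
  if (m < 1L) return(numeric(0))
  sc <- numeric(m)
  for (j in seq_len(L))
    sc <- sc + smat[codes[j:(j + m - 1L)], j]
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every offset on the forward strand and on the reverse complement
#' (reverse-strand hits are reported in forward coordinates: `offset` is the
#' 0-based leftmost position of the matched span). `N` bases contribute 0
#' bits.
#'
#' @param seq nucleotide string.
#' @param p a [pwm()].
#' @param score_min minimum score in bits for a hit; default 80% of the
#'   PWM's maximum attainable score.
#' @return data.frame with columns `offset` (0-based), `strand`, `score`,
#'   ordered by offset then strand.
#' @export
scan_pwm <- function(seq, p, score_min = NULL) {
  stopifnot(inherits(p, "pwm"))
  if (is.null(score_min)) score_min <- 0.8 * pwm_max_score(p)
  smat <- pwm_score_matrix(p)
  L <- ncol(smat)
  fwd <- scan_one_strand(encode_seq(seq), smat)
  rev <- scan_one_strand(encode_seq(reverse_complement(seq)), smat)
  m <- length(fwd)
  hf <- which(fwd >= score_min)
  hr <- which(rev >= score_min)
  out <- data.frame(
    offset = c(hf - 1L, m - hr),          # rc offset o maps to m - 1 - (o - 1)
    strand = c(rep("+", length(hf)), rep("-", length(hr))),
    score = c(fwd[hf], rev[hr]),
    stringsAsFactors = FALSE
  )
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Match a degenerate IUPAC consensus against a sequence
#'
#' Reports all positions (both strands, forward coordinates) where the
#' number of mismatches to the consensus is at most `max_mismatch`. A
#' sequence `N` matches only a consensus `N`.
#'
#' @param seq nucleotide string.
#' @param consensus IUPAC consensus string (e.g. [ECRE_IR1_CONSENSUS]).
#' @param max_mismatch mismatch budget (default 0).
#' @return data.frame with columns `offset` (0-based), `strand`,
#'   `mismatches`.
#' @export
match_ecre_consensus <- function(seq, consensus, max_mismatch = 0) {
  cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  if (!all(cons %in% names(IUPAC_SETS)))
    stopf("invalid IUPAC code '%s' in consensus",
          setdiff(cons, names(IUPAC_SETS))[1L])
  count_mm <- function(chars) {
    L <- length(cons)
    m <- length(chars) - L + 1L
    if (m < 1L) return(numeric(0))
    mm <- integer(m)
    for (j in seq_len(L)) {
      ok <- chars[j:(j + m - 1L)] %in% IUPAC_SETS[[cons[j]]] |
        (chars[j:(j + m - 1L)] == "N" & cons[j] == "N")
      mm <- mm + !ok
    }
    mm
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  fwd <- count_mm(chars)
  rev <- count_mm(strsplit(reverse_complement(seq), "", fixed = TRUE)[[1]])
  m <- length(fwd)
  hf <- which(fwd <= max_mismatch)
  hr <- which(rev <= max_mismatch)
  out <- data.frame(
    offset = c(hf - 1L, m - hr),
    strand = c(rep("+", length(hf)), rep("-", length(hr))),
    mismatches = c(fwd[hf], rev[hr]),
    stringsAsFactors = FALSE
  )
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Per-category known-motif enrichment
#'
#' For each motif, counts foreground sequences (the category) and background
#' sequences (all enhancers) with at least one hit, and tests enrichment
#' with the hypergeometric upper tail `P(X >= k)` given `N` total sequences,
#' `K` hit sequences and a foreground of size `n`. P-values are BH-adjusted
#' across motifs and results sorted ascending by p (ties by motif id).
#'
#' @param sequences named character vector, one sequence per enhancer.
#' @param category_assignment named character vector mapping enhancer name
#'   to category.
#' @param motifs list of [pwm()] objects.
#' @param category foreground category label.
#' @param score_min minimum hit score in bits, or `NULL` for the per-motif
#'   default (80% of maximum).
#' @return data.frame with columns `motif_id`, `k`, `n`, `K`, `N`, `fold`,
#'   `p`, `q`.
#' @export
enrich_by_category <- function(sequences, category_assignment, motifs,
                               category, score_min = NULL) {
  if (!length(motifs)) stopf("enrich_by_category: empty motif list")
  ids <- names(sequences)
  if (is.null(ids)) stopf("enrich_by_category: sequences must be named")
  cat_of <- category_assignment[ids]
  if (anyNA(cat_of))
    stopf("enrich_by_category: sequence(s) missing from category assignment")
  fg <- ids[cat_of == category]
  if (!length(fg)) stopf("enrich_by_category: empty category '%s'", category)
  N <- length(ids)
  n <- length(fg)
  res <- lapply(motifs, function(p) {
    has_hit <- vapply(sequences, function(s)
      nrow(scan_pwm(s, p, score_min)) > 0, logical(1))
    K <- sum(has_hit)
    k <- sum(has_hit[fg])
    data.frame(motif_id = p$motif_id, k = k, n = n, K = K, N = N,
               fold = if (K > 0) (k / n) / (K / N) else NA_real_,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read JASPAR-style motif files
#'
#' Parses plain-text JASPAR matrices: a `>id name` header followed by four
#' rows `A [ 1 2 3 ]` (counts or probabilities; columns are normalised).
#'
#' @param path motif file path.
#' @param pseudocount pseudocount passed to [pwm()].
#' @return List of [pwm()] objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stopf("no motif headers in '%s'", path)
  lapply(seq_along(starts), function(i) {
    id <- sub("^>\\s*(\\S+).*$", "\\1", lines[starts[i]])
    rows <- lines[(starts[i] + 1):(starts[i] + 4)]
    parsed <- lapply(rows, function(r) {
      body <- sub("^\\s*[ACGTacgt]\\s*", "", r)
      as.numeric(regmatches(body, gregexpr("[0-9.]+(?:[eE][+-]?[0-9]+)?",
                                           body))[[1]])
    })
    if (length(unique(lengths(parsed))) != 1L)
      stopf("motif '%s': rows of unequal length", id)
    mat <- do.call(rbind, parsed)
    mat <- sweep(mat, 2, colSums(mat), "/")
    pwm(id, mat, pseudocount = pseudocount)
  })
}

#' Write motifs in JASPAR-style plain text
#' @param motifs list of [pwm()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in motifs) {
    writeLines(sprintf(">%s %s", p$motif_id, p$motif_id), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$matrix[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Built-in synthetic motif set
#'
#' Four synthetic PWMs used by the data generator and examples: a
#' hormone-receptor-like inverted repeat (`EcR_syn`, consensus
#' AGGTCAATGACCT), an ETS-like repressor motif (`Eip74_syn`, consensus
#' ACCGGAAGT), and two neutral controls. Each column puts probability `w` on
#' the consensus base and `(1-w)/3` elsewhere.
#'
#' @param w consensus base probability (default 0.94).
#' @return Named list of [pwm()] objects.
#' @export
builtin_motifs <- function(w = 0.94) {
  from_consensus <- function(id, cons) {
    bases <- strsplit(cons, "", fixed = TRUE)[[1]]
    mat <- matrix((1 - w) / 3, nrow = 4, ncol = length(bases),
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(bases)) mat[bases[j], j] <- w
    pwm(id, mat)
  }
  list(
    EcR_syn = from_consensus("EcR_syn", "AGGTCAATGACCT"),
    Eip74_syn = from_consensus("Eip74_syn", "ACCGGAAGT"),
    ctrl_ebox = from_consensus("ctrl_ebox", "CACGTGCA"),
    ctrl_at = from_consensus("ctrl_at", "TTAGGGTTAG")
  )
}
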