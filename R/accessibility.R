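# Chromatin accessibility around enhancer summits.
#
# Meta-profiles are row-per-enhancer matrices of mean FAIRE read density
# (RPM per bp) in fixed offset bins around the summit; per-enhancer
# accessibility changes are floored RPM ratios over the quantification
# window, thresholded into an increased/not-increased call.

#' Read-density profile matrix around enhancer summits
#'
#' Row `i`, column `j` holds the mean density (RPM per bp) of `track` in
#' `[summit_i - flank + j*profile_bin, summit_i - flank + (j+1)*profile_bin)`
#' (0-based `j`). Positions outside the covered chromosome extent contribute
#' zero density.
#'
#' @param track a [signal_track()].
#' @param enhancers enhancer data frame with `chrom`, `summit`, `name`.
#' @param flank half-width of the profiled region in bp (default 3000).
#' @param profile_bin profile column width in bp (default 50); must divide
#'   `flank` and be a multiple of the track `bin_size`.
#' @param condition optional condition label stored on the result.
#' @return A numeric matrix of class `profile_matrix` (rows = enhancer
#'   names, columns labelled by bin-centre offset) with attributes `flank`,
#'   `profile_bin`, `condition`.
#' @export
profile_matrix <- function(track, enhancers, flank = 3000, profile_bin = 50,
                           condition = NA_character_) {
  stopifnot(inherits(track, "signal_track"))
  if (flank %% profile_bin != 0)
    stopf("profile_bin must divide flank")
  if (profile_bin %% track$bin_size != 0)
    stopf("profile_bin must be a multiple of the track bin_size")
  ncol <- as.integer(2 * flank / profile_bin)
  bs <- track$bin_size
  scale <- 1e6 / track$library_size
  m <- matrix(0, nrow = nrow(enhancers), ncol = ncol)
  for (i in seq_len(nrow(enhancers))) {
    v <- track$values[[enhancers$chrom[i]]]
    if (is.null(v)) {
      missing_chrom_warning(enhancers$chrom[i])
      next
    }
    # per-base density over the profiled span, zero outside coverage
    pos <- seq.int(enhancers$summit[i] - flank,
                   enhancers$summit[i] + flank - 1)
    idx <- floor(pos / bs) + 1
    ok <- pos >= 0 & idx <= length(v)
    d <- numeric(length(pos))
    d[ok] <- v[idx[ok]] / bs
    m[i, ] <- colMeans(matrix(d, nrow = profile_bin)) * scale
  }
  offsets <- seq.int(-flank, flank - profile_bin, by = profile_bin) +
    profile_bin / 2
  dimnames(m) <- list(enhancers$name, offsets)
  structure(m, flank = flank, profile_bin = profile_bin,
            condition = condition, class = c("profile_matrix", "matrix"))
}

#' Aggregate a profile matrix into per-category meta-profiles
#'
#' Column-wise mean over the rows of each category. Categories with no rows
#' are omitted with a warning; row names absent from the assignment are an
#' error.
#'
#' @param m a [profile_matrix()].
#' @param category_assignment named character vector mapping enhancer name to
#'   category.
#' @return A matrix with one row per (non-empty) category, same columns as
#'   `m`, carrying the `flank`/`profile_bin`/`condition` attributes.
#' @export
aggregate_profile <- function(m, category_assignment) {
  ids <- rownames(m)
  if (!all(ids %in% names(category_assignment)))
    stopf("aggregate_profile: unknown enhancer id '%s'",
          setdiff(ids, names(category_assignment))[1L])
  cat_of <- category_assignment[ids]
  present <- intersect(CATEGORY_LEVELS, unique(cat_of))
  missing <- setdiff(intersect(CATEGORY_LEVELS, unique(category_assignment)),
                     present)
  if (length(missing))
    warnf("aggregate_profile: no rows for category(ies) %s; omitted",
          paste(missing, collapse = ", "))
  out <- t(vapply(present, function(k)
    colMeans(m[cat_of == k, , drop = FALSE]), numeric(ncol(m))))
  rownames(out) <- present
  colnames(out) <- colnames(m)
  attr(out, "flank") <- attr(m, "flank")
  attr(out, "profile_bin") <- attr(m, "profile_bin")
  attr(out, "condition") <- attr(m, "condition")
  out
}

#' Per-enhancer accessibility change between conditions
#'
#' Windowed FAIRE RPM in the summit-centred window per condition;
#' `fold = stim / max(unstim, floor)`; `increased` iff
#' `fold >= threshold`.
#'
#' @param faire_unstim,faire_stim [signal_track()]s sharing `bin_size`.
#' @param enhancers enhancer data frame with `chrom`, `summit`, `name`.
#' @param window window width in bp (default 1500).
#' @param threshold fold threshold for an "increased" call (default 1.2).
#' @param floor denominator floor in RPM units (default 0.5).
#' @return data.frame with columns `name`, `faire_unstim`, `faire_stim`,
#'   `fold`, `increased`.
#' @export
accessibility_change <- function(faire_unstim, faire_stim, enhancers,
                                 window = 1500, threshold = 1.2,
                                 floor = 0.5) {
  if (faire_unstim$bin_size != faire_stim$bin_size)
    stopf("FAIRE tracks must share bin_size")
  n <- nrow(enhancers)
  u <- numeric(n); s <- numeric(n)
  half <- window / 2
  for (i in seq_len(n)) {
    ws <- max(enhancers$summit[i] - half, 0)
    we <- enhancers$summit[i] + half
    u[i] <- window_rpm(faire_unstim, enhancers$chrom[i], ws, we)
    s[i] <- window_rpm(faire_stim, enhancers$chrom[i], ws, we)
  }
  fold <- s / pmax(u, floor)
  data.frame(name = enhancers$name, faire_unstim = u, faire_stim = s,
             fold = fold, increased = fold >= threshold,
             stringsAsFactors = FALSE)
}

#' Fraction of a category with increased accessibility
#'
#' @param changes output of [accessibility_change()].
#' @param category_assignment named character vector mapping enhancer name to
#'   category.
#' @param category category label to summarise.
#' @return `|increased in category| / |category|`.
#' @export
fraction_increased <- function(changes, category_assignment, category) {
  cat_of <- category_assignment[changes$name]
  if (anyNA(cat_of))
    stopf("fraction_increased: enhancer(s) missing from category assignment")
  sel <- cat_of == category
  if (!any(sel)) stopf("fraction_increased: empty category '%s'", category)
  mean(changes$increased[sel])
}

#' Plot per-category accessibility meta-profiles
#'
#' Base-graphics line plot of aggregated meta-profiles (one line per
#' category/condition combination).
#'
#' @param profiles named list of aggregated profile matrices (e.g. one per
#'   condition), as returned by [aggregate_profile()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot_meta_profiles <- function(profiles, ...) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  all_rows <- do.call(rbind, unname(profiles))
  labs <- unlist(lapply(names(profiles), function(nm)
    paste(rownames(profiles[[nm]]), nm, sep = " / ")))
  off <- as.numeric(colnames(profiles[[1]]))
  graphics::matplot(off, t(all_rows), type = "l", lty = 1,
                    col = seq_len(nrow(all_rows)),
                    xlab = "offset from summit (bp)",
                    ylab = "mean density (RPM/bp)", ...)
  graphics::legend("topright", legend = labs, col = seq_len(nrow(all_rows)),
                   lty = 1, cex = 0.8, bty = "n")
  invisible(all_rows)
}

#' Write aggregated profiles as TSV
#'
#' One row per (category, condition), columns are bin-centre offsets.
#'
#' @param profiles named list (condition -> aggregated profile matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(names(profiles), function(cond) {
    m <- profiles[[cond]]
    data.frame(category = rownames(m), condition = cond,
               as.data.frame(unclass(m), check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
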