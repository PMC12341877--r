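#' Order and orient contigs along each linkage group
#'
#' Deterministic weighted ordering: a contig's position score is the
#' weighted mean of its markers' cM across parents (weights renormalised
#' over the parents actually carrying the markers); contigs are sorted by
#' score within each linkage group with ties broken by contig id.
#' Orientation is the sign of the weighted mean of per-parent Spearman
#' correlations between marker cM and marker offset (`+` positive, `-`
#' negative, `?` when fewer than two markers, no parent has two markers on
#' the contig, or the correlation is exactly zero).
#'
#' @param assignments data.frame from [assign_markers()].
#' @param maps filtered map rows.
#' @param weights named per-parent weights.
#' @return layout data.frame: `object` (`LG<k>`), `contig`, `orientation`,
#'   `gap_after` (TRUE between parts), `score`, ordered by placement.
#' @export
order_and_orient <- function(assignments, maps, weights) {
  m <- merge(assignments, maps, by = "marker_id")
  multi <- tapply(m$lg, m$contig_id, function(x) length(unique(x)))
  if (any(multi > 1L))
    stop("contig(s) with markers on multiple linkage groups (run the ",
         "chimera stage first): ",
         paste(names(multi)[multi > 1L], collapse = ", "))
  m$w <- unname(weights[m$parent])
  rows <- list()
  for (ctg in unique(m$contig_id)) {
    mc <- m[m$contig_id == ctg, , drop = FALSE]
    score <- sum(mc$w * mc$cM) / sum(mc$w)
    rho_w <- 0; w_tot <- 0
    for (p in unique(mc$parent)) {
      mp <- mc[mc$parent == p, , drop = FALSE]
      if (nrow(mp) < 2L || stats::sd(mp$pos0) == 0 || stats::sd(mp$cM) == 0)
        next
      rho <- stats::cor(mp$cM, mp$pos0, method = "spearman")
      if (is.na(rho)) next
      rho_w <- rho_w + weights[[p]] * rho
      w_tot <- w_tot + weights[[p]]
    }
    orientation <- if (w_tot == 0 || rho_w == 0) "?" else
      if (rho_w > 0) "+" else "-"
    rows[[length(rows) + 1L]] <- data.frame(
      object = sprintf("LG%d", mc$lg[1L]), contig = ctg,
      orientation = orientation, score = score, lg = mc$lg[1L],
      stringsAsFactors = FALSE)
  }
  lay <- do.call(rbind, rows)
  lay <- lay[order(lay$lg, lay$score, lay$contig), , drop = FALSE]
  lay$gap_after <- TRUE
  rownames(lay) <- NULL
  lay[, c("object", "contig", "orientation", "gap_after", "score")]
}

#' Project assigned markers onto pseudomolecule coordinates
#'
#' @param layout layout data.frame from [order_and_orient()].
#' @param contig_lengths named integer vector.
#' @param assignments data.frame from [assign_markers()].
#' @param gap_len gap inserted between consecutive parts (bp).
#' @return data.frame: `marker_id`, `object`, `pos` (0-based position on the
#'   pseudomolecule). Unoriented contigs are projected forward.
#' @export
layout_marker_positions <- function(layout, contig_lengths, assignments,
                                    gap_len = 100L) {
  out <- list()
  for (obj in unique(layout$object)) {
    lay <- layout[layout$object == obj, , drop = FALSE]
    at <- 0L
    for (i in seq_len(nrow(lay))) {
      ctg <- lay$contig[i]
      len <- contig_lengths[[ctg]]
      a <- assignments[assignments$contig_id == ctg, , drop = FALSE]
      if (nrow(a)) {
        pos <- if (lay$orientation[i] == "-") at + (len - 1L - a$pos0)
        else at + a$pos0
        out[[length(out) + 1L]] <- data.frame(
          marker_id = a$marker_id, object = obj, pos = pos,
          stringsAsFactors = FALSE)
      }
      at <- at + len + if (isTRUE(lay$gap_after[i]) && i < nrow(lay)) gap_len else 0L
    }
  }
  do.call(rbind, out)
}

#' Collinearity between linkage maps and the built pseudomolecules
#'
#' Spearman correlation between marker cM and marker position on the
#' pseudomolecule, per (parent, linkage group) pair with at least three
#' shared markers, plus the plain and weight-weighted means over pairs.
#'
#' @inheritParams layout_marker_positions
#' @param maps filtered map rows.
#' @param weights named per-parent weights.
#' @return list with `per_pair` (data.frame: `parent`, `lg`, `n`, `rho`),
#'   `mean_rho` and `weighted_mean_rho`.
#' @export
collinearity_stats <- function(layout, contig_lengths, assignments, maps,
                               weights, gap_len = 100L) {
  mpos <- layout_marker_positions(layout, contig_lengths, assignments, gap_len)
  m <- merge(mpos, maps, by = "marker_id")
  rows <- list()
  for (p in unique(m$parent)) {
    for (lg in sort(unique(m$linkage_group[m$parent == p]))) {
      ml <- m[m$parent == p & m$linkage_group == lg, , drop = FALSE]
      if (nrow(ml) < 3L) next
      rho <- suppressWarnings(stats::cor(ml$cM, ml$pos, method = "spearman"))
      rows[[length(rows) + 1L]] <- data.frame(
        parent = p, lg = lg, n = nrow(ml), rho = rho,
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  w <- unname(weights[per$parent])
  list(per_pair = per,
       mean_rho = mean(per$rho, na.rm = TRUE),
       weighted_mean_rho = sum(w * per$rho, na.rm = TRUE) / sum(w[!is.na(per$rho)]))
}

#' Windowed recombination-rate track (cM/Mb) along pseudomolecules
#'
#' Marker cM from one parent's map is interpolated piecewise-linearly over
#' pseudomolecule coordinates after clamping negative local slopes to zero
#' (clamp count reported as an attribute); the rate in each window is the
#' cM difference across the window divided by its length in Mb. Windows not
#' fully covered by the marker range are `NA`.
#'
#' @inheritParams collinearity_stats
#' @param window window size in bp.
#' @param parent map to use; default the highest-weight parent.
#' @return data.frame: `object`, `start`, `end`, `cm_per_mb`; attribute
#'   `clamped` counts markers whose cM was raised to restore monotonicity.
#' @export
recomb_rate_track <- function(layout, contig_lengths, assignments, maps,
                              weights, window = 1e6, parent = NULL,
                              gap_len = 100L) {
  if (is.null(parent)) parent <- names(which.max(weights))
  mpos <- layout_marker_positions(layout, contig_lengths, assignments, gap_len)
  m <- merge(mpos, maps[maps$parent == parent, , drop = FALSE], by = "marker_id")
  clamped <- 0L
  out <- list()
  for (obj in unique(layout$object)) {
    mo <- m[m$object == obj, , drop = FALSE]
    lay <- layout[layout$object == obj, , drop = FALSE]
    obj_len <- sum(contig_lengths[lay$contig]) +
      gap_len * sum(head(lay$gap_after, -1L))
    n_win <- ceiling(obj_len / window)
    starts <- (seq_len(n_win) - 1L) * window
    ends <- pmin(starts + window, obj_len)
    rate <- rep(NA_real_, n_win)
    if (nrow(mo) >= 2L) {
      mo <- mo[order(mo$pos), , drop = FALSE]
      cm <- cummax(mo$cM)                     # clamp negative slopes
      clamped <- clamped + sum(cm != mo$cM)
      ok <- !duplicated(mo$pos)
      if (sum(ok) >= 2L) {
        fx <- stats::approxfun(mo$pos[ok], cm[ok], rule = 1)
        lo <- fx(starts); hi <- fx(ends)
        rate <- (hi - lo) / ((ends - starts) / 1e6)
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      object = obj, start = starts, end = ends, cm_per_mb = rate,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "clamped") <- clamped
  res
}

#' Build pseudomolecule sequences (and AGP) from a layout
#'
#' Convenience wrapper: writes the AGP for the layout, builds the
#' pseudomolecule sequences from it, and collects unplaced contigs.
#'
#' @inheritParams layout_marker_positions
#' @param contigs named character vector of contig sequences.
#' @param agp_path optional path for the AGP file (a temporary file is used
#'   when NULL).
#' @return list with `pseudomolecules` (named character vector), `unplaced`
#'   (named character vector) and `agp` (the AGP table).
#' @export
build_pseudomolecules <- function(layout, contigs, agp_path = NULL,
                                  gap_len = 100L) {
  lens <- nchar(contigs)
  path <- if (is.null(agp_path)) tempfile(fileext = ".agp") else agp_path
  agp <- write_agp(layout, lens, path, gap_len = gap_len)
  ps <- build_fasta_from_agp(agp, contigs)
  unplaced <- contigs[setdiff(names(contigs), layout$contig)]
  list(pseudomolecules = ps, unplaced = unplaced, agp = agp)
}
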