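#' Detect chimeric contigs from marker linkage-group conflicts
#'
#' A contig is called chimeric when its assigned markers, ordered by offset,
#' form at least two maximal same-linkage-group blocks of at least `chunk`
#' markers each; one split is proposed between each adjacent pair of such
#' blocks (blocks smaller than `chunk` are ignored, and adjacent qualifying
#' blocks from the same linkage group do not trigger a split).
#'
#' @param assignments data.frame from [assign_markers()] (`marker_id`,
#'   `contig_id`, `pos0`, `lg`).
#' @param chunk minimum markers required on each side of a split.
#' @return data.frame with one row per proposed split: `contig`,
#'   `left_offset` (offset of the last marker of the left block),
#'   `right_offset` (first marker of the right block), `left_lg`, `right_lg`.
#' @export
detect_chimeras <- function(assignments, chunk = 2L) {
  out <- list()
  for (ctg in unique(assignments$contig_id)) {
    a <- assignments[assignments$contig_id == ctg, , drop = FALSE]
    if (length(unique(a$lg)) < 2L) next
    a <- a[order(a$pos0, a$marker_id), , drop = FALSE]
    r <- rle(a$lg)
    keep <- r$lengths >= chunk
    if (sum(keep) < 2L) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    kb <- which(keep)
    for (i in seq_len(length(kb) - 1L)) {
      b1 <- kb[i]; b2 <- kb[i + 1L]
      if (r$values[b1] == r$values[b2]) next
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg,
        left_offset = a$pos0[ends[b1]],
        right_offset = a$pos0[starts[b2]],
        left_lg = r$values[b1], right_lg = r$values[b2],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), left_offset = integer(0),
                      right_offset = integer(0), left_lg = integer(0),
                      right_lg = integer(0)))
  do.call(rbind, out)
}

#' Locate the cut interval for a proposed chimera split
#'
#' The cut is the largest N-run lying strictly between the flanking marker
#' offsets (ties broken towards the leftmost run); the whole run is removed.
#' With no N-run in the interval, the cut is the zero-width interval
#' directly after the final marker of the left block.
#'
#' @param n_runs integer matrix of 0-based half-open N-run intervals
#'   (columns `start`, `end`), e.g. from [contig_n_runs()].
#' @param left_offset,right_offset flanking marker offsets
#'   (`left_offset < right_offset`).
#' @return integer vector `c(start, end)`: the 0-based half-open cut
#'   interval (zero-width for the no-N fallback).
#' @export
locate_split <- function(n_runs, left_offset, right_offset) {
  stopifnot(left_offset < right_offset)
  if (nrow(n_runs)) {
    inside <- n_runs[, "start"] > left_offset & n_runs[, "end"] <= right_offset
    if (any(inside)) {
      runs <- n_runs[inside, , drop = FALSE]
      len <- runs[, "end"] - runs[, "start"]
      best <- which(len == max(len))[1L]      # leftmost of the ties
      return(c(start = unname(runs[best, "start"]),
               end = unname(runs[best, "end"])))
    }
  }
  c(start = left_offset + 1L, end = left_offset + 1L)
}

#' Split contigs at cut intervals and remap placements
#'
#' Each contig is cut at its (sorted, disjoint) cut intervals; the cut bases
#' themselves (the N-run) are removed. Children are named
#' `<parent>.1`, `<parent>.2`, ... left to right; placements on split
#' contigs are re-offset into the child holding them. The total child length
#' equals the parent length minus the removed bases.
#'
#' @param contigs named character vector of sequences.
#' @param cuts data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open cut intervals; zero-width allowed).
#' @param placements optional data.frame (`marker_id`, `contig_id`, `pos0`,
#'   `strand`, further columns carried through) to remap.
#' @return list with `contigs` (updated vector: children replace parents),
#'   `placements` (remapped, or NULL), and `id_map` (data.frame: `child`,
#'   `parent`, `src_start`, `src_end` of the child within the parent).
#' @export
split_contigs <- function(contigs, cuts, placements = NULL) {
  id_map <- list()
  for (ctg in unique(cuts$contig)) {
    if (!ctg %in% names(contigs)) stop("unknown contig id: ", ctg)
    cc <- cuts[cuts$contig == ctg, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    len <- nchar(contigs[[ctg]])
    bounds_s <- c(0L, cc$end)
    bounds_e <- c(cc$start, len)
    seqs <- character(0)
    for (i in seq_along(bounds_s)) {
      child <- sprintf("%s.%d", ctg, i)
      seqs[[child]] <- substr(contigs[[ctg]], bounds_s[i] + 1L, bounds_e[i])
      id_map[[length(id_map) + 1L]] <- data.frame(
        child = child, parent = ctg, src_start = bounds_s[i],
        src_end = bounds_e[i], stringsAsFactors = FALSE)
    }
    pos <- which(names(contigs) == ctg)
    contigs <- append(contigs[-pos], seqs, after = pos - 1L)
  }
  id_map <- if (length(id_map)) do.call(rbind, id_map) else
    data.frame(child = character(0), parent = character(0),
               src_start = integer(0), src_end = integer(0))
  if (!is.null(placements) && nrow(id_map)) {
    for (r in which(placements$contig_id %in% id_map$parent)) {
      im <- id_map[id_map$parent == placements$contig_id[r], , drop = FALSE]
      hit <- im$src_start <= placements$pos0[r] & placements$pos0[r] < im$src_end
      if (!any(hit)) {
        placements$contig_id[r] <- NA_character_   # fell inside a removed run
        next
      }
      im <- im[hit, ][1L, ]
      placements$pos0[r] <- placements$pos0[r] - im$src_start
      placements$contig_id[r] <- im$child
    }
    placements <- placements[!is.na(placements$contig_id), , drop = FALSE]
  }
  list(contigs = contigs, placements = placements, id_map = id_map)
}
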