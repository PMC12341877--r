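#' Filter linkage-map entries before anchoring
#'
#' Two exclusion rules, applied in order: (a) all rows matching a configured
#' (parent, linkage group) exclusion are dropped (the classic case being one
#' parent's linkage group carrying a putative rearrangement relative to the
#' others); (b) any marker whose remaining rows, across all parents, name
#' more than one linkage group is dropped entirely.
#'
#' @param maps data.frame of map rows (`parent`, `linkage_group`,
#'   `marker_id`, `cM`).
#' @param exclusions data.frame with columns `parent` and `linkage_group`,
#'   or NULL.
#' @return list with `maps` (filtered rows) and `report` (named vector:
#'   rows dropped by the exclusion rule, markers and rows dropped by the
#'   multi-LG rule, rows kept).
#' @export
filter_markers <- function(maps, exclusions = NULL) {
  stopifnot(nrow(maps) >= 1)
  n0 <- nrow(maps)
  if (!is.null(exclusions) && nrow(exclusions)) {
    key <- paste(maps$parent, maps$linkage_group)
    bad <- key %in% paste(exclusions$parent, exclusions$linkage_group)
    maps <- maps[!bad, , drop = FALSE]
  }
  n_excl <- n0 - nrow(maps)
  lg_per_marker <- tapply(maps$linkage_group, maps$marker_id,
                          function(x) length(unique(x)))
  multi <- names(lg_per_marker)[lg_per_marker > 1L]
  n1 <- nrow(maps)
  maps <- maps[!maps$marker_id %in% multi, , drop = FALSE]
  rownames(maps) <- NULL
  list(maps = maps,
       report = c(excluded_rows = n_excl,
                  multi_lg_markers = length(multi),
                  multi_lg_rows = n1 - nrow(maps),
                  kept_rows = nrow(maps)))
}

#' Assign each marker to a single contig
#'
#' Markers are processed in map order: the highest-weight parent's markers
#' first (sorted by linkage group, then cM), then any marker seen only on
#' lower-weight maps. A marker with one candidate placement takes it. With
#' several identical hits, the rule is: if either cM-adjacent marker (the
#' immediate neighbours in cM within the same linkage group, on the
#' highest-weight map carrying this marker) is already assigned to one of
#' the candidate contigs, that contig is chosen (a small contig spanning
#' consecutive markers beats a large one); otherwise the largest contig not
#' yet matched to any marker is chosen (falling back to the largest overall
#' if all candidates are matched), with ties broken by contig id. Markers
#' without any placement are reported as unanchorable.
#'
#' @param placements data.frame of candidate placements (`marker_id`,
#'   `contig_id`, `pos0`, `strand`), possibly several rows per marker.
#' @param contig_lengths named integer vector of contig lengths.
#' @param maps filtered map rows from [filter_markers()].
#' @param weights named per-parent weights.
#' @return list with `assignments` (data.frame: `marker_id`, `contig_id`,
#'   `pos0`, `strand`, `lg`) and `unanchorable` (character vector of marker
#'   ids with zero placements).
#' @export
assign_markers <- function(placements, contig_lengths, maps, weights) {
  stopifnot(all(maps$parent %in% names(weights)))
  marker_lg <- tapply(maps$linkage_group, maps$marker_id,
                      function(x) unique(x)[1L])
  parents_by_w <- names(sort(weights, decreasing = TRUE))
  # processing order: highest-weight parent first, then LG, then cM
  order_ids <- character(0)
  for (p in parents_by_w) {
    mp <- maps[maps$parent == p, , drop = FALSE]
    mp <- mp[order(mp$linkage_group, mp$cM, mp$marker_id), , drop = FALSE]
    order_ids <- c(order_ids, setdiff(mp$marker_id, order_ids))
  }
  # cM-neighbours on the highest-weight map carrying each marker
  neighbours <- new.env(parent = emptyenv())
  for (p in parents_by_w) {
    mp <- maps[maps$parent == p, , drop = FALSE]
    for (lg in unique(mp$linkage_group)) {
      ml <- mp[mp$linkage_group == lg, , drop = FALSE]
      ml <- ml[order(ml$cM, ml$marker_id), , drop = FALSE]
      ids <- ml$marker_id
      for (i in seq_along(ids)) {
        if (!is.null(neighbours[[ids[i]]])) next   # higher-weight map wins
        neighbours[[ids[i]]] <- c(if (i > 1L) ids[i - 1L],
                                  if (i < length(ids)) ids[i + 1L])
      }
    }
  }
  cand_by_marker <- split(placements, placements$marker_id)
  assigned <- new.env(parent = emptyenv())   # marker -> contig
  matched <- new.env(parent = emptyenv())    # contig -> TRUE once used
  rows <- list()
  unanchorable <- character(0)
  for (mk in order_ids) {
    cand <- cand_by_marker[[mk]]
    if (is.null(cand) || nrow(cand) == 0L) {
      unanchorable <- c(unanchorable, mk)
      next
    }
    choice <- NULL
    if (nrow(cand) > 1L) {
      nb <- neighbours[[mk]]
      for (nbm in nb) {
        ctg <- assigned[[nbm]]
        if (!is.null(ctg) && ctg %in% cand$contig_id) {
          choice <- cand[cand$contig_id == ctg, , drop = FALSE][1L, ]
          break
        }
      }
      if (is.null(choice)) {
        is_matched <- vapply(cand$contig_id, function(cid)
          isTRUE(matched[[cid]]), logical(1))
        pool <- if (any(!is_matched)) cand[!is_matched, , drop = FALSE] else cand
        len <- contig_lengths[pool$contig_id]
        pool <- pool[order(-len, pool$contig_id), , drop = FALSE]
        choice <- pool[1L, ]
      }
    } else choice <- cand[1L, ]
    assigned[[mk]] <- choice$contig_id
    matched[[choice$contig_id]] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      marker_id = mk, contig_id = choice$contig_id, pos0 = choice$pos0,
      strand = choice$strand, lg = as.integer(marker_lg[[mk]]),
      stringsAsFactors = FALSE)
  }
  list(assignments = if (length(rows)) do.call(rbind, rows) else
    data.frame(marker_id = character(0), contig_id = character(0),
               pos0 = integer(0), strand = character(0), lg = integer(0)),
    unanchorable = unanchorable)
}
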