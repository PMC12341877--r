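#' Write a pseudomolecule layout as AGP v2.1
#'
#' Each layout row places one contig (`W` component) on an object; a 100-N
#' gap (`U` row, evidence "map") is inserted after every part whose
#' `gap_after` flag is set. Coordinates in the emitted file are 1-based
#' inclusive, per the AGP standard; all package-internal coordinates are
#' 0-based half-open and converted only here.
#'
#' @param layout data.frame with columns `object` (pseudomolecule id),
#'   `contig` (component id), `orientation` (`+`, `-` or `?`) and
#'   `gap_after` (logical), ordered by placement within each object.
#' @param contig_lengths named integer vector of contig lengths (bp).
#' @param path output path.
#' @param gap_len gap length in bp for `U` rows.
#' @return the AGP table (data.frame of the emitted rows), invisibly.
#' @export
write_agp <- function(layout, contig_lengths, path, gap_len = 100L) {
  stopifnot(is.data.frame(layout),
            all(c("object", "contig", "orientation", "gap_after") %in% names(layout)))
  unknown <- setdiff(layout$contig, names(contig_lengths))
  if (length(unknown))
    stop("unknown contig id(s) in layout: ", paste(unknown, collapse = ", "))
  rows <- list()
  for (obj in unique(layout$object)) {
    part <- 0L
    at <- 0L   # 0-based cursor
    lay <- layout[layout$object == obj, , drop = FALSE]
    for (i in seq_len(nrow(lay))) {
      len <- contig_lengths[[lay$contig[i]]]
      part <- part + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object = obj, object_beg = at + 1L, object_end = at + len,
        part_number = part, component_type = "W",
        component_id = lay$contig[i], component_beg = 1L, component_end = len,
        orientation = lay$orientation[i], stringsAsFactors = FALSE)
      at <- at + len
      if (isTRUE(lay$gap_after[i]) && i < nrow(lay)) {
        part <- part + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          object = obj, object_beg = at + 1L, object_end = at + gap_len,
          part_number = part, component_type = "U",
          component_id = as.character(gap_len), component_beg = "scaffold",
          component_end = "yes", orientation = "map", stringsAsFactors = FALSE)
        at <- at + gap_len
      }
    }
  }
  agp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(object = character(0), object_beg = integer(0),
               object_end = integer(0), part_number = integer(0),
               component_type = character(0), component_id = character(0),
               component_beg = character(0), component_end = character(0),
               orientation = character(0), stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  if (nrow(agp))
    utils::write.table(agp, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(agp)
}

#' Read an AGP v2.1 file
#'
#' @param path AGP file written by [write_agp()] or a compatible tool.
#' @return data.frame with the nine AGP columns (`object`, `object_beg`,
#'   `object_end`, `part_number`, `component_type`, `component_id`,
#'   `component_beg`, `component_end`, `orientation`); gap (`U`) rows keep
#'   the gap length in `component_id`.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(object = character(0), object_beg = integer(0),
                      object_end = integer(0), part_number = integer(0),
                      component_type = character(0), component_id = character(0),
                      component_beg = character(0), component_end = character(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L))
    stop("malformed AGP: expected 9 columns at line ",
         which(lengths(f) != 9L)[1L])
  m <- do.call(rbind, f)
  data.frame(object = m[, 1L], object_beg = as.integer(m[, 2L]),
             object_end = as.integer(m[, 3L]), part_number = as.integer(m[, 4L]),
             component_type = m[, 5L], component_id = m[, 6L],
             component_beg = m[, 7L], component_end = m[, 8L],
             orientation = m[, 9L], stringsAsFactors = FALSE)
}

#' Build pseudomolecule sequences from an AGP table and contig sequences
#'
#' `W` rows contribute the (possibly reverse-complemented) contig sequence;
#' `U` rows contribute runs of N. Unoriented (`?`) components are inserted
#' forward, as scaffolders conventionally do.
#'
#' @param agp AGP table as returned by [read_agp()] / [write_agp()].
#' @param contigs named character vector of contig sequences.
#' @return named character vector of object sequences.
#' @export
build_fasta_from_agp <- function(agp, contigs) {
  objs <- unique(agp$object)
  out <- stats::setNames(character(length(objs)), objs)
  for (obj in objs) {
    rows <- agp[agp$object == obj, , drop = FALSE]
    rows <- rows[order(rows$part_number), , drop = FALSE]
    pieces <- character(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      if (rows$component_type[i] == "W") {
        id <- rows$component_id[i]
        if (!id %in% names(contigs)) stop("unknown contig id: ", id)
        s <- contigs[[id]]
        if (rows$orientation[i] == "-") s <- revcomp(s)
        pieces[i] <- s
      } else {
        pieces[i] <- strrep("N", as.integer(rows$component_id[i]))
      }
    }
    out[[obj]] <- paste(pieces, collapse = "")
  }
  out
}
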