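#' Read and write linkage-map tables
#'
#' Map files are TSV with columns `parent`, `linkage_group`, `marker_id`,
#' `cM`. cM values must be non-negative and each (parent, marker) pair must
#' occur at most once. CRLF line endings are accepted.
#'
#' @param path TSV file.
#' @return data.frame with the four columns, `linkage_group` integer, `cM`
#'   numeric.
#' @export
read_linkage_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("parent", "linkage_group", "marker_id", "cM")
  if (!all(need %in% names(d)))
    stop("linkage map must have columns: ", paste(need, collapse = ", "))
  d <- d[, need]
  d$parent <- as.character(d$parent)
  d$marker_id <- as.character(d$marker_id)
  d$linkage_group <- as.integer(d$linkage_group)
  d$cM <- as.numeric(d$cM)
  if (any(is.na(d$cM)) || any(d$cM < 0))
    stop("cM must be a non-negative decimal")
  key <- paste(d$parent, d$marker_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (parent, marker) rows: ",
         sub("\r", "/", key[duplicated(key)][1L]))
  d
}

#' @rdname read_linkage_map
#' @param map data.frame of map rows.
#' @export
write_linkage_map <- function(map, path) {
  utils::write.table(map[, c("parent", "linkage_group", "marker_id", "cM")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write marker physical placements
#'
#' Placement files are TSV with columns `marker_id`, `contig_id`, `pos0`
#' (0-based bp offset on the contig) and `strand`. A marker may have several
#' rows when its sequence hits several contigs equally well.
#'
#' @param path TSV file.
#' @return data.frame with the four columns, `pos0` integer.
#' @export
read_placements <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "contig_id", "pos0", "strand")
  if (!all(need %in% names(d)))
    stop("placements must have columns: ", paste(need, collapse = ", "))
  d <- d[, need]
  d$marker_id <- as.character(d$marker_id)
  d$contig_id <- as.character(d$contig_id)
  d$pos0 <- as.integer(d$pos0)
  if (any(is.na(d$pos0)) || any(d$pos0 < 0)) stop("pos0 must be >= 0")
  if (!all(d$strand %in% c("+", "-"))) stop("strand must be + or -")
  d
}

#' @rdname read_placements
#' @param placements data.frame of placement rows.
#' @export
write_placements <- function(placements, path) {
  utils::write.table(placements[, c("marker_id", "contig_id", "pos0", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write PAF alignment records
#'
#' The 12 mandatory PAF columns; query/target coordinates are 0-based
#' half-open as in the format itself.
#'
#' @param path PAF file.
#' @return data.frame with columns `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`.
#' @export
read_paf <- function(path) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "alen", "mapq")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    d <- as.data.frame(stats::setNames(rep(list(character(0)), 12), cols))
    return(d)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 12L))
    stop("malformed PAF: fewer than 12 fields at line ",
         which(lengths(f) < 12L)[1L])
  m <- do.call(rbind, lapply(f, `[`, 1:12))
  d <- data.frame(qname = m[, 1], qlen = as.integer(m[, 2]),
                  qstart = as.integer(m[, 3]), qend = as.integer(m[, 4]),
                  strand = m[, 5], tname = m[, 6], tlen = as.integer(m[, 7]),
                  tstart = as.integer(m[, 8]), tend = as.integer(m[, 9]),
                  nmatch = as.integer(m[, 10]), alen = as.integer(m[, 11]),
                  mapq = as.integer(m[, 12]), stringsAsFactors = FALSE)
  bad <- d$qstart < 0 | d$qstart >= d$qend | d$qend > d$qlen |
    d$tstart < 0 | d$tstart >= d$tend | d$tend > d$tlen
  if (any(bad)) stop("invalid PAF coordinates at line ", which(bad)[1L])
  d
}

#' @rdname read_paf
#' @param paf data.frame of PAF records.
#' @export
write_paf <- function(paf, path) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "alen", "mapq")
  utils::write.table(paf[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
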