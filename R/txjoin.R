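#' Filter transcript alignments for contig-joining evidence
#'
#' A transcript's alignment blocks are kept only if (a) the union of its
#' transcript-side intervals covers at least `min_cov` of the transcript,
#' (b) for every pair of blocks on different contigs the transcript-interval
#' overlap is at most `max_overlap` of the shorter block's transcript span,
#' and (c) strands are mutually compatible: blocks on one contig share a
#' strand and follow the transcript order under it, and when several block
#' pairs link the same ordered contig pair they must imply the same
#' junction. Transcripts failing any rule are dropped whole.
#'
#' @param paf data.frame of PAF records ([read_paf()] columns).
#' @param min_cov minimum matched fraction of the transcript.
#' @param max_overlap maximum cross-contig overlap, as a fraction of the
#'   shorter block's transcript span.
#' @return the retained PAF rows; `attr(, "report")` counts transcripts
#'   dropped per rule (`coverage`, `overlap`, `orientation`) and kept.
#' @export
filter_alignments <- function(paf, min_cov = 0.80, max_overlap = 0.50) {
  drop <- c(coverage = 0L, overlap = 0L, orientation = 0L, kept = 0L)
  keep_rows <- logical(nrow(paf))
  for (tid in unique(paf$qname)) {
    rows <- which(paf$qname == tid)
    b <- paf[rows, , drop = FALSE]
    b <- b[order(b$qstart, b$qend), , drop = FALSE]
    cov <- .interval_union_len(b$qstart, b$qend) / b$qlen[1L]
    if (cov < min_cov) {
      drop[["coverage"]] <- drop[["coverage"]] + 1L
      next
    }
    if (!.overlap_ok(b, max_overlap)) {
      drop[["overlap"]] <- drop[["overlap"]] + 1L
      next
    }
    if (!.strands_ok(b)) {
      drop[["orientation"]] <- drop[["orientation"]] + 1L
      next
    }
    drop[["kept"]] <- drop[["kept"]] + 1L
    keep_rows[rows] <- TRUE
  }
  out <- paf[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- drop
  out
}

.interval_union_len <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0L; cur_s <- s[1L]; cur_e <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    } else cur_e <- max(cur_e, e[i])
  }
  tot + (cur_e - cur_s)
}

# rule (b): pairwise transcript-interval overlap across contigs
.overlap_ok <- function(b, max_overlap) {
  n <- nrow(b)
  if (n < 2L) return(TRUE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (b$tname[i] == b$tname[j]) next
    ov <- min(b$qend[i], b$qend[j]) - max(b$qstart[i], b$qstart[j])
    if (ov <= 0L) next
    shorter <- min(b$qend[i] - b$qstart[i], b$qend[j] - b$qstart[j])
    if (ov > max_overlap * shorter) return(FALSE)
  }
  TRUE
}

# rule (c): strand consistency. Blocks are in transcript order.
.strands_ok <- function(b) {
  for (ctg in unique(b$tname)) {
    bc <- b[b$tname == ctg, , drop = FALSE]
    if (length(unique(bc$strand)) > 1L) return(FALSE)
    if (nrow(bc) >= 2L) {
      ord <- if (bc$strand[1L] == "+") bc$tstart else -bc$tstart
      if (is.unsorted(ord)) return(FALSE)
    }
  }
  # consecutive cross-contig pairs linking the same ordered contigs must
  # imply one junction (same exit/enter ends)
  if (nrow(b) >= 2L) {
    seen <- list()
    for (i in seq_len(nrow(b) - 1L)) {
      a <- b[i, ]; d <- b[i + 1L, ]
      if (a$tname == d$tname) next
      key <- paste(a$tname, d$tname)
      junc <- paste(if (a$strand == "+") "right" else "left",
                    if (d$strand == "+") "left" else "right")
      if (!is.null(seen[[key]]) && seen[[key]] != junc) return(FALSE)
      seen[[key]] <- junc
    }
  }
  TRUE
}

#' Propose contig joins from filtered transcript evidence
#'
#' Every consecutive pair of blocks on different contigs (in transcript
#' order) proposes one join: the transcript exits the first contig at its
#' strand-determined end (right for `+`, left for `-`) and enters the second
#' at the opposite-sense end. Identical (ends) proposals are aggregated;
#' support counts distinct transcripts.
#'
#' @param evidence filtered PAF rows from [filter_alignments()].
#' @return data.frame of candidates: `contig_a`, `end_a`, `contig_b`,
#'   `end_b` (canonical order: `contig_a < contig_b`), `support`, sorted by
#'   decreasing support then pair id.
#' @export
propose_joins <- function(evidence) {
  props <- list()
  for (tid in unique(evidence$qname)) {
    b <- evidence[evidence$qname == tid, , drop = FALSE]
    b <- b[order(b$qstart, b$qend), , drop = FALSE]
    if (length(unique(b$tname)) < 2L) next
    for (i in seq_len(nrow(b) - 1L)) {
      a <- b[i, ]; d <- b[i + 1L, ]
      if (a$tname == d$tname) next
      ea <- if (a$strand == "+") "right" else "left"
      eb <- if (d$strand == "+") "left" else "right"
      cand <- if (a$tname <= d$tname)
        c(a$tname, ea, d$tname, eb) else c(d$tname, eb, a$tname, ea)
      props[[length(props) + 1L]] <- data.frame(
        transcript = tid, contig_a = cand[1L], end_a = cand[2L],
        contig_b = cand[3L], end_b = cand[4L], stringsAsFactors = FALSE)
    }
  }
  if (!length(props))
    return(data.frame(contig_a = character(0), end_a = character(0),
                      contig_b = character(0), end_b = character(0),
                      support = integer(0)))
  pr <- unique(do.call(rbind, props))   # one vote per transcript per join
  key <- paste(pr$contig_a, pr$end_a, pr$contig_b, pr$end_b)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(agg$key, " ", fixed = TRUE))
  out <- data.frame(contig_a = parts[, 1L], end_a = parts[, 2L],
                    contig_b = parts[, 3L], end_b = parts[, 4L],
                    support = agg$Freq, stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$contig_a, out$end_a, out$contig_b,
                   out$end_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve conflicting join candidates by abundance
#'
#' Greedy acceptance in decreasing support order (ties: lexicographically
#' smaller pair first). A candidate is rejected when either involved contig
#' end is already consumed by an accepted join, or when it would close a
#' cycle among already-joined contigs.
#'
#' @param candidates data.frame from [propose_joins()].
#' @return the candidates with `accepted` (logical) and `reason`
#'   (`accepted`, `end_conflict` or `cycle`).
#' @export
resolve_conflicts <- function(candidates) {
  cand <- candidates[order(-candidates$support, candidates$contig_a,
                           candidates$end_a, candidates$contig_b,
                           candidates$end_b), , drop = FALSE]
  used_ends <- character(0)
  comp <- new.env(parent = emptyenv())     # union-find over contigs
  find <- function(x) {
    while (!is.null(comp[[x]]) && comp[[x]] != x) x <- comp[[x]]
    x
  }
  cand$accepted <- FALSE
  cand$reason <- ""
  for (i in seq_len(nrow(cand))) {
    ea <- paste0(cand$contig_a[i], ":", cand$end_a[i])
    eb <- paste0(cand$contig_b[i], ":", cand$end_b[i])
    if (ea %in% used_ends || eb %in% used_ends) {
      cand$reason[i] <- "end_conflict"
      next
    }
    ra <- find(cand$contig_a[i]); rb <- find(cand$contig_b[i])
    if (ra == rb) {
      cand$reason[i] <- "cycle"
      next
    }
    comp[[ra]] <- rb
    if (is.null(comp[[cand$contig_a[i]]])) comp[[cand$contig_a[i]]] <- rb
    if (is.null(comp[[cand$contig_b[i]]])) comp[[cand$contig_b[i]]] <- rb
    used_ends <- c(used_ends, ea, eb)
    cand$accepted[i] <- TRUE
    cand$reason[i] <- "accepted"
  }
  rownames(cand) <- NULL
  cand
}

#' Apply accepted joins: merge contig chains with N gaps
#'
#' Accepted joins form chains (each contig end used at most once, no
#' cycles); each chain is collapsed into one contig, members oriented so
#' consumed ends meet, separated by `gap_len` N. The chain direction is
#' chosen so the first member's id is lexicographically smaller than the
#' last's. The number of contigs shrinks by exactly the number of accepted
#' joins.
#'
#' @param contigs named character vector of sequences.
#' @param accepted data.frame of accepted joins (rows of
#'   [resolve_conflicts()] output with `accepted = TRUE`).
#' @param placements optional placements to remap (markers on reversed
#'   members are re-offset and strand-flipped).
#' @param gap_len gap length between joined members.
#' @return list with `contigs`, `placements` (or NULL), and `id_map`
#'   (data.frame: `old_contig`, `new_contig`, `order` in chain, `orient`,
#'   `offset` of the member's first base in the new contig).
#' @export
apply_joins <- function(contigs, accepted, placements = NULL, gap_len = 100L) {
  acc <- if ("accepted" %in% names(accepted))
    accepted[which(accepted$accepted), , drop = FALSE] else accepted
  edges <- new.env(parent = emptyenv())    # "ctg:end" -> "ctg:end"
  for (i in seq_len(nrow(acc))) {
    ea <- paste0(acc$contig_a[i], ":", acc$end_a[i])
    eb <- paste0(acc$contig_b[i], ":", acc$end_b[i])
    edges[[ea]] <- eb
    edges[[eb]] <- ea
  }
  members <- unique(c(acc$contig_a, acc$contig_b))
  visited <- new.env(parent = emptyenv())
  chains <- list()
  for (ctg in sort(members)) {
    if (isTRUE(visited[[ctg]])) next
    chain <- .walk_chain(ctg, edges)
    for (m in chain$contig) visited[[m]] <- TRUE
    # canonical direction: smaller terminal id first
    if (chain$contig[1L] > chain$contig[nrow(chain)]) {
      chain <- chain[rev(seq_len(nrow(chain))), , drop = FALSE]
      chain$orient <- ifelse(chain$orient == "+", "-", "+")
    }
    chains[[length(chains) + 1L]] <- chain
  }
  id_map <- list()
  new_contigs <- contigs
  for (k in seq_along(chains)) {
    chain <- chains[[k]]
    new_id <- sprintf("%s_j", chain$contig[1L])
    pieces <- character(nrow(chain))
    offset <- integer(nrow(chain))
    at <- 0L
    for (i in seq_len(nrow(chain))) {
      s <- contigs[[chain$contig[i]]]
      if (chain$orient[i] == "-") s <- revcomp(s)
      pieces[i] <- s
      offset[i] <- at
      at <- at + nchar(s) + gap_len
    }
    id_map[[length(id_map) + 1L]] <- data.frame(
      old_contig = chain$contig, new_contig = new_id,
      order = seq_len(nrow(chain)), orient = chain$orient, offset = offset,
      stringsAsFactors = FALSE)
    seq_new <- paste(pieces, collapse = strrep("N", gap_len))
    pos <- match(chain$contig[1L], names(new_contigs))
    new_contigs <- new_contigs[!names(new_contigs) %in% chain$contig]
    new_contigs <- append(new_contigs,
                          stats::setNames(seq_new, new_id),
                          after = min(pos, length(new_contigs) + 1L) - 1L)
  }
  id_map <- if (length(id_map)) do.call(rbind, id_map) else
    data.frame(old_contig = character(0), new_contig = character(0),
               order = integer(0), orient = character(0), offset = integer(0))
  if (!is.null(placements) && nrow(id_map)) {
    for (r in which(placements$contig_id %in% id_map$old_contig)) {
      im <- id_map[id_map$old_contig == placements$contig_id[r], ][1L, ]
      len <- nchar(contigs[[placements$contig_id[r]]])
      if (im$orient == "+") {
        placements$pos0[r] <- im$offset + placements$pos0[r]
      } else {
        placements$pos0[r] <- im$offset + (len - 1L - placements$pos0[r])
        placements$strand[r] <- if (placements$strand[r] == "+") "-" else "+"
      }
      placements$contig_id[r] <- im$new_contig
    }
  }
  list(contigs = new_contigs, placements = placements, id_map = id_map)
}

# follow a chain from one member to a terminal, then traverse to the other
# terminal; returns data.frame(contig, orient) in traversal order
.walk_chain <- function(start, edges) {
  other_end <- function(e) {
    parts <- strsplit(e, ":", fixed = TRUE)[[1L]]
    paste0(parts[1L], ":", if (parts[2L] == "left") "right" else "left")
  }
  # walk backwards to a terminal: the entry end of the chain's first contig
  # is the free end reached by following glued ends upstream
  entry <- paste0(start, ":left")
  seen <- character(0)
  repeat {
    prev_exit <- edges[[entry]]
    if (is.null(prev_exit) || prev_exit %in% seen) break
    seen <- c(seen, entry, prev_exit)
    entry <- other_end(prev_exit)
  }
  chain <- list()
  repeat {
    parts <- strsplit(entry, ":", fixed = TRUE)[[1L]]
    chain[[length(chain) + 1L]] <- data.frame(
      contig = parts[1L], orient = if (parts[2L] == "left") "+" else "-",
      stringsAsFactors = FALSE)
    exit <- other_end(entry)
    nxt <- edges[[exit]]
    if (is.null(nxt)) break
    entry <- nxt
  }
  do.call(rbind, chain)
}

#' Re-check joined contigs for chimerism
#'
#' Runs the same detection and split-localisation used in the anchoring
#' stage on a post-join contig set: linkage-group blocks of assigned markers
#' propose splits, each localised to the largest N-run between the flanking
#' markers (or a zero-width cut after the left block's last marker).
#'
#' @param contigs named character vector of sequences.
#' @param assignments marker assignments on those contigs (needs
#'   `contig_id`, `pos0`, `lg`, `marker_id`).
#' @param chunk minimum markers per side.
#' @return data.frame of cut intervals: `contig`, `start`, `end` (ready for
#'   [split_contigs()]).
#' @export
rejoin_chimera_check <- function(contigs, assignments, chunk = 2L) {
  chimera_cuts(contigs, assignments, chunk = chunk)
}

#' Chimera detection plus split localisation in one step
#'
#' @inheritParams rejoin_chimera_check
#' @return data.frame: `contig`, `start`, `end` cut intervals.
#' @export
chimera_cuts <- function(contigs, assignments, chunk = 2L) {
  det <- detect_chimeras(assignments, chunk = chunk)
  if (!nrow(det))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0)))
  out <- list()
  for (i in seq_len(nrow(det))) {
    runs <- contig_n_runs(contigs[[det$contig[i]]])
    cut <- locate_split(runs, det$left_offset[i], det$right_offset[i])
    out[[length(out) + 1L]] <- data.frame(
      contig = det$contig[i], start = cut[["start"]], end = cut[["end"]],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
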