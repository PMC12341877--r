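#' Simulate chromosomes fragmented into contigs, with planted chimeras
#'
#' Generates `n_chrom` random chromosomes of `chrom_len` bp, cuts each into
#' fragments, and emits contigs: most contigs are single fragments (stored
#' forward or reverse-complemented at random), while a configurable number
#' are inter-chromosomal chimeras made of two fragments from distinct
#' chromosomes, optionally separated by an N-run at the junction. The
#' returned truth table allows exact reconstruction and is the oracle for
#' anchoring, chimera detection and transcript joining.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_len chromosome length in bp.
#' @param n_contigs number of contigs to emit (chimeric contigs consume two
#'   fragments, so `n_contigs + n_chimera` fragments are cut in total).
#' @param chimera_rate fraction of contigs that are inter-chromosomal
#'   chimeras (requires `n_chrom >= 2` when positive).
#' @param n_run_rate probability that a chimera junction carries an N-run.
#' @param seed integer seed.
#' @param min_frag minimum fragment length in bp.
#' @param n_run_len length of the junction N-run in bp.
#' @param chimera_min_frag if set, chimera arms are drawn only from
#'   fragments at least this long (so each arm can carry linkage markers).
#' @return list of class `sim_genome` with elements `contigs` (named
#'   character vector), `truth` (list: `chromosomes` data.frame,
#'   `chrom_seq` named character vector, `origins` data.frame of contig
#'   segments with 0-based half-open source intervals and contig offsets,
#'   `chimera_junctions` data.frame, `n_runs` data.frame).
#' @export
simulate_genome <- function(n_chrom, chrom_len, n_contigs, chimera_rate = 0,
                            n_run_rate = 1, seed = 1L, min_frag = 500L,
                            n_run_len = 100L, chimera_min_frag = NULL) {
  stopifnot(n_chrom >= 1, chimera_rate >= 0, chimera_rate < 1,
            n_run_rate >= 0, n_run_rate <= 1)
  set.seed(seed)
  n_chimera <- round(chimera_rate * n_contigs)
  if (n_chimera > 0 && n_chrom < 2)
    stop("inter-chromosomal chimeras need n_chrom >= 2")
  n_frag <- n_contigs + n_chimera
  if (n_frag * min_frag > n_chrom * chrom_len)
    stop("contig count exceeds total sequence capacity: ", n_frag,
         " fragments of >= ", min_frag, " bp do not fit in ",
         n_chrom * chrom_len, " bp")
  chrom_ids <- sprintf("chr%02d", seq_len(n_chrom))
  chrom_seq <- stats::setNames(vapply(chrom_ids, function(i)
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = ""), character(1)), chrom_ids)

  # distribute fragments over chromosomes as evenly as the total allows
  per <- rep(n_frag %/% n_chrom, n_chrom)
  extra <- n_frag - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  frags <- list()
  for (k in seq_len(n_chrom)) {
    if (per[k] == 0L) next
    cuts <- .random_cuts(chrom_len, per[k], min_frag)
    frags[[k]] <- data.frame(chrom = chrom_ids[k],
                             start = cuts[-length(cuts)], end = cuts[-1L],
                             stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, frags)
  frags <- frags[sample.int(nrow(frags)), , drop = FALSE]   # shuffle

  chim_rows <- if (n_chimera > 0)
    .pick_chimera_pairs(frags, n_chimera, chimera_min_frag) else integer(0)
  plain_rows <- setdiff(seq_len(nrow(frags)), chim_rows)

  contigs <- character(0)
  origins <- list()
  junctions <- list()
  n_runs <- list()
  ctg_i <- 0L
  new_id <- function() {
    ctg_i <<- ctg_i + 1L
    sprintf("ctg%04d", ctg_i)
  }
  for (r in plain_rows) {
    id <- new_id()
    fr <- frags[r, ]
    s <- substr(chrom_seq[[fr$chrom]], fr$start + 1L, fr$end)
    ori <- if (stats::runif(1) < 0.5) "+" else "-"
    if (ori == "-") s <- revcomp(s)
    contigs[[id]] <- s
    origins[[length(origins) + 1L]] <- data.frame(
      contig = id, segment = 1L, chrom = fr$chrom, start = fr$start,
      end = fr$end, orientation = ori, ctg_start = 0L,
      ctg_end = fr$end - fr$start, stringsAsFactors = FALSE)
  }
  if (n_chimera > 0) {
    for (k in seq_len(n_chimera)) {
      id <- new_id()
      r1 <- chim_rows[2L * k - 1L]; r2 <- chim_rows[2L * k]
      f1 <- frags[r1, ]; f2 <- frags[r2, ]
      s1 <- substr(chrom_seq[[f1$chrom]], f1$start + 1L, f1$end)
      s2 <- substr(chrom_seq[[f2$chrom]], f2$start + 1L, f2$end)
      has_n <- stats::runif(1) < n_run_rate
      gap <- if (has_n) strrep("N", n_run_len) else ""
      l1 <- nchar(s1); lg <- nchar(gap)
      contigs[[id]] <- paste0(s1, gap, s2)
      origins[[length(origins) + 1L]] <- data.frame(
        contig = id, segment = c(1L, 2L), chrom = c(f1$chrom, f2$chrom),
        start = c(f1$start, f2$start), end = c(f1$end, f2$end),
        orientation = "+", ctg_start = c(0L, l1 + lg),
        ctg_end = c(l1, l1 + lg + nchar(s2)), stringsAsFactors = FALSE)
      junctions[[length(junctions) + 1L]] <- data.frame(
        contig = id, junction = l1, n_start = if (has_n) l1 else NA_integer_,
        n_end = if (has_n) l1 + lg else NA_integer_,
        left_chrom = f1$chrom, right_chrom = f2$chrom,
        stringsAsFactors = FALSE)
      if (has_n)
        n_runs[[length(n_runs) + 1L]] <- data.frame(
          contig = id, start = l1, end = l1 + lg, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    contigs = unlist(contigs),
    truth = list(
      chromosomes = data.frame(chrom = chrom_ids, length = chrom_len,
                               stringsAsFactors = FALSE),
      chrom_seq = chrom_seq,
      origins = do.call(rbind, origins),
      chimera_junctions = if (length(junctions)) do.call(rbind, junctions) else
        data.frame(contig = character(0), junction = integer(0),
                   n_start = integer(0), n_end = integer(0),
                   left_chrom = character(0), right_chrom = character(0)),
      n_runs = if (length(n_runs)) do.call(rbind, n_runs) else
        data.frame(contig = character(0), start = integer(0), end = integer(0)))),
    class = "sim_genome")
}

# n+1 cut points over [0, len] such that every piece is >= min_frag
.random_cuts <- function(len, n_pieces, min_frag) {
  if (n_pieces == 1L) return(c(0L, len))
  slack <- len - n_pieces * min_frag
  inner <- sort(sample.int(slack + 1L, n_pieces - 1L, replace = FALSE)) - 1L
  cuts <- c(0L, inner + min_frag * seq_len(n_pieces - 1L), len)
  as.integer(cuts)
}

# choose 2*n fragment rows for chimeras such that each pair spans two
# chromosomes; an optional minimum fragment length keeps both chimera arms
# long enough to catch linkage markers
.pick_chimera_pairs <- function(frags, n_chimera, min_len = NULL) {
  rows <- integer(0)
  avail <- seq_len(nrow(frags))
  if (!is.null(min_len)) {
    avail <- avail[frags$end[avail] - frags$start[avail] >= min_len]
    if (length(avail) < 2L * n_chimera)
      stop("not enough fragments of >= ", min_len, " bp for ", n_chimera,
           " chimeras")
  }
  for (k in seq_len(n_chimera)) {
    if (length(avail) < 2L) stop("not enough fragments for chimeras")
    r1 <- sample(avail, 1L)
    others <- avail[frags$chrom[avail] != frags$chrom[r1]]
    if (!length(others)) stop("cannot pair chimera across chromosomes")
    r2 <- if (length(others) == 1L) others else sample(others, 1L)
    rows <- c(rows, r1, r2)
    avail <- setdiff(avail, c(r1, r2))
  }
  rows
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d chromosome(s), %d contigs (%d chimeric)\n",
              nrow(x$truth$chromosomes), length(x$contigs),
              nrow(x$truth$chimera_junctions)))
  invisible(x)
}

# map chromosome positions (0-based) to (contig, offset, strand) using the
# truth origins; positions falling in no segment return NA rows
.truth_locate <- function(truth, chrom, pos0) {
  org <- truth$origins
  out <- data.frame(contig = rep(NA_character_, length(pos0)),
                    offset = NA_integer_, strand = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pos0)) {
    seg <- org[org$chrom == chrom[i] & org$start <= pos0[i] & org$end > pos0[i], ]
    if (!nrow(seg)) next
    seg <- seg[1L, ]
    if (seg$orientation == "+") {
      out$offset[i] <- seg$ctg_start + (pos0[i] - seg$start)
      out$strand[i] <- "+"
    } else {
      out$offset[i] <- seg$ctg_start + (seg$end - 1L - pos0[i])
      out$strand[i] <- "-"
    }
    out$contig[i] <- seg$contig
  }
  out
}

#' Simulate parental linkage maps and marker placements from a genome truth
#'
#' Places `markers_per_lg` markers along each chromosome (one linkage group
#' per chromosome), evenly spaced with uniform jitter so every region a few
#' spacings wide is guaranteed to carry markers. Every parent reports every marker with
#' genetic position `(pos / chrom_len) * cM_per_chrom` plus independent
#' Normal(0, `noise_sd`) noise, truncated at 0. Each marker is also emitted
#' as a physical placement on the contig covering its position.
#'
#' @param genome a `sim_genome` from [simulate_genome()].
#' @param n_parents number of parental maps.
#' @param markers_per_lg markers per linkage group (>= 2).
#' @param cM_per_chrom genetic length of each linkage group in cM.
#' @param noise_sd standard deviation of the per-parent cM noise.
#' @param weights per-parent integer weights (highest = most trusted map);
#'   defaults to `3, 2, 1, 1, ...`.
#' @param seed integer seed.
#' @param jitter_frac marker positions are evenly spaced with uniform jitter
#'   of this fraction of the spacing (< 0.5 keeps marker order).
#' @return list with `maps` (data.frame: `parent`, `linkage_group`,
#'   `marker_id`, `cM`), `placements` (data.frame: `marker_id`, `contig_id`,
#'   `pos0`, `strand`), `weights` (named vector), and `marker_truth`
#'   (data.frame with the true chromosome positions).
#' @export
simulate_linkage_maps <- function(genome, n_parents = 4, markers_per_lg = 10,
                                  cM_per_chrom = 100, noise_sd = 0,
                                  weights = NULL, seed = 1L,
                                  jitter_frac = 0.3) {
  stopifnot(inherits(genome, "sim_genome"), markers_per_lg >= 2)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(weights)) weights <- c(3L, 2L, rep(1L, max(0, n_parents - 2L)))[seq_len(n_parents)]
  stopifnot(length(weights) == n_parents, all(weights >= 1))
  set.seed(seed)
  parents <- sprintf("parent%d", seq_len(n_parents))
  names(weights) <- parents
  truth <- genome$truth
  maps <- list(); placements <- list(); mtruth <- list()
  for (k in seq_len(nrow(truth$chromosomes))) {
    ch <- truth$chromosomes$chrom[k]
    len <- truth$chromosomes$length[k]
    # evenly spaced with jitter: any region spanning a few marker spacings
    # is guaranteed to carry markers (uniform placement leaves gaps)
    spacing <- len / markers_per_lg
    pos <- (seq_len(markers_per_lg) - 0.5) * spacing +
      stats::runif(markers_per_lg, -jitter_frac, jitter_frac) * spacing
    pos <- sort(as.integer(pmin(pmax(round(pos), 0), len - 1L)))
    pos <- unique(pos)
    while (length(pos) < markers_per_lg)   # collisions after rounding
      pos <- sort(unique(c(pos, sample.int(len, 1L) - 1L)))
    ids <- sprintf("mk_%s_%03d", ch, seq_len(markers_per_lg))
    loc <- .truth_locate(truth, rep(ch, markers_per_lg), pos)
    placements[[k]] <- data.frame(marker_id = ids, contig_id = loc$contig,
                                  pos0 = loc$offset, strand = loc$strand,
                                  stringsAsFactors = FALSE)
    mtruth[[k]] <- data.frame(marker_id = ids, chrom = ch, pos0 = pos,
                              stringsAsFactors = FALSE)
    cm_true <- pos / len * cM_per_chrom
    for (p in parents) {
      cm <- pmax(0, cm_true + stats::rnorm(markers_per_lg, 0, noise_sd))
      maps[[length(maps) + 1L]] <- data.frame(
        parent = p, linkage_group = k, marker_id = ids, cM = cm,
        stringsAsFactors = FALSE)
    }
  }
  list(maps = do.call(rbind, maps),
       placements = do.call(rbind, placements),
       weights = weights,
       marker_truth = do.call(rbind, mtruth))
}
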