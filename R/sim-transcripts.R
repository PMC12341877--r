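#' Simulate transcript-to-contig alignments (PAF), some spanning junctions
#'
#' A configurable fraction of transcripts span the boundary between two
#' contigs that are physically adjacent on a source chromosome (split into
#' two alignment blocks with strands consistent with the contigs' stored
#' orientations); the rest lie wholly within one contig. Optional decoy
#' transcripts propose a conflicting join (same contig end as a true
#' junction, different partner) with support 1, and optional coverage noise
#' degrades a fraction of transcripts below the usual 80% coverage filter.
#'
#' Junction transcripts are only placed across pairs of non-chimeric contigs
#' whose flanking fragments can hold half a transcript each.
#'
#' @param genome a `sim_genome` from [simulate_genome()].
#' @param n_transcripts total number of ordinary transcripts.
#' @param junction_fraction fraction of them spanning a contig junction.
#' @param seed integer seed.
#' @param tlen transcript length in bp.
#' @param transcripts_per_pair how many junction transcripts to stack on
#'   each adjacency (1 spreads them over as many distinct pairs as possible;
#'   >1 concentrates support, useful against decoys).
#' @param decoy_n number of decoy transcripts proposing conflicting joins.
#' @param coverage_noise fraction of transcripts whose aligned coverage is
#'   degraded to 55-78% of the transcript (below the standard filter).
#' @return list with `paf` (data.frame of PAF records), `truth_pairs`
#'   (data.frame of distinct true adjacencies: `contig_a`, `end_a`,
#'   `contig_b`, `end_b`), and `n_junction`, `n_within`, `n_decoy` counts.
#' @export
simulate_transcripts <- function(genome, n_transcripts, junction_fraction,
                                 seed = 1L, tlen = 600L,
                                 transcripts_per_pair = 1L, decoy_n = 0L,
                                 coverage_noise = 0) {
  stopifnot(inherits(genome, "sim_genome"),
            junction_fraction >= 0, junction_fraction <= 1,
            coverage_noise >= 0, coverage_noise <= 1)
  set.seed(seed)
  truth <- genome$truth
  half <- tlen %/% 2L
  adj <- .true_adjacencies(truth, half)
  n_junc <- round(junction_fraction * n_transcripts)
  n_within <- n_transcripts - n_junc
  if (n_junc > 0 && nrow(adj) == 0L)
    stop("no usable adjacency for junction transcripts")
  paf <- list()
  tr_i <- 0L
  new_tid <- function() {
    tr_i <<- tr_i + 1L
    sprintf("tx%05d", tr_i)
  }
  used_pairs <- integer(0)
  if (n_junc > 0) {
    n_pairs <- min(nrow(adj), max(1L, ceiling(n_junc / transcripts_per_pair)))
    used_pairs <- sample.int(nrow(adj), n_pairs)
    alloc <- rep(used_pairs, length.out = n_junc)
    for (r in alloc) {
      tid <- new_tid()
      paf[[length(paf) + 1L]] <- .junction_paf(tid, adj[r, ], truth, half,
                                               genome$contigs)
    }
  }
  plain <- .plain_contigs(truth)
  long_enough <- plain[nchar(genome$contigs[plain]) >= tlen]
  if (n_within > 0 && !length(long_enough))
    stop("no contig long enough for within-contig transcripts")
  for (k in seq_len(n_within)) {
    tid <- new_tid()
    id <- if (length(long_enough) == 1L) long_enough else sample(long_enough, 1L)
    clen <- nchar(genome$contigs[[id]])
    s <- sample.int(clen - tlen + 1L, 1L) - 1L
    paf[[length(paf) + 1L]] <- data.frame(
      qname = tid, qlen = tlen, qstart = 0L, qend = tlen,
      strand = if (stats::runif(1) < 0.5) "+" else "-",
      tname = id, tlen = clen, tstart = s, tend = s + tlen,
      nmatch = tlen, alen = tlen, mapq = 60L, stringsAsFactors = FALSE)
  }
  n_decoy <- 0L
  if (decoy_n > 0 && length(used_pairs)) {
    for (k in seq_len(decoy_n)) {
      r <- adj[used_pairs[(k - 1L) %% length(used_pairs) + 1L], ]
      cand <- setdiff(long_enough, c(r$contig_a, r$contig_b))
      if (!length(cand)) next
      cid <- if (length(cand) == 1L) cand else sample(cand, 1L)
      tid <- new_tid()
      blkA <- .end_block(tid, r$contig_a, r$end_a, "A",
                         half, tlen, genome$contigs)
      clen <- nchar(genome$contigs[[cid]])
      blkC <- data.frame(qname = tid, qlen = tlen, qstart = half, qend = tlen,
                         strand = "+", tname = cid, tlen = clen,
                         tstart = 0L, tend = tlen - half, nmatch = tlen - half,
                         alen = tlen - half, mapq = 60L,
                         stringsAsFactors = FALSE)
      paf[[length(paf) + 1L]] <- rbind(blkA, blkC)
      n_decoy <- n_decoy + 1L
    }
  }
  paf <- do.call(rbind, paf)
  if (coverage_noise > 0 && nrow(paf)) {
    tids <- unique(paf$qname)
    hit <- tids[stats::runif(length(tids)) < coverage_noise]
    for (tid in hit) {
      rows <- which(paf$qname == tid)
      frac <- stats::runif(1, 0.55, 0.78)
      for (rr in rows) {
        span <- paf$qend[rr] - paf$qstart[rr]
        keep <- max(1L, as.integer(round(span * frac)))
        trim <- span - keep
        paf$qend[rr] <- paf$qend[rr] - trim
        if (paf$strand[rr] == "+") paf$tend[rr] <- paf$tend[rr] - trim
        else paf$tstart[rr] <- paf$tstart[rr] + trim
        paf$nmatch[rr] <- keep
        paf$alen[rr] <- keep
      }
    }
  }
  rownames(paf) <- NULL
  truth_pairs <- unique(adj[used_pairs, c("contig_a", "end_a",
                                          "contig_b", "end_b")])
  # canonical order (smaller contig id first) to match join candidates
  flip <- truth_pairs$contig_a > truth_pairs$contig_b
  if (any(flip)) {
    tmp <- truth_pairs[flip, c("contig_a", "end_a")]
    truth_pairs[flip, c("contig_a", "end_a")] <-
      truth_pairs[flip, c("contig_b", "end_b")]
    truth_pairs[flip, c("contig_b", "end_b")] <- tmp
  }
  rownames(truth_pairs) <- NULL
  list(paf = paf, truth_pairs = truth_pairs,
       n_junction = n_junc, n_within = n_within, n_decoy = n_decoy)
}

# contigs made of a single source fragment
.plain_contigs <- function(truth) {
  tab <- table(truth$origins$contig)
  names(tab)[tab == 1L]
}

# adjacent plain-contig pairs along each chromosome with >= half bp on each
# side of the boundary
.true_adjacencies <- function(truth, half) {
  org <- truth$origins
  plain <- .plain_contigs(truth)
  org <- org[org$contig %in% plain, , drop = FALSE]
  out <- list()
  for (ch in unique(org$chrom)) {
    seg <- org[org$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) < 2L) next
    for (i in seq_len(nrow(seg) - 1L)) {
      a <- seg[i, ]; b <- seg[i + 1L, ]
      if (a$end != b$start) next                      # not truly adjacent
      if (a$end - a$start < half || b$end - b$start < half) next
      out[[length(out) + 1L]] <- data.frame(
        contig_a = a$contig,
        end_a = if (a$orientation == "+") "right" else "left",
        contig_b = b$contig,
        end_b = if (b$orientation == "+") "left" else "right",
        chrom = ch, boundary = a$end, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig_a = character(0), end_a = character(0),
                      contig_b = character(0), end_b = character(0),
                      chrom = character(0), boundary = integer(0)))
  do.call(rbind, out)
}

# PAF rows for one transcript spanning the boundary of an adjacency
.junction_paf <- function(tid, r, truth, half, contigs) {
  tlen <- 2L * half
  blkA <- .chrom_block(tid, truth, r$chrom, r$boundary - half, r$boundary,
                       0L, half, tlen, contigs)
  blkB <- .chrom_block(tid, truth, r$chrom, r$boundary, r$boundary + half,
                       half, tlen, tlen, contigs)
  rbind(blkA, blkB)
}

# one PAF block: chromosome interval [s,e) expressed on its covering contig
.chrom_block <- function(tid, truth, chrom, s, e, qs, qe, tlen, contigs) {
  org <- truth$origins
  seg <- org[org$chrom == chrom & org$start <= s & org$end >= e, ][1L, ]
  clen <- nchar(contigs[[seg$contig]])
  if (seg$orientation == "+") {
    ts <- seg$ctg_start + (s - seg$start)
    te <- seg$ctg_start + (e - seg$start)
  } else {
    ts <- seg$ctg_start + (seg$end - e)
    te <- seg$ctg_start + (seg$end - s)
  }
  data.frame(qname = tid, qlen = tlen, qstart = qs, qend = qe,
             strand = seg$orientation, tname = seg$contig, tlen = clen,
             tstart = ts, tend = te, nmatch = qe - qs, alen = qe - qs,
             mapq = 60L, stringsAsFactors = FALSE)
}

# aligned block anchored at a given end of a contig (decoy helper)
.end_block <- function(tid, contig, end, which, half, tlen, contigs) {
  clen <- nchar(contigs[[contig]])
  if (end == "right") {
    ts <- clen - half; te <- clen; strand <- "+"
  } else {
    ts <- 0L; te <- half; strand <- "-"
  }
  data.frame(qname = tid, qlen = tlen, qstart = 0L, qend = half,
             strand = strand, tname = contig, tlen = clen, tstart = ts,
             tend = te, nmatch = half, alen = half, mapq = 60L,
             stringsAsFactors = FALSE)
}
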