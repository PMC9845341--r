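# SV breakpoint refinement.
#
# For each candidate cluster, subsequences of the supporting reads spanning
# the provisional breakpoint (+/- a 500 bp flank) are combined into a
# consensus by partial order alignment; the consensus is realigned to the
# local reference and the SV detected in that alignment replaces the
# cluster's provisional (mean-of-signals) coordinates. When POA or the
# realignment fails the provisional mean is kept (imprecise breakpoint).

POA_MATCH <- 2L; POA_MIS <- -4L; POA_GAP_OPEN <- -4L; POA_GAP_EXT <- -2L

poa_failure <- function(msg) structure(list(message = msg),
                                       class = c("PoaFailure", "condition"))
realign_failure <- function(msg) structure(list(message = msg),
                                           class = c("RealignFailure",
                                                     "condition"))

#' Build a POA consensus across supporting-read windows
#'
#' Reads are added to the partial order graph in a fixed order (descending
#' length, then name) and the consensus is the heaviest path; on
#' equal-length gap-free inputs this equals the column-wise majority vote.
#'
#' @param read_windows named character vector of read subsequences spanning
#'   the SV +/- flank (names = read ids).
#' @param band alignment band half-width.
#' @return list(seq, n_reads, region = NULL) of class "svd_consensus", or a
#'   "PoaFailure" condition object when fewer than 2 usable reads are given.
#' @export
build_poa_consensus <- function(read_windows, band = 250L) {
  read_windows <- read_windows[!is.na(read_windows) & nzchar(read_windows)]
  if (length(read_windows) < 2L)
    return(poa_failure("fewer than 2 usable reads"))
  nm <- names(read_windows) %||% as.character(seq_along(read_windows))
  ord <- order(-nchar(read_windows), nm)
  read_windows <- read_windows[ord]
  res <- cpp_poa_consensus(unname(read_windows), POA_MATCH, POA_MIS,
                           POA_GAP_OPEN, POA_GAP_EXT, as.integer(band))
  structure(list(seq = res$seq, n_reads = res$n_reads, region = NULL),
            class = "svd_consensus")
}

is_failure <- function(x) inherits(x, c("PoaFailure", "RealignFailure"))

# left-normalize a deletion/duplication interval [pos, pos+size) on refseq
# (refseq given with offset lo: refseq[1] is reference position lo)
normalize_del_left <- function(refseq, lo, pos, size) {
  i <- pos - lo
  while (i > 0 &&
         substr(refseq, i, i) == substr(refseq, i + size, i + size)) {
    i <- i - 1L
  }
  lo + i
}

# left-normalize an insertion (pos, content) against the reference
normalize_ins_left <- function(refseq, lo, pos, content) {
  i <- pos - lo
  n <- nchar(content)
  while (i > 0 && substr(refseq, i, i) == substr(content, n, n)) {
    content <- paste0(substr(refseq, i, i), substr(content, 1L, n - 1L))
    i <- i - 1L
  }
  list(pos = lo + i, content = content)
}

#' Realign a consensus to the local reference and detect the SV
#'
#' Detection uses a single-long-gap alignment model: for deletions and
#' duplications a forward/backward join with an unconstrained reference-side
#' jump (positive jump = deletion, negative = tandem-duplication junction);
#' for insertions a long query-side gap state. The consensus counts as
#' properly aligned when the alignment score reaches the aligned consensus
#' length (about 70-80% identity over the aligned bases at the +2/-4
#' scoring); otherwise a RealignFailure is returned.
#'
#' @param cons consensus object (or character string).
#' @param genome "svd_genome".
#' @param chrom,lo,hi reference window (0-based half-open).
#' @param sv_type expected type: "DEL", "INS" or "DUP".
#' @param min_signal_size minimum event size to report.
#' @return list(sv_type, pos, size, ins_seq, score) or "RealignFailure".
#' @export
realign_local <- function(cons, genome, chrom, lo, hi, sv_type,
                          min_signal_size = 30L) {
  qseq <- if (is.character(cons)) cons else cons$seq
  refseq <- seq_fetch(genome, chrom, lo, hi)
  m <- nchar(qseq)
  if (m < 50L || nchar(refseq) < 50L)
    return(realign_failure("window too small"))
  if (sv_type %in% c("DEL", "DUP")) {
    jn <- cpp_align_join(qseq, refseq, POA_MATCH, POA_MIS, POA_GAP_OPEN)
    g <- jn$jB - jn$jF
    if (jn$join_score < m)
      return(realign_failure("consensus not properly aligned"))
    # the split must genuinely beat the best single local alignment,
    # otherwise an SV-free consensus would fabricate a junction
    if (jn$join_score < jn$local_best + 20L)
      return(realign_failure("no junction in consensus alignment"))
    if (sv_type == "DEL" && g >= min_signal_size) {
      pos <- normalize_del_left(refseq, lo, lo + jn$jF, g)
      return(list(sv_type = "DEL", pos = pos, size = g, ins_seq = NA_character_,
                  score = jn$join_score))
    }
    if (sv_type == "DUP" && -g >= min_signal_size) {
      pos <- normalize_del_left(refseq, lo, lo + jn$jB, -g)
      return(list(sv_type = "DUP", pos = pos, size = -g,
                  ins_seq = NA_character_, score = jn$join_score))
    }
    return(realign_failure("no matching SV in consensus alignment"))
  }
  if (sv_type == "INS") {
    al <- cpp_align_ins(qseq, refseq, POA_MATCH, POA_MIS, POA_GAP_OPEN, -24L)
    gl <- al$q_gap_end - al$q_gap_start
    if (al$q_gap_start < 0 || gl < min_signal_size ||
        al$score <= al$plain_best)
      return(realign_failure("no insertion detected in consensus"))
    if (al$score < (m - gl))
      return(realign_failure("consensus not properly aligned"))
    content <- substr(qseq, al$q_gap_start + 1L, al$q_gap_end)
    nrm <- normalize_ins_left(refseq, lo, lo + al$ref_pos, content)
    return(list(sv_type = "INS", pos = nrm$pos, size = gl,
                ins_seq = nrm$content, score = al$score))
  }
  realign_failure(paste("unsupported type", sv_type))
}

# extract, for each supporting record, the read subsequence spanning
# [ref_lo, ref_hi); returns named character vector (read ids)
cluster_read_windows <- function(cluster, aln, ref_lo, ref_hi,
                                 max_reads = 20L) {
  mem <- cluster$members
  recs <- unique(mem$rec[!is.na(mem$rec)])
  recs <- recs[recs >= 1L & recs <= nrow(aln)]
  out <- character(0)
  for (i in recs) {
    if (is.na(aln$seq[i])) next
    w <- cpp_read_window(aln$cigar[i], aln$ref_start[i], ref_lo, ref_hi)
    if (w[3] != 1L || w[1] < 0) next
    out[[aln$read_id[i]]] <- substr(aln$seq[i], w[1] + 1L, w[2])
    if (length(out) >= max_reads) break
  }
  out
}

#' Refine a cluster's breakpoint with a POA consensus
#'
#' On success the breakpoint is consensus-derived (precise); on PoaFailure /
#' RealignFailure, or when no SV of the cluster's type is found in the
#' consensus alignment, the rounded mean of the raw signals is kept
#' (imprecise).
#'
#' @param cluster "svd_cluster" (INS/DEL/DUP are refined; other types fall
#'   back to the mean immediately).
#' @param genome "svd_genome".
#' @param aln alignment table the cluster's signals came from.
#' @param flank flank length around the provisional breakpoint (bp).
#' @param min_signal_size minimum event size.
#' @return list(pos, size, end, precise, ins_seq) ("svd_refined").
#' @export
refine_breakpoints <- function(cluster, genome, aln, flank = 500L,
                               min_signal_size = 30L) {
  mem <- cluster$members
  pos0 <- round_half_up(mean(mem$pos))
  size0 <- round_half_up(mean(mem$size))
  fallback <- function() {
    ins <- NA_character_
    if (cluster$sv_type == "INS" && any(!is.na(mem$ins_seq))) {
      k <- which(!is.na(mem$ins_seq))
      ins <- mem$ins_seq[k[which.min(abs(mem$size[k] - size0))]]
    }
    structure(list(pos = pos0, size = size0, end = pos0 + size0,
                   precise = FALSE, ins_seq = ins), class = "svd_refined")
  }
  if (!cluster$sv_type %in% c("INS", "DEL", "DUP")) return(fallback())
  span <- if (cluster$sv_type == "INS") 0L else size0
  win_lo <- max(0L, pos0 - flank)
  win_hi <- min(genome$lengths[[cluster$chrom]], pos0 + span + flank)
  max_reads <- if (cluster$sv_type == "INS" && size0 > 3000L) 12L else 20L
  rw <- cluster_read_windows(cluster, aln, win_lo, win_hi, max_reads)
  cons <- build_poa_consensus(rw)
  if (is_failure(cons)) return(fallback())
  expect_len <- mean(nchar(rw))
  if (nchar(cons$seq) < 0.5 * expect_len) return(fallback())
  ref_lo <- max(0L, pos0 - (size0 + flank))
  ref_hi <- min(genome$lengths[[cluster$chrom]], pos0 + size0 + flank)
  det <- realign_local(cons, genome, cluster$chrom, ref_lo, ref_hi,
                       cluster$sv_type, min_signal_size)
  if (is_failure(det)) return(fallback())
  # sanity: refinement must stay near the cluster
  win_span <- max(1000L, cluster$window_end - cluster$window_start)
  if (abs(det$pos - pos0) > win_span) return(fallback())
  structure(list(pos = det$pos, size = det$size, end = det$pos + det$size,
                 precise = TRUE,
                 ins_seq = det$ins_seq %||% NA_character_),
            class = "svd_refined")
}
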