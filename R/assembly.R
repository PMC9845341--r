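# Large insertion detection via clip-anchored local assembly.
#
# Insertions longer than the reads cannot be spanned, but the reads entering
# the insertion from both sides are soft-clipped at the breakpoint. Clusters
# with at least N_supp long clips on each side trigger a local assembly: the
# clipped reads are anchored by their clip coordinate, laid out greedily
# against the longest read, polished by per-column majority voting, and the
# two side consensuses are merged across their overlap. The single resulting
# contig is realigned to the local reference and the detected insertion is
# kept when it is >= 1 kbp and within 1 kbp of the candidate breakpoint.

#' Find candidate large-insertion breakpoint regions
#'
#' Clips are grouped within a 1 kbp window; a group is kept only when it has
#' at least n_supp left clips and at least n_supp right clips.
#'
#' @param clips clip-signal data.frame from [record_clip_signals()].
#' @param n_supp depth-adaptive support threshold.
#' @param window grouping window (bp).
#' @return list of clip clusters: list(chrom, pos, region_start, region_end,
#'   left_members, right_members).
#' @export
find_clip_clusters <- function(clips, n_supp, window = 1000L) {
  if (nrow(clips) == 0L) return(list())
  out <- list()
  for (ch in unique(clips$chrom)) {
    sub <- clips[clips$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    grp <- cumsum(c(1L, diff(sub$pos) > window))
    for (g in unique(grp)) {
      mem <- sub[grp == g, , drop = FALSE]
      left <- mem[mem$side == "left", , drop = FALSE]
      right <- mem[mem$side == "right", , drop = FALSE]
      if (nrow(left) < n_supp || nrow(right) < n_supp) next
      out[[length(out) + 1L]] <- list(
        chrom = ch, pos = round_half_up(median(mem$pos)),
        region_start = min(mem$pos), region_end = max(mem$pos) + 1L,
        left_members = left, right_members = right
      )
    }
  }
  out
}

# Extract anchored assembly input for one side of a clip cluster.
# For right clips (reads entering the insertion from the left) the sequence
# is [up to flank_take bp of aligned flank][clip]; anchor = position of the
# clip point within the extracted sequence. Left clips analogous.
clip_windows <- function(members, aln, flank_take = 500L) {
  seqs <- character(0); anchors <- integer(0)
  for (k in seq_len(nrow(members))) {
    i <- members$rec[k]
    if (is.na(aln$seq[i])) next
    sl <- nchar(aln$seq[i])
    if (members$side[k] == "right") {
      clip_start <- sl - aln$trail_S[i]
      from <- max(0L, clip_start - flank_take)
      s <- substr(aln$seq[i], from + 1L, sl)
      anchor <- clip_start - from
    } else {
      clip_end <- aln$lead_S[i]
      to <- min(sl, clip_end + flank_take)
      s <- substr(aln$seq[i], 1L, to)
      anchor <- clip_end
    }
    id <- members$read_id[k]
    seqs[[id]] <- s
    anchors[[id]] <- anchor
  }
  list(seqs = seqs, anchors = anchors)
}

# Greedy anchored layout + pileup polish of one side. side = "right" means
# sequences are anchored at the clip point going rightward (prefixes of the
# insertion); "left" sequences are anchored at their right end and are
# reversed before polishing. Returns list of layouts, each
# list(seq, n_reads).
polish_side <- function(cw, side, band = 150L, min_ident = 0.55) {
  seqs <- cw$seqs; anchors <- cw$anchors
  if (length(seqs) == 0L) return(list())
  if (side == "left") {
    seqs <- vapply(seqs, function(s)
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
      character(1))
    anchors <- nchar(seqs) - anchors
  }
  layouts <- list()
  remaining <- seq_along(seqs)
  for (round in 1:3) {
    if (length(remaining) == 0L) break
    bb <- remaining[which.max(nchar(seqs[remaining]))]
    others <- setdiff(remaining, bb)
    if (length(others) == 0L) {
      layouts[[length(layouts) + 1L]] <-
        list(seq = seqs[[bb]], n_reads = 1L, anchor = anchors[[bb]])
      remaining <- integer(0)
      break
    }
    offs <- anchors[[bb]] - anchors[others]
    pp <- cpp_pileup_polish(seqs[[bb]], unname(seqs[others]),
                            as.integer(offs), as.integer(band), min_ident)
    used <- which(pp$used)
    layouts[[length(layouts) + 1L]] <- list(
      seq = pp$seq, n_reads = 1L + length(used), anchor = anchors[[bb]]
    )
    remaining <- setdiff(others, others[used])
  }
  if (side == "left") {
    layouts <- lapply(layouts, function(l) {
      l$seq <- paste(rev(strsplit(l$seq, "", fixed = TRUE)[[1]]),
                     collapse = "")
      l
    })
  }
  layouts
}

#' Locally assemble the clipped reads of one clip cluster
#'
#' Right-clip and left-clip reads are polished into a prefix and a suffix
#' consensus (clip-anchored layout, majority-vote polish), which are merged
#' across a k-mer-seeded overlap (>= min_overlap bp at >= 80% identity on
#' polished sequence). A successful merge yields one contig spanning both
#' flanks and the full insertion; otherwise the side consensuses are
#' returned as separate contigs. Reads that fail to join a layout are
#' retried as their own layouts; single-read layouts are dropped as
#' fragments unless they are the only input.
#'
#' @param cluster clip cluster from [find_clip_clusters()].
#' @param aln alignment table.
#' @param min_overlap minimum merge overlap (bp).
#' @param min_ident_raw read-to-backbone acceptance identity.
#' @return list of contigs: list(seq, n_reads, source_region).
#' @export
assemble_local <- function(cluster, aln, min_overlap = 200L,
                           min_ident_raw = 0.55) {
  cwr <- clip_windows(cluster$right_members, aln)
  cwl <- clip_windows(cluster$left_members, aln)
  n_input <- length(cwr$seqs) + length(cwl$seqs)
  lay_r <- polish_side(cwr, "right", min_ident = min_ident_raw)
  lay_l <- polish_side(cwl, "left", min_ident = min_ident_raw)
  region <- list(chrom = cluster$chrom, start = cluster$region_start,
                 end = cluster$region_end)
  finish <- function(lst) {
    keep <- Filter(function(l) l$n_reads >= 2L, lst)
    if (length(keep) == 0L && n_input == 1L) keep <- lst[1]
    lapply(keep, function(l)
      list(seq = l$seq, n_reads = l$n_reads, source_region = region))
  }
  main_r <- if (length(lay_r)) lay_r[[which.max(vapply(lay_r, function(l)
    l$n_reads, integer(1)))]] else NULL
  main_l <- if (length(lay_l)) lay_l[[which.max(vapply(lay_l, function(l)
    l$n_reads, integer(1)))]] else NULL
  extras <- c(Filter(function(l) !identical(l, main_r) && l$n_reads >= 2L,
                     lay_r),
              Filter(function(l) !identical(l, main_l) && l$n_reads >= 2L,
                     lay_l))
  if (is.null(main_r) || is.null(main_l))
    return(finish(c(lay_r, lay_l)))
  # merge prefix consensus (P) with suffix consensus (S)
  P <- main_r$seq; S <- main_l$seq
  sd <- cpp_seed_offset(P, S, 13L)
  merged <- NULL
  if (sd[2] >= 5L) {
    al <- cpp_align_banded_ident(S, P, sd[1], 400L)
    if (!is.na(al$score[1]) && al$n_cols >= min_overlap &&
        al$n_match / al$n_cols >= 0.8) {
      contig <- paste0(substr(P, 1L, al$b_start), substr(S, al$a_start + 1L,
                                                         nchar(S)))
      merged <- list(seq = contig, n_reads = main_r$n_reads + main_l$n_reads)
    }
  }
  if (is.null(merged)) return(finish(c(lay_r, lay_l)))
  finish(c(list(merged), extras))
}

#' Call a large insertion from an assembled contig
#'
#' Applies the published filters: the call is dropped when (1) more than one
#' contig was assembled, (2) the detected insertion is on another chromosome
#' or more than 1 kbp from the candidate breakpoint, or (3) the insertion is
#' smaller than 1 kbp.
#'
#' @param cluster clip cluster.
#' @param contigs contig list from [assemble_local()].
#' @param genome "svd_genome".
#' @param realign_flank reference window half-width for contig realignment.
#' @return one-row SV call data.frame, or NULL.
#' @export
call_large_insertion <- function(cluster, contigs, genome,
                                 realign_flank = 5000L) {
  if (length(contigs) != 1L) return(NULL)
  contig <- contigs[[1]]
  lo <- max(0L, cluster$pos - realign_flank)
  hi <- min(genome$lengths[[cluster$chrom]], cluster$pos + realign_flank)
  refseq <- seq_fetch(genome, cluster$chrom, lo, hi)
  al <- cpp_align_ins(contig$seq, refseq, 2L, -4L, -4L, -24L)
  gl <- al$q_gap_end - al$q_gap_start
  if (al$q_gap_start < 0 || gl < 1000L) return(NULL)
  aligned <- nchar(contig$seq) - gl
  if (al$score < 0.5 * aligned) return(NULL)
  pos <- lo + al$ref_pos
  if (abs(pos - cluster$pos) > 1000L) return(NULL)
  content <- substr(contig$seq, al$q_gap_start + 1L, al$q_gap_end)
  nrm <- normalize_ins_left(refseq, lo, pos, content)
  n_reads <- length(unique(c(cluster$left_members$read_id,
                             cluster$right_members$read_id)))
  data.frame(
    sv_type = "INS", chrom = cluster$chrom, pos = nrm$pos, size = gl,
    end = nrm$pos, chrom2 = NA_character_, pos2 = NA_integer_,
    n_supp_reads = n_reads,
    mapq_mean = mean(c(cluster$left_members$mapq,
                       cluster$right_members$mapq)),
    precise = TRUE, ins_seq = nrm$content, source = "assembly",
    stringsAsFactors = FALSE
  )
}
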