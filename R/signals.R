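# Raw SV signal detection.
#
# Two signal sources: intra-alignment (I/D CIGAR operations within one
# record) and inter-alignment (split reads: adjacent segment pairs in read
# coordinates). Long clipped ends (>= 200 bp) are recorded separately as
# candidate evidence for insertions longer than the reads.

#' Extract intra-alignment SV signals
#'
#' One INS signal per CIGAR insertion >= min_signal_size (position = reference
#' coordinate of the insertion point), one DEL per D/N operation >=
#' min_signal_size. Same-type operations are merged when the intervening gap
#' (read gap for I, reference gap for D) is at most
#' max(100, 0.5 x summed size); aligners fragment single events in noisy
#' reads. Records with MAPQ 0 and secondary records yield no signals.
#'
#' @param aln alignment table.
#' @param min_signal_size minimum raw-signal size in bp (default 30).
#' @return raw-signal data.frame (sv_type, chrom, pos, size, read_id, source,
#'   ins_seq, mapq, rec).
#' @export
extract_intra_signals <- function(aln, min_signal_size = 30L) {
  keep <- !aln$is_secondary & aln$mapq > 0L
  idx <- which(keep)
  if (length(idx) == 0L) return(new_signal_df())
  sub <- aln[idx, , drop = FALSE]
  raw <- cpp_intra_signals(sub$cigar, sub$ref_start, sub$seq,
                           as.integer(min_signal_size))
  if (nrow(raw) == 0L) return(new_signal_df())
  rec <- idx[raw$rec]
  out <- new_signal_df(nrow(raw))
  out$sv_type <- ifelse(raw$type == 1L, "INS", "DEL")
  out$chrom <- aln$chrom[rec]
  out$pos <- raw$pos
  out$size <- raw$size
  out$read_id <- aln$read_id[rec]
  out$source <- "intra"
  out$ins_seq <- raw$ins_seq
  out$mapq <- aln$mapq[rec]
  out$chrom2 <- NA_character_
  out$pos2 <- NA_integer_
  out$inv_end <- NA_integer_
  out$rec <- rec
  out
}

# read-orientation span of each record's aligned block
aln_read_spans <- function(aln) {
  cpp_read_span(aln$read_len, aln$left_clip, aln$right_clip,
                aln$strand == "+")
}

#' Classify one adjacent split-read segment pair
#'
#' Priority: different chromosomes -> TRA; different strands -> INV;
#' otherwise the read-gap g and reference-gap r decide: DEL when r - g >=
#' min_signal_size, INS when g - r >= min_signal_size, DUP when the segments
#' overlap on the reference by at least min_signal_size.
#'
#' @param seg_a,seg_b single-row alignment-table slices of the same read,
#'   ordered by read coordinate (seg_a first). Each needs the extra columns
#'   read_start/read_end (read-orientation coordinates).
#' @param min_signal_size minimum size (bp).
#' @param read_seq full read sequence in read orientation (optional, for INS
#'   content).
#' @return one-row raw-signal data.frame, or NULL.
#' @export
classify_split_pair <- function(seg_a, seg_b, min_signal_size = 30L,
                                read_seq = NULL) {
  if (seg_a$read_id != seg_b$read_id)
    stop("classify_split_pair: segments from different reads")
  if (seg_a$mapq == 0L && seg_b$mapq == 0L) return(NULL)
  mq <- min(seg_a$mapq, seg_b$mapq)
  sig <- new_signal_df(1L)
  sig$read_id <- seg_a$read_id
  sig$source <- "split"
  sig$mapq <- mq
  sig$ins_seq <- NA_character_
  sig$chrom2 <- NA_character_
  sig$pos2 <- NA_integer_
  sig$inv_end <- NA_integer_
  sig$rec <- NA_integer_
  # junction coordinate in traversal order
  j_a <- if (seg_a$strand == "+") seg_a$ref_end else seg_a$ref_start
  j_b <- if (seg_b$strand == "+") seg_b$ref_start else seg_b$ref_end
  if (seg_a$chrom != seg_b$chrom) {
    # canonical breakpoint order
    if (seg_a$chrom < seg_b$chrom) {
      sig$sv_type <- "TRA"; sig$chrom <- seg_a$chrom; sig$pos <- j_a
      sig$chrom2 <- seg_b$chrom; sig$pos2 <- j_b
    } else {
      sig$sv_type <- "TRA"; sig$chrom <- seg_b$chrom; sig$pos <- j_b
      sig$chrom2 <- seg_a$chrom; sig$pos2 <- j_a
    }
    sig$size <- 0L
    return(sig)
  }
  if (seg_a$strand != seg_b$strand) {
    sig$sv_type <- "INV"
    sig$chrom <- seg_a$chrom
    sig$pos <- min(j_a, j_b)
    sig$inv_end <- max(j_a, j_b)
    sig$size <- sig$inv_end - sig$pos
    if (sig$size < min_signal_size) return(NULL)
    return(sig)
  }
  g <- seg_b$read_start - seg_a$read_end
  r <- if (seg_a$strand == "+") seg_b$ref_start - seg_a$ref_end
       else seg_a$ref_start - seg_b$ref_end
  sig$chrom <- seg_a$chrom
  if (r - g >= min_signal_size) {
    sig$sv_type <- "DEL"
    sig$pos <- if (seg_a$strand == "+") seg_a$ref_end else seg_b$ref_end
    sig$size <- r - g
    return(sig)
  }
  if (g - r >= min_signal_size && g > 0) {
    sig$sv_type <- "INS"
    sig$pos <- if (seg_a$strand == "+") seg_a$ref_end else seg_b$ref_end
    sig$size <- g - r
    if (!is.null(read_seq) && !is.na(read_seq)) {
      ins <- substr(read_seq, seg_a$read_end + 1L, seg_b$read_start)
      if (seg_a$strand == "-") ins <- cpp_revcomp(ins)
      sig$ins_seq <- ins
    }
    return(sig)
  }
  if (r < 0 && -r >= min_signal_size) {
    sig$sv_type <- "DUP"
    sig$pos <- if (seg_a$strand == "+") seg_b$ref_start else seg_a$ref_start
    sig$size <- -r
    return(sig)
  }
  NULL
}

#' Extract split-read signals for one read
#'
#' Sorts the read's segments by read coordinate and classifies each adjacent
#' pair.
#'
#' @param segments alignment-table rows of one read (primary +
#'   supplementary), with read_start/read_end columns already attached.
#' @param min_signal_size minimum size (bp).
#' @return raw-signal data.frame (possibly empty).
#' @export
extract_split_signals <- function(segments, min_signal_size = 30L) {
  n <- nrow(segments)
  if (n < 2L) return(new_signal_df())
  ord <- order(segments$read_start)
  segments <- segments[ord, , drop = FALSE]
  # read sequence in read orientation, from any record that has it
  read_seq <- NA_character_
  wi <- which(!is.na(segments$seq) &
                nchar(segments$seq) == segments$read_len)
  if (length(wi)) {
    w <- wi[1]
    read_seq <- if (segments$strand[w] == "+") segments$seq[w]
                else cpp_revcomp(segments$seq[w])
  }
  out <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    out[[k]] <- classify_split_pair(segments[k, ], segments[k + 1L, ],
                                    min_signal_size, read_seq)
  }
  res <- rbind_dfs(out)
  if (is.null(res)) new_signal_df() else res
}

# split signals across a whole alignment table
split_signals_all <- function(aln, min_signal_size = 30L) {
  use <- which(!aln$is_secondary)
  if (length(use) == 0L) return(new_signal_df())
  ids <- aln$read_id[use]
  multi <- names(which(table(ids) >= 2L))
  if (length(multi) == 0L) return(new_signal_df())
  spans <- aln_read_spans(aln)
  aln$read_start <- spans[, 1]
  aln$read_end <- spans[, 2]
  parts <- lapply(multi, function(id) {
    segs <- aln[use[ids == id], , drop = FALSE]
    extract_split_signals(segs, min_signal_size)
  })
  res <- rbind_dfs(parts)
  if (is.null(res)) new_signal_df() else res
}

#' Record long clipped alignment ends
#'
#' Alignments with >= clip_min unaligned bases on a side are "clipped"; a clip
#' already explained by another segment of the same read (the clipped portion
#' maps elsewhere as a supplementary) is suppressed.
#'
#' @param aln alignment table.
#' @param clip_min minimum clip length (default 200 bp).
#' @return data.frame(chrom, pos, side, read_id, clip_len, clip_seq, rec).
#' @export
record_clip_signals <- function(aln, clip_min = 200L) {
  keep <- !aln$is_secondary & aln$mapq > 0L
  cand <- which(keep & (aln$left_clip >= clip_min | aln$right_clip >= clip_min))
  if (length(cand) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      side = character(0), read_id = character(0),
                      clip_len = integer(0), clip_seq = character(0),
                      mapq = integer(0), rec = integer(0),
                      stringsAsFactors = FALSE))
  }
  spans <- aln_read_spans(aln)
  # integer-indexed segment lists per read (for clip suppression)
  grp_levels <- unique(aln$read_id[cand])
  grp_all <- match(aln$read_id, grp_levels)
  in_grp <- which(keep & !is.na(grp_all))
  seg_by_grp <- split(in_grp, factor(grp_all[in_grp],
                                     levels = seq_along(grp_levels)))
  clip_interval <- function(i, side) {
    # read-orientation interval occupied by the clip
    L <- aln$read_len[i]
    if (side == "left") {
      if (aln$strand[i] == "+") c(0L, aln$left_clip[i])
      else c(L - aln$left_clip[i], L)
    } else {
      if (aln$strand[i] == "+") c(L - aln$right_clip[i], L)
      else c(0L, aln$right_clip[i])
    }
  }
  covered_frac <- function(iv, others) {
    if (length(others) == 0L || iv[2] <= iv[1]) return(0)
    cov <- 0L
    for (o in others) {
      lo <- max(iv[1], spans[o, 1]); hi <- min(iv[2], spans[o, 2])
      if (hi > lo) cov <- cov + (hi - lo)
    }
    cov / (iv[2] - iv[1])
  }
  out <- list()
  for (i in cand) {
    others <- setdiff(seg_by_grp[[grp_all[i]]], i)
    for (side in c("left", "right")) {
      cl <- if (side == "left") aln$left_clip[i] else aln$right_clip[i]
      if (cl < clip_min) next
      iv <- clip_interval(i, side)
      if (covered_frac(iv, others) >= 0.5) next
      cs <- NA_character_
      if (!is.na(aln$seq[i])) {
        # clip sequence in stored (reference) orientation
        if (side == "left") {
          if (aln$lead_S[i] >= cl)
            cs <- substr(aln$seq[i], aln$left_clip[i] - cl + 1L, aln$left_clip[i])
        } else {
          ln <- nchar(aln$seq[i])
          if (aln$trail_S[i] >= cl)
            cs <- substr(aln$seq[i], ln - aln$right_clip[i] + 1L,
                         ln - aln$right_clip[i] + cl)
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = aln$chrom[i],
        pos = if (side == "left") aln$ref_start[i] else aln$ref_end[i],
        side = side, read_id = aln$read_id[i], clip_len = cl, clip_seq = cs,
        mapq = aln$mapq[i], rec = i, stringsAsFactors = FALSE
      )
    }
  }
  res <- rbind_dfs(out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), pos = integer(0),
                      side = character(0), read_id = character(0),
                      clip_len = integer(0), clip_seq = character(0),
                      mapq = integer(0), rec = integer(0),
                      stringsAsFactors = FALSE)
  }
  res
}

#' Estimate sequencing depth and the support threshold
#'
#' Records the total aligned read length per chromosome, the genome-average
#' depth, and the depth-adaptive minimum supporting-read count
#' N_supp = floor(depth / 10) + 2.
#'
#' @param aln alignment table (secondary records are excluded).
#' @param genome "svd_genome" object (or list with a lengths element).
#' @return object of class "svd_depth_profile".
#' @export
estimate_depth <- function(aln, genome) {
  keep <- !aln$is_secondary
  ab <- tapply(aln$aligned_read[keep], aln$chrom[keep], sum)
  per_chrom <- setNames(rep(0, length(genome$lengths)), names(genome$lengths))
  per_chrom[names(ab)] <- as.numeric(ab)
  mean_depth <- sum(per_chrom) / sum(as.numeric(genome$lengths))
  structure(list(
    per_chrom_aligned_bases = per_chrom,
    chrom_lengths = genome$lengths,
    mean_depth = mean_depth,
    n_supp = compute_nsupp(mean_depth)
  ), class = "svd_depth_profile")
}

#' @export
print.svd_depth_profile <- function(x, ...) {
  cat(sprintf("svd_depth_profile: mean depth %.2fx over %d chromosome(s), N_supp = %d\n",
              x$mean_depth, length(x$chrom_lengths), x$n_supp))
  invisible(x)
}
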