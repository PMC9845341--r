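# Read simulation and oracle alignment emission.

#' Simulate error-model long reads from the two haplotypes
#'
#' Read lengths follow a gamma distribution with the configured mean and
#' shape; start positions are uniform per haplotype chromosome; per-base
#' errors (substitution / insertion / deletion) follow the preset rates.
#' Reads are drawn until the target depth is reached, so the achieved depth
#' is within a read length of the target. Fully seeded.
#'
#' @param sim result of [apply_svs_to_genome()].
#' @param cfg "svd_sim_config".
#' @return "svd_readset": list(reads = data.frame(read_id, hap, chrom,
#'   start, len, strand), edits = per-read list(sub_pos, sub_k, ins_pos,
#'   ins_k, del_pos), cfg).
#' @export
simulate_reads <- function(sim, cfg) {
  set.seed(cfg$seed + 7919L)
  er <- cfg$error_rates
  e_tot <- sum(er)
  reads <- list()
  edits <- list()
  rid <- 0L
  for (hap in c("1", "2")) {
    for (ch in names(sim$haps[[hap]])) {
      hlen <- nchar(sim$haps[[hap]][[ch]])
      target <- cfg$depth_per_hap * hlen
      got <- 0
      while (got < target) {
        n_draw <- max(16L, ceiling((target - got) / cfg$read_mean))
        lens <- pmin(pmax(round(rgamma(n_draw, shape = cfg$read_shape,
                                       scale = cfg$read_mean /
                                         cfg$read_shape)), 200L), hlen)
        for (L in lens) {
          if (got >= target) break
          rid <- rid + 1L
          start <- floor(runif(1, 0, hlen - L + 1))
          strand <- if (runif(1) < 0.5) "+" else "-"
          n_err <- rbinom(1L, L, e_tot)
          ed <- list(sub_pos = integer(0), sub_k = integer(0),
                     ins_pos = integer(0), ins_k = integer(0),
                     del_pos = integer(0))
          if (n_err > 0L) {
            pos <- sort(sample.int(L, n_err)) - 1L
            ty <- sample.int(3L, n_err, replace = TRUE, prob = er / e_tot)
            ed$sub_pos <- pos[ty == 1L]
            ed$sub_k <- sample.int(3L, length(ed$sub_pos),
                                   replace = TRUE) - 1L
            ed$ins_pos <- pos[ty == 2L]
            ed$ins_k <- sample.int(4L, length(ed$ins_pos),
                                   replace = TRUE) - 1L
            ed$del_pos <- pos[ty == 3L]
          }
          reads[[rid]] <- list(read_id = sprintf("r%06d", rid), hap = hap,
                               chrom = ch, start = as.integer(start),
                               len = as.integer(L), strand = strand)
          edits[[rid]] <- ed
          got <- got + L
        }
      }
    }
  }
  df <- data.frame(
    read_id = vapply(reads, `[[`, "", "read_id"),
    hap = vapply(reads, `[[`, "", "hap"),
    chrom = vapply(reads, `[[`, "", "chrom"),
    start = vapply(reads, `[[`, 0L, "start"),
    len = vapply(reads, `[[`, 0L, "len"),
    strand = vapply(reads, `[[`, "", "strand"),
    stringsAsFactors = FALSE
  )
  structure(list(reads = df, edits = edits, cfg = cfg),
            class = "svd_readset")
}

BASES <- c("A", "C", "G", "T")

# deterministic error bases: substitution picks one of the 3 other bases by
# the pre-drawn index k; insertions use the pre-drawn base index directly
edit_bases <- function(clean, ed) {
  sub_base <- character(0)
  if (length(ed$sub_pos)) {
    orig <- match(substring(clean, ed$sub_pos + 1L, ed$sub_pos + 1L),
                  BASES)
    orig[is.na(orig)] <- 1L
    sub_base <- BASES[((orig - 1L + 1L + ed$sub_k) %% 4L) + 1L]
  }
  ins_base <- if (length(ed$ins_pos)) BASES[ed$ins_k + 1L] else character(0)
  list(sub_base = sub_base, ins_base = ins_base)
}

# split the clean-read interval [s, e) into liftover runs
read_runs <- function(lift_tab, s, e) {
  i0 <- findInterval(s, lift_tab$hap_start)
  i1 <- findInterval(e - 1L, lift_tab$hap_start)
  runs <- lift_tab[i0:i1, , drop = FALSE]
  rs <- pmax(runs$hap_start, s); re_ <- pmin(runs$hap_end, e)
  keep <- re_ > rs
  runs <- runs[keep, , drop = FALSE]
  rs <- rs[keep]; re_ <- re_[keep]
  runs$read_start <- rs - s
  runs$read_end <- re_ - s
  # run reference interval restricted to the covered part
  off_lo <- rs - runs$hap_start
  off_hi <- runs$hap_end - re_
  fwd <- runs$strand == "+"
  runs$run_ref_start <- ifelse(fwd, runs$ref_start + off_lo,
                               runs$ref_start + off_hi)
  runs$run_ref_end <- ifelse(fwd, runs$ref_end - off_hi,
                             runs$ref_end - off_lo)
  runs
}

# group runs into alignment segments; returns list of segments with ops in
# clean-read order
segment_runs <- function(runs, min_anchor = 50L) {
  segs <- list()
  cur <- NULL
  pending_I <- 0L
  close_seg <- function() {
    if (!is.null(cur) &&
        (cur$ref_end - cur$ref_start) >= min_anchor)
      segs[[length(segs) + 1L]] <<- cur
    cur <<- NULL
    pending_I <<- 0L
  }
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    if (r$kind == "I") {
      if (!is.null(cur)) pending_I <- pending_I + (r$read_end - r$read_start)
      next
    }
    rl <- r$run_ref_end - r$run_ref_start
    if (is.null(cur)) {
      cur <- list(chrom = r$chrom, strand = r$strand,
                  read_start = r$read_start, read_end = r$read_end,
                  ref_start = r$run_ref_start, ref_end = r$run_ref_end,
                  op = 0L, len = rl)
      pending_I <- 0L
      next
    }
    gap <- if (cur$strand == "+") r$run_ref_start - cur$ref_end
           else cur$ref_start - r$run_ref_end
    same <- r$chrom == cur$chrom && r$strand == cur$strand && gap >= 0L
    if (!same) {
      close_seg()
      cur <- list(chrom = r$chrom, strand = r$strand,
                  read_start = r$read_start, read_end = r$read_end,
                  ref_start = r$run_ref_start, ref_end = r$run_ref_end,
                  op = 0L, len = rl)
      pending_I <- 0L
      next
    }
    if (pending_I > 0L) {
      cur$op <- c(cur$op, 1L); cur$len <- c(cur$len, pending_I)
      pending_I <- 0L
    }
    if (gap > 0L) { cur$op <- c(cur$op, 2L); cur$len <- c(cur$len, gap) }
    cur$op <- c(cur$op, 0L); cur$len <- c(cur$len, rl)
    cur$read_end <- r$read_end
    if (cur$strand == "+") cur$ref_end <- r$run_ref_end
    else cur$ref_start <- r$run_ref_start
  }
  close_seg()
  segs
}

#' Emit oracle alignments computed from the known read placement
#'
#' Each read's alignment is derived by composing its simulated error edits
#' with the haplotype-to-reference liftover: reads crossing a deletion or a
#' spanned insertion get the corresponding D/I CIGAR operations; reads
#' crossing inversion, duplication or translocation junctions are split
#' into primary + supplementary records with correct SA tags; reads ending
#' inside long insertions are soft-clipped. Aligned segments shorter than
#' min_anchor are clipped away; reads entirely inside inserted sequence are
#' unmapped and dropped. MAPQ is 60 throughout.
#'
#' @param readset "svd_readset" from [simulate_reads()].
#' @param sim result of [apply_svs_to_genome()].
#' @param min_anchor minimum aligned reference span per segment (bp).
#' @return alignment table.
#' @export
emit_oracle_alignments <- function(readset, sim, min_anchor = 50L) {
  reads <- readset$reads
  n <- nrow(reads)
  acc <- vector("list", n)
  for (k in seq_len(n)) {
    rd <- reads[k, ]
    lift_tab <- sim$lift[[rd$hap]][[rd$chrom]]
    s <- rd$start; e <- s + rd$len
    runs <- read_runs(lift_tab, s, e)
    segs <- segment_runs(runs, min_anchor)
    if (length(segs) == 0L) next
    ed <- readset$edits[[k]]
    clean <- substr(sim$haps[[rd$hap]][[rd$chrom]], s + 1L, e)
    eb <- edit_bases(clean, ed)
    errored <- cpp_apply_edits_seq(clean, ed$sub_pos, eb$sub_base,
                                   ed$ins_pos, eb$ins_base, ed$del_pos)
    err_rc <- NULL
    nseg <- length(segs)
    recs <- vector("list", nseg)
    for (si in seq_len(nseg)) {
      sg <- segs[[si]]
      # full clean-coordinate op list including soft clips
      op <- c(if (sg$read_start > 0L) 3L, sg$op,
              if (rd$len - sg$read_end > 0L) 3L)
      ln <- c(if (sg$read_start > 0L) sg$read_start, sg$len,
              if (rd$len - sg$read_end > 0L) rd$len - sg$read_end)
      inj <- cpp_inject_edits_ops(as.integer(op), as.integer(ln), 0L,
                                  ed$ins_pos, ed$del_pos)
      oo <- inj$op; ol <- inj$len
      if (sg$strand == "-") { oo <- rev(oo); ol <- rev(ol) }
      seq_out <- if (sg$strand == "+") errored else {
        if (is.null(err_rc)) err_rc <- cpp_revcomp(errored)
        err_rc
      }
      recs[[si]] <- list(chrom = sg$chrom, strand = sg$strand,
                         ref_start = sg$ref_start,
                         cigar = cpp_ops_to_cigar(oo, ol), seq = seq_out,
                         aligned = sum(ol[oo == 0L | oo == 1L]))
    }
    prim <- which.max(vapply(recs, `[[`, 0, "aligned"))
    sa_of <- function(j) {
      r <- recs[[j]]
      sprintf("%s,%d,%s,%s,60,0", r$chrom, r$ref_start + 1L, r$strand,
              r$cigar)
    }
    rows <- vector("list", nseg)
    for (si in seq_len(nseg)) {
      r <- recs[[si]]
      others <- setdiff(seq_len(nseg), si)
      sa <- if (length(others))
        paste0(paste(vapply(others, sa_of, ""), collapse = ";"), ";")
        else NA_character_
      # read-level strand flips the record strand flag
      rec_strand <- if (rd$strand == "+") r$strand
                    else if (r$strand == "+") "-" else "+"
      rows[[si]] <- data.frame(
        read_id = rd$read_id, chrom = r$chrom, ref_start = r$ref_start,
        strand = rec_strand, mapq = 60L, cigar = r$cigar, seq = r$seq,
        is_supplementary = si != prim, is_secondary = FALSE, sa = sa,
        stringsAsFactors = FALSE
      )
    }
    acc[[k]] <- do.call(rbind, rows)
  }
  out <- rbind_dfs(acc)
  if (is.null(out)) stop("no reads could be aligned")
  alignment_table(out)
}

#' One-call simulation of a complete dataset
#'
#' Synthesizes (or accepts) a genome, samples the truth set, builds the
#' haplotypes, simulates reads and emits oracle alignments.
#'
#' @param cfg "svd_sim_config".
#' @param genome optional "svd_genome"; default: random synthetic genome of
#'   cfg$chrom_lengths.
#' @return list(genome, truth, sim, readset, aln).
#' @export
simulate_dataset <- function(cfg, genome = NULL) {
  if (is.null(genome)) genome <- synthetic_genome(cfg$chrom_lengths,
                                                  cfg$seed + 104729L)
  truth <- sample_sv_set(cfg)
  sim <- apply_svs_to_genome(genome, truth)
  readset <- simulate_reads(sim, cfg)
  aln <- emit_oracle_alignments(readset, sim)
  list(genome = genome, truth = sim$truth, sim = sim, readset = readset,
       aln = aln)
}

#' Write simulated reads as FASTQ
#'
#' Reads on the minus strand are written reverse-complemented (the physical
#' read); base qualities are flat.
#'
#' @param readset "svd_readset".
#' @param sim result of [apply_svs_to_genome()].
#' @param path output path.
#' @export
write_fastq <- function(readset, sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(readset$reads))) {
    rd <- readset$reads[k, ]
    ed <- readset$edits[[k]]
    clean <- substr(sim$haps[[rd$hap]][[rd$chrom]], rd$start + 1L,
                    rd$start + rd$len)
    eb <- edit_bases(clean, ed)
    seq <- cpp_apply_edits_seq(clean, ed$sub_pos, eb$sub_base, ed$ins_pos,
                               eb$ins_base, ed$del_pos)
    if (rd$strand == "-") seq <- cpp_revcomp(seq)
    writeLines(c(paste0("@", rd$read_id), seq, "+",
                 strrep("I", nchar(seq))), con)
  }
  invisible(path)
}

#' Write a truth set as TSV (BED-like) and VCF
#'
#' @param truth truth data.frame.
#' @param genome "svd_genome".
#' @param tsv_path,vcf_path output paths (NULL skips).
#' @export
write_truth <- function(truth, genome, tsv_path = NULL, vcf_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- truth
    df$end <- ifelse(df$sv_type == "INS", df$pos, df$pos + df$size)
    utils::write.table(df[, c("chrom", "pos", "end", "sv_type", "size",
                              "zygosity", "haplotype", "chrom2", "pos2")],
                       tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(vcf_path)) {
    calls <- data.frame(
      sv_type = truth$sv_type, chrom = truth$chrom, pos = truth$pos,
      size = truth$size,
      end = ifelse(truth$sv_type == "INS", truth$pos,
                   truth$pos + truth$size),
      chrom2 = truth$chrom2, pos2 = truth$pos2,
      n_supp_reads = 0L, local_depth = NA_real_,
      genotype = ifelse(truth$zygosity == "hom", "1/1", "0/1"),
      precise = TRUE, ins_seq = truth$ins_seq, mapq_mean = 60,
      locus_id = seq_len(nrow(truth)), allele_index = 0L, filter = "PASS",
      stringsAsFactors = FALSE
    )
    write_vcf(calls, genome, vcf_path)
  }
  invisible(truth)
}
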