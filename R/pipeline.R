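# End-to-end SV calling pipeline.

#' Caller options
#'
#' @param min_signal_size minimum raw-signal size (bp); sub-call-threshold
#'   fragments are collected so merged events can reach min_sv_size.
#' @param min_sv_size minimum reported SV size (bp).
#' @param mapq_min minimum mean MAPQ of supporting segments.
#' @param clip_min minimum clip length for large-insertion evidence (bp).
#' @param n_supp explicit support threshold; NULL uses floor(depth/10)+2.
#' @param refine run POA breakpoint refinement.
#' @param assembly run the large-insertion local-assembly module.
#' @param rescue_dup run the duplication-rescue step on insertion calls.
#' @param hom_ratio support-ratio cutoff for homozygous genotypes.
#' @param flank refinement flank (bp).
#' @return list of options.
#' @export
sv_opts <- function(min_signal_size = 30L, min_sv_size = 45L, mapq_min = 20,
                    clip_min = 200L, n_supp = NULL, refine = TRUE,
                    assembly = TRUE, rescue_dup = TRUE, hom_ratio = 0.75,
                    flank = 500L) {
  list(min_signal_size = min_signal_size, min_sv_size = min_sv_size,
       mapq_min = mapq_min, clip_min = clip_min, n_supp = n_supp,
       refine = refine, assembly = assembly, rescue_dup = rescue_dup,
       hom_ratio = hom_ratio, flank = flank)
}

# cluster all raw signals into candidate clusters
cluster_signals <- function(signals, n_supp) {
  clusters <- list()
  std <- signals[signals$sv_type %in% c("INS", "DEL", "DUP", "INV"), ,
                 drop = FALSE]
  if (nrow(std)) {
    for (key in unique(paste(std$sv_type, std$chrom))) {
      parts <- strsplit(key, " ", fixed = TRUE)[[1]]
      sub <- std[std$sv_type == parts[1] & std$chrom == parts[2], ,
                 drop = FALSE]
      cls <- density_cluster(sub, n_supp)
      for (cl in cls) clusters <- c(clusters, split_multiallele(cl))
    }
  }
  tra <- signals[signals$sv_type == "TRA", , drop = FALSE]
  if (nrow(tra)) clusters <- c(clusters, cluster_translocations(tra, n_supp))
  clusters
}

cluster_to_call <- function(cluster, ref, locus_id) {
  mem <- cluster$members
  n_reads <- length(unique(mem$read_id))
  if (cluster$sv_type == "TRA") {
    pos <- round_half_up(mean(mem$pos))
    pos2 <- round_half_up(mean(mem$pos2))
    return(data.frame(
      sv_type = "TRA", chrom = cluster$chrom, pos = pos, size = 0L,
      end = pos, chrom2 = mem$chrom2[1], pos2 = pos2,
      n_supp_reads = n_reads, local_depth = NA_real_, genotype = "./.",
      precise = FALSE, ins_seq = NA_character_, mapq_mean = mean(mem$mapq),
      locus_id = locus_id, allele_index = 0L, filter = "PASS",
      stringsAsFactors = FALSE
    ))
  }
  data.frame(
    sv_type = cluster$sv_type, chrom = cluster$chrom, pos = ref$pos,
    size = ref$size, end = ref$end, chrom2 = NA_character_,
    pos2 = NA_integer_, n_supp_reads = n_reads, local_depth = NA_real_,
    genotype = "./.", precise = ref$precise,
    ins_seq = ref$ins_seq %||% NA_character_, mapq_mean = mean(mem$mapq),
    locus_id = locus_id, allele_index = cluster$allele_index,
    filter = "PASS", stringsAsFactors = FALSE
  )
}

#' Call structural variants from long-read alignments
#'
#' Runs the full pipeline: raw signal extraction (intra-alignment +
#' split-read), depth estimation, density-based clustering with multi-allele
#' separation, POA breakpoint refinement, clip-cluster local assembly for
#' read-length-exceeding insertions, depth-adaptive filtering, genotyping
#' and duplication rescue.
#'
#' @param aln alignment table (from [read_alignments()] or
#'   [emit_oracle_alignments()]), or a SAM/BAM path.
#' @param genome "svd_genome" object or FASTA path.
#' @param opts options from [sv_opts()].
#' @return object of class "svd_callset": list(calls, profile, n_signals,
#'   clusters).
#' @export
sv_call <- function(aln, genome, opts = sv_opts()) {
  if (is.character(aln)) aln <- read_alignments(aln)
  if (is.character(genome)) genome <- read_fasta(genome)
  profile <- estimate_depth(aln, genome)
  n_supp <- opts$n_supp %||% profile$n_supp
  sig_intra <- extract_intra_signals(aln, opts$min_signal_size)
  sig_split <- split_signals_all(aln, opts$min_signal_size)
  signals <- rbind_dfs(list(sig_intra, sig_split))
  if (is.null(signals)) signals <- new_signal_df()
  clusters <- cluster_signals(signals, n_supp)
  calls <- list()
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    ref <- if (opts$refine) {
      refine_breakpoints(cl, genome, aln, opts$flank, opts$min_signal_size)
    } else {
      mem <- cl$members
      pos0 <- round_half_up(mean(mem$pos))
      size0 <- round_half_up(mean(mem$size))
      ins <- NA_character_
      if (cl$sv_type == "INS" && any(!is.na(mem$ins_seq))) {
        ki <- which(!is.na(mem$ins_seq))
        ins <- mem$ins_seq[ki[which.min(abs(mem$size[ki] - size0))]]
      }
      list(pos = pos0, size = size0, end = pos0 + size0, precise = FALSE,
           ins_seq = ins)
    }
    calls[[k]] <- cluster_to_call(cl, ref, k)
  }
  calls <- rbind_dfs(calls)
  if (is.null(calls)) calls <- empty_calls()
  # large-insertion module
  if (opts$assembly) {
    clips <- record_clip_signals(aln, opts$clip_min)
    ccl <- find_clip_clusters(clips, n_supp)
    for (cc in ccl) {
      contigs <- assemble_local(cc, aln)
      bigins <- call_large_insertion(cc, contigs, genome)
      if (is.null(bigins)) next
      bigins$local_depth <- NA_real_
      bigins$genotype <- "./."
      bigins$locus_id <- max(c(0L, calls$locus_id)) + 1L
      bigins$allele_index <- 0L
      bigins$filter <- "PASS"
      bigins$end <- bigins$pos
      bigins <- bigins[, names(empty_calls())]
      # dedup: an insertion already called within 1 kbp at 0.5-2x size is
      # replaced (the assembly size is kept)
      dup <- which(calls$sv_type == "INS" & calls$chrom == bigins$chrom &
                     abs(calls$pos - bigins$pos) <= 1000L &
                     calls$size >= 0.5 * bigins$size &
                     calls$size <= 2 * bigins$size)
      if (length(dup)) {
        bigins$n_supp_reads <- max(bigins$n_supp_reads,
                                   calls$n_supp_reads[dup])
        calls <- calls[-dup, , drop = FALSE]
      }
      calls <- rbind(calls, bigins)
    }
  }
  # size floor (TRA exempt), then depth filter + genotyping
  calls <- calls[calls$sv_type == "TRA" | calls$size >= opts$min_sv_size, ,
                 drop = FALSE]
  calls <- filter_candidates(calls, profile, opts$mapq_min, opts$n_supp)
  nb <- calls$sv_type != "TRA"
  calls$local_depth[nb] <- local_depth_at(calls[nb, , drop = FALSE], aln)
  calls <- genotype_calls(calls, opts$hom_ratio)
  # duplication rescue on INS calls
  if (opts$rescue_dup && nrow(calls)) {
    for (i in which(calls$sv_type == "INS" & calls$filter == "PASS")) {
      cl_id <- calls$locus_id[i]
      seqs <- character(0)
      if (cl_id <= length(clusters) &&
          !is.null(clusters[[cl_id]]$members$ins_seq))
        seqs <- clusters[[cl_id]]$members$ins_seq
      calls[i, ] <- rescue_duplication(calls[i, ], seqs, genome)
    }
  }
  rownames(calls) <- NULL
  structure(list(calls = calls, profile = profile,
                 n_signals = nrow(signals), clusters = clusters),
            class = "svd_callset")
}

#' @export
print.svd_callset <- function(x, ...) {
  p <- x$calls[x$calls$filter == "PASS", , drop = FALSE]
  cat(sprintf("svd_callset: %d PASS calls (%d candidates), depth %.1fx, N_supp %d\n",
              nrow(p), nrow(x$calls), x$profile$mean_depth,
              x$profile$n_supp))
  if (nrow(p)) print(table(p$sv_type))
  invisible(x)
}
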