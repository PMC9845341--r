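# Depth-adaptive filtering, genotyping, duplication rescue and VCF output.

#' Depth-adaptive minimum supporting-read count
#'
#' N_supp = floor(mean_depth / 10) + 2, with a floor of 2.
#'
#' @param mean_depth genome-average sequencing depth.
#' @return integer threshold.
#' @export
compute_nsupp <- function(mean_depth) {
  max(2L, as.integer(floor(mean_depth / 10) + 2))
}

empty_calls <- function() {
  data.frame(
    sv_type = character(0), chrom = character(0), pos = integer(0),
    size = integer(0), end = integer(0), chrom2 = character(0),
    pos2 = integer(0), n_supp_reads = integer(0), local_depth = numeric(0),
    genotype = character(0), precise = logical(0), ins_seq = character(0),
    mapq_mean = numeric(0), locus_id = integer(0), allele_index = integer(0),
    filter = character(0), stringsAsFactors = FALSE
  )
}

#' Filter SV candidates by support and mapping quality
#'
#' Calls with fewer than N_supp supporting reads are flagged low_support,
#' calls with mean MAPQ below mapq_min are flagged low_mapq; each allele of
#' a multi-allele SV is filtered independently, and when exactly one allele
#' passes it is demoted to a single-allele call.
#'
#' @param calls SV call data.frame (with locus_id/allele_index columns).
#' @param profile "svd_depth_profile" (or NULL when n_supp is given).
#' @param mapq_min minimum mean MAPQ (default 20).
#' @param n_supp explicit support threshold overriding the profile.
#' @return calls with a filter column ("PASS", "low_support", "low_mapq").
#' @export
filter_candidates <- function(calls, profile = NULL, mapq_min = 20,
                              n_supp = NULL) {
  if (nrow(calls) == 0L) return(calls)
  ns <- n_supp %||% profile$n_supp
  calls$filter <- "PASS"
  calls$filter[calls$n_supp_reads < ns] <- "low_support"
  calls$filter[calls$filter == "PASS" & calls$mapq_mean < mapq_min] <-
    "low_mapq"
  # multi-allele demotion: one passing allele -> single-allele call
  if (any(calls$allele_index > 0L)) {
    for (lid in unique(calls$locus_id[calls$allele_index > 0L])) {
      idx <- which(calls$locus_id == lid & calls$allele_index > 0L)
      passing <- idx[calls$filter[idx] == "PASS"]
      if (length(passing) == 1L) calls$allele_index[passing] <- 0L
    }
  }
  calls
}

#' Genotype a call from its support ratio
#'
#' r = supporting reads / local depth; r >= hom_ratio is called homozygous
#' (1/1), otherwise heterozygous (0/1). Multi-allele loci where both alleles
#' pass are genotyped 1/2.
#'
#' @param calls SV call data.frame with local_depth filled in.
#' @param hom_ratio homozygous cutoff (default 0.75).
#' @return calls with the genotype column set.
#' @export
genotype_calls <- function(calls, hom_ratio = 0.75) {
  if (nrow(calls) == 0L) return(calls)
  ld <- calls$local_depth
  has <- !is.na(ld) & ld > 0
  r <- ifelse(has, calls$n_supp_reads / pmax(ld, 1e-9), 0)
  calls$genotype <- ifelse(has, ifelse(r >= hom_ratio, "1/1", "0/1"),
                           calls$genotype)
  if (any(calls$allele_index > 0L)) {
    for (lid in unique(calls$locus_id[calls$allele_index > 0L])) {
      idx <- which(calls$locus_id == lid & calls$allele_index > 0L &
                     calls$filter == "PASS")
      if (length(idx) == 2L) calls$genotype[idx] <- "1/2"
    }
  }
  calls
}

# mean aligned coverage of [pos-w, pos+w) per call
local_depth_at <- function(calls, aln, w = 500L) {
  keep <- which(!aln$is_secondary)
  out <- numeric(nrow(calls))
  for (ch in unique(calls$chrom)) {
    ci <- which(calls$chrom == ch)
    ri <- keep[aln$chrom[keep] == ch]
    if (length(ri) == 0L) { out[ci] <- 0; next }
    rs <- aln$ref_start[ri]; re <- aln$ref_end[ri]
    for (k in ci) {
      lo <- calls$pos[k] - w; hi <- calls$pos[k] + w
      ov <- pmin(re, hi) - pmax(rs, lo)
      out[k] <- sum(ov[ov > 0]) / (hi - lo)
    }
  }
  out
}

#' Rescue tandem duplications mis-called as insertions
#'
#' The inserted sequence of a tandem duplication matches the reference
#' immediately around the breakpoint. Each supporting read's inserted
#' sequence is locally aligned to the +/- 1 kbp reference window; a sequence
#' counts as "aligned back" when at least 50% of its bases sit in an
#' alignment with >= 80% identity. When strictly more than half of the
#' inserted sequences align back, the call type is corrected to DUP.
#'
#' @param call one-row SV call (INS).
#' @param ins_seqs character vector of supporting inserted sequences.
#' @param genome "svd_genome".
#' @param flank local window half-width (1 kbp).
#' @param max_seqs cap on tested sequences (majority is decided early).
#' @return the call, possibly with sv_type changed to "DUP".
#' @export
rescue_duplication <- function(call, ins_seqs, genome, flank = 1000L,
                               max_seqs = 12L) {
  if (call$sv_type != "INS") return(call)
  ins_seqs <- ins_seqs[!is.na(ins_seqs) & nzchar(ins_seqs)]
  if (length(ins_seqs) == 0L) return(call)
  # an insertion longer than the window can never reach 50% aligned
  if (call$size > 2L * flank) return(call)
  lo <- max(0L, call$pos - flank)
  hi <- min(genome$lengths[[call$chrom]], call$pos + flank)
  refseq <- seq_fetch(genome, call$chrom, lo, hi)
  if (length(ins_seqs) > max_seqs)
    ins_seqs <- ins_seqs[round(seq(1L, length(ins_seqs),
                                   length.out = max_seqs))]
  n <- length(ins_seqs)
  need <- floor(n / 2) + 1L  # strict majority
  hit <- 0L; miss <- 0L
  for (s in ins_seqs) {
    al <- cpp_align_local(s, refseq)
    ident <- if (al$n_cols > 0) al$n_match / al$n_cols else 0
    ok <- ident >= 0.8 && al$q_aligned >= 0.5 * nchar(s)
    if (ok) hit <- hit + 1L else miss <- miss + 1L
    if (hit >= need || miss > n - need) break
  }
  if (hit >= need) call$sv_type <- "DUP"
  if (call$sv_type == "DUP") call$end <- call$pos + call$size
  call
}

vcf_alt_of <- function(type) {
  switch(type, DEL = "<DEL>", DUP = "<DUP:TANDEM>", INV = "<INV>",
         INS = "<INS>", "<SV>")
}

#' Write SV calls to VCF 4.2
#'
#' Coordinates are converted to the 1-based VCF convention; deletions carry
#' negative SVLEN; translocations are written as paired BND records;
#' multi-allele loci become one record with two ALT alleles and GT 1/2.
#'
#' @param calls SV call data.frame.
#' @param genome "svd_genome" (contig header lines).
#' @param path output path.
#' @param emit_all also write non-PASS records (default FALSE).
#' @param sample_name sample column name.
#' @return the path, invisibly.
#' @export
write_vcf <- function(calls, genome, path, emit_all = FALSE,
                      sample_name = "SAMPLE") {
  con <- file(path, "w")
  on.exit(close(con))
  h <- c(
    "##fileformat=VCFv4.2",
    "##source=svdense",
    sprintf("##contig=<ID=%s,length=%d>", names(genome$lengths),
            as.integer(genome$lengths)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=DUP:TANDEM,Description=\"Tandem duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=A,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SUPPORT,Number=A,Type=Integer,Description=\"Supporting reads\">",
    "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"Consensus-refined breakpoint\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Mean-of-signals breakpoint\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  writeLines(h, con)
  if (nrow(calls) == 0L) return(invisible(path))
  if (!emit_all) {
    pass_loci <- calls$locus_id[calls$filter == "PASS"]
    calls <- calls[calls$filter == "PASS", , drop = FALSE]
  }
  if (nrow(calls) == 0L) return(invisible(path))
  lines <- character(0)
  done <- rep(FALSE, nrow(calls))
  vid <- 0L
  ref_base <- function(ch, pos0) {
    b <- seq_fetch(genome, ch, max(0L, pos0), max(0L, pos0) + 1L)
    if (nzchar(b)) b else "N"
  }
  for (i in seq_len(nrow(calls))) {
    if (done[i]) next
    ci <- calls[i, ]
    vid <- vid + 1L
    mates <- integer(0)
    if (ci$allele_index > 0L) {
      mates <- which(!done & calls$locus_id == ci$locus_id &
                       seq_len(nrow(calls)) != i)
    }
    if (ci$sv_type == "TRA") {
      id1 <- sprintf("svd_%d_1", vid); id2 <- sprintf("svd_%d_2", vid)
      rb1 <- ref_base(ci$chrom, ci$pos)
      rb2 <- ref_base(ci$chrom2, ci$pos2)
      info1 <- sprintf("SVTYPE=BND;MATEID=%s;SUPPORT=%d;%s", id2,
                       ci$n_supp_reads,
                       if (isTRUE(ci$precise)) "PRECISE" else "IMPRECISE")
      info2 <- sprintf("SVTYPE=BND;MATEID=%s;SUPPORT=%d;%s", id1,
                       ci$n_supp_reads,
                       if (isTRUE(ci$precise)) "PRECISE" else "IMPRECISE")
      alt1 <- sprintf("%s[%s:%d[", rb1, ci$chrom2, ci$pos2 + 1L)
      alt2 <- sprintf("%s]%s:%d]", rb2, ci$chrom, ci$pos + 1L)
      lines <- c(lines,
        paste(ci$chrom, ci$pos + 1L, id1, rb1, alt1, ".", ci$filter, info1,
              "GT", ci$genotype, sep = "\t"),
        paste(ci$chrom2, ci$pos2 + 1L, id2, rb2, alt2, ".", ci$filter, info2,
              "GT", ci$genotype, sep = "\t"))
      done[i] <- TRUE
      next
    }
    grp <- c(i, mates)
    done[grp] <- TRUE
    sub <- calls[grp, , drop = FALSE]
    sub <- sub[order(sub$allele_index), , drop = FALSE]
    rb <- ref_base(ci$chrom, ci$pos)
    alts <- vapply(seq_len(nrow(sub)), function(k) {
      if (sub$sv_type[k] == "INS" && !is.na(sub$ins_seq[k]) &&
          nzchar(sub$ins_seq[k])) paste0(rb, sub$ins_seq[k])
      else vcf_alt_of(sub$sv_type[k])
    }, character(1))
    svlen <- ifelse(sub$sv_type == "DEL", -sub$size, sub$size)
    gt <- if (nrow(sub) == 2L) "1/2" else sub$genotype[1]
    end1 <- if (ci$sv_type == "INS") ci$pos + 1L else max(sub$end) + 1L
    info <- sprintf("SVTYPE=%s;SVLEN=%s;END=%d;SUPPORT=%s;%s",
                    ci$sv_type, paste(svlen, collapse = ","),
                    end1, paste(sub$n_supp_reads, collapse = ","),
                    if (isTRUE(ci$precise)) "PRECISE" else "IMPRECISE")
    lines <- c(lines, paste(ci$chrom, ci$pos + 1L, sprintf("svd_%d", vid), rb,
                            paste(alts, collapse = ","), ".", ci$filter,
                            info, "GT", gt, sep = "\t"))
  }
  # sort body by chrom then POS
  f <- strsplit(lines, "\t", fixed = TRUE)
  ord <- order(match(vapply(f, `[`, "", 1), names(genome$lengths)),
               as.integer(vapply(f, `[`, "", 2)))
  writeLines(lines[ord], con)
  invisible(path)
}

parse_info <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- list()
  for (p in kv) out[[p[1]]] <- if (length(p) > 1L) p[2] else TRUE
  out
}

#' Read an SV VCF written by [write_vcf()]
#'
#' @param path VCF path.
#' @return SV call data.frame (TRA records re-paired via MATEID; multi-ALT
#'   records expanded back to two allele rows).
#' @export
read_sv_vcf <- function(path) {
  ln <- readLines(path)
  body <- ln[!startsWith(ln, "#")]
  out <- list()
  seen_bnd <- character(0)
  lid <- 0L
  for (l in body) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    info <- parse_info(f[8])
    gt <- if (length(f) >= 10L) strsplit(f[10], ":", fixed = TRUE)[[1]][1]
          else "./."
    lid <- lid + 1L
    if (identical(info$SVTYPE, "BND")) {
      if (f[3] %in% seen_bnd) next
      seen_bnd <- c(seen_bnd, info$MATEID)
      m <- regmatches(f[5], regexec("[][]([^:]+):([0-9]+)[][]", f[5]))[[1]]
      out[[length(out) + 1L]] <- data.frame(
        sv_type = "TRA", chrom = f[1], pos = as.integer(f[2]) - 1L,
        size = 0L, end = as.integer(f[2]) - 1L, chrom2 = m[2],
        pos2 = as.integer(m[3]) - 1L,
        n_supp_reads = as.integer(info$SUPPORT %||% NA),
        local_depth = NA_real_, genotype = gt,
        precise = isTRUE(info$PRECISE), ins_seq = NA_character_,
        mapq_mean = NA_real_, locus_id = lid, allele_index = 0L,
        filter = f[7], stringsAsFactors = FALSE
      )
      next
    }
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    svlen <- as.integer(strsplit(as.character(info$SVLEN), ",")[[1]])
    supp <- as.integer(strsplit(as.character(info$SUPPORT %||% "0"), ",")[[1]])
    for (k in seq_along(alts)) {
      size <- abs(svlen[min(k, length(svlen))])
      ins <- NA_character_
      if (!startsWith(alts[k], "<")) {
        ins <- substr(alts[k], 2L, nchar(alts[k]))
        size <- nchar(ins)
      }
      pos0 <- as.integer(f[2]) - 1L  # POS is the 1-based first affected base
      type <- as.character(info$SVTYPE)
      out[[length(out) + 1L]] <- data.frame(
        sv_type = type, chrom = f[1], pos = pos0, size = size,
        end = if (type == "INS") pos0 else pos0 + size,
        chrom2 = NA_character_, pos2 = NA_integer_,
        n_supp_reads = supp[min(k, length(supp))], local_depth = NA_real_,
        genotype = if (length(alts) == 2L) "1/2" else gt,
        precise = isTRUE(info$PRECISE), ins_seq = ins, mapq_mean = NA_real_,
        locus_id = lid,
        allele_index = if (length(alts) == 2L) k else 0L,
        filter = f[7], stringsAsFactors = FALSE
      )
    }
  }
  res <- rbind_dfs(out)
  if (is.null(res)) empty_calls() else res
}
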