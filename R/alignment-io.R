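# Alignment and sequence input/output.
#
# All coordinates are 0-based half-open internally; conversion to/from the
# 1-based SAM/VCF convention happens only at the file boundary. Alignments
# are carried as a plain data.frame ("alignment table") with one row per
# alignment record (primary, supplementary or secondary segment).

ALN_COLS <- c(
  "read_id", "chrom", "ref_start", "ref_end", "strand", "mapq", "cigar",
  "seq", "is_supplementary", "is_secondary", "sa",
  "left_clip", "right_clip", "lead_S", "trail_S", "read_len", "aligned_read"
)

#' Build a normalized alignment table
#'
#' Completes an alignment record data.frame with the CIGAR-derived columns
#' (reference end, clip lengths, aligned read bases) and validates the
#' coordinate invariants.
#'
#' @param df data.frame with at least read_id, chrom, ref_start (0-based),
#'   strand ("+"/"-"), mapq, cigar and optionally seq (NA when unavailable),
#'   is_supplementary, is_secondary, sa (raw SA tag string or NA).
#' @return data.frame with the full alignment-table columns.
#' @export
alignment_table <- function(df) {
  n <- nrow(df)
  if (is.null(df$seq)) df$seq <- rep(NA_character_, n)
  if (is.null(df$is_supplementary)) df$is_supplementary <- rep(FALSE, n)
  if (is.null(df$is_secondary)) df$is_secondary <- rep(FALSE, n)
  if (is.null(df$sa)) df$sa <- rep(NA_character_, n)
  if (is.null(df$mapq)) df$mapq <- rep(60L, n)
  stats <- cpp_cigar_stats(as.character(df$cigar))
  df$ref_end <- as.integer(df$ref_start) + stats[, "ref_len"]
  df$left_clip <- stats[, "lead_clip"]
  df$right_clip <- stats[, "trail_clip"]
  df$lead_S <- stats[, "lead_S"]
  df$trail_S <- stats[, "trail_S"]
  # full read length (hard-clipped bases included)
  df$read_len <- stats[, "read_len"] +
    (stats[, "lead_clip"] - stats[, "lead_S"]) +
    (stats[, "trail_clip"] - stats[, "trail_S"])
  df$aligned_read <- stats[, "aligned_read"]
  df$ref_start <- as.integer(df$ref_start)
  df$strand <- as.character(df$strand)
  df$read_id <- as.character(df$read_id)
  df$chrom <- as.character(df$chrom)
  df[, ALN_COLS]
}

#' Read long-read alignments from SAM/BAM
#'
#' SAM input is converted on the fly with Rsamtools. Primary, supplementary
#' and secondary records are all returned; secondary records are flagged so
#' downstream stages can ignore them. Whole-genome BAM input must be
#' coordinate-sorted.
#'
#' @param path SAM or BAM file.
#' @param region optional list(chrom, start, end) (0-based half-open);
#'   requires an indexed BAM.
#' @return alignment table (see [alignment_table()]).
#' @export
read_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- path
  if (is_sam) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, indexDestination = TRUE)
  } else {
    hdr <- Rsamtools::scanBamHeader(path)[[1]]
    so <- sub(".*SO:", "", grep("SO:", unlist(hdr$text["@HD"]), value = TRUE)[1])
    if (is.null(region) && length(so) && !is.na(so) && so != "coordinate")
      stop("whole-genome mode requires a coordinate-sorted BAM (SO:", so, ")")
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = what, tag = "SA")
  } else {
    gr <- GenomicRanges::GRanges(region[[1]],
      IRanges::IRanges(region[[2]] + 1L, region[[3]]))
    Rsamtools::ScanBamParam(what = what, tag = "SA", which = gr)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  parts <- lapply(res, function(x) {
    n <- length(x$qname)
    if (n == 0L) return(NULL)
    seqs <- as.character(x$seq)
    seqs[seqs == "" | seqs == "*"] <- NA_character_
    sa <- x$tag$SA
    if (is.null(sa)) sa <- rep(NA_character_, n)
    data.frame(
      read_id = x$qname, chrom = as.character(x$rname),
      ref_start = x$pos - 1L,
      strand = ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+"),
      mapq = as.integer(x$mapq), cigar = x$cigar, seq = seqs,
      is_supplementary = bitwAnd(x$flag, 2048L) > 0L,
      is_secondary = bitwAnd(x$flag, 256L) > 0L,
      sa = as.character(sa), stringsAsFactors = FALSE
    )
  })
  out <- rbind_dfs(parts)
  if (is.null(out)) {
    out <- data.frame(
      read_id = character(0), chrom = character(0), ref_start = integer(0),
      strand = character(0), mapq = integer(0), cigar = character(0),
      seq = character(0), is_supplementary = logical(0),
      is_secondary = logical(0), sa = character(0), stringsAsFactors = FALSE
    )
  }
  out <- out[!is.na(out$chrom) & !is.na(out$ref_start), , drop = FALSE]
  alignment_table(out)
}

#' Parse an SA (supplementary alignment) tag
#'
#' @param tag_value SA:Z value: semicolon-separated
#'   "rname,pos,strand,CIGAR,mapQ,NM" entries.
#' @return data.frame(chrom, pos (0-based), strand, cigar, mapq), one row per
#'   well-formed entry. Malformed entries are skipped with a warning.
#' @export
parse_sa_tag <- function(tag_value) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), cigar = character(0),
                      mapq = integer(0), stringsAsFactors = FALSE)
  if (is.null(tag_value) || is.na(tag_value) || !nzchar(tag_value))
    return(empty)
  entries <- strsplit(tag_value, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  rows <- lapply(entries, function(e) {
    f <- strsplit(e, ",", fixed = TRUE)[[1]]
    pos <- suppressWarnings(as.integer(f[2]))
    if (length(f) < 5L || is.na(pos) || !(f[3] %in% c("+", "-"))) {
      warning("skipping malformed SA entry: ", e)
      return(NULL)
    }
    data.frame(chrom = f[1], pos = pos - 1L, strand = f[3], cigar = f[4],
               mapq = suppressWarnings(as.integer(f[5])),
               stringsAsFactors = FALSE)
  })
  out <- rbind_dfs(rows)
  if (is.null(out)) empty else out
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file (optionally with an .fai index alongside; unused).
#' @return an object of class "svd_genome": list(seq = named uppercase
#'   character vector, lengths = named integer vector).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate FASTA headers in ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  genome_from_seqs(seqs)
}

#' Build a genome object from named sequences
#' @param seqs named character vector of chromosome sequences.
#' @return "svd_genome" object.
#' @export
genome_from_seqs <- function(seqs) {
  seqs <- toupper(seqs)
  structure(list(seq = as.list(seqs),
                 lengths = setNames(as.integer(nchar(seqs)), names(seqs))),
            class = "svd_genome")
}

#' Write a genome object to FASTA
#' @param genome "svd_genome" object.
#' @param path output path.
#' @param width line width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unlist(genome$seq))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write an alignment table as SAM
#'
#' Records are written coordinate-sorted with SA tags when present.
#'
#' @param aln alignment table.
#' @param chrom_lengths named integer vector (header SQ lines).
#' @param path output .sam path.
#' @export
write_sam <- function(aln, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (cn in names(chrom_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", cn, as.integer(chrom_lengths[[cn]])),
               con)
  }
  if (nrow(aln) == 0L) return(invisible(path))
  ord <- order(match(aln$chrom, names(chrom_lengths)), aln$ref_start)
  aln <- aln[ord, , drop = FALSE]
  flag <- ifelse(aln$strand == "-", 16L, 0L) +
    ifelse(aln$is_supplementary, 2048L, 0L) +
    ifelse(aln$is_secondary, 256L, 0L)
  seq <- ifelse(is.na(aln$seq), "*", aln$seq)
  lines <- paste(aln$read_id, flag, aln$chrom, aln$ref_start + 1L, aln$mapq,
                 aln$cigar, "*", 0L, 0L, seq, "*", sep = "\t")
  has_sa <- !is.na(aln$sa) & nzchar(aln$sa)
  lines[has_sa] <- paste0(lines[has_sa], "\tSA:Z:", aln$sa[has_sa])
  writeLines(lines, con)
  invisible(path)
}
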