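# Ground-truth SV simulation: truth sampling, haplotype construction with
# coordinate liftover, error-model reads, and oracle alignments computed
# from the known read placement (so every downstream stage can be tested
# without an external aligner).

# GRCh38 chromosome lengths (chr1-22, X): the default placement substrate
# for full-scale truth sets (lengths only; sequences are never required
# for sampling).
GRCH38_LENGTHS <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468, chrX = 156040895
)

ERROR_PRESETS <- list(
  "pacbio-clr" = c(sub = 0.060, ins = 0.045, del = 0.045),
  "hifi" = c(sub = 0.004, ins = 0.003, del = 0.003),
  "nanopore" = c(sub = 0.030, ins = 0.042, del = 0.048)
)

#' Simulation configuration
#'
#' Defaults reproduce the reference simulation protocol: 22,200 SVs
#' (10,000 DEL, 10,000 INS, 1,000 DUP, 1,000 INV, 200 TRA) with a size
#' mixture of a geometric-decay background plus Gaussian peaks near 350 bp
#' (Alu) and 6,000 bp (LINE), a 2:1 het:hom ratio with heterozygous events
#' assigned randomly to the two haplotypes, 25x depth per haplotype and
#' 15 kbp mean read length.
#'
#' @param counts named integer vector of SV counts per type.
#' @param chrom_lengths placement substrate (named lengths); defaults to the
#'   GRCh38 autosomes + X.
#' @param depth_per_hap sequencing depth per haplotype.
#' @param read_mean,read_shape gamma read-length model (mean bp, shape).
#' @param preset error preset: "pacbio-clr" (15% total), "hifi" (1%),
#'   "nanopore" (12%); or NULL with explicit error_rates.
#' @param error_rates named c(sub, ins, del) per-base rates.
#' @param het_fraction fraction of events that are heterozygous (2/3).
#' @param size_weights mixture weights c(background, peak350, peak6000).
#' @param bg_mean geometric background mean size above min_size.
#' @param min_size,max_size truth size clamp (bp).
#' @param end_margin placement margin from chromosome ends (bp).
#' @param seed RNG seed driving every random choice.
#' @return list of class "svd_sim_config".
#' @export
sim_config <- function(counts = c(DEL = 10000, INS = 10000, DUP = 1000,
                                  INV = 1000, TRA = 200),
                       chrom_lengths = GRCH38_LENGTHS,
                       depth_per_hap = 25, read_mean = 15000,
                       read_shape = 4, preset = "pacbio-clr",
                       error_rates = NULL, het_fraction = 2 / 3,
                       size_weights = c(0.6, 0.3, 0.1), bg_mean = 300,
                       min_size = 50, max_size = 10000,
                       end_margin = 20000, seed = 1L) {
  if (is.null(error_rates)) {
    if (is.null(preset)) stop("either preset or error_rates is required")
    error_rates <- ERROR_PRESETS[[preset]]
    if (is.null(error_rates)) stop("unknown preset: ", preset)
  }
  structure(list(
    counts = counts, chrom_lengths = chrom_lengths,
    depth_per_hap = depth_per_hap, read_mean = read_mean,
    read_shape = read_shape, preset = preset, error_rates = error_rates,
    het_fraction = het_fraction, size_weights = size_weights,
    bg_mean = bg_mean, min_size = min_size, max_size = max_size,
    end_margin = end_margin, seed = as.integer(seed)
  ), class = "svd_sim_config")
}

#' Random synthetic genome
#' @param lengths named integer vector of chromosome lengths.
#' @param seed RNG seed.
#' @return "svd_genome".
#' @export
synthetic_genome <- function(lengths, seed = 1L) {
  set.seed(seed)
  genome_from_seqs(vapply(lengths, random_dna, character(1)))
}

sample_sizes <- function(n, cfg) {
  comp <- sample.int(3L, n, replace = TRUE, prob = cfg$size_weights)
  sz <- numeric(n)
  nb <- sum(comp == 1L)
  sz[comp == 1L] <- cfg$min_size +
    stats::rgeom(nb, 1 / (cfg$bg_mean - cfg$min_size + 1))
  sz[comp == 2L] <- stats::rnorm(sum(comp == 2L), 350, 30)
  sz[comp == 3L] <- stats::rnorm(sum(comp == 3L), 6000, 500)
  pmin(pmax(round(sz), cfg$min_size), cfg$max_size)
}

#' Sample a ground-truth SV set
#'
#' Emits exactly the configured per-type counts. Sizes follow the mixture
#' model; zygosity is deterministic (round(het_fraction x n) heterozygotes
#' per type, remainder homozygotes) so the 2:1 ratio is exact; heterozygous
#' SVs are assigned to a random haplotype. Events are placed uniformly with
#' a 2 x max(size, 1 kbp) exclusion zone around each accepted event and an
#' end margin per chromosome.
#'
#' @param cfg "svd_sim_config".
#' @return truth data.frame (id, sv_type, chrom, pos, size, zygosity,
#'   haplotype, ins_seq, chrom2, pos2).
#' @export
sample_sv_set <- function(cfg) {
  set.seed(cfg$seed)
  lens <- cfg$chrom_lengths
  chroms <- names(lens)
  placed <- lapply(chroms, function(x) matrix(numeric(0), ncol = 3))
  names(placed) <- chroms
  margin <- cfg$end_margin
  try_place <- function(size) {
    r <- 2 * max(size, 1000)
    for (attempt in 1:200) {
      ch <- sample(chroms, 1, prob = as.numeric(lens))
      hi <- lens[[ch]] - margin - size
      if (hi <= margin) next
      pos <- floor(runif(1, margin, hi))
      blk <- placed[[ch]]
      if (nrow(blk) == 0L) ok <- TRUE
      else {
        rr <- pmax(r, blk[, 3])  # pairwise spacing uses the larger radius
        ok <- all(pos + size + rr <= blk[, 1] | pos - rr >= blk[, 2])
      }
      if (ok) {
        placed[[ch]] <<- rbind(blk, c(pos, pos + size, r))
        return(list(chrom = ch, pos = as.integer(pos)))
      }
    }
    NULL
  }
  rows <- list()
  id <- 0L
  for (type in names(cfg$counts)) {
    n <- as.integer(cfg$counts[[type]])
    if (n == 0L) next
    sizes <- if (type == "TRA") rep(0L, n) else sample_sizes(n, cfg)
    n_het <- round_half_up(cfg$het_fraction * n)
    zyg <- sample(c(rep("het", n_het), rep("hom", n - n_het)))
    hap <- ifelse(zyg == "hom", "both",
                  as.character(sample(1:2, n, replace = TRUE)))
    for (k in seq_len(n)) {
      id <- id + 1L
      if (type == "TRA") {
        a <- try_place(0L); b <- try_place(0L)
        # both breakpoints on distinct chromosomes
        tries <- 0L
        while (!is.null(a) && !is.null(b) && a$chrom == b$chrom &&
               tries < 50L) {
          b <- try_place(0L); tries <- tries + 1L
        }
        if (is.null(a) || is.null(b) || a$chrom == b$chrom) next
        # canonical order
        if (a$chrom > b$chrom) { tmp <- a; a <- b; b <- tmp }
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, sv_type = "TRA", chrom = a$chrom, pos = a$pos, size = 0L,
          zygosity = zyg[k], haplotype = hap[k], ins_seq = NA_character_,
          chrom2 = b$chrom, pos2 = b$pos, stringsAsFactors = FALSE
        )
      } else {
        span <- if (type == "INS") 0L else sizes[k]
        p <- try_place(span)
        if (is.null(p)) next
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, sv_type = type, chrom = p$chrom, pos = p$pos,
          size = sizes[k], zygosity = zyg[k], haplotype = hap[k],
          ins_seq = if (type == "INS") random_dna(sizes[k])
                    else NA_character_,
          chrom2 = NA_character_, pos2 = NA_integer_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- rbind_dfs(rows)
  if (is.null(out)) {
    return(data.frame(id = integer(0), sv_type = character(0),
                      chrom = character(0), pos = integer(0),
                      size = integer(0), zygosity = character(0),
                      haplotype = character(0), ins_seq = character(0),
                      chrom2 = character(0), pos2 = integer(0),
                      stringsAsFactors = FALSE))
  }
  out[order(match(out$chrom, chroms), out$pos), ]
}

# left-normalize truth coordinates against the reference (the same
# normalization the caller's realignment applies)
normalize_truth <- function(truth, genome) {
  for (i in seq_len(nrow(truth))) {
    type <- truth$sv_type[i]
    if (!type %in% c("DEL", "DUP", "INS")) next
    ch <- truth$chrom[i]
    refseq <- genome$seq[[ch]]
    pos <- truth$pos[i]; size <- truth$size[i]
    if (type %in% c("DEL", "DUP")) {
      while (pos > 0 && substr(refseq, pos, pos) ==
             substr(refseq, pos + size, pos + size)) pos <- pos - 1L
      truth$pos[i] <- pos
    } else {
      content <- truth$ins_seq[i]
      n <- nchar(content)
      while (pos > 0 && substr(refseq, pos, pos) == substr(content, n, n)) {
        content <- paste0(substr(refseq, pos, pos),
                          substr(content, 1L, n - 1L))
        pos <- pos - 1L
      }
      truth$pos[i] <- pos
      truth$ins_seq[i] <- content
    }
  }
  truth
}

# build the block table (liftover) for one haplotype chromosome, without TRA
hap_blocks_chrom <- function(truth, hap, ch, chrom_len) {
  svs <- truth[truth$sv_type %in% c("DEL", "INS", "DUP", "INV") &
                 truth$chrom == ch &
                 (truth$haplotype == "both" | truth$haplotype == hap), ,
               drop = FALSE]
  svs <- svs[order(svs$pos), , drop = FALSE]
  blocks <- list()
  addM <- function(a, b, strand = "+") {
    if (b > a)
      blocks[[length(blocks) + 1L]] <<- list(kind = "M", chrom = ch,
                                             ref_start = a, ref_end = b,
                                             strand = strand,
                                             content = NA_character_)
  }
  cur <- 0L
  for (i in seq_len(nrow(svs))) {
    type <- svs$sv_type[i]; pos <- svs$pos[i]; size <- svs$size[i]
    if (type == "DEL") {
      addM(cur, pos); cur <- pos + size
    } else if (type == "INS") {
      addM(cur, pos)
      blocks[[length(blocks) + 1L]] <- list(kind = "I", chrom = ch,
                                            ref_start = pos, ref_end = pos,
                                            strand = "+",
                                            content = svs$ins_seq[i])
      cur <- pos
    } else if (type == "DUP") {
      addM(cur, pos + size)
      addM(pos, pos + size)
      cur <- pos + size
    } else if (type == "INV") {
      addM(cur, pos)
      addM(pos, pos + size, strand = "-")
      cur <- pos + size
    }
  }
  addM(cur, chrom_len)
  blocks
}

block_len <- function(b) {
  if (b$kind == "I") nchar(b$content) else b$ref_end - b$ref_start
}

#' Apply SVs to a genome: haplotype sequences + liftover maps
#'
#' Deletions excise, insertions insert, duplications append a tandem copy,
#' inversions reverse-complement the interval, and translocations swap the
#' chromosome tails at the two breakpoints. Truth coordinates are
#' left-normalized first and the normalized truth is returned.
#'
#' @param genome "svd_genome".
#' @param truth truth data.frame from [sample_sv_set()].
#' @return list(truth, haps = per-hap list of chromosome sequences,
#'   lift = per-hap list of block data.frames, genome).
#' @export
apply_svs_to_genome <- function(genome, truth) {
  truth <- normalize_truth(truth, genome)
  chroms <- names(genome$lengths)
  out <- list(truth = truth, haps = list(), lift = list(), genome = genome)
  applied_tra <- integer(0)
  for (hap in c("1", "2")) {
    blocks <- lapply(chroms, function(ch)
      hap_blocks_chrom(truth, hap, ch, genome$lengths[[ch]]))
    names(blocks) <- chroms
    # translocations: swap tails between the two haplotype chromosomes that
    # *currently* carry the breakpoints (earlier swaps may have moved them)
    tra <- truth[truth$sv_type == "TRA" &
                   (truth$haplotype == "both" | truth$haplotype == hap), ,
                 drop = FALSE]
    locate_cut <- function(ch, pos) {
      for (hc in names(blocks)) {
        blks <- blocks[[hc]]
        for (j in seq_along(blks)) {
          b <- blks[[j]]
          if (b$kind == "M" && b$strand == "+" && b$chrom == ch &&
              b$ref_start <= pos && pos < b$ref_end)
            return(list(hc = hc, idx = j, pos = pos))
        }
      }
      NULL
    }
    cut_blocks <- function(blks, loc) {
      b <- blks[[loc$idx]]
      head <- if (loc$idx > 1L) blks[seq_len(loc$idx - 1L)] else list()
      tail <- if (loc$idx < length(blks))
        blks[(loc$idx + 1L):length(blks)] else list()
      if (loc$pos > b$ref_start) {
        b1 <- b; b1$ref_end <- loc$pos
        head <- c(head, list(b1))
      }
      b2 <- b; b2$ref_start <- loc$pos
      if (b2$ref_end > b2$ref_start) tail <- c(list(b2), tail)
      list(head = head, tail = tail)
    }
    for (i in seq_len(nrow(tra))) {
      locA <- locate_cut(tra$chrom[i], tra$pos[i])
      locB <- locate_cut(tra$chrom2[i], tra$pos2[i])
      if (is.null(locA) || is.null(locB) || locA$hc == locB$hc) next
      a <- cut_blocks(blocks[[locA$hc]], locA)
      b <- cut_blocks(blocks[[locB$hc]], locB)
      blocks[[locA$hc]] <- c(a$head, b$tail)
      blocks[[locB$hc]] <- c(b$head, a$tail)
      applied_tra <- c(applied_tra, tra$id[i])
    }
    # materialize sequences and block tables with haplotype coordinates
    seqs <- list()
    tables <- list()
    for (ch in chroms) {
      blks <- blocks[[ch]]
      pieces <- vapply(blks, function(b) {
        if (b$kind == "I") b$content
        else if (b$strand == "+")
          substr(genome$seq[[b$chrom]], b$ref_start + 1L, b$ref_end)
        else cpp_revcomp(substr(genome$seq[[b$chrom]],
                                b$ref_start + 1L, b$ref_end))
      }, character(1))
      lens <- vapply(blks, block_len, numeric(1))
      ends <- cumsum(lens)
      starts <- c(0, head(ends, -1))
      tables[[ch]] <- data.frame(
        hap_start = as.integer(starts), hap_end = as.integer(ends),
        kind = vapply(blks, function(b) b$kind, character(1)),
        chrom = vapply(blks, function(b) b$chrom, character(1)),
        ref_start = vapply(blks, function(b) as.integer(b$ref_start),
                           integer(1)),
        ref_end = vapply(blks, function(b) as.integer(b$ref_end),
                         integer(1)),
        strand = vapply(blks, function(b) b$strand, character(1)),
        stringsAsFactors = FALSE
      )
      seqs[[ch]] <- paste(pieces, collapse = "")
    }
    out$haps[[hap]] <- seqs
    out$lift[[hap]] <- tables
  }
  # translocations that could not be applied on any haplotype (cut points
  # displaced into the same derived chromosome by an earlier swap) are not
  # present in the haplotypes and are removed from the truth
  drop <- out$truth$sv_type == "TRA" & !(out$truth$id %in% applied_tra)
  out$truth <- out$truth[!drop, , drop = FALSE]
  out
}
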