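# Shared fixtures and independent brute-force oracles.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one-row alignment record (defaults suit split-pair construction)
aln_row <- function(read_id = "r1", chrom = "c1", ref_start = 0L,
                    strand = "+", mapq = 60L, cigar = "100M",
                    seq = NA_character_, is_supplementary = FALSE,
                    is_secondary = FALSE, sa = NA_character_) {
  alignment_table(data.frame(
    read_id = read_id, chrom = chrom, ref_start = ref_start,
    strand = strand, mapq = mapq, cigar = cigar, seq = seq,
    is_supplementary = is_supplementary, is_secondary = is_secondary,
    sa = sa, stringsAsFactors = FALSE
  ))
}

# segment rows with read-orientation coordinates attached (as the split-read
# scanner sees them)
with_read_spans <- function(aln) {
  sp <- svdense:::aln_read_spans(aln)
  aln$read_start <- sp[, 1]
  aln$read_end <- sp[, 2]
  aln
}

# brute-force same-type CIGAR-op merging: ops (pos, size) sorted; merge when
# gap <= max(100, 0.5 * (sa + sb))
oracle_merge_ops <- function(pos, size) {
  stopifnot(length(pos) == length(size))
  out <- list()
  for (k in seq_along(pos)) {
    if (length(out)) {
      last <- out[[length(out)]]
      gap <- pos[k] - (last$pos + last$size)
      if (gap <= max(100, 0.5 * (last$size + size[k]))) {
        last$size <- last$size + size[k]
        out[[length(out)]] <- last
        next
      }
    }
    out[[length(out) + 1L]] <- list(pos = pos[k], size = size[k])
  }
  out
}

# single-linkage gap clustering (groups separated by > gap)
oracle_gap_cluster <- function(pos, gap) {
  pos <- sort(pos)
  split(pos, cumsum(c(1L, diff(pos) > gap)))
}

# exhaustive optimal 1-D 2-partition by within-cluster sum of squares
oracle_best_split <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf
  for (k in seq_len(n - 1L)) {
    a <- xs[1:k]; b <- xs[(k + 1L):n]
    w <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (w < best) best <- w
  }
  best
}

# maximum bipartite matching size by exhaustive recursion (tiny instances)
oracle_max_matching <- function(edges, nt, nc) {
  if (nrow(edges) == 0L) return(0L)
  best <- 0L
  recurse <- function(k, used_c, count) {
    if (k > nt) { best <<- max(best, count); return(invisible()) }
    recurse(k + 1L, used_c, count)
    for (c in edges$ci[edges$ti == k]) {
      if (!used_c[c]) {
        used_c[c] <- TRUE
        recurse(k + 1L, used_c, count + 1L)
        used_c[c] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nc), 0L)
  best
}

# small simulated dataset helper
mini_sim <- function(counts, lens = c(cA = 300000, cB = 300000),
                     depth = 12, err = "zero", seed = 5, mean_len = 10000,
                     end_margin = 15000, ...) {
  er <- if (identical(err, "zero")) c(sub = 0, ins = 0, del = 0) else NULL
  preset <- if (is.character(err) && err != "zero") err else NULL
  cfg <- sim_config(counts = counts, chrom_lengths = lens,
                    depth_per_hap = depth, read_mean = mean_len,
                    error_rates = er, preset = preset,
                    end_margin = end_margin, seed = seed, ...)
  simulate_dataset(cfg)
}
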