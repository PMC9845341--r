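# small shared helpers (internal)

# round half up to integer (pinned convention for mean-of-signal fallbacks)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based half-open substring of a chromosome sequence
seq_fetch <- function(genome, chrom, start, end) {
  len <- genome$lengths[[chrom]]
  if (is.null(len)) stop("unknown chromosome: ", chrom)
  start <- max(0L, as.integer(start))
  end <- min(as.integer(end), len)
  if (end <= start) return("")
  substr(genome$seq[[chrom]], start + 1L, end)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

new_signal_df <- function(n = 0L) {
  data.frame(
    sv_type = character(n), chrom = character(n), pos = integer(n),
    size = integer(n), read_id = character(n), source = character(n),
    ins_seq = character(n), mapq = integer(n), chrom2 = character(n),
    pos2 = integer(n), inv_end = integer(n), rec = integer(n),
    stringsAsFactors = FALSE
  )
}

rbind_dfs <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  lst <- lst[vapply(lst, nrow, integer(1)) > 0L]
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
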