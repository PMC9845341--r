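# clip clustering and local assembly of read-length-exceeding insertions

clip_df <- function(n_left, n_right, center = 50000L, spread = 150L,
                    chrom = "c1") {
  n <- n_left + n_right
  if (n == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      side = character(0), read_id = character(0),
                      clip_len = integer(0), clip_seq = character(0),
                      mapq = integer(0), rec = integer(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    chrom = chrom,
    pos = center + sample(seq(-spread, spread), n, replace = TRUE),
    side = c(rep("left", n_left), rep("right", n_right)),
    read_id = paste0("r", seq_len(n)),
    clip_len = 5000L, clip_seq = NA_character_, mapq = 60L,
    rec = seq_len(n), stringsAsFactors = FALSE
  )
}

test_that("clip clusters require N_supp support on both sides", {
  set.seed(91)
  expect_length(find_clip_clusters(clip_df(8, 8), 7), 1L)
  expect_length(find_clip_clusters(clip_df(0, 8), 7), 0L)
  expect_length(find_clip_clusters(clip_df(6, 6), 7), 0L)
})

test_that("an error-free ultra-large insertion is recovered within 5% size", {
  ds <- mini_sim(c(INS = 1), lens = c(cA = 220000), depth = 25, seed = 92,
                 mean_len = 12000, het_fraction = 0,
                 size_weights = c(1, 0, 0), bg_mean = 21000,
                 min_size = 20000, max_size = 24000, end_margin = 30000)
  expect_equal(ds$truth$size >= 20000, TRUE)
  res <- sv_call(ds$aln, ds$genome)
  calls <- res$calls[res$calls$filter == "PASS", ]
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$sv_type, "INS")
  expect_lt(abs(calls$size - ds$truth$size) / ds$truth$size, 0.05)
  expect_lte(abs(calls$pos - ds$truth$pos), 1000L)
  expect_gte(calls$n_supp_reads, res$profile$n_supp)
})

test_that("assembly filters drop multi-contig and sub-1 kbp detections", {
  set.seed(93)
  ref <- rand_dna(20000)
  g <- genome_from_seqs(c(c1 = ref))
  cluster <- list(chrom = "c1", pos = 10000L, region_start = 9900L,
                  region_end = 10100L,
                  left_members = clip_df(4, 0, 10000L, 50L),
                  right_members = clip_df(0, 4, 10000L, 50L))
  contig_with_ins <- function(n) {
    list(seq = paste0(substr(ref, 8001, 10000), rand_dna(n),
                      substr(ref, 10001, 12000)),
         n_reads = 8L, source_region = list("c1", 9900L, 10100L))
  }
  big <- contig_with_ins(5000)
  expect_null(call_large_insertion(cluster, list(big, big), g))   # 2 contigs
  expect_null(call_large_insertion(cluster, list(contig_with_ins(800)), g))
  one <- call_large_insertion(cluster, list(big), g)
  expect_equal(one$sv_type, "INS")
  expect_equal(one$size, 5000L)
  expect_equal(one$pos, 10000L)
})

test_that("reads from two unrelated loci assemble into separate contigs", {
  set.seed(94)
  insA <- rand_dna(8000); insB <- rand_dna(8000)
  mk <- function(ins, tag, n) {
    # right-clipped reads: 400 bp flank + a prefix of the insertion
    flank <- rand_dna(400)
    do.call(rbind, lapply(seq_len(n), function(i) {
      clip <- substr(ins, 1, 3000 + 400 * i)
      aln_row(read_id = paste0(tag, "_r", i), chrom = "c1",
              ref_start = 50000L - 400L,
              cigar = sprintf("400M%dS", nchar(clip)),
              seq = paste0(flank, clip))
    }))
  }
  aln <- rbind(mk(insA, "locA", 4), mk(insB, "locB", 4))
  cluster <- list(chrom = "c1", pos = 50000L, region_start = 49900L,
                  region_end = 50100L,
                  left_members = clip_df(0, 0),
                  right_members = data.frame(
                    chrom = "c1", pos = 50000L, side = "right",
                    read_id = aln$read_id, clip_len = 3000L,
                    clip_seq = NA_character_, mapq = 60L,
                    rec = seq_len(nrow(aln)), stringsAsFactors = FALSE))
  contigs <- assemble_local(cluster, aln)
  expect_gte(length(contigs), 2L)
  # a single read assembles as its own contig
  solo <- cluster
  solo$right_members <- solo$right_members[1, ]
  expect_length(assemble_local(solo, aln), 1L)
})

test_that("assembly-path insertions keep the support and size invariants", {
  ds <- mini_sim(c(INS = 2), lens = c(cA = 400000), depth = 25, seed = 95,
                 mean_len = 12000, err = "pacbio-clr", het_fraction = 0,
                 size_weights = c(1, 0, 0), bg_mean = 21000,
                 min_size = 20000, max_size = 26000, end_margin = 30000)
  res <- sv_call(ds$aln, ds$genome)
  calls <- res$calls[res$calls$filter == "PASS", ]
  expect_true(all(calls$size >= 1000L))
  expect_true(all(calls$n_supp_reads >= res$profile$n_supp))
  # no double reporting: at most one call per truth locus
  for (i in seq_len(nrow(ds$truth))) {
    near <- sum(abs(calls$pos - ds$truth$pos[i]) <= 1000L &
                  calls$chrom == ds$truth$chrom[i])
    expect_lte(near, 1L)
  }
})
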