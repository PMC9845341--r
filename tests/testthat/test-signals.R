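# raw SV signal extraction

test_that("intra-alignment insertions and deletions are extracted", {
  aln <- aln_row(ref_start = 10000L, cigar = "500M100I500M",
                 seq = strrep("A", 1100))
  s <- extract_intra_signals(aln, 50L)
  expect_equal(s$sv_type, "INS")
  expect_equal(s$pos, 10500L)
  expect_equal(s$size, 100L)
  expect_equal(nchar(s$ins_seq), 100L)
  expect_equal(nrow(extract_intra_signals(
    aln_row(cigar = "500M40D500M"), 50L)), 0L)
})

test_that("same-type op merging matches the brute-force merging oracle", {
  s <- extract_intra_signals(aln_row(cigar = "200M60D30M70D200M"), 50L)
  expect_equal(s$sv_type, "DEL")
  expect_equal(s$pos, 200L)
  expect_equal(s$size, 130L)
  # oracle agreement: D ops at 200 (60) and 290 (70), gap 30 <= max(100, 65)
  orc <- oracle_merge_ops(c(200L, 290L), c(60L, 70L))
  expect_length(orc, 1L)
  expect_equal(orc[[1]]$size, 130L)
  # far-apart ops stay separate on both paths
  s2 <- extract_intra_signals(aln_row(cigar = "200M60D500M70D200M"), 50L)
  expect_equal(nrow(s2), 2L)
  expect_length(oracle_merge_ops(c(200L, 760L), c(60L, 70L)), 2L)
})

test_that("split pairs classify by priority TRA > INV > gap arithmetic", {
  # DEL: reference skips 500 bp, read contiguous
  a <- with_read_spans(aln_row(cigar = "1000M1000S", ref_start = 19000L,
                               read_id = "r"))
  b <- with_read_spans(aln_row(cigar = "1000S1000M", ref_start = 20500L,
                               read_id = "r"))
  del <- classify_split_pair(a[1, ], b[1, ], 30L)
  expect_equal(del$sv_type, "DEL")
  expect_equal(del$pos, 20000L)
  expect_equal(del$size, 500L)
  # DUP: right segment starts 300 bp before the left segment ends
  b2 <- with_read_spans(aln_row(cigar = "1000S1000M", ref_start = 19700L,
                                read_id = "r"))
  dup <- classify_split_pair(a[1, ], b2[1, ], 30L)
  expect_equal(dup$sv_type, "DUP")
  expect_equal(dup$size, 300L)
  expect_equal(dup$pos, 19700L)
  # INV: strands differ
  b3 <- with_read_spans(aln_row(cigar = "1000S1000M", ref_start = 25000L,
                                strand = "-", read_id = "r"))
  expect_equal(classify_split_pair(a[1, ], b3[1, ], 30L)$sv_type, "INV")
  # TRA: chromosomes differ, both breakpoints recorded
  b4 <- with_read_spans(aln_row(cigar = "1000S1000M", ref_start = 5000L,
                                chrom = "c5", read_id = "r"))
  tra <- classify_split_pair(a[1, ], b4[1, ], 30L)
  expect_equal(tra$sv_type, "TRA")
  expect_equal(sort(c(tra$pos, tra$pos2)), c(5000L, 20000L))
  expect_setequal(c(tra$chrom, tra$chrom2), c("c1", "c5"))
  # contract violation
  b5 <- with_read_spans(aln_row(cigar = "1000S1000M", read_id = "other"))
  expect_error(classify_split_pair(a[1, ], b5[1, ], 30L), "different reads")
})

test_that("per-read split scanning bounds an inversion with two signals", {
  segs <- rbind(
    aln_row(read_id = "r", cigar = "1000M2000S", ref_start = 0L),
    aln_row(read_id = "r", cigar = "1000S1000M1000S", ref_start = 1000L,
            strand = "-", is_supplementary = TRUE),
    aln_row(read_id = "r", cigar = "2000S1000M", ref_start = 2000L,
            is_supplementary = TRUE)
  )
  sig <- extract_split_signals(with_read_spans(segs), 30L)
  expect_equal(nrow(sig), 2L)
  expect_true(all(sig$sv_type == "INV"))
  expect_equal(sig$pos, c(1000L, 1000L))
  expect_equal(sig$inv_end, c(2000L, 2000L))
  # unsplit read yields nothing
  expect_equal(nrow(extract_split_signals(
    with_read_spans(aln_row(cigar = "1000M")), 30L)), 0L)
})

test_that("long clips are recorded above the 200 bp threshold", {
  one <- record_clip_signals(aln_row(cigar = "250S1000M", ref_start = 5000L,
                                     seq = strrep("A", 1250)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$side, "left")
  expect_equal(one$pos, 5000L)
  expect_equal(one$clip_len, 250L)
  expect_equal(nrow(record_clip_signals(aln_row(cigar = "150S1000M"))), 0L)
  both <- record_clip_signals(aln_row(cigar = "300S1000M400S",
                                      seq = strrep("A", 1700)))
  expect_equal(nrow(both), 2L)
  expect_setequal(both$side, c("left", "right"))
})

test_that("depth estimation and the N_supp rule follow the depth formula", {
  g <- genome_from_seqs(c(c1 = strrep("A", 10000)))
  aln <- do.call(rbind, lapply(1:10, function(i)
    aln_row(read_id = paste0("r", i), cigar = "1000M",
            ref_start = (i - 1L) * 900L)))
  prof <- estimate_depth(aln, g)
  expect_equal(prof$mean_depth, 1.0)
  expect_equal(prof$n_supp, 2L)
  expect_equal(compute_nsupp(50), 7L)
  expect_equal(compute_nsupp(45), 6L)
})

test_that("signal extraction is order-independent across records", {
  ds <- mini_sim(c(DEL = 4, INS = 4, DUP = 1, INV = 1, TRA = 0), depth = 6,
                 seed = 21)
  s1 <- extract_intra_signals(ds$aln)
  shuffled <- ds$aln[sample(nrow(ds$aln)), ]
  s2 <- extract_intra_signals(shuffled)
  key <- function(s) do.call(paste, s[order(s$chrom, s$pos, s$read_id),
                                      c("sv_type", "chrom", "pos", "size",
                                        "read_id")])
  expect_equal(key(s1), key(s2))
  # no signal below the floor, no clip below 200
  expect_true(all(s1$size >= 30L))
  expect_true(all(record_clip_signals(ds$aln)$clip_len >= 200L))
})
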