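# POA consensus and breakpoint refinement

test_that("POA consensus equals the read set's majority", {
  five <- setNames(rep("ACGTACGTACGTACGT", 5), paste0("r", 1:5))
  expect_equal(build_poa_consensus(five)$seq, "ACGTACGTACGTACGT")
  # one read differing at one column: majority base wins
  reads <- c(r1 = "ACGTACGTAC", r2 = "ACGTACGTAC", r3 = "ACGTTCGTAC",
             r4 = "ACGTACGTAC", r5 = "ACGTACGTAC")
  expect_equal(build_poa_consensus(reads)$seq, "ACGTACGTAC")
  # column-majority oracle on random gap-free equal-length inputs
  set.seed(81)
  for (rep in 1:10) {
    hap <- strsplit(rand_dna(120), "")[[1]]
    mat <- replicate(7, {
      x <- hap
      k <- sample(120, 6)
      x[k] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
      x
    })
    majority <- apply(mat, 1, function(col) {
      tb <- sort(table(col), decreasing = TRUE)
      # unique majority only (ties depend on read order)
      if (length(tb) > 1L && tb[1] == tb[2]) NA_character_ else names(tb)[1]
    })
    reads <- setNames(apply(mat, 2, paste, collapse = ""),
                      sprintf("r%02d", 1:7))
    cons <- strsplit(build_poa_consensus(reads)$seq, "")[[1]]
    ok <- !is.na(majority)
    expect_equal(cons[ok], majority[ok])
  }
})

test_that("POA needs at least two usable reads", {
  expect_s3_class(build_poa_consensus(c(r1 = "ACGT")), "PoaFailure")
  expect_s3_class(build_poa_consensus(character(0)), "PoaFailure")
})

test_that("consensus from noisy reads beats the raw read error rate", {
  set.seed(82)
  mutate <- function(hap, etot) {
    n <- nchar(hap)
    m <- rbinom(1, n, etot)
    pos <- sort(sample.int(n, m)) - 1L
    ty <- sample.int(3, m, replace = TRUE, prob = c(.4, .3, .3))
    svdense:::cpp_apply_edits_seq(
      hap, pos[ty == 1], sample(c("A", "C", "G", "T"), sum(ty == 1), TRUE),
      pos[ty == 2], sample(c("A", "C", "G", "T"), sum(ty == 2), TRUE),
      pos[ty == 3])
  }
  wins <- 0L
  trials <- 40L
  for (t in seq_len(trials)) {
    hap <- rand_dna(600)
    reads <- setNames(vapply(1:10, function(i) mutate(hap, 0.15),
                             character(1)), sprintf("r%02d", 1:10))
    cons <- build_poa_consensus(reads)$seq
    al <- svdense:::cpp_align_local(cons, hap)
    cons_err <- 1 - al$n_match / max(al$n_cols, 1)
    if (cons_err < 0.15) wins <- wins + 1L
  }
  expect_gte(wins / trials, 0.95)
})

test_that("local realignment recovers excisions, insertions and junctions", {
  set.seed(83)
  ref <- rand_dna(3000)
  g <- genome_from_seqs(c(c1 = ref))
  # deletion: consensus = window with 500 bp excised; the detected interval
  # must reconstruct the consensus exactly from the reference (independent
  # sequence-identity oracle, no alignment involved)
  cons <- paste0(substr(ref, 1, 1200), substr(ref, 1701, 3000))
  det <- realign_local(cons, g, "c1", 0L, 3000L, "DEL")
  expect_equal(det$sv_type, "DEL")
  expect_equal(det$size, 500L)
  rebuilt <- paste0(substr(ref, 1, det$pos),
                    substr(ref, det$pos + det$size + 1, 3000))
  expect_equal(rebuilt, cons)
  # insertion
  ins <- rand_dna(300)
  cons2 <- paste0(substr(ref, 1, 1500), ins, substr(ref, 1501, 3000))
  det2 <- realign_local(cons2, g, "c1", 0L, 3000L, "INS")
  expect_equal(det2$size, 300L)
  rebuilt2 <- paste0(substr(ref, 1, det2$pos), det2$ins_seq,
                     substr(ref, det2$pos + 1, 3000))
  expect_equal(rebuilt2, cons2)
  # tandem duplication junction (reference-backward jump)
  cons3 <- paste0(substr(ref, 1, 1400), substr(ref, 1001, 1400),
                  substr(ref, 1401, 3000))
  det3 <- realign_local(cons3, g, "c1", 0L, 3000L, "DUP")
  expect_equal(det3$size, 400L)
  # SV-free and random consensus both fail
  expect_s3_class(realign_local(substr(ref, 500, 2500), g, "c1", 0L, 3000L,
                                "DEL"), "RealignFailure")
  expect_s3_class(realign_local(rand_dna(1500), g, "c1", 0L, 3000L, "INS"),
                  "RealignFailure")
})

test_that("refinement lands on the exact constructed breakpoint", {
  ds <- mini_sim(c(DEL = 3, INS = 3, DUP = 0, INV = 0, TRA = 0),
                 lens = c(cA = 250000), depth = 12, err = "pacbio-clr",
                 seed = 84, het_fraction = 0)
  res <- sv_call(ds$aln, ds$genome)
  calls <- res$calls[res$calls$filter == "PASS", ]
  expect_true(all(calls$precise))
  ev <- match_calls(ds$truth, calls)
  expect_equal(sort(ev$matches$pos_shift), rep(0L, nrow(ds$truth)))
})

test_that("failed refinement falls back to the rounded mean of signals", {
  mem <- svdense:::new_signal_df(3L)
  mem$sv_type <- "DEL"; mem$chrom <- "c1"
  mem$pos <- c(1000L, 1001L, 1001L); mem$size <- c(60L, 61L, 62L)
  mem$read_id <- paste0("r", 1:3); mem$mapq <- 60L
  mem$rec <- NA_integer_
  cl <- svdense:::new_cluster("DEL", "c1", mem, 1001L, 3)
  g <- genome_from_seqs(c(c1 = rand_dna(5000)))
  aln <- aln_row(cigar = "100M")  # no usable spanning reads
  ref <- refine_breakpoints(cl, g, aln)
  expect_false(ref$precise)
  expect_equal(ref$pos, 1001L)  # mean 1000.67 rounds half-up to 1001
  expect_equal(ref$size, 61L)
})

test_that("refinement is deterministic in read input order", {
  set.seed(85)
  hap <- rand_dna(900)
  reads <- setNames(vapply(1:8, function(i) {
    n <- nchar(hap); m <- rbinom(1, n, 0.1)
    pos <- sort(sample.int(n, m)) - 1L
    svdense:::cpp_apply_edits_seq(hap, pos,
      sample(c("A", "C", "G", "T"), m, TRUE), integer(0), character(0),
      integer(0))
  }, character(1)), sprintf("r%02d", 1:8))
  c1 <- build_poa_consensus(reads)$seq
  c2 <- build_poa_consensus(rev(reads))$seq
  expect_identical(c1, c2)
})
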