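# filtering, genotyping, duplication rescue and VCF output

mk_call <- function(sv_type = "DEL", pos = 10000L, size = 500L,
                    n_supp = 10L, local_depth = 40, mapq = 60,
                    locus_id = 1L, allele_index = 0L, ins_seq = NA) {
  data.frame(
    sv_type = sv_type, chrom = "c1", pos = pos, size = size,
    end = if (sv_type == "INS") pos else pos + size,
    chrom2 = NA_character_, pos2 = NA_integer_, n_supp_reads = n_supp,
    local_depth = local_depth, genotype = "./.", precise = TRUE,
    ins_seq = as.character(ins_seq), mapq_mean = mapq,
    locus_id = locus_id, allele_index = allele_index, filter = "PASS",
    stringsAsFactors = FALSE
  )
}

test_that("N_supp follows floor(depth/10) + 2 with a floor of 2", {
  expect_equal(compute_nsupp(50), 7L)
  expect_equal(compute_nsupp(0), 2L)
  expect_equal(compute_nsupp(10), 3L)
  expect_equal(compute_nsupp(45), 6L)
})

test_that("support and MAPQ filters flag candidates", {
  calls <- rbind(mk_call(n_supp = 6L), mk_call(n_supp = 8L, locus_id = 2L),
                 mk_call(n_supp = 20L, mapq = 5, locus_id = 3L))
  f <- filter_candidates(calls, mapq_min = 20, n_supp = 7L)
  expect_equal(f$filter, c("low_support", "PASS", "low_mapq"))
})

test_that("multi-allele loci with one passing allele demote to single", {
  calls <- rbind(mk_call(n_supp = 8L, allele_index = 1L),
                 mk_call(n_supp = 3L, allele_index = 2L, size = 900L))
  f <- filter_candidates(calls, n_supp = 7L)
  pass <- f[f$filter == "PASS", ]
  expect_equal(nrow(pass), 1L)
  expect_equal(pass$allele_index, 0L)  # demoted to single-allele
  expect_equal(pass$n_supp_reads, 8L)
})

test_that("genotypes follow the support ratio with a 0.75 hom cutoff", {
  g <- genotype_calls(rbind(mk_call(n_supp = 40L, local_depth = 40),
                            mk_call(n_supp = 20L, local_depth = 40,
                                    locus_id = 2L)))
  expect_equal(g$genotype, c("1/1", "0/1"))
  both <- genotype_calls(rbind(
    mk_call(n_supp = 20L, local_depth = 40, allele_index = 1L),
    mk_call(n_supp = 18L, local_depth = 40, allele_index = 2L,
            size = 900L)))
  expect_equal(both$genotype, c("1/2", "1/2"))
  # monotonicity: more support never moves 1/1 back to 0/1
  ratios <- vapply(c(10, 20, 30, 35, 40), function(ns)
    genotype_calls(mk_call(n_supp = ns, local_depth = 40))$genotype,
    character(1))
  expect_false(any(ratios == "0/1" & c("", head(ratios, -1)) == "1/1"))
})

test_that("duplication rescue realigns inserted sequences to the flank", {
  set.seed(101)
  ref <- rand_dna(6000)
  g <- genome_from_seqs(c(c1 = ref))
  copy <- substr(ref, 2701, 3000)  # the 300 bp immediately left of pos 3000
  call <- mk_call("INS", pos = 3000L, size = 300L, ins_seq = copy)
  resc <- rescue_duplication(call, rep(copy, 8), g)
  expect_equal(resc$sv_type, "DUP")
  # random inserted sequences stay INS
  rnd <- vapply(1:8, function(i) rand_dna(300), character(1))
  expect_equal(rescue_duplication(call, rnd, g)$sv_type, "INS")
  # exactly 50% aligning is not enough ("more than 50%" is strict)
  half <- c(rep(copy, 4), vapply(1:4, function(i) rand_dna(300),
                                 character(1)))
  expect_equal(rescue_duplication(call, half, g)$sv_type, "INS")
})

test_that("VCF output uses 1-based coordinates and negative DEL SVLEN", {
  g <- genome_from_seqs(c(c1 = rand_dna(20000)))
  del <- mk_call("DEL", pos = 9999L, size = 500L)
  del <- genotype_calls(del)
  path <- tempfile(fileext = ".vcf")
  write_vcf(del, g, path)
  body <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  f <- strsplit(body, "\t")[[1]]
  expect_equal(as.integer(f[2]), 10000L)
  expect_match(f[8], "SVLEN=-500;")
  expect_match(f[8], "END=10500;")
})

test_that("an empty call set writes a valid header-only VCF", {
  g <- genome_from_seqs(c(c1 = rand_dna(100)))
  path <- tempfile(fileext = ".vcf")
  write_vcf(svdense:::empty_calls(), g, path)
  ln <- readLines(path)
  expect_true(all(startsWith(ln, "#")))
  expect_equal(nrow(read_sv_vcf(path)), 0L)
})

test_that("VCF writing and parsing round-trip all pipeline call fields", {
  ds <- mini_sim(c(DEL = 4, INS = 4, DUP = 2, INV = 2, TRA = 1), depth = 8,
                 err = "hifi", seed = 9)
  res <- sv_call(ds$aln, ds$genome)
  path <- tempfile(fileext = ".vcf")
  write_vcf(res$calls, ds$genome, path)
  back <- read_sv_vcf(path)
  p <- res$calls[res$calls$filter == "PASS", ]
  p <- p[order(p$chrom, p$pos, p$sv_type), ]
  back <- back[order(back$chrom, back$pos, back$sv_type), ]
  expect_equal(nrow(back), nrow(p))
  for (col in c("sv_type", "chrom", "pos", "size", "genotype", "precise",
                "n_supp_reads", "filter")) {
    expect_equal(unname(back[[col]]), unname(p[[col]]),
                 ignore_attr = TRUE, label = col)
  }
  tra <- back[back$sv_type == "TRA", ]
  expect_equal(tra$chrom2, p$chrom2[p$sv_type == "TRA"])
  expect_equal(tra$pos2, p$pos2[p$sv_type == "TRA"])
})
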