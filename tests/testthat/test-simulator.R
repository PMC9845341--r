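# ground-truth simulation, haplotype construction and oracle alignments

test_that("truth sets carry exact counts and a deterministic 2:1 ratio", {
  cfg <- sim_config(counts = c(DEL = 30, INS = 20, DUP = 5, INV = 5,
                               TRA = 2),
                    chrom_lengths = c(cA = 2e6, cB = 2e6), seed = 3)
  truth <- sample_sv_set(cfg)
  expect_equal(unname(table(truth$sv_type)[c("DEL", "INS", "DUP", "INV",
                                             "TRA")]),
               c(30L, 20L, 5L, 5L, 2L), ignore_attr = TRUE)
  # n = 9 of one type -> 6 het, 3 hom (round(2n/3) heterozygotes)
  t9 <- sample_sv_set(sim_config(counts = c(DEL = 9),
                                 chrom_lengths = c(cA = 2e6), seed = 4))
  expect_equal(sum(t9$zygosity == "het"), 6L)
  expect_equal(sum(t9$zygosity == "hom"), 3L)
  expect_true(all(t9$haplotype[t9$zygosity == "hom"] == "both"))
  expect_true(all(t9$haplotype[t9$zygosity == "het"] %in% c("1", "2")))
  # empty config -> empty truth
  expect_equal(nrow(sample_sv_set(sim_config(counts = c(DEL = 0),
                                             chrom_lengths = c(cA = 2e6)))),
               0L)
})

test_that("haplotype construction follows the SV edits", {
  set.seed(31)
  g <- genome_from_seqs(c(cA = rand_dna(10000)))
  truth <- data.frame(
    id = 1L, sv_type = "DEL", chrom = "cA", pos = 4000L, size = 500L,
    zygosity = "hom", haplotype = "both", ins_seq = NA_character_,
    chrom2 = NA_character_, pos2 = NA_integer_, stringsAsFactors = FALSE
  )
  sim <- apply_svs_to_genome(g, truth)
  expect_equal(nchar(sim$haps[["1"]]$cA), 9500L)
  expect_equal(nchar(sim$haps[["2"]]$cA), 9500L)
  ins <- truth
  ins$sv_type <- "INS"; ins$zygosity <- "het"; ins$haplotype <- "1"
  ins$size <- 300L; ins$ins_seq <- rand_dna(300)
  sim2 <- apply_svs_to_genome(g, ins)
  expect_equal(nchar(sim2$haps[["1"]]$cA), 10300L)
  expect_equal(sim2$haps[["2"]]$cA, g$seq$cA)
  inv <- truth
  inv$sv_type <- "INV"
  sim3 <- apply_svs_to_genome(g, inv)
  p <- sim3$truth$pos; s <- sim3$truth$size
  expect_equal(substr(sim3$haps[["1"]]$cA, p + 1, p + s),
               svdense:::cpp_revcomp(substr(g$seq$cA, p + 1, p + s)))
})

test_that("error-free reads are exact haplotype substrings", {
  ds <- mini_sim(c(DEL = 3, INS = 3), depth = 5, seed = 32)
  for (k in sample(nrow(ds$readset$reads), 5)) {
    rd <- ds$readset$reads[k, ]
    expect_equal(substr(ds$sim$haps[[rd$hap]][[rd$chrom]], rd$start + 1,
                        rd$start + rd$len) != "", TRUE)
    rec <- ds$aln[ds$aln$read_id == rd$read_id, ][1, ]
    hsub <- substr(ds$sim$haps[[rd$hap]][[rd$chrom]], rd$start + 1,
                   rd$start + rd$len)
    expect_true(identical(rec$seq, hsub) ||
                  identical(rec$seq, svdense:::cpp_revcomp(hsub)))
  }
})

test_that("oracle alignments encode the spanned SVs in the CIGAR", {
  ds <- mini_sim(c(DEL = 1), lens = c(cA = 100000), depth = 10, seed = 33,
                 mean_len = 20000, het_fraction = 0,
                 size_weights = c(0, 1, 0))  # one hom ~350 bp deletion
  tr <- ds$truth
  spanning <- ds$aln[ds$aln$ref_start < tr$pos - 100 &
                       ds$aln$ref_end > tr$pos + tr$size + 100, ]
  expect_gt(nrow(spanning), 0L)
  expect_true(all(grepl(sprintf("%dD", tr$size), spanning$cigar)))
  # a read away from any SV has a pure-match CIGAR
  clean <- ds$aln[ds$aln$ref_end < tr$pos - 2000, ]
  expect_true(all(grepl("^[0-9]+M$", clean$cigar)))
})

test_that("simulation is seeded and deterministic end to end", {
  ds1 <- mini_sim(c(DEL = 3, INS = 3, INV = 1), depth = 4, seed = 34,
                  err = "nanopore")
  ds2 <- mini_sim(c(DEL = 3, INS = 3, INV = 1), depth = 4, seed = 34,
                  err = "nanopore")
  expect_identical(ds1$truth, ds2$truth)
  expect_identical(ds1$readset$reads, ds2$readset$reads)
  expect_identical(ds1$readset$edits, ds2$readset$edits)
  expect_identical(ds1$aln, ds2$aln)
})

test_that("achieved depth is within 2% of the configured target", {
  ds <- mini_sim(c(DEL = 2), lens = c(cA = 400000), depth = 15, seed = 35)
  total <- sum(as.numeric(ds$readset$reads$len))
  target <- 15 * sum(vapply(ds$sim$haps, function(h)
    sum(nchar(unlist(h))), 1))  / 2  # per-hap depth over both haplotypes
  expect_lt(abs(total - 2 * target) / (2 * target), 0.02)
})

test_that("written truth files are internally consistent", {
  ds <- mini_sim(c(DEL = 3, INS = 3, DUP = 1, INV = 1), depth = 4,
                 seed = 36)
  tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  write_truth(ds$truth, ds$genome, tsv, vcf)
  tt <- read.table(tsv, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  nonins <- tt$sv_type != "INS"
  expect_equal(tt$end[nonins], tt$pos[nonins] + tt$size[nonins])
  expect_equal(tt$end[!nonins], tt$pos[!nonins])
  back <- read_sv_vcf(vcf)
  expect_equal(nrow(back), nrow(ds$truth))
  expect_equal(sort(back$pos[back$sv_type == "DEL"]),
               sort(ds$truth$pos[ds$truth$sv_type == "DEL"]))
})
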