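# density-based clustering and multi-allele separation

sig_at <- function(pos, type = "DEL", size = 300L, chrom = "c1") {
  n <- length(pos)
  s <- svdense:::new_signal_df(n)
  s$sv_type <- type; s$chrom <- chrom; s$pos <- as.integer(pos)
  s$size <- as.integer(size)
  s$read_id <- paste0("r", seq_len(n)); s$source <- "intra"
  s$mapq <- 60L
  s
}

test_that("sparse density counts signals within the bandwidth window", {
  expect_equal(compute_density(rep(100L, 5), 100), rep(5L, 5))
  expect_equal(compute_density(c(100L, 1000100L), 100), c(1L, 1L))
  expect_equal(compute_density(c(100L, 140L, 180L), 100)[2], 3L)
})

test_that("density peaks above N_supp become clusters with 10% boundaries", {
  cl <- density_cluster(sig_at(rep(5000L, 10)), n_supp = 7)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]$members), 10L)
  expect_length(density_cluster(sig_at(rep(5000L, 4)), n_supp = 7), 0L)
  two <- density_cluster(sig_at(c(rep(5000L, 10), rep(55000L, 10))),
                         n_supp = 7)
  expect_length(two, 2L)
  expect_equal(sort(vapply(two, function(x) nrow(x$members), 1L)),
               c(10L, 10L))
})

test_that("well-separated groups equal single-linkage gap clustering", {
  set.seed(71)
  for (rep in 1:50) {
    k <- sample(2:4, 1)
    centers <- sort(sample.int(1e6, k)) * 10L  # >> max bandwidth apart
    pos <- unlist(lapply(centers, function(c)
      c + sample(-40:40, sample(5:12, 1), replace = TRUE)))
    cl <- density_cluster(sig_at(pos), n_supp = 3)
    orc <- oracle_gap_cluster(pos, 1000)
    sizes_cl <- sort(vapply(cl, function(x) nrow(x$members), 1L))
    sizes_or <- sort(lengths(orc))
    expect_equal(sizes_cl, unname(sizes_or))
  }
})

test_that("raising N_supp never increases the number of clusters", {
  set.seed(72)
  for (rep in 1:20) {
    pos <- sort(sample.int(200000L,
                           sample(20:60, 1), replace = TRUE))
    counts <- vapply(c(2, 4, 7, 10), function(ns)
      length(density_cluster(sig_at(pos), n_supp = ns)), 1L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("translocation windows adapt to breakpoint spread", {
  tra <- function(pos, pos2) {
    s <- sig_at(pos, type = "TRA", size = 0L)
    s$chrom2 <- "c2"; s$pos2 <- as.integer(pos2)
    s
  }
  tight <- cluster_translocations(tra(10000 + sample(-50:50, 8),
                                      90000 + sample(-50:50, 8)))
  expect_length(tight, 1L)
  expect_equal(tight[[1]]$window, 400)
  spread <- seq(-525, 525, by = 150)
  wide <- cluster_translocations(tra(10000 + spread, 90000 + spread))
  expect_length(wide, 1L)
  expect_equal(wide[[1]]$window, 800)
  two <- cluster_translocations(tra(c(rep(10000, 5), rep(10000, 5)),
                                    c(rep(90000, 5), rep(1090000, 5))))
  expect_length(two, 2L)
})

test_that("Q1/Q3 rule separates alleles and trims outliers", {
  single <- split_multiallele(density_cluster(sig_at(rep(1000L, 8),
                                                     size = 300L), 2)[[1]])
  expect_length(single, 1L)
  expect_equal(single[[1]]$allele_index, 0L)
  # bimodal sizes: Q1 = 300, Q3 = 900 >= 2 x Q1
  bi <- sig_at(rep(1000L, 10), size = c(rep(300L, 5), rep(900L, 5)))
  cl <- density_cluster(bi, 2)[[1]]
  two <- split_multiallele(cl)
  expect_length(two, 2L)
  means <- sort(vapply(two, function(x) mean(x$members$size), 1))
  expect_equal(means, c(300, 900))
  expect_setequal(vapply(two, function(x) x$allele_index, 1L), 1:2)
  # single member passes through unchanged
  one <- density_cluster(sig_at(1000L), 1)[[1]]
  expect_length(split_multiallele(one), 1L)
  # low outlier below Q1/2 is removed on the single-allele branch
  out <- sig_at(rep(1000L, 9), size = c(rep(100L, 8), 20L))
  kept <- split_multiallele(density_cluster(out, 2)[[1]])[[1]]
  expect_equal(nrow(kept$members), 8L)
})

test_that("exact 1-D 2-means equals the exhaustive optimal threshold split", {
  set.seed(73)
  for (rep in 1:100) {
    x <- sample.int(2000L, sample(2:12, 1), replace = TRUE)
    km <- kmeans1d_2(x)
    expect_equal(km$wss, oracle_best_split(x), tolerance = 1e-9)
    # assignment is a threshold split consistent with the means
    expect_true(max(x[km$assign == 1]) <= min(x[km$assign == 2]) ||
                  km$means[1] == km$means[2])
  }
})

test_that("clustering partitions signals: no signal is in two clusters", {
  set.seed(74)
  pos <- sort(c(sample.int(50000L, 40, replace = TRUE),
                rep(80000L, 12), rep(81000L, 9)))
  sig <- sig_at(pos)
  cl <- density_cluster(sig, 3)
  ids <- unlist(lapply(cl, function(x) x$members$read_id))
  expect_equal(anyDuplicated(ids), 0L)
  # windows of same-type clusters do not overlap
  if (length(cl) > 1L) {
    w <- t(vapply(cl, function(x) c(x$window_start, x$window_end),
                  c(0, 0)))
    w <- w[order(w[, 1]), , drop = FALSE]
    expect_true(all(w[-1, 1] >= w[-nrow(w), 2]))
  }
})
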