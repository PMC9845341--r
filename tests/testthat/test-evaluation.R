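# truth matching, metrics and breakpoint-shift profiling

truth_row <- function(sv_type = "DEL", chrom = "c1", pos = 10000L,
                      size = 500L, chrom2 = NA, pos2 = NA) {
  data.frame(sv_type = sv_type, chrom = chrom, pos = pos, size = size,
             chrom2 = as.character(chrom2), pos2 = as.integer(pos2),
             stringsAsFactors = FALSE)
}

call_row <- function(sv_type = "DEL", chrom = "c1", pos = 10000L,
                     size = 500L, chrom2 = NA, pos2 = NA) {
  df <- truth_row(sv_type, chrom, pos, size, chrom2, pos2)
  df$filter <- "PASS"
  df
}

test_that("the three TP conditions are enforced", {
  tg <- truth_row()
  # shift 900 <= 1 kbp and 250 <= 600 <= 1000: TP
  ev <- match_calls(tg, call_row(pos = 10900L, size = 600L))
  expect_equal(ev$tp, 1L)
  # size 1001 > 2 x 500: FP + FN
  ev2 <- match_calls(tg, call_row(pos = 10000L, size = 1001L))
  expect_equal(ev2$tp, 0L)
  expect_length(ev2$fp_calls, 1L)
  # wrong type: FP
  ev3 <- match_calls(tg, call_row(sv_type = "INS", size = 500L))
  expect_equal(ev3$tp, 0L)
  # translocations need both breakpoints within 1 kbp
  tgt <- truth_row("TRA", "c1", 10000L, 0L, "c2", 50000L)
  expect_equal(match_calls(tgt, call_row("TRA", "c1", 10500L, 0L, "c2",
                                         50400L))$tp, 1L)
  expect_equal(match_calls(tgt, call_row("TRA", "c1", 10500L, 0L, "c2",
                                         52000L))$tp, 0L)
})

test_that("metrics follow the recall/precision/F1 definitions", {
  truth <- do.call(rbind, lapply(1:10, function(i)
    truth_row(pos = i * 10000L)))
  calls <- do.call(rbind, c(lapply(1:9, function(i)
    call_row(pos = i * 10000L)), list(call_row(pos = 990000L))))
  m <- compute_metrics(match_calls(truth, calls))
  all_row <- m[m$type == "ALL", ]
  expect_equal(all_row$recall, 0.9)
  expect_equal(all_row$precision, 0.9)
  expect_equal(all_row$f1, 0.9)
  # no calls: recall 0, precision defined as 0
  m0 <- compute_metrics(match_calls(truth, calls[0, ]))
  expect_equal(m0$recall[m0$type == "ALL"], 0)
  expect_equal(m0$precision[m0$type == "ALL"], 0)
  # perfect recovery
  m1 <- compute_metrics(match_calls(truth, calls[1:9, ][rep(1:9, 1), ][
    order(1:9), ][1:9, ]))
  expect_equal(m1$f1[m1$type == "ALL"], 2 * 0.9 / 1.9)
})

test_that("breakpoint shifts are profiled with clamped +/-100 bins", {
  truth <- do.call(rbind, lapply(1:4, function(i)
    truth_row(pos = i * 10000L)))
  calls <- do.call(rbind, lapply(seq_along(c(0L, 0L, 1L, -3L)), function(i)
    call_row(pos = i * 10000L + c(0L, 0L, 1L, -3L)[i])))
  bp <- breakpoint_shift_profile(match_calls(truth, calls))
  expect_equal(bp$frac_exact, 0.5)
  expect_equal(bp$frac_within1, 0.75)
  big <- breakpoint_shift_profile(
    match_calls(truth_row(), call_row(pos = 10250L)))
  expect_equal(unname(big$histogram["100"]), 1L)
})

test_that("matching is one-to-one and permutation invariant", {
  set.seed(111)
  truth <- do.call(rbind, lapply(1:6, function(i)
    truth_row(pos = 10000L + i * 300L)))
  calls <- do.call(rbind, lapply(1:6, function(i)
    call_row(pos = 10050L + i * 300L)))
  ev <- match_calls(truth, calls)
  expect_equal(anyDuplicated(ev$matches$truth_idx), 0L)
  expect_equal(anyDuplicated(ev$matches$call_idx), 0L)
  ev2 <- match_calls(truth[sample(6), ], calls[sample(6), ])
  expect_equal(ev2$tp, ev$tp)
})

test_that("greedy matching attains the optimal TP count on small instances", {
  set.seed(112)
  disagreements <- 0L
  for (rep in 1:200) {
    nt <- sample(1:6, 1); nc <- sample(1:6, 1)
    truth <- do.call(rbind, lapply(seq_len(nt), function(i)
      truth_row(pos = sample.int(20000L, 1) + 10000L,
                size = sample(c(100L, 300L), 1))))
    calls <- do.call(rbind, lapply(seq_len(nc), function(i)
      call_row(pos = sample.int(20000L, 1) + 10000L,
               size = sample(c(100L, 300L, 900L), 1))))
    ev <- match_calls(truth, calls, min_size = 0)
    edges <- expand.grid(ti = seq_len(nt), ci = seq_len(nc))
    ok <- vapply(seq_len(nrow(edges)), function(k) {
      tg <- truth[edges$ti[k], ]; cc <- calls[edges$ci[k], ]
      abs(cc$pos - tg$pos) <= 1000 && cc$size >= 0.5 * tg$size &&
        cc$size <= 2 * tg$size
    }, logical(1))
    opt <- oracle_max_matching(edges[ok, , drop = FALSE], nt, nc)
    if (ev$tp != opt) disagreements <- disagreements + 1L
  }
  expect_lte(disagreements / 200, 0.01)
})

test_that("multimatch mode lets one truth validate several calls", {
  truth <- truth_row()
  calls <- rbind(call_row(pos = 10050L), call_row(pos = 10100L))
  expect_equal(match_calls(truth, calls)$tp, 1L)
  mm <- match_calls(truth, calls, multimatch = TRUE)
  expect_equal(nrow(mm$matches), 2L)
  expect_length(mm$fp_calls, 0L)
})
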