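# Benchmarking a call set against a simulated truth set.
#
# A call is a true positive when (1) its type matches the truth type, (2)
# its start coordinate is within 1 kbp of the truth coordinate and (3) its
# size is within 0.5-2x of the truth size. Translocations match when both
# breakpoints are within 1 kbp. Matching is greedy one-to-one by ascending
# coordinate distance (a multi-match mode is available).

#' Match SV calls to a truth set
#'
#' @param truth truth data.frame (sv_type, chrom, pos, size, chrom2, pos2,
#'   ...), e.g. from [sample_sv_set()] / [apply_svs_to_genome()].
#' @param calls SV call data.frame (PASS rows of a callset, or
#'   [read_sv_vcf()] output).
#' @param max_shift coordinate tolerance (bp).
#' @param min_size size floor applied symmetrically to truth and calls
#'   (TRA exempt); 0 disables.
#' @param multimatch allow one truth to match several calls (and vice
#'   versa).
#' @param ins_dup_equiv treat INS calls as matching DUP truths and vice
#'   versa.
#' @return object of class "svd_eval": list(matches, tp, fp_calls,
#'   fn_truth, per_type, n_truth, n_calls).
#' @export
match_calls <- function(truth, calls, max_shift = 1000, min_size = 45,
                        multimatch = FALSE, ins_dup_equiv = FALSE) {
  truth <- truth[truth$sv_type == "TRA" | truth$size >= min_size, ,
                 drop = FALSE]
  calls <- calls[calls$sv_type == "TRA" | calls$size >= min_size, ,
                 drop = FALSE]
  if (!is.null(calls$filter))
    calls <- calls[calls$filter == "PASS", , drop = FALSE]
  nt <- nrow(truth); nc <- nrow(calls)
  type_ok <- function(tg, tc) {
    tg == tc | (ins_dup_equiv & tg %in% c("INS", "DUP") &
                  tc %in% c("INS", "DUP"))
  }
  # candidate pairs
  cand <- NULL
  if (nt > 0L && nc > 0L) {
    pairs <- list()
    for (i in seq_len(nt)) {
      tg <- truth[i, ]
      sel <- which(type_ok(tg$sv_type, calls$sv_type) &
                     calls$chrom == tg$chrom &
                     abs(calls$pos - tg$pos) <= max_shift)
      if (tg$sv_type == "TRA") {
        sel <- sel[!is.na(calls$chrom2[sel]) &
                     calls$chrom2[sel] == tg$chrom2 &
                     abs(calls$pos2[sel] - tg$pos2) <= max_shift]
      } else {
        sel <- sel[calls$size[sel] >= 0.5 * tg$size &
                     calls$size[sel] <= 2 * tg$size]
      }
      if (length(sel))
        pairs[[length(pairs) + 1L]] <- data.frame(
          ti = i, ci = sel, dist = abs(calls$pos[sel] - tg$pos))
    }
    cand <- rbind_dfs(pairs)
  }
  matches <- NULL
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$dist, cand$ti, cand$ci), , drop = FALSE]
    used_t <- rep(FALSE, nt); used_c <- rep(FALSE, nc)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      ti <- cand$ti[k]; ci <- cand$ci[k]
      if (multimatch || (!used_t[ti] && !used_c[ci])) {
        keep[k] <- TRUE
        used_t[ti] <- TRUE; used_c[ci] <- TRUE
      }
    }
    m <- cand[keep, , drop = FALSE]
    matches <- data.frame(
      truth_idx = m$ti, call_idx = m$ci,
      sv_type = truth$sv_type[m$ti],
      pos_shift = calls$pos[m$ci] - truth$pos[m$ti],
      size_ratio = ifelse(truth$size[m$ti] > 0,
                          calls$size[m$ci] / truth$size[m$ti], 1),
      stringsAsFactors = FALSE
    )
  }
  tp_t <- if (is.null(matches)) integer(0) else unique(matches$truth_idx)
  tp_c <- if (is.null(matches)) integer(0) else unique(matches$call_idx)
  types <- c("DEL", "INS", "DUP", "INV", "TRA")
  per_type <- lapply(types, function(ty) {
    ti <- which(truth$sv_type == ty)
    ci <- which(calls$sv_type == ty)
    tp <- length(intersect(ti, tp_t))
    list(type = ty, tp = tp, fn = length(ti) - tp,
         fp = length(setdiff(ci, tp_c)))
  })
  names(per_type) <- types
  structure(list(
    matches = matches, tp = length(tp_t),
    fp_calls = setdiff(seq_len(nc), tp_c),
    fn_truth = setdiff(seq_len(nt), tp_t),
    per_type = per_type, n_truth = nt, n_calls = nc
  ), class = "svd_eval")
}

safe_div <- function(a, b) if (b > 0) a / b else 0

#' Recall / precision / F1 from a matching
#'
#' @param result "svd_eval" from [match_calls()].
#' @return data.frame with one row per SV type plus an overall row
#'   (tp, fp, fn, recall, precision, f1; proportions in `[0,1]`).
#' @export
compute_metrics <- function(result) {
  rows <- lapply(result$per_type, function(p) {
    rec <- safe_div(p$tp, p$tp + p$fn)
    pre <- safe_div(p$tp, p$tp + p$fp)
    f1 <- if (rec + pre > 0) 2 * rec * pre / (rec + pre) else 0
    data.frame(type = p$type, tp = p$tp, fp = p$fp, fn = p$fn, recall = rec,
               precision = pre, f1 = f1, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  tp <- sum(df$tp); fp <- sum(df$fp); fn <- sum(df$fn)
  rec <- safe_div(tp, tp + fn); pre <- safe_div(tp, tp + fp)
  f1 <- if (rec + pre > 0) 2 * rec * pre / (rec + pre) else 0
  rbind(df, data.frame(type = "ALL", tp = tp, fp = fp, fn = fn,
                       recall = rec, precision = pre, f1 = f1,
                       stringsAsFactors = FALSE))
}

#' Breakpoint-shift profile of the true positives
#'
#' @param result "svd_eval".
#' @return list(histogram = named counts over shifts -100..100 (clamped),
#'   frac_exact, frac_within1, n).
#' @export
breakpoint_shift_profile <- function(result) {
  shifts <- if (is.null(result$matches)) integer(0)
            else result$matches$pos_shift
  clamped <- pmin(pmax(shifts, -100L), 100L)
  hist <- table(factor(clamped, levels = -100:100))
  n <- length(shifts)
  list(histogram = hist,
       frac_exact = safe_div(sum(shifts == 0L), n),
       frac_within1 = safe_div(sum(abs(shifts) <= 1L), n),
       n = n)
}

#' @export
print.svd_eval <- function(x, ...) {
  m <- compute_metrics(x)
  cat("svd_eval:", x$n_truth, "truth /", x$n_calls, "calls\n")
  print(m, row.names = FALSE)
  invisible(x)
}
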