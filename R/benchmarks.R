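# Desk-scale benchmark experiments: a scaled-down version of the full
# simulation protocol (same type proportions, size model, 2:1 het:hom ratio
# and per-haplotype depth, on a 5 Mbp synthetic genome) and the ultra-large
# insertion study (homozygous 20-30 kbp insertions against 15 kbp reads).

#' Scaled-down whole-genome benchmark configuration
#'
#' 5 Mbp synthetic genome (4 chromosomes), ~400 SVs in the standard type
#' proportions (180 DEL, 180 INS, 18 DUP, 18 INV, 4 TRA = the 22,200-SV
#' composition scaled by 1/55.5), 2:1 het:hom, 25x per haplotype, 15 kbp
#' mean reads.
#'
#' @param preset error preset ("pacbio-clr" or "nanopore").
#' @param seed RNG seed.
#' @return "svd_sim_config".
#' @export
bench_sim_config <- function(preset = "pacbio-clr", seed = 1L) {
  sim_config(
    counts = c(DEL = 180, INS = 180, DUP = 18, INV = 18, TRA = 4),
    chrom_lengths = c(c1 = 1250000, c2 = 1250000, c3 = 1250000,
                      c4 = 1250000),
    depth_per_hap = 25, read_mean = 15000, preset = preset, seed = seed
  )
}

#' Run the scaled-down benchmark end to end
#'
#' Simulates the dataset, runs the full caller on the oracle alignments and
#' scores it against the truth with the standard TP criteria (matching
#' type, breakpoint within 1 kbp, size within 0.5-2x).
#'
#' @param preset error preset.
#' @param seed RNG seed.
#' @return list(metrics, shift, eval, callset, truth).
#' @export
bench_run <- function(preset = "pacbio-clr", seed = 1L) {
  ds <- simulate_dataset(bench_sim_config(preset, seed))
  res <- sv_call(ds$aln, ds$genome)
  ev <- match_calls(ds$truth, res$calls)
  list(metrics = compute_metrics(ev), shift = breakpoint_shift_profile(ev),
       eval = ev, callset = res, truth = ds$truth)
}

#' Ultra-large insertion benchmark configuration
#'
#' 2 Mbp genome, 20 homozygous insertions of 20-30 kbp, 25x per haplotype
#' (50x total), 15 kbp mean reads: every insertion exceeds the mean read
#' length, so detection relies on the clip-cluster local-assembly module.
#'
#' @param seed RNG seed.
#' @return "svd_sim_config".
#' @export
bench_large_ins_config <- function(seed = 1L) {
  sim_config(
    counts = c(DEL = 0, INS = 20, DUP = 0, INV = 0, TRA = 0),
    chrom_lengths = c(c1 = 1000000, c2 = 1000000),
    depth_per_hap = 25, read_mean = 15000, preset = "pacbio-clr",
    het_fraction = 0, size_weights = c(1, 0, 0), bg_mean = 25000,
    min_size = 20000, max_size = 30000, end_margin = 25000, seed = seed
  )
}

#' Run the ultra-large insertion benchmark
#'
#' @param seed RNG seed.
#' @return list(recall, n_truth, metrics, eval, callset, truth); recall is
#'   the homozygous-insertion recall in the 20-30 kbp bin (proportion).
#' @export
bench_large_ins_run <- function(seed = 1L) {
  ds <- simulate_dataset(bench_large_ins_config(seed))
  res <- sv_call(ds$aln, ds$genome)
  ev <- match_calls(ds$truth, res$calls)
  m <- compute_metrics(ev)
  list(recall = m$recall[m$type == "INS"], n_truth = nrow(ds$truth),
       metrics = m, eval = ev, callset = res, truth = ds$truth)
}
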