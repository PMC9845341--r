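# Density-based clustering of raw SV signals.
#
# Signals of one type on one chromosome are merged into SV candidates by
# scanning for density peaks: a peak needs summit density >= the
# depth-adaptive support threshold, and the cluster window extends on both
# sides of the summit until the signal density drops below 10% of the summit
# height. The clustering bandwidth adapts to the event size (larger windows
# for longer SVs). Translocations use fixed 400/800 bp windows instead.
# Candidate clusters whose member sizes are bimodal (Q3 >= 2 x Q1) are split
# into two alleles with an exact one-dimensional 2-means.

#' Sparse signal density
#'
#' density(p) = number of signals within bandwidth/2 of p, evaluated at the
#' signal positions themselves.
#'
#' @param positions sorted integer positions.
#' @param bandwidth window width in bp (scalar or per-position vector).
#' @return integer vector of densities, one per position.
#' @export
compute_density <- function(positions, bandwidth = 100) {
  if (is.unsorted(positions)) stop("positions must be sorted")
  h <- bandwidth / 2
  hi <- findInterval(positions + h, positions)
  lo <- findInterval(positions - h - 0.5, positions)
  hi - lo
}

# peak scan over sorted positions with per-signal bandwidths; returns a list
# of integer index vectors (cluster members), highest peak first
scan_peaks <- function(positions, bw, n_supp, boundary_frac = 0.10) {
  n <- length(positions)
  alive <- rep(TRUE, n)
  clusters <- list()
  repeat {
    idx <- which(alive)
    if (length(idx) == 0L) break
    pos <- positions[idx]
    dens <- {
      h <- bw[idx] / 2
      findInterval(pos + h, pos) - findInterval(pos - h - 0.5, pos)
    }
    peak <- which.max(dens)
    if (dens[peak] < n_supp) break
    cut <- boundary_frac * dens[peak]
    lo <- peak
    while (lo > 1L && dens[lo - 1L] >= cut &&
           pos[lo] - pos[lo - 1L] <= bw[idx[lo]]) lo <- lo - 1L
    hi <- peak
    while (hi < length(pos) && dens[hi + 1L] >= cut &&
           pos[hi + 1L] - pos[hi] <= bw[idx[hi]]) hi <- hi + 1L
    members <- idx[lo:hi]
    clusters[[length(clusters) + 1L]] <-
      list(members = members, summit_pos = positions[idx[peak]],
           summit_density = dens[peak])
    alive[members] <- FALSE
  }
  clusters
}

new_cluster <- function(sv_type, chrom, members, summit_pos, summit_density,
                        allele_index = 0L) {
  structure(list(
    sv_type = sv_type, chrom = chrom,
    window_start = min(members$pos), window_end = max(members$pos) + 1L,
    summit_pos = summit_pos, summit_density = summit_density,
    members = members, allele_index = allele_index
  ), class = "svd_cluster")
}

#' Density-cluster raw signals of one type on one chromosome
#'
#' Two passes: a provisional pass with a 100 bp bandwidth, then a final pass
#' in which each provisionally clustered signal carries a bandwidth of
#' clamp(0.5 x median member size, 100, 1000) bp, so longer events get wider
#' clustering windows. Peaks are processed from highest summit to lowest and
#' consumed signals are removed, so each signal joins at most one cluster.
#'
#' @param signals raw-signal data.frame of one sv_type/chrom.
#' @param n_supp minimum summit density (peak threshold).
#' @param bw_min,bw_max bandwidth clamp in bp.
#' @return list of "svd_cluster" objects.
#' @export
density_cluster <- function(signals, n_supp, bw_min = 100, bw_max = 1000) {
  if (nrow(signals) == 0L) return(list())
  if (length(unique(signals$sv_type)) > 1L ||
      length(unique(signals$chrom)) > 1L)
    stop("density_cluster expects one sv_type on one chromosome")
  signals <- signals[order(signals$pos), , drop = FALSE]
  pos <- signals$pos
  bw <- rep(bw_min, length(pos))
  prov <- scan_peaks(pos, bw, n_supp)
  for (cl in prov) {
    med <- median(signals$size[cl$members])
    bw[cl$members] <- min(max(0.5 * med, bw_min), bw_max)
  }
  final <- scan_peaks(pos, bw, n_supp)
  lapply(final, function(cl) {
    new_cluster(signals$sv_type[1], signals$chrom[1],
                signals[cl$members, , drop = FALSE],
                cl$summit_pos, cl$summit_density)
  })
}

#' Cluster translocation signals with fixed 400/800 bp windows
#'
#' Signals are grouped when both breakpoints co-locate; groups with small
#' breakpoint-position spread (sd <= 200 bp) use a 400 bp window, groups with
#' larger spread an 800 bp window.
#'
#' @param signals TRA raw-signal data.frame (canonical breakpoint order:
#'   chrom/pos is the smaller side).
#' @param n_supp minimum member count for a cluster to be kept (0 keeps all).
#' @return list of "svd_cluster" objects.
#' @export
cluster_translocations <- function(signals, n_supp = 0L) {
  if (nrow(signals) == 0L) return(list())
  out <- list()
  key <- paste(signals$chrom, signals$chrom2)
  for (k in unique(key)) {
    sub <- signals[key == k, , drop = FALSE]
    sub <- sub[order(sub$pos, sub$pos2), , drop = FALSE]
    # provisional single-linkage with the wide window
    grp_of <- function(df, w) {
      g <- integer(nrow(df)); g[1] <- 1L
      for (i in seq_len(nrow(df))[-1]) {
        prev <- which(g == g[i - 1L])
        if (df$pos[i] - max(df$pos[prev]) <= w &&
            abs(df$pos2[i] - median(df$pos2[prev])) <= w)
          g[i] <- g[i - 1L]
        else g[i] <- g[i - 1L] + 1L
      }
      g
    }
    g800 <- grp_of(sub, 800)
    for (gi in unique(g800)) {
      grp <- sub[g800 == gi, , drop = FALSE]
      spread <- max(sd(grp$pos), sd(grp$pos2))
      if (is.na(spread)) spread <- 0
      w <- if (spread <= 200) 400 else 800
      gfin <- if (w == 400) grp_of(grp, 400) else rep(1L, nrow(grp))
      for (gj in unique(gfin)) {
        mem <- grp[gfin == gj, , drop = FALSE]
        if (nrow(mem) < n_supp) next
        cl <- new_cluster("TRA", mem$chrom[1], mem,
                          round_half_up(mean(mem$pos)), nrow(mem))
        cl$window <- w
        out[[length(out) + 1L]] <- cl
      }
    }
  }
  out
}

#' Exact one-dimensional 2-means
#'
#' The optimal 1-D 2-partition is a threshold split of the sorted values;
#' all n-1 splits are scored by within-cluster sum of squares and the best
#' is returned, so the result always equals the exhaustive optimum (no
#' random initialization).
#'
#' @param x numeric vector (n >= 2).
#' @return list(assign = 1/2 per element (1 = smaller-mean cluster),
#'   means = cluster means, wss = within-cluster sum of squares).
#' @export
kmeans1d_2 <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 values")
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  wss_pre <- cs2 - cs^2 / seq_len(n)
  tot <- cs[n]; tot2 <- cs2[n]
  k <- seq_len(n - 1L)
  wss_suf <- (tot2 - cs2[k]) - (tot - cs[k])^2 / (n - k)
  wss <- wss_pre[k] + wss_suf
  split <- which.min(wss)
  assign_sorted <- rep(2L, n)
  assign_sorted[seq_len(split)] <- 1L
  assign <- integer(n)
  assign[ord] <- assign_sorted
  list(assign = assign,
       means = c(mean(xs[seq_len(split)]), mean(xs[(split + 1L):n])),
       wss = wss[split])
}

#' Separate a cluster into alleles (multi-allele SV detection)
#'
#' Based on the first and third quartiles (inclusive linear-interpolation
#' definition) of member sizes: if Q3 < 2 x Q1 the cluster stays
#' single-allele with size outliers (outside [Q1/2, 2 x Q3]) removed;
#' otherwise the member sizes are split into two alleles with the exact 1-D
#' 2-means. Applies to INS/DEL/DUP clusters only.
#'
#' @param cluster "svd_cluster" object.
#' @return list of 1 or 2 "svd_cluster" objects (allele_index 0, or 1 and 2).
#' @export
split_multiallele <- function(cluster) {
  if (!cluster$sv_type %in% c("INS", "DEL", "DUP") ||
      nrow(cluster$members) < 2L)
    return(list(cluster))
  sizes <- cluster$members$size
  q <- quantile(sizes, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[2] < 2 * q[1]) {
    keep <- sizes >= q[1] / 2 & sizes <= 2 * q[2]
    if (!all(keep) && any(keep)) {
      cluster$members <- cluster$members[keep, , drop = FALSE]
      cluster$window_start <- min(cluster$members$pos)
      cluster$window_end <- max(cluster$members$pos) + 1L
    }
    return(list(cluster))
  }
  km <- kmeans1d_2(sizes)
  lapply(1:2, function(a) {
    mem <- cluster$members[km$assign == a, , drop = FALSE]
    cl <- new_cluster(cluster$sv_type, cluster$chrom, mem,
                      cluster$summit_pos, cluster$summit_density,
                      allele_index = a)
    cl
  })
}
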