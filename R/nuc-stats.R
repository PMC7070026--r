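# Per-site translational positioning statistics, occupancy, usable-site
# filtering, stability terciles and the three-way genome context partition.

#' Per-site nucleosome positioning statistics
#'
#' For each focal site, considers the absolute distances d_i = |midpoint -
#' site| of all fragment midpoints with d_i <= `window` (closed bound) and
#' computes their count `n`, mean `d_mean` and sample variance `d_var`
#' (n-1 denominator). A site with no midpoint in the window has missing
#' (`NA`) statistics, not zeros; `d_var` is missing when n < 2.
#'
#' @param sites data.frame with `chrom` and `pos0` (0-based positions).
#' @param midpoints A `midpoint_set`.
#' @param window Distance bound in bp (default 95, i.e. half the ~191 bp
#'   nucleosome repeat length).
#' @param min_midpoints Minimum midpoint count for a site to be usable.
#' @return data.frame: chrom, pos0, n, d_mean, d_var, d_mean_bin, usable.
#' @export
site_positioning_stats <- function(sites, midpoints, window = 95L,
                                   min_midpoints = 10L) {
  if (window <= 0) stop_nucmut("window must be > 0")
  pos <- as.integer(sites$pos0)
  chrom <- as.character(sites$chrom)
  n <- integer(length(pos))
  d_mean <- rep(NA_real_, length(pos))
  d_var <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- midpoints$positions[[ch]]
    if (is.null(m) || length(m) == 0L) next
    lo <- findInterval(pos[idx] - window - 1L, m)   # count m <= pos-w-1
    hi <- findInterval(pos[idx] + window, m)        # count m <= pos+w
    n[idx] <- hi - lo
    for (k in seq_along(idx)) {
      nk <- hi[k] - lo[k]
      if (nk < 1L) next
      j <- idx[k]
      d <- abs(m[(lo[k] + 1L):hi[k]] - pos[j])
      dm <- mean(d)
      d_mean[j] <- dm
      if (nk >= 2L) d_var[j] <- sum((d - dm)^2) / (nk - 1L)
    }
  }
  bin <- rep(NA_integer_, length(pos))
  okm <- !is.na(d_mean)
  if (any(okm)) bin[okm] <- bin_dmean(d_mean[okm])
  data.frame(chrom = chrom, pos0 = pos, n = n, d_mean = d_mean,
             d_var = d_var, d_mean_bin = bin,
             usable = n >= min_midpoints, stringsAsFactors = FALSE)
}

#' Bin mean midpoint distances into the five canonical categories
#'
#' Bins as printed for integer distances: [0,18], [19,36], [37,54],
#' [55,73], [74,95]. Real-valued means fall in bin k iff they lie in
#' (upper(k-1), upper(k)] with upper = (18, 36, 54, 73, 95), so e.g.
#' 18.5 maps to bin 2.
#'
#' @param d_mean Numeric vector in [0, 95].
#' @return Integer bin labels in 1..5.
#' @export
bin_dmean <- function(d_mean) {
  if (any(is.na(d_mean)) || any(d_mean < 0 | d_mean > 95)) {
    stop_nucmut("d_mean out of range [0, 95]")
  }
  findInterval(d_mean, c(18, 36, 54, 73), left.open = TRUE) + 1L
}

#' Nucleosome occupancy from observed vs control coverage
#'
#' Occupancy is the per-bin ratio of observed MNase fragment coverage to
#' composition-matched control coverage, in bins tiling each chromosome
#' from position 0. Bins with zero control coverage are missing, not 0.
#'
#' @param observed,control Named lists of per-base coverage vectors (one
#'   per chromosome), e.g. from [coverage_from_midpoints()].
#' @param bin Bin width in bp.
#' @return A `signal_track` of occupancy ratios.
#' @export
compute_occupancy <- function(observed, control, bin = 10L) {
  data <- list()
  for (ch in names(observed)) {
    obs <- observed[[ch]]
    ctl <- control[[ch]]
    if (length(obs) != length(ctl)) stop_nucmut("coverage length mismatch on %s", ch)
    if (any(obs < 0) || any(ctl < 0)) stop_nucmut("negative coverage on %s", ch)
    len <- length(obs)
    idx <- (seq_len(len) - 1L) %/% bin
    so <- rowsum(obs, idx)
    sc <- rowsum(ctl, idx)
    ratio <- ifelse(sc > 0, so / sc, NA_real_)
    starts <- as.integer(rownames(so)) * bin
    data[[ch]] <- data.table(start0 = starts,
                             end0 = pmin(starts + bin, len),
                             value = as.numeric(ratio))
  }
  signal_track(data, name = "occupancy", units = "ratio")
}

#' Simulate composition-matched control fragments
#'
#' Control fragment starts are sampled uniformly over the workspace, or
#' weighted by a 5-mer GC-composition model estimated from the observed
#' fragment start positions (enrichment of each GC count 0..5 at observed
#' starts relative to the genome).
#'
#' @param workspace `GRanges` of allowed regions.
#' @param n Number of fragments.
#' @param length Fragment length in bp (default 25, matching short
#'   control reads).
#' @param mode `"uniform"` or `"gc_weighted"`.
#' @param seed Integer seed.
#' @param genome Required for `gc_weighted` mode.
#' @param observed Optional `midpoint_set` of observed fragment midpoints
#'   used to estimate the GC model (gc_weighted mode).
#' @return A `midpoint_set` of control fragment midpoints.
#' @export
simulate_control_fragments <- function(workspace, n, length = 25L,
                                       mode = c("uniform", "gc_weighted"),
                                       seed = 1L, genome = NULL,
                                       observed = NULL) {
  mode <- match.arg(mode)
  if (n == 0L) return(midpoint_set(list()))
  with_seed(seed, {
    if (mode == "uniform") {
      pos <- sample_positions_in_gr(workspace, n)
    } else {
      if (is.null(genome) || is.null(observed)) {
        stop_nucmut("gc_weighted mode needs `genome` and `observed`")
      }
      cand <- sample_positions_in_gr(workspace, n * 10L)
      gc_at <- function(chrom, pos0) {
        counts <- integer(length(pos0))
        for (ch in unique(chrom)) {
          i <- which(chrom == ch)
          s <- as.character(genome[[ch]])
          kmer <- substring(s, pmax(pos0[i] - 1L, 0L) + 1L, pos0[i] + 4L)
          counts[i] <- nchar(gsub("[AT]", "", kmer))
        }
        counts
      }
      obs_pos <- data.table(
        chrom = rep(names(observed$positions),
                    vapply(observed$positions, base::length, 0L)),
        pos0 = unlist(observed$positions, use.names = FALSE))
      obs_gc <- tabulate(gc_at(obs_pos$chrom, obs_pos$pos0) + 1L, 6L)
      cand_gc_counts <- gc_at(cand$chrom, cand$pos0)
      bg_gc <- tabulate(cand_gc_counts + 1L, 6L)
      w_tab <- ifelse(bg_gc > 0, (obs_gc / sum(obs_gc)) /
                        (bg_gc / sum(bg_gc)), 0)
      w <- w_tab[cand_gc_counts + 1L]
      pick <- sample.int(nrow(cand), n, replace = TRUE,
                         prob = pmax(w, 1e-12))
      pos <- cand[pick, ]
    }
    mid <- fragment_midpoint(pos$pos0, length)
    midpoint_set(split(mid, pos$chrom))
  })
}

#' Usable-site filter
#'
#' A site is usable iff it has at least `min_midpoints` midpoints within
#' the window and a non-missing mappability value >= `min_mappability` at
#' the focal base (or over `+/- map_window` bases when requested).
#'
#' @param stats Output of [site_positioning_stats()].
#' @param mappability `signal_track` of mappability scores, or `NULL` to
#'   skip the mappability condition.
#' @param min_midpoints Minimum midpoint count.
#' @param min_mappability Score threshold (inclusive).
#' @param map_window Half-width over which the minimum mappability is
#'   required (0 = focal base only).
#' @return Logical mask over rows of `stats`.
#' @export
usable_sites_filter <- function(stats, mappability = NULL,
                                min_midpoints = 10L, min_mappability = 90,
                                map_window = 0L) {
  ok <- stats$n >= min_midpoints
  if (!is.null(mappability)) {
    if (map_window == 0L) {
      mv <- track_value(mappability, stats$chrom, stats$pos0)
      ok <- ok & !is.na(mv) & mv >= min_mappability
    } else {
      for (dd in seq.int(-map_window, map_window)) {
        mv <- track_value(mappability, stats$chrom, stats$pos0 + dd)
        ok <- ok & !is.na(mv) & mv >= min_mappability
      }
    }
  }
  ok
}

#' Classify dyads into stability terciles
#'
#' Splits dyads into "high", "middle" and "low" stability groups of equal
#' size (differing by at most 1; remainders go to the lower-score groups
#' first). Ties in the score are broken by (chrom, pos0) order, so the
#' labels are invariant to the input row order.
#'
#' @param dyads data.frame with `chrom`, `pos0` and `stability_score`
#'   (higher = more stable).
#' @return Factor of labels ("high", "middle", "low") aligned to the rows
#'   of `dyads`.
#' @export
classify_stability_terciles <- function(dyads) {
  n <- nrow(dyads)
  if (n < 3L) stop_nucmut("need at least 3 dyads")
  s <- dyads$stability_score
  if (any(!is.finite(s))) stop_nucmut("non-finite stability scores")
  if (length(unique(s)) == 1L) stop_nucmut("all stability scores equal: no ordering")
  base <- n %/% 3L
  rem <- n %% 3L
  n_low <- base + (rem >= 1L)
  n_mid <- base + (rem >= 2L)
  ord <- order(s, dyads$chrom, dyads$pos0)   # ascending stability
  lab <- character(n)
  lab[ord[seq_len(n_low)]] <- "low"
  lab[ord[n_low + seq_len(n_mid)]] <- "middle"
  lab[ord[(n_low + n_mid + 1L):n]] <- "high"
  factor(lab, levels = c("high", "middle", "low"))
}

#' Partition the genome workspace by nucleosome context
#'
#' Splits the workspace into regions covered by strong (translationally
#' stable) nucleosomes, regions covered by rotationally but not
#' translationally stable nucleosomes, and everything else. Strong takes
#' precedence over rotational; the three classes are disjoint and tile
#' the workspace.
#'
#' @param strong,rotational,workspace `GRanges`.
#' @return List of class `context_partition` with elements `strong`,
#'   `rotational_only`, `other`.
#' @export
partition_genome_context <- function(strong, rotational, workspace) {
  workspace <- GenomicRanges::reduce(GenomicRanges::sort(workspace))
  out_s <- GenomicRanges::setdiff(strong, workspace)
  out_r <- GenomicRanges::setdiff(rotational, workspace)
  if (sum(BiocGenerics::width(out_s)) > 0 || sum(BiocGenerics::width(out_r)) > 0) {
    stop_nucmut("strong/rotational intervals extend outside the workspace")
  }
  strong_p <- GenomicRanges::reduce(strong)
  rot_only <- GenomicRanges::setdiff(GenomicRanges::reduce(rotational), strong_p)
  other <- GenomicRanges::setdiff(workspace,
                                  GenomicRanges::union(strong_p, rot_only))
  structure(list(strong = strong_p, rotational_only = rot_only,
                 other = other), class = "context_partition")
}
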