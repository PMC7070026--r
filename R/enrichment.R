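# Randomization enrichment, dyad-anchored meta-profiles, and repair
# escape-ratio profiles with their region-level Fisher test.

#' Randomization enrichment of events in an annotation
#'
#' Repeatedly re-places every event uniformly within the workspace
#' (chromosome-preserving; interval events keep their lengths and are
#' placed wholly inside a workspace segment) and compares the observed
#' overlap count with the sampling distribution. The empirical p-value
#' uses the +1 correction and the two-sided p doubles the smaller tail
#' (capped at 1); the fold CI is the 2.5/97.5 percentile band of
#' observed / sample-count.
#'
#' @param events data.frame of point events (`chrom`, `pos0`) or a
#'   `GRanges` of interval events; must lie within the workspace.
#' @param annotation `GRanges` within the workspace.
#' @param workspace `GRanges`.
#' @param n_samples Number of randomizations.
#' @param seed Integer seed.
#' @return Object of class `enrichment_result`: observed, expected, fold,
#'   ci (length 2), p, n_samples.
#' @export
randomized_enrichment <- function(events, annotation, workspace,
                                  n_samples = 10000L, seed = 1L) {
  workspace <- GenomicRanges::reduce(GenomicRanges::sort(workspace))
  annotation <- GenomicRanges::reduce(GenomicRanges::sort(annotation))
  if (sum(BiocGenerics::width(GenomicRanges::setdiff(annotation, workspace))) > 0) {
    stop_nucmut("annotation extends outside the workspace")
  }
  interval_mode <- inherits(events, "GRanges")
  ann_bed <- split(gr_to_bed0(annotation),
                   gr_to_bed0(annotation)$chrom)
  ws_bed <- split(gr_to_bed0(workspace), gr_to_bed0(workspace)$chrom)
  count_points <- function(chrom, pos0) {
    sum(positions_in_gr(chrom, pos0, annotation))
  }
  with_seed(seed, {
    if (!interval_mode) {
      obs <- count_points(events$chrom, events$pos0)
      counts <- numeric(n_samples)
      for (ch in unique(events$chrom)) {
        k <- sum(events$chrom == ch)
        ws <- ws_bed[[ch]]
        if (is.null(ws)) stop_nucmut("events on %s outside workspace", ch)
        w <- ws$end0 - ws$start0
        offs <- cumsum(c(0, as.numeric(w)))
        total <- offs[length(offs)]
        u <- floor(runif(n_samples * k) * total)
        u[u >= total] <- total - 1
        seg <- findInterval(u, offs)
        pos <- ws$start0[seg] + (u - offs[seg])
        ab <- ann_bed[[ch]]
        if (is.null(ab) || nrow(ab) == 0L) next
        j <- findInterval(pos, ab$start0)
        hit <- j >= 1L & pos < ab$end0[pmax(j, 1L)]
        counts <- counts +
          rowsum(as.numeric(hit), rep(seq_len(n_samples), each = k))[, 1L]
      }
    } else {
      ev_bed <- gr_to_bed0(events)
      if (!all(positions_in_gr(ev_bed$chrom, ev_bed$start0, workspace))) {
        stop_nucmut("interval events must start inside the workspace")
      }
      overlap_any <- function(chrom, s0, e0) {
        res <- logical(length(s0))
        for (ch in unique(chrom)) {
          i <- which(chrom == ch)
          ab <- ann_bed[[ch]]
          if (is.null(ab) || nrow(ab) == 0L) next
          j <- findInterval(e0[i] - 1L, ab$start0)  # last ann starting before event end
          res[i] <- j >= 1L & ab$end0[pmax(j, 1L)] > s0[i]
        }
        res
      }
      obs <- sum(overlap_any(ev_bed$chrom, ev_bed$start0, ev_bed$end0))
      lens <- ev_bed$end0 - ev_bed$start0
      counts <- numeric(n_samples)
      for (ch in unique(ev_bed$chrom)) {
        iev <- which(ev_bed$chrom == ch)
        ws <- ws_bed[[ch]]
        for (ii in iev) {
          len <- lens[ii]
          valid <- ws$end0 - ws$start0 - len + 1L
          if (all(valid <= 0L)) {
            stop_nucmut("event of length %d longer than any workspace segment on %s",
                        len, ch)
          }
          segs <- which(valid > 0L)
          offs <- cumsum(c(0, as.numeric(valid[segs])))
          total <- offs[length(offs)]
          u <- floor(runif(n_samples) * total)
          u[u >= total] <- total - 1
          sg <- findInterval(u, offs)
          s0 <- ws$start0[segs[sg]] + (u - offs[sg])
          counts <- counts +
            as.numeric(overlap_any(rep(ch, n_samples), s0, s0 + len))
        }
      }
    }
    expected <- mean(counts)
    fold_samples <- ifelse(counts > 0, obs / counts, Inf)
    p_up <- (1 + sum(counts >= obs)) / (n_samples + 1)
    p_dn <- (1 + sum(counts <= obs)) / (n_samples + 1)
    structure(list(observed = obs, expected = expected,
                   fold = if (expected > 0) obs / expected else NA_real_,
                   ci = unname(quantile(fold_samples, c(0.025, 0.975),
                                        na.rm = TRUE)),
                   p = min(1, 2 * min(p_up, p_dn)),
                   n_samples = n_samples),
              class = "enrichment_result")
  })
}

#' Meta-profile of events or signal around anchor positions
#'
#' Bins signed offsets (event - anchor) into `bin`-bp bins covering
#' [-window, window); bin 0 starts at the anchor, negative offsets are
#' upstream. In `event_density` mode the per-bin value is
#' count / (bin * n_anchors), so summing value * bin * n_anchors
#' recovers the total anchored event count. In `signal_mean` mode the
#' value is the mean signal over non-missing bases. Anchors whose window
#' leaves the chromosome are dropped and counted.
#'
#' @param anchors data.frame (`chrom`, `pos0`).
#' @param events data.frame of point events (event mode) or a
#'   `signal_track` (signal mode).
#' @param window Half-width (bp), a multiple of `bin`.
#' @param bin Bin width (bp).
#' @param mode `"event_density"` or `"signal_mean"`.
#' @param chrom_sizes Named vector of chromosome lengths (needed to drop
#'   edge anchors; inferred from the track in signal mode).
#' @return Object of class `meta_profile`: data.frame `profile`
#'   (offset_start, offset_end, value), `n_anchors`, `n_dropped`,
#'   `mode`, `bin`.
#' @export
meta_profile <- function(anchors, events, window = 1000L, bin = 10L,
                         mode = c("event_density", "signal_mean"),
                         chrom_sizes = NULL) {
  mode <- match.arg(mode)
  if (window %% bin != 0L) stop_nucmut("window must be a multiple of bin")
  if (nrow(anchors) == 0L) stop_nucmut("zero anchors")
  if (is.null(chrom_sizes)) {
    if (mode == "signal_mean") {
      chrom_sizes <- vapply(events$data, function(d) max(d$end0), 0)
    } else {
      stop_nucmut("chrom_sizes required in event mode")
    }
  }
  ok <- anchors$pos0 - window >= 0L &
    anchors$pos0 + window <= chrom_sizes[anchors$chrom]
  n_dropped <- sum(!ok)
  anchors <- anchors[ok, , drop = FALSE]
  if (nrow(anchors) == 0L) stop_nucmut("all anchors dropped at contig edges")
  edges <- seq.int(-window, window, by = bin)
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  cnt <- numeric(nb)
  for (ch in unique(anchors$chrom)) {
    apos <- anchors$pos0[anchors$chrom == ch]
    if (mode == "event_density") {
      ev <- sort(events$pos0[events$chrom == ch])
      if (length(ev) == 0L) next
      for (a in apos) {
        acc <- acc + diff(findInterval(a + edges - 0.5, ev))
      }
    } else {
      vec <- track_to_vector(events, ch, chrom_sizes[[ch]])
      bin_idx <- rep(seq_len(nb), each = bin)
      for (a in apos) {
        sl <- vec[(a - window + 1L):(a + window)]
        okv <- !is.na(sl)
        acc <- acc + rowsum(ifelse(okv, sl, 0), bin_idx)[, 1L]
        cnt <- cnt + rowsum(as.numeric(okv), bin_idx)[, 1L]
      }
    }
  }
  value <- if (mode == "event_density") {
    acc / (bin * nrow(anchors))
  } else {
    ifelse(cnt > 0, acc / cnt, NA_real_)
  }
  structure(list(profile = data.frame(offset_start = edges[-length(edges)],
                                      offset_end = edges[-1L],
                                      value = value),
                 n_anchors = nrow(anchors), n_dropped = n_dropped,
                 mode = mode, bin = bin),
            class = "meta_profile")
}

#' Escape-ratio profile around dyads
#'
#' Per 10-bp bin i, computes mutation densities `m_i` for two cohorts
#' (repair-proficient A, repair-deficient B) around dyads, background
#' densities from an equal number of random `bg_width`-bp windows in the
#' workspace, and the background-normalized escape ratio
#' `R_i = (m_i^A / m_i^B) / (bg_A / bg_B)`. Bins where cohort B has no
#' mutations are missing unless a +0.5 pseudocount is requested. An
#' optional mappability filter keeps only dyads whose full +/- `window`
#' neighborhood meets the threshold.
#'
#' @param cohort_a,cohort_b `variant_set`s.
#' @param dyads data.frame (`chrom`, `pos0`).
#' @param window Half-width (bp).
#' @param bin Bin width (bp).
#' @param workspace `GRanges` for background window sampling.
#' @param bg_width Background window width (bp).
#' @param n_bg Number of background windows (default: number of dyads).
#' @param mappability Optional `signal_track`.
#' @param min_mappability Threshold applied across each dyad's window.
#' @param pseudocount Add 0.5 to per-bin counts of both cohorts.
#' @param seed Integer seed.
#' @param chrom_sizes Named chromosome lengths.
#' @return Object of class `escape_profile`: data.frame `profile`
#'   (offset_start, m_a, m_b, ratio), `bg_a`, `bg_b`, `n_dyads`,
#'   `n_bg`.
#' @export
escape_ratio_profile <- function(cohort_a, cohort_b, dyads, window = 800L,
                                 bin = 10L, workspace, bg_width = 1600L,
                                 n_bg = NULL, mappability = NULL,
                                 min_mappability = NULL,
                                 pseudocount = FALSE, seed = 1L,
                                 chrom_sizes = NULL) {
  if (nrow(cohort_a) == 0L || nrow(cohort_b) == 0L) {
    stop_nucmut("both cohorts must be nonempty")
  }
  if (is.null(chrom_sizes)) {
    ws <- gr_to_bed0(workspace)
    chrom_sizes <- tapply(ws$end0, ws$chrom, max)
  }
  if (!is.null(mappability) && !is.null(min_mappability)) {
    keep <- vapply(seq_len(nrow(dyads)), function(i) {
      vec <- track_value(mappability, rep(dyads$chrom[i], 2L * window + 1L),
                         dyads$pos0[i] + seq.int(-window, window))
      all(!is.na(vec) & vec >= min_mappability)
    }, logical(1))
    dyads <- dyads[keep, , drop = FALSE]
  }
  if (nrow(dyads) == 0L) stop_nucmut("no usable dyads after filtering")
  prof_a <- meta_profile(dyads, cohort_a, window = window, bin = bin,
                         mode = "event_density", chrom_sizes = chrom_sizes)
  prof_b <- meta_profile(dyads, cohort_b, window = window, bin = bin,
                         mode = "event_density", chrom_sizes = chrom_sizes)
  n_dy <- prof_a$n_anchors
  cnt_a <- prof_a$profile$value * bin * n_dy
  cnt_b <- prof_b$profile$value * bin * n_dy
  if (pseudocount) { cnt_a <- cnt_a + 0.5; cnt_b <- cnt_b + 0.5 }
  m_a <- cnt_a / (bin * n_dy)
  m_b <- cnt_b / (bin * n_dy)
  if (is.null(n_bg)) n_bg <- nrow(dyads)
  bg <- with_seed(child_seed(seed, 7L),
                  sample_background_windows(workspace, n_bg, bg_width))
  bg_gr <- bed0_to_gr(bg$chrom, bg$start0, bg$start0 + bg_width)
  nb_a <- sum(positions_in_gr(cohort_a$chrom, cohort_a$pos0, bg_gr))
  nb_b <- sum(positions_in_gr(cohort_b$chrom, cohort_b$pos0, bg_gr))
  if (nb_a == 0L || nb_b == 0L) {
    stop_nucmut("zero background mutations in a cohort: ratio undefined")
  }
  bg_a <- nb_a / (n_bg * bg_width)
  bg_b <- nb_b / (n_bg * bg_width)
  ratio <- ifelse(m_b > 0, (m_a / m_b) / (bg_a / bg_b), NA_real_)
  structure(list(profile = data.frame(
    offset_start = prof_a$profile$offset_start,
    m_a = m_a, m_b = m_b, ratio = ratio),
    bg_a = bg_a, bg_b = bg_b, n_dyads = n_dy, n_bg = n_bg),
    class = "escape_profile")
}

# Random fixed-width windows inside workspace segments; sampled without
# replacement from non-overlapping candidates when feasible, otherwise
# overlap is allowed with a warning.
sample_background_windows <- function(workspace, n, width) {
  bed <- gr_to_bed0(GenomicRanges::reduce(GenomicRanges::sort(workspace)))
  caps <- pmax((bed$end0 - bed$start0) %/% width, 0L)
  if (sum(caps) >= n) {
    seg <- rep(seq_len(nrow(bed)), caps)
    slot <- unlist(lapply(caps, seq_len)) - 1L
    pick <- sample.int(length(seg), n)
    data.table(chrom = bed$chrom[seg[pick]],
               start0 = bed$start0[seg[pick]] + slot[pick] * width)
  } else {
    warning("not enough non-overlapping background windows; sampling with overlap")
    valid <- bed$end0 - bed$start0 - width + 1L
    segs <- which(valid > 0L)
    if (length(segs) == 0L) stop_nucmut("no workspace segment fits a background window")
    offs <- cumsum(c(0, as.numeric(valid[segs])))
    u <- floor(runif(n) * offs[length(offs)])
    sg <- findInterval(u, offs)
    data.table(chrom = bed$chrom[segs[sg]],
               start0 = bed$start0[segs[sg]] + (u - offs[sg]))
  }
}

#' Fisher test for differential repair performance in strong regions
#'
#' Tests whether cohort A (repair-proficient) mutations concentrate in
#' strong nucleosomal regions (dyad +/- `region_halfwidth`) more than
#' cohort B mutations do, among all mutations within +/- `window` of
#' dyads. The 2x2 table is
#' `[[N_strong^p, N_all^p - N_strong^p], [N_strong^d, N_all^d - N_strong^d]]`
#' with a two-sided exact test.
#'
#' @param cohort_a,cohort_b `variant_set`s.
#' @param dyads data.frame (`chrom`, `pos0`).
#' @param region_halfwidth Strong-region half-width (bp).
#' @param window Considered-region half-width (bp).
#' @return List: `p`, `odds_ratio` (sample OR), `table`.
#' @export
fisher_escape_region <- function(cohort_a, cohort_b, dyads,
                                 region_halfwidth = 95L, window = 800L) {
  strong <- GenomicRanges::reduce(bed0_to_gr(
    dyads$chrom, pmax(dyads$pos0 - region_halfwidth, 0L),
    dyads$pos0 + region_halfwidth + 1L))
  all_reg <- GenomicRanges::reduce(bed0_to_gr(
    dyads$chrom, pmax(dyads$pos0 - window, 0L), dyads$pos0 + window + 1L))
  np_all <- sum(positions_in_gr(cohort_a$chrom, cohort_a$pos0, all_reg))
  np_s <- sum(positions_in_gr(cohort_a$chrom, cohort_a$pos0, strong))
  nd_all <- sum(positions_in_gr(cohort_b$chrom, cohort_b$pos0, all_reg))
  nd_s <- sum(positions_in_gr(cohort_b$chrom, cohort_b$pos0, strong))
  tab <- matrix(c(np_s, np_all - np_s, nd_s, nd_all - nd_s), nrow = 2L,
                byrow = TRUE,
                dimnames = list(c("proficient", "deficient"),
                                c("strong", "nonstrong")))
  if (any(tab < 0)) stop_nucmut("negative derived cell in escape Fisher table")
  ft <- fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / max(tab[1, 2] * tab[2, 1], .Machine$double.eps)
  list(p = ft$p.value, odds_ratio = or, table = tab)
}
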