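# Synthetic nucleosome landscape: dyads with NRL-spaced positions, per-dyad
# Gaussian translational jitter, MNase fragment midpoints, and strong /
# rotational region sets derived from jitter terciles.

#' Generate a synthetic nucleosome landscape
#'
#' Dyads are placed with inter-dyad spacing ~ Normal(NRL, NRL/10)
#' truncated positive; each dyad k receives `fragments_per_dyad` fragment
#' midpoints ~ round(Normal(dyad, sigma_k)), where sigma_k is the dyad's
#' translational jitter SD drawn from the configured sampler. "Strong"
#' regions are dyad +/- 73 bp for dyads in the lowest-jitter tercile
#' (the most translationally stable third); the middle tercile plays the
#' role of rotationally-but-not-translationally stable regions so that the
#' three-way genome partition can be exercised. The ground truth
#' (dyad position, sigma_k, stability score) is returned and is the only
#' source recovery tests read.
#'
#' @param genome A `DNAStringSet` (only lengths are used).
#' @param cfg A [sim_config()].
#' @return List with `dyads` (data.frame: chrom, pos0, sigma,
#'   stability_score = -sigma), `midpoints` (`midpoint_set`), `strong` and
#'   `rotational` (`GRanges`).
#' @export
gen_nucleosome_landscape <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sizes <- chrom_sizes(genome)
  with_seed(child_seed(cfg$seed, 2L), {
    dy <- list()
    mids <- list()
    for (ch in names(sizes)) {
      len <- sizes[[ch]]
      n_max <- ceiling(len / (cfg$nrl * 0.5)) + 10L
      gaps <- rnorm(n_max, cfg$nrl, cfg$nrl / 10)
      gaps <- pmax(gaps, cfg$fragment_length / 2)   # truncate positive, > jitter support
      pos <- round(runif(1, 100, 100 + cfg$nrl) + cumsum(c(0, gaps)))
      pos <- pos[pos < len - 100]
      sigma <- cfg$jitter_sampler(length(pos))
      dy[[ch]] <- data.frame(chrom = ch, pos0 = as.integer(pos),
                             sigma = sigma, stability_score = -sigma,
                             stringsAsFactors = FALSE)
      f <- cfg$fragments_per_dyad
      m <- rep(pos, each = f) +
        round(rnorm(length(pos) * f, 0, rep(sigma, each = f)))
      mids[[ch]] <- pmin(pmax(m, 0L), len - 1L)
    }
    dyads <- do.call(rbind, dy)
    rownames(dyads) <- NULL
    # degenerate case: a constant jitter sampler makes every dyad equally
    # stable, so all dyads count as strong and no tercile split exists
    terc <- if (length(unique(dyads$sigma)) == 1L) {
      factor(rep("high", nrow(dyads)), levels = c("high", "middle", "low"))
    } else {
      classify_stability_terciles(dyads)
    }
    strong_d <- dyads[terc == "high", , drop = FALSE]
    rot_d <- dyads[terc == "middle", , drop = FALSE]
    mk_regions <- function(d, half = 73L) {
      if (nrow(d) == 0L) return(GenomicRanges::GRanges())
      GenomicRanges::reduce(bed0_to_gr(d$chrom, pmax(d$pos0 - half, 0L),
                                       d$pos0 + half + 1L))
    }
    list(dyads = dyads,
         midpoints = midpoint_set(mids),
         strong = mk_regions(strong_d),
         rotational = mk_regions(rot_d))
  })
}
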