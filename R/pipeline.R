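# Convenience glue used by the CLI and the acceptance workflow.

#' Sample usable candidate sites with positioning features
#'
#' Draws `n` random genomic positions, computes their positioning
#' statistics against the midpoint set, and keeps usable sites (enough
#' midpoints, defined d_var), attaching `log_d_var = log(d_var + 1)`.
#'
#' @param genome `DNAStringSet`.
#' @param midpoints `midpoint_set`.
#' @param n Number of positions to draw.
#' @param seed Integer seed.
#' @param window,min_midpoints Passed to [site_positioning_stats()].
#' @return data.frame: chrom, pos0, n, d_mean, d_var, d_mean_bin,
#'   log_d_var.
#' @export
candidate_sites <- function(genome, midpoints, n, seed, window = 95L,
                            min_midpoints = 10L) {
  pos <- with_seed(child_seed(seed, 11L), {
    p <- sample_positions_in_gr(genome_workspace(genome), n)
    p[!duplicated(paste(p$chrom, p$pos0)), ]
  })
  st <- site_positioning_stats(pos, midpoints, window = window,
                               min_midpoints = min_midpoints)
  st <- st[st$usable & !is.na(st$d_var), , drop = FALSE]
  st$log_d_var <- log(st$d_var + 1)
  rownames(st) <- NULL
  st
}
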