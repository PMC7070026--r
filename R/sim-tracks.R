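# Synthetic functional tracks: smooth Gaussian-process-like fields
# (moving average of white noise at a stated bandwidth) or constants,
# written/represented at a fixed step resolution.

#' Generate synthetic signal tracks
#'
#' Each spec is either `list(type = "constant", value = c)` or
#' `list(type = "smooth", mean = m, sd = s, bandwidth = bw)` where the
#' smooth field is a moving average of white noise with averaging window
#' `bandwidth` bp, rescaled to the requested mean and SD. Optional
#' `clamp = c(lo, hi)` truncates values (used e.g. for mappability scores
#' in [0, 100]).
#'
#' @param genome `DNAStringSet` (lengths only).
#' @param specs Named list of track specs.
#' @param seed Integer seed.
#' @param resolution Step size (bp) at which values are emitted.
#' @return Named list of `signal_track` objects.
#' @export
gen_tracks <- function(genome, specs = default_track_specs(), seed = 1L,
                       resolution = 10L) {
  sizes <- chrom_sizes(genome)
  with_seed(seed, {
    out <- list()
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      data <- list()
      for (ch in names(sizes)) {
        len <- sizes[[ch]]
        ngrid <- ceiling(len / resolution)
        starts <- (seq_len(ngrid) - 1L) * resolution
        ends <- pmin(starts + resolution, len)
        if (identical(sp$type, "constant")) {
          vals <- rep(sp$value, ngrid)
        } else if (identical(sp$type, "smooth")) {
          k <- max(1L, round(sp$bandwidth / resolution))
          noise <- rnorm(ngrid + k)
          sm <- as.numeric(stats::filter(noise, rep(1 / k, k), sides = 1L))
          sm <- sm[(k + 1L):(ngrid + k)]
          sm <- (sm - mean(sm)) / max(sd(sm), 1e-12)
          vals <- sp$mean + sp$sd * sm
        } else {
          stop_nucmut("unknown track spec type for %s", nm)
        }
        if (!is.null(sp$clamp)) {
          vals <- pmin(pmax(vals, sp$clamp[1]), sp$clamp[2])
        }
        data[[ch]] <- data.table(start0 = starts, end0 = ends, value = vals)
      }
      out[[nm]] <- signal_track(data, name = nm, units = sp$units %||% "")
    }
    out
  })
}

#' Default synthetic track specification
#'
#' Emulates the functional covariates the analysis adjusts for:
#' methylation, H3K9me3, ATAC, replication timing, recombination and
#' expression as smooth fields, plus a perfect (constant 100) mappability
#' track.
#'
#' @return Named list of track specs for [gen_tracks()].
#' @export
default_track_specs <- function() {
  list(
    methylation = list(type = "smooth", mean = 0.7, sd = 0.15,
                       bandwidth = 1000, clamp = c(0, 1)),
    h3k9me3 = list(type = "smooth", mean = 1, sd = 0.5, bandwidth = 5000),
    atac = list(type = "smooth", mean = 1, sd = 0.5, bandwidth = 2000),
    replication_timing = list(type = "smooth", mean = 0, sd = 1,
                              bandwidth = 50000),
    recombination = list(type = "smooth", mean = 1, sd = 0.4,
                         bandwidth = 20000, clamp = c(0, Inf)),
    expression = list(type = "smooth", mean = 2, sd = 1, bandwidth = 10000,
                      clamp = c(0, Inf)),
    mappability = list(type = "constant", value = 100)
  )
}
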