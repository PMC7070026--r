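# MNase-seq fragment midpoints: per-chromosome sorted integer positions
# (0-based). Duplicates are allowed and meaningful (coverage).

#' Construct a fragment midpoint set
#'
#' @param positions Named list, one sorted (or sortable) integer vector of
#'   0-based midpoint positions per chromosome.
#' @return An object of class `midpoint_set`.
#' @export
midpoint_set <- function(positions) {
  stopifnot(is.list(positions))
  positions <- lapply(positions, function(p) sort(as.integer(p)))
  structure(list(positions = positions,
                 total = sum(vapply(positions, length, 0L))),
            class = "midpoint_set")
}

#' @export
print.midpoint_set <- function(x, ...) {
  cat(sprintf("<midpoint_set> %d midpoints on %d chromosome(s)\n",
              x$total, length(x$positions)))
  invisible(x)
}

#' Midpoints of fragments
#'
#' For even fragment lengths the midpoint is taken left of center:
#' `start + (length - 1) %/% 2`.
#'
#' @param start0 0-based fragment start positions.
#' @param length Fragment length(s) in bp.
#' @return Integer midpoint positions (0-based).
#' @export
fragment_midpoint <- function(start0, length) {
  as.integer(start0) + (as.integer(length) - 1L) %/% 2L
}

#' Read fragment midpoints from a BED file
#'
#' Each BED interval is interpreted as a fragment; its midpoint is
#' `start + (width - 1) %/% 2`. Width-1 intervals therefore encode
#' midpoints directly.
#'
#' @param path BED file of fragments or precomputed midpoints.
#' @return A `midpoint_set`.
#' @export
read_midpoints_bed <- function(path) {
  gr <- read_bed(path)
  bed <- gr_to_bed0(gr)
  mid <- fragment_midpoint(bed$start0, bed$end0 - bed$start0)
  midpoint_set(split(mid, bed$chrom))
}

#' Write midpoints as a width-1 BED file
#'
#' @param mps A `midpoint_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_midpoints_bed <- function(mps, path) {
  out <- data.table::rbindlist(lapply(names(mps$positions), function(ch) {
    p <- mps$positions[[ch]]
    if (length(p) == 0L) return(NULL)
    data.table(chrom = ch, start0 = p, end0 = p + 1L)
  }))
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
         scipen = 50L)
  invisible(path)
}

# Per-base fragment coverage implied by midpoints of fixed-length
# fragments; returns a named list of numeric vectors (one per chromosome).
coverage_from_midpoints <- function(mps, fragment_length, sizes) {
  half_l <- (fragment_length - 1L) %/% 2L
  out <- list()
  for (ch in names(sizes)) {
    len <- sizes[[ch]]
    diffarr <- numeric(len + 1L)
    p <- mps$positions[[ch]]
    if (!is.null(p) && length(p) > 0L) {
      s <- pmax(p - half_l, 0L)
      e <- pmin(p - half_l + fragment_length, len)
      ok <- s < e
      if (any(ok)) {
        add <- tabulate(s[ok] + 1L, nbins = len + 1L)
        sub <- tabulate(e[ok] + 1L, nbins = len + 1L)
        diffarr <- add - sub
      }
    }
    out[[ch]] <- cumsum(diffarr)[seq_len(len)]
  }
  out
}
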