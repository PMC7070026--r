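# Signal tracks: per-chromosome sorted non-overlapping step functions with
# an explicit "missing" state (uncovered bases are NA, never 0).

#' Construct a signal track
#'
#' @param data Named list (one entry per chromosome) of data.frames with
#'   columns `start0`, `end0` (0-based half-open) and `value`.
#' @param name Track name.
#' @param units Free-text units.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(data, name = "track", units = "") {
  stopifnot(is.list(data))
  for (ch in names(data)) {
    d <- as.data.table(data[[ch]])
    stopifnot(all(c("start0", "end0", "value") %in% names(d)))
    if (nrow(d) > 0) {
      if (any(d$start0 >= d$end0)) stop_nucmut("empty interval in track on %s", ch)
      setorder(d, start0)
      if (any(d$start0[-1L] < d$end0[-nrow(d)])) {
        stop_nucmut("overlapping intervals in track on %s", ch)
      }
    }
    data[[ch]] <- d
  }
  structure(list(data = data, name = name, units = units),
            class = "signal_track")
}

#' Read a 4-column bedGraph file
#'
#' Overlapping input intervals are a validation error; uncovered bases are
#' treated as missing (`NA`), not as zero.
#'
#' @param path Path to a bedGraph file.
#' @param name,units Track metadata.
#' @return A `signal_track`.
#' @export
read_bedgraph <- function(path, name = basename(path), units = "") {
  if (!file.exists(path)) stop_nucmut("bedGraph file not found: %s", path)
  d <- fread(path, header = FALSE, sep = "\t", skip = "")
  if (ncol(d) != 4L) stop_nucmut("bedGraph must have exactly 4 columns, got %d", ncol(d))
  names(d) <- c("chrom", "start0", "end0", "value")
  if (any(!is.finite(d$start0)) || any(!is.finite(d$end0))) {
    stop_nucmut("non-numeric coordinates in bedGraph %s", path)
  }
  if (any(d$start0 >= d$end0)) stop_nucmut("invalid interval (start >= end) in %s", path)
  signal_track(split(d[, c("start0", "end0", "value")], d$chrom),
               name = name, units = units)
}

#' Write a signal track as bedGraph
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @param drop_na Drop missing-value intervals rather than writing them.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, drop_na = TRUE) {
  out <- data.table::rbindlist(lapply(names(track$data), function(ch) {
    d <- track$data[[ch]]
    if (nrow(d) == 0L) return(NULL)
    data.table(chrom = ch, start0 = d$start0, end0 = d$end0, value = d$value)
  }))
  if (drop_na && nrow(out) > 0L) out <- out[!is.na(out$value), ]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
         scipen = 50L)
  invisible(path)
}

#' Value of a track at single base positions
#'
#' @param track A `signal_track`.
#' @param chrom,pos0 Parallel vectors of chromosome names and 0-based
#'   positions.
#' @return Numeric vector; `NA` where the track has no coverage.
#' @export
track_value <- function(track, chrom, pos0) {
  chrom <- rep_len(chrom, length(pos0))
  res <- rep(NA_real_, length(pos0))
  for (ch in unique(chrom)) {
    d <- track$data[[ch]]
    idx <- which(chrom == ch)
    if (is.null(d) || nrow(d) == 0L) next
    j <- findInterval(pos0[idx], d$start0)
    ok <- j >= 1L & pos0[idx] < d$end0[pmax(j, 1L)]
    res[idx[ok]] <- d$value[j[ok]]
  }
  res
}

# Expand one chromosome of a track to a per-base numeric vector of length
# `len` with NA in uncovered gaps. Used for fast window averaging.
track_to_vector <- function(track, chrom, len) {
  v <- rep(NA_real_, len)
  d <- track$data[[chrom]]
  if (!is.null(d) && nrow(d) > 0L) {
    for (i in seq_len(nrow(d))) {
      s <- max(d$start0[i], 0L)
      e <- min(d$end0[i], len)
      if (s < e) v[(s + 1L):e] <- d$value[i]
    }
  }
  v
}

# Mean of `vec` (per-base values, NA = missing) over windows
# [pos0-flank, pos0+flank], skipping missing bases. Returns list(mean,
# coverage) with coverage the fraction of non-missing bases in the window.
window_mean_from_vector <- function(vec, pos0, flank) {
  len <- length(vec)
  ok <- !is.na(vec)
  cs <- cumsum(ifelse(ok, vec, 0))
  cn <- cumsum(ok)
  lo <- pmax(pos0 - flank, 0L)          # 0-based inclusive
  hi <- pmin(pos0 + flank, len - 1L)
  tot <- cs[hi + 1L] - ifelse(lo > 0L, cs[lo], 0)
  n <- cn[hi + 1L] - ifelse(lo > 0L, cn[lo], 0)
  m <- ifelse(n > 0, tot / n, NA_real_)
  list(mean = m, coverage = n / (hi - lo + 1L))
}
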