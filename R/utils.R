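# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Complement/reverse-complement for plain character vectors of DNA.
comp_chr <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_chr(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a master seed (kept < 2^31).
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + as.numeric(stream) * 12347L) %% 2147483587
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nucmut <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# chrom sizes of a DNAStringSet genome as a named integer vector
chrom_sizes <- function(genome) {
  stopifnot(inherits(genome, "DNAStringSet"))
  stats::setNames(Biostrings::width(genome), names(genome))
}

# Convert a GRanges to a 0-based half-open data.table (chrom, start0, end0).
gr_to_bed0 <- function(gr) {
  data.table(
    chrom = as.character(seqnames(gr)),
    start0 = BiocGenerics::start(gr) - 1L,
    end0 = BiocGenerics::end(gr)
  )
}

# Build a GRanges from 0-based half-open coordinates.
bed0_to_gr <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges(start = start0 + 1L, end = end0))
}

# GRanges covering whole chromosomes of a genome / sizes vector.
genome_workspace <- function(x) {
  sizes <- if (inherits(x, "DNAStringSet")) chrom_sizes(x) else x
  bed0_to_gr(names(sizes), rep(0L, length(sizes)), unname(sizes))
}

# Flatten a GRanges into per-chromosome sorted disjoint 0-based segments.
flatten_segments <- function(gr) {
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  split(gr_to_bed0(gr), as.character(seqnames(gr)))
}

# Uniformly sample n 0-based point positions from a workspace GRanges.
sample_positions_in_gr <- function(workspace, n) {
  bed <- gr_to_bed0(GenomicRanges::reduce(GenomicRanges::sort(workspace)))
  w <- bed$end0 - bed$start0
  total <- sum(as.numeric(w))
  if (total <= 0) stop_nucmut("empty workspace")
  offs <- cumsum(c(0, as.numeric(w)))
  u <- floor(runif(n) * total)           # 0 .. total-1
  u[u >= total] <- total - 1
  seg <- findInterval(u, offs, rightmost.closed = FALSE)
  data.table(
    chrom = bed$chrom[seg],
    pos0 = as.integer(bed$start0[seg] + (u - offs[seg]))
  )
}

# TRUE for each (chrom, pos0) that lies inside the interval set `gr`.
positions_in_gr <- function(chrom, pos0, gr) {
  chrom <- rep_len(chrom, length(pos0))
  bed <- gr_to_bed0(GenomicRanges::reduce(GenomicRanges::sort(gr)))
  res <- logical(length(pos0))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    b <- bed[bed$chrom == ch, ]
    if (nrow(b) == 0L) next
    j <- findInterval(pos0[idx], b$start0)
    hit <- j >= 1L & pos0[idx] < b$end0[pmax(j, 1L)]
    res[idx] <- hit
  }
  res
}
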