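#' Read a BED3/BED6 file as a GRanges
#'
#' BED coordinates are 0-based half-open and are preserved verbatim; the
#' returned `GRanges` uses the usual 1-based closed convention, so
#' `start(gr) == bed_start + 1` and `end(gr) == bed_end`. Malformed lines
#' are rejected with an error naming the line number; records are never
#' silently repaired.
#'
#' @param path Path to a tab-separated BED3/BED6 file. Lines starting with
#'   `#`, `track` or `browser` are ignored.
#' @param has_score If `TRUE`, require at least 5 columns and attach the
#'   score column (and the name column as `label`).
#' @return A `GRanges` sorted by (chrom, start), with optional `label` and
#'   `score` metadata columns.
#' @export
read_bed <- function(path, has_score = FALSE) {
  if (!file.exists(path)) stop_nucmut("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  need <- if (has_score) 5L else 3L
  if (any(nf < need)) {
    bad <- lineno[which(nf < need)[1]]
    stop_nucmut("malformed BED line %d: expected >= %d tab-separated fields",
                bad, need)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 != floor(start0) |
                 end0 != floor(end0))
  if (length(bad) > 0L) {
    stop_nucmut("malformed BED line %d: non-integer coordinates", lineno[bad[1]])
  }
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad) > 0L) {
    stop_nucmut("invalid BED interval at line %d: need 0 <= start < end",
                lineno[bad[1]])
  }
  gr <- bed0_to_gr(chrom, as.integer(start0), as.integer(end0))
  if (has_score || any(nf >= 5L)) {
    label <- ifelse(nf >= 4L, vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else ".", ""), ".")
    score <- ifelse(nf >= 5L,
                    suppressWarnings(as.numeric(vapply(parts, function(p) if (length(p) >= 5L) p[[5L]] else "0", ""))),
                    NA_real_)
    mcols(gr)$label <- label
    mcols(gr)$score <- score
  }
  GenomicRanges::sort(gr)
}

#' Write a GRanges to a BED file (0-based half-open)
#'
#' @param gr A `GRanges`; `label` and `score` metadata columns, when
#'   present, are written as BED columns 4-5.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  bed <- gr_to_bed0(gr)
  if (!is.null(mcols(gr)$score)) {
    bed$label <- mcols(gr)$label %||% rep(".", length(gr))
    bed$score <- mcols(gr)$score
    bed$strand <- rep(".", length(gr))
  }
  fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE,
         scipen = 50L)
  invisible(path)
}
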