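# Variant I/O. Internal representation is a data.frame with class
# "variant_set": chrom, pos0 (0-based), ref, alt, vtype (SNV/INS/DEL),
# group, sample. VCF positions are converted from 1-based on read.

new_variant_set <- function(chrom, pos0, ref, alt, group = "default",
                            sample = "s1", n_dropped_indel = 0L,
                            n_split = 0L) {
  vtype <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
                  ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
  bad <- which(vtype == "SNV" & ref == alt)
  if (length(bad) > 0L) stop_nucmut("SNV with ref == alt at record %d", bad[1])
  if (any(grepl("[^ACGT]", ref)) || any(grepl("[^ACGT]", alt))) {
    stop_nucmut("ref/alt alleles must be over {A,C,G,T}")
  }
  v <- data.frame(chrom = as.character(chrom), pos0 = as.integer(pos0),
                  ref = as.character(ref), alt = as.character(alt),
                  vtype = vtype,
                  group = rep_len(as.character(group), length(chrom)),
                  sample = rep_len(as.character(sample), length(chrom)),
                  stringsAsFactors = FALSE)
  v <- v[order(v$chrom, v$pos0), , drop = FALSE]
  rownames(v) <- NULL
  structure(v, class = c("variant_set", "data.frame"),
            n_dropped_indel = n_dropped_indel, n_split = n_split)
}

#' Read variants from VCF or TSV
#'
#' Positions are normalized to the internal 0-based convention (`pos0`).
#' Multi-allelic VCF records are split into one record per alternate
#' allele. INDELs longer than `max_indel_len` are dropped; the number of
#' dropped records is reported in the `n_dropped_indel` attribute.
#'
#' The TSV dialect requires a header line naming the columns
#' `chrom`, `pos0` (0-based) or `pos1` (1-based), `ref`, `alt`, and
#' optionally `group` and `sample`; `#`-prefixed comment lines are allowed.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param max_indel_len Maximum INDEL length kept (difference between
#'   allele lengths); defaults to 5 bp.
#' @param genome Optional `DNAStringSet`; when given, reference alleles of
#'   SNVs are validated against it and mismatches are an error.
#' @return A `variant_set` data.frame.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          max_indel_len = 5L, genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop_nucmut("variant file not found: %s", path)
  if (format == "vcf") {
    lines <- readLines(path)
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(body) == 0L) {
      return(new_variant_set(character(), integer(), character(), character()))
    }
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 5L)) {
      stop_nucmut("malformed VCF record %d: fewer than 5 fields", which(nf < 5L)[1])
    }
    chrom <- vapply(parts, `[[`, "", 1L)
    pos1 <- as.integer(vapply(parts, `[[`, "", 2L))
    ref <- toupper(vapply(parts, `[[`, "", 4L))
    alt_raw <- toupper(vapply(parts, `[[`, "", 5L))
    alts <- strsplit(alt_raw, ",", fixed = TRUE)
    n_alt <- lengths(alts)
    n_split <- sum(n_alt > 1L)
    idx <- rep(seq_along(chrom), n_alt)
    chrom <- chrom[idx]; pos1 <- pos1[idx]; ref <- ref[idx]
    alt <- unlist(alts, use.names = FALSE)
    grp <- "default"; smp <- "s1"
  } else {
    d <- fread(path, header = TRUE, sep = "\t")
    cn <- names(d)
    if (!("chrom" %in% cn) || !any(c("pos0", "pos1") %in% cn) ||
        !all(c("ref", "alt") %in% cn)) {
      stop_nucmut("variant TSV needs header columns chrom, pos0|pos1, ref, alt")
    }
    chrom <- as.character(d$chrom)
    pos1 <- if ("pos0" %in% cn) as.integer(d$pos0) + 1L else as.integer(d$pos1)
    ref <- toupper(as.character(d$ref))
    alt <- toupper(as.character(d$alt))
    grp <- if ("group" %in% cn) as.character(d$group) else "default"
    smp <- if ("sample" %in% cn) as.character(d$sample) else "s1"
    n_split <- 0L
  }
  indel_len <- abs(nchar(ref) - nchar(alt))
  keep <- indel_len <= max_indel_len
  n_dropped <- sum(!keep)
  v <- new_variant_set(chrom[keep], pos1[keep] - 1L, ref[keep], alt[keep],
                       group = if (length(grp) > 1L) grp[keep] else grp,
                       sample = if (length(smp) > 1L) smp[keep] else smp,
                       n_dropped_indel = n_dropped, n_split = n_split)
  if (!is.null(genome)) validate_variant_refs(v, genome)
  v
}

# Error listing records whose reference allele disagrees with the genome.
validate_variant_refs <- function(variants, genome) {
  snv <- variants[variants$vtype == "SNV", , drop = FALSE]
  if (nrow(snv) == 0L) return(invisible(TRUE))
  obs <- genome_bases(genome, snv$chrom, snv$pos0)
  bad <- which(obs != snv$ref)
  if (length(bad) > 0L) {
    ex <- head(sprintf("%s:%d %s!=%s", snv$chrom[bad], snv$pos0[bad],
                       snv$ref[bad], obs[bad]), 5L)
    stop_nucmut("reference mismatch for %d variant(s): %s",
                length(bad), paste(ex, collapse = ", "))
  }
  invisible(TRUE)
}

# Bases of `genome` (DNAStringSet) at 0-based positions, as characters.
genome_bases <- function(genome, chrom, pos0) {
  chrom <- rep_len(chrom, length(pos0))
  res <- character(length(pos0))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- as.character(genome[[ch]])
    res[idx] <- substring(s, pos0[idx] + 1L, pos0[idx] + 1L)
  }
  res
}

#' Write variants as TSV (0-based positions) or minimal VCF
#'
#' @param variants A `variant_set`.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return Invisibly, `path`.
#' @export
write_variants <- function(variants, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    fwrite(data.table(chrom = variants$chrom, pos0 = variants$pos0,
                      ref = variants$ref, alt = variants$alt,
                      group = variants$group, sample = variants$sample),
           path, sep = "\t", quote = FALSE, scipen = 50L)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (nrow(variants) > 0L) {
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tGROUP=%s;SAMPLE=%s",
                         variants$chrom, variants$pos0 + 1L, variants$ref,
                         variants$alt, variants$group, variants$sample), con)
    }
  }
  invisible(path)
}
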