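# 96-type mutation spectra, trinucleotide background correction, per-type
# Fisher tests and signature refitting by non-negative least squares.

#' Canonical 96 mutation type labels
#'
#' Pyrimidine-strand substitutions (C>A, C>G, C>T, T>A, T>C, T>G), each in
#' the 16 contexts of the immediate 5' and 3' bases, labelled e.g.
#' `"A[C>T]G"`. Substitution-major order, contexts ordered 5' then 3'
#' alphabetically.
#'
#' @return Character vector of length 96.
#' @export
sbs96_types <- function() {
  out <- character(0)
  for (ref in c("C", "T")) {
    for (alt in setdiff(BASES, ref)) {
      for (five in BASES) {
        for (three in BASES) {
          out <- c(out, sprintf("%s[%s>%s]%s", five, ref, alt, three))
        }
      }
    }
  }
  out
}

# Parse labels into five/ref/alt/three/context components.
parse_sbs96 <- function(labels) {
  five <- substring(labels, 1L, 1L)
  ref <- substring(labels, 3L, 3L)
  alt <- substring(labels, 5L, 5L)
  three <- substring(labels, 7L, 7L)
  list(five = five, ref = ref, alt = alt, three = three,
       context = paste0(five, ref, three))
}

#' The 32 pyrimidine-centered trinucleotide contexts
#'
#' @return Character vector of length 32 (center base C or T).
#' @export
trinuc32_contexts <- function() {
  out <- character(0)
  for (ref in c("C", "T")) {
    for (five in BASES) for (three in BASES) {
      out <- c(out, paste0(five, ref, three))
    }
  }
  out
}

#' Classify SNVs into the 96 types
#'
#' Purine-reference variants are reverse-complemented (ref, alt and both
#' flanks) so the reference is pyrimidine. Non-SNVs and variants whose
#' flank leaves the chromosome or contains N are unclassifiable (`NA`),
#' and their count is reported in the `n_unclassifiable` attribute.
#'
#' @param variants A `variant_set` (or data.frame with chrom, pos0, ref,
#'   alt, vtype).
#' @param genome `DNAStringSet`.
#' @return Character vector of labels (NA = unclassifiable) with
#'   attribute `n_unclassifiable`.
#' @export
classify_96 <- function(variants, genome) {
  n <- nrow(variants)
  lab <- rep(NA_character_, n)
  sizes <- chrom_sizes(genome)
  is_snv <- variants$vtype == "SNV"
  ok <- is_snv & variants$pos0 >= 1L &
    variants$pos0 + 1L < sizes[variants$chrom]
  if (any(ok)) {
    i <- which(ok)
    five <- genome_bases(genome, variants$chrom[i], variants$pos0[i] - 1L)
    three <- genome_bases(genome, variants$chrom[i], variants$pos0[i] + 1L)
    ref <- variants$ref[i]
    alt <- variants$alt[i]
    good <- five %in% BASES & three %in% BASES
    flip <- ref %in% c("A", "G")
    f5 <- ifelse(flip, comp_chr(three), five)
    f3 <- ifelse(flip, comp_chr(five), three)
    rr <- ifelse(flip, comp_chr(ref), ref)
    aa <- ifelse(flip, comp_chr(alt), alt)
    lab[i[good]] <- sprintf("%s[%s>%s]%s", f5[good], rr[good], aa[good],
                            f3[good])
  }
  attr(lab, "n_unclassifiable") <- sum(is.na(lab))
  lab
}

#' Strand-collapsed trinucleotide context counts
#'
#' Counts occurrences of each pyrimidine-centered trinucleotide whose
#' center base lies in `regions` (or anywhere, when `regions` is NULL);
#' purine-centered occurrences are counted under their reverse
#' complement. Centers at contig edges (no full trinucleotide) are
#' excluded.
#'
#' @param genome `DNAStringSet`.
#' @param regions Optional `GRanges` restricting center positions.
#' @return Named integer vector over [trinuc32_contexts()].
#' @export
trinuc_counts_32 <- function(genome, regions = NULL) {
  c64 <- rep(0, 64)
  names64 <- Biostrings::mkAllStrings(BASES, 3L)
  names(c64) <- names64
  if (is.null(regions)) {
    for (ch in names(genome)) {
      c64 <- c64 + trinucleotideFrequency(genome[[ch]])[names64]
    }
  } else {
    regions <- GenomicRanges::reduce(GenomicRanges::sort(regions))
    bed <- gr_to_bed0(regions)
    sizes <- chrom_sizes(genome)
    for (k in seq_len(nrow(bed))) {
      ch <- bed$chrom[k]
      s <- max(bed$start0[k] - 1L, 0L)
      e <- min(bed$end0[k] + 1L, sizes[[ch]])
      if (e - s < 3L) next
      sub <- Biostrings::subseq(genome[[ch]], s + 1L, e)
      c64 <- c64 + trinucleotideFrequency(sub)[names64]
    }
  }
  ctx <- trinuc32_contexts()
  out <- stats::setNames(numeric(32L), ctx)
  for (t in ctx) out[t] <- c64[t] + c64[revcomp_chr(t)]
  out
}

#' 96-type spectrum with trinucleotide background
#'
#' Counts classifiable SNVs in the region set and in the whole workspace,
#' together with the strand-collapsed trinucleotide context counts of
#' both, i.e. everything the background correction and the per-type
#' Fisher tests need.
#'
#' @param variants `variant_set`.
#' @param regions `GRanges` region set (e.g. strong nucleosomes).
#' @param genome `DNAStringSet`.
#' @param workspace Optional `GRanges` (defaults to the whole genome).
#' @return Object of class `spectrum_counts`: `types`, `F` (region
#'   counts), `F_genome`, `N_tri` (32 region context counts),
#'   `N_tri_genome`.
#' @export
spectrum_with_background <- function(variants, regions, genome,
                                     workspace = NULL) {
  if (is.null(workspace)) workspace <- genome_workspace(genome)
  types <- sbs96_types()
  lab <- classify_96(variants, genome)
  in_ws <- positions_in_gr(variants$chrom, variants$pos0, workspace)
  in_reg <- positions_in_gr(variants$chrom, variants$pos0, regions)
  tab_of <- function(keep) {
    t0 <- table(factor(lab[keep], levels = types))
    stats::setNames(as.numeric(t0), types)
  }
  structure(list(types = types,
                 F = tab_of(in_reg & !is.na(lab)),
                 F_genome = tab_of(in_ws & !is.na(lab)),
                 N_tri = trinuc_counts_32(genome, regions),
                 N_tri_genome = trinuc_counts_32(genome, workspace)),
            class = "spectrum_counts")
}

#' Trinucleotide background correction of a 96-type spectrum
#'
#' Corrected occurrence per type i:
#' `F_i / N_tri(context_i) * N_tri_genome(context_i)`, i.e. region counts
#' rescaled to the genome-wide availability of each context. Types with
#' zero context count in the region must have zero observed count.
#'
#' @param counts A `spectrum_counts`.
#' @return Named numeric 96-vector of corrected occurrences.
#' @export
background_correct <- function(counts) {
  info <- parse_sbs96(counts$types)
  n_reg <- counts$N_tri[info$context]
  n_gen <- counts$N_tri_genome[info$context]
  bad <- which(counts$F > 0 & n_reg == 0)
  if (length(bad) > 0L) {
    stop_nucmut("type %s observed but its context is absent from regions",
                counts$types[bad[1]])
  }
  out <- ifelse(n_reg > 0, counts$F / n_reg * n_gen, 0)
  stats::setNames(as.numeric(out), counts$types)
}

#' Per-type Fisher tests of regional mutation-type enrichment
#'
#' For each of the 96 types, tests the 2x2 table
#' `[[F_region, N_tri_region - F_region],
#'   [F_genome - F_region, (N_tri_genome - N_tri_region) - (F_genome - F_region)]]`
#' with a two-sided exact test; BH correction across the 96 types.
#' Direction is the sign of (sample odds ratio - 1) from the raw counts.
#'
#' @param counts A `spectrum_counts`.
#' @return data.frame: type, p, p_adj, direction, and the table cells.
#' @export
fisher_per_type <- function(counts) {
  info <- parse_sbs96(counts$types)
  a <- counts$F
  b <- counts$N_tri[info$context] - a
  cc <- counts$F_genome - a
  d <- (counts$N_tri_genome[info$context] - counts$N_tri[info$context]) - cc
  if (any(c(a, b, cc, d) < 0)) stop_nucmut("negative contingency cell: inconsistent counts")
  p <- vapply(seq_along(a), function(i) {
    fisher.test(matrix(c(a[i], b[i], cc[i], d[i]), nrow = 2L,
                       byrow = TRUE))$p.value
  }, numeric(1))
  direction <- sign(a * d - b * cc)
  data.frame(type = counts$types, a = as.numeric(a), b = as.numeric(b),
             c = as.numeric(cc), d = as.numeric(d), p = p,
             p_adj = p.adjust(p, method = "BH"),
             direction = as.integer(direction), stringsAsFactors = FALSE)
}

#' Refit a spectrum against fixed mutational signatures
#'
#' Non-negative least squares: `w = argmin_{w>=0} ||S w - spectrum||_2`,
#' with percent contributions `100 w_k / sum(w)`. Corrected (non-integer)
#' spectra are accepted as-is.
#'
#' @param spectrum Non-negative 96-vector (raw or background-corrected
#'   counts), ordered as [sbs96_types()] (names, when present, are used
#'   to reorder).
#' @param signatures 96 x K matrix; columns must sum to 1.
#' @return Object of class `signature_fit`: `weights`, `percent`,
#'   `residual` (L2), `fitted`.
#' @export
refit_signatures <- function(spectrum, signatures) {
  types <- sbs96_types()
  signatures <- as.matrix(signatures)
  if (nrow(signatures) != 96L) stop_nucmut("signature matrix must have 96 rows")
  if (!is.null(rownames(signatures))) {
    signatures <- signatures[types, , drop = FALSE]
  }
  if (!is.null(names(spectrum))) spectrum <- spectrum[types]
  spectrum <- as.numeric(spectrum)
  if (any(spectrum < 0)) stop_nucmut("spectrum must be non-negative")
  if (any(abs(colSums(signatures) - 1) > 1e-6)) {
    stop_nucmut("signature columns must sum to 1")
  }
  K <- ncol(signatures)
  if (sum(spectrum) == 0) {
    w <- rep(0, K)
  } else {
    w <- pracma::lsqnonneg(signatures, spectrum)$x
  }
  names(w) <- colnames(signatures) %||% paste0("S", seq_len(K))
  fitted <- as.vector(signatures %*% w)
  pct <- if (sum(w) > 0) 100 * w / sum(w) else w
  structure(list(weights = w, percent = pct,
                 residual = sqrt(sum((fitted - spectrum)^2)),
                 fitted = fitted),
            class = "signature_fit")
}

#' Read/write a signature matrix as TSV
#'
#' TSV with a `type` column (96 canonical labels) and one column per
#' signature.
#'
#' @param path File path.
#' @return 96 x K numeric matrix with rownames.
#' @export
read_signature_matrix <- function(path) {
  d <- fread(path, header = TRUE, sep = "\t")
  if (!("type" %in% names(d))) stop_nucmut("signature TSV needs a 'type' column")
  m <- as.matrix(d[, setdiff(names(d), "type"), with = FALSE])
  rownames(m) <- d$type
  m[sbs96_types(), , drop = FALSE]
}

#' @rdname read_signature_matrix
#' @param m Matrix to write.
#' @export
write_signature_matrix <- function(m, path) {
  fwrite(data.table(type = rownames(m), as.data.table(m)), path,
         sep = "\t", quote = FALSE)
  invisible(path)
}
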