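# Per-site feature assembly for the mutation-rate regression: strand
# normalization, control-site sampling, and the covariate table.

#' Strand-normalize sites and classify mutation context
#'
#' Sites with reference base T or G are reverse-complemented (ref, alt and
#' the +/- `flank` bp context) so the normalized reference is A or C.
#' Site classes: `AT` (normalized ref A), `CpG` (normalized ref C with G
#' immediately 3'), `nonCpG_CG` otherwise.
#'
#' @param chrom,pos0 Site coordinates (0-based).
#' @param genome `DNAStringSet`.
#' @param alt Optional alternate alleles (normalized alongside).
#' @param flank Context half-width (bp).
#' @return data.frame: class, ref_norm, alt_norm, usable, and one `ctx_*`
#'   column per offset (-flank..-1, +1..+flank), all on the normalized
#'   strand. Sites whose context leaves the chromosome or contains N are
#'   flagged unusable.
#' @export
normalize_site_strand <- function(chrom, pos0, genome, alt = NULL,
                                  flank = 5L) {
  n <- length(pos0)
  sizes <- chrom_sizes(genome)
  ctx <- character(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    s <- as.character(genome[[ch]])
    ctx[i] <- substring(s, pos0[i] + 1L - flank, pos0[i] + 1L + flank)
  }
  usable <- pos0 - flank >= 0L & pos0 + flank < sizes[chrom] &
    !grepl("[^ACGT]", ctx) & nchar(ctx) == 2L * flank + 1L
  ref <- substring(ctx, flank + 1L, flank + 1L)
  flip <- ref %in% c("T", "G")
  ctx[flip & usable] <- revcomp_chr(ctx[flip & usable])
  ref_norm <- ifelse(flip, comp_chr(ref), ref)
  alt_norm <- if (is.null(alt)) rep(NA_character_, n) else {
    ifelse(flip, comp_chr(alt), alt)
  }
  plus1 <- substring(ctx, flank + 2L, flank + 2L)
  cls <- ifelse(ref_norm == "A", "AT",
                ifelse(plus1 == "G", "CpG", "nonCpG_CG"))
  cls[!usable] <- NA_character_
  out <- data.frame(class = cls, ref_norm = ref_norm, alt_norm = alt_norm,
                    usable = usable, stringsAsFactors = FALSE)
  offs <- setdiff(seq.int(-flank, flank), 0L)
  for (o in offs) {
    nm <- paste0("ctx_", ifelse(o < 0, "m", "p"), abs(o))
    out[[nm]] <- substring(ctx, flank + 1L + o, flank + 1L + o)
    out[[nm]][!usable] <- NA_character_
  }
  out
}

#' Sample non-mutated control sites
#'
#' Uniform sample without replacement from the usable sites, excluding
#' mutated positions; the control count is `round(ratio * n_mutated)`,
#' mirroring the ~10x control-to-case design.
#'
#' @param usable data.frame of candidate sites (`chrom`, `pos0`).
#' @param mutated data.frame of mutated sites (`chrom`, `pos0`).
#' @param ratio Controls per mutated site.
#' @param seed Integer seed.
#' @return data.frame of sampled control sites.
#' @export
sample_control_sites <- function(usable, mutated, ratio = 10, seed = 1L) {
  n_ctrl <- round(ratio * nrow(mutated))
  if (n_ctrl == 0L) {
    return(data.frame(chrom = character(), pos0 = integer()))
  }
  key <- paste(usable$chrom, usable$pos0)
  mkey <- paste(mutated$chrom, mutated$pos0)
  pool <- which(!(key %in% mkey))
  if (length(pool) < n_ctrl) {
    stop_nucmut("insufficient usable sites: need %d controls, have %d",
                n_ctrl, length(pool))
  }
  with_seed(seed, {
    pick <- sort(pool[sample.int(length(pool), n_ctrl)])
    data.frame(chrom = usable$chrom[pick], pos0 = usable$pos0[pick],
               stringsAsFactors = FALSE)
  })
}

#' Assemble the per-site feature table
#'
#' One row per retained site with: outcome `y`, site class, strand-
#' normalized context nucleotides at offsets -5..+5, `d_mean_bin`
#' (categorical, reference bin 1), `log_d_var = log(d_var + 1)`,
#' occupancy (value of the occupancy bin at the focal base), the mean of
#' each functional track over +/- `flank` bp (missing bases skipped), and
#' repeat status with precedence Alu > L1 > other_repeat > nonrepeat.
#' Rows with any missing modeled value are dropped and counted in the
#' `n_dropped` attribute.
#'
#' @param sites data.frame with `chrom`, `pos0`, `y` (0/1) and optionally
#'   `alt`.
#' @param genome `DNAStringSet`.
#' @param stats Output of [site_positioning_stats()] covering the sites.
#' @param tracks Named list of `signal_track`s.
#' @param occupancy Optional occupancy `signal_track`.
#' @param repeats Optional `GRanges` with a `label` metadata column
#'   (values "Alu", "L1" or other repeat family names).
#' @param flank Track-averaging half-width (bp).
#' @return data.frame of modeled covariates with attribute `n_dropped`.
#' @export
assemble_feature_table <- function(sites, genome, stats, tracks = list(),
                                   occupancy = NULL, repeats = NULL,
                                   flank = 10L) {
  norm <- normalize_site_strand(sites$chrom, sites$pos0, genome,
                                alt = sites$alt %||% NULL)
  idx <- match(paste(sites$chrom, sites$pos0),
               paste(stats$chrom, stats$pos0))
  tab <- data.table(chrom = sites$chrom, pos0 = sites$pos0,
                    y = as.integer(sites$y),
                    n = stats$n[idx], d_mean = stats$d_mean[idx],
                    d_var = stats$d_var[idx],
                    d_mean_bin = stats$d_mean_bin[idx],
                    usable = stats$usable[idx])
  tab <- cbind(tab, as.data.table(norm))
  tab$log_d_var <- log(tab$d_var + 1)
  if (!is.null(occupancy)) {
    tab$occupancy <- track_value(occupancy, tab$chrom, tab$pos0)
  }
  sizes <- chrom_sizes(genome)
  for (nm in names(tracks)) {
    vals <- rep(NA_real_, nrow(tab))
    for (ch in unique(tab$chrom)) {
      i <- which(tab$chrom == ch)
      vec <- track_to_vector(tracks[[nm]], ch, sizes[[ch]])
      vals[i] <- window_mean_from_vector(vec, tab$pos0[i], flank)$mean
    }
    tab[[nm]] <- vals
  }
  rep_status <- rep("nonrepeat", nrow(tab))
  if (!is.null(repeats) && length(repeats) > 0L) {
    lab <- as.character(mcols(repeats)$label)
    fam <- ifelse(lab == "Alu", "Alu",
                  ifelse(lab == "L1", "L1", "other_repeat"))
    site_gr <- bed0_to_gr(tab$chrom, tab$pos0, tab$pos0 + 1L)
    for (f in c("other_repeat", "L1", "Alu")) {  # increasing precedence
      hits <- GenomicRanges::findOverlaps(site_gr, repeats[fam == f])
      rep_status[unique(queryHits(hits))] <- f
    }
  }
  tab$repeat_status <- factor(rep_status,
                              levels = c("nonrepeat", "Alu", "L1",
                                         "other_repeat"))
  tab$d_mean_bin <- factor(tab$d_mean_bin, levels = 1:5)
  for (nm in grep("^ctx_", names(tab), value = TRUE)) {
    tab[[nm]] <- factor(tab[[nm]], levels = BASES)  # reference base A
  }
  tab$class <- factor(tab$class, levels = c("AT", "CpG", "nonCpG_CG"))
  modeled <- setdiff(names(tab), c("alt_norm", "ref_norm"))
  keep <- stats::complete.cases(tab[, ..modeled]) & (tab$usable %in% TRUE)
  dropped <- sum(!keep)
  out <- as.data.frame(tab[keep, ])
  attr(out, "n_dropped") <- dropped
  out
}
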