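# Synthetic mutation generators with recorded ground truth: logistic-model
# mutations, paired repair-proficient/deficient cohorts with a known escape
# profile, and signature-mixture SNV sets.

#' Generate mutations from a known logistic model
#'
#' Each usable site is mutated independently with probability
#' `plogis(b0 + X beta)`, where `beta` is the supplied ground-truth
#' coefficient vector over numeric feature columns and the intercept `b0`
#' is calibrated so that the expected mutation count is `n_target`.
#'
#' @param genome `DNAStringSet` (for reference alleles).
#' @param features data.frame with `chrom`, `pos0` and one numeric column
#'   per name in `beta`.
#' @param beta Named numeric vector of true coefficients (keys must be
#'   feature columns).
#' @param n_target Expected number of mutations.
#' @param seed Integer seed.
#' @param cpg_ts_boost Relative weight of the C>T alternate at CpG sites
#'   (1 = uniform over the three alternates).
#' @return List with `variants` (`variant_set`), and `truth` (list with
#'   `beta` and calibrated `intercept`).
#' @export
gen_mutations_from_model <- function(genome, features, beta, n_target,
                                     seed, cpg_ts_boost = 1) {
  miss <- setdiff(names(beta), names(features))
  if (length(miss) > 0L) {
    stop_nucmut("beta names not in features: %s", paste(miss, collapse = ", "))
  }
  eta <- if (length(beta) > 0L) {
    as.vector(as.matrix(features[names(beta)]) %*% beta)
  } else {
    rep(0, nrow(features))
  }
  f <- function(b0) sum(plogis(b0 + eta)) - n_target
  if (f(-40) > 0 || f(10) < 0) stop_nucmut("cannot calibrate intercept for n_target=%g", n_target)
  b0 <- uniroot(f, c(-40, 10), tol = 1e-10)$root
  if (n_target < 50) warning("expected mutation count < 50: recovery tests underpowered")
  with_seed(seed, {
    p <- plogis(b0 + eta)
    hit <- which(runif(nrow(features)) < p)
    chrom <- features$chrom[hit]
    pos0 <- features$pos0[hit]
    ref <- genome_bases(genome, chrom, pos0)
    nxt <- genome_bases(genome, chrom, pmin(pos0 + 1L,
                                            chrom_sizes(genome)[chrom] - 1L))
    alt <- draw_alt_alleles(ref, is_cpg = (ref == "C" & nxt == "G"),
                            cpg_ts_boost = cpg_ts_boost)
    list(variants = new_variant_set(chrom, pos0, ref, alt, group = "sim"),
         truth = list(beta = beta, intercept = b0, n_sites = nrow(features)))
  })
}

# Alternate allele per site: uniform over the three non-reference bases,
# optionally boosting C>T at CpG sites (and nothing else).
draw_alt_alleles <- function(ref, is_cpg = rep(FALSE, length(ref)),
                             cpg_ts_boost = 1) {
  alt <- character(length(ref))
  for (b in BASES) {
    idx <- which(ref == b)
    if (length(idx) == 0L) next
    alts <- setdiff(BASES, b)
    w <- matrix(1, nrow = length(idx), ncol = 3L)
    if (b == "C" && cpg_ts_boost != 1) {
      w[is_cpg[idx], which(alts == "T")] <- cpg_ts_boost
    }
    pick <- apply(w, 1L, function(wi) sample.int(3L, 1L, prob = wi))
    alt[idx] <- alts[pick]
  }
  alt
}

#' Generate paired repair-proficient / repair-deficient cohorts
#'
#' Mutations are placed by independent per-base Bernoulli draws. Within
#' +/- `window` of each dyad the per-bp rate follows the supplied offset
#' profiles `rate_a(offset)` / `rate_b(offset)`; elsewhere the uniform
#' background rates apply. The ground-truth per-bin escape ratio
#' `R_i = (rate_a(i)/rate_b(i)) / (bg_a/bg_b)` is recorded.
#'
#' @param genome `DNAStringSet`.
#' @param dyads data.frame with `chrom`, `pos0`.
#' @param rate_a,rate_b Functions of signed offset (bp) returning per-bp
#'   mutation probabilities for the two cohorts within the dyad window.
#' @param bg_a,bg_b Uniform background per-bp rates outside dyad windows.
#' @param window Half-width (bp) over which the offset profiles apply.
#' @param bin Bin size (bp) for the recorded ground-truth ratio.
#' @param seed Integer seed.
#' @return List with `cohort_a`, `cohort_b` (`variant_set`s), `truth`
#'   (data.frame: offset_start, ratio) and `dyads_used` (the subset of
#'   dyads retained so that their windows are disjoint).
#' @export
gen_paired_cohorts <- function(genome, dyads, rate_a, rate_b, bg_a, bg_b,
                               window = 800L, bin = 10L, seed = 1L) {
  offs <- seq.int(-window, window - 1L)
  pa <- rate_a(offs); pb <- rate_b(offs)
  if (any(c(pa, pb, bg_a, bg_b) > 1)) stop_nucmut("mutation rate > 1")
  if (any(c(pa, pb) < 0) || bg_a < 0 || bg_b < 0) stop_nucmut("negative rate")
  sizes <- chrom_sizes(genome)
  # keep only dyads whose +/- window neighborhoods are disjoint, so each
  # position is governed by exactly one offset profile and the recorded
  # ground-truth ratio is exact
  dyads <- dyads[order(dyads$chrom, dyads$pos0), , drop = FALSE]
  keep <- logical(nrow(dyads))
  last_pos <- -Inf; last_chrom <- ""
  for (i in seq_len(nrow(dyads))) {
    if (dyads$chrom[i] != last_chrom ||
        dyads$pos0[i] - last_pos >= 2L * window) {
      keep[i] <- TRUE
      last_pos <- dyads$pos0[i]
      last_chrom <- dyads$chrom[i]
    }
  }
  dyads <- dyads[keep, , drop = FALSE]
  dyad_gr <- bed0_to_gr(dyads$chrom, pmax(dyads$pos0 - window, 0L),
                        pmin(dyads$pos0 + window, sizes[dyads$chrom]))
  complement <- GenomicRanges::setdiff(genome_workspace(genome),
                                       GenomicRanges::reduce(dyad_gr))
  with_seed(seed, {
    draw_cohort <- function(p_prof, bg, group) {
      # near-dyad positions
      all_pos <- rep(dyads$pos0, each = length(offs)) + offs
      all_chrom <- rep(dyads$chrom, each = length(offs))
      ok <- all_pos >= 0L & all_pos < sizes[all_chrom]
      pvec <- rep(p_prof, times = nrow(dyads))
      hit <- ok & (runif(length(all_pos)) < pvec)
      chrom <- all_chrom[hit]; pos0 <- all_pos[hit]
      # uniform background outside dyad windows
      bg_len <- sum(as.numeric(BiocGenerics::width(complement)))
      n_bg <- rpois(1L, bg * bg_len)
      if (n_bg > 0L) {
        bgp <- sample_positions_in_gr(complement, n_bg)
        chrom <- c(chrom, bgp$chrom); pos0 <- c(pos0, bgp$pos0)
      }
      ref <- genome_bases(genome, chrom, pos0)
      alts <- draw_alt_alleles(ref)
      new_variant_set(chrom, pos0, ref, alts, group = group)
    }
    cohort_a <- draw_cohort(pa, bg_a, "proficient")
    cohort_b <- draw_cohort(pb, bg_b, "deficient")
    bin_starts <- seq.int(-window, window - bin, by = bin)
    bin_id <- findInterval(offs, bin_starts)
    ra <- tapply(pa, bin_id, mean); rb <- tapply(pb, bin_id, mean)
    truth <- data.frame(offset_start = bin_starts,
                        ratio = as.numeric((ra / rb) / (bg_a / bg_b)))
    list(cohort_a = cohort_a, cohort_b = cohort_b, truth = truth,
         dyads_used = dyads)
  })
}

#' Generate an SNV set from a mutational-signature mixture
#'
#' Samples `n` SNVs with 96-type probabilities `S w` and places each at a
#' genome position whose (strand-collapsed) trinucleotide context matches
#' the type, recording the true mixture weights.
#'
#' @param signatures 96 x K matrix of signature probabilities (columns sum
#'   to 1), rownames in canonical `A[C>T]G` form (see [sbs96_types()]).
#' @param weights Non-negative K-vector of mixture weights (normalized
#'   internally).
#' @param n Number of SNVs to draw.
#' @param genome `DNAStringSet`.
#' @param seed Integer seed.
#' @return List with `variants` (`variant_set`) and `truth` (list with
#'   normalized `weights` and expected `spectrum`).
#' @export
gen_signature_mixture <- function(signatures, weights, n, genome, seed) {
  types <- sbs96_types()
  signatures <- as.matrix(signatures)
  if (nrow(signatures) != 96L) stop_nucmut("signature matrix must have 96 rows")
  if (is.null(rownames(signatures))) rownames(signatures) <- types
  signatures <- signatures[types, , drop = FALSE]
  if (any(abs(colSums(signatures) - 1) > 1e-6)) {
    stop_nucmut("signature columns must sum to 1")
  }
  if (any(weights < 0)) stop_nucmut("weights must be non-negative")
  w <- weights / sum(weights)
  p96 <- as.vector(signatures %*% w)
  ctx_idx <- trinuc_position_index(genome)
  with_seed(seed, {
    counts <- as.vector(rmultinom(1L, n, p96))
    chrom <- character(0); pos0 <- integer(0)
    ref <- character(0); alt <- character(0)
    info <- parse_sbs96(types)
    for (i in which(counts > 0L)) {
      ctx <- info$context[i]
      cand <- ctx_idx[[ctx]]
      if (is.null(cand) || nrow(cand) == 0L) {
        stop_nucmut("trinucleotide context %s absent from genome", ctx)
      }
      k <- counts[i]
      pick <- cand[sample.int(nrow(cand), k, replace = k > nrow(cand)), ]
      base <- genome_bases(genome, pick$chrom, pick$pos0)
      on_pyr <- base %in% c("C", "T")
      chrom <- c(chrom, pick$chrom)
      pos0 <- c(pos0, pick$pos0)
      ref <- c(ref, base)
      alt <- c(alt, ifelse(on_pyr, info$alt[i], comp_chr(info$alt[i])))
    }
    list(variants = new_variant_set(chrom, pos0, ref, alt, group = "sigmix"),
         truth = list(weights = w, spectrum = p96))
  })
}

# Index genome positions by strand-collapsed (pyrimidine-centered)
# trinucleotide context: for each of the 32 contexts, the 0-based center
# positions on either strand whose context matches.
trinuc_position_index <- function(genome) {
  idx <- list()
  for (ch in names(genome)) {
    s <- as.character(genome[[ch]])
    len <- nchar(s)
    if (len < 3L) next
    code <- utf8ToInt(s)
    map <- integer(128)
    map[utf8ToInt("A")] <- 0L; map[utf8ToInt("C")] <- 1L
    map[utf8ToInt("G")] <- 2L; map[utf8ToInt("T")] <- 3L
    b <- map[code]
    tri <- b[1:(len - 2L)] * 16L + b[2:(len - 1L)] * 4L + b[3:len]
    centers <- seq.int(1L, len - 2L)            # 0-based center positions
    for (ctx in names(trinuc32_codes())) {
      codes <- trinuc32_codes()[[ctx]]
      hit <- centers[tri %in% codes]
      if (length(hit) > 0L) {
        idx[[ctx]] <- rbind(idx[[ctx]],
                            data.table(chrom = ch, pos0 = hit))
      }
    }
  }
  idx
}

# For each pyrimidine-centered trinucleotide, the numeric codes (b1*16 +
# b2*4 + b3 over A=0,C=1,G=2,T=3) of itself and its reverse complement.
trinuc32_codes <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code_of <- function(tri) {
      b <- match(strsplit(tri, "")[[1]], BASES) - 1L
      b[1] * 16L + b[2] * 4L + b[3]
    }
    res <- list()
    for (ctx in trinuc32_contexts()) {
      res[[ctx]] <- c(code_of(ctx), code_of(revcomp_chr(ctx)))
    }
    cache <<- res
    res
  }
})
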