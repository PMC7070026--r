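# Shared fixtures and independent oracles, built in code at test time.

# Small deterministic genome + nucleosome landscape, memoised per options.
.fixture_cache <- new.env(parent = emptyenv())

test_system <- function(len = 200000L, seed = 101L, ...) {
  key <- paste0("sys_", len, "_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- sim_config(seed = seed, chrom_lengths = c(chr1 = len), ...)
  genome <- gen_genome(cfg)
  land <- gen_nucleosome_landscape(genome, cfg)
  out <- list(cfg = cfg, genome = genome, land = land,
              sizes = c(chr1 = len))
  .fixture_cache[[key]] <- out
  out
}

# Brute-force positioning-statistics oracle: full pass over all midpoints
# per site, keeping |midpoint - site| <= window.
oracle_site_stats <- function(sites, midpoints, window = 95L) {
  n <- integer(nrow(sites))
  d_mean <- rep(NA_real_, nrow(sites))
  d_var <- rep(NA_real_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    m <- midpoints$positions[[sites$chrom[i]]]
    if (is.null(m)) next
    d <- abs(m - sites$pos0[i])
    d <- d[d <= window]
    n[i] <- length(d)
    if (length(d) >= 1L) d_mean[i] <- mean(d)
    if (length(d) >= 2L) d_var[i] <- sum((d - mean(d))^2) / (length(d) - 1L)
  }
  list(n = n, d_mean = d_mean, d_var = d_var)
}

# Full hypergeometric enumeration oracle for the two-sided Fisher exact
# test of a 2x2 table (rows fixed margins), using the standard tie
# tolerance on the observed table's probability.
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + c          # first-column total
  n_ <- b + d
  k <- a + b          # first-row total
  support <- max(0L, k - n_):min(k, m)
  probs <- dhyper(support, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A K-signature matrix with disjoint (orthogonal) supports.
orthogonal_signatures <- function(K = 2L, seed = 1L) {
  set.seed(seed)
  types <- sbs96_types()
  S <- matrix(0, 96L, K, dimnames = list(types, paste0("Sig", seq_len(K))))
  blocks <- split(seq_len(96L), rep(seq_len(K), length.out = 96L))
  for (k in seq_len(K)) S[blocks[[k]], k] <- runif(length(blocks[[k]]))
  sweep(S, 2L, colSums(S), "/")
}

# Random GRanges inside [0, len) on one chromosome.
random_regions <- function(n, len, max_width = 500L, chrom = "chr1") {
  s <- sort(sample.int(len - max_width - 1L, n))
  w <- sample.int(max_width, n, replace = TRUE)
  GenomicRanges::reduce(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = s + 1L, width = w)))
}

make_variants <- function(chrom, pos0, ref, alt, group = "g") {
  nucmut:::new_variant_set(chrom, pos0, ref, alt, group = group)
}
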