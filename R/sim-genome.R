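# Synthetic genome generation: first-order Markov base chain with tunable
# GC fraction and CpG dinucleotide enrichment/depletion.

#' Simulation configuration
#'
#' Collects the ground-truth parameters of the synthetic study system.
#' Defaults emulate the human germline setting the pipeline targets:
#' GC fraction 0.41, CpG observed/expected ratio ~0.2 (mammalian CpG
#' depletion), nucleosome repeat length 191.4 bp, 147-bp core-particle
#' fragments, and per-dyad translational jitter drawn uniformly from
#' 3-35 bp so that stability terciles are well separated.
#'
#' @param seed Mandatory integer seed; every generator derives its
#'   randomness from it.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param gc GC fraction in (0,1).
#' @param cpg_factor Multiplier on the CpG dinucleotide frequency relative
#'   to independence (0 = no CpG at all, 1 = independent bases).
#' @param nrl Nucleosome repeat length (bp).
#' @param fragments_per_dyad MNase fragments simulated per dyad.
#' @param fragment_length Fragment length in bp (147 = core particle).
#' @param jitter_sampler Function(n) returning n per-dyad midpoint jitter
#'   standard deviations (bp).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       chrom_lengths = c(chr1 = 1000000L),
                       gc = 0.41,
                       cpg_factor = 0.2,
                       nrl = 191.4,
                       fragments_per_dyad = 20L,
                       fragment_length = 147L,
                       jitter_sampler = function(n) runif(n, 3, 35)) {
  if (missing(seed)) stop_nucmut("sim_config: `seed` is mandatory")
  if (gc <= 0 || gc >= 1) stop_nucmut("gc must be in (0,1)")
  if (cpg_factor < 0) stop_nucmut("cpg_factor must be >= 0")
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 gc = gc, cpg_factor = cpg_factor, nrl = nrl,
                 fragments_per_dyad = as.integer(fragments_per_dyad),
                 fragment_length = as.integer(fragment_length),
                 jitter_sampler = jitter_sampler),
            class = "sim_config")
}

# Transition rows of the base chain for a given input GC parameter.
chain_dists <- function(gc, cpg_factor) {
  q <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)   # A C G T
  qc <- q
  qc[3] <- q[3] * cpg_factor
  rest <- q[c(1, 2, 4)]
  qc[c(1, 2, 4)] <- rest * (1 - qc[3]) / sum(rest)
  list(q = q, qc = qc)
}

# Stationary GC fraction of the chain (rows A/G/T share q; row C is qc).
stationary_gc <- function(gc_in, cpg_factor) {
  d <- chain_dists(gc_in, cpg_factor)
  P <- rbind(d$q, d$qc, d$q, d$q)
  v <- rep(0.25, 4)
  for (i in 1:200) v <- as.vector(v %*% P)
  v[2] + v[3]
}

# Input GC parameter whose stationary GC equals the target.
calibrate_gc <- function(gc, cpg_factor) {
  if (cpg_factor == 1) return(gc)
  uniroot(function(g) stationary_gc(g, cpg_factor) - gc,
          c(1e-4, 1 - 1e-4), tol = 1e-10)$root
}

# Sample one chromosome of the base chain. Transitions from A/G/T use the
# marginal distribution q; transitions from C rescale the G probability by
# `cpg_factor` (renormalizing the other bases). Vectorized as a coupled
# fixpoint iteration: both candidate draws share one uniform per position,
# so corrections propagate only through positions where the two draws
# disagree and the loop converges in a handful of passes.
markov_chain_bases <- function(len, gc, cpg_factor) {
  d <- chain_dists(calibrate_gc(gc, cpg_factor), cpg_factor)
  q <- d$q
  qc <- d$qc
  u <- runif(len)
  bq <- findInterval(u, cumsum(q)[1:3]) + 1L    # draw under q
  bc <- findInterval(u, cumsum(qc)[1:3]) + 1L   # draw under C-conditional
  b <- bq
  for (iter in seq_len(len)) {
    prev_c <- c(FALSE, b[-len] == 2L)
    tgt <- bq
    tgt[prev_c] <- bc[prev_c]
    if (identical(tgt, b)) break
    b <- tgt
  }
  b
}

#' Generate a synthetic genome
#'
#' I.i.d.-like bases at the configured GC fraction, with the CpG
#' dinucleotide frequency scaled by `cpg_factor` through a first-order
#' Markov chain. Reproducible from the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A `DNAStringSet`, one sequence per chromosome.
#' @export
gen_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(child_seed(cfg$seed, 1L), {
    seqs <- lapply(cfg$chrom_lengths, function(len) {
      paste(BASES[markov_chain_bases(len, cfg$gc, cfg$cpg_factor)],
            collapse = "")
    })
    DNAStringSet(unlist(seqs))
  })
}
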