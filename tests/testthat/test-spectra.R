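# 96-type classification, background correction, Fisher tests, NNLS refit.

test_that("classify_96 collapses to the pyrimidine strand", {
  # A(G>A)G is the reverse complement of C(C>T)T
  gy <- Biostrings::DNAStringSet(c(chr1 = "AAAAGGAA"))   # pos0 4: 5' A, ref G, 3' G
  v <- make_variants("chr1", 4L, "G", "A")
  expect_equal(as.vector(classify_96(v, gy)), "C[C>T]T")
  # pyrimidine reference is kept as-is
  gz <- Biostrings::DNAStringSet(c(chr1 = "AAATCAAA"))   # pos0 4: 5' T, ref C, 3' A
  v2 <- make_variants("chr1", 4L, "C", "T")
  expect_equal(as.vector(classify_96(v2, gz)), "T[C>T]A")
  # exhaustive enumeration yields exactly the 96 canonical labels
  labs <- character(0)
  for (five in c("A", "C", "G", "T")) for (ref in c("A", "C", "G", "T"))
    for (three in c("A", "C", "G", "T")) for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      gg <- Biostrings::DNAStringSet(
        c(chr1 = paste0("AA", five, ref, three, "AA")))
      labs <- c(labs, classify_96(make_variants("chr1", 3L, ref, alt), gg))
    }
  expect_setequal(unique(labs), sbs96_types())
  expect_equal(length(unique(labs)), 96L)
})

test_that("classify_96 is strand-involutive", {
  sys <- test_system(len = 50000L, seed = 401L)
  set.seed(21)
  pos <- sample(100:49000, 100L)
  ref <- nucmut:::genome_bases(sys$genome, rep("chr1", 100L), pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  v <- make_variants(rep("chr1", 100L), pos, ref, unname(alt))
  lab <- classify_96(v, sys$genome)
  # same variants on the reverse-complemented genome at mirrored positions
  grc <- Biostrings::DNAStringSet(Biostrings::reverseComplement(sys$genome[[1]]))
  names(grc) <- "chr1"
  len <- 50000L
  vrc <- make_variants(rep("chr1", 100L), len - 1L - pos,
                       nucmut:::comp_chr(ref), nucmut:::comp_chr(unname(alt)))
  lab_rc <- classify_96(vrc, grc)
  # variant sets are kept position-sorted: align the two by site
  lab_by_pos <- stats::setNames(as.vector(classify_96(v, sys$genome)),
                                v$pos0)
  expect_equal(as.vector(lab_rc),
               unname(lab_by_pos[as.character(len - 1L - vrc$pos0)]))
})

test_that("spectrum counts conserve totals and match the sliding-window oracle", {
  sys <- test_system(len = 50000L, seed = 402L)
  S <- orthogonal_signatures(K = 1L)
  mix <- gen_signature_mixture(S, 1, 500L, sys$genome, seed = 403L)
  regions <- bed0_to_gr("chr1", 10000L, 30000L)
  counts <- spectrum_with_background(mix$variants, regions, sys$genome)
  expect_equal(sum(counts$F_genome), 500)
  in_reg <- mix$variants$pos0 >= 10000L & mix$variants$pos0 < 30000L
  expect_equal(sum(counts$F), sum(in_reg))
  # genome-wide trinucleotide total: workspace length - 2 per contig
  expect_equal(sum(counts$N_tri_genome), 50000 - 2)
  # region trinucleotide total: every interior center has a context
  expect_equal(sum(counts$N_tri), 20000)
  # oracle: direct sliding-window count of one context
  s <- as.character(sys$genome[[1]])
  tri <- substring(s, 10000:29999, 10002:30001)  # centers 10000..29999 (0-based)
  ctx <- "ACA"
  manual <- sum(tri == ctx | tri == nucmut:::revcomp_chr(ctx))
  expect_equal(unname(counts$N_tri[ctx]), manual)
  # regions = workspace gives the identity
  all_reg <- bed0_to_gr("chr1", 0L, 50000L)
  c2 <- spectrum_with_background(mix$variants, all_reg, sys$genome)
  expect_equal(c2$F, c2$F_genome)
  expect_equal(c2$N_tri, c2$N_tri_genome)
})

test_that("background correction applies the printed formula", {
  types <- sbs96_types()
  counts <- structure(list(
    types = types,
    F = stats::setNames(rep(0, 96), types),
    F_genome = stats::setNames(rep(0, 96), types),
    N_tri = stats::setNames(rep(2000, 32), trinuc32_contexts()),
    N_tri_genome = stats::setNames(rep(20000, 32), trinuc32_contexts())),
    class = "spectrum_counts")
  counts$F["A[C>T]G"] <- 10
  corr <- background_correct(counts)
  expect_equal(unname(corr["A[C>T]G"]), 100)   # 10 / 2000 * 20000
  # N_region = N_genome is the identity
  counts$N_tri[] <- 20000
  expect_equal(unname(background_correct(counts)), unname(counts$F))
  # impossible count: observed mutation in an absent context
  counts$N_tri[] <- 0
  expect_error(background_correct(counts), "absent")
})

test_that("per-type Fisher tests match the enumeration oracle and degenerate cases", {
  types <- sbs96_types()
  mk <- function(Fs, Ns, Fg, Ng) {
    counts <- structure(list(
      types = types,
      F = stats::setNames(rep(0, 96), types),
      F_genome = stats::setNames(rep(0, 96), types),
      N_tri = stats::setNames(rep(Ns, 32), trinuc32_contexts()),
      N_tri_genome = stats::setNames(rep(Ng, 32), trinuc32_contexts())),
      class = "spectrum_counts")
    counts$F[1] <- Fs
    counts$F_genome[1] <- Fg
    counts
  }
  res <- fisher_per_type(mk(5, 1000, 55, 100000))
  orc <- oracle_fisher_2x2(5, 995, 50, 98950)
  expect_lt(abs(res$p[1] - orc), 1e-12)
  # zero margin: no regional mutations of any type -> p = 1
  res0 <- fisher_per_type(mk(0, 1000, 0, 100000))
  expect_true(all(res0$p == 1))
  expect_error(fisher_per_type(mk(10, 5, 10, 100000)), "negative")
})

test_that("signature refitting recovers exact and scaled mixtures", {
  S <- orthogonal_signatures(K = 2L)
  spec <- 0.7 * S[, 1] + 0.3 * S[, 2]
  fit <- refit_signatures(spec, S)
  expect_equal(unname(fit$weights), c(0.7, 0.3), tolerance = 1e-10)
  expect_lt(fit$residual, 1e-10)
  expect_equal(unname(fit$percent), c(70, 30), tolerance = 1e-8)
  # scale equivariance
  fit2 <- refit_signatures(1000 * S[, 1], S)
  expect_equal(unname(fit2$weights), c(1000, 0), tolerance = 1e-8)
  # all-zero spectrum
  fit0 <- refit_signatures(rep(0, 96), S)
  expect_equal(unname(fit0$weights), c(0, 0))
  expect_equal(fit0$residual, 0)
  # residual is non-increasing when a signature is added
  S3 <- orthogonal_signatures(K = 3L, seed = 2L)
  target <- as.numeric(S3 %*% c(0.2, 0.3, 0.5)) + abs(rnorm(96, 0, 0.001))
  r2 <- refit_signatures(target, S3[, 1:2])$residual
  r3 <- refit_signatures(target, S3)$residual
  expect_lte(r3, r2 + 1e-12)
})

test_that("signature matrix TSV round trips", {
  S <- orthogonal_signatures(K = 3L)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_signature_matrix(S, p)
  back <- read_signature_matrix(p)
  expect_equal(back, S, tolerance = 1e-12)
})
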