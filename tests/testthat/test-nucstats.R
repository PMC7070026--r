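# Positioning statistics, occupancy, filters, terciles, genome partition.

test_that("site positioning stats match hand-computed values", {
  mps <- midpoint_set(list(chr1 = c(990L, 1000L, 1020L)))
  st <- site_positioning_stats(data.frame(chrom = "chr1", pos0 = 1000L), mps)
  expect_equal(st$n, 3L)
  expect_equal(st$d_mean, 10)       # (10 + 0 + 20)/3
  expect_equal(st$d_var, 100)       # (0 + 100 + 100)/2
  expect_false(st$usable)           # < 10 midpoints

  # zero variance when all distances equal
  mps2 <- midpoint_set(list(chr1 = c(970L, 1030L, 1030L)))
  st2 <- site_positioning_stats(data.frame(chrom = "chr1", pos0 = 1000L), mps2)
  expect_equal(st2$d_var, 0)

  # window bound is closed at 95; n = 0 and n = 1 give missing stats
  mps3 <- midpoint_set(list(chr1 = c(905L, 904L)))
  st3 <- site_positioning_stats(data.frame(chrom = "chr1", pos0 = 1000L), mps3)
  expect_equal(st3$n, 1L)           # 905 at d = 95 in, 904 at 96 out
  expect_equal(st3$d_mean, 95)
  expect_true(is.na(st3$d_var))
  st4 <- site_positioning_stats(data.frame(chrom = "chr1", pos0 = 5000L), mps3)
  expect_equal(st4$n, 0L)
  expect_true(is.na(st4$d_mean))

  # 9 midpoints in window -> not usable; 10 -> usable
  mps5 <- midpoint_set(list(chr1 = 1000L + seq_len(9L)))
  expect_false(site_positioning_stats(
    data.frame(chrom = "chr1", pos0 = 1000L), mps5)$usable)
  mps6 <- midpoint_set(list(chr1 = 1000L + seq_len(10L)))
  expect_true(site_positioning_stats(
    data.frame(chrom = "chr1", pos0 = 1000L), mps6)$usable)
})

test_that("positioning stats equal the brute-force oracle on random instances", {
  set.seed(71)
  mps <- midpoint_set(list(chr1 = sample.int(50000L, 20000L, replace = TRUE),
                           chr2 = sample.int(30000L, 5000L, replace = TRUE)))
  sites <- data.frame(chrom = sample(c("chr1", "chr2"), 300L, replace = TRUE),
                      pos0 = sample.int(30000L, 300L))
  st <- site_positioning_stats(sites, mps)
  orc <- oracle_site_stats(sites, mps)
  expect_identical(st$n, orc$n)
  expect_identical(st$d_mean, orc$d_mean)
  expect_identical(st$d_var, orc$d_var)
})

test_that("d_mean binning reproduces the printed five categories", {
  expect_equal(bin_dmean(c(0, 18, 19, 36, 37, 54, 55, 73, 74, 95)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  expect_equal(bin_dmean(18.5), 2L)   # gap between printed bins -> upper bin
  expect_equal(bin_dmean(73.2), 5L)
  expect_error(bin_dmean(-1), "range")
  expect_error(bin_dmean(95.5), "range")
})

test_that("occupancy is a per-bin coverage ratio with missing for zero control", {
  obs <- list(chr1 = rep(2, 30))
  ctl <- list(chr1 = rep(2, 30))
  occ <- compute_occupancy(obs, ctl, bin = 10L)
  expect_equal(occ$data$chr1$value, c(1, 1, 1))
  occ2 <- compute_occupancy(list(chr1 = rep(4, 30)), ctl, bin = 10L)
  expect_equal(occ2$data$chr1$value, c(2, 2, 2))
  # scale invariance: multiplying both coverages leaves occupancy unchanged
  occ3 <- compute_occupancy(lapply(obs, `*`, 7), lapply(ctl, `*`, 7))
  expect_equal(occ3$data$chr1$value, occ$data$chr1$value)
  ctl0 <- list(chr1 = c(rep(1, 10), rep(0, 10), rep(1, 10)))
  occ4 <- compute_occupancy(obs, ctl0, bin = 10L)
  expect_true(is.na(occ4$data$chr1$value[2]))
  expect_error(compute_occupancy(list(chr1 = c(-1, 1)), list(chr1 = c(1, 1))),
               "negative")
})

test_that("control fragment simulation is uniform, seeded, and respects n = 0", {
  ws <- bed0_to_gr("chr1", 0L, 100000L)
  expect_equal(simulate_control_fragments(ws, 0L)$total, 0L)
  s1 <- simulate_control_fragments(ws, 5000L, seed = 81L)
  s2 <- simulate_control_fragments(ws, 5000L, seed = 81L)
  expect_identical(s1$positions, s2$positions)
  # chi-square GOF against uniform expectation over 1-kb bins
  cnt <- tabulate(s1$positions$chr1 %/% 1000L + 1L, 100L)
  gof <- suppressWarnings(stats::chisq.test(cnt))
  expect_gt(gof$p.value, 0.001)
})

test_that("usable-site filter applies inclusive mappability threshold", {
  st <- data.frame(chrom = "chr1", pos0 = c(10L, 20L, 30L, 40L),
                   n = c(10L, 10L, 10L, 9L))
  mp <- signal_track(list(chr1 = data.frame(
    start0 = c(10L, 20L), end0 = c(11L, 21L), value = c(89, 90))))
  ok <- usable_sites_filter(st, mp)
  expect_equal(ok, c(FALSE, TRUE, FALSE, FALSE))  # 89 out, 90 in, missing out, n<10 out
})

test_that("stability terciles are equal-sized, tie-stable and order-invariant", {
  dy <- data.frame(chrom = "chr1", pos0 = seq_len(9L) * 100L,
                   stability_score = c(9, 8, 7, 6, 5, 4, 3, 2, 1))
  lab <- classify_stability_terciles(dy)
  expect_equal(as.vector(table(lab)), c(3L, 3L, 3L))
  expect_equal(as.character(lab[1:3]), rep("high", 3))

  dy10 <- data.frame(chrom = "chr1", pos0 = seq_len(10L) * 100L,
                     stability_score = 10:1)
  tab10 <- table(classify_stability_terciles(dy10))
  expect_equal(as.vector(tab10[c("high", "middle", "low")]), c(3L, 3L, 4L))

  perm <- sample(nrow(dy10))
  lab_p <- classify_stability_terciles(dy10[perm, ])
  expect_equal(as.character(lab_p), as.character(classify_stability_terciles(dy10))[perm])

  expect_error(classify_stability_terciles(
    data.frame(chrom = "chr1", pos0 = 1:5, stability_score = rep(1, 5))),
    "equal")
})

test_that("genome context partition is disjoint and tiles the workspace", {
  ws <- bed0_to_gr("chr1", 0L, 200L)
  strong <- bed0_to_gr("chr1", 0L, 100L)
  rot <- bed0_to_gr("chr1", 50L, 150L)
  part <- partition_genome_context(strong, rot, ws)
  expect_equal(gr_to_bed0(part$strong), data.table::data.table(
    chrom = "chr1", start0 = 0L, end0 = 100L))
  expect_equal(gr_to_bed0(part$rotational_only), data.table::data.table(
    chrom = "chr1", start0 = 100L, end0 = 150L))
  expect_equal(gr_to_bed0(part$other), data.table::data.table(
    chrom = "chr1", start0 = 150L, end0 = 200L))

  # empty inputs: everything is "other"
  p0 <- partition_genome_context(GenomicRanges::GRanges(),
                                 GenomicRanges::GRanges(), ws)
  expect_equal(sum(BiocGenerics::width(p0$other)), 200L)

  # property: total bp conserved, classes disjoint, on random inputs
  set.seed(91)
  for (i in 1:20) {
    ws_r <- bed0_to_gr("chr1", 0L, 50000L)
    s_r <- random_regions(15L, 50000L)
    r_r <- random_regions(15L, 50000L)
    pr <- partition_genome_context(s_r, r_r, ws_r)
    tot <- sum(BiocGenerics::width(pr$strong)) +
      sum(BiocGenerics::width(pr$rotational_only)) +
      sum(BiocGenerics::width(pr$other))
    expect_equal(tot, 50000L)
    expect_equal(sum(BiocGenerics::width(
      GenomicRanges::intersect(pr$strong, pr$rotational_only))), 0L)
  }

  expect_error(partition_genome_context(bed0_to_gr("chr1", 0L, 300L),
                                        rot, ws), "workspace")
})

test_that("d_var at true dyads increases with generator jitter", {
  cfg <- sim_config(seed = 95L, chrom_lengths = c(chr1 = 200000L),
                    fragments_per_dyad = 500L,
                    jitter_sampler = function(n) runif(n, 2, 40))
  land <- gen_nucleosome_landscape(gen_genome(cfg), cfg)
  st <- site_positioning_stats(land$dyads, land$midpoints)
  rho <- cor(land$dyads$sigma, st$d_var, method = "spearman")
  expect_gt(rho, 0.9)
})
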