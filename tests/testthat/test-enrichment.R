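# Randomization enrichment, meta-profiles, escape ratios.

test_that("enrichment is exactly 1 when the annotation is the workspace", {
  ws <- bed0_to_gr("chr1", 0L, 10000L)
  set.seed(501)
  ev <- data.frame(chrom = "chr1", pos0 = sample.int(10000L, 50L) - 1L)
  res <- randomized_enrichment(ev, ws, ws, n_samples = 200L, seed = 1L)
  expect_equal(res$fold, 1)
  expect_equal(res$p, 1)
  expect_equal(res$ci, c(1, 1))
})

test_that("events packed into a small annotation give maximal enrichment", {
  ws <- bed0_to_gr("chr1", 0L, 100000L)
  ann <- bed0_to_gr("chr1", 0L, 10000L)    # 10% of workspace
  set.seed(502)
  ev <- data.frame(chrom = "chr1", pos0 = sample.int(10000L, 200L) - 1L)
  res <- randomized_enrichment(ev, ann, ws, n_samples = 1000L, seed = 2L)
  expect_equal(res$observed, 200)
  expect_lt(abs(res$expected - 20) / 20, 0.15)
  expect_lt(abs(res$fold - 10) / 10, 0.15)
  expect_equal(res$p, 2 / 1001)            # doubled minimal one-sided tail
})

test_that("interval events keep lengths and stay inside workspace segments", {
  ws <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(1L, 50001L), end = c(20000L, 70000L)))
  ann <- bed0_to_gr("chr1", 5000L, 15000L)
  ev <- bed0_to_gr("chr1", c(6000L, 52000L), c(6150L, 52150L))
  res <- randomized_enrichment(ev, ann, ws, n_samples = 500L, seed = 3L)
  expect_equal(res$observed, 1)
  expect_gt(res$expected, 0)
  big <- bed0_to_gr("chr1", 1000L, 45000L)   # longer than any segment
  expect_error(randomized_enrichment(big, ann, ws, n_samples = 10L, seed = 3L),
               "longer than any workspace segment")
})

test_that("meta-profile bins events and conserves totals", {
  anchors <- data.frame(chrom = "chr1", pos0 = 1000L)
  ev <- data.frame(chrom = "chr1", pos0 = c(995L, 1004L))
  mp <- meta_profile(anchors, ev, window = 10L, bin = 10L,
                     chrom_sizes = c(chr1 = 5000L))
  expect_equal(mp$profile$offset_start, c(-10L, 0L))
  expect_equal(mp$profile$value, c(0.1, 0.1))
  # conservation: sum(value) * bin * n_anchors = anchored events
  expect_equal(sum(mp$profile$value) * 10 * mp$n_anchors, 2)

  # uniform events give a flat profile
  set.seed(503)
  ev2 <- data.frame(chrom = "chr1",
                    pos0 = sample.int(1000000L, 100000L, TRUE) - 1L)
  anchors2 <- data.frame(chrom = "chr1",
                         pos0 = sort(sample(2000:998000, 1000L)))
  mp2 <- meta_profile(anchors2, ev2, window = 1000L, bin = 10L,
                      chrom_sizes = c(chr1 = 1000000L))
  expect_lt(max(mp2$profile$value) / min(mp2$profile$value), 1.3)

  # edge anchors are dropped and counted
  mp3 <- meta_profile(data.frame(chrom = "chr1", pos0 = c(5L, 1000L)), ev,
                      window = 10L, bin = 10L, chrom_sizes = c(chr1 = 5000L))
  expect_equal(mp3$n_dropped, 1L)
  expect_error(meta_profile(anchors, ev, window = 15L, bin = 10L,
                            chrom_sizes = c(chr1 = 5000L)), "multiple")
})

test_that("meta-profile signal mode averages and skips missing bases", {
  anchors <- data.frame(chrom = "chr1", pos0 = 1000L)
  const <- signal_track(list(chr1 = data.frame(start0 = 0L, end0 = 5000L,
                                               value = 4.5)))
  mp <- meta_profile(anchors, const, window = 100L, bin = 10L,
                     mode = "signal_mean")
  expect_true(all(mp$profile$value == 4.5))
  gap <- signal_track(list(chr1 = data.frame(
    start0 = c(0L, 1020L), end0 = c(1000L, 5000L), value = c(1, 3))))
  mp2 <- meta_profile(anchors, gap, window = 100L, bin = 10L,
                      mode = "signal_mean", chrom_sizes = c(chr1 = 5000L))
  # bin [0,10) covers pos0 1000..1009: entirely missing
  expect_true(is.na(mp2$profile$value[mp2$profile$offset_start == 0]))
  expect_equal(mp2$profile$value[mp2$profile$offset_start == -20], 1)
  expect_equal(mp2$profile$value[mp2$profile$offset_start == 30], 3)
})

test_that("escape ratio reproduces the defining arithmetic", {
  # one dyad; background workspace admits exactly one 1600-bp window, so
  # the background densities are known exactly
  set.seed(504)
  cohort_a <- make_variants("chr1", c(10000L, 10001L, 10002L, 10003L,
                                      sample(0:1599, 16L)),
                            rep("A", 20L), rep("G", 20L), group = "p")
  cohort_b <- make_variants("chr1", c(10000L, 10005L,
                                      sample(0:1599, 16L)),
                            rep("A", 18L), rep("G", 18L), group = "d")
  dy <- data.frame(chrom = "chr1", pos0 = 10000L)
  ws <- bed0_to_gr("chr1", 0L, 1600L)
  ep <- escape_ratio_profile(cohort_a, cohort_b, dy, window = 800L,
                             bin = 10L, workspace = ws, bg_width = 1600L,
                             seed = 5L, chrom_sizes = c(chr1 = 20000L))
  # bin [0,10): m_a = 4/10, m_b = 2/10; backgrounds = 16/1600 each
  i0 <- which(ep$profile$offset_start == 0L)
  expect_equal(ep$profile$m_a[i0], 0.4)
  expect_equal(ep$profile$m_b[i0], 0.2)
  expect_equal(ep$profile$ratio[i0], 2)
  # scale invariance of the ratio: doubling cohort counts leaves R_i
  dbl <- function(v) make_variants(rep(v$chrom, 2L), c(v$pos0, v$pos0),
                                   rep(v$ref, 2L), rep(v$alt, 2L))
  ep2 <- escape_ratio_profile(dbl(cohort_a), dbl(cohort_b), dy,
                              window = 800L, bin = 10L, workspace = ws,
                              bg_width = 1600L, seed = 5L,
                              chrom_sizes = c(chr1 = 20000L))
  expect_equal(ep2$profile$ratio[i0], 2)
  # empty bins in cohort B are missing without pseudocount
  expect_true(anyNA(ep$profile$ratio))
  ep3 <- escape_ratio_profile(cohort_a, cohort_b, dy, window = 800L,
                              bin = 10L, workspace = ws, bg_width = 1600L,
                              pseudocount = TRUE, seed = 5L,
                              chrom_sizes = c(chr1 = 20000L))
  expect_false(anyNA(ep3$profile$ratio))
})

test_that("escape-region Fisher table matches hand counts and the oracle", {
  # cohorts placed to give the table [[30, 970], [10, 990]]
  dy <- data.frame(chrom = "chr1", pos0 = 100000L)
  pa <- c(rep(100000L, 30L), 100000L + 200L + seq_len(970L))
  pb <- c(rep(100000L, 10L), 100000L + 200L + seq_len(990L))
  ca <- make_variants(rep("chr1", 1000L), pa, rep("A", 1000L), rep("G", 1000L))
  cb <- make_variants(rep("chr1", 1000L), pb, rep("A", 1000L), rep("G", 1000L))
  fe <- fisher_escape_region(ca, cb, dy, region_halfwidth = 95L,
                             window = 1500L)
  expect_equal(unname(as.vector(fe$table)), c(30, 10, 970, 990))
  expect_lt(abs(fe$p - oracle_fisher_2x2(30, 970, 10, 990)), 1e-12)
  # zero margin -> p = 1
  fe0 <- fisher_escape_region(
    make_variants("chr1", 100000L + 300L, "A", "G"),
    make_variants("chr1", 100000L + 400L, "A", "G"), dy)
  expect_equal(fe0$p, 1)
})
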