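# per-sample SE calling: promoter exclusion, stitching, density, cutoff

test_that("promoter-overlapping peaks are removed whole", {
  genes <- make_genes(3000)
  peaks <- genomic_intervals("chr1", c(1000, 10000), c(2000, 11000))
  kept <- exclude_promoter_peaks(peaks, genes, tss_window = 2500)
  expect_equal(kept$start, 10000)

  # degenerate window: only peaks containing the TSS base go
  kept0 <- exclude_promoter_peaks(
    genomic_intervals("chr1", c(2999, 3001), c(3001, 4000)), genes,
    tss_window = 0)
  expect_equal(kept0$start, 3001)
  expect_error(exclude_promoter_peaks(peaks, genes, tss_window = -1),
               ">= 0")
})

test_that("stitching chains peaks across gaps <= threshold (inclusive)", {
  st <- stitch_peaks(genomic_intervals("chr1", c(100, 5000), c(600, 5400)))
  expect_equal(nrow(st), 1L)
  expect_equal(c(st$start, st$end, st$n_constituents), c(100, 5400, 2))

  st2 <- stitch_peaks(genomic_intervals("chr1", c(100, 20000),
                                        c(600, 20500)))
  expect_equal(nrow(st2), 2L)

  # boundary: gap of exactly 12500 stitches, 12501 does not
  at <- stitch_peaks(genomic_intervals("chr1", c(0, 13500), c(1000, 14000)))
  expect_equal(nrow(at), 1L)
  over <- stitch_peaks(genomic_intervals("chr1", c(0, 13501),
                                         c(1000, 14000)))
  expect_equal(nrow(over), 2L)
})

test_that("stitching is idempotent, order-invariant, peak-conserving", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 40
    s <- sort(sample.int(4e5, n))
    peaks <- genomic_intervals("chr1", s, s + sample(200:2000, n, TRUE))
    st <- stitch_peaks(peaks)
    expect_equal(sum(st$n_constituents), n)
    # order invariance
    st_sh <- stitch_peaks(peaks[sample.int(n), ])
    expect_equal(st_sh[c("chrom", "start", "end", "n_constituents")],
                 st[c("chrom", "start", "end", "n_constituents")])
    # restitching the stitched regions changes nothing
    st2 <- stitch_peaks(st[c("chrom", "start", "end")])
    expect_equal(st2$start, st$start)
    expect_equal(st2$end, st$end)
    # consecutive constituents within a region respect the gap bound
    for (i in seq_len(nrow(st))) {
      cc <- st$constituents[[i]]
      if (nrow(cc) > 1L) {
        # gap measured to the furthest end seen so far (peaks may nest)
        reach <- cummax(cc$end)[-nrow(cc)]
        expect_true(all(cc$start[-1] - reach <= 12500))
      }
    }
  }
})

test_that("density is background-subtracted RPKM floored at zero", {
  reg <- data.frame(chrom = "chr1", start = 0, end = 2000)
  trk <- make_track("chr1", c(0, 5000), c(2000, 1003000), c(2.0, 2.0))
  expect_equal(trk$total_signal, 2e6)
  expect_equal(quantify_density(reg, trk), 1000.0)

  # control subtraction floors at 0
  ctl <- make_track("chr1", 0, 2000, 3.0)
  expect_equal(quantify_density(reg, trk, ctl), 0.0)

  # zero coverage
  expect_equal(quantify_density(data.frame(chrom = "chr1", start = 3000,
                                           end = 4000), trk), 0.0)
  empty <- make_track("chr1", 0, 10, 0)
  expect_error(quantify_density(reg, empty), "zero total")
})

test_that("rank-curve cutoff follows the scaled max-distance criterion", {
  expect_equal(find_cutoff(c(1, 1, 2, 3, 10, 50)), 10.0)

  # convex curve y = x^2 on 101 points: tangent slope 1 at x = 0.5
  y <- (seq(0, 1, length.out = 101))^2
  expect_lt(abs(find_cutoff(y) - 0.25), (0.51^2 - 0.49^2))

  # linear ramp: every index ties, smallest wins -> minimum density
  expect_equal(find_cutoff(seq(2, 20, by = 2)), 2)

  expect_error(find_cutoff(c(1, 2)), "at least 3")
  expect_error(find_cutoff(c(5, 5, 5)), "degenerate")
})

test_that("cutoff equals the exhaustive oracle on random vectors", {
  set.seed(13)
  for (rep in 1:200) {
    d <- round(rexp(sample(5:200, 1), rate = 1 / 50), 4)
    if (max(d) == min(d)) next
    expect_identical(find_cutoff(d), brute_cutoff(d))
  }
})

test_that("call_superenhancers composes the stages and is scale-free", {
  # 6 disjoint regions whose densities realize [1,1,2,3,10,50]
  vals <- c(1, 1, 2, 3, 10, 50)
  s <- (0:5) * 1e5
  peaks <- genomic_intervals("chr1", s, s + 1000)
  trk <- make_track("chr1", s, s + 1000, vals)
  cl <- call_superenhancers(peaks, trk, genes = NULL, sample_id = "demo")
  expect_s3_class(cl, "se_call")
  expect_equal(sum(cl$regions$is_super), 1L)
  expect_equal(cl$regions$rank[cl$regions$is_super], 1L)
  # partition + monotone split
  expect_true(min(cl$regions$density[cl$regions$is_super]) >
                max(cl$regions$density[!cl$regions$is_super]))

  # doubling all signal leaves the partition unchanged
  trk2 <- make_track("chr1", s, s + 1000, vals * 2)
  cl2 <- call_superenhancers(peaks, trk2, genes = NULL)
  expect_equal(cl2$regions$is_super, cl$regions$is_super)

  # single stitched region cannot define a cutoff
  expect_error(call_superenhancers(genomic_intervals("chr1", 0, 1000),
                                   trk, genes = NULL), "at least 3")

  # everything promoter-overlapping -> empty result with warning
  genes <- make_genes(s + 500)
  expect_warning(cl0 <- call_superenhancers(peaks, trk, genes = genes),
                 "no peaks")
  expect_equal(nrow(cl0$regions), 0L)
})

test_that("ranks are a permutation and the SE/TE split is at the cutoff", {
  set.seed(21)
  s <- sort(sample.int(5e6, 120)) * 2
  s <- s[c(TRUE, diff(s) > 15000)]
  peaks <- genomic_intervals("chr1", s, s + 1500)
  trk <- make_track("chr1", s, s + 1500, round(rexp(length(s), 1 / 3), 3))
  cl <- call_superenhancers(peaks, trk, genes = NULL)
  expect_setequal(cl$regions$rank, seq_len(nrow(cl$regions)))
  expect_equal(cl$regions$is_super,
               cl$regions$density > cl$cutoff_density)
})
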