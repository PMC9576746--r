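# consensus catalog, signal matrix, promoter normalization

# build a minimal se_call by hand
fake_call <- function(sample_id, se, te = NULL) {
  reg <- function(df, is_super) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    data.frame(df, n_constituents = 1L, density = if (is_super) 10 else 1,
               rank = NA_integer_, is_super = is_super)
  }
  regions <- rbind(reg(se, TRUE), reg(te, FALSE))
  structure(list(sample_id = sample_id, regions = regions,
                 cutoff_density = 5,
                 params = list(stitch_gap = 12500, tss_window = 2500)),
            class = "se_call")
}

test_that("consensus merges SE calls and records membership", {
  A <- fake_call("A", genomic_intervals("chr1", 0, 100))
  B <- fake_call("B", genomic_intervals("chr1", 50, 150))
  cat1 <- build_consensus(list(A, B))
  expect_equal(nrow(cat1$loci), 1L)
  expect_equal(cat1$loci$end, 150)
  expect_true(all(cat1$membership[1, c("A", "B")]))

  C <- fake_call("C", genomic_intervals("chr1", c(0, 200), c(100, 300)))
  cat2 <- build_consensus(list(C))
  expect_equal(nrow(cat2$loci), 2L)
  expect_true(all(cat2$membership[, "C"]))

  # identical calls from many samples: loci count is one sample's count
  same <- lapply(sprintf("S%02d", 1:15), function(id)
    fake_call(id, genomic_intervals("chr1", c(0, 5e4), c(1e4, 6e4))))
  cat3 <- build_consensus(same)
  expect_equal(nrow(cat3$loci), 2L)
  expect_true(all(cat3$membership))

  # order invariance
  cat1r <- build_consensus(list(B, A))
  expect_equal(cat1r$loci, cat1$loci)
  expect_equal(cat1r$membership[, c("A", "B")],
               cat1$membership[, c("A", "B")])

  expect_warning(empty <- build_consensus(list(fake_call("Z", NULL,
    te = genomic_intervals("chr1", 0, 10)))), "no super-enhancers")
  expect_equal(nrow(empty$loci), 0L)
})

test_that("membership column sums count loci touched per sample", {
  set.seed(9)
  calls <- lapply(sprintf("S%d", 1:6), function(id) {
    s <- sort(sample.int(1e6, 8)) * 4
    s <- s[c(TRUE, diff(s) > 2000)]
    fake_call(id, genomic_intervals("chr1", s, s + 1500))
  })
  catl <- build_consensus(calls)
  for (k in seq_along(calls)) {
    se <- calls[[k]]$regions
    se <- se[se$is_super, ]
    hits <- GenomicRanges::countOverlaps(
      GenomicRanges::GRanges(catl$loci$chrom,
                             IRanges::IRanges(catl$loci$start + 1,
                                              catl$loci$end)),
      GenomicRanges::GRanges(se$chrom, IRanges::IRanges(se$start + 1,
                                                        se$end)))
    expect_equal(unname(colSums(catl$membership)[k]), sum(hits > 0))
    # every per-sample SE maps to >= 1 consensus locus
    expect_equal(sum(GenomicRanges::countOverlaps(
      GenomicRanges::GRanges(se$chrom, IRanges::IRanges(se$start + 1,
                                                        se$end)),
      GenomicRanges::GRanges(catl$loci$chrom,
                             IRanges::IRanges(catl$loci$start + 1,
                                              catl$loci$end))) == 0), 0)
  }
})

test_that("quantify_matrix equals locus-by-locus density calls", {
  sim <- mini_cohort(tempfile("mini"))
  calls <- lapply(seq_len(nrow(sim$manifest)), function(i)
    call_sample(sim$manifest[i, ], genes = sim$genes))
  catl <- build_consensus(calls)
  mat <- quantify_matrix(catl, sim$manifest)
  expect_false(mat$normalized)
  expect_true(all(mat$values >= 0))
  for (i in sample.int(nrow(catl$loci), 5)) {
    for (s in sample.int(nrow(sim$manifest), 2)) {
      trk <- read_signal(sim$manifest$signal_path[s])
      expect_equal(mat$values[i, s],
                   quantify_density(catl$loci[i, ], trk),
                   tolerance = 1e-12)
    }
  }
})

test_that("promoter normalization equalizes promoter means to the median", {
  sim <- mini_cohort(tempfile("mini"))
  calls <- lapply(seq_len(nrow(sim$manifest)), function(i)
    call_sample(sim$manifest[i, ], genes = sim$genes))
  catl <- build_consensus(calls)
  mat <- quantify_matrix(catl, sim$manifest)
  norm <- promoter_normalize(mat, sim$manifest, sim$genes)
  expect_true(norm$normalized)

  prom <- data.frame(chrom = sim$genes$chrom,
                     start = sim$genes$tss - 1000,
                     end = sim$genes$tss + 1000)
  pm <- vapply(seq_len(nrow(sim$manifest)), function(i)
    mean(quantify_density(prom, read_signal(sim$manifest$signal_path[i]))),
    0)
  scaled <- pm * norm$scale_factors
  expect_equal(scaled, rep(median(pm), length(pm)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # within-sample rank order of loci preserved
  for (s in seq_len(ncol(mat$values))) {
    expect_equal(order(norm$values[, s]), order(mat$values[, s]))
  }
  # raw matrix with differing promoter means got genuinely rescaled
  expect_gt(diff(range(pm / median(pm))), 0.1)
})

test_that("promoter normalization formula and identity cases", {
  # two identical samples plus one at half scale-to-signal ratio
  genes <- make_genes(seq(1e5, 1e6, by = 5e4))
  peaks <- genomic_intervals("chr1", 5e6 + (0:9) * 1e5,
                             5e6 + (0:9) * 1e5 + 2000)
  mk <- function(prom_val, extra_mass) {
    df <- rbind(
      data.frame(chrom = "chr1", start = genes$tss - 1000,
                 end = genes$tss + 1000, value = prom_val),
      data.frame(chrom = "chr1", start = peaks$start, end = peaks$end,
                 value = 4),
      data.frame(chrom = "chrU", start = 0, end = 1e6,
                 value = extra_mass))
    write_bedgraph_tmp(df)
  }
  man <- data.frame(sample_id = c("S1", "S2", "S3"),
                    group = c("tumor", "tumor", "normal"),
                    pair_id = NA, control_path = NA,
                    peaks_path = NA,
                    signal_path = c(mk(2, 1), mk(2, 1), mk(2, 4)),
                    stringsAsFactors = FALSE)
  catl <- list(loci = data.frame(chrom = peaks$chrom, start = peaks$start,
                                 end = peaks$end,
                                 locus_id = sprintf("L%02d", 1:10)),
               membership = NULL, samples = man$sample_id)
  class(catl) <- "se_catalog"
  mat <- quantify_matrix(catl, man)
  # identical tracks give identical columns
  expect_equal(mat$values[, "S1"], mat$values[, "S2"])
  norm <- promoter_normalize(mat, man, genes)
  # S1/S2 sit at the cohort median: factor 1; S3 has more off-target mass,
  # hence lower promoter mean, hence factor median/p3 > 1
  expect_equal(unname(norm$scale_factors[c("S1", "S2")]), c(1, 1))
  expect_gt(norm$scale_factors[["S3"]], 1)
  # after scaling, S3 equals S1 at every locus again
  expect_equal(norm$values[, "S3"], norm$values[, "S1"],
               tolerance = 1e-12)
})

test_that("fraction of signal mass in SEs", {
  cl <- fake_call("A", genomic_intervals("chr1", 0, 9000),
                  te = genomic_intervals("chr1", c(2e4, 4e4),
                                         c(7.5e4, 9.5e4)))
  # SE mass 10*9000, TE mass 1*55000+1*55000
  expect_equal(fraction_signal_in_ses(cl), 90000 / 200000)
  all_se <- fake_call("B", genomic_intervals("chr1", 0, 1000))
  expect_equal(fraction_signal_in_ses(all_se), 1.0)
  no_se <- fake_call("C", NULL, te = genomic_intervals("chr1", 0, 1000))
  expect_equal(fraction_signal_in_ses(no_se), 0.0)
})
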