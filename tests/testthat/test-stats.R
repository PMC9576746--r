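# differential statistics, ranking, recurrence, saturation, candidates

mat_of <- function(values, samples, normalized = TRUE) {
  structure(list(values = values, normalized = normalized,
                 scale_factors = NULL), class = "se_signal_matrix")
}

test_that("pooled t, fold change and degenerate cases", {
  v <- rbind(L1 = c(2, 4, 6, 1, 2, 3),
             L2 = c(5, 5, 5, 5, 5, 5),
             L3 = c(8, 8, 8, 2, 2, 2))
  colnames(v) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  res <- differential_ses(mat_of(v), c("a1", "a2", "a3"),
                          c("b1", "b2", "b3"), eps = 0)
  # closed form: pooled s^2 = 2.5, df = 4
  expect_equal(res$t_stat[1], 2 / sqrt(2.5 * (2 / 3)), tolerance = 1e-12)
  expect_equal(res$p_value[1], 2 * pt(-2 / sqrt(5 / 3), 4),
               tolerance = 1e-12)
  # identical groups: lfc 0, p 1 (zero variance handled, not NaN)
  expect_equal(res$log2fc[2], 0)
  expect_equal(res$p_value[2], 1.0)
  # means 8 vs 2 with eps = 0 -> exactly 2
  expect_equal(res$log2fc[3], 2.0)
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
})

test_that("differential matches t.test(var.equal=TRUE) on random cases", {
  set.seed(17)
  na <- 5; nb <- 7
  v <- matrix(rexp(200 * (na + nb), 1 / 10), 200)
  colnames(v) <- c(sprintf("a%d", 1:na), sprintf("b%d", 1:nb))
  rownames(v) <- sprintf("L%03d", 1:200)
  res <- differential_ses(mat_of(v), colnames(v)[1:na],
                          colnames(v)[na + 1:nb])
  for (i in sample.int(200, 40)) {
    tt <- t.test(v[i, 1:na], v[i, na + 1:nb], var.equal = TRUE)
    expect_equal(res$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
  }
  # group swap negates lfc and t, preserves p
  sw <- differential_ses(mat_of(v), colnames(v)[na + 1:nb],
                         colnames(v)[1:na])
  expect_equal(sw$log2fc, -res$log2fc, tolerance = 1e-12)
  expect_equal(sw$t_stat, -res$t_stat, tolerance = 1e-12)
  expect_equal(sw$p_value, res$p_value, tolerance = 1e-12)
})

test_that("paired variant uses within-pair differences", {
  v <- rbind(L1 = c(3, 5, 9, 1, 2, 3))
  colnames(v) <- c("t1", "t2", "t3", "n1", "n2", "n3")
  res <- differential_ses(mat_of(v), c("t1", "t2", "t3"),
                          c("n1", "n2", "n3"), paired = TRUE)
  tt <- t.test(v[1, 1:3], v[1, 4:6], paired = TRUE)
  expect_equal(res$t_stat[1], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p_value[1], tt$p.value, tolerance = 1e-10)
})

test_that("ranking is by fold change with p then id tie-breaks", {
  res <- data.frame(locus_id = c("ASCL2_SE", "PDZK1IP1_SE", "OTHER"),
                    log2fc = c(2.73, -2.07, 0.1),
                    p_value = c(0.0027, 1.7e-6, 0.5))
  expect_equal(rank_by_fold_change(res)$locus_id,
               c("ASCL2_SE", "OTHER", "PDZK1IP1_SE"))
  ties <- data.frame(locus_id = c("B", "A", "C"), log2fc = 1,
                     p_value = c(0.2, 0.01, 0.2))
  expect_equal(rank_by_fold_change(ties)$locus_id, c("A", "B", "C"))
  expect_equal(nrow(rank_by_fold_change(res[0, ])), 0L)
})

test_that("divergent selection applies strict p and directional lfc", {
  res <- data.frame(locus_id = c("a", "b", "c"),
                    log2fc = c(-1.5, -0.9, -3.0),
                    p_value = c(0.005, 0.005, 0.02))
  expect_equal(select_divergent(res, direction = "down")$locus_id, "a")
  expect_equal(nrow(select_divergent(res, direction = "up")), 0L)
  expect_equal(select_divergent(res, direction = "both")$locus_id, "a")
})

test_that("recurrence counts group membership per locus", {
  memb <- rbind(L1 = c(TRUE, TRUE, FALSE, TRUE, FALSE),
                L2 = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  colnames(memb) <- c("T1", "T2", "T3", "T4", "N1")
  catl <- structure(list(loci = data.frame(locus_id = c("L1", "L2")),
                         membership = memb,
                         samples = colnames(memb)), class = "se_catalog")
  man <- data.frame(sample_id = colnames(memb),
                    group = c(rep("tumor", 4), "normal"))
  k <- recurrence_counts(catl, man, "tumor")
  expect_equal(unname(k), c(3L, 0L), ignore_attr = TRUE)
  expect_equal(attr(k, "n_group"), 4L)
  # double-counting identity
  expect_equal(sum(k), sum(memb[, 1:4]))
  expect_error(recurrence_counts(catl, man, "organoid"), "no samples")
})

test_that("saturation curve: worked example, monotone, permutation-safe", {
  memb <- rbind(L_A = c(TRUE, FALSE, FALSE),
                L_B = c(TRUE, TRUE, FALSE),
                L_C = c(FALSE, TRUE, TRUE))
  colnames(memb) <- c("S1", "S2", "S3")
  catl <- structure(list(loci = data.frame(locus_id = rownames(memb)),
                         membership = memb, samples = colnames(memb)),
                    class = "se_catalog")
  man <- data.frame(sample_id = colnames(memb), group = "tumor")
  cur <- saturation_curve(catl, man, "tumor")
  expect_equal(cur$cumulative_unique, c(2L, 3L, 3L))
  expect_equal(cur$fraction_of_final, c(2 / 3, 1, 1))
  expect_equal(saturation_index(cur, 0.95), 2L)

  # all 3! orders end at the same final count, all curves non-decreasing
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    cp <- saturation_curve(catl, man, "tumor", order = colnames(memb)[p])
    expect_equal(cp$cumulative_unique[3], 3L)
    expect_true(all(diff(cp$cumulative_unique) >= 0))
  }
  expect_error(saturation_curve(catl, man, "tumor",
                                order = c("S1", "S2")), "permutation")

  # single sample
  one <- structure(list(loci = catl$loci,
                        membership = memb[, 1, drop = FALSE],
                        samples = "S1"), class = "se_catalog")
  man1 <- data.frame(sample_id = "S1", group = "tumor")
  c1 <- saturation_curve(one, man1, "tumor")
  expect_equal(c1$cumulative_unique, 2L)
  expect_equal(saturation_index(c1), 1L)
})

test_that("candidate prioritization intersects ranking and recurrence", {
  ranked <- data.frame(locus_id = c("S1", "S2", "S3", "S4", "S5"),
                       log2fc = 5:1, p_value = 0.01)
  rec <- c(S1 = 10, S2 = 3, S3 = 9, S4 = 15, S5 = 9)
  expect_equal(as.character(prioritize_candidates(ranked, rec, top_n = 3,
                                                  min_k = 9)),
               c("S1", "S3"))
  expect_equal(as.character(prioritize_candidates(ranked, rec, top_n = 3,
                                                  min_k = 0)),
               c("S1", "S2", "S3"))
  expect_warning(all5 <- prioritize_candidates(ranked, rec, top_n = 10,
                                               min_k = 99), "top_n")
  expect_length(all5, 0L)
})

test_that("row z-scoring centers and scales, warns on constant rows", {
  m <- rbind(a = c(1, 2, 3), b = c(7, 7, 7))
  expect_warning(z <- zscore_rows(m), "zero-variance")
  expect_equal(z["a", ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(z["b", ], c(0, 0, 0), ignore_attr = TRUE)
  set.seed(2)
  mm <- matrix(rnorm(50), 5)
  zz <- zscore_rows(mm)
  expect_equal(rowMeans(zz), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(zz, 1, sd), rep(1, 5), tolerance = 1e-12)
})
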