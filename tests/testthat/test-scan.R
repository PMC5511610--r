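test_that("SIM profiles peak at a strong simulated QTL", {
  q <- data.frame(chrom = 1, pos = 50, type = "biallelic", scale = 2)
  sim <- small_sim(51, qtl = q)
  ctx <- mpp_context(sim$ds)
  for (tp in c("biallelic", "parental", "ancestral")) {
    prof <- scan_genome(ctx, tp, "hrt")
    top <- prof[which.max(prof$score), ]
    expect_equal(top$chrom, 1)
    expect_lt(abs(top$pos - sim$truth$qtl$pos_marker), 10)
    expect_true(all(prof$score >= 0))
    expect_true(all(prof$score[!prof$testable] == 0))
  }
})

test_that("cofactors are excluded within the window around the test", {
  q <- data.frame(chrom = 2, pos = 40, type = "biallelic", scale = 1.5)
  sim <- small_sim(52, qtl = q)
  ctx <- mpp_context(sim$ds)
  prof_sim <- scan_genome(ctx, "biallelic", "hrt")
  cof <- data.frame(marker = sim$truth$qtl$marker, chrom = 2,
                    pos = sim$truth$qtl$pos_marker,
                    effect_type = "biallelic")
  prof_cim <- scan_genome(ctx, "biallelic", "hrt", cofactors = cof)
  near <- prof_cim$chrom == 2 & abs(prof_cim$pos - cof$pos) < 20
  # inside the exclusion window the cofactor is dropped, so CIM = SIM
  expect_equal(prof_cim$score[near], prof_sim$score[near],
               tolerance = 1e-10)
  # outside it the cofactor absorbs the QTL and scores change
  far <- prof_cim$chrom == 1
  expect_false(isTRUE(all.equal(prof_cim$score[far],
                                prof_sim$score[far])))
})

test_that("greedy peak selection enforces the spacing rule", {
  prof <- data.frame(marker = sprintf("m%d", 1:5),
                     chrom = c(1, 1, 1, 2, 2),
                     pos = c(0, 10, 40, 5, 90),
                     score = c(8, 6, 2, 7, 1),
                     testable = TRUE)
  attr(prof, "effect_type") <- "biallelic"
  class(prof) <- c("scan_profile", "data.frame")
  sel <- select_cofactors(prof, threshold = 3, min_space_cm = 20)
  # peaks 10 cM apart: only the stronger (8) kept; chrom 2 peak kept
  expect_equal(sort(sel$marker), c("m1", "m4"))
  # below-threshold profile: empty selection
  expect_equal(nrow(select_cofactors(prof, threshold = 10)), 0L)
  # different chromosomes never conflict
  prof$score <- c(8, 2, 2, 7, 6)
  sel2 <- select_cofactors(prof, threshold = 3, min_space_cm = 20)
  expect_equal(sort(sel2$marker), c("m1", "m4", "m5"))
})

test_that("permutation thresholds are reproducible and monotone", {
  sim <- null_sim(53, chrom_lengths = c(60, 60))
  ctx <- mpp_context(sim$ds)
  t1 <- permutation_threshold(ctx, "biallelic", n_perm = 40, seed = 9)
  t2 <- permutation_threshold(ctx, "biallelic", n_perm = 40, seed = 9)
  expect_identical(t1$value, t2$value)
  tmax <- permutation_threshold(ctx, "biallelic", n_perm = 40,
                                quantile = 1, seed = 9)
  expect_equal(tmax$value, max(t1$maxima))
  t50 <- permutation_threshold(ctx, "biallelic", n_perm = 40,
                               quantile = 0.5, seed = 9)
  expect_lte(t50$value, t1$value)
  expect_error(permutation_threshold(ctx, "biallelic", n_perm = 5),
               "n_perm")
})

test_that("the MQE threshold averages its components", {
  expect_equal(mqe_threshold(3, 3, 3)$value, 3)
  expect_equal(mqe_threshold(2, 3, 4)$value, 3)
  expect_equal(mqe_threshold(2.5, 3.1, 4.0)$value, 3.2, tolerance = 1e-12)
  expect_equal(mqe_threshold(2, 3, 4, rule = "max")$value, 4)
})

test_that("backward elimination keeps significant QTLs and drops noise", {
  q <- data.frame(chrom = 1, pos = 30, type = "biallelic", scale = 2)
  sim <- small_sim(54, qtl = q)
  ctx <- mpp_context(sim$ds)
  true_mk <- sim$truth$qtl$marker
  far_mk <- ctx$ds$map$marker[ctx$ds$map$chrom == 2][10]
  cand <- data.frame(
    marker = c(true_mk, far_mk),
    chrom = c(1, 2),
    pos = c(sim$truth$qtl$pos_marker,
            ctx$ds$map$pos_cM[match(far_mk, ctx$ds$map$marker)]),
    effect_type = "biallelic")
  kept <- backward_eliminate(ctx, cand, "hrt", alpha = 0.01)
  expect_true(true_mk %in% kept$marker)
  expect_false(far_mk %in% kept$marker)
  # retained QTLs are significant at alpha
  expect_true(all(10^(-kept$score) <= 0.01))
})

test_that("the detection pipeline respects spacing and the threshold", {
  q <- data.frame(chrom = c(1, 2), pos = c(30, 70),
                  type = c("biallelic", "biallelic"), scale = c(2, 2))
  sim <- small_sim(55, qtl = q)
  ctx <- mpp_context(sim$ds)
  thr <- permutation_threshold(ctx, "biallelic", n_perm = 50, seed = 3)
  det <- detect_qtls(ctx, "biallelic", "hrt", thr)
  expect_gte(det$n_qtl, 1L)
  if (det$n_qtl > 1) {
    for (ch in unique(det$qtl$chrom)) {
      p <- sort(det$qtl$pos[det$qtl$chrom == ch])
      if (length(p) > 1) expect_true(all(diff(p) >= 20))
    }
  }
  expect_true(all(10^(-det$qtl$score) <= 0.01))
  expect_gt(det$r2_adj, 0)

  # the same pipeline runs under all residual kinds (eight-model surface)
  for (res in c("fcsrt", "csrt")) {
    d2 <- detect_qtls(ctx, "biallelic", res, thr)
    expect_s3_class(d2, "qtl_detection")
  }
})

test_that("f-CSRT and HRT scans agree when cross variances are equal", {
  q <- data.frame(chrom = 1, pos = 30, type = "biallelic", scale = 1)
  sim <- small_sim(56, qtl = q, lines = 100L, chrom_lengths = 100,
                   resid_sd = rep(1, 4))
  ctx <- mpp_context(sim$ds)
  ph <- scan_genome(ctx, "biallelic", "hrt")
  pf <- scan_genome(ctx, "biallelic", "fcsrt")
  ok <- ph$testable
  expect_gt(cor(ph$score[ok], pf$score[ok], method = "spearman"), 0.99)
})
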