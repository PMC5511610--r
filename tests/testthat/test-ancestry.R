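test_that("simple matching coefficient matches hand counts", {
  x <- c(0, 2, 2, 0, 0, 2, 0, 2, 0, 2)
  expect_equal(simple_matching(x, x), 1)
  expect_equal(simple_matching(x, 2 - x), 0)
  # 10 loci, 3 mismatches, 1 missing pair -> 6/9
  y <- x; y[c(1, 2, 3)] <- 2 - y[c(1, 2, 3)]; y[10] <- NA
  expect_equal(simple_matching(x, y), 6 / 9, tolerance = 1e-12)
  # symmetry on random vectors
  set.seed(1)
  for (i in 1:10) {
    a <- sample(c(0, 2, NA), 30, replace = TRUE)
    b <- sample(c(0, 2, NA), 30, replace = TRUE)
    if (!any(!is.na(a) & !is.na(b))) next
    expect_equal(simple_matching(a, b), simple_matching(b, a))
  }
  expect_error(simple_matching(c(NA, 0), c(2, NA)), "undefined")
})

test_that("windowed clustering groups parents by similarity", {
  sim <- null_sim(31, n_per = 4L, lines = 10L, chrom_lengths = 60,
                  spacing = 0.5)
  ds <- sim$ds
  # threshold 1 with distinct parents: every parent its own group
  asg <- cluster_parents_at(ds, 1, 30, window_cm = 10, sim_threshold = 1)
  expect_equal(asg$n_groups, 5L)
  expect_true(all(rowSums(asg$A) == 1))

  # duplicate one peripheral parent as a copy of the central one
  ds2 <- ds
  ds2$parent_geno["P1", ] <- ds2$parent_geno["P0", ]
  asg2 <- cluster_parents_at(ds2, 1, 30, window_cm = 10,
                             sim_threshold = 0.9)
  expect_equal(asg2$groups[["P0"]], asg2$groups[["P1"]])

  # group count is monotone non-increasing as the threshold drops
  ks <- vapply(c(1, 0.9, 0.7, 0.5, 0.2),
               function(t) cluster_parents_at(ds, 1, 30, window_cm = 10,
                                              sim_threshold = t)$n_groups,
               integer(1))
  expect_true(all(diff(ks) <= 0))

  # empty window falls back to the nearest marker with a notice
  expect_message(cluster_parents_at(ds, 1, 59.76, window_cm = 0.01),
                 "nearest")
})

test_that("clustering recovers the founder assignment of related parents", {
  cfg <- sim_config(n_peripheral = 5L, lines_per_cross = 10L,
                    chrom_lengths = 100, marker_spacing = 0.1,
                    n_ancestral = 3L, parent_divergence = 0.01,
                    h2_target = NULL, cross_residual_sd = rep(1, 5),
                    seed = 32)
  sim <- simulate_nam(cfg)
  truth <- sim$truth$assignment
  pos <- seq(5, 95, by = 5)
  hits <- vapply(pos, function(p) {
    asg <- cluster_parents_at(sim$ds, 1, p, window_cm = 2,
                              sim_threshold = 0.9)
    g <- asg$groups[names(truth)]
    # same partition up to labels
    all(outer(g, g, "==") == outer(truth, truth, "=="))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("ancestral transformation pools related parents' dosages", {
  ds <- toy_dataset()
  post <- dh_origin_posteriors(ds)
  par_inc <- parental_incidence(post, ds, "m4")

  # each parent its own group: ancestral = parental (up to reference drop)
  asg_id <- cluster_parents_at(ds, 1, 20, window_cm = 50,
                               sim_threshold = 1)
  if (asg_id$n_groups == 3L) {
    anc <- ancestral_incidence(par_inc, asg_id)
    per_groups <- setdiff(colnames(asg_id$A),
                          colnames(asg_id$A)[asg_id$ref_group])
    expect_equal(unname(anc$X),
                 unname(par_inc$X[, order(asg_id$groups[c("P1", "P2")])]))
  }

  # hand-built assignment mirroring two crosses whose central and second
  # peripheral parent share an ancestor: {P0, P2}, {P1}
  A <- matrix(c(1L, 0L, 0L, 1L, 1L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("P0", "P1", "P2"), c("G1", "G2")))
  asg <- structure(list(groups = c(P0 = 1L, P1 = 2L, P2 = 1L), A = A,
                        ref_group = 1L, n_groups = 2L),
                   class = "ancestral_assignment")
  anc <- ancestral_incidence(par_inc, asg)
  expect_equal(colnames(anc$X), "G2")
  cr <- cross_of(ds)
  # cross-2 dosage (P2) collapses into the dropped reference group:
  # its rows are zero in the kept column
  expect_true(all(anc$X[cr == "c2", ] == 0))
  expect_equal(anc$X[cr == "c1", 1], par_inc$X[cr == "c1", "P1"])

  # allele-count conservation: full ancestral matrix rows sum to 2
  Xfull_anc <- cbind(2 - rowSums(anc$X), anc$X)
  expect_true(all(abs(rowSums(Xfull_anc) - 2) < 1e-12))
  Xfull_par <- cbind(2 - rowSums(par_inc$X), par_inc$X)
  expect_true(all(abs(rowSums(Xfull_par) - 2) < 1e-12))

  # all parents one group: nothing segregates, incidence is empty
  A1 <- matrix(1L, 3, 1, dimnames = list(c("P0", "P1", "P2"), "G1"))
  asg1 <- structure(list(groups = c(P0 = 1L, P1 = 1L, P2 = 1L), A = A1,
                         ref_group = 1L, n_groups = 1L),
                    class = "ancestral_assignment")
  anc1 <- ancestral_incidence(par_inc, asg1)
  expect_equal(ncol(anc1$X), 0L)
})
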