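test_that("dataset construction validates the NAM invariants", {
  ds <- toy_dataset()
  expect_s3_class(ds, "mpp_dataset")
  expect_equal(nrow(ds$crosses), 2L)
  expect_equal(n_mark(ds), 4L)

  # map marker absent from genotypes
  bad_map <- rbind(ds$map, data.frame(marker = "m9", chrom = 1, pos_cM = 30))
  expect_error(mpp_dataset(bad_map, ds$parent_geno, ds$geno, ds$cross_ind,
                           ds$crosses, ds$pheno, ds$h2),
               "integrity error")

  # heterozygous parent call
  pg <- ds$parent_geno; pg["P1", "m1"] <- 1
  expect_error(mpp_dataset(ds$map, pg, ds$geno, ds$cross_ind, ds$crosses,
                           ds$pheno, ds$h2),
               "heterozygous")

  # two central parents violate the NAM constraint
  cx <- ds$crosses; cx$parent_central <- c("P0", "P1")
  expect_error(mpp_dataset(ds$map, ds$parent_geno, ds$geno, ds$cross_ind,
                           cx, ds$pheno, ds$h2),
               "central parent")
})

test_that("write/read round trip reproduces the dataset exactly", {
  ds <- toy_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- read_dataset(file.path(dir, "genotypes.csv"),
                      file.path(dir, "map.csv"),
                      file.path(dir, "cross.csv"),
                      file.path(dir, "pheno.csv"),
                      file.path(dir, "h2.csv"))
  expect_equal(ds2$map, ds$map)
  expect_equal(ds2$geno, ds$geno)
  expect_equal(ds2$parent_geno, ds$parent_geno)
  expect_equal(ds2$pheno, ds$pheno)
  expect_equal(ds2$h2, ds$h2)
  expect_equal(ds2$cross_ind, ds$cross_ind)

  expect_error(read_dataset(file.path(dir, "map.csv"),
                            file.path(dir, "map.csv"),
                            file.path(dir, "cross.csv"),
                            file.path(dir, "pheno.csv"),
                            file.path(dir, "h2.csv")),
               "missing column")
})

test_that("marker filtering applies the MAF/missingness/segregation rules", {
  map <- data.frame(marker = c("a", "b", "c", "d", "e"),
                    chrom = 1L, pos_cM = c(0, 10, 10, 20, 30))
  # offspring dosages chosen to give MAF a=0 (monomorphic), b=0.30,
  # c=0.10, d=0.25 with 20% missing, e=0.25
  og <- cbind(a = rep(0, 20),
              b = rep(c(2, 2, 2, 0, 0, 0, 2, 0, 0, 0), 2),
              c = rep(c(2, 0, 0, 0, 0, 2, 0, 0, 0, 0), 2),
              d = c(rep(2, 5), rep(0, 11), rep(NA, 4)),
              e = c(rep(2, 5), rep(0, 15)))
  rownames(og) <- sprintf("i%02d", 1:20)
  pg <- rbind(P0 = c(0, 0, 0, 0, 0), P1 = c(0, 2, 2, 2, 2),
              P2 = c(0, 2, 2, 2, 2))
  colnames(pg) <- map$marker
  ds <- mpp_dataset(map, pg, og,
                    data.frame(id = rownames(og),
                               cross = rep(c("c1", "c2"), each = 10)),
                    data.frame(cross = c("c1", "c2"),
                               parent_central = "P0",
                               parent_peripheral = c("P1", "P2")),
                    data.frame(id = rownames(og), trait = "t",
                               value = rnorm(20)),
                    data.frame(cross = c("c1", "c2"), h2 = 0.7))
  out <- filter_markers(ds, maf_min = 0.01, miss_max = 0.10)
  # a: monomorphic, removed; c: loses the position tie against b
  # (MAF 0.10 < 0.30); d: 20% missing > 10%, removed
  expect_equal(out$map$marker, c("b", "e"))

  # idempotence
  out2 <- filter_markers(out, maf_min = 0.01, miss_max = 0.10)
  expect_equal(out2$map, out$map)
  expect_equal(out2$geno, out$geno)

  expect_error(filter_markers(ds, maf_min = 0.5, miss_max = 0),
               "empty dataset")
})

test_that("thinning keeps the most polymorphic marker per bin", {
  # markers at 0.2 and 0.8 cM with MAF 0.10 and 0.40: 0.8 kept
  map <- data.frame(marker = c("x1", "x2", "y1"),
                    chrom = c(1L, 1L, 2L), pos_cM = c(0.2, 0.8, 3))
  og <- cbind(x1 = rep(c(2, rep(0, 9)), 2),
              x2 = rep(c(2, 2, 2, 2, 0, 0, 0, 0, 0, 0), 2),
              y1 = rep(c(2, 0), 10))
  rownames(og) <- sprintf("i%02d", 1:20)
  pg <- rbind(P0 = c(0, 0, 0), P1 = c(2, 2, 2), P2 = c(2, 2, 2))
  colnames(pg) <- map$marker
  ds <- mpp_dataset(map, pg, og,
                    data.frame(id = rownames(og),
                               cross = rep(c("c1", "c2"), each = 10)),
                    data.frame(cross = c("c1", "c2"),
                               parent_central = "P0",
                               parent_peripheral = c("P1", "P2")),
                    data.frame(id = rownames(og), trait = "t",
                               value = rnorm(20)),
                    data.frame(cross = c("c1", "c2"), h2 = 0.7))
  out <- thin_markers(ds, bin_cm = 1)
  expect_equal(out$map$marker, c("x2", "y1"))

  # bin wider than the chromosome: one marker per chromosome
  out <- thin_markers(ds, bin_cm = 1000)
  expect_equal(nrow(out$map), 2L)
  expect_true(all(out$map$marker %in% ds$map$marker))

  # equispaced markers, one per bin: all kept
  sim <- null_sim(42, chrom_lengths = 9, spacing = 1)
  expect_equal(n_mark(thin_markers(sim$ds, 1)), 10L)
})
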