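# Fixtures are built in code: a tiny hand-set NAM dataset and small
# simulator wrappers shared across test files.

toy_dataset <- function() {
  map <- data.frame(marker = c("m1", "m2", "m3", "m4"),
                    chrom = 1L, pos_cM = c(0, 5, 5, 20))
  pg <- rbind(P0 = c(0, 0, 0, 0),
              P1 = c(2, 2, 0, 2),
              P2 = c(2, 0, 2, 2))
  colnames(pg) <- map$marker
  og <- rbind(i1 = c(0, 0, 0, 0), i2 = c(2, 2, 0, 2),
              i3 = c(2, 2, 0, 0), i4 = c(0, 0, 0, 2),
              i5 = c(2, 0, 2, 2), i6 = c(0, 0, 0, 0),
              i7 = c(2, 0, 2, 0), i8 = c(0, 0, NA, 2))
  colnames(og) <- map$marker
  mpp_dataset(
    map = map, parent_geno = pg, geno = og,
    cross_ind = data.frame(id = rownames(og),
                           cross = rep(c("c1", "c2"), each = 4)),
    crosses = data.frame(cross = c("c1", "c2"), parent_central = "P0",
                         parent_peripheral = c("P1", "P2")),
    pheno = data.frame(id = rownames(og), trait = "t",
                       value = c(1.2, 3.4, 2.2, 1.8, 4.1, 0.7, 3.3, 1.5)),
    h2 = data.frame(cross = c("c1", "c2"), h2 = c(0.8, 0.6)))
}

# Small NAM simulation: distinct founders per parent (every marker
# informative in ~half the crosses), one optional QTL.
small_sim <- function(seed, qtl = NULL, n_per = 4L, lines = 50L,
                      chrom_lengths = c(100, 100), spacing = 2,
                      h2 = 0.6, resid_sd = NULL) {
  cfg <- sim_config(n_peripheral = n_per, lines_per_cross = lines,
                    chrom_lengths = chrom_lengths,
                    marker_spacing = spacing,
                    n_ancestral = n_per + 1L, parent_divergence = 0,
                    qtl = qtl, h2_target = if (is.null(resid_sd)) h2,
                    cross_residual_sd = resid_sd, seed = seed)
  # a QTL that happens not to segregate in some cross triggers the
  # documented zero-genetic-variance warning; expected here
  quiet_zero_vg(simulate_nam(cfg))
}

quiet_zero_vg <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("zero genetic variance", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# Null NAM dataset: no QTLs, homogeneous gaussian residuals.
null_sim <- function(seed, n_per = 4L, lines = 50L,
                     chrom_lengths = c(100, 100), spacing = 2,
                     resid_sd = 1) {
  small_sim(seed, qtl = NULL, n_per = n_per, lines = lines,
            chrom_lengths = chrom_lengths, spacing = spacing,
            resid_sd = rep(resid_sd, n_per))
}

# Incidence wrapper for raw design columns (used by oracle tests).
raw_incidence <- function(X, marker = "mX") {
  structure(list(X = X, effect_type = "biallelic",
                 labels = colnames(X), ref = "ref", marker = marker,
                 testable = TRUE),
            class = "qtl_incidence")
}
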