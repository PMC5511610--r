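# ---- NAM doubled-haploid simulator -----------------------------------------

#' Simulation configuration for a NAM DH population
#'
#' Describes the stated world the simulator generates: one central parent
#' crossed to \code{n_peripheral} peripheral parents, each cross producing
#' \code{lines_per_cross} doubled-haploid lines. Parents descend from
#' \code{n_ancestral} founder haplotypes; each parent copies one founder and
#' mutates each marker independently with probability
#' \code{parent_divergence}, which controls parental relatedness (simple
#' matching within a founder group has expectation
#' 1 - 2 p (1 - p) for divergence p).
#'
#' Default sizes mirror a maize NAM subset of moderate size: 5 crosses of
#' 72 DH lines (361 lines in total, rounded to 360), a genome of 10
#' chromosomes of 160 cM at 1 cM marker spacing (a thinned consensus-map
#' density), 4 ancestral founders, and a within-cross heritability target
#' of 0.6 (between typical yield and height heritabilities).
#'
#' @param n_peripheral number of peripheral parents (>= 2)
#' @param lines_per_cross DH lines per cross
#' @param chrom_lengths numeric vector of chromosome lengths (cM)
#' @param marker_spacing marker spacing in cM
#' @param n_ancestral number of founder haplotypes (<= n_peripheral + 1)
#' @param parent_divergence per-marker mutation probability in [0, 0.5]
#' @param qtl data.frame with columns \code{chrom}, \code{pos},
#'   \code{type} (\code{parental}, \code{ancestral} or \code{biallelic})
#'   and \code{scale} (trait units, >= 0); QTLs are placed at the nearest
#'   marker. NULL for a null genome.
#' @param h2_target within-cross heritability target in (0, 1), or NULL to
#'   use \code{cross_residual_sd} directly
#' @param cross_residual_sd per-cross residual SD (length
#'   \code{n_peripheral}); only used when \code{h2_target} is NULL
#' @param seed integer seed fixing every random draw
#' @return an object of class \code{sim_config}
#' @export
sim_config <- function(n_peripheral = 5L, lines_per_cross = 72L,
                       chrom_lengths = rep(160, 10L), marker_spacing = 1,
                       n_ancestral = 4L, parent_divergence = 0.05,
                       qtl = NULL, h2_target = 0.6,
                       cross_residual_sd = NULL, seed = 1L) {
  stopifnot(n_peripheral >= 2L, lines_per_cross >= 2L,
            all(chrom_lengths > 0), marker_spacing > 0,
            n_ancestral >= 1L, n_ancestral <= n_peripheral + 1L,
            parent_divergence >= 0, parent_divergence <= 0.5)
  if (!is.null(qtl)) {
    qtl <- as.data.frame(qtl)
    stopifnot(all(c("chrom", "pos", "type", "scale") %in% names(qtl)),
              all(qtl$type %in% c("parental", "ancestral", "biallelic")),
              all(qtl$scale >= 0),
              all(qtl$chrom >= 1 & qtl$chrom <= length(chrom_lengths)),
              all(qtl$pos >= 0 & qtl$pos <= chrom_lengths[qtl$chrom]))
  }
  if (is.null(h2_target)) {
    stopifnot(length(cross_residual_sd) == n_peripheral,
              all(cross_residual_sd >= 0))
  } else {
    stopifnot(h2_target > 0, h2_target < 1)
  }
  structure(list(n_peripheral = as.integer(n_peripheral),
                 lines_per_cross = as.integer(lines_per_cross),
                 chrom_lengths = chrom_lengths,
                 marker_spacing = marker_spacing,
                 n_ancestral = as.integer(n_ancestral),
                 parent_divergence = parent_divergence,
                 qtl = qtl, h2_target = h2_target,
                 cross_residual_sd = cross_residual_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.sim_map <- function(cfg) {
  pieces <- lapply(seq_along(cfg$chrom_lengths), function(ch) {
    pos <- seq(0, cfg$chrom_lengths[ch], by = cfg$marker_spacing)
    data.frame(marker = sprintf("c%d_m%04d", ch, seq_along(pos)),
               chrom = ch, pos_cM = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Simulate inbred parents from founder haplotypes
#'
#' Draws \code{n_ancestral} founder haplotypes i.i.d. Bernoulli(0.5) per
#' marker (coded 0/2); each of the \code{n_peripheral + 1} parents copies
#' one founder (founders are recycled in order so every founder is used)
#' and flips each marker independently with probability
#' \code{parent_divergence}.
#'
#' @param cfg a \code{sim_config}
#' @param map genetic map data.frame (made internally by
#'   \code{\link{simulate_nam}}); columns \code{marker,chrom,pos_cM}
#' @return list with \code{geno} (parent dosage matrix, central parent
#'   first), \code{founders} (founder dosage matrix) and
#'   \code{assignment} (named integer vector parent -> founder)
#' @export
simulate_parents <- function(cfg, map) {
  m <- nrow(map)
  n_par <- cfg$n_peripheral + 1L
  founders <- matrix(2 * rbinom(cfg$n_ancestral * m, 1L, 0.5),
                     nrow = cfg$n_ancestral, ncol = m)
  assignment <- rep_len(seq_len(cfg$n_ancestral), n_par)
  geno <- founders[assignment, , drop = FALSE]
  flip <- matrix(rbinom(n_par * m, 1L, cfg$parent_divergence) == 1L,
                 nrow = n_par)
  geno[flip] <- 2 - geno[flip]
  ids <- c("P0", sprintf("P%d", seq_len(cfg$n_peripheral)))
  rownames(geno) <- ids
  colnames(geno) <- map$marker
  rownames(founders) <- sprintf("F%d", seq_len(cfg$n_ancestral))
  colnames(founders) <- map$marker
  names(assignment) <- ids
  list(geno = geno, founders = founders, assignment = assignment)
}

#' Simulate doubled-haploid lines from a biparental cross
#'
#' One gamete per DH line, simulated as a two-state Markov chain along each
#' chromosome: origin starts A or B with probability 1/2 and switches
#' between adjacent markers with the Haldane recombination fraction
#' r(d) = (1 - exp(-2 d / 100)) / 2 (no interference). The gamete is
#' doubled, so every marker dosage is 0 or 2.
#'
#' @param parentA,parentB named dosage vectors (0/2) over the map's markers
#' @param map genetic map data.frame
#' @param n_lines number of DH lines
#' @param prefix id prefix for the lines
#' @return list with \code{geno} (lines x markers dosage matrix) and
#'   \code{origin} (matrix of 1 = parent A, 2 = parent B)
#' @export
simulate_dh_cross <- function(parentA, parentB, map, n_lines,
                              prefix = "DH") {
  if (any(!is.na(parentA) & !(parentA %in% c(0, 2))) ||
      any(!is.na(parentB) & !(parentB %in% c(0, 2))))
    stop("parents must be homozygous (dosages 0/2)")
  m <- nrow(map)
  origin <- matrix(NA_integer_, n_lines, m)
  for (ch in unique(map$chrom)) {
    ix <- which(map$chrom == ch)
    o <- matrix(NA_integer_, n_lines, length(ix))
    o[, 1L] <- 1L + rbinom(n_lines, 1L, 0.5)
    if (length(ix) > 1L) {
      r <- haldane_r(diff(map$pos_cM[ix]))
      for (k in 2L:length(ix)) {
        sw <- rbinom(n_lines, 1L, r[k - 1L]) == 1L
        o[, k] <- ifelse(sw, 3L - o[, k - 1L], o[, k - 1L])
      }
    }
    origin[, ix] <- o
  }
  geno <- matrix(parentA[map$marker], n_lines, m, byrow = TRUE)
  gb <- matrix(parentB[map$marker], n_lines, m, byrow = TRUE)
  geno[origin == 2L] <- gb[origin == 2L]
  rownames(geno) <- rownames(origin) <- sprintf("%s_%03d", prefix,
                                                seq_len(n_lines))
  colnames(geno) <- colnames(origin) <- map$marker
  list(geno = geno, origin = origin)
}

# Draw allele effects for one QTL. For parental/ancestral types each
# parent/founder group receives an i.i.d. N(0, scale^2) diplotype effect;
# for the bi-allelic type the allele coded 2 adds `scale` relative to
# allele 0. A DH line's contribution at the locus is the effect of the
# parent (or group) it inherited from, or dosage/2 * scale for biallelic;
# on the 0..2 allele-dosage scale of the fitted models a coefficient is
# therefore half of the parent-vs-parent substitution contrast.
.draw_qtl_effects <- function(type, scale, parent_ids, assignment) {
  if (type == "parental") {
    eff <- stats::rnorm(length(parent_ids), 0, scale)
    names(eff) <- parent_ids
  } else if (type == "ancestral") {
    groups <- sort(unique(assignment))
    geff <- stats::rnorm(length(groups), 0, scale)
    names(geff) <- as.character(groups)
    eff <- geff[as.character(assignment[parent_ids])]
    names(eff) <- parent_ids
    attr(eff, "group_effects") <- geff
  } else {
    eff <- scale
  }
  eff
}

#' Simulate phenotypes for a NAM population with known QTL architecture
#'
#' y = cross mean (N(0, 1) per cross) + genetic value + residual, with the
#' residual drawn N(0, sigma_rc^2) per cross. When \code{h2_target} is set,
#' sigma_rc is scaled so the within-cross heritability equals the target in
#' expectation (sigma_rc^2 = var_g,c (1 - h2) / h2); realized h2 =
#' var(g) / var(g + e) within cross is recorded and becomes the dataset's
#' per-cross h2. The polygenic background and plot error are collapsed into
#' the single cross-specific residual because the analysis unit is an
#' adjusted mean.
#'
#' @param cfg a \code{sim_config}
#' @param genetic named numeric vector of per-individual genetic values
#' @param cross_ids character vector of cross ids aligned with
#'   \code{genetic}
#' @return list with \code{pheno} (data.frame id, trait, value), \code{h2}
#'   (data.frame cross, h2 — realized values) and \code{residual_sd} per
#'   cross
#' @export
simulate_phenotypes <- function(cfg, genetic, cross_ids) {
  crosses <- unique(cross_ids)
  y <- numeric(length(genetic))
  h2r <- sdr <- setNames(numeric(length(crosses)), crosses)
  for (k in seq_along(crosses)) {
    ix <- which(cross_ids == crosses[k])
    g <- genetic[ix]
    vg <- stats::var(g)
    if (!is.null(cfg$h2_target)) {
      if (vg <= 0) {
        warning("zero genetic variance in cross ", crosses[k],
                "; heritability floored at 0.01")
        sdc <- 1
      } else {
        sdc <- sqrt(vg * (1 - cfg$h2_target) / cfg$h2_target)
      }
    } else {
      sdc <- cfg$cross_residual_sd[k]
    }
    mu <- stats::rnorm(1L)
    e <- stats::rnorm(length(ix), 0, sdc)
    y[ix] <- mu + g + e
    vt <- stats::var(g + e)
    h2r[k] <- if (vg <= 0 || vt <= 0) 0.01 else min(max(vg / vt, 0.01), 1)
    sdr[k] <- sdc
  }
  list(pheno = data.frame(id = names(genetic), trait = "sim",
                          value = y, stringsAsFactors = FALSE),
       h2 = data.frame(cross = crosses, h2 = as.numeric(h2r),
                       stringsAsFactors = FALSE),
       residual_sd = sdr)
}

#' Simulate a complete NAM DH dataset with known truth
#'
#' End-to-end generator: map, founders, parents, DH crosses, QTL effects and
#' phenotypes. Fixing \code{cfg$seed} fixes every output. QTLs are placed at
#' the marker nearest the requested position; at bi-allelic QTL markers the
#' founder alleles are redrawn until the parents are polymorphic (otherwise
#' the locus would carry no signal by construction).
#'
#' @param cfg a \code{sim_config}
#' @return list of class \code{nam_sim} with \code{ds} (an
#'   \code{\link{mpp_dataset}}) and \code{truth}: founders, parent->founder
#'   \code{assignment}, per-QTL marker/type/allele effects (and the
#'   model-scale contrasts \code{contrast}, i.e. (effect - central effect)/2
#'   on the 0..2 dosage scale), true origin matrices, per-individual genetic
#'   values and realized per-cross h2.
#' @export
simulate_nam <- function(cfg) {
  set.seed(cfg$seed)
  map <- .sim_map(cfg)
  par <- simulate_parents(cfg, map)
  parent_ids <- rownames(par$geno)
  central <- parent_ids[1L]
  peripheral <- parent_ids[-1L]

  qtl <- cfg$qtl
  qtl_mark <- character(0)
  if (!is.null(qtl) && nrow(qtl)) {
    qtl_mark <- vapply(seq_len(nrow(qtl)), function(i) {
      ix <- which(map$chrom == qtl$chrom[i])
      map$marker[ix[which.min(abs(map$pos_cM[ix] - qtl$pos[i]))]]
    }, character(1L))
    # bi-allelic QTLs need a polymorphic SNP among the parents in use
    for (i in which(qtl$type == "biallelic")) {
      mk <- qtl_mark[i]
      while (length(unique(par$geno[, mk])) < 2L) {
        newf <- 2 * rbinom(cfg$n_ancestral, 1L, 0.5)
        par$founders[, mk] <- newf
        g <- newf[par$assignment]
        flip <- rbinom(length(g), 1L, cfg$parent_divergence) == 1L
        g[flip] <- 2 - g[flip]
        par$geno[, mk] <- g
      }
    }
  }

  effects <- lapply(seq_along(qtl_mark), function(i)
    .draw_qtl_effects(qtl$type[i], qtl$scale[i], parent_ids,
                      par$assignment))

  geno <- NULL; origin <- NULL
  cross_ind <- crosses <- NULL
  for (k in seq_len(cfg$n_peripheral)) {
    cid <- sprintf("CR%02d", k)
    sim <- simulate_dh_cross(par$geno[central, ], par$geno[peripheral[k], ],
                             map, cfg$lines_per_cross,
                             prefix = sprintf("%s_L", cid))
    geno <- rbind(geno, sim$geno)
    origin <- rbind(origin, sim$origin)
    cross_ind <- rbind(cross_ind,
                       data.frame(id = rownames(sim$geno), cross = cid,
                                  stringsAsFactors = FALSE))
    crosses <- rbind(crosses,
                     data.frame(cross = cid, parent_central = central,
                                parent_peripheral = peripheral[k],
                                stringsAsFactors = FALSE))
  }

  # genetic values: per QTL, effect of the inherited parent (or its founder
  # group), or dosage/2 * scale for bi-allelic loci
  genetic <- setNames(numeric(nrow(geno)), rownames(geno))
  cross_parent <- setNames(crosses$parent_peripheral, crosses$cross)
  for (i in seq_along(qtl_mark)) {
    mk <- qtl_mark[i]
    if (qtl$type[i] == "biallelic") {
      genetic <- genetic + geno[, mk] / 2 * effects[[i]]
    } else {
      par_origin <- ifelse(origin[, mk] == 1L, central,
                           cross_parent[cross_ind$cross])
      genetic <- genetic + effects[[i]][par_origin]
    }
  }

  ph <- simulate_phenotypes(cfg, genetic, cross_ind$cross)
  ds <- mpp_dataset(map, par$geno, geno, cross_ind, crosses, ph$pheno,
                    ph$h2)

  contrasts <- lapply(seq_along(qtl_mark), function(i) {
    if (qtl$type[i] == "biallelic") return(effects[[i]] / 2)
    (effects[[i]][peripheral] - effects[[i]][central]) / 2
  })
  truth <- list(founders = par$founders, assignment = par$assignment,
                qtl = if (length(qtl_mark))
                  cbind(qtl, marker = qtl_mark,
                        pos_marker = map$pos_cM[match(qtl_mark, map$marker)])
                else NULL,
                effects = effects, contrast = contrasts,
                origin = origin, genetic = genetic,
                h2_realized = setNames(ph$h2$h2, ph$h2$cross),
                residual_sd = ph$residual_sd)
  structure(list(ds = ds, truth = truth, config = cfg), class = "nam_sim")
}
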