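# ---- MPP dataset container -------------------------------------------------

#' Construct and validate an MPP dataset
#'
#' Bundles the five ingredients of a multi-parent-population (MPP) analysis:
#' a genetic map, parent and offspring marker dosage matrices, the cross
#' structure (which offspring belongs to which cross, and which parent pair
#' made each cross), adjusted-mean phenotypes and per-cross heritabilities.
#' The population is assumed to be a NAM design of doubled-haploid (DH)
#' lines: one central parent shared by all crosses, each peripheral parent
#' used in exactly one cross, offspring fully homozygous (dosages 0/2).
#'
#' @param map data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos_cM}; one row per marker. Markers are sorted by
#'   (\code{chrom}, \code{pos_cM}, \code{marker}).
#' @param parent_geno numeric matrix (parents x markers) with entries in
#'   \{0, 2, NA\}; rownames are parent ids, colnames marker ids.
#' @param geno numeric matrix (offspring x markers) with entries in
#'   \{0, 1, 2, NA\}; rownames are offspring ids. DH offspring should carry
#'   only 0/2/NA; a dosage 1 in an offspring is tolerated at input but is
#'   rejected in a parent.
#' @param cross_ind data.frame with columns \code{id}, \code{cross}: one row
#'   per offspring.
#' @param crosses data.frame with columns \code{cross},
#'   \code{parent_central}, \code{parent_peripheral}.
#' @param pheno data.frame with columns \code{id}, \code{trait},
#'   \code{value} (adjusted means).
#' @param h2 data.frame with columns \code{cross}, \code{h2}; within-cross
#'   heritability in (0, 1], the denominator of pTS/pVS.
#' @return An object of class \code{mpp_dataset}.
#' @export
mpp_dataset <- function(map, parent_geno, geno, cross_ind, crosses, pheno, h2) {
  map <- as.data.frame(map)
  need <- c("marker", "chrom", "pos_cM")
  if (!all(need %in% names(map)))
    stop("format error: map must have columns ", paste(need, collapse = ", "))
  map$marker <- as.character(map$marker)
  if (anyDuplicated(map$marker))
    stop("integrity error: duplicated marker ids in map: ",
         paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  map <- map[order(map$chrom, map$pos_cM, map$marker), , drop = FALSE]
  rownames(map) <- NULL

  parent_geno <- as.matrix(parent_geno)
  geno <- as.matrix(geno)
  for (nm in c("parent_geno", "geno")) {
    m <- get(nm)
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stop("format error: ", nm, " needs row and column names")
  }
  miss <- setdiff(map$marker, colnames(geno))
  if (length(miss))
    stop("integrity error: markers in map absent from offspring genotypes: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  miss <- setdiff(map$marker, colnames(parent_geno))
  if (length(miss))
    stop("integrity error: markers in map absent from parent genotypes: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  extra <- setdiff(colnames(geno), map$marker)
  if (length(extra))
    stop("integrity error: genotyped markers missing from map: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  parent_geno <- parent_geno[, map$marker, drop = FALSE]
  geno <- geno[, map$marker, drop = FALSE]

  if (any(!is.na(parent_geno) & !(parent_geno %in% c(0, 2))))
    stop("integrity error: heterozygous or invalid parent call; parent rows ",
         "must contain only 0/2/NA")
  if (any(!is.na(geno) & !(geno %in% c(0, 1, 2))))
    stop("integrity error: offspring dosages must be 0/1/2/NA")

  cross_ind <- as.data.frame(cross_ind)
  if (!all(c("id", "cross") %in% names(cross_ind)))
    stop("format error: cross table must have columns id, cross")
  cross_ind$id <- as.character(cross_ind$id)
  cross_ind$cross <- as.character(cross_ind$cross)
  crosses <- as.data.frame(crosses)
  if (!all(c("cross", "parent_central", "parent_peripheral") %in% names(crosses)))
    stop("format error: crosses table must have columns cross, ",
         "parent_central, parent_peripheral")
  crosses$cross <- as.character(crosses$cross)
  crosses$parent_central <- as.character(crosses$parent_central)
  crosses$parent_peripheral <- as.character(crosses$parent_peripheral)
  if (length(unique(crosses$parent_central)) != 1L)
    stop("integrity error: NAM design requires a single central parent, got: ",
         paste(unique(crosses$parent_central), collapse = ", "))
  if (anyDuplicated(crosses$parent_peripheral))
    stop("integrity error: peripheral parent used in more than one cross: ",
         paste(crosses$parent_peripheral[duplicated(crosses$parent_peripheral)],
               collapse = ", "))
  if (anyDuplicated(crosses$cross))
    stop("integrity error: duplicated cross ids")
  bad <- setdiff(cross_ind$cross, crosses$cross)
  if (length(bad))
    stop("integrity error: offspring assigned to unknown cross: ",
         paste(unique(bad), collapse = ", "))
  par_ids <- unique(c(crosses$parent_central, crosses$parent_peripheral))
  bad <- setdiff(par_ids, rownames(parent_geno))
  if (length(bad))
    stop("integrity error: parents without genotypes: ",
         paste(bad, collapse = ", "))

  bad <- setdiff(rownames(geno), cross_ind$id)
  if (length(bad))
    stop("integrity error: offspring without cross assignment: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  cross_ind <- cross_ind[match(rownames(geno), cross_ind$id), , drop = FALSE]
  rownames(cross_ind) <- NULL

  pheno <- as.data.frame(pheno)
  if (!all(c("id", "trait", "value") %in% names(pheno)))
    stop("format error: pheno must have columns id, trait, value")
  pheno$id <- as.character(pheno$id)
  bad <- setdiff(pheno$id, cross_ind$id)
  if (length(bad))
    stop("integrity error: phenotyped individuals absent from cross table: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  pheno <- pheno[match(rownames(geno), pheno$id), , drop = FALSE]
  rownames(pheno) <- NULL

  h2 <- as.data.frame(h2)
  if (!all(c("cross", "h2") %in% names(h2)))
    stop("format error: h2 table must have columns cross, h2")
  h2$cross <- as.character(h2$cross)
  bad <- setdiff(crosses$cross, h2$cross)
  if (length(bad))
    stop("integrity error: crosses without heritability: ",
         paste(bad, collapse = ", "))
  if (any(!is.finite(h2$h2) | h2$h2 <= 0 | h2$h2 > 1))
    stop("integrity error: h2 must lie in (0, 1]")

  structure(list(map = map, parent_geno = parent_geno, geno = geno,
                 cross_ind = cross_ind, crosses = crosses,
                 pheno = pheno, h2 = h2),
            class = "mpp_dataset")
}

#' @export
print.mpp_dataset <- function(x, ...) {
  cat("MPP dataset (NAM, DH lines)\n")
  cat(sprintf("  %d offspring in %d crosses, central parent %s\n",
              nrow(x$geno), nrow(x$crosses), x$crosses$parent_central[1L]))
  cat(sprintf("  %d markers on %d chromosome(s)\n",
              nrow(x$map), length(unique(x$map$chrom))))
  invisible(x)
}

n_ind <- function(ds) nrow(ds$geno)
n_mark <- function(ds) nrow(ds$map)

#' Cross id of every offspring, in genotype row order
#' @param ds an \code{mpp_dataset}
#' @return character vector of cross ids (one per offspring)
#' @export
cross_of <- function(ds) ds$cross_ind$cross

#' Phenotype vector in genotype row order
#' @param ds an \code{mpp_dataset}
#' @return named numeric vector of adjusted means
#' @export
pheno_vector <- function(ds) {
  y <- ds$pheno$value
  names(y) <- ds$pheno$id
  y
}

# ---- I/O -------------------------------------------------------------------

.read_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("format error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "))
  d
}

#' Read an MPP dataset from CSV files
#'
#' File dialects: \code{genotype_path} holds one row per line with columns
#' \code{id}, \code{role} (\code{parent} or \code{offspring}) and one column
#' per marker (values 0/1/2/NA); \code{map_path} has columns
#' \code{marker,chrom,pos_cM}; \code{cross_path} has
#' \code{id,cross,parent_central,parent_peripheral} (offspring rows only);
#' \code{pheno_path} has \code{id,trait,value}; \code{h2_path} has
#' \code{cross,h2}.
#'
#' @param genotype_path,map_path,cross_path,pheno_path,h2_path file paths
#' @return a validated \code{\link{mpp_dataset}} with markers sorted by
#'   (chromosome, position)
#' @export
read_dataset <- function(genotype_path, map_path, cross_path, pheno_path,
                         h2_path) {
  g <- .read_csv(genotype_path, c("id", "role"))
  if (!all(g$role %in% c("parent", "offspring")))
    stop("format error: role must be parent|offspring")
  mk <- setdiff(names(g), c("id", "role"))
  gm <- as.matrix(g[, mk, drop = FALSE])
  storage.mode(gm) <- "double"
  rownames(gm) <- as.character(g$id)
  map <- .read_csv(map_path, c("marker", "chrom", "pos_cM"))
  cr <- .read_csv(cross_path,
                  c("id", "cross", "parent_central", "parent_peripheral"))
  crosses <- unique(cr[, c("cross", "parent_central", "parent_peripheral")])
  pheno <- .read_csv(pheno_path, c("id", "trait", "value"))
  h2 <- .read_csv(h2_path, c("cross", "h2"))
  mpp_dataset(map = map,
              parent_geno = gm[g$role == "parent", , drop = FALSE],
              geno = gm[g$role == "offspring", , drop = FALSE],
              cross_ind = cr[, c("id", "cross")],
              crosses = crosses, pheno = pheno, h2 = h2)
}

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1L))
  out
}

#' Write an MPP dataset to CSV files
#'
#' Inverse of \code{\link{read_dataset}}: writes \code{genotypes.csv},
#' \code{map.csv}, \code{cross.csv}, \code{pheno.csv} and \code{h2.csv}
#' into \code{dir}. Numeric values are written with full precision so that
#' the round trip reproduces the dataset exactly.
#'
#' @param ds an \code{mpp_dataset}
#' @param dir output directory (created if absent)
#' @return invisibly, the directory path
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gm <- rbind(ds$parent_geno, ds$geno)
  role <- c(rep("parent", nrow(ds$parent_geno)),
            rep("offspring", nrow(ds$geno)))
  gd <- data.frame(id = rownames(gm), role = role,
                   apply(gm, 2L, function(col) ifelse(is.na(col), "NA",
                                                      format(col))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(gd, file.path(dir, "genotypes.csv"), row.names = FALSE,
                   quote = FALSE)
  mp <- ds$map
  mp$pos_cM <- .fmt_num(mp$pos_cM)
  utils::write.csv(mp, file.path(dir, "map.csv"), row.names = FALSE,
                   quote = FALSE)
  cr <- merge(ds$cross_ind, ds$crosses, by = "cross", sort = FALSE)
  cr <- cr[match(rownames(ds$geno), cr$id),
           c("id", "cross", "parent_central", "parent_peripheral")]
  utils::write.csv(cr, file.path(dir, "cross.csv"), row.names = FALSE,
                   quote = FALSE)
  ph <- ds$pheno
  ph$value <- .fmt_num(ph$value)
  utils::write.csv(ph, file.path(dir, "pheno.csv"), row.names = FALSE,
                   quote = FALSE)
  h2 <- ds$h2
  h2$h2 <- .fmt_num(h2$h2)
  utils::write.csv(h2, file.path(dir, "h2.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

# ---- marker statistics and preprocessing -----------------------------------

# Offspring-based allele-2 frequency per marker; parents excluded because
# the offspring carry the segregation information.
.freq2 <- function(ds) {
  colMeans(ds$geno, na.rm = TRUE) / 2
}

#' Minor allele frequency per marker (offspring-based)
#' @param ds an \code{mpp_dataset}
#' @return numeric vector, one value per marker (NaN if all missing)
#' @export
marker_maf <- function(ds) {
  f <- .freq2(ds)
  pmin(f, 1 - f)
}

# TRUE if the marker shows >= 2 distinct non-missing dosages in >= 1 cross
.segregating_any_cross <- function(ds) {
  cr <- cross_of(ds)
  seg <- rep(FALSE, n_mark(ds))
  for (c in unique(cr)) {
    g <- ds$geno[cr == c, , drop = FALSE]
    mx <- suppressWarnings(apply(g, 2L, max, na.rm = TRUE))
    mn <- suppressWarnings(apply(g, 2L, min, na.rm = TRUE))
    seg <- seg | (is.finite(mx) & is.finite(mn) & mx > mn)
  }
  seg
}

#' Subset an MPP dataset to a set of markers
#' @param ds an \code{mpp_dataset}
#' @param markers character vector of marker ids to keep
#' @return an \code{mpp_dataset}
#' @export
subset_markers <- function(ds, markers) {
  keep <- ds$map$marker %in% markers
  if (!any(keep)) stop("empty dataset: no markers left")
  mpp_dataset(ds$map[keep, , drop = FALSE],
              ds$parent_geno[, ds$map$marker[keep], drop = FALSE],
              ds$geno[, ds$map$marker[keep], drop = FALSE],
              ds$cross_ind, ds$crosses, ds$pheno, ds$h2)
}

#' Subset an MPP dataset to a set of offspring
#' @param ds an \code{mpp_dataset}
#' @param ids character vector of offspring ids to keep
#' @return an \code{mpp_dataset}
#' @export
subset_individuals <- function(ds, ids) {
  keep <- rownames(ds$geno) %in% ids
  if (!any(keep)) stop("empty dataset: no individuals left")
  mpp_dataset(ds$map, ds$parent_geno, ds$geno[keep, , drop = FALSE],
              ds$cross_ind[keep, , drop = FALSE],
              ds$crosses[ds$crosses$cross %in% ds$cross_ind$cross[keep], ,
                         drop = FALSE],
              ds$pheno[keep, , drop = FALSE],
              ds$h2)
}

#' Filter markers by segregation, MAF and missingness
#'
#' Removes markers that do not segregate in any cross, markers whose
#' MPP-wide minor allele frequency (computed over all non-missing offspring
#' dosages, parents excluded) is below \code{maf_min}, and markers with a
#' missing fraction above \code{miss_max}. Among markers mapping to an
#' identical position (equal after rounding to 1e-6 cM) only the most
#' polymorphic locus is kept (ties broken by lexicographically smallest
#' marker id).
#'
#' @param ds an \code{mpp_dataset}
#' @param maf_min minimum minor allele frequency (default 0.01)
#' @param miss_max maximum missing fraction (default 0.10)
#' @return filtered \code{mpp_dataset}
#' @export
filter_markers <- function(ds, maf_min = 0.01, miss_max = 0.10) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1)
  maf <- marker_maf(ds)
  maf[is.nan(maf)] <- 0
  missfrac <- colMeans(is.na(ds$geno))
  keep <- .segregating_any_cross(ds) & maf >= maf_min & missfrac <= miss_max
  if (!any(keep)) stop("empty dataset: all markers removed by filtering")
  map <- ds$map[keep, , drop = FALSE]
  mafk <- maf[keep]
  posk <- paste(map$chrom, round(map$pos_cM, 6L))
  sel <- unlist(lapply(split(seq_len(nrow(map)), posk), function(ix) {
    ix[order(-mafk[ix], map$marker[ix])][1L]
  }), use.names = FALSE)
  subset_markers(ds, map$marker[sort(sel)])
}

#' Thin markers to a genetic-distance grid
#'
#' Per chromosome, positions are partitioned into consecutive bins of width
#' \code{bin_cm} starting at 0; within each non-empty bin the marker with
#' the highest MAF is kept (ties broken by smallest position, then marker
#' id). Used to reduce marker density before cross-validation.
#'
#' @param ds an \code{mpp_dataset}
#' @param bin_cm bin width in centi-Morgan (> 0)
#' @return thinned \code{mpp_dataset}
#' @export
thin_markers <- function(ds, bin_cm) {
  stopifnot(bin_cm > 0)
  maf <- marker_maf(ds)
  maf[is.nan(maf)] <- 0
  map <- ds$map
  bin <- paste(map$chrom, floor(map$pos_cM / bin_cm))
  sel <- unlist(lapply(split(seq_len(nrow(map)), bin), function(ix) {
    ix[order(-maf[ix], map$pos_cM[ix], map$marker[ix])][1L]
  }), use.names = FALSE)
  subset_markers(ds, map$marker[sort(sel)])
}
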