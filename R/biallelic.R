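# ---- bi-allelic (IBS) incidence --------------------------------------------

.mode_dosage <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  tab <- sort(table(v), decreasing = TRUE)
  as.numeric(names(tab)[1L])
}

#' Deterministic modal imputation of missing dosages
#'
#' Each missing offspring dosage is replaced by the modal dosage of its own
#' cross at that marker (MPP-wide mode if the whole cross is missing);
#' missing parent dosages are replaced by the MPP-wide parent mode.
#' Observed values are never changed. This deterministic rule substitutes
#' for haplotype-based imputation: after standard filtering the missing
#' fraction is small (<= 10%) and determinism keeps analyses reproducible.
#'
#' @param ds an \code{mpp_dataset}
#' @return an \code{mpp_dataset} without missing values
#' @export
impute_missing <- function(ds) {
  geno <- ds$geno
  pg <- ds$parent_geno
  cr <- cross_of(ds)
  for (j in which(colSums(is.na(geno)) > 0L)) {
    col <- geno[, j]
    mpp_mode <- .mode_dosage(col)
    if (is.na(mpp_mode))
      stop("marker ", ds$map$marker[j], " missing everywhere; ",
           "filter before imputing")
    for (c in unique(cr[is.na(col)])) {
      rows <- which(cr == c & is.na(col))
      m <- .mode_dosage(col[cr == c])
      geno[rows, j] <- if (is.na(m)) mpp_mode else m
    }
  }
  if (anyNA(pg)) {
    for (j in which(colSums(is.na(pg)) > 0L)) {
      m <- .mode_dosage(pg[, j])
      if (is.na(m)) m <- 0
      pg[is.na(pg[, j]), j] <- m
    }
  }
  mpp_dataset(ds$map, pg, geno, ds$cross_ind, ds$crosses, ds$pheno, ds$h2)
}

#' Bi-allelic (minor-allele dosage) QTL incidence at a marker
#'
#' Single-column incidence holding the number of copies of the MPP-wide
#' minor allele (0/1/2; 0/2 for DH offspring), identity-by-state
#' information only. The major allele is the reference. Minor/major status
#' is determined from the offspring allele frequency; at exactly 0.5 the
#' allele coded 2 is taken as minor.
#'
#' @param ds an imputed \code{mpp_dataset} (no missing values at the
#'   marker)
#' @param marker marker id
#' @return a \code{qtl_incidence}; a monomorphic marker yields an incidence
#'   with \code{testable = FALSE} and an empty column set
#' @export
biallelic_incidence <- function(ds, marker) {
  j <- match(marker, ds$map$marker)
  if (is.na(j)) stop("unknown marker: ", marker)
  col <- ds$geno[, j]
  if (anyNA(col)) stop("marker ", marker, " has missing values; impute first")
  f2 <- mean(col) / 2
  if (f2 <= 0 || f2 >= 1) {
    return(structure(list(X = matrix(numeric(0), nrow = length(col),
                                     ncol = 0,
                                     dimnames = list(rownames(ds$geno),
                                                     NULL)),
                          effect_type = "biallelic", labels = character(0),
                          ref = "major", marker = marker, testable = FALSE),
                     class = "qtl_incidence"))
  }
  X <- if (f2 <= 0.5) col else 2 - col
  X <- matrix(X, ncol = 1L,
              dimnames = list(rownames(ds$geno),
                              if (f2 <= 0.5) "allele2" else "allele0"))
  structure(list(X = X, effect_type = "biallelic",
                 labels = colnames(X), ref = "major", marker = marker,
                 testable = TRUE),
            class = "qtl_incidence")
}
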