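# ---- IBD: parental-origin posteriors for DH lines --------------------------

#' Haldane map function
#'
#' Converts a genetic distance in centi-Morgan into a recombination
#' fraction, r(d) = (1 - exp(-2 d / 100)) / 2, assuming no crossover
#' interference.
#'
#' @param d genetic distance(s) in cM (>= 0)
#' @return recombination fraction(s) in [0, 0.5)
#' @export
haldane_r <- function(d) {
  if (any(d < 0)) stop("distance must be non-negative")
  0.5 * (1 - exp(-2 * d / 100))
}

#' Parental-origin posteriors for DH offspring
#'
#' For every offspring and chromosome, runs a two-state hidden Markov model
#' over the markers: hidden state = parental origin (central or peripheral),
#' initial probabilities 1/2 each, transition probabilities from
#' \code{\link{haldane_r}} of the inter-marker distances, and emissions
#' 1 - error_rate when the observed offspring allele matches that parent's
#' allele and error_rate otherwise. Markers that are uninformative (the two
#' parents carry the same allele, or a parent is missing) or missing in the
#' offspring emit 1 for both states. Forward-backward smoothing yields
#' P(origin = peripheral) at every marker.
#'
#' @param ds an \code{mpp_dataset} of DH offspring (dosages 0/2/NA)
#' @param error_rate genotyping error probability (default 1e-3)
#' @return numeric matrix (offspring x markers) of P(origin = peripheral
#'   parent), an "origin posterior"
#' @export
dh_origin_posteriors <- function(ds, error_rate = 1e-3) {
  if (any(ds$geno == 1, na.rm = TRUE))
    stop("integrity error: DH offspring cannot carry dosage 1")
  post <- matrix(NA_real_, n_ind(ds), n_mark(ds),
                 dimnames = list(rownames(ds$geno), ds$map$marker))
  cr <- cross_of(ds)
  for (ci in seq_len(nrow(ds$crosses))) {
    cid <- ds$crosses$cross[ci]
    rows <- which(cr == cid)
    if (!length(rows)) next
    pc <- ds$parent_geno[ds$crosses$parent_central[ci], ]
    pp <- ds$parent_geno[ds$crosses$parent_peripheral[ci], ]
    for (ch in unique(ds$map$chrom)) {
      ix <- which(ds$map$chrom == ch)
      post[rows, ix] <- .fb_dh(ds$geno[rows, ix, drop = FALSE],
                               pc[ix], pp[ix], ds$map$pos_cM[ix],
                               error_rate)
    }
  }
  post
}

# Forward-backward over one chromosome, vectorized over the lines of one
# cross. States: 1 = central, 2 = peripheral. Returns P(state 2).
.fb_dh <- function(obs, pc, pp, pos, err) {
  n <- nrow(obs); m <- ncol(obs)
  # emission matrices, n x m, for each state
  e1 <- matrix(1, n, m); e2 <- matrix(1, n, m)
  informative <- !is.na(pc) & !is.na(pp) & pc != pp
  for (k in which(informative)) {
    o <- obs[, k]
    seen <- !is.na(o)
    e1[seen, k] <- ifelse(o[seen] == pc[k], 1 - err, err)
    e2[seen, k] <- ifelse(o[seen] == pp[k], 1 - err, err)
  }
  r <- if (m > 1L) haldane_r(diff(pos)) else numeric(0)
  # forward with per-marker scaling
  a1 <- 0.5 * e1[, 1L, drop = TRUE]; a2 <- 0.5 * e2[, 1L, drop = TRUE]
  sc <- a1 + a2; a1 <- a1 / sc; a2 <- a2 / sc
  A1 <- matrix(NA_real_, n, m); A2 <- matrix(NA_real_, n, m)
  A1[, 1L] <- a1; A2[, 1L] <- a2
  if (m > 1L) for (k in 2L:m) {
    t1 <- (a1 * (1 - r[k - 1L]) + a2 * r[k - 1L]) * e1[, k]
    t2 <- (a1 * r[k - 1L] + a2 * (1 - r[k - 1L])) * e2[, k]
    sc <- t1 + t2
    a1 <- t1 / sc; a2 <- t2 / sc
    A1[, k] <- a1; A2[, k] <- a2
  }
  # backward
  b1 <- rep(1, n); b2 <- rep(1, n)
  g <- matrix(NA_real_, n, m)
  g[, m] <- A2[, m] * b2 / (A1[, m] * b1 + A2[, m] * b2)
  if (m > 1L) for (k in (m - 1L):1L) {
    nb1 <- (1 - r[k]) * e1[, k + 1L] * b1 + r[k] * e2[, k + 1L] * b2
    nb2 <- r[k] * e1[, k + 1L] * b1 + (1 - r[k]) * e2[, k + 1L] * b2
    sc <- nb1 + nb2
    b1 <- nb1 / sc; b2 <- nb2 / sc
    g[, k] <- A2[, k] * b2 / (A1[, k] * b1 + A2[, k] * b2)
  }
  g
}

#' Parental-model QTL incidence at a marker
#'
#' Builds the parental-model incidence: one column per peripheral parent
#' holding the expected number of allele copies received from that parent
#' (2 x the origin posterior), non-zero only for individuals of the
#' corresponding cross — in a NAM design peripheral-parent effects are
#' nested within crosses. The central parent is the reference allele (its
#' column, reconstructible as 2 minus the row sum, is dropped): it is the
#' most frequent origin, shared by all crosses.
#'
#' @param post origin-posterior matrix from
#'   \code{\link{dh_origin_posteriors}}
#' @param ds the \code{mpp_dataset} the posteriors were computed on
#' @param marker marker id at which to build the incidence
#' @return an object of class \code{qtl_incidence}: list with \code{X}
#'   (N x n_peripheral matrix, entries in [0, 2]), \code{effect_type},
#'   \code{labels}, \code{ref} (dropped reference label)
#' @export
parental_incidence <- function(post, ds, marker) {
  if (!marker %in% colnames(post)) stop("unknown marker: ", marker)
  p <- post[, marker]
  per <- ds$crosses$parent_peripheral
  X <- matrix(0, n_ind(ds), length(per),
              dimnames = list(rownames(ds$geno), per))
  cr <- cross_of(ds)
  for (ci in seq_len(nrow(ds$crosses))) {
    rows <- cr == ds$crosses$cross[ci]
    X[rows, per[ci]] <- 2 * p[rows]
  }
  structure(list(X = X, effect_type = "parental", labels = per,
                 ref = ds$crosses$parent_central[1L], marker = marker),
            class = "qtl_incidence")
}

#' @export
print.qtl_incidence <- function(x, ...) {
  cat(sprintf("QTL incidence (%s) at %s: %d x %d, reference %s\n",
              x$effect_type, x$marker, nrow(x$X), ncol(x$X), x$ref))
  invisible(x)
}
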