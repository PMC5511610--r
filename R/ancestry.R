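# ---- ancestral clustering of parents ---------------------------------------

#' Simple matching coefficient between two inbred marker vectors
#'
#' Fraction of pairwise-complete loci at which the two lines carry the same
#' dosage; loci missing in either vector are excluded. For inbred lines
#' coded 0/2 this is the classic simple matching (SM) similarity.
#'
#' @param x,y numeric dosage vectors of equal length (0/2/NA)
#' @return similarity in [0, 1]
#' @export
simple_matching <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("undefined similarity: no pairwise-complete loci")
  mean(x[ok] == y[ok])
}

# Average-linkage agglomerative clustering on a similarity matrix.
# Merges the pair of clusters with the highest average similarity, ties
# broken by the lexicographically smallest member-name pair; stops when no
# pair reaches `threshold`. Returns an integer group vector.
.avg_link_cluster <- function(S, threshold) {
  n <- nrow(S)
  ids <- rownames(S)
  groups <- lapply(seq_len(n), function(i) i)
  repeat {
    if (length(groups) == 1L) break
    best <- NULL; best_sim <- -Inf; best_key <- NULL
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (a >= b) next
      sim <- mean(S[groups[[a]], groups[[b]]])
      key <- paste(min(ids[c(groups[[a]][1L], groups[[b]][1L])]),
                   max(ids[c(groups[[a]][1L], groups[[b]][1L])]))
      if (sim > best_sim + 1e-12 ||
          (abs(sim - best_sim) <= 1e-12 && !is.null(best_key) &&
           key < best_key)) {
        best_sim <- sim; best <- c(a, b); best_key <- key
      }
    }
    if (best_sim < threshold) break
    groups[[best[1L]]] <- c(groups[[best[1L]]], groups[[best[2L]]])
    groups[[best[2L]]] <- NULL
  }
  out <- integer(n)
  # group numbering by order of first (smallest-index) member
  ord <- order(vapply(groups, min, 1L))
  for (k in seq_along(ord)) out[groups[[ord[k]]]] <- k
  names(out) <- ids
  out
}

#' Cluster parents into ancestral groups at a map position
#'
#' Pairwise simple-matching similarities are computed over the markers in a
#' window around the position (inclusive bounds, default 2 cM wide), then
#' parents are grouped by average-linkage agglomerative clustering: merging
#' proceeds from the most similar pair and stops when no pair of clusters
#' has average similarity at or above \code{sim_threshold}. Parents in one
#' group are assumed to transmit the same ancestral allele at the position.
#' This windowed-SM rule is a declared, swappable stand-in for
#' kinship-blended local-similarity scoring.
#'
#' @param ds an \code{mpp_dataset}
#' @param chrom chromosome of the focal position
#' @param pos focal position in cM
#' @param window_cm window width in cM (markers within pos +/- window_cm/2)
#' @param sim_threshold similarity needed to keep merging (default 0.9)
#' @return an object of class \code{ancestral_assignment}: list with
#'   \code{groups} (named integer vector parent -> group), \code{A} (0/1
#'   matrix parents x groups), \code{ref_group} (group containing the
#'   central parent), \code{n_groups}
#' @export
cluster_parents_at <- function(ds, chrom, pos, window_cm = 2,
                               sim_threshold = 0.9) {
  stopifnot(sim_threshold > 0, sim_threshold <= 1)
  ix <- which(ds$map$chrom == chrom &
              abs(ds$map$pos_cM - pos) <= window_cm / 2)
  if (!length(ix)) {
    message("empty window at ", chrom, ":", pos,
            " cM; falling back to nearest marker")
    ixc <- which(ds$map$chrom == chrom)
    if (!length(ixc)) stop("no markers on chromosome ", chrom)
    ix <- ixc[which.min(abs(ds$map$pos_cM[ixc] - pos))]
  }
  central <- ds$crosses$parent_central[1L]
  pars <- c(central, ds$crosses$parent_peripheral)
  G <- ds$parent_geno[pars, ix, drop = FALSE]
  P <- length(pars)
  S <- diag(1, P); dimnames(S) <- list(pars, pars)
  for (a in seq_len(P - 1L)) for (b in (a + 1L):P)
    S[a, b] <- S[b, a] <- simple_matching(G[a, ], G[b, ])
  groups <- .avg_link_cluster(S, sim_threshold)
  A <- matrix(0L, P, max(groups),
              dimnames = list(pars, paste0("G", seq_len(max(groups)))))
  A[cbind(seq_len(P), groups)] <- 1L
  structure(list(groups = groups, A = A,
                 ref_group = unname(groups[central]),
                 n_groups = max(groups)),
            class = "ancestral_assignment")
}

#' Ancestral-model QTL incidence from a parental incidence
#'
#' Transforms a parental incidence into the ancestral model: the full
#' parental matrix (central-parent column reconstructed as 2 minus the row
#' sum of the peripheral columns) is post-multiplied by the 0/1 ancestral
#' matrix A, pooling the allele dosages of parents that share an ancestral
#' group. The group containing the central parent is the reference and its
#' column is dropped. A single-group assignment yields a non-segregating
#' (empty) incidence, flagged non-testable downstream.
#'
#' @param par_inc a parental \code{qtl_incidence}
#' @param asg an \code{ancestral_assignment} covering the same parents
#' @return an ancestral \code{qtl_incidence} (entries remain in [0, 2])
#' @export
ancestral_incidence <- function(par_inc, asg) {
  if (par_inc$effect_type != "parental")
    stop("ancestral transformation needs a parental incidence")
  pars <- rownames(asg$A)
  if (!all(c(par_inc$ref, par_inc$labels) %in% pars))
    stop("integrity error: assignment does not cover all parents")
  Xfull <- cbind(2 - rowSums(par_inc$X), par_inc$X)
  colnames(Xfull) <- c(par_inc$ref, par_inc$labels)
  Xanc <- Xfull[, pars, drop = FALSE] %*% asg$A
  keep <- setdiff(seq_len(ncol(Xanc)), asg$ref_group)
  structure(list(X = Xanc[, keep, drop = FALSE], effect_type = "ancestral",
                 labels = colnames(asg$A)[keep],
                 ref = colnames(asg$A)[asg$ref_group],
                 marker = par_inc$marker),
            class = "qtl_incidence")
}
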