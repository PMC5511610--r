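# ---- analysis context: cached incidence builders ---------------------------

#' Precompute the incidence machinery for an MPP dataset
#'
#' Genome scans evaluate QTL incidences at every marker, repeatedly.
#' \code{mpp_context} computes the expensive, phenotype-independent parts
#' once: parental-origin posteriors (\code{\link{dh_origin_posteriors}}),
#' per-marker ancestral assignments (\code{\link{cluster_parents_at}}) and
#' the imputed minor-allele dosage matrix
#' (\code{\link{biallelic_incidence}}). All scan and detection functions
#' accept either an \code{mpp_dataset} (the context is built on the fly) or
#' an \code{mpp_context}.
#'
#' @param ds an \code{mpp_dataset}
#' @param error_rate genotyping error rate for the origin HMM
#' @param window_cm window width for ancestral clustering (cM)
#' @param sim_threshold similarity threshold for ancestral clustering
#' @return an object of class \code{mpp_context}
#' @export
mpp_context <- function(ds, error_rate = 1e-3, window_cm = 2,
                        sim_threshold = 0.9) {
  post <- dh_origin_posteriors(ds, error_rate)
  asg <- lapply(seq_len(n_mark(ds)), function(j)
    cluster_parents_at(ds, ds$map$chrom[j], ds$map$pos_cM[j],
                       window_cm = window_cm,
                       sim_threshold = sim_threshold))
  names(asg) <- ds$map$marker
  imp <- impute_missing(ds)
  structure(list(ds = ds, post = post, asg = asg, imputed = imp,
                 error_rate = error_rate, window_cm = window_cm,
                 sim_threshold = sim_threshold),
            class = "mpp_context")
}

#' @export
print.mpp_context <- function(x, ...) {
  cat("MPP analysis context\n")
  print(x$ds)
  invisible(x)
}

#' Coerce to an analysis context
#' @param x an \code{mpp_dataset} or \code{mpp_context}
#' @param ... passed to \code{\link{mpp_context}} when building
#' @return an \code{mpp_context}
#' @export
as_mpp_context <- function(x, ...) {
  if (inherits(x, "mpp_context")) return(x)
  if (inherits(x, "mpp_dataset")) return(mpp_context(x, ...))
  stop("need an mpp_dataset or mpp_context")
}

#' Restrict a context to a subset of offspring
#'
#' Origin posteriors and dosages are per-individual, and ancestral
#' assignments depend only on the parents, so a context can be subset by
#' rows without recomputation — used heavily by cross-validation.
#'
#' @param ctx an \code{mpp_context}
#' @param ids offspring ids to keep
#' @return an \code{mpp_context}
#' @export
subset_context <- function(ctx, ids) {
  ds <- subset_individuals(ctx$ds, ids)
  ord <- rownames(ds$geno)
  imp <- ctx$imputed
  imp <- mpp_dataset(imp$map, imp$parent_geno,
                     imp$geno[ord, , drop = FALSE],
                     ds$cross_ind, ds$crosses, ds$pheno, ds$h2)
  structure(list(ds = ds, post = ctx$post[ord, , drop = FALSE],
                 asg = ctx$asg, imputed = imp,
                 error_rate = ctx$error_rate, window_cm = ctx$window_cm,
                 sim_threshold = ctx$sim_threshold),
            class = "mpp_context")
}

#' QTL incidence at a marker under a chosen effect type
#'
#' Dispatch point used by every scan: builds the parental, ancestral or
#' bi-allelic incidence at \code{marker} from the cached context.
#'
#' @param ctx an \code{mpp_context}
#' @param marker marker id
#' @param effect_type one of \code{"parental"}, \code{"ancestral"},
#'   \code{"biallelic"}
#' @return a \code{qtl_incidence}
#' @export
incidence_at <- function(ctx, marker,
                         effect_type = c("parental", "ancestral",
                                         "biallelic")) {
  effect_type <- match.arg(effect_type)
  switch(effect_type,
         parental = parental_incidence(ctx$post, ctx$ds, marker),
         ancestral = ancestral_incidence(
           parental_incidence(ctx$post, ctx$ds, marker),
           ctx$asg[[marker]]),
         biallelic = biallelic_incidence(ctx$imputed, marker))
}
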