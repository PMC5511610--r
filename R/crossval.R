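# ---- cross-validation: explained vs predicted genetic variance -------------

#' Within-cross fold assignments for replicated k-fold CV
#'
#' Per replication, each cross is randomly partitioned into \code{n_fold}
#' near-equal folds; run (r, f) uses fold f of every cross as the
#' validation set, so each individual appears in the validation set
#' exactly once per replication. 20 replications of a fivefold scheme give
#' the standard 100 CV runs.
#'
#' @param ds an \code{mpp_dataset}
#' @param n_fold folds per replication (default 5)
#' @param n_rep replications (default 20)
#' @param seed optional integer seed
#' @return integer matrix (individuals x replications) of fold indices,
#'   rownames = individual ids; class \code{cv_folds}
#' @export
make_folds <- function(ds, n_fold = 5L, n_rep = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cross <- cross_of(ds)
  sizes <- table(cross)
  if (any(sizes < n_fold))
    stop("cross smaller than n_fold: ",
         paste(names(sizes)[sizes < n_fold], collapse = ", "))
  out <- matrix(NA_integer_, n_ind(ds), n_rep,
                dimnames = list(rownames(ds$geno), NULL))
  for (r in seq_len(n_rep)) {
    for (c in unique(cross)) {
      ix <- which(cross == c)
      f <- rep_len(seq_len(n_fold), length(ix))
      out[ix, r] <- f[sample.int(length(ix))]
    }
  }
  class(out) <- c("cv_folds", class(out))
  out
}

#' Proportion of genetic variance explained in the training set
#'
#' pTS = R2_adj / mean h2, where the heritability denominator is the
#' cross-size-weighted mean of the per-cross heritabilities (consistent
#' with the weighting used for the predicted counterpart).
#'
#' @param r2_adj adjusted R-squared of the detected-QTL model on the
#'   training set
#' @param h2_by_cross named numeric vector of per-cross heritabilities
#' @param cross_sizes named numeric vector of (training-set) cross sizes
#' @return pTS
#' @export
compute_pts <- function(r2_adj, h2_by_cross, cross_sizes) {
  cs <- cross_sizes[names(h2_by_cross)]
  h2bar <- sum(h2_by_cross * cs) / sum(cs)
  if (!is.finite(h2bar) || h2bar <= 0) stop("non-positive heritability")
  r2_adj / h2bar
}

#' Proportion of genetic variance predicted in the validation set
#'
#' Within every cross, pVS_c = cor(y_VS, y-hat_VS) / h2_c (Pearson); the
#' MPP-level estimate is the cross-size-weighted average of the
#' within-cross values. Crosses with fewer than 3 validation individuals
#' are skipped (weights renormalized); a cross with zero variance in
#' either vector contributes 0 with a notice. Note the printed convention
#' divides the correlation itself (not its square) by h2, so values can
#' exceed 1; set \code{squared = TRUE} for the squared-correlation
#' variant.
#'
#' @param y_vs observed validation phenotypes
#' @param yhat_vs predicted values
#' @param cross_ids cross id per validation individual
#' @param h2_by_cross named per-cross heritabilities
#' @param squared use cor^2 / h2 instead of cor / h2 (default FALSE)
#' @return list with \code{per_cross} (named pVS_c) and \code{weighted}
#'   (the cross-size-weighted average)
#' @export
compute_pvs <- function(y_vs, yhat_vs, cross_ids, h2_by_cross,
                        squared = FALSE) {
  crosses <- unique(cross_ids)
  pvs <- numeric(0); wts <- numeric(0)
  for (c in crosses) {
    ix <- which(cross_ids == c)
    if (length(ix) < 3L) {
      message("cross ", c, " has < 3 validation individuals; skipped")
      next
    }
    yv <- y_vs[ix]; yh <- yhat_vs[ix]
    if (stats::sd(yv) == 0 || stats::sd(yh) == 0) {
      message("zero variance in cross ", c, "; pVS set to 0")
      r <- 0
    } else {
      r <- stats::cor(yv, yh)
      if (squared) r <- r^2
    }
    pvs <- c(pvs, r / h2_by_cross[[c]])
    names(pvs)[length(pvs)] <- c
    wts <- c(wts, length(ix))
  }
  if (!length(pvs)) return(list(per_cross = pvs, weighted = 0))
  list(per_cross = pvs, weighted = sum(pvs * wts) / sum(wts))
}

#' Cross-validated explained and predicted genetic variance
#'
#' For each of the \code{n_rep} x \code{n_fold} runs: QTL detection on the
#' training set (single effect type via \code{\link{detect_qtls}}, or the
#' MQE forward selection), pTS from the training-set adjusted R2, then
#' prediction of the validation set from the training-set coefficients and
#' pVS within crosses. Zero-QTL runs contribute pTS = pVS = 0 (a model
#' with only cross means carries no within-cross signal). Significance
#' thresholds are computed once on the full dataset and reused across
#' runs; scans under cross-specific residuals use the f-CSRT
#' approximation.
#'
#' @param x an \code{mpp_dataset} or \code{mpp_context}
#' @param effect_type \code{"parental"}, \code{"ancestral"},
#'   \code{"biallelic"} or \code{"mqe"}
#' @param residual \code{"hrt"} or \code{"fcsrt"}
#' @param threshold an \code{mpp_threshold} or number; for
#'   \code{effect_type = "mqe"} a list of the three component thresholds
#'   (see \code{\link{mqe_forward}})
#' @param n_fold,n_rep folds and replications (defaults 5 and 20)
#' @param seed optional integer seed for the fold draws
#' @param window_cm,alpha passed to the detection pipeline
#' @param squared squared-correlation pVS variant (default FALSE)
#' @return an object of class \code{cv_summary}: per-run data.frame
#'   (\code{rep}, \code{fold}, \code{n_qtl}, \code{pts}, \code{pvs_bar})
#'   plus means, SDs and \code{bias} = mean pTS - mean pVS-bar
#' @export
run_cv <- function(x, effect_type, residual = "hrt", threshold,
                   n_fold = 5L, n_rep = 20L, seed = NULL, window_cm = 20,
                   alpha = 0.01, squared = FALSE) {
  ctx <- as_mpp_context(x)
  ds <- ctx$ds
  folds <- make_folds(ds, n_fold, n_rep, seed = seed)
  y <- pheno_vector(ds)
  h2 <- stats::setNames(ds$h2$h2, ds$h2$cross)
  runs <- NULL
  for (r in seq_len(n_rep)) {
    for (f in seq_len(n_fold)) {
      vs <- rownames(folds)[folds[, r] == f]
      ts <- setdiff(rownames(folds), vs)
      ctx_ts <- subset_context(ctx, ts)
      det <- if (effect_type == "mqe") {
        mqe_forward(ctx_ts, residual = residual, thresholds = threshold,
                    window_cm = window_cm, alpha = alpha)
      } else {
        detect_qtls(ctx_ts, effect_type, residual = residual,
                    threshold = threshold, window_cm = window_cm,
                    alpha = alpha)
      }
      if (det$n_qtl == 0L) {
        runs <- rbind(runs, data.frame(rep = r, fold = f, n_qtl = 0L,
                                       pts = 0, pvs_bar = 0))
        next
      }
      cs_ts <- table(cross_of(ctx_ts$ds))
      pts <- compute_pts(det$r2_adj, h2, cs_ts[names(h2)])
      ctx_vs <- subset_context(ctx, vs)
      yhat <- predict(det, ctx_vs)
      pv <- compute_pvs(y[vs], yhat[vs], cross_of(ctx_vs$ds), h2,
                        squared = squared)
      runs <- rbind(runs, data.frame(rep = r, fold = f, n_qtl = det$n_qtl,
                                     pts = pts, pvs_bar = pv$weighted))
    }
  }
  structure(list(runs = runs,
                 pts_mean = mean(runs$pts), pts_sd = stats::sd(runs$pts),
                 pvs_mean = mean(runs$pvs_bar),
                 pvs_sd = stats::sd(runs$pvs_bar),
                 bias = mean(runs$pts) - mean(runs$pvs_bar),
                 effect_type = effect_type, residual = residual,
                 n_fold = n_fold, n_rep = n_rep),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("CV (%s, %s): %d runs\n", x$effect_type, x$residual,
              nrow(x$runs)))
  cat(sprintf("  pTS  = %.3f (sd %.3f)\n", x$pts_mean, x$pts_sd))
  cat(sprintf("  pVS  = %.3f (sd %.3f)\n", x$pvs_mean, x$pvs_sd))
  cat(sprintf("  bias = %.3f\n", x$bias))
  invisible(x)
}
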