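# ---- multi-QTL-effect (MQE) forward selection ------------------------------

#' Forward selection of a multi-QTL-effect model
#'
#' Builds a multi-locus model in which every QTL carries its own effect
#' type. At each step three genome-wide profiles are computed (parental,
#' ancestral, bi-allelic), each conditioning on all already-selected QTLs
#' (with their own effect types, 20 cM exclusion window). From each profile
#' the top-scoring position above the MQE threshold and at least
#' \code{min_space_cm} from every selected QTL is taken; among these (at
#' most three) candidates the one whose addition increases the model
#' adjusted R2 the most enters the model (ties: higher score, then lower
#' chromosome/position). Selection stops when no profile offers a
#' significant position. An optional backward-elimination pass (default
#' on) at \code{alpha} prunes the final model.
#'
#' @inheritParams detect_qtls
#' @param thresholds list with components \code{parental},
#'   \code{ancestral}, \code{biallelic} (numbers or \code{mpp_threshold}s)
#'   from which the MQE bar is built, or a single pre-averaged
#'   \code{mpp_threshold}/number
#' @param threshold_rule \code{"mean"} (default) or \code{"max"} of the
#'   three component thresholds
#' @param min_space_cm minimum spacing between selected QTLs (default 20)
#' @param max_steps cap on forward steps (safety, default 20)
#' @param backward run backward elimination after forward selection
#'   (default TRUE)
#' @return a \code{qtl_detection} whose \code{qtl} table carries a per-QTL
#'   \code{effect_type}
#' @export
mqe_forward <- function(x, residual = "hrt", thresholds,
                        threshold_rule = c("mean", "max"),
                        window_cm = 20, min_space_cm = 20, alpha = 0.01,
                        max_steps = 20L, backward = TRUE, y = NULL,
                        sigma2_cross = NULL) {
  residual <- match.arg(residual, .residual_kinds)
  threshold_rule <- match.arg(threshold_rule)
  ctx <- as_mpp_context(x)
  if (is.null(y)) y <- pheno_vector(ctx$ds)
  cross <- cross_of(ctx$ds)
  if (residual == "fcsrt" && is.null(sigma2_cross))
    sigma2_cross <- null_cross_variances(y, cross)$sigma2_cross
  thr <- if (is.list(thresholds) && !inherits(thresholds, "mpp_threshold"))
    mqe_threshold(thresholds$parental, thresholds$ancestral,
                  thresholds$biallelic, rule = threshold_rule)$value
  else if (inherits(thresholds, "mpp_threshold")) thresholds$value
  else as.numeric(thresholds)

  types <- c("parental", "ancestral", "biallelic")
  selected <- data.frame(marker = character(0), chrom = integer(0),
                         pos = numeric(0), score = numeric(0),
                         effect_type = character(0),
                         stringsAsFactors = FALSE)
  n <- length(y)
  r2_of <- function(entries) {
    if (!nrow(entries)) return(0)
    incs <- .cof_incidences(ctx, entries)
    if (residual == "hrt") {
      fm <- .fit_multi(y, cross, incs, "hrt")
      r2_adj_hrt(fm$fit, fit_hrt(y, cross))
    } else {
      full <- fit_csrt_reml(y, cross, qtl_inc = NULL, cofactors = incs,
                            method = "ml")
      red <- fit_csrt_reml(y, cross, method = "ml")
      df_qtl <- length(grep("^cof", names(full$beta)))
      utz_adjust(r2_lr_csrt(full$loglik_ml, red$loglik_ml, n),
                 df_qtl, full$df_resid)
    }
  }
  for (step in seq_len(max_steps)) {
    cands <- NULL
    for (tp in types) {
      prof <- scan_genome(ctx, tp, residual, cofactors = selected,
                          window_cm = window_cm, y = y,
                          sigma2_cross = sigma2_cross)
      ok <- prof$testable & prof$score > thr
      if (nrow(selected))
        for (k in seq_len(nrow(selected)))
          ok <- ok & (prof$chrom != selected$chrom[k] |
                      abs(prof$pos - selected$pos[k]) >= min_space_cm)
      if (!any(ok)) next
      top <- prof[ok, , drop = FALSE]
      top <- top[order(-top$score, top$chrom, top$pos), , drop = FALSE][1L, ]
      cands <- rbind(cands,
                     data.frame(marker = top$marker, chrom = top$chrom,
                                pos = top$pos, score = top$score,
                                effect_type = tp,
                                stringsAsFactors = FALSE))
    }
    if (is.null(cands)) break
    r2 <- vapply(seq_len(nrow(cands)), function(i)
      r2_of(rbind(selected, cands[i, , drop = FALSE])), numeric(1))
    ord <- order(-r2, -cands$score, cands$chrom, cands$pos)
    selected <- rbind(selected, cands[ord[1L], , drop = FALSE])
  }
  if (backward && nrow(selected))
    selected <- backward_eliminate(ctx, selected, residual, alpha, y,
                                   sigma2_cross)
  selected <- selected[order(selected$chrom, selected$pos), , drop = FALSE]
  rownames(selected) <- NULL
  .report_detection(ctx, selected, residual, y, sigma2_cross, thr, "mqe")
}
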