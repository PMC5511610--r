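# ---- genome scans, thresholds, detection pipeline --------------------------

.residual_kinds <- c("hrt", "fcsrt", "csrt")

# Cofactor entries -> incidence objects (one per entry, own effect type).
.cof_incidences <- function(ctx, entries) {
  if (is.null(entries) || !nrow(entries)) return(list())
  lapply(seq_len(nrow(entries)), function(k)
    incidence_at(ctx, entries$marker[k], entries$effect_type[k]))
}

# Cofactors to keep at a tested position: different chromosome, or at
# least window_cm away (and never the tested marker itself).
.cof_keep <- function(entries, chrom, pos, marker, window_cm) {
  if (is.null(entries) || !nrow(entries)) return(integer(0))
  which(entries$marker != marker &
        (entries$chrom != chrom | abs(entries$pos - pos) >= window_cm))
}

# Prepared per-marker designs for repeated scoring (thresholds permute the
# phenotype thousands of times; everything phenotype-independent is built
# once). For residual "csrt" no useful precomputation exists (a REML fit
# per position); prep then stores the incidences themselves.
.scan_engine <- function(ctx, effect_type, residual, cofactors = NULL,
                         window_cm = 20, sigma2_cross = NULL, y = NULL) {
  ds <- ctx$ds
  cross <- cross_of(ds)
  cof_inc <- .cof_incidences(ctx, cofactors)
  w <- NULL
  if (residual == "fcsrt") {
    if (is.null(sigma2_cross)) {
      if (is.null(y)) y <- pheno_vector(ds)
      sigma2_cross <- null_cross_variances(y, cross,
                                           cofactors = cof_inc)$sigma2_cross
    }
    w <- unname(1 / sigma2_cross[cross])
  }
  n <- n_ind(ds)
  prep <- vector("list", n_mark(ds))
  for (j in seq_len(n_mark(ds))) {
    mk <- ds$map$marker[j]
    inc <- incidence_at(ctx, mk, effect_type)
    if (!is.null(inc$testable) && !inc$testable) next
    keep <- .cof_keep(cofactors, ds$map$chrom[j], ds$map$pos_cM[j], mk,
                      window_cm)
    d <- .assemble_design(cross, inc, cof_inc[keep])
    if (!length(d$idxQ)) next
    if (residual == "csrt") {
      prep[[j]] <- list(inc = inc, cof = cof_inc[keep])
      next
    }
    X <- d$X
    Xw <- if (is.null(w)) X else X * sqrt(w)
    qd <- qr(Xw)
    if (qd$rank < ncol(X)) {            # drop aliased columns, QTL last
      aliased <- qd$pivot[-seq_len(qd$rank)]
      if (all(d$idxQ %in% aliased)) next
      X <- X[, -aliased, drop = FALSE]
      d$idxQ <- grep("^Q:", colnames(X))
      Xw <- if (is.null(w)) X else X * sqrt(w)
      qd <- qr(Xw)
      if (!length(d$idxQ)) next
    }
    r <- qd$rank
    XtXinv <- chol2inv(qr.R(qd)[seq_len(r), seq_len(r), drop = FALSE])
    posQ <- match(d$idxQ, qd$pivot[seq_len(r)])
    B <- XtXinv[posQ, posQ, drop = FALSE]
    Binv <- tryCatch(solve(B), error = function(e) MASS::ginv(B))
    prep[[j]] <- list(qd = qd, idxQ = d$idxQ, Binv = Binv,
                      df = length(posQ), r = r)
  }
  list(prep = prep, w = w, n = n, residual = residual, cross = cross,
       sigma2_cross = sigma2_cross)
}

# Score one phenotype vector against a prepared engine.
.engine_score <- function(eng, ctx, y) {
  ds <- ctx$ds
  m <- n_mark(ds)
  score <- numeric(m)
  testable <- !vapply(eng$prep, is.null, logical(1))
  yw <- if (is.null(eng$w)) y else y * sqrt(eng$w)
  for (j in which(testable)) {
    pj <- eng$prep[[j]]
    if (eng$residual == "csrt") {
      fit <- fit_csrt_reml(y, eng$cross, qtl_inc = pj$inc,
                           cofactors = pj$cof)
      if (fit$df_Q < 1L) { testable[j] <- FALSE; next }
      score[j] <- wald_test(fit)$score
      next
    }
    cf <- qr.coef(pj$qd, yw)
    bQ <- cf[pj$idxQ]
    res <- qr.resid(pj$qd, yw)
    rss <- sum(res^2)
    quad <- drop(t(bQ) %*% pj$Binv %*% bQ)
    W <- if (eng$residual == "hrt") {
      s2 <- rss / (eng$n - pj$r)
      quad / s2
    } else quad
    W <- max(0, W)
    logp <- stats::pchisq(W, pj$df, lower.tail = FALSE, log.p = TRUE)
    score[j] <- -logp / log(10)
  }
  list(score = score, testable = testable)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wald-test genome scan (SIM / CIM)
#'
#' At every testable marker, builds the QTL incidence for the requested
#' effect type, adds cofactor incidences (excluding cofactors within
#' \code{window_cm} of the tested position, so a position is never
#' conditioned on itself), fits the model under the requested residual
#' structure and records the -log10 p of the Wald test of the QTL block.
#' An empty cofactor list gives simple interval mapping; scan positions
#' are the marker positions.
#'
#' @param x an \code{mpp_dataset} or \code{mpp_context}
#' @param effect_type \code{"parental"}, \code{"ancestral"} or
#'   \code{"biallelic"}
#' @param residual \code{"hrt"} (homogeneous residual, least squares),
#'   \code{"fcsrt"} (cross-specific variances estimated once in the
#'   no-QTL model and held fixed) or \code{"csrt"} (exact REML refit at
#'   every position; slow)
#' @param cofactors data.frame of cofactor entries (columns
#'   \code{marker}, \code{chrom}, \code{pos}, \code{effect_type}), e.g.
#'   from \code{\link{select_cofactors}}, or NULL for SIM
#' @param window_cm cofactor exclusion window around the tested position
#'   (default 20 cM, the same constant as the QTL spacing rule)
#' @param y phenotype vector (defaults to the dataset's)
#' @param sigma2_cross optional fixed per-cross variances for
#'   \code{"fcsrt"}
#' @return a \code{scan_profile} data.frame: \code{marker}, \code{chrom},
#'   \code{pos}, \code{score} (-log10 p; 0 at non-testable positions) and
#'   \code{testable}
#' @export
scan_genome <- function(x, effect_type, residual = "hrt", cofactors = NULL,
                        window_cm = 20, y = NULL, sigma2_cross = NULL) {
  residual <- match.arg(residual, .residual_kinds)
  ctx <- as_mpp_context(x)
  if (is.null(y)) y <- pheno_vector(ctx$ds)
  eng <- .scan_engine(ctx, effect_type, residual, cofactors, window_cm,
                      sigma2_cross, y)
  sc <- .engine_score(eng, ctx, y)
  out <- data.frame(marker = ctx$ds$map$marker, chrom = ctx$ds$map$chrom,
                    pos = ctx$ds$map$pos_cM, score = sc$score,
                    testable = sc$testable, stringsAsFactors = FALSE)
  attr(out, "effect_type") <- effect_type
  attr(out, "residual") <- residual
  class(out) <- c("scan_profile", "data.frame")
  out
}

#' Greedy peak selection with a minimum spacing rule
#'
#' Repeatedly selects the highest-scoring testable position above the
#' threshold that is at least \code{min_space_cm} away (on the same
#' chromosome) from every already-selected position. Ties are broken by
#' lower chromosome, then lower position. Used both for cofactor selection
#' and for the candidate-QTL list after CIM.
#'
#' @param profile a \code{scan_profile}
#' @param threshold numeric threshold on the -log10 p scale, or an
#'   \code{mpp_threshold}
#' @param min_space_cm minimum spacing (default 20 cM)
#' @return data.frame of selected entries (\code{marker}, \code{chrom},
#'   \code{pos}, \code{score}, \code{effect_type}); zero rows if nothing
#'   exceeds the threshold
#' @export
select_cofactors <- function(profile, threshold, min_space_cm = 20) {
  thr <- if (inherits(threshold, "mpp_threshold")) threshold$value
         else threshold
  cand <- profile[profile$testable & profile$score > thr, , drop = FALSE]
  cand <- cand[order(-cand$score, cand$chrom, cand$pos), , drop = FALSE]
  sel <- cand[0, , drop = FALSE]
  while (nrow(cand)) {
    top <- cand[1L, , drop = FALSE]
    sel <- rbind(sel, top)
    keep <- cand$chrom != top$chrom |
            abs(cand$pos - top$pos) >= min_space_cm
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(sel)) {
    sel$effect_type <- attr(profile, "effect_type")
    sel <- sel[order(sel$chrom, sel$pos), , drop = FALSE]
    rownames(sel) <- NULL
  } else {
    sel$effect_type <- character(0)
  }
  sel[, c("marker", "chrom", "pos", "score", "effect_type")]
}

#' Genome-wide permutation significance threshold
#'
#' Empirical genome-wide null distribution of the maximum Wald score:
#' phenotypes are permuted (within cross by default, preserving the cross
#' means that the intercepts absorb), a SIM scan is run per permutation,
#' and the threshold is the \code{quantile} (default upper 95%) of the
#' per-permutation maxima. Thresholds are always computed with the HRT
#' scan mechanics: for cross-specific residual models the same threshold
#' as the corresponding HRT model is used, since permuting and rescanning
#' under exact CSRT is computationally prohibitive.
#'
#' @inheritParams scan_genome
#' @param n_perm number of permutations (>= 20; 1000 for production use)
#' @param quantile quantile of the maxima (default 0.95)
#' @param within_cross permute within cross (default TRUE) or globally
#' @param seed optional integer seed for the permutations
#' @return an object of class \code{mpp_threshold}: list with
#'   \code{value}, \code{n_perm}, \code{quantile}, \code{maxima}
#' @export
permutation_threshold <- function(x, effect_type, residual = "hrt",
                                  n_perm = 1000L, quantile = 0.95,
                                  within_cross = TRUE, seed = NULL,
                                  window_cm = 20) {
  if (n_perm < 20L) stop("n_perm < 20: quantile estimate unstable")
  ctx <- as_mpp_context(x)
  if (!is.null(seed)) set.seed(seed)
  y <- pheno_vector(ctx$ds)
  cross <- cross_of(ctx$ds)
  eng <- .scan_engine(ctx, effect_type, "hrt", NULL, window_cm)
  maxima <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- if (within_cross) {
      out <- y
      for (c in unique(cross)) {
        ix <- which(cross == c)
        out[ix] <- y[ix][sample.int(length(ix))]
      }
      out
    } else y[sample.int(length(y))]
    sc <- .engine_score(eng, ctx, yp)
    maxima[b] <- if (any(sc$testable)) max(sc$score[sc$testable]) else 0
  }
  structure(list(value = unname(stats::quantile(maxima, quantile)),
                 n_perm = n_perm, quantile = quantile,
                 effect_type = effect_type, residual = residual,
                 maxima = maxima),
            class = "mpp_threshold")
}

#' @export
print.mpp_threshold <- function(x, ...) {
  cat(sprintf("Permutation threshold: %.3f (-log10 p, %d permutations, ",
              x$value, x$n_perm), sprintf("quantile %.2f)\n", x$quantile))
  invisible(x)
}

#' Threshold for the multi-QTL-effect model
#'
#' The MQE significance bar is the arithmetic mean of the parental,
#' ancestral and bi-allelic thresholds (optionally their maximum, a
#' stricter variant).
#'
#' @param t_par,t_anc,t_bi thresholds (numbers or \code{mpp_threshold}s)
#' @param rule \code{"mean"} (default) or \code{"max"}
#' @return an \code{mpp_threshold}
#' @export
mqe_threshold <- function(t_par, t_anc, t_bi, rule = c("mean", "max")) {
  rule <- match.arg(rule)
  v <- vapply(list(t_par, t_anc, t_bi), function(t)
    if (inherits(t, "mpp_threshold")) t$value else as.numeric(t),
    numeric(1))
  structure(list(value = if (rule == "mean") mean(v) else max(v),
                 n_perm = NA_integer_, quantile = NA_real_,
                 effect_type = "mqe", rule = rule, components = v),
            class = "mpp_threshold")
}

# ---- multi-QTL fits and backward elimination -------------------------------

# Joint fit of several QTL incidences (each kept as its own block).
# Returns the fit plus, per block, the column names in the design.
.fit_multi <- function(y, cross, incs, residual, sigma2_cross = NULL) {
  if (residual == "fcsrt" && is.null(sigma2_cross))
    sigma2_cross <- null_cross_variances(y, cross)$sigma2_cross
  fit <- switch(residual,
    hrt = fit_hrt(y, cross, qtl_inc = NULL, cofactors = incs),
    fcsrt = fit_fcsrt(y, cross, sigma2_cross, qtl_inc = NULL,
                      cofactors = incs),
    csrt = fit_csrt_reml(y, cross, qtl_inc = NULL, cofactors = incs))
  blocks <- lapply(seq_along(incs), function(k)
    grep(sprintf("^cof%d:", k), names(fit$beta), value = TRUE))
  list(fit = fit, blocks = blocks, sigma2_cross = sigma2_cross)
}

# Wald test of one named column block of a joint fit.
.block_wald <- function(fit, cols) {
  cols <- intersect(cols, colnames(fit$XtXinv))
  if (!length(cols)) return(list(W = 0, df = 0L, p = 1, score = 0))
  b <- fit$beta[cols]
  V <- fit$XtXinv[cols, cols, drop = FALSE]
  if (fit$kind == "HRT") V <- fit$sigma2 * V
  Vi <- tryCatch(solve(V), error = function(e) MASS::ginv(V))
  W <- max(0, drop(t(b) %*% Vi %*% b))
  df <- length(b)
  logp <- stats::pchisq(W, df, lower.tail = FALSE, log.p = TRUE)
  list(W = W, df = df, p = exp(logp), score = -logp / log(10))
}

#' Backward elimination of candidate QTLs
#'
#' Fits the joint multi-QTL model with all candidates (each with its own
#' effect type) and repeatedly removes the QTL whose block-Wald p value is
#' largest and above \code{alpha}, refitting after each removal, until
#' every remaining QTL is significant at \code{alpha}. Candidates whose
#' whole block is pruned from the joint model (confounded or aliased) are
#' removed first.
#'
#' @param x an \code{mpp_dataset} or \code{mpp_context}
#' @param candidates data.frame of candidate entries (\code{marker},
#'   \code{chrom}, \code{pos}, \code{effect_type})
#' @param residual residual kind (\code{"hrt"}, \code{"fcsrt"},
#'   \code{"csrt"})
#' @param alpha significance level (default 0.01)
#' @param y phenotype vector (defaults to the dataset's)
#' @param sigma2_cross fixed per-cross variances for \code{"fcsrt"}
#' @return the retained subset of \code{candidates} (possibly empty), with
#'   the final block scores in column \code{score}
#' @export
backward_eliminate <- function(x, candidates, residual = "hrt",
                               alpha = 0.01, y = NULL,
                               sigma2_cross = NULL) {
  ctx <- as_mpp_context(x)
  if (is.null(y)) y <- pheno_vector(ctx$ds)
  cross <- cross_of(ctx$ds)
  cur <- candidates
  repeat {
    if (!nrow(cur)) return(cur)
    incs <- .cof_incidences(ctx, cur)
    fm <- .fit_multi(y, cross, incs, residual, sigma2_cross)
    wt <- lapply(fm$blocks, function(cols) .block_wald(fm$fit, cols))
    p <- vapply(wt, `[[`, numeric(1), "p")
    empty <- vapply(fm$blocks, function(cols)
      !length(intersect(cols, names(fm$fit$beta))), logical(1))
    p[empty] <- 1
    if (max(p) > alpha) {
      cur <- cur[-which.max(p), , drop = FALSE]
      next
    }
    cur$score <- vapply(wt, `[[`, numeric(1), "score")
    rownames(cur) <- NULL
    return(cur)
  }
}

# Final report shared by detect_qtls() and mqe_forward(): joint fit of the
# retained QTLs, per-QTL effects, and the variance-explained measure
# appropriate to the residual kind (adjusted R2 for HRT; ML likelihood R2
# with the df adjustment for CSRT-family models).
.report_detection <- function(ctx, entries, residual, y, sigma2_cross,
                              threshold, label) {
  cross <- cross_of(ctx$ds)
  n <- length(y)
  if (!nrow(entries)) {
    red <- fit_hrt(y, cross)
    return(structure(list(qtl = entries, effects = list(), r2_adj = 0,
                          n_qtl = 0L, fit = NULL, fit_red = red,
                          effect_type = label, residual = residual,
                          threshold = threshold,
                          cross_levels = unique(cross)),
                     class = "qtl_detection"))
  }
  incs <- .cof_incidences(ctx, entries)
  fm <- .fit_multi(y, cross, incs, residual, sigma2_cross)
  fit <- fm$fit
  effects <- lapply(seq_along(incs), function(k) {
    cols <- intersect(fm$blocks[[k]], names(fit$beta))
    b <- fit$beta[cols]
    names(b) <- sub(sprintf("^cof%d:[^:]+:", k), "", cols)
    b
  })
  names(effects) <- entries$marker
  df_qtl <- sum(lengths(effects))
  if (residual == "hrt") {
    red <- fit_hrt(y, cross)
    r2 <- r2_adj_hrt(fit, red)
  } else {
    full_ml <- fit_csrt_reml(y, cross, qtl_inc = NULL, cofactors = incs,
                             method = "ml")
    red_ml <- fit_csrt_reml(y, cross, method = "ml")
    r2 <- utz_adjust(r2_lr_csrt(full_ml$loglik_ml, red_ml$loglik_ml, n),
                     df_qtl, full_ml$df_resid)
    red <- red_ml
  }
  structure(list(qtl = entries, effects = effects, r2_adj = r2,
                 n_qtl = nrow(entries), fit = fit, fit_red = red,
                 effect_type = label, residual = residual,
                 threshold = threshold, cross_levels = unique(cross)),
            class = "qtl_detection")
}

#' @export
print.qtl_detection <- function(x, ...) {
  cat(sprintf("QTL detection (%s, %s): %d QTL(s), R2_adj = %.3f\n",
              x$effect_type, x$residual, x$n_qtl, x$r2_adj))
  if (x$n_qtl) print(x$qtl)
  invisible(x)
}

#' Full single-effect-type QTL detection pipeline
#'
#' Orchestrates the detection procedure for one effect type: a SIM scan,
#' cofactor selection, two CIM rounds (cofactors re-selected between
#' rounds), candidate selection with the 20 cM spacing rule, and backward
#' elimination at \code{alpha}. Returns the retained QTLs together with
#' the joint-model fit and the explained-variance measure used by pTS
#' (adjusted R2 for HRT, df-adjusted likelihood R2 for CSRT models).
#'
#' @inheritParams scan_genome
#' @param threshold an \code{mpp_threshold} (from
#'   \code{\link{permutation_threshold}}) or a number on the -log10 p
#'   scale
#' @param alpha backward-elimination level (default 0.01)
#' @return an object of class \code{qtl_detection}: \code{qtl}
#'   (data.frame), \code{effects} (per-QTL named coefficient vectors on
#'   the 0..2 allele-dosage scale), \code{r2_adj}, the joint \code{fit}
#'   and the reduced fit
#' @export
detect_qtls <- function(x, effect_type, residual = "hrt", threshold,
                        window_cm = 20, alpha = 0.01, y = NULL,
                        sigma2_cross = NULL) {
  residual <- match.arg(residual, .residual_kinds)
  ctx <- as_mpp_context(x)
  if (is.null(y)) y <- pheno_vector(ctx$ds)
  if (residual == "fcsrt" && is.null(sigma2_cross))
    sigma2_cross <- null_cross_variances(y, cross_of(ctx$ds))$sigma2_cross
  prof <- scan_genome(ctx, effect_type, residual, NULL, window_cm, y,
                      sigma2_cross)
  cof <- select_cofactors(prof, threshold, window_cm)
  if (nrow(cof)) {
    for (round in 1:2) {
      prof <- scan_genome(ctx, effect_type, residual, cof, window_cm, y,
                          sigma2_cross)
      cof <- select_cofactors(prof, threshold, window_cm)
      if (!nrow(cof)) break
    }
  }
  candidates <- select_cofactors(prof, threshold, window_cm)
  final <- backward_eliminate(ctx, candidates, residual, alpha, y,
                              sigma2_cross)
  .report_detection(ctx, final, residual, y, sigma2_cross, threshold,
                    effect_type)
}

#' Predict phenotypes for new individuals from detected QTLs
#'
#' Builds the detected QTLs' incidence matrices for the individuals in
#' \code{x} and applies the training-set coefficients:
#' y-hat = Xc bc + sum_k XQk bQk. Incidence columns are matched to the
#' retained training-set coefficients by allele label; a bi-allelic column
#' whose minor-allele orientation flipped in the new set is recoded
#' (2 - dosage) before applying the coefficient.
#'
#' @param object a \code{qtl_detection} with at least the reduced fit
#' @param x an \code{mpp_dataset} or \code{mpp_context} holding the
#'   individuals to predict (e.g. a validation fold)
#' @param ... unused
#' @return named numeric vector of predicted values
#' @export
predict.qtl_detection <- function(object, x, ...) {
  ctx <- as_mpp_context(x)
  cross <- cross_of(ctx$ds)
  fit <- object$fit %||% object$fit_red
  bc <- fit$beta[paste0("cross:", cross)]
  yhat <- unname(bc)
  if (object$n_qtl) {
    for (k in seq_len(object$n_qtl)) {
      b <- object$effects[[k]]
      if (!length(b)) next
      inc <- incidence_at(ctx, object$qtl$marker[k],
                          object$qtl$effect_type[k])
      X <- inc$X
      if (object$qtl$effect_type[k] == "biallelic") {
        have <- colnames(X)
        want <- names(b)
        if (length(have) && length(want) && !identical(have, want)) {
          X <- 2 - X            # minor allele flipped in the new subset
          colnames(X) <- want
        } else if (!length(have)) {
          # monomorphic in the new set: reconstruct the dosage directly
          j <- match(object$qtl$marker[k], ctx$imputed$map$marker)
          d <- ctx$imputed$geno[, j]
          X <- matrix(if (want == "allele2") d else 2 - d, ncol = 1L,
                      dimnames = list(rownames(ctx$ds$geno), want))
        }
      }
      use <- intersect(names(b), colnames(X))
      if (length(use))
        yhat <- yhat + drop(X[, use, drop = FALSE] %*% b[use])
    }
  }
  names(yhat) <- rownames(ctx$ds$geno)
  yhat
}
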