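# ---- single-locus MPP model fitting ----------------------------------------
#
# The fitted model is y = Xc bc + Xq bq + XQ bQ + r with Xc the cross
# intercepts, Xq optional cofactor incidences, XQ the QTL incidence, and r
# either homogeneous (HRT, R = I sigma_r^2) or cross-specific (CSRT,
# R = direct sum of sigma_rc^2).

# Cross-intercept block: one indicator column per cross (no global
# intercept).
.cross_design <- function(cross) {
  lev <- unique(cross)
  Xc <- matrix(0, length(cross), length(lev),
               dimnames = list(NULL, paste0("cross:", lev)))
  Xc[cbind(seq_along(cross), match(cross, lev))] <- 1
  Xc
}

# Drop incidence columns with (numerically) no within-cross variation:
# such columns are confounded with the cross intercepts and make the QTL
# block untestable. Returns column indices kept.
.seg_columns <- function(X, cross) {
  if (!ncol(X)) return(integer(0))
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ssw <- sum((x - stats::ave(x, cross))^2)
    keep[j] <- ssw > 1e-8
  }
  which(keep)
}

# Assemble [Xc | Xq | XQ] with segregation pruning of the Xq and XQ blocks.
# `cofactors` is a list of qtl_incidence objects.
.assemble_design <- function(cross, qtl_inc = NULL, cofactors = NULL) {
  Xc <- .cross_design(cross)
  Xq <- NULL; q_labels <- character(0)
  if (length(cofactors)) {
    parts <- lapply(seq_along(cofactors), function(k) {
      ci <- cofactors[[k]]
      keep <- .seg_columns(ci$X, cross)
      X <- ci$X[, keep, drop = FALSE]
      if (ncol(X))
        colnames(X) <- paste0("cof", k, ":", ci$marker, ":",
                              ci$labels[keep])
      X
    })
    Xq <- do.call(cbind, parts)
    if (!is.null(Xq) && !ncol(Xq)) Xq <- NULL
  }
  XQ <- NULL; Q_labels <- character(0)
  if (!is.null(qtl_inc)) {
    keep <- .seg_columns(qtl_inc$X, cross)
    XQ <- qtl_inc$X[, keep, drop = FALSE]
    Q_labels <- qtl_inc$labels[keep]
    if (ncol(XQ)) colnames(XQ) <- paste0("Q:", Q_labels)
  }
  X <- cbind(Xc, Xq, XQ)
  idxQ <- if (!is.null(XQ) && ncol(XQ))
    (ncol(X) - ncol(XQ) + 1L):ncol(X) else integer(0)
  list(X = X, idxQ = idxQ, Q_labels = Q_labels)
}

# Core (weighted) least-squares fit with rank handling.
# w = NULL: ordinary LS, vcov of beta_Q scaled by sigma2_hat (HRT).
# w given and scale_vcov = FALSE: generalized LS with known weights, vcov
# = (X'WX)^{-1} (f-CSRT Wald).
.ls_fit <- function(y, X, idxQ, Q_labels, w = NULL, scale_vcov = TRUE,
                    cross = NULL) {
  n <- length(y)
  if (is.null(w)) { Xw <- X; yw <- y } else {
    sw <- sqrt(w); Xw <- X * sw; yw <- y * sw
  }
  qd <- qr(Xw)
  r <- qd$rank
  if (n <= r) stop("not enough observations for the design (n <= p)")
  piv <- qd$pivot[seq_len(r)]
  beta_all <- qr.coef(qd, yw)          # NA for aliased columns
  aliased <- which(is.na(beta_all))
  fitted <- drop(X[, piv, drop = FALSE] %*% beta_all[piv])
  res <- y - fitted
  rss_w <- if (is.null(w)) sum(res^2) else sum(w * res^2)
  XtXinv_piv <- chol2inv(qr.R(qd)[seq_len(r), seq_len(r), drop = FALSE])
  dimnames(XtXinv_piv) <- list(colnames(X)[piv], colnames(X)[piv])
  keptQ <- setdiff(idxQ, aliased)
  posQ <- match(keptQ, piv)
  # floored so an exact fit (RSS = 0) keeps the Wald test defined
  sigma2 <- max(rss_w / (n - r), 1e-12 * max(mean(yw^2), .Machine$double.eps))
  VQ <- XtXinv_piv[posQ, posQ, drop = FALSE]
  if (scale_vcov) VQ <- sigma2 * VQ
  logdet <- 2 * sum(log(abs(diag(qr.R(qd))[seq_len(r)])))
  if (is.null(w)) {
    s2_ml <- rss_w / n
    ll_ml <- -0.5 * n * (log(2 * pi) + log(s2_ml) + 1)
    # REML: -1/2 [ (n-p)(log 2pi + 1) + (n-p) log s2 + log|X'X| ]
    ll_reml <- -0.5 * ((n - r) * (log(2 * pi) + 1) +
                       (n - r) * log(sigma2) + logdet)
  } else {
    ll_ml <- -0.5 * (n * log(2 * pi) - sum(log(w)) + rss_w)
    ll_reml <- -0.5 * ((n - r) * log(2 * pi) - sum(log(w)) + rss_w + logdet)
  }
  structure(list(beta = beta_all[piv], XtXinv = XtXinv_piv,
                 beta_Q = beta_all[keptQ],
                 labels_Q = Q_labels[match(keptQ, idxQ)],
                 vcov_Q = VQ, df_Q = length(keptQ),
                 rss = sum(res^2), rss_w = rss_w,
                 sigma2 = sigma2, n = n, p = r,
                 df_resid = n - r, fitted = fitted, residuals = res,
                 loglik_ml = ll_ml, loglik_reml = ll_reml,
                 kind = if (is.null(w)) "HRT" else "f-CSRT",
                 weights = w, cross = cross),
            class = "mpp_fit")
}

#' @export
print.mpp_fit <- function(x, ...) {
  cat(sprintf("MPP model fit (%s): n = %d, p = %d, %d QTL column(s)\n",
              x$kind, x$n, x$p, x$df_Q))
  invisible(x)
}

#' Fit the single-locus MPP model with a homogeneous residual (HRT)
#'
#' Least-squares fit of y = Xc bc + Xq bq + XQ bQ + r with R = I sigma_r^2.
#' QTL columns without within-cross variation (confounded with the cross
#' intercepts) are pruned, as are rank-deficient columns; the covariance of
#' the QTL block is sigma_r^2-hat times the corresponding block of
#' (X'X)^{-1} with sigma_r^2-hat = RSS / (n - p).
#'
#' @param y phenotype vector
#' @param cross cross id per observation
#' @param qtl_inc a \code{qtl_incidence} (or NULL for the reduced,
#'   cross-intercepts-only model)
#' @param cofactors optional list of \code{qtl_incidence} cofactor blocks
#' @return an object of class \code{mpp_fit}
#' @export
fit_hrt <- function(y, cross, qtl_inc = NULL, cofactors = NULL) {
  d <- .assemble_design(cross, qtl_inc, cofactors)
  .ls_fit(y, d$X, d$idxQ, d$Q_labels, cross = cross)
}

#' Fit with fixed cross-specific residual variances (f-CSRT)
#'
#' Generalized least squares with known per-cross residual variances (from
#' \code{\link{null_cross_variances}}), the fast CSRT approximation: the
#' covariance of the QTL block is the exact (X' R^{-1} X)^{-1} block, not
#' rescaled, so the Wald test treats the variances as known.
#'
#' @inheritParams fit_hrt
#' @param sigma2_cross named numeric vector of per-cross residual variances
#' @return an \code{mpp_fit}
#' @export
fit_fcsrt <- function(y, cross, sigma2_cross, qtl_inc = NULL,
                      cofactors = NULL) {
  d <- .assemble_design(cross, qtl_inc, cofactors)
  w <- 1 / sigma2_cross[cross]
  .ls_fit(y, d$X, d$idxQ, d$Q_labels, w = unname(w), scale_vcov = FALSE,
          cross = cross)
}

#' Fit the CSRT model by REML (or ML)
#'
#' Iterative fit of the cross-specific residual model R = direct sum of
#' sigma_rc^2. Alternates generalized least squares for the fixed effects
#' with closed-form per-cross variance updates: an EM-type update for REML
#' (monotone in the REML log-likelihood) or the per-cross mean squared
#' residual for ML (coordinate ascent). Variances are floored at
#' 1e-8 var(y). Convergence: relative log-likelihood change below
#' \code{tol}.
#'
#' @inheritParams fit_hrt
#' @param method \code{"reml"} (default) or \code{"ml"}
#' @param tol convergence tolerance (default 1e-8)
#' @param max_iter iteration cap (default 200); non-convergence raises a
#'   warning and returns the best iterate with \code{converged = FALSE}
#' @return an \code{mpp_fit} with per-cross variances
#'   (\code{sigma2_cross}), the requested log-likelihood trace
#'   (\code{loglik_trace}) and both ML and REML log-likelihood values at
#'   the final estimates
#' @export
fit_csrt_reml <- function(y, cross, qtl_inc = NULL, cofactors = NULL,
                          method = c("reml", "ml"), tol = 1e-8,
                          max_iter = 200L) {
  method <- match.arg(method)
  d <- .assemble_design(cross, qtl_inc, cofactors)
  X <- d$X
  lev <- unique(cross)
  ci <- match(cross, lev)
  nc <- tabulate(ci, length(lev))
  if (any(nc < 3L)) stop("every cross needs >= 3 observations for CSRT")
  n <- length(y)
  floor_v <- 1e-8 * stats::var(y)
  s2 <- vapply(seq_along(lev), function(k) stats::var(y[ci == k]),
               numeric(1))
  s2 <- pmax(s2, floor_v)
  trace <- numeric(0)
  fit <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- 1 / s2[ci]
    fit <- .ls_fit(y, X, d$idxQ, d$Q_labels, w = w, scale_vcov = FALSE,
                   cross = cross)
    ll <- if (method == "reml") fit$loglik_reml else fit$loglik_ml
    trace <- c(trace, ll)
    if (it > 1L &&
        abs(ll - trace[it - 1L]) <=
          tol * (abs(trace[it - 1L]) + tol)) {
      converged <- TRUE
      break
    }
    res <- fit$residuals
    if (method == "reml") {
      # EM update: E[(y - X b)'(y - X b)] per cross given b | y
      sw <- sqrt(w)
      qd <- qr(X * sw)
      r <- qd$rank
      piv <- qd$pivot[seq_len(r)]
      A <- chol2inv(qr.R(qd)[seq_len(r), seq_len(r), drop = FALSE])
      Xp <- X[, piv, drop = FALSE]
      h <- rowSums((Xp %*% A) * Xp)   # x_i' (X'WX)^{-1} x_i
      for (k in seq_along(lev)) {
        rows <- ci == k
        s2[k] <- (sum(res[rows]^2) + sum(h[rows])) / nc[k]
      }
    } else {
      for (k in seq_along(lev)) s2[k] <- mean(res[ci == k]^2)
    }
    s2 <- pmax(s2, floor_v)
  }
  if (!converged)
    warning("CSRT ", method, " did not converge in ", max_iter,
            " iterations")
  fit$kind <- "CSRT"
  fit$method <- method
  fit$sigma2_cross <- stats::setNames(s2, lev)
  fit$loglik_trace <- trace
  fit$converged <- converged
  fit
}

#' Null-model cross-specific residual variances (f-CSRT weights)
#'
#' Estimates the per-cross residual variances by REML in a model without
#' any QTL term (cross intercepts plus cofactors only). During a fast-CSRT
#' scan these variances are held fixed in the Wald test at every position,
#' avoiding a REML fit per marker.
#'
#' @inheritParams fit_hrt
#' @return a residual model: list with \code{kind = "CSRT"} and
#'   \code{sigma2_cross} (named per-cross variances)
#' @export
null_cross_variances <- function(y, cross, cofactors = NULL) {
  fit <- fit_csrt_reml(y, cross, qtl_inc = NULL, cofactors = cofactors,
                       method = "reml")
  structure(list(kind = "CSRT", sigma2_cross = fit$sigma2_cross,
                 fit = fit),
            class = "residual_model")
}

#' Wald test of the QTL block
#'
#' Tests the global null hypothesis that all QTL allele effects are zero:
#' W = bQ' V(bQ)^{-1} bQ referred to a chi-square with df = rank of the
#' tested block. A singular covariance falls back to a generalized inverse
#' with df equal to the rank.
#'
#' @param fit an \code{mpp_fit} with at least one retained QTL column
#' @return list with \code{W}, \code{df}, \code{p} and \code{score}
#'   (-log10 p)
#' @export
wald_test <- function(fit) {
  if (fit$df_Q < 1L) stop("no retained QTL columns to test")
  b <- fit$beta_Q
  V <- fit$vcov_Q
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  df <- length(b)
  if (is.null(Vi)) {
    Vi <- MASS::ginv(V)
    df <- qr(V)$rank
    message("singular QTL covariance; generalized inverse, df = ", df)
  }
  W <- max(0, drop(t(b) %*% Vi %*% b))
  logp <- stats::pchisq(W, df, lower.tail = FALSE, log.p = TRUE)
  list(W = W, df = df, p = exp(logp), score = -logp / log(10))
}

# ---- variance-explained measures -------------------------------------------

#' Adjusted R-squared for HRT models
#'
#' R2_adj = 1 - (RSS_full / df_full) / (RSS_red / df_red), where the full
#' model contains the QTLs and the reduced model only the cross-specific
#' intercepts (both always include the cross intercepts, which remove the
#' between-cross variation). May be negative.
#'
#' @param fit_full,fit_red \code{mpp_fit}s on the same phenotype vector
#' @return adjusted R-squared
#' @export
r2_adj_hrt <- function(fit_full, fit_red) {
  if (fit_full$df_resid <= 0 || fit_red$df_resid <= 0)
    stop("non-positive residual degrees of freedom")
  1 - (fit_full$rss / fit_full$df_resid) /
      (fit_red$rss / fit_red$df_resid)
}

#' Cox-Snell likelihood R-squared (CSRT models)
#'
#' R2_LR = 1 - exp(-(2/n) (logL_full - logL_red)) with both likelihoods
#' from maximum likelihood (not REML) fits of the same phenotype vector.
#' A full likelihood below the reduced one (numerical violation of
#' nesting) is clamped to 0 with a warning.
#'
#' @param loglik_full,loglik_red ML log-likelihoods
#' @param n number of observations
#' @return likelihood R-squared in [0, 1)
#' @export
r2_lr_csrt <- function(loglik_full, loglik_red, n) {
  if (loglik_full < loglik_red) {
    warning("full-model likelihood below reduced model; R2 clamped to 0")
    return(0)
  }
  1 - exp(-(2 / n) * (loglik_full - loglik_red))
}

#' Degrees-of-freedom adjustment of a likelihood R-squared
#'
#' R2_adj = R2 - (df_QTL / df_full) (1 - R2): penalizes the likelihood
#' R-squared for the number of QTL parameters relative to the residual
#' degrees of freedom of the full model.
#'
#' @param r2 unadjusted R-squared in [0, 1]
#' @param df_qtl number of QTL parameters
#' @param df_full residual degrees of freedom of the full model
#' @return adjusted R-squared (may be negative)
#' @export
utz_adjust <- function(r2, df_qtl, df_full) {
  stopifnot(r2 >= 0, r2 <= 1, df_qtl >= 0, df_full > 0)
  r2 - (df_qtl / df_full) * (1 - r2)
}
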