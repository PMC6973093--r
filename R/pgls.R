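#' Brownian-motion covariance matrix of a phylogeny
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths. This is the residual covariance (up to
#' the rate sigma^2) of a trait evolving by Brownian motion on the tree.
#'
#' @param tree A `phylo` object.
#' @param tips Ordered tip labels selecting and ordering rows/columns
#'   (default: all tips in `tree$tip.label` order).
#' @return An n x n symmetric positive semi-definite matrix (time units).
#' @export
phylo_covariance <- function(tree, tips = tree$tip.label) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  V <- ape::vcv.phylo(tree)
  # a root edge (left by pruning) is ancestry shared by every tip
  V <- V + (tree$root.edge %||% 0)
  V[tips, tips, drop = FALSE]
}

#' Maximum-likelihood phylogenetic GLS regression
#'
#' Fits `formula` by generalized least squares with residual covariance
#' `sigma^2 * V` where `V` is the Brownian-motion covariance of `tree`
#' ([phylo_covariance()]). The variance is estimated by maximum likelihood
#' (`sigma2 = RSS_V / n`), as required for likelihood-ratio and
#' marginal-likelihood model comparison; standard errors use the unbiased
#' `RSS_V / (n - p)` with t-tests on `n - p` degrees of freedom. Categorical
#' predictors use treatment (reference-level) coding via their factor levels.
#'
#' No additional covariance transform (e.g. Pagel's lambda) is applied: rate
#' heterogeneity is handled upstream by fitting on a rate-scaled tree.
#'
#' @param formula Model formula over columns of `data`.
#' @param data Data frame with a `species` column matching tree tip labels.
#' @param tree A `phylo` object covering every species in `data`.
#' @return An object of class `pgls_fit` with coefficients, standard errors,
#'   t/p values, `sigma2` (ML), `logLik`, `r2` (1 - RSS/TSS in the whitened
#'   space), and bookkeeping needed by [likelihood_ratio_test()] and
#'   [predict()].
#' @export
gls_fit <- function(formula, data, tree) {
  stopifnot(is.data.frame(data), "species" %in% names(data))
  data <- droplevels(data)  # unused factor levels would give all-zero columns
  rownames(data) <- NULL    # model.frame row names index into data below
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  trms <- attr(mf, "terms")
  X <- stats::model.matrix(trms, mf)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1)
    stop("too few observations (n = ", n, ") for ", p, " coefficients")

  species <- data$species[as.integer(rownames(mf))]
  V <- phylo_covariance(tree, species)
  L <- tryCatch(chol(V), error = function(e)
    stop("singular phylogenetic covariance: ", conditionMessage(e), call. = FALSE))
  # whiten: solve L' z = x  (V = L'L with chol() returning upper triangular)
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)

  qrx <- qr(Xw)
  if (qrx$rank < p) {
    drop_cols <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("rank-deficient design matrix; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  beta <- qr.coef(qrx, yw)
  resid_w <- yw - Xw %*% beta
  rss <- sum(resid_w^2)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetV + n)

  XtX_inv <- chol2inv(qr.R(qrx))[order(qrx$pivot), order(qrx$pivot), drop = FALSE]
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  sigma2_unb <- rss / (n - p)
  se <- sqrt(sigma2_unb * diag(XtX_inv))
  tval <- as.vector(beta) / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)

  # whitened TSS: RSS of the intercept-only GLS fit on the same V
  ones_w <- backsolve(L, rep(1, n), transpose = TRUE)
  mu_gls <- sum(ones_w * yw) / sum(ones_w^2)
  tss <- sum((yw - ones_w * mu_gls)^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_

  structure(list(
    coefficients = stats::setNames(as.vector(beta), colnames(X)),
    se = stats::setNames(se, colnames(X)),
    t = stats::setNames(tval, colnames(X)),
    p = stats::setNames(pval, colnames(X)),
    vcov = sigma2_unb * XtX_inv,
    sigma2 = sigma2, sigma2_unbiased = sigma2_unb,
    logLik = ll, n = n, p_cols = p, r2 = r2, rss = rss,
    formula = formula, terms = trms,
    xlevels = stats::.getXlevels(trms, mf),
    species = species,
    fitted = as.vector(X %*% beta),
    residuals = y - as.vector(X %*% beta),
    v_fingerprint = c(n, sum(V), sum(V^2))
  ), class = "pgls_fit")
}

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$logLik, df = object$p_cols + 1, class = "logLik")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS (ML), n =", x$n, "\n")
  cat(deparse(x$formula), "\n\n")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
               t = x$t, `p` = x$p)
  print(round(tab, 4))
  cat("\nsigma^2 (ML) =", signif(x$sigma2, 4),
      " logLik =", round(x$logLik, 3),
      " r^2 =", round(x$r2, 3), "\n")
  invisible(x)
}

#' Predict from a phylogenetic GLS fit
#'
#' Evaluates the linear predictor at new covariate values (population-level
#' prediction; no phylogenetic BLUP correction).
#'
#' @param object A `pgls_fit`.
#' @param newdata Data frame with the model's predictor columns.
#' @param grams If `TRUE`, also return the back-transformed value `10^pred`
#'   (the response is modelled on the log10 scale).
#' @param ... Unused.
#' @return Numeric vector of predictions (or a data frame when `grams`).
#' @export
predict.pgls_fit <- function(object, newdata, grams = FALSE, ...) {
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  miss <- setdiff(colnames(X), names(object$coefficients))
  if (length(miss)) stop("coefficients missing for: ", paste(miss, collapse = ", "))
  pred <- as.vector(X %*% object$coefficients[colnames(X)])
  if (grams) data.frame(log10 = pred, grams = 10^pred) else pred
}

#' Likelihood-ratio (D) test between nested phylogenetic GLS fits
#'
#' `D = 2 (logLik_full - logLik_nested)`, compared to a chi-squared
#' distribution with degrees of freedom equal to the difference in the number
#' of estimated regression coefficients. Both fits must be on the same data
#' and the same tree.
#'
#' @param fit_full,fit_nested `pgls_fit` objects; the nested model's columns
#'   must be a subset of the full model's.
#' @return A list with `D`, `df` and `p`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_nested) {
  stopifnot(inherits(fit_full, "pgls_fit"), inherits(fit_nested, "pgls_fit"))
  if (fit_full$n != fit_nested$n)
    stop("models fitted to different data (n = ", fit_full$n, " vs ",
         fit_nested$n, ")")
  if (!isTRUE(all.equal(fit_full$v_fingerprint, fit_nested$v_fingerprint)))
    stop("models fitted on different trees/covariances; not comparable")
  if (!all(names(fit_nested$coefficients) %in% names(fit_full$coefficients)))
    stop("models are not nested (nested model has terms absent from the full model)")
  df <- fit_full$p_cols - fit_nested$p_cols
  if (df < 0) stop("full model has fewer coefficients than the nested model")
  D <- 2 * (fit_full$logLik - fit_nested$logLik)
  if (D < -1e-6)
    stop("log-likelihood of the full model is below the nested model's; ",
         "models are not nested or a fit failed")
  D <- max(D, 0)
  p <- if (df == 0) 1 else stats::pchisq(D, df = df, lower.tail = FALSE)
  list(D = D, df = df, p = p)
}
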