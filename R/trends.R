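# Directionality analyses: does accumulated adaptive change (path-wise rate)
# predict relative trait mass, and does the effect differ among social mating
# systems? Fitted by ML phylogenetic GLS on the median rate-scaled tree.

# attach the median path-wise rate, drop rows without mating data, apply the
# merge map, and enforce the 10-points-per-parameter (n >= min_n) rule
.trends_prep <- function(table, pathrates, min_n = 20, merge = NULL,
                         ref = "M") {
  stopifnot(is.data.frame(table), "mating" %in% names(table))
  pr <- if (inherits(pathrates, "pathwise_rates")) {
    stats::setNames(pathrates$summary$median, pathrates$summary$species)
  } else pathrates
  tab <- table[!is.na(table$mating), , drop = FALSE]
  if (!nrow(tab)) stop("group not analysable: no mating-system data")
  tab$pathrate <- unname(pr[tab$species])
  if (anyNA(tab$pathrate)) stop("path-wise rates missing for some species")
  if (stats::var(tab$pathrate) < 1e-12)
    stop("path-wise rates are constant across species (no rate ",
         "heterogeneity): the trend slope is not estimable")
  ms <- as.character(tab$mating)
  for (new in names(merge)) ms[ms %in% merge[[new]]] <- new
  counts <- table(ms)
  excluded <- names(counts)[counts < min_n]
  tab <- tab[!(ms %in% excluded), , drop = FALSE]
  ms <- ms[!(ms %in% excluded)]
  counts <- table(ms)
  if (length(counts) < 2)
    stop("group not analysable: fewer than two mating-system categories ",
         "with n >= ", min_n)
  lev <- names(counts)
  if (ref %in% lev) lev <- c(ref, setdiff(lev, ref))
  tab$mating <- factor(ms, levels = lev)
  list(table = tab, counts = counts, excluded = excluded, ref = lev[1])
}

#' Trends model: trait on body mass, mating system and path-wise rate
#'
#' Fits `trait ~ body + mating + pathrate + mating:pathrate` by ML
#' phylogenetic GLS on the median rate-scaled tree, then derives the
#' per-mating-system slope of the trait on path-wise rate (with standard
#' error and two-sided p-value) from the interaction coefficients. Following
#' the 10-data-points-per-parameter rule, categories with fewer than `min_n`
#' species are merged per `merge` or excluded (recorded, never silent). The
#' interaction is tested against the no-interaction model by a
#' likelihood-ratio (D) test, and per-category slope p-values are
#' Bonferroni-adjusted over the number of categories fitted.
#'
#' @param table Trait table for one group (class), with `mating`; rows with
#'   missing mating system are dropped.
#' @param scaled_tree The median rate-scaled tree from [median_scaled_tree()].
#' @param pathrates A [pathwise_rates()] object (its median summary is used)
#'   or a named vector of per-species path-wise rates.
#' @param group Label for reporting.
#' @param min_n Minimum species per category (default 20: 10 per estimated
#'   parameter for a slope and an intercept).
#' @param merge Named list merging categories, e.g.
#'   `list("M+PG" = c("M", "PG"))` where monogamous and polygynous species
#'   are too few to separate.
#' @param ref Reference category (default monogamy).
#' @return A `trends_result`: `slopes` (per-category estimate, se, p, p_adj),
#'   `interaction` (D, df, p), the underlying `fit`, `counts`, `excluded`,
#'   and `model_branch = "slope"`.
#' @export
fit_trends_model <- function(table, scaled_tree, pathrates, group = "group",
                             min_n = 20, merge = NULL, ref = "M") {
  prep <- .trends_prep(table, pathrates, min_n, merge, ref)
  tab <- prep$table
  fit_full <- gls_fit(testes ~ body + mating + pathrate + mating:pathrate,
                      tab, scaled_tree)
  fit_main <- gls_fit(testes ~ body + mating + pathrate, tab, scaled_tree)
  lrt <- likelihood_ratio_test(fit_full, fit_main)

  lev <- levels(tab$mating)
  V <- fit_full$vcov
  cf <- fit_full$coefficients
  df <- fit_full$n - fit_full$p_cols
  slope_tab <- do.call(rbind, lapply(lev, function(cat) {
    if (cat == lev[1]) {
      est <- cf[["pathrate"]]
      se <- sqrt(V["pathrate", "pathrate"])
    } else {
      ia <- paste0("mating", cat, ":pathrate")
      est <- cf[["pathrate"]] + cf[[ia]]
      se <- sqrt(V["pathrate", "pathrate"] + V[ia, ia] +
                 2 * V["pathrate", ia])
    }
    p <- 2 * stats::pt(-abs(est / se), df = df)
    data.frame(category = cat, n = as.integer(prep$counts[[cat]]),
               slope = est, se = se, p = p, stringsAsFactors = FALSE)
  }))
  slope_tab$p_adj <- bonferroni_adjust(slope_tab$p, m = length(lev))
  rownames(slope_tab) <- NULL

  structure(list(group = group, model_branch = "slope",
                 slopes = slope_tab,
                 interaction = lrt, fit = fit_full, fit_no_interaction = fit_main,
                 counts = prep$counts, excluded = prep$excluded,
                 merge = merge, ref = prep$ref),
            class = "trends_result")
}

#' Intercept-difference model among mating systems
#'
#' Fallback when the path-wise-rate slope is non-significant: fits
#' `trait ~ body + mating` on the median rate-scaled tree and tests it
#' against `trait ~ body` by a likelihood-ratio (D) test with
#' `df = levels - 1` — are average relative trait masses different among
#' mating systems after accounting for ancestry and rate heterogeneity?
#' Pairwise intercept contrasts are reported with the convention that a
#' positive estimate means the second (column) system has the larger
#' intercept.
#'
#' @inheritParams fit_trends_model
#' @return A `trends_result` with `model_branch = "intercept"`, the overall
#'   `lrt` (D, df, p) and `contrasts` (a, b, estimate of b - a, se, p, p_adj).
#' @export
fit_intercept_model <- function(table, scaled_tree, pathrates = NULL,
                                group = "group", min_n = 20, merge = NULL,
                                ref = "M") {
  if (is.null(pathrates)) {
    # path-wise rates only matter for category filtering alignment; allow a
    # pure intercept analysis without them
    table$pathrate <- 0
    prep <- .trends_prep(table, stats::setNames(rep(0, nrow(table)),
                                                table$species),
                         min_n, merge, ref)
  } else {
    prep <- .trends_prep(table, pathrates, min_n, merge, ref)
  }
  tab <- prep$table
  lev <- levels(tab$mating)
  if (length(lev) < 2) stop("a single mating-system level is present")
  fit_ms <- gls_fit(testes ~ body + mating, tab, scaled_tree)
  fit_base <- gls_fit(testes ~ body, tab, scaled_tree)
  lrt <- likelihood_ratio_test(fit_ms, fit_base)

  cf <- fit_ms$coefficients
  V <- fit_ms$vcov
  df <- fit_ms$n - fit_ms$p_cols
  coef_of <- function(cat) if (cat == lev[1]) 0 else cf[[paste0("mating", cat)]]
  var_of <- function(a, b) {
    na <- if (a == lev[1]) NULL else paste0("mating", a)
    nb <- if (b == lev[1]) NULL else paste0("mating", b)
    va <- if (is.null(na)) 0 else V[na, na]
    vb <- if (is.null(nb)) 0 else V[nb, nb]
    cab <- if (is.null(na) || is.null(nb)) 0 else V[na, nb]
    va + vb - 2 * cab
  }
  pairs <- utils::combn(lev, 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    est <- coef_of(b) - coef_of(a)   # positive: system b larger
    se <- sqrt(var_of(a, b))
    data.frame(a = a, b = b, estimate = est, se = se,
               p = 2 * stats::pt(-abs(est / se), df = df),
               stringsAsFactors = FALSE)
  }))
  contrasts$p_adj <- bonferroni_adjust(contrasts$p, m = nrow(contrasts))
  rownames(contrasts) <- NULL

  structure(list(group = group, model_branch = "intercept",
                 lrt = lrt, contrasts = contrasts, fit = fit_ms,
                 fit_base = fit_base, counts = prep$counts,
                 excluded = prep$excluded, merge = merge, ref = prep$ref),
            class = "trends_result")
}

#' Full trends analysis with the documented fallback
#'
#' Fits the slope (trends) model first; if no category's Bonferroni-adjusted
#' path-wise-rate slope is significant at `alpha` (or `force_intercept`),
#' additionally fits the intercept-difference model. The decision and both
#' results are recorded.
#'
#' @inheritParams fit_trends_model
#' @param alpha Significance threshold on the adjusted slope p-values.
#' @param force_intercept Fit the intercept model regardless.
#' @return List with `slope_model`, `intercept_model` (or `NULL`),
#'   `slope_significant`, and `model_branch`.
#' @export
run_trends <- function(table, scaled_tree, pathrates, group = "group",
                       min_n = 20, merge = NULL, ref = "M", alpha = 0.05,
                       force_intercept = FALSE) {
  slope_model <- fit_trends_model(table, scaled_tree, pathrates, group,
                                  min_n, merge, ref)
  sig <- any(slope_model$slopes$p_adj < alpha)
  intercept_model <- NULL
  if (!sig || force_intercept) {
    intercept_model <- fit_intercept_model(table, scaled_tree, pathrates,
                                           group, min_n, merge, ref)
  }
  list(group = group, slope_model = slope_model,
       intercept_model = intercept_model, slope_significant = sig,
       model_branch = if (sig) "slope" else "intercept")
}

#' @export
print.trends_result <- function(x, ...) {
  cat("Trends analysis (", x$group, "), ", x$model_branch, " model\n", sep = "")
  if (x$model_branch == "slope") {
    print(transform(x$slopes, slope = signif(slope, 4), se = signif(se, 3),
                    p = signif(p, 3), p_adj = signif(p_adj, 3)))
    cat("interaction LRT: D =", round(x$interaction$D, 3),
        "df =", x$interaction$df, "p =", signif(x$interaction$p, 3), "\n")
  } else {
    print(transform(x$contrasts, estimate = signif(estimate, 4),
                    se = signif(se, 3), p = signif(p, 3),
                    p_adj = signif(p_adj, 3)))
    cat("mating-system LRT: D =", round(x$lrt$D, 3), "df =", x$lrt$df,
        "p =", signif(x$lrt$p, 3), "\n")
  }
  if (length(x$excluded))
    cat("not fitted (n <", 20, "):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `adjusted = min(1, p * m)`, order preserved. `m` may exceed the number of
#' p-values supplied (tests planned but not run still count).
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @param m Number of tests (>= `length(pvalues)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(pvalues, m = length(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < length(pvalues)) stop("m must be at least the number of tests")
  pmin(1, pvalues * m)
}

#' Predict trait mass from a fitted model
#'
#' Evaluates the linear predictor of a `pgls_fit` or the underlying fit of a
#' `trends_result` at the supplied covariates; returns the prediction on the
#' log10 scale and back-transformed to grams.
#'
#' @param fit A `pgls_fit` or `trends_result`.
#' @param body log10 body mass (g).
#' @param category Mating-system category (if the model includes `mating`).
#' @param pathrate Path-wise rate (if the model includes `pathrate`).
#' @param class Taxonomic class (if the model includes `class`).
#' @return One-row data frame: `log10` and `grams`.
#' @export
predict_trait <- function(fit, body, category = NULL, pathrate = NULL,
                          class = NULL) {
  if (inherits(fit, "trends_result")) fit <- fit$fit
  stopifnot(inherits(fit, "pgls_fit"))
  nd <- data.frame(body = body)
  vars <- all.vars(stats::delete.response(fit$terms))
  if ("mating" %in% vars) {
    if (is.null(category)) stop("model includes mating; supply `category`")
    if (!category %in% fit$xlevels$mating)
      stop("category '", category, "' absent from fit (levels: ",
           paste(fit$xlevels$mating, collapse = ", "), ")")
    nd$mating <- factor(category, levels = fit$xlevels$mating)
  }
  if ("pathrate" %in% vars) {
    if (is.null(pathrate)) stop("model includes pathrate; supply `pathrate`")
    nd$pathrate <- pathrate
  }
  if ("class" %in% vars) {
    if (is.null(class)) stop("model includes class; supply `class`")
    nd$class <- factor(class, levels = fit$xlevels$class)
  }
  pred <- predict(fit, nd)
  data.frame(log10 = pred, grams = 10^pred)
}
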