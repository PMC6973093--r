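#' Sampler settings for the variable-rates chain
#'
#' Defaults (200k sweeps, 50k burn-in, thin 20) are a desk-scale preset; the
#' `production = TRUE` preset lengthens the chain for real analyses where
#' effective sample sizes above 500 are required for every parameter.
#'
#' @param iterations,burnin,thin Chain length, burn-in, thinning (sweeps).
#' @param n_rj,n_scalar Reversible-jump and scalar-walk attempts per sweep;
#'   `NULL` scales them with the number of branches.
#' @param beta_step,sigma_step,r_step Proposal scales; `beta_step = NULL`
#'   uses 2.4x the GLS standard errors.
#' @param production If `TRUE`, 2M iterations / 500k burn-in / thin 200.
#' @return A list of class `vr_settings`.
#' @export
vr_settings <- function(iterations = 200000, burnin = 50000, thin = 20,
                        n_rj = NULL, n_scalar = NULL,
                        beta_step = NULL, sigma_step = 0.3, r_step = 0.5,
                        production = FALSE) {
  if (production) { iterations <- 2e6; burnin <- 5e5; thin <- 200 }
  stopifnot(iterations > burnin, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 n_rj = n_rj, n_scalar = n_scalar, beta_step = beta_step,
                 sigma_step = sigma_step, r_step = r_step),
            class = "vr_settings")
}

#' Priors of the variable-rates model
#'
#' Every branch hosts two potential scalar sites, mirroring the two ways a
#' rate shift can arise: a *branch-local* scalar multiplying that branch
#' alone (a one-off burst of change) and a *clade* scalar multiplying the
#' branch and all its descendants (an inherited, heritable shift that costs a
#' single parameter). Each site is "active" (carries a free scalar r) with
#' prior probability `p_active`, otherwise r = 1 exactly; a branch's
#' effective scalar is the product of its local scalar and all clade scalars
#' anchored on its root-ward path. Active scalars have
#' `log r ~ Normal(0, logr_sd^2)`; the background rate sigma_b^2 has a
#' half-Cauchy prior; regression coefficients are wide normal (proper, as
#' stepping-stone sampling requires a proper prior).
#'
#' @param p_active Prior activation probability per scalar site (default
#'   0.025; with two sites per branch this puts a scalar on ~5% of branches
#'   a priori).
#' @param logr_sd Prior sd of log r for active branches.
#' @param sigma_scale Half-Cauchy scale of the sigma_b^2 prior.
#' @param beta_sd Normal prior sd of each regression coefficient.
#' @return A list of class `vr_priors`.
#' @export
vr_priors <- function(p_active = 0.025, logr_sd = 1, sigma_scale = 1,
                      beta_sd = 10) {
  stopifnot(p_active > 0, p_active < 1, logr_sd > 0, sigma_scale > 0,
            beta_sd > 0)
  structure(list(p_active = p_active, logr_sd = logr_sd,
                 sigma_scale = sigma_scale, beta_sd = beta_sd),
            class = "vr_priors")
}

# Align data/tree, build the design matrix, and put the tree in postorder.
# The postorder edge rows define the canonical branch order used by every
# trace, summary and scaled tree downstream.
.vr_prep <- function(formula, data, tree) {
  stopifnot("species" %in% names(data))
  if (!setequal(data$species, tree$tip.label))
    stop("data species and tree tips differ; run match_and_prune() first")
  data <- droplevels(data[match(tree$tip.label, data$species), , drop = FALSE])
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  ptree <- ape::reorder.phylo(tree, "postorder")
  list(X = X, y = y, tree = ptree,
       edge_parent = ptree$edge[, 1] - 1L, edge_child = ptree$edge[, 2] - 1L,
       edge_length = ptree$edge.length, root_edge = ptree$root.edge %||% 0,
       n_nodes = length(ptree$tip.label) + ptree$Nnode)
}

# flattened per-edge clade membership (each edge + all its descendant edges),
# 0-based for the C++ kernel
.clade_lists <- function(tree) {
  E <- nrow(tree$edge)
  lists <- lapply(seq_len(E), function(e)
    c(e, .descendant_edges(tree, tree$edge[e, 2])))
  list(ptr = c(0L, cumsum(lengths(lists))),
       idx = as.integer(unlist(lists) - 1L))
}

#' Log-likelihood of one variable-rates posterior sample
#'
#' Multivariate-normal log density of `y - X beta` with covariance
#' `sigma2 * V(tree with branch i scaled by r_i)`, evaluated in O(n) by the
#' pruning algorithm. `r` is ordered by the postorder edge rows of `tree`
#' (the order used by [run_chain()] traces).
#'
#' @param sample List with `beta`, `sigma2`, `r`.
#' @param formula,data,tree As in [run_chain()].
#' @return Log-likelihood (scalar).
#' @export
vr_loglik <- function(sample, formula, data, tree) {
  prep <- .vr_prep(formula, data, tree)
  if (length(sample$r) != nrow(prep$tree$edge))
    stop("scalar vector length ", length(sample$r), " != ",
         nrow(prep$tree$edge), " branches")
  .vr_loglik_cpp(prep$X, prep$y, prep$edge_parent, prep$edge_child,
                 prep$edge_length, prep$n_nodes, prep$root_edge,
                 as.numeric(sample$beta), sample$sigma2, as.numeric(sample$r))
}

#' Run the variable-rates MCMC
#'
#' Samples regression coefficients, the background rate sigma_b^2 and
#' per-branch rate scalars from their joint posterior. Each sweep performs
#' Gaussian random walks on every coefficient, a multiplicative walk on
#' sigma_b^2, reversible-jump birth/death moves toggling scalar sites
#' (branch-local and clade-anchored; see [vr_priors()]) between inactive
#' (r = 1) and active (r drawn from its prior), and multiplicative walks on
#' active scalars. The recorded `r` draws are the per-branch *effective*
#' scalars (local times inherited clade products), the quantity all
#' downstream rate analyses operate on. `model = "single"` disables the
#' scalar moves, giving the single-rate model m0.
#'
#' @param formula Regression formula (e.g. `testes ~ body`).
#' @param data Trait table with a `species` column matching the tree tips.
#' @param tree Time-calibrated `phylo`.
#' @param settings A [vr_settings()].
#' @param priors A [vr_priors()].
#' @param model `"vr"` (variable rates, m1) or `"single"` (single rate, m0).
#' @param power Likelihood tempering exponent in \[0, 1\]; 1 is the posterior,
#'   0 samples the prior (used by stepping-stone sampling and prior checks).
#' @param seed Integer seed (`NULL`: current RNG state).
#' @param init Optional initial state `list(beta, sigma2, rb, ab, rc, ac)`
#'   (branch-local and clade scalar values and activations, as returned in
#'   `$final`); default initializes at the fixed-tree GLS estimate with all
#'   scalars inactive.
#' @param record_r Store the per-branch scalar draws (needed for all rate
#'   post-processing; disable only for tempered bridging runs).
#' @return A `vr_trace`: matrices `beta` (draws x coefficients) and `r`
#'   (draws x branches, postorder edge order of `$tree`), vectors `sigma2`,
#'   `loglik`, `n_active`, per-parameter `ess`, acceptance rates, the aligned
#'   postorder `tree`, and the final chain state.
#' @export
run_chain <- function(formula, data, tree, settings = vr_settings(),
                      priors = vr_priors(), model = c("vr", "single"),
                      power = 1, seed = NULL, init = NULL, record_r = TRUE) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  prep <- .vr_prep(formula, data, tree)
  E <- nrow(prep$tree$edge)
  p <- ncol(prep$X)

  if (is.null(init)) {
    g <- tryCatch(gls_fit(formula, data, tree), error = function(e) NULL)
    init <- list(
      beta = if (is.null(g)) rep(0, p) else unname(g$coefficients),
      sigma2 = if (is.null(g)) stats::var(prep$y) else g$sigma2,
      rb = rep(1, E), ab = rep(0L, E), rc = rep(1, E), ac = rep(0L, E))
    beta_step <- if (is.null(settings$beta_step)) {
      if (is.null(g)) rep(0.1, p) else pmax(2.4 * unname(g$se), 1e-3)
    } else rep_len(settings$beta_step, p)
  } else {
    beta_step <- rep_len(if (is.null(settings$beta_step)) 0.1
                         else settings$beta_step, p)
  }
  n_rj <- if (is.null(settings$n_rj)) max(8L, as.integer(round(E / 8))) else
    as.integer(settings$n_rj)
  n_scalar <- if (is.null(settings$n_scalar)) max(4L, as.integer(round(E / 16)))
    else as.integer(settings$n_scalar)
  clades <- .clade_lists(prep$tree)

  raw <- .vr_chain_cpp(prep$X, prep$y, prep$edge_parent, prep$edge_child,
                       prep$edge_length, prep$n_nodes, prep$root_edge,
                       clades$ptr, clades$idx,
                       as.numeric(init$beta), init$sigma2,
                       as.numeric(init$rb), as.integer(init$ab),
                       as.numeric(init$rc), as.integer(init$ac),
                       priors$beta_sd, priors$sigma_scale, priors$p_active,
                       priors$logr_sd,
                       beta_step, settings$sigma_step, settings$r_step,
                       n_rj, n_scalar, power, model == "vr",
                       settings$iterations, settings$burnin, settings$thin,
                       record_r)

  colnames(raw$beta) <- colnames(prep$X)
  ess <- c(vapply(seq_len(p), function(j) ess_imse(raw$beta[, j]), 0),
           ess_imse(raw$sigma2),
           if (model == "vr") ess_imse(as.numeric(raw$n_active)))
  names(ess) <- c(colnames(prep$X), "sigma2_b",
                  if (model == "vr") "n_active")
  if (power == 1 && any(ess < 500))
    warning("effective sample size below 500 for: ",
            paste(names(ess)[ess < 500], collapse = ", "),
            " (consider longer chains)")

  structure(list(
    beta = raw$beta, sigma2 = raw$sigma2, loglik = raw$loglik,
    n_active = raw$n_active, n_active_branch = raw$n_active_branch,
    n_active_clade = raw$n_active_clade,
    r = if (record_r) raw$r else NULL,
    tree = prep$tree, species = prep$tree$tip.label,
    formula = formula, model = model, power = power,
    settings = settings, priors = priors, ess = ess, accept = raw$accept,
    final = list(beta = raw$final_beta, sigma2 = raw$final_sigma2,
                 rb = raw$final_rb, ab = raw$final_ab,
                 rc = raw$final_rc, ac = raw$final_ac)
  ), class = "vr_trace")
}

#' Run multiple independent chains
#'
#' @inheritParams run_chain
#' @param n_chains Number of chains.
#' @param seeds Integer seeds, one per chain.
#' @param ... Passed to [run_chain()].
#' @return List of `vr_trace` objects.
#' @export
run_chains <- function(formula, data, tree, n_chains = 2,
                       seeds = seq_len(n_chains), ...) {
  stopifnot(length(seeds) == n_chains)
  lapply(seeds, function(s) run_chain(formula, data, tree, seed = s, ...))
}

#' @export
print.vr_trace <- function(x, ...) {
  cat("Variable-rates trace (", x$model, "): ", length(x$sigma2),
      " samples, ", ncol(x$beta), " coefficients, ",
      nrow(x$tree$edge), " branches\n", sep = "")
  cat("posterior mean sigma_b^2 =", signif(mean(x$sigma2), 4),
      "; mean active branches =", round(mean(x$n_active), 1), "\n")
  cat("min ESS =", round(min(x$ess)), "(", names(x$ess)[which.min(x$ess)], ")\n")
  invisible(x)
}

#' Effective sample size (initial monotone sequence estimator)
#'
#' Geyer's initial monotone positive sequence estimator of the integrated
#' autocorrelation time; ESS = n / tau.
#'
#' @param x Numeric vector of ordered MCMC draws.
#' @return Estimated effective sample size.
#' @export
ess_imse <- function(x) {
  n <- length(x)
  if (n < 4) return(n)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2, 2000), plot = FALSE)$acf[, 1, 1]
  m <- floor(length(ac) / 2)
  gamma <- ac[2 * seq_len(m) - 1] + ac[2 * seq_len(m)]  # pair sums
  pos <- which(gamma <= 0)
  keep <- if (length(pos)) seq_len(pos[1] - 1) else seq_len(m)
  if (!length(keep)) return(n)
  gamma <- cummin(gamma[keep])  # enforce monotone decrease
  tau <- max(2 * sum(gamma) - 1, 1e-8)
  n / tau
}

#' Proportion of a posterior distribution crossing zero (Px)
#'
#' The fraction of draws on the minority side of zero; a parameter with
#' `Px < 0.05` has less than 5% of its posterior overlapping zero and is
#' considered substantially different from zero. Exact zeros count toward
#' crossing. Bounded above by 0.5.
#'
#' @param draws Numeric vector of posterior draws.
#' @return Px in \[0, 0.5\].
#' @export
compute_px <- function(draws) {
  if (length(draws) == 0) stop("no posterior draws supplied")
  min(0.5, mean(draws <= 0), mean(draws >= 0))
}

#' Px of the paired difference of two posteriors (Pxdiff)
#'
#' Computes the per-iteration differences `a - b` and their [compute_px()].
#' Draws must be iteration-aligned samples from the same chain. When
#' `Pxdiff < 0.05` the two parameters are considered different. If every
#' difference is exactly zero (degenerate; e.g. a parameter compared with
#' itself) the conventional value 0.5 is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param a,b Equal-length, iteration-aligned draws.
#' @return Pxdiff with attributes `different` (logical) and `degenerate`.
#' @export
compute_px_diff <- function(a, b) {
  if (length(a) != length(b))
    stop("draw vectors differ in length (", length(a), " vs ", length(b), ")")
  d <- a - b
  degenerate <- all(d == 0)
  px <- if (degenerate) 0.5 else compute_px(d)
  structure(px, different = !degenerate && px < 0.05, degenerate = degenerate)
}
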