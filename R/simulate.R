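#' Configuration for the synthetic test-bed generator
#'
#' Bundles every knob of the simulator: tree size and birth/death rates,
#' the true allometry (per-class intercepts and slopes on the log10-log10
#' scale), the background Brownian rate of the residuals, planted rate shifts,
#' an optional planted directional trend, and mating-system frequencies.
#'
#' Defaults emulate a vertebrate testes-mass-on-body-mass allometry: slope
#' 0.67, intercept -2 (log10 g), background rate 0.05 (log10-g^2 per unit
#' time), body mass evolving by Brownian motion on the same tree from a root
#' at 3 (1 kg).
#'
#' @param n_tips Number of surviving tips (>= 3 for any model fit).
#' @param birth,death Birth-death rates per unit time; the tree is conditioned
#'   on `n_tips` survivors.
#' @param intercepts,slopes Named numeric vectors, one entry per taxonomic
#'   class; names define the classes present.
#' @param sigma2_b Background Brownian variance of the regression residuals.
#' @param shifts List of planted shifts. Each is
#'   `list(anchor = c(tipA, tipB), multiplier = , type = "variance"|"mean",
#'   offset = )`: the clade is the MRCA of the two anchor tips; a variance
#'   shift multiplies the stem and all descendant branch rates, a mean shift
#'   adds `offset` to the response of all tips in the clade.
#' @param trend Optional `list(category = , coef = )`: response of tips in
#'   that mating-system category is shifted by
#'   `coef * (true path-wise rate - category mean path-wise rate)`.
#' @param class_probs Probabilities of class membership per tip (named,
#'   summing to 1). Tips are assigned i.i.d.
#' @param mating_probs Named list: per class, probabilities over the mating
#'   codes `M`, `PG`, `PA` (must sum to 1).
#' @param mating_mode `"iid"` (multinomial per tip) or `"clade"` (contiguous
#'   blocks of the cladewise tip order, mimicking phylogenetic clustering).
#' @param body_mode `"bm"` (Brownian motion on the tree, realistic
#'   phylogenetic signal in the predictor) or `"iid"` (independent normal,
#'   used by oracle tests).
#' @param body_root,body_sigma2 Root state and BM variance for body mass
#'   (`body_sd` plays the sd role when `body_mode = "iid"`).
#' @param body_sd sd of i.i.d. body mass draws.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 100, birth = 1, death = 0,
                       intercepts = c(birds = -2), slopes = c(birds = 0.67),
                       sigma2_b = 0.05,
                       shifts = list(), trend = NULL,
                       class_probs = NULL,
                       mating_probs = NULL,
                       mating_mode = c("iid", "clade"),
                       body_mode = c("bm", "iid"),
                       body_root = 3, body_sigma2 = 0.25, body_sd = 1,
                       seed = NULL) {
  stopifnot(n_tips >= 3, birth >= 0, death >= 0, sigma2_b >= 0)
  classes <- names(intercepts)
  if (is.null(classes) || !identical(sort(classes), sort(names(slopes))))
    stop("intercepts and slopes must be named vectors over the same classes")
  if (is.null(class_probs)) {
    class_probs <- stats::setNames(rep(1 / length(classes), length(classes)), classes)
  }
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  if (is.null(mating_probs)) {
    mating_probs <- stats::setNames(
      rep(list(c(M = 0.4, PG = 0.4, PA = 0.2)), length(classes)), classes)
  }
  for (cl in names(mating_probs)) {
    if (abs(sum(mating_probs[[cl]]) - 1) > 1e-8)
      stop("mating_probs for class '", cl, "' must sum to 1")
  }
  for (s in shifts) {
    if (!is.null(s$multiplier) && s$multiplier <= 0)
      stop("shift multipliers must be > 0")
  }
  structure(list(
    n_tips = as.integer(n_tips), birth = birth, death = death,
    intercepts = intercepts, slopes = slopes, sigma2_b = sigma2_b,
    shifts = shifts, trend = trend,
    class_probs = class_probs, mating_probs = mating_probs,
    mating_mode = match.arg(mating_mode),
    body_mode = match.arg(body_mode),
    body_root = body_root, body_sigma2 = body_sigma2, body_sd = body_sd,
    seed = seed
  ), class = "sim_config")
}

#' Simulate a birth-death phylogeny
#'
#' Ultrametric tree conditioned on `cfg$n_tips` surviving tips (so lineage
#' extinction can never leave fewer tips than requested). Deterministic for a
#' fixed `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `phylo` object with `n_tips` tips.
#' @export
simulate_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tree <- ape::rphylo(cfg$n_tips, birth = cfg$birth, death = cfg$death)
  tree$tip.label <- sprintf("sp%03d", seq_len(cfg$n_tips))
  validate_phylogeny(tree)
}

#' Apply planted variance shifts to a tree
#'
#' Multiplies the stem branch of each shift's anchor clade (the MRCA of the
#' two anchor tips) and all branches descending from it by the shift's
#' multiplier — the generative counterpart of a heritable rate shift. Mean
#' shifts do not alter branch lengths and are handled in [simulate_traits()].
#'
#' @param tree A `phylo` object.
#' @param shifts List of shift specs (see [sim_config()]).
#' @return A list: `tree` (rate-scaled), `scalars` (true per-edge multiplier,
#'   in `tree$edge` row order), `clades` (tip labels per variance shift).
#' @export
apply_rate_shifts <- function(tree, shifts) {
  scalars <- rep(1, nrow(tree$edge))
  clades <- list()
  for (s in shifts) {
    if (!identical(s$type, "variance")) next
    node <- .anchor_mrca(tree, s$anchor)
    edges <- .clade_edges(tree, node, include_stem = TRUE)
    scalars[edges] <- scalars[edges] * s$multiplier
    clades[[length(clades) + 1]] <-
      tree$tip.label[.clade_tips(tree, node)]
  }
  scaled <- tree
  scaled$edge.length <- tree$edge.length * scalars
  list(tree = scaled, scalars = scalars, clades = clades)
}

.anchor_mrca <- function(tree, anchor) {
  miss <- setdiff(anchor, tree$tip.label)
  if (length(miss)) stop("anchor tip(s) not in tree: ", paste(miss, collapse = ", "))
  if (length(anchor) == 1) return(match(anchor, tree$tip.label))
  ape::getMRCA(tree, anchor)
}

# indices (rows of tree$edge) of all edges inside the clade rooted at `node`,
# optionally including the stem edge leading to it
.clade_edges <- function(tree, node, include_stem = TRUE) {
  n <- length(tree$tip.label)
  inside <- logical(n + tree$Nnode)
  inside[node] <- TRUE
  tr_edge <- tree$edge
  # cladewise order: parents before children
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(ord))) {
    if (inside[ord[k, 1]]) inside[ord[k, 2]] <- TRUE
  }
  sel <- inside[tr_edge[, 2]] & (inside[tr_edge[, 1]] | include_stem)
  if (!include_stem) sel <- inside[tr_edge[, 2]] & inside[tr_edge[, 1]]
  which(sel)
}

.clade_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  inside <- logical(n + tree$Nnode)
  inside[node] <- TRUE
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(ord))) {
    if (inside[ord[k, 1]]) inside[ord[k, 2]] <- TRUE
  }
  which(inside[seq_len(n)])
}

#' Simulate a trait table on a tree
#'
#' Body mass evolves by Brownian motion on the (unscaled) tree or is drawn
#' i.i.d.; the response is `intercept(class) + slope(class) * body + eps`
#' where `eps` is multivariate normal with covariance
#' `sigma2_b * V(shift-scaled tree)`. Mean-type shifts add their offset to all
#' tips of their clade. Classes and mating systems are assigned
#' per `cfg`.
#'
#' @param tree A `phylo` object (the original time tree).
#' @param cfg A [sim_config()].
#' @param seed Optional seed; `NULL` continues the current RNG stream (the
#'   dataset-level wrapper [simulate_dataset()] seeds once up front).
#' @return A trait table (`species`, `testes`, `body`, `class`, `mating`) with
#'   attributes `true_scalars` (per-edge rate multipliers),
#'   `scaled_tree` (the shift-scaled tree) and `true_pathwise` (per-tip true
#'   path-wise rates, i.e. tip depths on the scaled tree).
#' @export
simulate_traits <- function(tree, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), length(tree$tip.label) >= 3)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  classes <- names(cfg$intercepts)

  cls <- sample(classes, n, replace = TRUE, prob = cfg$class_probs)
  mating <- character(n)
  if (cfg$mating_mode == "iid") {
    for (cl in classes) {
      sel <- cls == cl
      if (any(sel))
        mating[sel] <- sample(names(cfg$mating_probs[[cl]]), sum(sel),
                              replace = TRUE, prob = cfg$mating_probs[[cl]])
    }
  } else {
    # contiguous blocks of the cladewise tip order approximate phylogenetically
    # clustered mating systems
    ord <- seq_len(n)
    block <- pmax(2L, rpois(n, lambda = 6))
    pos <- 1L
    while (pos <= n) {
      len <- min(block[pos], n - pos + 1L)
      idx <- ord[pos:(pos + len - 1L)]
      cl <- cls[idx[1]]
      mating[idx] <- sample(names(cfg$mating_probs[[cl]]), 1,
                            prob = cfg$mating_probs[[cl]])
      pos <- pos + len
    }
  }

  if (cfg$body_mode == "bm") {
    Vb <- ape::vcv.phylo(tree)
    Lb <- .chol_psd(Vb * cfg$body_sigma2)
    body <- cfg$body_root + as.vector(t(Lb) %*% stats::rnorm(n))
  } else {
    body <- stats::rnorm(n, cfg$body_root, cfg$body_sd)
  }
  names(body) <- tree$tip.label

  sc <- apply_rate_shifts(tree, cfg$shifts)
  eps <- rep(0, n)
  if (cfg$sigma2_b > 0) {
    V <- ape::vcv.phylo(sc$tree)
    L <- .chol_psd(V * cfg$sigma2_b)
    eps <- as.vector(t(L) %*% stats::rnorm(n))
  }
  y <- cfg$intercepts[cls] + cfg$slopes[cls] * body + eps

  for (s in cfg$shifts) {
    if (identical(s$type, "mean")) {
      node <- .anchor_mrca(tree, s$anchor)
      y[.clade_tips(tree, node)] <- y[.clade_tips(tree, node)] + s$offset
    }
  }

  out <- data.frame(species = tree$tip.label,
                    testes = unname(y), body = unname(body),
                    class = factor(cls, levels = classes),
                    mating = factor(mating, levels = c("M", "PG", "PA", "M+PG")),
                    stringsAsFactors = FALSE)
  attr(out, "true_scalars") <- sc$scalars
  attr(out, "scaled_tree") <- sc$tree
  attr(out, "true_pathwise") <- tip_depths(sc$tree)
  out
}

.chol_psd <- function(V) {
  tryCatch(chol(V), error = function(e)
    stop("singular trait covariance (duplicate tips with zero-length ",
         "branches?): ", conditionMessage(e), call. = FALSE))
}

#' Plant a directional trend in one mating-system category
#'
#' Shifts the response of every tip in the target category by
#' `coef * (path-wise rate - category mean path-wise rate)`, where the
#' path-wise rate is the tip depth on the supplied rate-scaled tree. A
#' negative `coef` makes high-rate species evolve toward relatively smaller
#' trait values, emulating directional adaptive change concentrated in fast
#' lineages. Centering within the category leaves its mean response unchanged.
#'
#' @param table Trait table from [simulate_traits()].
#' @param scaled_tree The shift-scaled tree defining true path-wise rates.
#' @param trend `list(category = , coef = )`.
#' @return The modified trait table (attributes preserved).
#' @export
plant_directional_trend <- function(table, scaled_tree, trend) {
  stopifnot(is.data.frame(table), !is.null(trend$category), !is.null(trend$coef))
  sel <- !is.na(table$mating) & table$mating == trend$category
  if (!any(sel)) stop("category '", trend$category, "' absent from table")
  if (trend$coef == 0) return(table)
  pr <- tip_depths(scaled_tree)[table$species]
  if (anyNA(pr)) stop("table species missing from scaled tree")
  table$testes[sel] <- table$testes[sel] +
    trend$coef * (pr[sel] - mean(pr[sel]))
  table
}

#' Pick a clade of a given size from a tree
#'
#' Returns the tip labels of a monophyletic group with exactly `size` tips,
#' preferring the candidate with the longest stem branch (the clade whose
#' planted shift carries the most signal). Returns `NULL` when the tree has
#' no clade of that size.
#'
#' @param tree A `phylo` object.
#' @param size Required number of tips.
#' @return Character vector of tip labels, or `NULL`.
#' @export
pick_clade <- function(tree, size) {
  n <- length(tree$tip.label)
  ptree <- ape::reorder.phylo(tree, "postorder")
  inc_len <- numeric(n + tree$Nnode)
  inc_len[ptree$edge[, 2]] <- ptree$edge.length
  cand <- Filter(function(nd) length(.tips_below(ptree, nd)) == size,
                 (n + 1):(n + tree$Nnode))
  if (!length(cand)) return(NULL)
  best <- cand[[which.max(vapply(cand, function(nd) inc_len[nd], 0))]]
  tree$tip.label[.tips_below(ptree, best)]
}

#' Simulate a dataset with one planted clade rate shift
#'
#' Convenience scenario builder: draws birth-death trees until one contains a
#' clade of exactly `clade_size` tips (bounded retries), plants a variance
#' shift of the given multiplier on it, and simulates traits. The returned
#' ground truth names the shifted clade.
#'
#' @param n_tips,clade_size,multiplier Scenario dimensions.
#' @param seed Integer seed (also drives the tree retries, deterministically).
#' @param ... Further arguments passed to [sim_config()].
#' @return As [simulate_dataset()], plus `clade_tips` (labels of the planted
#'   clade).
#' @export
shift_scenario <- function(n_tips = 100, clade_size = 10, multiplier = 8,
                           seed = 1, ...) {
  for (try in 0:24) {
    cfg0 <- sim_config(n_tips = n_tips, seed = seed + 7919L * try, ...)
    tree <- simulate_tree(cfg0)
    tipsK <- pick_clade(tree, clade_size)
    if (!is.null(tipsK)) {
      cfg <- sim_config(n_tips = n_tips, seed = seed + 7919L * try,
                        shifts = list(list(anchor = tipsK,
                                           multiplier = multiplier,
                                           type = "variance")), ...)
      out <- simulate_dataset(cfg)
      out$clade_tips <- tipsK
      return(out)
    }
  }
  stop("no tree with a clade of ", clade_size, " tips found in 25 attempts")
}

#' Simulate a complete dataset (tree + traits + planted structure)
#'
#' Seeds the RNG once from `cfg$seed`, then draws the tree, the traits (with
#' planted variance and mean shifts) and, if configured, the planted
#' directional trend. Identical configs give byte-identical outputs.
#'
#' @param cfg A [sim_config()].
#' @return A list: `tree` (time tree), `table` (trait table),
#'   `scaled_tree`, `true_scalars`, `true_pathwise` — the planted ground truth.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tree <- ape::rphylo(cfg$n_tips, birth = cfg$birth, death = cfg$death)
  tree$tip.label <- sprintf("sp%03d", seq_len(cfg$n_tips))
  validate_phylogeny(tree)
  table <- simulate_traits(tree, cfg)
  scaled <- attr(table, "scaled_tree")
  if (!is.null(cfg$trend)) {
    table <- plant_directional_trend(table, scaled, cfg$trend)
  }
  list(tree = tree, table = table, scaled_tree = scaled,
       true_scalars = attr(table, "true_scalars"),
       true_pathwise = attr(table, "true_pathwise"))
}
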