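# Posterior post-processing: branch classification, heritable rate shifts,
# mean-shift diagnosis, the median rate-scaled tree and path-wise rates.
# All functions are pure in the trace: permuting iteration order never
# changes an output.

# incoming edge index (postorder row) of every node; 0 for the root
.incoming_edge <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  inc <- integer(n_nodes)
  inc[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  inc
}

# tips x edges incidence: M[i, e] = 1 iff edge e lies on the root-to-tip-i path
.path_incidence <- function(tree) {
  n <- length(tree$tip.label)
  inc <- .incoming_edge(tree)
  parent_of <- integer(n + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  M <- matrix(0, n, nrow(tree$edge))
  for (i in seq_len(n)) {
    node <- i
    while (inc[node] > 0L) {
      M[i, inc[node]] <- 1
      node <- parent_of[node]
    }
  }
  rownames(M) <- tree$tip.label
  M
}

# edge indices strictly inside the clade below `node` (not the stem edge)
.descendant_edges <- function(tree, node) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  inside <- logical(n_nodes)
  inside[node] <- TRUE
  # postorder reversed = parents before children
  for (k in rev(seq_len(nrow(tree$edge)))) {
    if (inside[tree$edge[k, 1]]) inside[tree$edge[k, 2]] <- TRUE
  }
  which(inside[tree$edge[, 1]] & inside[tree$edge[, 2]])
}

.tips_below <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  inside <- logical(n + tree$Nnode)
  inside[node] <- TRUE
  for (k in rev(seq_len(nrow(tree$edge)))) {
    if (inside[tree$edge[k, 1]]) inside[tree$edge[k, 2]] <- TRUE
  }
  which(inside[seq_len(n)])
}

#' Per-branch posterior rate summaries and classification
#'
#' For every branch: the posterior fraction of iterations with r > 1 and
#' r < 1, the median scalar, and the median optimized rate
#' sigma_v^2 = sigma_b^2 * r. A branch is classified a rate `increase` when
#' r > 1 in more than 50% of the posterior, a `decrease` when r < 1 in more
#' than 50%, and `background` otherwise (strict inequalities: a branch at
#' exactly 50% stays background).
#'
#' @param trace A `vr_trace` from [run_chain()] with scalar draws recorded.
#' @return Data frame, one row per branch in the postorder edge order of
#'   `trace$tree`: `branch`, `parent_node`, `child_node`, `frac_gt1`,
#'   `frac_lt1`, `median_r`, `median_sigma_v2`, `classification`.
#' @export
summarize_branch_rates <- function(trace) {
  stopifnot(inherits(trace, "vr_trace"))
  if (is.null(trace$r) || nrow(trace$r) == 0)
    stop("trace has no scalar draws (record_r = FALSE or empty trace)")
  tree <- trace$tree
  if (ncol(trace$r) != nrow(tree$edge))
    stop("trace and tree disagree on branch count")
  frac_gt1 <- colMeans(trace$r > 1)
  frac_lt1 <- colMeans(trace$r < 1)
  cls <- ifelse(frac_gt1 > 0.5, "increase",
                ifelse(frac_lt1 > 0.5, "decrease", "background"))
  data.frame(
    branch = seq_len(nrow(tree$edge)),
    parent_node = tree$edge[, 1], child_node = tree$edge[, 2],
    frac_gt1 = frac_gt1, frac_lt1 = frac_lt1,
    median_r = apply(trace$r, 2, stats::median),
    median_sigma_v2 = apply(trace$r * trace$sigma2, 2, stats::median),
    classification = cls,
    stringsAsFactors = FALSE
  )
}

#' Detect heritable rate shifts
#'
#' A heritable shift is a clade that inherits a wholescale new rate, defined
#' by two criteria evaluated per posterior iteration on the optimized rates
#' sigma_v^2 (within an iteration sigma_b^2 is common to all branches, so the
#' comparisons reduce to the scalars r): (1) the clade's stem branch differs
#' in rate from its ancestor branch in more than 50% of iterations, and
#' (2) no branch inside the clade differs from the stem in more than 50% of
#' iterations — the descendants inherit the stem's rate. Qualifying clades
#' with at least `min_size` tips are `heritable`; smaller ones (2 or more
#' tips) are `incipient`; single tips are `single-species`. The shift's
#' direction is the direction of the stem-ancestor comparison (which must
#' agree with the stem's own classification). Branches attached to the root
#' have no ancestor and are skipped. When a candidate's tip set is nested
#' inside an accepted candidate of the same direction, the largest clade
#' wins.
#'
#' An internal branch that deviates from its ancestor while every branch of
#' its clade stays at the background rate fails criterion 2 in a specific,
#' diagnostic way: the rate change is not inherited. Such anchors are
#' reported with kind `mean-shift-candidate` — the signature of an intercept
#' (mean) shift in the allometry — and can be confirmed or dismissed with
#' [flag_mean_shift()].
#'
#' @param trace A `vr_trace` with scalar draws.
#' @param min_size Minimum clade size (tips) for a heritable shift.
#' @return Data frame with one row per shift: `anchor_branch`, `anchor_node`,
#'   `size`, `kind`, `direction`, `frac_vs_ancestor`,
#'   `max_descendant_diff`, and a `tips` list-column of tip labels.
#' @export
detect_heritable_shifts <- function(trace, min_size = 10) {
  stopifnot(inherits(trace, "vr_trace"))
  if (is.null(trace$r)) stop("trace has no scalar draws")
  tree <- trace$tree
  inc <- .incoming_edge(tree)
  R <- trace$r
  E <- ncol(R)

  frac_gt1 <- colMeans(R > 1)
  frac_lt1 <- colMeans(R < 1)
  own_class <- ifelse(frac_gt1 > 0.5, "increase",
                      ifelse(frac_lt1 > 0.5, "decrease", "background"))

  cand <- list()
  for (b in seq_len(E)) {
    if (own_class[b] == "background") next  # the branch itself must deviate
    parent_node <- tree$edge[b, 1]
    pe <- inc[parent_node]
    if (pe == 0L) next  # stem attaches to the root: no ancestor branch
    up <- mean(R[, b] > R[, pe])
    down <- mean(R[, b] < R[, pe])
    if ((own_class[b] == "increase" && up <= 0.5) ||
        (own_class[b] == "decrease" && down <= 0.5)) next  # criterion 1
    direction <- own_class[b]
    child <- tree$edge[b, 2]
    desc <- .descendant_edges(tree, child)
    max_diff <- 0
    if (length(desc)) {
      diffs <- vapply(desc, function(d)
        max(mean(R[, d] > R[, b]), mean(R[, d] < R[, b])), 0)
      max_diff <- max(diffs)
    }
    inherited <- max_diff <= 0.5  # criterion 2: the clade keeps the new rate
    if (!inherited) {
      # a lone elevated internal branch whose clade stays at the background
      # rate is the signature of a mean (intercept) shift, not a heritable
      # variance shift; anything else is unresolved nested structure
      if (length(desc) == 0 || any(own_class[desc] != "background")) next
    }
    tips <- .tips_below(tree, child)
    cand[[length(cand) + 1]] <- list(
      anchor_branch = b, anchor_node = child, size = length(tips),
      direction = direction, inherited = inherited,
      frac_vs_ancestor = max(up, down),
      max_descendant_diff = max_diff,
      tips = tree$tip.label[tips])
  }
  empty <- data.frame(anchor_branch = integer(), anchor_node = integer(),
                      size = integer(), kind = character(),
                      direction = character(), frac_vs_ancestor = numeric(),
                      max_descendant_diff = numeric(),
                      tips = I(list()), stringsAsFactors = FALSE)
  if (!length(cand)) return(empty)
  # largest clade wins among nested same-direction candidates
  ord <- order(vapply(cand, `[[`, 0L, "size"), decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    nested <- any(vapply(kept, function(k)
      k$direction == cand[[i]]$direction &&
        all(cand[[i]]$tips %in% k$tips), TRUE))
    if (!nested) kept[[length(kept) + 1]] <- cand[[i]]
  }
  kept <- kept[order(vapply(kept, `[[`, 0L, "anchor_branch"))]
  sizes <- vapply(kept, `[[`, 0L, "size")
  inh <- vapply(kept, `[[`, TRUE, "inherited")
  kind <- ifelse(!inh, "mean-shift-candidate",
                 ifelse(sizes >= min_size, "heritable",
                        ifelse(sizes >= 2, "incipient", "single-species")))
  data.frame(
    anchor_branch = vapply(kept, `[[`, 0L, "anchor_branch"),
    anchor_node = vapply(kept, `[[`, 0L, "anchor_node"),
    size = sizes, kind = kind,
    direction = vapply(kept, `[[`, "", "direction"),
    frac_vs_ancestor = vapply(kept, `[[`, 0, "frac_vs_ancestor"),
    max_descendant_diff = vapply(kept, `[[`, 0, "max_descendant_diff"),
    tips = I(lapply(kept, `[[`, "tips")),
    stringsAsFactors = FALSE
  )
}

#' Diagnose a rate shift as a mean-shift candidate
#'
#' A change in the *intercept* of the trait-body allometry within a clade can
#' masquerade as a rate increase along the clade's stem branch. This post-hoc
#' diagnostic refits the regression on the original time tree with a
#' clade-membership intercept dummy: if the dummy is significant (LRT
#' p < 0.05) and the stem's rate elevation is not inherited (all branches
#' inside the clade classified `background`), the shift is marked
#' `mean-shift-candidate` with the sign of the estimated offset.
#'
#' @param shift One row of [detect_heritable_shifts()] output (or a list with
#'   `anchor_node` and `tips`).
#' @param formula,data Base regression and trait table.
#' @param tree The original time tree (not rate-scaled).
#' @param summaries Output of [summarize_branch_rates()] on the same trace.
#' @return The shift record as a one-row data frame with added columns
#'   `mean_shift` (logical), `mean_offset`, `mean_p`, and `note`.
#' @export
flag_mean_shift <- function(shift, formula, data, tree, summaries) {
  shift <- as.list(shift)
  tips <- unlist(shift$tips)
  out <- data.frame(anchor_node = shift$anchor_node, size = length(tips),
                    mean_shift = FALSE, mean_offset = NA_real_,
                    mean_p = NA_real_, note = "", stringsAsFactors = FALSE)
  if (length(tips) < 2 || nrow(data) < 4) {
    out$note <- "clade too small to evaluate"
    return(out)
  }
  desc <- .descendant_edges(ape::reorder.phylo(tree, "postorder"),
                            shift$anchor_node)
  inherited <- length(desc) > 0 &&
    any(summaries$classification[desc] != "background")
  data$in_clade <- as.integer(data$species %in% tips)
  full_formula <- stats::update(formula, . ~ . + in_clade)
  fits <- tryCatch({
    f1 <- gls_fit(full_formula, data, tree)
    f0 <- gls_fit(formula, data, tree)
    list(f1 = f1, f0 = f0)
  }, error = function(e) e)
  if (inherits(fits, "error")) {
    out$note <- paste("not evaluated:", conditionMessage(fits))
    return(out)
  }
  lrt <- likelihood_ratio_test(fits$f1, fits$f0)
  out$mean_offset <- unname(fits$f1$coefficients["in_clade"])
  out$mean_p <- lrt$p
  if (lrt$p < 0.05 && !inherited) {
    out$mean_shift <- TRUE
    out$note <- sprintf("intercept offset %s (%.3f), rate elevation not inherited",
                        if (out$mean_offset < 0) "negative" else "positive",
                        out$mean_offset)
  } else if (lrt$p < 0.05 && inherited) {
    out$note <- "intercept dummy significant but clade inherits the rate (variance shift)"
  }
  out
}

#' Median rate-scaled tree
#'
#' Each branch length is the original time length multiplied by that branch's
#' posterior median scalar. The trends analyses are conducted on this tree.
#'
#' @param trace A `vr_trace` with scalar draws.
#' @return A `phylo` (postorder, same tip labels as `trace$tree`).
#' @export
median_scaled_tree <- function(trace) {
  stopifnot(inherits(trace, "vr_trace"))
  if (is.null(trace$r)) stop("trace has no scalar draws")
  tree <- trace$tree
  tree$edge.length <- tree$edge.length * apply(trace$r, 2, stats::median)
  tree
}

#' Path-wise rates
#'
#' For every tip and every posterior draw, the sum of rate-scaled branch
#' lengths along the root-to-tip path — a per-species measure of accumulated
#' adaptive change. Summaries (median, mean, mode) are taken per tip over the
#' posterior of per-draw path sums (not path sums over a summary tree).
#'
#' @param trace A `vr_trace` with scalar draws.
#' @return List of class `pathwise_rates`: `draws` (draws x tips) and
#'   `summary` (data frame: `species`, `median`, `mean`, `mode`).
#' @export
pathwise_rates <- function(trace) {
  stopifnot(inherits(trace, "vr_trace"))
  if (is.null(trace$r)) stop("trace has no scalar draws")
  tree <- trace$tree
  M <- .path_incidence(tree)
  # draws x tips: (r * elen) %*% t(M)
  P <- trace$r %*% (t(M) * tree$edge.length)
  colnames(P) <- tree$tip.label
  mode_of <- function(x) {
    if (length(unique(x)) == 1) return(x[1])
    d <- stats::density(x)
    d$x[which.max(d$y)]
  }
  structure(list(
    draws = P,
    summary = data.frame(
      species = tree$tip.label,
      median = apply(P, 2, stats::median),
      mean = colMeans(P),
      mode = apply(P, 2, mode_of),
      row.names = NULL, stringsAsFactors = FALSE)
  ), class = "pathwise_rates")
}
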