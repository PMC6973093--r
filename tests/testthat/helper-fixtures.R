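# Shared fixtures: tiny hand-checkable trees and dense-matrix oracles kept
# deliberately independent of the package's own linear-algebra paths.

# the worked 3-tip tree: V = [[2,1,0],[1,2,0],[0,0,2]]
tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2):0;")

write_tmp <- function(lines, ext = ".nwk") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05  # keep away from zero
  tr
}

# brute-force shared root-to-MRCA path length for every tip pair, by
# explicit root-to-tip edge walks (independent of ape::vcv.phylo)
brute_vcv <- function(tree) {
  n <- length(tree$tip.label)
  parent_of <- integer(n + tree$Nnode)
  elen_of <- numeric(n + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  elen_of[tree$edge[, 2]] <- tree$edge.length
  path_nodes <- function(tip) {
    nodes <- integer(0); node <- tip
    while (node != n + 1) { nodes <- c(nodes, node); node <- parent_of[node] }
    nodes
  }
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), path_nodes)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    V[i, j] <- sum(elen_of[shared])
  }
  V
}

# dense multivariate-normal log density oracle
dense_mvn_loglik <- function(y, mean, Sigma) {
  n <- length(y)
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(Sigma, logarithm = TRUE)$modulus +
                       t(y - mean) %*% solve(Sigma) %*% (y - mean)))
}

# small trait table aligned to a tree, linear in body with optional noise
toy_table <- function(tree, intercept = -2, slope = 0.67, noise = NULL) {
  n <- length(tree$tip.label)
  body <- seq(1, 3, length.out = n)
  eps <- if (is.null(noise)) 0 else noise
  data.frame(species = tree$tip.label, body = body,
             testes = intercept + slope * body + eps,
             stringsAsFactors = FALSE)
}

# fabricate a vr_trace with prescribed per-branch scalar draws (postorder
# edge order), for exercising the posterior post-processing deterministically
make_fake_trace <- function(tree, r_draws, sigma2 = NULL) {
  ptree <- ape::reorder.phylo(tree, "postorder")
  stopifnot(ncol(r_draws) == nrow(ptree$edge))
  S <- nrow(r_draws)
  structure(list(
    beta = matrix(0, S, 1, dimnames = list(NULL, "(Intercept)")),
    sigma2 = if (is.null(sigma2)) rep(1, S) else sigma2,
    loglik = rep(0, S), n_active = rowSums(r_draws != 1),
    r = r_draws, tree = ptree, species = ptree$tip.label,
    formula = testes ~ body, model = "vr", power = 1,
    settings = NULL, priors = NULL, ess = c(sigma2_b = S), accept = NULL,
    final = NULL), class = "vr_trace")
}

# postorder edge index whose child is `node`
edge_to_node <- function(ptree, node) which(ptree$edge[, 2] == node)

# a simulated tree guaranteed to contain a clade of exactly `size` tips
tree_with_clade <- function(n_tips, size, base_seed = 1) {
  for (s in base_seed + 0:30) {
    tree <- simulate_tree(sim_config(n_tips = n_tips, seed = s))
    tips <- pick_clade(tree, size)
    if (!is.null(tips)) return(list(tree = tree, tips = tips))
  }
  stop("fixture: no clade of size ", size, " found")
}
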