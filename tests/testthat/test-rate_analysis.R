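test_that("branch classification counts posterior fractions with strict rules", {
  tr <- tree3()
  ptr <- ape::reorder.phylo(tr, "postorder")
  E <- nrow(ptr$edge)
  R <- matrix(1, 4, E)
  R[, 1] <- c(2.0, 1.5, 0.9, 3.0)   # 75% above 1 -> increase
  R[, 2] <- c(0.5, 0.5, 2.0, 2.0)   # exactly 50/50 -> background (strict)
  trace <- make_fake_trace(tr, R)
  su <- summarize_branch_rates(trace)
  expect_equal(su$frac_gt1[1], 0.75)
  expect_equal(su$classification[1], "increase")
  expect_equal(su$classification[2], "background")  # tie stays background
  expect_equal(su$classification[3], "background")  # inactive throughout
  expect_equal(su$median_r[1], 1.75)
  # permutation invariance: classification is a pure function of fractions
  su2 <- summarize_branch_rates(make_fake_trace(tr, R[c(3, 1, 4, 2), ]))
  expect_identical(su$classification, su2$classification)
})

test_that("optimized rate draws combine sigma_b^2 and r per iteration", {
  tr <- tree3()
  E <- nrow(tr$edge)
  R <- matrix(2, 4, E)
  trace <- make_fake_trace(tr, R, sigma2 = c(0.1, 0.2, 0.3, 0.4))
  su <- summarize_branch_rates(trace)
  expect_equal(su$median_sigma_v2, rep(2 * 0.25, E))
})

test_that("a handcrafted uniform clade elevation is one heritable shift", {
  fx <- tree_with_clade(30, 12, base_seed = 10)
  tree <- fx$tree; tipsK <- fx$tips
  ptr <- ape::reorder.phylo(tree, "postorder")
  node <- ape::getMRCA(ptr, tipsK)
  stem <- edge_to_node(ptr, node)
  ins <- ratescape:::.descendant_edges(ptr, node)
  R <- matrix(1, 4, nrow(ptr$edge))
  R[, c(stem, ins)] <- 3  # whole clade elevated in every sample
  sh <- detect_heritable_shifts(make_fake_trace(tree, R))
  expect_equal(nrow(sh), 1)
  expect_equal(sh$kind, "heritable")
  expect_equal(sh$direction, "increase")
  expect_equal(sh$size, 12)
  expect_setequal(sh$tips[[1]], tipsK)
  # decreases detect symmetrically
  Rd <- matrix(1, 4, nrow(ptr$edge)); Rd[, c(stem, ins)] <- 1 / 3
  shd <- detect_heritable_shifts(make_fake_trace(tree, Rd))
  expect_equal(shd$direction, "decrease")
})

test_that("clades below the size threshold report incipient, tips single-species", {
  fx <- tree_with_clade(40, 9, base_seed = 17)
  tree <- fx$tree; tips9 <- fx$tips
  ptr <- ape::reorder.phylo(tree, "postorder")
  node <- ape::getMRCA(ptr, tips9)
  stem <- edge_to_node(ptr, node)
  ins <- ratescape:::.descendant_edges(ptr, node)
  R <- matrix(1, 6, nrow(ptr$edge))
  R[, c(stem, ins)] <- 4
  sh <- detect_heritable_shifts(make_fake_trace(tree, R))
  expect_equal(sh$kind, "incipient")  # 9 tips: never heritable
  expect_equal(sh$size, 9)
  # single terminal branch
  tipedge <- which(ptr$edge[, 2] == 1)
  R2 <- matrix(1, 6, nrow(ptr$edge)); R2[, tipedge] <- 5
  sh2 <- detect_heritable_shifts(make_fake_trace(tree, R2))
  expect_equal(sh2$kind, "single-species")
  expect_equal(sh2$size, 1)
})

test_that("an all-background trace yields an empty report", {
  tree <- simulate_tree(sim_config(n_tips = 20, seed = 3))
  R <- matrix(1, 5, nrow(tree$edge))
  sh <- detect_heritable_shifts(make_fake_trace(tree, R))
  expect_equal(nrow(sh), 0)
})

test_that("a nested clade with no further rate change is never double-reported", {
  fx <- tree_with_clade(30, 12, base_seed = 10)
  tree <- fx$tree; tipsK <- fx$tips
  ptr <- ape::reorder.phylo(tree, "postorder")
  node <- ape::getMRCA(ptr, tipsK)
  stem <- edge_to_node(ptr, node)
  ins <- ratescape:::.descendant_edges(ptr, node)
  R <- matrix(1, 4, nrow(ptr$edge))
  R[, c(stem, ins)] <- 3
  sh <- detect_heritable_shifts(make_fake_trace(tree, R))
  # the sub-clades inside tipsK inherit the same rate: only the whole clade
  # appears, once
  expect_equal(nrow(sh), 1)
  expect_equal(sh$size, 12)
})

test_that("median_scaled_tree multiplies lengths by per-branch medians", {
  tree <- tree3()
  ptr <- ape::reorder.phylo(tree, "postorder")
  E <- nrow(ptr$edge)
  # all-inactive trace: identity
  t0 <- median_scaled_tree(make_fake_trace(tree, matrix(1, 5, E)))
  expect_equal(t0$edge.length, ptr$edge.length)
  # a branch with median 2 doubles
  R <- matrix(1, 5, E); R[, 1] <- c(2, 2, 2, 0.1, 9)
  t1 <- median_scaled_tree(make_fake_trace(tree, R))
  expect_equal(t1$edge.length[1], ptr$edge.length[1] * 2)
  # random trace: scaled tip depths equal a brute-force recomputation
  set.seed(33)
  tr2 <- random_tree(15)
  ptr2 <- ape::reorder.phylo(tr2, "postorder")
  R2 <- matrix(exp(rnorm(40 * nrow(ptr2$edge), 0, 0.5)), 40)
  t2 <- median_scaled_tree(make_fake_trace(tr2, R2))
  med <- apply(R2, 2, median)
  manual <- ptr2
  manual$edge.length <- ptr2$edge.length * med
  expect_equal(tip_depths(t2), tip_depths(manual), tolerance = 1e-12)
})

test_that("path-wise rates sum rate-scaled branches per draw", {
  tree <- tree3()  # A,B depth 2; C depth 2
  E <- nrow(ape::reorder.phylo(tree, "postorder")$edge)
  # all r = 1 on an ultrametric tree: every draw equals the depth
  pw <- pathwise_rates(make_fake_trace(tree, matrix(1, 5, E)))
  expect_true(all(pw$draws == 2))
  expect_equal(pw$summary$median, rep(2, 3))
  # tip path branches (2, 3) with scalars (2, 1) -> 7
  tr <- ape::read.tree(text = "((A:2,B:2):3,C:5):0;")
  ptr <- ape::reorder.phylo(tr, "postorder")
  R <- matrix(1, 1, nrow(ptr$edge))
  eA <- edge_to_node(ptr, which(ptr$tip.label == "A"))
  estem <- edge_to_node(ptr, ptr$edge[eA, 1])
  R[1, eA] <- 2    # terminal branch of A, length 2, scalar 2
  pw2 <- pathwise_rates(make_fake_trace(tr, R))
  expect_equal(unname(pw2$draws[1, "A"]), 2 * 2 + 3)
  # median of per-draw path sums, not the path sum of per-branch medians:
  # draws chosen so the two disagree on tip A (terminal length 2, stem 3)
  R3 <- matrix(1, 3, nrow(ptr$edge))
  R3[, eA] <- c(10, 1, 2)
  R3[, estem] <- c(1, 10, 2)
  pw3 <- pathwise_rates(make_fake_trace(tr, R3))
  per_draw_A <- R3[, eA] * 2 + R3[, estem] * 3  # 23, 32, 10
  expect_equal(unname(pw3$summary$median[pw3$summary$species == "A"]),
               median(per_draw_A))
  sum_of_medians <- median(R3[, eA]) * 2 + median(R3[, estem]) * 3
  expect_false(isTRUE(all.equal(median(per_draw_A), sum_of_medians)))
})

test_that("mean shifts are diagnosed from the intercept dummy on the time tree", {
  fx <- tree_with_clade(60, 12, base_seed = 55)
  tree <- fx$tree; tipsK <- fx$tips
  ptr <- ape::reorder.phylo(tree, "postorder")
  node <- ape::getMRCA(ptr, tipsK)
  stem <- edge_to_node(ptr, node)
  ins <- ratescape:::.descendant_edges(ptr, node)
  # planted intercept offset, no variance change
  cfg <- sim_config(n_tips = 60,
                    shifts = list(list(anchor = tipsK, type = "mean",
                                       offset = -0.6)))
  tab <- simulate_traits(tree, cfg, seed = 56)
  # posterior that elevates only the stem (the signature of a mean shift)
  R <- matrix(1, 10, nrow(ptr$edge)); R[1:8, stem] <- 6
  trace <- make_fake_trace(tree, R)
  su <- summarize_branch_rates(trace)
  sh <- detect_heritable_shifts(trace)
  expect_equal(sh$kind, "mean-shift-candidate")
  expect_equal(sh$size, length(tipsK))
  flagged <- flag_mean_shift(sh[1, ], testes ~ body, tab, ptr, su)
  expect_true(flagged$mean_shift)
  expect_lt(flagged$mean_offset, 0)
  # pure variance shift: dummy not significant, not flagged
  cfgv <- sim_config(n_tips = 60,
                     shifts = list(list(anchor = tipsK, multiplier = 8,
                                        type = "variance")))
  tabv <- simulate_traits(tree, cfgv, seed = 57)
  flag2 <- flag_mean_shift(sh[1, ], testes ~ body, tabv, ptr, su)
  expect_false(isTRUE(flag2$mean_shift) && flag2$note == "")
})
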