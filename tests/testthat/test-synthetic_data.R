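test_that("simulate_tree is ultrametric, sized, and seed-deterministic", {
  cfg <- sim_config(n_tips = 100, seed = 3)
  tr <- simulate_tree(cfg)
  expect_equal(length(tr$tip.label), 100)
  expect_equal(tr$Nnode, 99)  # binary: n - 1 internal nodes
  d <- tip_depths(tr)
  expect_lt(max(d) - min(d), 1e-8)
  # same config, same newick string
  tr2 <- simulate_tree(sim_config(n_tips = 100, seed = 3))
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # two tips form a cherry with equal depths
  cherry <- simulate_tree(sim_config(n_tips = 3, seed = 1))
  expect_lt(diff(range(tip_depths(cherry))), 1e-8)
})

test_that("zero background rate gives an exactly linear response", {
  cfg <- sim_config(n_tips = 20, sigma2_b = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  expect_equal(sim$table$testes, -2 + 0.67 * sim$table$body, tolerance = 1e-12)
})

test_that("planted variance shift scales within-clade residual variance", {
  # Monte-Carlo oracle: empirical tip variance against the analytic covariance
  set.seed(21)
  cfg0 <- sim_config(n_tips = 40, seed = 21)
  tree <- simulate_tree(cfg0)
  tipsK <- pick_clade(tree, 8)
  shifts <- list(list(anchor = tipsK, multiplier = 8, type = "variance"))
  sc <- apply_rate_shifts(tree, shifts)
  iK <- match(tipsK, tree$tip.label)
  Vexp <- phylo_covariance(sc$tree) * 0.05
  cfg <- sim_config(n_tips = 40, shifts = shifts, body_mode = "iid")
  reps <- replicate(3000, {
    tb <- simulate_traits(tree, cfg)
    tb$testes - (-2 + 0.67 * tb$body)
  })
  emp <- apply(reps, 1, var)
  expect_equal(mean(emp[iK]) / mean(emp[-iK]),
               mean(diag(Vexp)[iK]) / mean(diag(Vexp)[-iK]),
               tolerance = 0.1)
  # analytic diagonal is reproduced tip by tip
  expect_equal(emp, unname(diag(Vexp)[tree$tip.label]), tolerance = 0.15)
})

test_that("sister tips share residual correlation equal to their path fraction", {
  # two tips whose shared path is 90% of total depth
  tr <- ape::read.tree(text = "((A:1,B:1):9,C:10):0;")
  cfg <- sim_config(n_tips = 3, sigma2_b = 1, body_mode = "iid")
  reps <- replicate(5000, {
    tb <- simulate_traits(tr, cfg)
    tb$testes - (-2 + 0.67 * tb$body)
  })
  iA <- match("A", tr$tip.label); iB <- match("B", tr$tip.label)
  expect_equal(cor(reps[iA, ], reps[iB, ]), 0.9, tolerance = 0.03)
})

test_that("mean-type shifts offset the clade without touching branch rates", {
  set.seed(8)
  tree <- simulate_tree(sim_config(n_tips = 30, seed = 8))
  tipsK <- pick_clade(tree, 6)
  cfg0 <- sim_config(n_tips = 30, sigma2_b = 0)
  cfg1 <- sim_config(n_tips = 30, sigma2_b = 0,
                     shifts = list(list(anchor = tipsK, type = "mean",
                                        offset = -0.6)))
  set.seed(99); t0 <- simulate_traits(tree, cfg0)
  set.seed(99); t1 <- simulate_traits(tree, cfg1)
  iK <- t0$species %in% tipsK
  expect_equal(t1$testes[iK], t0$testes[iK] - 0.6)
  expect_equal(t1$testes[!iK], t0$testes[!iK])
  expect_equal(attr(t1, "true_scalars"), attr(t0, "true_scalars"))
})

test_that("plant_directional_trend applies hand-computable offsets", {
  # 5-tip tree with known scaled depths; offsets by direct arithmetic
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,(D:1,E:1):2):0;")
  tab <- data.frame(species = c("A", "B", "C", "D", "E"),
                    testes = rep(0, 5), body = rep(1, 5),
                    class = factor(rep("birds", 5)),
                    mating = factor(c("M", "M", "M", "PG", "PG"),
                                    levels = c("M", "PG", "PA", "M+PG")))
  # scale the D/E clade x3: stem 2 -> 6, terminals 1 -> 3
  sc <- apply_rate_shifts(tr, list(list(anchor = c("D", "E"), multiplier = 3,
                                        type = "variance")))
  pr <- tip_depths(sc$tree)
  expect_equal(unname(pr[c("A", "D")]), c(3, 9))
  out <- plant_directional_trend(tab, sc$tree, list(category = "M", coef = -0.5))
  # M tips all have path-wise rate 3 -> centered offsets are zero
  expect_equal(out$testes, tab$testes)
  out2 <- plant_directional_trend(tab, sc$tree, list(category = "PG", coef = -0.5))
  # PG tips: both depth 9, centered -> zero again; single-tip category instead:
  tab$mating <- factor(c("M", "M", "PA", "PG", "PG"),
                       levels = c("M", "PG", "PA", "M+PG"))
  out3 <- plant_directional_trend(tab, sc$tree, list(category = "M", coef = -0.5))
  # A and B at rate 3, mean 3 -> unchanged
  expect_equal(out3$testes[1:2], c(0, 0))
  # heterogeneous rates inside the category produce the arithmetic offsets
  tab$mating <- factor(c("M", "M", "M", "M", "PG"), levels = levels(tab$mating))
  out4 <- plant_directional_trend(tab, sc$tree, list(category = "M", coef = -0.5))
  prM <- pr[c("A", "B", "C", "D")]
  expect_equal(out4$testes[1:4], -0.5 * (prM - mean(prM)), ignore_attr = TRUE)
  # identity and error contracts
  expect_equal(plant_directional_trend(tab, sc$tree,
                                       list(category = "M", coef = 0)), tab)
  expect_error(plant_directional_trend(tab, sc$tree,
                                       list(category = "PA", coef = 1)),
               "absent")
})

test_that("GLS-whitened residuals of shift-free simulations are standard normal", {
  # with all multipliers 1 and no trend, whitening by the true covariance
  # must give i.i.d. N(0,1): KS test rarely rejects
  set.seed(31)
  tree <- simulate_tree(sim_config(n_tips = 60, seed = 31))
  L <- chol(phylo_covariance(tree) * 0.05)
  pass <- 0
  for (i in 1:60) {
    tb <- simulate_traits(tree, sim_config(n_tips = 60, body_mode = "iid"))
    z <- backsolve(L, tb$testes - (-2 + 0.67 * tb$body), transpose = TRUE)
    pass <- pass + (stats::ks.test(z, "pnorm")$p.value > 0.01)
  }
  expect_gte(pass / 60, 0.95)
})

test_that("simulate_dataset is byte-deterministic in its config", {
  cfg <- sim_config(n_tips = 25, seed = 77,
                    trend = list(category = "M", coef = -0.5))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$table$testes, b$table$testes)
  expect_identical(a$true_pathwise, b$true_pathwise)
})
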