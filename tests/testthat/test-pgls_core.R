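test_that("phylo_covariance reads shared path lengths off the tree", {
  V <- phylo_covariance(tree3())
  expect_equal(unname(V[c("A", "B", "C"), c("A", "B", "C")]),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3))
  # star tree: diagonal
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1):0;")
  expect_equal(unname(phylo_covariance(star)), diag(4))
  expect_error(phylo_covariance(tree3(), c("A", "Z")), "unknown tip")
})

test_that("phylo_covariance equals a brute-force double traversal", {
  set.seed(7)
  tr <- random_tree(50)
  expect_equal(phylo_covariance(tr), brute_vcv(tr), tolerance = 1e-10)
})

test_that("gls_fit reduces to OLS on a star tree", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1):0;")
  set.seed(2)
  tab <- toy_table(star, noise = rnorm(6, 0, 0.2))
  f <- gls_fit(testes ~ body, tab, star)
  ols <- lm(testes ~ body, tab)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-8)
  # any sigma * identity leaves the coefficients unchanged
  star5 <- star; star5$edge.length <- star5$edge.length * 5
  f5 <- gls_fit(testes ~ body, tab, star5)
  expect_equal(f5$coefficients, f$coefficients, tolerance = 1e-8)
})

test_that("gls_fit matches direct matrix arithmetic on the 3-tip example", {
  tr <- tree3()
  tab <- data.frame(species = c("A", "B", "C"), testes = c(1, 2, 3),
                    body = c(0, 1, 2))
  expect_error(gls_fit(testes ~ body, tab, tr), "too few")
  # fit intercept-only so n > p + 1 holds; oracle by hand matrices
  f <- gls_fit(testes ~ 1, tab, tr)
  V <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3)
  ones <- rep(1, 3); y <- c(1, 2, 3)
  bhat <- solve(t(ones) %*% solve(V) %*% ones) %*% t(ones) %*% solve(V) %*% y
  expect_equal(unname(f$coefficients), as.vector(bhat), tolerance = 1e-10)
  s2 <- as.numeric(t(y - ones %*% bhat) %*% solve(V) %*% (y - ones %*% bhat)) / 3
  expect_equal(f$sigma2, s2, tolerance = 1e-10)
  expect_equal(f$logLik, dense_mvn_loglik(y, as.vector(bhat) * ones, s2 * V),
               tolerance = 1e-8)
})

test_that("gls_fit log-likelihood equals dense MVN density on random trees", {
  set.seed(12)
  for (i in 1:10) {
    tr <- random_tree(sample(6:20, 1))
    n <- length(tr$tip.label)
    tab <- toy_table(tr, noise = rnorm(n, 0, 0.3))
    f <- gls_fit(testes ~ body, tab, tr)
    V <- phylo_covariance(tr, tab$species)
    X <- cbind(1, tab$body)
    mu <- as.vector(X %*% f$coefficients)
    expect_equal(f$logLik, dense_mvn_loglik(tab$testes, mu, f$sigma2 * V),
                 tolerance = 1e-6)
  }
})

test_that("gls_fit recovers the generating slope without bias", {
  set.seed(41)
  slopes <- replicate(60, {
    sim <- simulate_dataset(sim_config(n_tips = 120))
    gls_fit(testes ~ body, sim$table, sim$tree)$coefficients[["body"]]
  })
  expect_lt(abs(mean(slopes) - 0.67), 0.02)
})

test_that("design-matrix faults are reported, not silently absorbed", {
  set.seed(4)
  tr <- random_tree(10)
  tab <- toy_table(tr, noise = rnorm(10, 0, 0.1))
  tab$body2 <- tab$body * 2  # exactly collinear
  expect_error(gls_fit(testes ~ body + body2, tab, tr), "collinear")
})

test_that("likelihood_ratio_test computes D with its chi-squared p-value", {
  set.seed(15)
  tr <- random_tree(25)
  tab <- toy_table(tr, noise = rnorm(25, 0, 0.3))
  tab$z <- rnorm(25)
  full <- gls_fit(testes ~ body + z, tab, tr)
  nested <- gls_fit(testes ~ body, tab, tr)
  lrt <- likelihood_ratio_test(full, nested)
  expect_equal(lrt$D, 2 * (full$logLik - nested$logLik))
  expect_equal(lrt$df, 1)
  expect_gte(lrt$D, 0)
  expect_equal(lrt$p, pchisq(lrt$D, 1, lower.tail = FALSE))
  # identical models: D = 0, p = 1
  self <- likelihood_ratio_test(full, full)
  expect_equal(self$D, 0)
  expect_equal(self$p, 1)
  # D = 16.094 arises from log-likelihoods -10 and -18.047
  fake_full <- full; fake_full$logLik <- -10
  fake_nested <- nested; fake_nested$logLik <- -18.047
  expect_equal(likelihood_ratio_test(fake_full, fake_nested)$D, 16.094)
  # different data are not comparable
  tr2 <- random_tree(25)
  other <- gls_fit(testes ~ body, toy_table(tr2, noise = rnorm(25, 0, .3)), tr2)
  expect_error(likelihood_ratio_test(full, other), "different trees|different data")
})

test_that("LRT type-I error is calibrated under the null", {
  set.seed(62)
  tr <- random_tree(40)
  rej <- replicate(400, {
    tab <- toy_table(tr)
    # simulate under the nested model: z is pure noise
    eps <- as.vector(t(chol(phylo_covariance(tr) * 0.05)) %*% rnorm(40))
    tab$testes <- tab$testes + eps
    tab$z <- rnorm(40)
    lrt <- likelihood_ratio_test(gls_fit(testes ~ body + z, tab, tr),
                                 gls_fit(testes ~ body, tab, tr))
    lrt$p < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.08)
})

test_that("r2 is bounded and extra predictors never reduce the log-likelihood", {
  set.seed(5)
  tr <- random_tree(30)
  tab <- toy_table(tr, noise = rnorm(30, 0, 0.3))
  tab$z <- rnorm(30)
  f1 <- gls_fit(testes ~ body, tab, tr)
  f2 <- gls_fit(testes ~ body + z, tab, tr)
  expect_gte(f1$r2, 0); expect_lte(f1$r2, 1)
  expect_gte(f2$logLik, f1$logLik - 1e-8)
})

test_that("predict evaluates the linear predictor (and inverts the log scale)", {
  set.seed(6)
  tr <- random_tree(12)
  tab <- toy_table(tr, noise = rnorm(12, 0, 0.1))
  f <- gls_fit(testes ~ body, tab, tr)
  pr <- predict(f, data.frame(body = 2))
  expect_equal(pr, unname(f$coefficients[1] + 2 * f$coefficients[2]))
  pt <- predict_trait(f, body = 2)
  expect_equal(pt$grams, 10^pt$log10)
})
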