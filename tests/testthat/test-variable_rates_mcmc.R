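test_that("vr_loglik reduces to the fixed-tree GLS likelihood when all r = 1", {
  set.seed(3)
  sim <- simulate_dataset(sim_config(n_tips = 20, seed = 3))
  f <- gls_fit(testes ~ body, sim$table, sim$tree)
  E <- nrow(sim$tree$edge)
  ll <- vr_loglik(list(beta = unname(f$coefficients), sigma2 = f$sigma2,
                       r = rep(1, E)),
                  testes ~ body, sim$table, sim$tree)
  expect_equal(ll, f$logLik, tolerance = 1e-8)
})

test_that("vr_loglik matches a dense MVN oracle and is rescaling-invariant", {
  set.seed(9)
  sim <- simulate_dataset(sim_config(n_tips = 10, seed = 9))
  ptree <- ape::reorder.phylo(sim$tree, "postorder")
  E <- nrow(ptree$edge)
  r <- exp(rnorm(E, 0, 0.7))
  beta <- c(-1.8, 0.6); s2 <- 0.07
  scaled <- ptree; scaled$edge.length <- ptree$edge.length * r
  V <- phylo_covariance(scaled, sim$table$species)
  mu <- beta[1] + beta[2] * sim$table$body
  oracle <- dense_mvn_loglik(sim$table$testes, mu, s2 * V)
  ll <- vr_loglik(list(beta = beta, sigma2 = s2, r = r),
                  testes ~ body, sim$table, sim$tree)
  expect_equal(ll, oracle, tolerance = 1e-6)
  # (r -> c r, sigma2 -> sigma2 / c) leaves the likelihood unchanged
  for (cc in c(2, 7.5, 0.31)) {
    ll2 <- vr_loglik(list(beta = beta, sigma2 = s2 / cc, r = cc * r),
                     testes ~ body, sim$table, sim$tree)
    expect_equal(ll2, ll, tolerance = 1e-10)
  }
})

test_that("chains are deterministic under a fixed seed and bookkeeping holds", {
  sim <- simulate_dataset(sim_config(n_tips = 15, seed = 2))
  st <- vr_settings(iterations = 4000, burnin = 1000, thin = 10)
  a <- suppressWarnings(run_chain(testes ~ body, sim$table, sim$tree, st, seed = 5))
  b <- suppressWarnings(run_chain(testes ~ body, sim$table, sim$tree, st, seed = 5))
  expect_identical(a$beta, b$beta)
  expect_identical(a$r, b$r)
  expect_equal(length(a$sigma2), (4000 - 1000) / 10)  # trace-length contract
})

test_that("prior-only sampling recovers the activation probability and the sigma2 prior", {
  sim <- simulate_dataset(sim_config(n_tips = 25, seed = 4))
  tr <- suppressWarnings(run_chain(
    testes ~ body, sim$table, sim$tree,
    vr_settings(iterations = 30000, burnin = 3000, thin = 10),
    power = 0, seed = 11))
  E <- nrow(tr$tree$edge)
  # activation: each of the 2E scalar sites is Bernoulli(p_active) a priori
  frac <- tr$n_active / (2 * E)
  se <- sd(frac) / sqrt(ess_imse(as.numeric(tr$n_active)))
  expect_lt(abs(mean(frac) - tr$priors$p_active), 3 * se + 1e-3)
  # sigma_b^2 ~ half-Cauchy(1): check quantile coverage at the theoretical
  # quartiles (the prior has no finite moments)
  for (q in c(0.25, 0.5, 0.75)) {
    hit <- tr$sigma2 <= tan(pi * q / 2)
    se_q <- sd(hit) / sqrt(ess_imse(as.numeric(hit)))
    expect_lt(abs(mean(hit) - q), 3 * se_q + 5e-3)
  }
  # beta samples its wide normal prior
  expect_lt(abs(sd(tr$beta[, 1]) - tr$priors$beta_sd) / tr$priors$beta_sd, 0.25)
})

test_that("posterior coefficients agree with GLS on homogeneous-rate data", {
  ok <- 0
  for (s in 1:5) {
    sim <- simulate_dataset(sim_config(n_tips = 40, seed = 100 + s))
    f <- gls_fit(testes ~ body, sim$table, sim$tree)
    tr <- suppressWarnings(run_chain(
      testes ~ body, sim$table, sim$tree,
      vr_settings(iterations = 12000, burnin = 4000, thin = 10), seed = s))
    post_mean <- mean(tr$beta[, "body"])
    post_sd <- sd(tr$beta[, "body"])
    ok <- ok + (abs(post_mean - f$coefficients[["body"]]) < 2 * post_sd)
  }
  expect_gte(ok, 4)
})

test_that("a symmetric proposal with unit posterior ratio is always accepted", {
  # Metropolis-Hastings identity, exercised through the kernel: with power 0
  # and a degenerate prior-ratio-1 move (sigma step so small the prior ratio
  # is ~1), acceptance approaches 1
  sim <- simulate_dataset(sim_config(n_tips = 10, seed = 6))
  st <- vr_settings(iterations = 2000, burnin = 100, thin = 5,
                    sigma_step = 1e-8, beta_step = 1e-8, n_rj = 0, n_scalar = 0)
  tr <- suppressWarnings(run_chain(testes ~ body, sim$table, sim$tree, st,
                                   power = 0, seed = 2))
  expect_gt(tr$accept[["beta"]], 0.99)
  expect_gt(tr$accept[["sigma2"]], 0.99)
})

test_that("ess_imse tracks the effective size of autocorrelated series", {
  set.seed(14)
  x <- rnorm(5000)
  expect_gt(ess_imse(x), 2500)  # i.i.d.: close to n
  rho <- 0.9
  y <- as.numeric(stats::filter(rnorm(5000), rho, method = "recursive"))
  e <- ess_imse(y)
  # AR(1): true ESS = n (1 - rho) / (1 + rho) ~ 263
  expect_gt(e, 100); expect_lt(e, 600)
  if (requireNamespace("coda", quietly = TRUE)) {
    expect_lt(abs(e - coda::effectiveSize(y)) / coda::effectiveSize(y), 0.5)
  }
})

test_that("Px counts the minority side of zero", {
  expect_equal(compute_px(c(-0.1, 0.2, 0.3, 0.4)), 0.25)
  expect_equal(compute_px(c(0.1, 0.2)), 0)
  expect_equal(compute_px(c(-2, -1, 1, 2)), 0.5)
  expect_error(compute_px(numeric(0)), "no posterior draws")
})

test_that("Pxdiff is the Px of paired differences with its degenerate convention", {
  a <- c(1, 2, 3, 4); b <- c(0.5, 1, 2, 3)
  d <- compute_px_diff(a, b)
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "different"))
  same <- compute_px_diff(a, a)
  expect_equal(as.numeric(same), 0.5)
  expect_true(attr(same, "degenerate"))
  expect_false(attr(same, "different"))
  expect_error(compute_px_diff(a, b[1:3]), "length")
})

test_that("Pxdiff separates genuinely different class slopes", {
  # two classes with slopes differing by 0.3: the posterior distribution of
  # the interaction coefficient rarely crosses zero
  hits <- 0
  for (s in 1:3) {
    sim <- simulate_dataset(sim_config(
      n_tips = 150, seed = 200 + s,
      intercepts = c(birds = -2, mammals = -2),
      slopes = c(birds = 0.52, mammals = 0.82), body_mode = "iid"))
    tr <- suppressWarnings(run_chain(
      testes ~ body * class, sim$table, sim$tree,
      vr_settings(iterations = 10000, burnin = 3000, thin = 10), seed = s))
    slope_birds <- tr$beta[, "body"]
    slope_mamm <- tr$beta[, "body"] + tr$beta[, "body:classmammals"]
    hits <- hits + (compute_px_diff(slope_mamm, slope_birds) < 0.05)
  }
  expect_gte(hits, 2)
})
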