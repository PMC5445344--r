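test_that("power ladder spans [0,1], strictly increasing, endpoints present", {
  for (K in c(2, 5, 11, 21)) {
    b <- power_ladder(K)
    expect_length(b, K)
    expect_equal(b[1], 0)
    expect_equal(b[K], 1)
    expect_true(all(diff(b) > 0))
  }
})

test_that("at beta = 0 the sampler reproduces the prior", {
  tr <- mh_sample(function(x) 0, prior = 5, init = 0.3, beta = 0,
                  iterations = 8000, seed = 9)
  keep <- tr$samples[saxdiv:::trace_keep(tr), 1]
  ess <- effective_size(keep)
  mc_se <- sd(keep) / sqrt(ess)
  expect_lt(abs(mean(keep) - 0.2), 3 * mc_se)
})

test_that("at beta = 1 the conjugate pure-birth posterior mean is recovered", {
  # L = lambda^k exp(-lambda T), prior Exp(alpha): posterior Gamma(k+1, T+alpha)
  k <- 3; TT <- 10; alpha <- 1
  tr <- mh_sample(function(x) k * log(x[1]) - x[1] * TT, prior = alpha,
                  init = 0.5, beta = 1, iterations = 8000, seed = 4)
  keep <- tr$samples[saxdiv:::trace_keep(tr), 1]
  ess <- effective_size(keep)
  mc_se <- sd(keep) / sqrt(ess)
  expect_lt(abs(mean(keep) - (k + 1) / (TT + alpha)), 3 * mc_se)
})

test_that("the sampler is deterministic given its seed", {
  a <- mh_sample(function(x) -sum(x), prior = c(1, 1), init = c(1, 1),
                 beta = 1, iterations = 200, seed = 42)
  b <- mh_sample(function(x) -sum(x), prior = c(1, 1), init = c(1, 1),
                 beta = 1, iterations = 200, seed = 42)
  expect_identical(a$samples, b$samples)
  expect_identical(a$loglik, b$loglik)
})

test_that("TI reproduces the conjugate marginal likelihood and is ladder-stable", {
  # exact logML = log(alpha) + log(k!) - (k+1) log(T+alpha); k=1, T=2.5,
  # alpha=1 gives -2 log(3.5)
  exact <- -2 * log(3.5)
  run_ti <- function(K, seed) {
    ladder <- power_ladder(K)
    traces <- lapply(seq_along(ladder), function(i)
      mh_sample(function(x) log(x[1]) - 2.5 * x[1], prior = 1, init = 0.5,
                beta = ladder[i], iterations = 6000,
                seed = seed + i))
    thermodynamic_logml(traces)
  }
  t11 <- run_ti(11, 100)
  expect_lt(abs(t11$logml - exact), 0.05)
  # flat likelihood: logML = log c exactly
  ladder <- power_ladder(5)
  traces <- lapply(seq_along(ladder), function(i)
    mh_sample(function(x) log(3), prior = 1, init = 1, beta = ladder[i],
              iterations = 500, seed = i))
  expect_equal(thermodynamic_logml(traces)$logml, log(3), tolerance = 1e-12)
  # finer ladder moves the estimate by less than rough MC error
  t21 <- run_ti(21, 500)
  expect_lt(abs(t21$logml - t11$logml), 0.05)
  # Jensen bound: logML <= max observed loglik
  expect_lte(t11$logml, max(vapply(seq_along(t11$ladder), function(i)
    max(t11$means), numeric(1))) + 1e-9)
})

test_that("thermodynamic_logml demands complete converged ladders", {
  tr1 <- mh_sample(function(x) 0, 1, 1, 0.5, 100, seed = 1)
  tr2 <- mh_sample(function(x) 0, 1, 1, 1.0, 100, seed = 2)
  expect_error(thermodynamic_logml(list(tr1, tr2)), "beta = 0")
})

test_that("Bayes factors use the 2 ln scale and are antisymmetric", {
  expect_equal(as.numeric(bayes_factor(-1, -1)), 0)
  expect_equal(as.numeric(bayes_factor(-660, -662.5)), 5)
  for (i in 1:10) {
    a <- rnorm(1, -700, 10); b <- rnorm(1, -700, 10)
    expect_equal(as.numeric(bayes_factor(a, b)),
                 -as.numeric(bayes_factor(b, a)))
  }
  expect_identical(attr(bayes_factor(-660, -666), "interpretation"),
                   "very strong")
})

test_that("HPD: constant traces, normal quantiles, brute-force equivalence", {
  expect_equal(hpd_interval(rep(2.5, 200)), c(2.5, 2.5))
  set.seed(8)
  z <- rnorm(1e5)
  h <- hpd_interval(z, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
  for (i in 1:200) {
    x <- switch(1 + i %% 3, rnorm(50), rexp(50), runif(50))
    expect_equal(hpd_interval(x, 0.9), hpd_brute(x, 0.9))
  }
})

test_that("tree-set TI averages per-tree marginal likelihoods reproducibly", {
  tr <- sim_bd_tree(0.25, 0, list(taxa = 25), 1, seed = 21)
  model <- regime_model(list(list(clade = NULL, process = "PB", link = "a",
                                  rho = 1)))
  one <- treeset_logml(tr, model, power_ladder(6), iterations = 600, seed = 3)
  expect_length(one$per_tree, 1)
  expect_equal(one$logml, one$per_tree[1])
  # same master seed: identical end-to-end
  again <- treeset_logml(tr, model, power_ladder(6), iterations = 600, seed = 3)
  expect_identical(one$per_tree, again$per_tree)
  expect_identical(one$pooled, again$pooled)

  # jittered copies of one tree stay within MC error of the single-tree value
  jit <- lapply(1:5, function(i) {
    t2 <- tr
    t2$edge.length <- t2$edge.length * exp(rnorm(1, 0, 0.001))
    t2
  })
  class(jit) <- "multiPhylo"
  many <- treeset_logml(jit, model, power_ladder(6), iterations = 600, seed = 3)
  expect_lt(abs(many$logml - one$logml), 0.5)
})

test_that("pooled posterior recovers the generating Yule rate across trees", {
  model <- regime_model(list(list(clade = NULL, process = "PB", link = "a",
                                  rho = 1)))
  trees <- lapply(1:20, function(i)
    sim_bd_tree(0.2, 0, list(taxa = 100), 1, seed = 400 + i))
  class(trees) <- "multiPhylo"
  res <- treeset_logml(trees, model, power_ladder(6), iterations = 800,
                       seed = 11)
  pooled_mean <- mean(res$pooled[, "lambda.a"])
  expect_gte(pooled_mean, 0.15)
  expect_lte(pooled_mean, 0.25)
})

test_that("compare_regime_models ranks with BF 0 for the best model", {
  tr <- sim_bd_tree(0.3, 0, list(taxa = 20), 1, seed = 31)
  m_pb <- regime_model(list(list(clade = NULL, process = "PB", link = "a",
                                 rho = 1)))
  m_bd <- regime_model(list(list(clade = NULL, process = "BD", link = "a",
                                 rho = 1)))
  tab <- compare_regime_models(tr, list(PB = m_pb, BD = m_bd),
                               ladder = power_ladder(6), iterations = 500,
                               seed = 5)
  expect_equal(tab$BF[1], 0)
  expect_true(all(tab$BF >= 0))
})
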