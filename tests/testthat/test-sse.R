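test_that("single absorbing state reduces MuSSE to the birth-death likelihood", {
  tr <- sim_bd_tree(0.3, 0.1, list(taxa = 20), 1, seed = 51)
  st <- tip_states(setNames(rep(0, 20), tr$tip.label), rho = 1, k = 2)
  mp <- musse_params(c(0.3, 0.7), c(0.1, 0.2), matrix(0, 2, 2))
  a <- musse_loglik(tr, st, mp)
  b <- bd_loglik(branching_times(tr), bd_params(0.3, 0.1, 1))
  expect_equal(a, b, tolerance = 1e-7)
})

test_that("MuSSE pruning matches a monolithic hand-assembled ODE solve", {
  skip_if_not_installed("deSolve")
  tr <- tree3()
  lambda <- c(0.3, 0.5); mu <- c(0.1, 0.05)
  q <- matrix(c(0, 0.07, 0.04, 0), 2, 2, byrow = TRUE)
  rho <- c(0.9, 0.7)
  for (comb in list(c(A = 0, B = 1, C = 0), c(A = 1, B = 1, C = 0),
                    c(A = 0, B = 0, C = 1))) {
    st <- tip_states(comb, rho = rho)
    a <- musse_loglik(tr, st, musse_params(lambda, mu, q))
    b <- musse3_oracle(comb, lambda, mu, q, rho)
    expect_lt(abs(a - b), 1e-8)
  }
})

test_that("state-independent MuSSE factorizes into birth-death times Mk", {
  skip_if_not_installed("deSolve")
  set.seed(3)
  for (rep in 1:20) {
    tr <- sim_bd_tree(0.25, 0.05, list(taxa = 30), 1, seed = 4000 + rep)
    q01 <- runif(1, 0.02, 0.1); q10 <- runif(1, 0.02, 0.1)
    Q <- matrix(c(0, q01, q10, 0), 2, 2, byrow = TRUE)
    st <- sim_mk(tr, Q, seed = rep, rho = 0.8)
    lam <- runif(1, 0.15, 0.4); mu <- runif(1, 0, 0.1)
    a <- musse_loglik(tr, st, musse_params(c(lam, lam), c(mu, mu), Q))
    b <- bd_loglik(branching_times(tr), bd_params(lam, mu, 0.8)) +
      mk_fitzjohn_oracle(tr, st$states - 1, Q)
    expect_lt(abs(a - b), 1e-6)
  }
})

test_that("GeoSSE pruning matches its monolithic oracle and A/B symmetry", {
  skip_if_not_installed("deSolve")
  tr <- tree3()
  p <- list(sA = 0.3, sB = 0.2, sAB = 0.05, xA = 0.07, xB = 0.03,
            dA = 0.1, dB = 0.04)
  rho <- c(0.5, 0.7, 0.7)
  for (comb in list(c(A = "A", B = "AB", C = "B"),
                    c(A = "AB", B = "AB", C = "A"),
                    c(A = "B", B = "B", C = "AB"))) {
    st <- tip_states(comb, rho = rho)
    a <- geosse_loglik(tr, st, do.call(geosse_params, p))
    b <- geosse3_oracle(comb, p, rho)
    expect_lt(abs(a - b), 1e-8)
  }
  # symmetric parameters: swapping A and B on all tips leaves logL unchanged
  ps <- geosse_params(0.3, 0.3, 0.05, 0.07, 0.07, 0.1, 0.1)
  swap <- c(A = "B", B = "A", AB = "AB")
  tr2 <- sim_bd_tree(0.3, 0, list(taxa = 15), 1, seed = 61)
  st1 <- sim_mk(tr2, saxdiv:::null_chain_matrix("geosse", c(0.1, 0.1, 0.05, 0.05)),
                seed = 2, geo = TRUE, rho = c(0.6, 0.6, 0.8))
  lab1 <- GEOSSE <- c("A", "B", "AB")[st1$states]
  st1v <- setNames(lab1, names(st1$states))
  st2v <- setNames(unname(swap[st1v]), names(st1v))
  l1 <- geosse_loglik(tr2, tip_states(st1v, rho = c(0.6, 0.6, 0.8)), ps)
  l2 <- geosse_loglik(tr2, tip_states(st2v, rho = c(0.6, 0.6, 0.8)), ps)
  expect_lt(abs(l1 - l2), 1e-10)
  # and the full relabeling symmetry under parameter swap
  pa <- geosse_params(0.3, 0.2, 0.05, 0.07, 0.03, 0.1, 0.04)
  pb <- geosse_params(0.2, 0.3, 0.05, 0.03, 0.07, 0.04, 0.1)
  l3 <- geosse_loglik(tr2, tip_states(st1v, rho = c(0.6, 0.6, 0.8)), pa)
  l4 <- geosse_loglik(tr2, tip_states(st2v, rho = c(0.6, 0.6, 0.8)), pb)
  expect_lt(abs(l3 - l4), 1e-10)
})

test_that("sampling fractions of 1 recover the complete-sampling likelihood", {
  tr <- sim_bd_tree(0.3, 0.05, list(taxa = 20), 1, seed = 71)
  Q <- matrix(c(0, 0.05, 0.05, 0), 2, 2, byrow = TRUE)
  st_full <- sim_mk(tr, Q, seed = 3, rho = 1)
  st_near <- tip_states(setNames(st_full$states - 1, names(st_full$states)),
                        rho = 1 - 1e-9)
  mp <- musse_params(c(0.3, 0.4), c(0.05, 0.1), Q)
  expect_lt(abs(musse_loglik(tr, st_full, mp) - musse_loglik(tr, st_near, mp)),
            1e-5)
})

test_that("likelihood is invariant to tip-label order in the state table", {
  tr <- sim_bd_tree(0.3, 0, list(taxa = 15), 1, seed = 81)
  Q <- matrix(c(0, 0.05, 0.05, 0), 2, 2, byrow = TRUE)
  st <- sim_mk(tr, Q, seed = 4)
  perm <- sample(seq_along(st$states))
  st2 <- tip_states(setNames((st$states - 1)[perm], names(st$states)[perm]),
                    rho = 1)
  mp <- musse_params(c(0.2, 0.5), c(0.02, 0.1), Q)
  expect_equal(musse_loglik(tr, st, mp), musse_loglik(tr, st2, mp),
               tolerance = 1e-12)
})

test_that("constraint resolution counts free parameters and rejects nonsense", {
  pn <- sse_param_names("geosse")
  rc <- resolve_constraints <- saxdiv:::resolve_constraints
  full <- rc(pn, constraint_spec())
  expect_length(full$free, 7)
  one <- rc(pn, constraint_spec(zero = "xA"))
  expect_length(one$free, 6)
  eq <- rc(pn, constraint_spec(equal = list(c("sA", "sB")), zero = "sAB"))
  expect_length(eq$free, 5)
  # zero propagates through an equality group
  z <- rc(pn, constraint_spec(equal = list(c("xA", "xB")), zero = "xA"))
  expect_length(z$free, 5)
  expect_error(rc(pn, constraint_spec(zero = "bogus")), "unknown parameter")
})

test_that("the GeoSSE model space has 36 constrained models plus the full model", {
  mods <- enumerate_geosse_models()
  expect_length(mods, 37)
  expect_true("full" %in% names(mods))
  expect_length(setdiff(names(mods), "full"), 36)
  pn <- sse_param_names("geosse")
  sigs <- vapply(mods, function(m) saxdiv:::constraint_signature(pn, m),
                 character(1))
  expect_false(any(duplicated(sigs)))
  # contains pure birth in region A with everything else free
  target <- saxdiv:::constraint_signature(pn, constraint_spec(zero = "xA"))
  expect_true(target %in% sigs)
  # free-parameter counts: full has 7, all others fewer
  kfree <- vapply(mods, function(m)
    length(saxdiv:::resolve_constraints(pn, m)$free), numeric(1))
  expect_equal(kfree[["full"]], 7)
  expect_true(all(kfree[names(kfree) != "full"] < 7))
})

test_that("degenerate single-state ML fit recovers the analytic Yule rate", {
  tr <- sim_bd_tree(0.2, 0, list(taxa = 40), 1, seed = 91)
  st <- tip_states(setNames(rep(0, 40), tr$tip.label), rho = 1, k = 1)
  f <- fit_ml(tr, st, "musse", constraint_spec(zero = "mu0"),
              starts = 1, maxit = 800)
  times <- branching_times(tr)
  lam_hat <- (length(times) - 1) / (sum(times) + times[1])
  expect_equal(f$par[["lambda0"]], lam_hat, tolerance = 1e-4)
  expect_equal(f$k, 1)
})

test_that("nested constrained fits never beat the warm-started full model", {
  mp <- musse_params(c(0.1, 0.25), c(0.03, 0.03),
                     matrix(c(0, 0.03, 0.03, 0), 2, 2, byrow = TRUE))
  sim <- sim_sse_tree("bisse", mp, list(taxa = 60), rho = 1, seed = 101)
  null <- constraint_spec(equal = list(c("lambda0", "lambda1"),
                                       c("mu0", "mu1")))
  f0 <- fit_ml(sim$tree, sim$states, "bisse", null, starts = 1, maxit = 400)
  f1 <- fit_ml(sim$tree, sim$states, "bisse", starts = 1, maxit = 400,
               init = f0$par)
  expect_lte(f0$logLik, f1$logLik + 1e-6)
})

test_that("AIC tables carry weights that sum to one and flag good fits", {
  mk <- function(ll, k) list(logLik = ll, k = k)
  tab <- aic_table(list(a = mk(-100, 2), b = mk(-100, 2)))
  expect_equal(tab$weight, c(0.5, 0.5))
  # dAIC of 2 means a weight ratio of e
  tab2 <- aic_table(list(a = mk(-100, 2), b = mk(-101, 2)))
  expect_equal(tab2$weight[1] / tab2$weight[2], exp(1), tolerance = 1e-12)
  set.seed(5)
  tab3 <- aic_table(lapply(1:8, function(i) mk(rnorm(1, -300, 5),
                                               sample(2:7, 1))))
  expect_equal(sum(tab3$weight), 1, tolerance = 1e-12)
  expect_equal(tab3$dAIC[1], 0)
  expect_true(all(tab3$good_fit == (tab3$dAIC < 6)))
})

test_that("SSE MCMC respects constraints and matches the conjugate degenerate case", {
  tr <- sim_bd_tree(0.2, 0, list(taxa = 30), 1, seed = 111)
  st <- tip_states(setNames(rep(0, 30), tr$tip.label), rho = 1, k = 1)
  mc <- mcmc_sse(tr, st, "musse", constraint_spec(zero = "mu0"),
                 iterations = 4000, burn_in = 400, seed = 6)
  # a parameter constrained to zero stays exactly zero
  expect_identical(unname(mc$mean[["mu0"]]), 0)
  expect_equal(unname(mc$hpd[, "mu0"]), c(0, 0))
  # conjugate check: PB likelihood lambda^(n-2) e^(-lambda T) with the
  # exponential prior the sampler itself uses
  times <- branching_times(tr)
  n <- length(times) + 1
  TT <- sum(times) + times[1]
  r_hat <- (n - 2) / sum(tr$edge.length)
  alpha <- 1 / (2 * r_hat)
  post_mean <- (n - 2 + 1) / (TT + alpha)
  keep <- mc$trace$samples[saxdiv:::trace_keep(mc$trace), 1]
  mc_se <- sd(keep) / sqrt(effective_size(keep))
  expect_lt(abs(mean(keep) - post_mean), 3 * mc_se)
})
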