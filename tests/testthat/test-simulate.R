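test_that("taxa-stopped Yule simulation yields exactly n sampled tips", {
  for (i in 1:5) {
    tr <- sim_bd_tree(0.3, 0, list(taxa = 50), 1, seed = 5000 + i)
    expect_length(tr$tip.label, 50)
    expect_silent(validate_ultrametric(tr))
  }
})

test_that("age-stopped Yule mean tip count matches the branching-process mean", {
  lambda <- 0.5; age <- 3
  counts <- vapply(1:600, function(i)
    length(sim_bd_tree(lambda, 0, list(age = age), 1,
                       seed = 6000 + i)$tip.label), numeric(1))
  # E[N] = 2 e^(lambda t) without conditioning; conditioning on both crown
  # lineages surviving is vacuous for a Yule process
  expect_lt(abs(mean(counts) - 2 * exp(lambda * age)),
            3 * sd(counts) / sqrt(length(counts)))
})

test_that("incomplete sampling retains a Binomial number of tips", {
  kept <- vapply(1:100, function(i)
    length(sim_bd_tree(0.4, 0, list(taxa = 200), rho = 0.5,
                       seed = 7000 + i)$tip.label), numeric(1))
  expect_lt(abs(mean(kept) - 100), 3 * sd(kept) / sqrt(length(kept)))
  expect_true(all(kept <= 200))
})

test_that("simulators replay byte-identically under a fixed seed", {
  a <- sim_bd_tree(0.3, 0.1, list(taxa = 30), 0.8, seed = 12)
  b <- sim_bd_tree(0.3, 0.1, list(taxa = 30), 0.8, seed = 12)
  expect_identical(write_newick(a), write_newick(b))
  s1 <- sim_sse_tree("bisse",
                     musse_params(c(0.2, 0.4), c(0.05, 0.05),
                                  matrix(c(0, 0.05, 0.05, 0), 2, 2)),
                     list(taxa = 40), seed = 13)
  s2 <- sim_sse_tree("bisse",
                     musse_params(c(0.2, 0.4), c(0.05, 0.05),
                                  matrix(c(0, 0.05, 0.05, 0), 2, 2)),
                     list(taxa = 40), seed = 13)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))
  expect_identical(s1$states$states, s2$states$states)
})

test_that("Markov characters: frozen chain, stationarity, change counts", {
  tr <- sim_bd_tree(0.3, 0, list(taxa = 20), 1, seed = 14)
  # Q = 0: every tip inherits the root state
  st0 <- sim_mk(tr, matrix(0, 2, 2), root_state = 0, seed = 1)
  expect_true(all(st0$states == 1))
  # star-like saturation: symmetric chain run far past mixing is 50/50
  star <- ape::read.tree(text = paste0("(",
    paste(sprintf("t%d:100", 1:1000), collapse = ","), ");"))
  star <- ape::multi2di(star)
  star$edge.length[star$edge.length == 0] <- 1e-9
  stS <- sim_mk(star, matrix(c(0, 0.1, 0.1, 0), 2, 2), seed = 2)
  p1 <- mean(stS$states == 2)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 1000))
  # expected changes per branch ~ rate x length in aggregate: on a long
  # two-tip tree the number of 0->1 boundaries reflects the rates
  counts <- vapply(1:300, function(i) {
    st <- sim_mk(read_newick(text = "(A:5,B:5);"),
                 matrix(c(0, 0.2, 0.2, 0), 2, 2), root_state = 0,
                 seed = 8000 + i)
    sum(st$states - 1)
  }, numeric(1))
  # P(tip in state 1) = 0.5 (1 - e^(-2qt)) with q=0.2, t=5
  p_exp <- 0.5 * (1 - exp(-2 * 0.2 * 5))
  expect_lt(abs(mean(counts) / 2 - p_exp), 3 * sqrt(0.25 / 600))
})

test_that("shift trees mark the founding clade and enrich its tip share", {
  sh <- sim_shift_tree(bd_params(0.2, 0), list(age = 6, lambda = 0.5, mu = 0),
                       stop = list(age = 15), seed = 15, min_clade_tips = 2)
  expect_s3_class(sh$tree, "phylo")
  expect_gte(length(sh$clade_tips), 2)
  expect_true(all(sh$clade_tips %in% sh$tree$tip.label))
  expect_s3_class(sh$truth, "regime_model")
  # the shifted clade is a proper subset spanned by one MRCA
  sub <- extract_clade(sh$tree, clade_def("s", sh$clade_tips))
  expect_setequal(sub$tip.label, sh$clade_tips)
  expect_error(sim_shift_tree(bd_params(0.2, 0),
                              list(age = 30, lambda = 0.5, mu = 0),
                              stop = list(age = 15), seed = 1),
               "older than crown")

  # elevated-rate clades hold more tips than same-rate clades on average
  share <- function(ratio, seeds) {
    vapply(seeds, function(s) {
      sh <- sim_shift_tree(bd_params(0.2, 0),
                           list(age = 6, lambda = 0.2 * ratio, mu = 0),
                           stop = list(age = 15), seed = s,
                           min_clade_tips = 1)
      length(sh$clade_tips) / length(sh$tree$tip.label)
    }, numeric(1))
  }
  up <- share(2.5, 1:60)
  same <- share(1, 61:120)
  expect_gt(mean(up), mean(same))
})

test_that("joint SSE simulation collapses to plain birth-death with one state", {
  # state-independent BiSSE simulation: crown-age distribution matches the
  # plain simulator (two-sample KS)
  mp <- musse_params(c(0.35, 0.35), c(0.05, 0.05),
                     matrix(c(0, 0.05, 0.05, 0), 2, 2))
  a <- vapply(1:150, function(i)
    max(branching_times(sim_sse_tree("bisse", mp, list(taxa = 25),
                                     seed = 9000 + i)$tree)), numeric(1))
  b <- vapply(1:150, function(i)
    max(branching_times(sim_bd_tree(0.35, 0.05, list(taxa = 25), 1,
                                    seed = 9500 + i))), numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
})

test_that("GeoSSE simulation honours its event table", {
  # no dispersal, endemic root: the other region is unreachable
  gp <- geosse_params(0.4, 0.4, 0.1, 0, 0, 0, 0)
  s <- sim_sse_tree("geosse", gp, list(taxa = 30), seed = 16,
                    root_state = "A")
  expect_true(all(s$states$states == 1))
  # with dispersal every state occurs eventually
  gp2 <- geosse_params(0.3, 0.2, 0.05, 0.02, 0.02, 0.2, 0.2)
  s2 <- sim_sse_tree("geosse", gp2, list(taxa = 150), seed = 17)
  expect_setequal(unique(s2$states$states), 1:3)
})
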