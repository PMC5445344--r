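## Metropolis-Hastings sampling of diversification models, power-posterior
## thermodynamic integration (TI) for marginal likelihoods, Bayes factors
## on the 2*ln scale, HPD intervals, and tree-set averaging.

#' Power-posterior temperature ladder
#'
#' Ladder of inverse temperatures beta in [0, 1] placed at quantiles of a
#' Beta(alpha, 1) distribution, `beta_k = ((k-1)/(K-1))^(1/alpha)`: the
#' standard geometric-style schedule that concentrates rungs near the prior
#' (beta = 0), where the integrand changes fastest. Both endpoints are
#' always included.
#'
#' @param K Number of rungs (>= 2).
#' @param alpha Beta-distribution shape (default 0.3).
#' @return Strictly increasing numeric vector with `beta[1] = 0` and
#'   `beta[K] = 1`.
#' @export
power_ladder <- function(K = 11, alpha = 0.3) {
  if (K < 2) stop("need at least 2 rungs")
  ((seq_len(K) - 1) / (K - 1))^(1 / alpha)
}

#' Metropolis-Hastings sampling of a power posterior
#'
#' Samples `prior(theta) * L(theta)^beta` by single-component
#' multiplicative (log-scale sliding-window) proposals on each positive
#' rate parameter: `theta' = theta * exp(U)`, `U ~ Uniform(-w, w)`, with
#' the Hastings correction `theta'/theta`. Deterministic given `seed`.
#'
#' @param loglik Function of the parameter vector returning a
#'   log-likelihood.
#' @param prior Either a numeric vector of Exponential prior rates (one
#'   per parameter) or a function returning the log prior density.
#' @param init Initial parameter vector (positive).
#' @param beta Inverse temperature in [0, 1].
#' @param iterations Number of sweeps (every parameter updated once per
#'   sweep).
#' @param seed Integer seed.
#' @param window Half-width of the log-scale proposal window.
#' @param burn_in Number of initial sweeps flagged as burn-in in the
#'   returned trace (default 10%).
#' @return Object of class `mcmc_trace`: list with matrix `samples`
#'   (iterations x parameters), vectors `loglik` and `logprior`, and
#'   fields `beta`, `seed`, `burn_in`, `acceptance`.
#' @export
mh_sample <- function(loglik, prior, init, beta, iterations, seed,
                      window = 0.6, burn_in = ceiling(iterations / 10)) {
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (iterations < 1) stop("positive iteration count required")
  if (burn_in >= iterations) stop("burn-in must be smaller than iterations")
  logprior <- if (is.function(prior)) prior else {
    rates <- prior
    function(theta) sum(stats::dexp(theta, rate = rates, log = TRUE))
  }
  set.seed(seed)
  p <- length(init)
  theta <- as.numeric(init)
  ll <- loglik(theta)
  if (!is.finite(ll)) stop("non-finite initial likelihood")
  lp <- logprior(theta)
  samples <- matrix(NA_real_, iterations, p)
  ll_tr <- lp_tr <- numeric(iterations)
  n_acc <- 0L; n_prop <- 0L
  for (it in seq_len(iterations)) {
    for (j in seq_len(p)) {
      prop <- theta
      u <- runif(1, -window, window)
      prop[j] <- theta[j] * exp(u)
      ll_p <- loglik(prop)
      lp_p <- logprior(prop)
      # Hastings ratio for the multiplicative proposal: theta_j'/theta_j
      logr <- beta * (ll_p - ll) + (lp_p - lp) + u
      n_prop <- n_prop + 1L
      if (is.finite(logr) && log(runif(1)) < logr) {
        theta <- prop; ll <- ll_p; lp <- lp_p; n_acc <- n_acc + 1L
      }
    }
    samples[it, ] <- theta
    ll_tr[it] <- ll
    lp_tr[it] <- lp
  }
  structure(list(samples = samples, loglik = ll_tr, logprior = lp_tr,
                 beta = beta, seed = seed, burn_in = as.integer(burn_in),
                 acceptance = n_acc / n_prop),
            class = "mcmc_trace")
}

## Post-burn-in rows of a trace.
trace_keep <- function(trace) {
  idx <- seq.int(trace$burn_in + 1L, length(trace$loglik))
  idx
}

#' Effective sample size of a trace vector
#'
#' Initial-positive-sequence autocorrelation estimator: `n / (1 + 2 *
#' sum(acf))`, truncating at the first non-positive autocorrelation.
#'
#' @param x Numeric vector of (post-burn-in) samples.
#' @return Effective sample size.
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 3 || sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (a in ac) {
    if (a <= 0) break
    s <- s + a
  }
  n / (1 + 2 * s)
}

#' Thermodynamic-integration log marginal likelihood
#'
#' Trapezoidal integral over beta of the post-burn-in mean log-likelihood
#' of each rung's power-posterior trace. Requires traces at beta = 0 and
#' beta = 1.
#'
#' @param traces List of `mcmc_trace` objects, one per ladder rung.
#' @return List with `logml`, per-rung `means`, `ladder`, and per-rung
#'   effective sample sizes `ess`.
#' @export
thermodynamic_logml <- function(traces) {
  betas <- vapply(traces, function(tr) tr$beta, numeric(1))
  o <- order(betas)
  traces <- traces[o]; betas <- betas[o]
  if (abs(betas[1]) > 1e-12 || abs(betas[length(betas)] - 1) > 1e-12)
    stop("ladder must include beta = 0 and beta = 1")
  means <- vapply(traces, function(tr) mean(tr$loglik[trace_keep(tr)]), numeric(1))
  ess <- vapply(traces, function(tr) effective_size(tr$loglik[trace_keep(tr)]), numeric(1))
  K <- length(betas)
  logml <- sum(diff(betas) * (means[-K] + means[-1]) / 2)
  list(logml = logml, means = means, ladder = betas, ess = ess)
}

#' Bayes factor on the 2*ln scale
#'
#' `BF = 2 * (logml_a - logml_b)`. Positive values favour model a;
#' conventional interpretation thresholds (Kass & Raftery) are attached as
#' an attribute: 0-2 negligible, 2-6 positive, 6-10 strong, >10 very
#' strong.
#'
#' @param logml_a,logml_b Log marginal likelihoods.
#' @return Numeric Bayes factor (2*ln scale) with attribute
#'   `interpretation`.
#' @export
bayes_factor <- function(logml_a, logml_b) {
  if (!is.finite(logml_a) || !is.finite(logml_b)) stop("non-finite log marginal likelihood")
  bf <- 2 * (logml_a - logml_b)
  interp <- if (abs(bf) < 2) "negligible" else if (abs(bf) < 6) "positive"
            else if (abs(bf) < 10) "strong" else "very strong"
  structure(bf, interpretation = interp)
}

#' Highest posterior density interval
#'
#' Shortest interval containing `ceiling(mass * n)` of the sorted samples
#' (sliding-window algorithm); ties are broken by the lowest lower
#' endpoint.
#'
#' @param x Numeric vector of (post-burn-in) samples.
#' @param mass Posterior mass (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @export
hpd_interval <- function(x, mass = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) stop("empty trace")
  m <- ceiling(mass * n)
  xs <- sort(x)
  if (m >= n) return(c(xs[1], xs[n]))
  widths <- xs[seq.int(m, n)] - xs[seq.int(1, n - m + 1)]
  i <- which.min(widths)  # which.min returns the first (lowest lo) on ties
  c(xs[i], xs[i + m - 1])
}

#' Model comparison by TI across a posterior tree set
#'
#' Runs the full ladder of power-posterior chains for a regime model on
#' every tree of a set, averaging the per-tree log marginal likelihoods
#' (accounting for phylogenetic uncertainty) and pooling the post-burn-in
#' beta = 1 traces as the parameter posterior. Per-tree seeds are derived
#' deterministically from the master seed.
#'
#' @param trees A `multiPhylo` from [read_tree_set()] (or a single
#'   `phylo`).
#' @param model A [regime_model()].
#' @param ladder Ladder from [power_ladder()].
#' @param iterations MCMC sweeps per rung.
#' @param seed Master seed.
#' @param prior_rate Exponential prior rate applied to every rate
#'   parameter; default `NULL` sets the prior mean to 10x the crude Yule
#'   rate `(n - 2) / T` of each tree (T = total branch length).
#' @return List with `logml` (tree-averaged), `per_tree` log marginal
#'   likelihoods, `pooled` posterior sample matrix, and `param_names`.
#' @export
treeset_logml <- function(trees, model, ladder = power_ladder(),
                          iterations = 2000, seed = 1, prior_rate = NULL) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  links <- vapply(model$regimes, function(r) as.character(r$link), character(1))
  procs <- vapply(model$regimes, function(r) r$process, character(1))
  groups <- unique(links)
  gproc <- vapply(groups, function(g) procs[links == g][1], character(1))
  pnames <- unlist(lapply(seq_along(groups), function(gi) {
    if (gproc[gi] == "PB") paste0("lambda.", groups[gi])
    else paste0(c("lambda.", "mu."), groups[gi])
  }))
  unpack <- function(theta) {
    out <- list(); j <- 1
    for (gi in seq_along(groups)) {
      if (gproc[gi] == "PB") {
        out[[groups[gi]]] <- bd_params(theta[j], 0, 1); j <- j + 1
      } else {
        out[[groups[gi]]] <- bd_params(theta[j], theta[j + 1], 1); j <- j + 2
      }
    }
    out
  }
  per_tree <- numeric(length(trees))
  pooled <- NULL
  for (ti in seq_along(trees)) {
    tree <- trees[[ti]]
    if (is.null(prior_rate)) {
      # prior mean = 10x the crude Yule rate (n-2)/T: diffuse on the right
      # scale without drowning model comparisons in prior-width penalties
      crude0 <- (length(tree$tip.label) - 2) / sum(tree$edge.length)
      pr <- 1 / (10 * max(crude0, 1e-6))
    } else pr <- prior_rate
    ll_fun <- function(theta) {
      if (any(theta <= 0)) return(-Inf)
      tryCatch(regime_loglik(tree, model, unpack(theta)),
               error = function(e) -Inf)
    }
    # start every chain at the ML solution: rate ridges (e.g. lambda ~ mu)
    # mix poorly from arbitrary inits under single-parameter proposals
    crude <- length(tree$tip.label) / (2 * max(branching_times(tree)))
    fit <- tryCatch(fit_regime_ml(tree, model), error = function(e) NULL)
    init <- unlist(lapply(seq_along(groups), function(gi) {
      p <- if (is.null(fit)) NULL else fit$params[[groups[gi]]]
      lam <- if (is.null(p)) crude else p$lambda
      if (gproc[gi] == "PB") lam else c(lam, if (is.null(p)) crude / 4 else p$mu)
    }))
    init <- pmax(init, crude / 50)
    traces <- lapply(seq_along(ladder), function(bi) {
      mh_sample(ll_fun, rep(pr, length(pnames)), init, ladder[bi],
                iterations, derive_seed(seed, ti * 1000 + bi))
    })
    per_tree[ti] <- thermodynamic_logml(traces)$logml
    post <- traces[[length(ladder)]]
    keep <- post$samples[trace_keep(post), , drop = FALSE]
    pooled <- rbind(pooled, keep)
  }
  colnames(pooled) <- pnames
  list(logml = mean(per_tree), per_tree = per_tree,
       pooled = pooled, param_names = pnames)
}

#' Rank regime models by tree-averaged marginal likelihood
#'
#' Runs [treeset_logml()] for each candidate model and tabulates log
#' marginal likelihoods with Bayes factors against the best model (best
#' model has BF 0; all others >= 0).
#'
#' @param trees Tree set.
#' @param models Named list of [regime_model()] objects.
#' @param ... Passed to [treeset_logml()].
#' @return `data.frame` with columns `model`, `logml`, `BF`, sorted best
#'   first.
#' @export
compare_regime_models <- function(trees, models, ...) {
  if (is.null(names(models))) names(models) <- paste0("M", seq_along(models))
  lm <- vapply(names(models), function(nm)
    treeset_logml(trees, models[[nm]], ...)$logml, numeric(1))
  best <- max(lm)
  out <- data.frame(model = names(models), logml = lm,
                    BF = 2 * (best - lm), row.names = NULL)
  out[order(-out$logml), ]
}
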