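## Constant-rate pure-birth / birth-death likelihoods of branching times
## with incomplete-sampling correction, and clade-partitioned regime models.
##
## The likelihood follows the single-state specialization of the
## state-dependent speciation-extinction recursion: along a branch,
##   E' = mu - (lambda+mu) E + lambda E^2
##   D' = -(lambda+mu) D + 2 lambda E D
## with tip conditions E(0) = 1 - rho, D(0) = rho; at every internal node
## D <- D_left * D_right * lambda; at the root the likelihood is divided by
## lambda * (1 - E(crown))^2 (conditioning on the crown age and on both
## crown lineages surviving to be sampled). Both ODEs have closed forms
## (logistic E; D as a Riccati companion), so the likelihood is evaluated
## exactly from the branching times. Under this convention a pure-birth
## complete-sampling likelihood equals (n-2) log(lambda) - lambda * T with
## T the total branch length below the crown; no labelled-history factorial
## is included, so likelihood *differences* are convention-free.

#' Birth-death parameter set
#'
#' @param lambda Speciation rate (events per lineage per Myr, > 0).
#' @param mu Extinction rate (>= 0; must be 0 for a pure-birth process).
#' @param rho Sampling fraction in (0, 1]: probability that an extant
#'   species is included in the tree.
#' @return Object of class `bd_params` with the derived net
#'   diversification rate `r = lambda - mu`.
#' @export
bd_params <- function(lambda, mu = 0, rho = 1) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be finite and > 0")
  if (!is.finite(mu) || mu < 0) stop("mu must be finite and >= 0")
  if (!is.finite(rho) || rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  structure(list(lambda = lambda, mu = mu, rho = rho, r = lambda - mu),
            class = "bd_params")
}

#' Net diversification rate
#'
#' `r = lambda - mu`, in species per Myr.
#'
#' @param params A [bd_params()] object, or a numeric speciation rate
#'   (then supply `mu`).
#' @param mu Extinction rate when `params` is numeric.
#' @return Numeric net diversification rate.
#' @export
net_diversification <- function(params, mu = NULL) {
  if (inherits(params, "bd_params")) return(params$lambda - params$mu)
  if (is.null(mu)) stop("supply mu when params is a bare speciation rate")
  params - mu
}

## E(t): probability a lineage alive at age t leaves no sampled descendant.
## Closed form of the logistic ODE with E(0) = 1 - rho.
bd_E <- function(t, lambda, mu, rho) {
  u0 <- rho                      # u = 1 - E
  r <- lambda - mu
  if (abs(r) < 1e-12 * max(lambda, 1)) {
    1 - u0 / (1 + lambda * u0 * t)
  } else {
    1 - r * u0 / (lambda * u0 + (r - lambda * u0) * exp(-r * t))
  }
}

## log g(t) where g is the per-lineage D attenuation: D(t) = D(0) g(t) for
## the linear D ODE driven by E(t) (all lineages share tip conditions).
bd_log_g <- function(t, lambda, mu, rho) {
  u0 <- rho
  r <- lambda - mu
  if (abs(r) < 1e-12 * max(lambda, 1)) {
    -2 * log1p(lambda * u0 * t)
  } else {
    # g(t) = e^{rt} r^2 / (lambda u0 e^{rt} + r - lambda u0)^2, evaluated
    # on the log scale to stay finite for large |r| t; the squared
    # denominator is strictly positive for r > 0 and strictly negative for
    # r < 0, so its absolute value is taken on the branch that keeps the
    # exponential bounded.
    rt <- r * t
    ln_den <- if (r > 0) rt + log(lambda * u0 + (r - lambda * u0) * exp(-rt))
              else log(abs(lambda * u0 * exp(rt) + r - lambda * u0))
    rt + 2 * log(abs(r)) - 2 * ln_den
  }
}

#' Birth-death log-likelihood of branching times
#'
#' Log-likelihood (nats) of a descending sequence of node ages under a
#' constant-rate birth-death process with sampling fraction `rho`,
#' conditioned on the crown age and the survival of both crown lineages
#' (see the convention documented in the package vignette).
#'
#' @param times Branching times (node ages, Myr before present),
#'   descending; length `n - 1` for an `n`-tip tree.
#' @param params A [bd_params()] object.
#' @param conditioning `"crown_survival"` (default, the only supported
#'   scheme): condition on the crown age and both crown lineages leaving
#'   sampled descendants.
#' @return Finite log-likelihood.
#' @export
bd_loglik <- function(times, params, conditioning = "crown_survival") {
  stopifnot(inherits(params, "bd_params"))
  conditioning <- match.arg(conditioning, "crown_survival")
  if (length(times) < 1) stop("empty branching-time sequence")
  if (any(!is.finite(times)) || any(times < 0)) stop("invalid branching times")
  times <- sort(times, decreasing = TRUE)
  lambda <- params$lambda; mu <- params$mu; rho <- params$rho
  n <- length(times) + 1
  crown <- times[1]
  lg <- vapply(times, bd_log_g, numeric(1), lambda = lambda, mu = mu, rho = rho)
  E_crown <- bd_E(crown, lambda, mu, rho)
  n * log(rho) + (n - 2) * log(lambda) +
    sum(lg) + bd_log_g(crown, lambda, mu, rho) -
    2 * log1p(-E_crown)
}

#' Clade-partitioned diversification regime model
#'
#' A regime model assigns disjoint named clades (plus the background, the
#' complement of all clades) to pure-birth or birth-death parameter
#' regimes. Regimes sharing a `link` group are constrained to share
#' parameters. Rate shifts apply from a clade's crown: the clade's stem
#' branch belongs to the parent regime.
#'
#' @param regimes A list of regimes, each a list with elements
#'   `clade` (a [clade_def()], or `NULL` for the background),
#'   `process` (`"PB"` or `"BD"`), `link` (link-group id, any scalar), and
#'   `rho` (sampling fraction for the regime).
#' @return Object of class `regime_model`.
#' @export
regime_model <- function(regimes) {
  if (length(regimes) == 0) stop("no regimes")
  procs <- vapply(regimes, function(r) r$process, character(1))
  if (!all(procs %in% c("PB", "BD"))) stop("process must be 'PB' or 'BD'")
  links <- vapply(regimes, function(r) as.character(r$link), character(1))
  for (g in unique(links)) {
    if (length(unique(procs[links == g])) > 1)
      stop("linked regimes must share the same process type (group ", g, ")")
  }
  nbg <- sum(vapply(regimes, function(r) is.null(r$clade), logical(1)))
  if (nbg != 1) stop("exactly one background regime (clade = NULL) required")
  structure(list(regimes = regimes), class = "regime_model")
}

## Partition a tree's branching times among the regimes of a model.
## Named clades take the node ages internal to their MRCA subtree
## (crown shift semantics); the background takes the remaining ages, which
## are exactly the internal-node ages of the tree with each clade collapsed
## to a single tip. Returns a list of descending age vectors, one per
## regime, in model order.
regime_times <- function(tree, model) {
  n <- length(tree$tip.label)
  ages <- ape::branching.times(tree)           # named by node id
  node_ids <- as.integer(names(ages))
  taken <- integer(0)
  members <- list()
  out <- vector("list", length(model$regimes))
  bg_idx <- NULL
  for (i in seq_along(model$regimes)) {
    r <- model$regimes[[i]]
    if (is.null(r$clade)) { bg_idx <- i; next }
    mrca <- resolve_mrca(tree, r$clade)
    if (mrca <= n) stop("clade '", r$clade$name, "' resolves to a single tip")
    sub <- subtree_nodes(tree, mrca)
    internal <- sub[sub > n]
    if (length(intersect(internal, taken)) > 0)
      stop("overlapping clades in regime model")
    taken <- c(taken, internal)
    members[[length(members) + 1]] <- tree$tip.label[sub[sub <= n]]
    out[[i]] <- sort(unname(ages[match(internal, node_ids)]), decreasing = TRUE)
  }
  if (length(members) > 1 &&
      anyDuplicated(unlist(members)) > 0)
    stop("overlapping clades in regime model")
  bg_nodes <- setdiff(node_ids, taken)
  out[[bg_idx]] <- sort(unname(ages[match(bg_nodes, node_ids)]), decreasing = TRUE)
  out
}

#' Log-likelihood of a regime model on a tree
#'
#' Sum of independent birth-death likelihood terms, one per regime: each
#' named clade contributes the likelihood of its crown subtree's branching
#' times under its regime parameters and sampling fraction, and the
#' background contributes the likelihood of the remaining branching times
#' (the collapsed tree's node ages) under the background parameters.
#'
#' @param tree A validated ultrametric `phylo`.
#' @param model A [regime_model()].
#' @param params Named list mapping link-group id to a [bd_params()].
#' @return Total log-likelihood.
#' @export
regime_loglik <- function(tree, model, params) {
  tms <- regime_times(tree, model)
  total <- 0
  for (i in seq_along(model$regimes)) {
    r <- model$regimes[[i]]
    p <- params[[as.character(r$link)]]
    if (is.null(p)) stop("no parameters for link group ", r$link)
    if (r$process == "PB" && p$mu > 0) stop("mu > 0 under a pure-birth regime")
    p <- bd_params(p$lambda, p$mu, r$rho)
    total <- total + bd_loglik(tms[[i]], p)
  }
  total
}

#' Maximum-likelihood fit of a regime model
#'
#' Maximizes the regime log-likelihood over the per-link-group rates on
#' the log scale. For pure-birth regimes with complete sampling the
#' speciation rate has the analytic solution `lambda = (sum n_g - 2 m) /
#' sum T_g` per link group, which is used directly; otherwise a quasi-Newton
#' optimization is run from a crude initial estimate.
#'
#' @param tree A validated ultrametric `phylo`.
#' @param model A [regime_model()].
#' @return List with `params` (per link group), `logLik`, `k` (free
#'   parameter count) and `convergence`.
#' @export
fit_regime_ml <- function(tree, model) {
  tms <- regime_times(tree, model)
  links <- vapply(model$regimes, function(r) as.character(r$link), character(1))
  procs <- vapply(model$regimes, function(r) r$process, character(1))
  rhos <- vapply(model$regimes, function(r) r$rho, numeric(1))
  groups <- unique(links)
  gproc <- vapply(groups, function(g) procs[links == g][1], character(1))
  all_pb_full <- all(gproc == "PB") && all(rhos == 1)
  if (all_pb_full) {
    out <- list(); ll <- 0
    for (g in groups) {
      idx <- which(links == g)
      kk <- 0; TT <- 0
      for (i in idx) {
        x <- tms[[i]]
        kk <- kk + length(x) - 1          # (n - 2) per regime component
        TT <- TT + sum(x) + x[1]          # total branch length below crown
      }
      lam <- if (kk > 0) kk / TT else 1e-8  # boundary: 2-tip components
      lam <- max(lam, 1e-10)
      out[[g]] <- bd_params(lam, 0, 1)
      for (i in idx) ll <- ll + bd_loglik(tms[[i]], bd_params(lam, 0, rhos[i]))
    }
    k <- length(groups)
    return(list(params = out, logLik = ll, k = k, convergence = 0L))
  }
  # general case: numeric optimization on log rates
  npar <- sum(ifelse(gproc == "PB", 1L, 2L))
  unpack <- function(theta) {
    out <- list(); j <- 1
    for (gi in seq_along(groups)) {
      if (gproc[gi] == "PB") {
        out[[groups[gi]]] <- list(lambda = exp(theta[j]), mu = 0); j <- j + 1
      } else {
        out[[groups[gi]]] <- list(lambda = exp(theta[j]), mu = exp(theta[j + 1])); j <- j + 2
      }
    }
    out
  }
  nll <- function(theta) {
    pars <- unpack(theta)
    ll <- 0
    for (i in seq_along(model$regimes)) {
      p <- pars[[links[i]]]
      v <- tryCatch(bd_loglik(tms[[i]], bd_params(p$lambda, p$mu, rhos[i])),
                    error = function(e) -Inf)
      ll <- ll + v
    }
    if (!is.finite(ll)) 1e10 else -ll
  }
  crude <- (length(tree$tip.label) - 2) / sum(tree$edge.length)
  init <- numeric(npar); j <- 1
  for (gi in seq_along(groups)) {
    init[j] <- log(crude); j <- j + 1
    if (gproc[gi] == "BD") { init[j] <- log(crude / 4); j <- j + 1 }
  }
  fit <- optim(init, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  fit2 <- optim(fit$par, nll, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-12))
  pars <- unpack(fit2$par)
  out <- lapply(pars, function(p) bd_params(p$lambda, p$mu, 1))
  list(params = out, logLik = -fit2$value, k = npar, convergence = fit2$convergence)
}
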