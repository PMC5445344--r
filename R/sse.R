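## State-dependent speciation-extinction (SSE) likelihoods: BiSSE / MuSSE-k
## and GeoSSE, with state-specific sampling fractions, constraint-based
## model enumeration, ML fitting with AIC / Akaike weights, and MCMC
## parameter estimation. Binary-trait analyses run as the k = 2 case of
## the multistate engine.

GEOSSE_STATES <- c("A", "B", "AB")

#' Tip states with state-specific sampling fractions
#'
#' @param states Named vector (names = tip labels) of states: integers
#'   `0..k-1` for binary/multistate characters, or `"A"`, `"B"`, `"AB"`
#'   for geographic ranges (A = target area, B = elsewhere, AB =
#'   widespread).
#' @param rho Per-state sampling fractions in (0, 1]: the probability that
#'   an extant species in that state is included in the tree. Either a
#'   single value recycled to all states, or a vector of length k in state
#'   order (0..k-1, or A, B, AB).
#' @param k Number of states (default: inferred from the data; supply
#'   explicitly if some state is unobserved).
#' @return Object of class `tip_states` with fields `states` (integer
#'   codes 1..k), `labels`, `k`, `rho`, `type` (`"multistate"` or
#'   `"geographic"`).
#' @export
tip_states <- function(states, rho = 1, k = NULL) {
  if (is.factor(states)) states <- setNames(as.character(states), names(states))
  if (is.null(names(states))) stop("states must be named by tip label")
  if (is.character(states) && all(states %in% GEOSSE_STATES)) {
    type <- "geographic"
    code <- match(states, GEOSSE_STATES)
    kk <- 3L
  } else {
    type <- "multistate"
    st <- as.integer(as.character(states))
    if (anyNA(st) || any(st < 0)) stop("unknown state: states must be 0..k-1")
    kk <- if (is.null(k)) max(st) + 1L else as.integer(k)
    if (any(st >= kk)) stop("state exceeds k-1")
    code <- st + 1L
  }
  rho <- rep_len(as.numeric(rho), kk)
  if (any(rho <= 0 | rho > 1)) stop("rho must be in (0, 1]")
  structure(list(states = setNames(code, names(states)),
                 labels = names(states), k = kk, rho = rho, type = type),
            class = "tip_states")
}

#' Read tip states from a two-column CSV
#'
#' @param file CSV with columns `label,state` (header optional but
#'   recommended).
#' @param rho Per-state sampling fractions, see [tip_states()].
#' @param k Number of states, see [tip_states()].
#' @return A [tip_states()] object.
#' @export
read_tip_states <- function(file, rho = 1, k = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected two columns: label, state")
  tip_states(setNames(df[[2]], df[[1]]), rho = rho, k = k)
}

#' MuSSE / BiSSE parameter set
#'
#' @param lambda Per-state speciation rates (length k, >= 0).
#' @param mu Per-state extinction rates (length k, >= 0).
#' @param q Transition-rate matrix (k x k, off-diagonal >= 0; the diagonal
#'   is ignored and defined as minus the row sum).
#' @return Object of class `musse_params`.
#' @export
musse_params <- function(lambda, mu, q) {
  k <- length(lambda)
  q <- as.matrix(q)
  if (length(mu) != k || !all(dim(q) == k)) stop("inconsistent dimensions")
  if (any(lambda < 0) || any(mu < 0) || any(q[row(q) != col(q)] < 0))
    stop("negative rates")
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  structure(list(lambda = lambda, mu = mu, q = q, k = k),
            class = "musse_params")
}

#' GeoSSE parameter set
#'
#' Within-region speciation `sA`, `sB`; between-region speciation `sAB`
#' (splitting a widespread lineage into an A and a B daughter); local
#' extinction `xA`, `xB` (range contraction of AB, and true extinction of
#' endemics); dispersal `dA` (A -> AB) and `dB` (B -> AB). All rates per
#' lineage per Myr, >= 0. Derived per-region net diversification rates
#' `rA = sA - xA`, `rB = sB - xB` are reported alongside.
#'
#' @param sA,sB,sAB,xA,xB,dA,dB Non-negative rates.
#' @return Object of class `geosse_params`.
#' @export
geosse_params <- function(sA, sB, sAB, xA, xB, dA, dB) {
  v <- c(sA = sA, sB = sB, sAB = sAB, xA = xA, xB = xB, dA = dA, dB = dB)
  if (any(!is.finite(v)) || any(v < 0)) stop("negative or non-finite rates")
  structure(c(as.list(v), list(rA = sA - xA, rB = sB - xB)),
            class = "geosse_params")
}

## Shared pruning setup: postorder edges and the tip D matrix.
sse_prepare <- function(tree, states) {
  if (!setequal(tree$tip.label, states$labels) ||
      length(tree$tip.label) != length(states$labels))
    stop("every tree tip needs exactly one state")
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  k <- states$k
  code <- states$states[tree$tip.label]
  tip_d <- matrix(0, ntip, k)
  tip_d[cbind(seq_len(ntip), code)] <- states$rho[code]
  list(edge = po$edge, edge_length = po$edge.length, ntip = ntip,
       tip_d = tip_d, e0 = 1 - states$rho)
}

## Root treatment shared by both families.
sse_root_loglik <- function(res, lambda_root, root = "fitzjohn",
                            condition_surv = TRUE) {
  D <- res$d_root; E <- res$e_root
  if (!is.finite(res$log_scale) || sum(D) <= 0) return(-Inf)
  w <- if (root == "fitzjohn") D / sum(D) else rep(1 / length(D), length(D))
  num <- sum(w * D)
  L <- if (condition_surv) {
    den <- sum(w * lambda_root * (1 - E)^2)
    if (den <= 0) return(-Inf)
    num / den
  } else num
  log(L) + res$log_scale
}

#' MuSSE / BiSSE log-likelihood
#'
#' Pruning likelihood of a k-state character and tree under
#' state-dependent speciation-extinction: along each branch the coupled
#' E/D ODE system is integrated (adaptive Runge-Kutta, compiled); tip
#' conditions are `D_i = rho_i * [observed state = i]`,
#' `E_i = 1 - rho_i`; at nodes `D_i <- lambda_i * D_left_i * D_right_i`;
#' at the root states are weighted by their data likelihood (FitzJohn
#' weighting) and the likelihood is conditioned on survival of both crown
#' lineages.
#'
#' @param tree A validated ultrametric `phylo`.
#' @param states A [tip_states()] object (multistate, k states).
#' @param params A [musse_params()].
#' @param root `"fitzjohn"` (default) or `"equal"` root-state weighting.
#' @param condition_surv Condition on survival (default TRUE).
#' @param atol,rtol ODE integration tolerances.
#' @return Log-likelihood (may be `-Inf` for impossible data).
#' @export
musse_loglik <- function(tree, states, params, root = "fitzjohn",
                         condition_surv = TRUE, atol = 1e-10, rtol = 1e-8) {
  stopifnot(inherits(params, "musse_params"))
  if (states$k != params$k) stop("unknown state: data and parameters disagree on k")
  prep <- sse_prepare(tree, states)
  qq <- params$q; diag(qq) <- 0
  res <- musse_prune_cpp(prep$edge, prep$edge_length, prep$ntip, prep$tip_d,
                         prep$e0, params$lambda, params$mu, qq, atol, rtol)
  sse_root_loglik(res, params$lambda, root, condition_surv)
}

#' GeoSSE log-likelihood
#'
#' Pruning likelihood of geographic ranges (A, B, AB) under the
#' three-state geographic speciation-extinction model: endemics speciate
#' within-region; widespread lineages additionally undergo between-region
#' speciation `sAB` and lose regions at `xA`, `xB`; dispersal `dA`, `dB`
#' expands ranges. Node combination uses the symmetrized half-sum for
#' widespread parents; the root uses FitzJohn weighting and survival
#' conditioning with per-state speciation rates `(sA, sB, sA + sB + sAB)`.
#'
#' @param tree A validated ultrametric `phylo`.
#' @param states A geographic [tip_states()] (states A/B/AB).
#' @param params A [geosse_params()].
#' @inheritParams musse_loglik
#' @return Log-likelihood.
#' @export
geosse_loglik <- function(tree, states, params, root = "fitzjohn",
                          condition_surv = TRUE, atol = 1e-10, rtol = 1e-8) {
  stopifnot(inherits(params, "geosse_params"))
  if (states$type != "geographic") stop("unknown state: GeoSSE needs A/B/AB states")
  prep <- sse_prepare(tree, states)
  pv <- unlist(params[c("sA", "sB", "sAB", "xA", "xB", "dA", "dB")])
  res <- geosse_prune_cpp(prep$edge, prep$edge_length, prep$ntip, prep$tip_d,
                          prep$e0, pv, atol, rtol)
  lambda_root <- c(pv[["sA"]], pv[["sB"]], pv[["sA"]] + pv[["sB"]] + pv[["sAB"]])
  sse_root_loglik(res, lambda_root, root, condition_surv)
}

#' Canonical SSE parameter names
#'
#' @param family `"bisse"`, `"musse"` or `"geosse"`.
#' @param k Number of states (multistate families).
#' @return Character vector of parameter names, e.g. `lambda0`, `mu1`,
#'   `q01` or `sA`, `xB`, `dA`.
#' @export
sse_param_names <- function(family, k = 2) {
  family <- match.arg(family, c("bisse", "musse", "geosse"))
  if (family == "geosse")
    return(c("sA", "sB", "sAB", "xA", "xB", "dA", "dB"))
  if (family == "bisse") k <- 2
  st <- seq_len(k) - 1
  qn <- outer(st, st, function(i, j) paste0("q", i, j))
  c(paste0("lambda", st), paste0("mu", st), t(qn)[t(row(qn) != col(qn))])
}

#' Constraint specification for SSE model fitting
#'
#' Equality constraints tie named parameters to a shared free value; zero
#' constraints fix parameters at 0. Constraints must be consistent (a
#' parameter cannot be both zero and tied to a non-zero group).
#'
#' @param equal List of character vectors of parameter names to equate.
#' @param zero Character vector of parameter names fixed to 0.
#' @return Object of class `constraint_spec`.
#' @export
constraint_spec <- function(equal = list(), zero = character(0)) {
  structure(list(equal = equal, zero = unique(as.character(zero))),
            class = "constraint_spec")
}

## Resolve a constraint spec against a parameter-name vector: returns
## list(map, free) where map[i] = 0 (fixed zero) or index into free names.
resolve_constraints <- function(pnames, spec) {
  group <- seq_along(pnames)           # union-find by smallest index
  names(group) <- pnames
  find <- function(i) { while (group[i] != i) i <- group[i]; i }
  for (eq in spec$equal) {
    idx <- match(eq, pnames)
    if (anyNA(idx)) stop("unknown parameter in constraint: ",
                         paste(eq[is.na(idx)], collapse = ", "))
    r <- min(vapply(idx, find, integer(1)))
    for (i in idx) group[find(i)] <- r
  }
  root <- vapply(seq_along(pnames), find, integer(1))
  zidx <- match(spec$zero, pnames)
  if (anyNA(zidx)) stop("unknown parameter in zero constraint")
  zero_roots <- unique(root[zidx])
  # any group containing a zeroed parameter is entirely zero
  is_zero <- root %in% zero_roots
  free_roots <- unique(root[!is_zero])
  map <- integer(length(pnames))
  map[!is_zero] <- match(root[!is_zero], free_roots)
  list(map = map, free = pnames[free_roots])
}

## Free-parameter signature for deduplication of enumerated models.
constraint_signature <- function(pnames, spec) {
  rc <- resolve_constraints(pnames, spec)
  paste(rc$map, collapse = ".")
}

## Expand a free vector to the full named parameter vector.
expand_params <- function(theta, map, pnames) {
  full <- numeric(length(pnames))
  full[map > 0] <- theta[map[map > 0]]
  setNames(full, pnames)
}

## Build the likelihood closure over the full parameter vector.
sse_full_loglik <- function(tree, states, family, root = "fitzjohn",
                            condition_surv = TRUE, atol = 1e-8, rtol = 1e-7) {
  prep <- sse_prepare(tree, states)
  k <- states$k
  if (family == "geosse") {
    function(full) {
      res <- geosse_prune_cpp(prep$edge, prep$edge_length, prep$ntip,
                              prep$tip_d, prep$e0, unname(full), atol, rtol)
      lr <- c(full[["sA"]], full[["sB"]],
              full[["sA"]] + full[["sB"]] + full[["sAB"]])
      sse_root_loglik(res, lr, root, condition_surv)
    }
  } else {
    function(full) {
      lambda <- full[seq_len(k)]
      mu <- full[k + seq_len(k)]
      qq <- matrix(0, k, k)
      qq[t(row(qq) != col(qq))] <- full[2 * k + seq_len(k * (k - 1))]
      qq <- t(qq)
      res <- musse_prune_cpp(prep$edge, prep$edge_length, prep$ntip,
                             prep$tip_d, prep$e0, unname(lambda), unname(mu),
                             qq, atol, rtol)
      sse_root_loglik(res, lambda, root, condition_surv)
    }
  }
}

## Heuristic starting point for SSE optimization, on the full vector.
sse_heuristic_start <- function(tree, states, family) {
  n <- length(tree$tip.label)
  TT <- sum(tree$edge.length)
  crude <- max((n - 2) / TT, 1e-4)
  pnames <- sse_param_names(family, states$k)
  full <- setNames(numeric(length(pnames)), pnames)
  if (family == "geosse") {
    full[c("sA", "sB")] <- crude
    full["sAB"] <- crude / 10
    full[c("xA", "xB")] <- crude / 4
    full[c("dA", "dB")] <- crude / 10
  } else {
    k <- states$k
    full[seq_len(k)] <- crude
    full[k + seq_len(k)] <- crude / 4
    full[2 * k + seq_len(k * (k - 1))] <- crude / 10
  }
  full
}

#' Maximum-likelihood fit of an SSE model
#'
#' Box-constrained maximization of the SSE likelihood over the free
#' parameters on the log scale (Nelder-Mead with restarts), under an
#' equality/zero constraint specification. Multiple jittered starts guard
#' against local optima; the best start is polished.
#'
#' @param tree A validated ultrametric `phylo`.
#' @param states A [tip_states()] object.
#' @param family `"bisse"`, `"musse"` or `"geosse"`.
#' @param constraints A [constraint_spec()] (default: unconstrained).
#' @param starts Number of starts (first from the heuristic initial point,
#'   the rest jittered).
#' @param seed Integer seed for jitter.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param init Optional full named parameter vector used as the first
#'   starting point (e.g. a nested model's optimum as a warm start).
#' @param root,condition_surv,atol,rtol See [musse_loglik()].
#' @return Object of class `sse_fit`: list with `par` (full named
#'   parameter vector), `free`, `logLik`, `k` (free-parameter count),
#'   `AIC`, `convergence`, `family`, `constraints`.
#' @export
fit_ml <- function(tree, states, family = c("bisse", "musse", "geosse"),
                   constraints = constraint_spec(), starts = 3, seed = 1,
                   maxit = 500, init = NULL, root = "fitzjohn",
                   condition_surv = TRUE, atol = 1e-8, rtol = 1e-7) {
  family <- match.arg(family)
  pnames <- sse_param_names(family, states$k)
  rc <- resolve_constraints(pnames, constraints)
  llfull <- sse_full_loglik(tree, states, family, root, condition_surv,
                            atol, rtol)
  h <- if (is.null(init)) sse_heuristic_start(tree, states, family)
       else init[pnames]
  theta0 <- pmax(h[match(rc$free, pnames)], 1e-6)
  nfree <- length(rc$free)
  nll <- function(lt) {
    full <- expand_params(exp(lt), rc$map, pnames)
    v <- llfull(full)
    if (!is.finite(v)) 1e10 else -v
  }
  set.seed(seed)
  run_opt <- function(lt0, reltol) {
    if (nfree == 1)
      optim(lt0, nll, method = "Brent", lower = log(1e-8), upper = log(1e3))
    else
      optim(lt0, nll, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = reltol))
  }
  best <- NULL
  ok <- FALSE
  for (s in seq_len(starts)) {
    lt0 <- log(theta0) + if (s == 1) 0 else stats::rnorm(nfree, 0, 0.7)
    fit <- tryCatch(run_opt(lt0, 1e-8), error = function(e) NULL)
    if (is.null(fit)) next
    ok <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!ok) stop("all optimization starts failed")
  best <- run_opt(best$par, 1e-10)
  par_full <- expand_params(exp(best$par), rc$map, pnames)
  ll <- -best$value
  structure(list(par = par_full, free = rc$free, logLik = ll, k = nfree,
                 AIC = 2 * nfree - 2 * ll, convergence = best$convergence,
                 family = family, constraints = constraints),
            class = "sse_fit")
}

#' @export
print.sse_fit <- function(x, ...) {
  cat("<sse_fit>", x$family, "- logLik", format(x$logLik, digits = 6),
      "k =", x$k, "AIC =", format(x$AIC, digits = 6), "\n")
  print(round(x$par, 5))
  invisible(x)
}

#' Enumerate the constrained GeoSSE model space
#'
#' Generates the lattice of constrained geographic diversification models:
#' every combination of a speciation option (free; `sA = sB`; `sAB = 0`),
#' an extinction option (free; `xA = xB`; `xA = 0`; `xB = 0`) and a
#' dispersal option (free; `dA = dB`; `dA = dB = 0`), plus the fully
#' symmetric two-region null model (`sA = sB`, `sAB = 0`, `xA = xB`,
#' `dA = dB`). This yields 36 distinct constrained models and the fully
#' unconstrained model, 37 in total, including the pure-birth-in-region-A
#' model (`xA = 0`, all other parameters free).
#'
#' @return Named list of [constraint_spec()] objects; the unconstrained
#'   model is named `"full"`.
#' @export
enumerate_geosse_models <- function() {
  s_opts <- list(free = list(), `sA=sB` = list(equal = list(c("sA", "sB"))),
                 `sAB=0` = list(zero = "sAB"))
  x_opts <- list(free = list(), `xA=xB` = list(equal = list(c("xA", "xB"))),
                 `xA=0` = list(zero = "xA"), `xB=0` = list(zero = "xB"))
  d_opts <- list(free = list(), `dA=dB` = list(equal = list(c("dA", "dB"))),
                 `dA=dB=0` = list(zero = c("dA", "dB")))
  out <- list()
  for (sn in names(s_opts)) for (xn in names(x_opts)) for (dn in names(d_opts)) {
    s <- s_opts[[sn]]; x <- x_opts[[xn]]; d <- d_opts[[dn]]
    spec <- constraint_spec(
      equal = c(s$equal, x$equal, d$equal),
      zero = c(s$zero, x$zero, d$zero))
    nm <- paste(c(sn, xn, dn)[c(sn, xn, dn) != "free"], collapse = ",")
    if (nm == "") nm <- "full"
    out[[nm]] <- spec
  }
  out[["symmetric"]] <- constraint_spec(
    equal = list(c("sA", "sB"), c("xA", "xB"), c("dA", "dB")),
    zero = "sAB")
  pn <- sse_param_names("geosse")
  sigs <- vapply(out, function(s) constraint_signature(pn, s), character(1))
  stopifnot(!anyDuplicated(sigs))
  # full model first, constrained models after
  out[c("full", setdiff(names(out), "full"))]
}

#' AIC model-comparison table
#'
#' @param fits Named list of [fit_ml()] results (or any objects with
#'   `logLik` and `k` fields).
#' @return `data.frame` with columns `model`, `logLik`, `k`, `AIC`,
#'   `dAIC`, `weight` (Akaike weights summing to 1) and `good_fit`
#'   (`dAIC < 6`), sorted best first.
#' @export
aic_table <- function(fits) {
  if (length(fits) < 1) stop("at least one fit required")
  if (is.null(names(fits))) names(fits) <- paste0("M", seq_along(fits))
  ll <- vapply(fits, function(f) f$logLik, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  aic <- 2 * k - 2 * ll
  d <- aic - min(aic)
  w <- exp(-d / 2); w <- w / sum(w)
  out <- data.frame(model = names(fits), logLik = ll, k = k, AIC = aic,
                    dAIC = d, weight = w, good_fit = d < 6, row.names = NULL)
  out[order(out$AIC), ]
}

#' MCMC parameter estimation for an SSE model
#'
#' Metropolis-Hastings sampling of the free parameters on the log scale
#' with independent Exponential priors of rate `1 / (2 * r_hat)`, where
#' `r_hat` is the crude net diversification estimate `(n - 2) / T`.
#' Defaults mirror a 50,000-generation analysis with the first 500 steps
#' discarded as burn-in.
#'
#' @inheritParams fit_ml
#' @param iterations MCMC sweeps.
#' @param burn_in Sweeps discarded as burn-in.
#' @param init Optional full named start vector (default: ML heuristic, or
#'   the parameters of `fit` when supplied).
#' @param fit Optional [fit_ml()] result used as the starting point.
#' @return List with `trace` (an `mcmc_trace`), posterior `mean` and 95%
#'   `hpd` per (full) parameter, and derived net diversification rates
#'   `r`.
#' @export
mcmc_sse <- function(tree, states, family = c("bisse", "musse", "geosse"),
                     constraints = constraint_spec(), iterations = 50000,
                     burn_in = 500, seed = 1, init = NULL, fit = NULL,
                     root = "fitzjohn", condition_surv = TRUE,
                     atol = 1e-8, rtol = 1e-7) {
  family <- match.arg(family)
  pnames <- sse_param_names(family, states$k)
  rc <- resolve_constraints(pnames, constraints)
  llfull <- sse_full_loglik(tree, states, family, root, condition_surv,
                            atol, rtol)
  llfree <- function(theta) {
    if (any(theta <= 0)) return(-Inf)
    llfull(expand_params(theta, rc$map, pnames))
  }
  if (!is.null(fit)) init <- fit$par
  theta0 <- if (is.null(init)) {
    pmax(sse_heuristic_start(tree, states, family)[match(rc$free, pnames)], 1e-6)
  } else pmax(init[match(rc$free, pnames)], 1e-6)
  n <- length(tree$tip.label)
  r_hat <- max((n - 2) / sum(tree$edge.length), 1e-4)
  prior_rate <- 1 / (2 * r_hat)
  tr <- mh_sample(llfree, rep(prior_rate, length(rc$free)), theta0,
                  beta = 1, iterations = iterations, seed = seed,
                  burn_in = burn_in)
  keep <- tr$samples[trace_keep(tr), , drop = FALSE]
  full_mat <- t(apply(keep, 1, function(th) expand_params(th, rc$map, pnames)))
  colnames(full_mat) <- pnames
  means <- colMeans(full_mat)
  hpds <- apply(full_mat, 2, hpd_interval)
  r <- if (family == "geosse") {
    rbind(mean = c(rA = means[["sA"]] - means[["xA"]],
                   rB = means[["sB"]] - means[["xB"]]),
          t(cbind(rA = hpd_interval(full_mat[, "sA"] - full_mat[, "xA"]),
                  rB = hpd_interval(full_mat[, "sB"] - full_mat[, "xB"]))))
  } else {
    k <- states$k
    rmat <- full_mat[, seq_len(k), drop = FALSE] -
      full_mat[, k + seq_len(k), drop = FALSE]
    colnames(rmat) <- paste0("r", seq_len(k) - 1)
    rbind(mean = colMeans(rmat), t(apply(rmat, 2, hpd_interval)))
  }
  list(trace = tr, mean = means, hpd = hpds, r = r,
       free = rc$free, family = family)
}
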