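## Forward (Gillespie) simulators: birth-death trees with incomplete
## sampling, clade rate-shift trees, Markov characters on fixed trees, and
## joint tree-plus-state simulation under BiSSE-style and GeoSSE processes.
##
## All simulators start from two crown lineages (matching the
## crown-conditioned likelihoods), are conditioned on survival by
## resimulation (attempt counts are recorded), and are deterministic given
## their seed.

## Event-rate tables. A "class" is an integer; the functions below return,
## for a lineage in a class, the per-event rates and the outcome of each
## event. Outcomes: list(type = "speciate"/"die"/"move",
## daughters = c(class, class) or new class).

## Core simulator. classes: initial classes of the two crown lineages.
## rates_fn(class) -> list(total, events = list(list(rate, type, ...))).
## stop: list(taxa = n) or list(age = T).
sim_forward <- function(rates_fn, init_classes, stop, seed,
                        max_attempts = 10000, require_both_crown = TRUE,
                        sample_fn = NULL, shift = NULL) {
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    out <- sim_forward_once(rates_fn, init_classes, stop, shift)
    if (is.null(out)) next
    # sampling: keep each extant tip with its class-specific probability
    keep <- rep(TRUE, length(out$tip_nodes))
    if (!is.null(sample_fn)) {
      pr <- vapply(out$tip_class, sample_fn, numeric(1))
      keep <- runif(length(pr)) < pr
    }
    if (sum(keep) < 2) next
    crown_ok <- !require_both_crown ||
      length(unique(out$tip_crown[keep])) == 2
    if (!crown_ok) next
    res <- build_phylo(out, keep)
    res$attempts <- attempt
    return(res)
  }
  stop("simulation failed: > ", max_attempts, " attempts without survival")
}

## One unconditioned forward pass; NULL on total extinction before the
## stopping rule. Implements both stopping rules; for taxa stopping the
## present is placed at the would-be next event after reaching n lineages.
sim_forward_once <- function(rates_fn, init_classes, stop, shift = NULL) {
  # lineage records, grown dynamically
  parent <- c(0L, 0L)
  t0 <- c(0, 0)
  t1 <- c(NA_real_, NA_real_)
  cls <- init_classes
  crown <- c(1L, 2L)                  # which crown lineage each descends from
  kind <- c(NA_integer_, NA_integer_) # 1 tip (extant), 2 extinct, 3 internal
  alive <- c(1L, 2L)
  t <- 0
  shift_done <- is.null(shift)
  repeat {
    na <- length(alive)
    if (!is.null(stop$taxa) && na >= stop$taxa) {
      rates <- vapply(alive, function(i) rates_fn(cls[i])$total, numeric(1))
      t <- t + rexp(1, sum(rates))
      break
    }
    if (na == 0) return(NULL)
    rates <- vapply(alive, function(i) rates_fn(cls[i])$total, numeric(1))
    tot <- sum(rates)
    dt <- if (tot > 0) rexp(1, tot) else Inf
    t_next <- t + dt
    if (!shift_done && t_next > shift$time) {
      # a randomly chosen lineage alive at the shift time founds the
      # shifted class; no event is consumed
      t <- shift$time
      pick <- alive[sample.int(na, 1)]
      cls[pick] <- shift$class
      shift_done <- TRUE
      next
    }
    if (!is.null(stop$age) && t_next >= stop$age) { t <- stop$age; break }
    t <- t_next
    if (!is.finite(dt)) break
    li <- alive[sample.int(na, 1, prob = rates)]
    rr <- rates_fn(cls[li])
    erates <- vapply(rr$events, function(e) e$rate, numeric(1))
    ev <- rr$events[[sample.int(length(erates), 1, prob = erates)]]
    if (ev$type == "speciate") {
      t1[li] <- t; kind[li] <- 3L
      for (d in 1:2) {
        parent <- c(parent, li); t0 <- c(t0, t); t1 <- c(t1, NA_real_)
        cls <- c(cls, ev$daughters[d]); crown <- c(crown, crown[li])
        kind <- c(kind, NA_integer_)
      }
      alive <- c(setdiff(alive, li), length(parent) - 1L, length(parent))
    } else if (ev$type == "die") {
      t1[li] <- t; kind[li] <- 2L
      alive <- setdiff(alive, li)
    } else {  # move
      cls[li] <- ev$to
    }
  }
  if (length(alive) < 2) return(NULL)
  t1[alive] <- t; kind[alive] <- 1L
  list(parent = parent, t0 = t0, t1 = t1, cls = cls, crown = crown,
       kind = kind, present = t,
       tip_nodes = which(kind == 1L),
       tip_class = cls[kind == 1L],
       tip_crown = crown[kind == 1L])
}

## Assemble a phylo from a simulation record, keeping the flagged extant
## tips and pruning everything else.
build_phylo <- function(out, keep) {
  terminal <- which(out$kind %in% c(1L, 2L))
  internal <- which(out$kind == 3L)
  nt <- length(terminal)
  id <- integer(length(out$parent))
  id[terminal] <- seq_len(nt)
  id[internal] <- nt + 1L + seq_along(internal)  # nt+1 reserved for root
  pid <- out$parent
  pid[pid == 0L] <- NA_integer_
  from <- id[pid]
  from[is.na(from)] <- nt + 1L                    # root joins the crown pair
  edge <- cbind(from, id)
  len <- out$t1 - out$t0
  labels <- paste0("t", seq_len(nt))
  tr <- list(edge = edge, edge.length = len, tip.label = labels,
             Nnode = length(internal) + 1L)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  kept_nodes <- out$tip_nodes[keep]
  tr <- ape::keep.tip(tr, labels[match(kept_nodes, terminal)])
  states <- out$cls[kept_nodes]
  names(states) <- labels[match(kept_nodes, terminal)]
  states <- states[tr$tip.label]
  list(tree = tr, tip_class = states)
}

#' Simulate a birth-death tree
#'
#' Gillespie forward simulation of a constant-rate birth-death process
#' from two crown lineages, conditioned (by resimulation) on both crown
#' lineages leaving sampled descendants. Each surviving tip is then
#' retained independently with probability `rho` and the tree pruned to
#' the retained tips.
#'
#' @param lambda Speciation rate (/Myr).
#' @param mu Extinction rate (/Myr).
#' @param stop Stopping rule: `list(taxa = n)` (exact extant tip count
#'   before sampling) or `list(age = T)` (crown age, Myr).
#' @param rho Sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @return A validated ultrametric `phylo`; the number of resimulation
#'   `attempts` is attached as an attribute.
#' @export
sim_bd_tree <- function(lambda, mu = 0, stop = list(taxa = 50), rho = 1,
                        seed = 1) {
  if (lambda <= mu) warning("lambda <= mu: process is not supercritical")
  check_stop(stop)
  rf <- bd_rates_fn(lambda, mu)
  res <- sim_forward(rf, c(1L, 1L), stop, seed,
                     sample_fn = function(cl) rho)
  tr <- res$tree
  attr(tr, "attempts") <- res$attempts
  validate_ultrametric(tr)
  tr
}

check_stop <- function(stop) {
  if (sum(c("taxa", "age") %in% names(stop)) != 1)
    stop("stopping rule must have exactly one of 'taxa' or 'age'")
  if (!is.null(stop$taxa) && stop$taxa < 2) stop("need at least 2 taxa")
  if (!is.null(stop$age) && stop$age <= 0) stop("age must be positive")
  invisible(stop)
}

bd_rates_fn <- function(lambda, mu, lambda2 = lambda, mu2 = mu) {
  tabs <- list(
    `1` = list(total = lambda + mu, events = list(
      list(rate = lambda, type = "speciate", daughters = c(1L, 1L)),
      list(rate = mu, type = "die"))),
    `2` = list(total = lambda2 + mu2, events = list(
      list(rate = lambda2, type = "speciate", daughters = c(2L, 2L)),
      list(rate = mu2, type = "die"))))
  function(cl) tabs[[cl]]
}

#' Simulate a tree with one clade-specific rate shift
#'
#' Forward birth-death simulation in which one randomly chosen lineage
#' alive at the specified shift age founds a second rate regime inherited
#' by all its descendants (crown semantics: the regime's clade is
#' addressed by its crown group, so the founding stem belongs to the
#' background). The true partition is returned alongside the tree.
#'
#' @param background A [bd_params()] for the background regime.
#' @param shift List with `age` (Myr before present at which the shifted
#'   lineage is chosen), `lambda` and `mu` for the shifted regime.
#' @param stop Stopping rule `list(age = T)` (crown age; the shift age
#'   must be younger than `T`).
#' @param seed Integer seed.
#' @param min_clade_tips Minimum number of sampled tips required in the
#'   shifted clade (replicates failing this are resimulated); 0 disables.
#' @param rho Sampling fraction applied to all tips.
#' @return List with `tree`, `clade_tips` (labels of the shifted clade, or
#'   `NULL` if the shifted lineage left no sampled tips), `truth` (a
#'   [regime_model()] with the generating partition when the clade has at
#'   least 2 tips) and `attempts`.
#' @export
sim_shift_tree <- function(background, shift, stop = list(age = 20), seed = 1,
                           min_clade_tips = 2, rho = 1) {
  check_stop(stop)
  if (is.null(stop$age)) stop("shift trees use an age stopping rule")
  if (shift$age >= stop$age) stop("shift age older than crown")
  mu_s <- if (is.null(shift$mu)) 0 else shift$mu
  rf <- bd_rates_fn(background$lambda, background$mu, shift$lambda, mu_s)
  set.seed(seed)
  for (attempt in seq_len(10000)) {
    sub_seed <- derive_seed(seed, attempt)
    res <- tryCatch(
      sim_forward(rf, c(1L, 1L), stop, sub_seed,
                  sample_fn = function(cl) rho,
                  shift = list(time = stop$age - shift$age, class = 2L),
                  max_attempts = 1),
      error = function(e) NULL)
    if (is.null(res)) next
    clade_tips <- names(res$tip_class)[res$tip_class == 2L]
    if (length(clade_tips) < min_clade_tips) next
    tr <- res$tree
    validate_ultrametric(tr)
    truth <- NULL
    if (length(clade_tips) >= 2) {
      truth <- regime_model(list(
        list(clade = clade_def("shift", clade_tips), process = "BD",
             link = "shift", rho = rho),
        list(clade = NULL, process = "BD", link = "bg", rho = rho)))
    }
    return(list(tree = tr, clade_tips = clade_tips, truth = truth,
                attempts = attempt))
  }
  stop("simulation failed: > 10000 attempts")
}

#' Simulate a Markov character on a fixed tree
#'
#' Exact stochastic simulation of a continuous-time Markov chain down each
#' branch (exponential waiting times between changes). Deterministic given
#' `seed`.
#'
#' @param tree A validated ultrametric `phylo`.
#' @param Q Transition-rate matrix (k x k; off-diagonal rates >= 0;
#'   diagonal ignored). Row/column order defines states `0..k-1` (or
#'   A/B/AB when `geo = TRUE`).
#' @param root_state `"stationary"` (draw the root state from the chain's
#'   stationary distribution) or an integer state in `0..k-1`.
#' @param seed Integer seed.
#' @param geo Return states labelled A/B/AB (3-state range chain) instead
#'   of 0..k-1.
#' @param rho Per-state sampling fractions forwarded to the returned
#'   [tip_states()] object.
#' @return A [tip_states()] object covering every tip.
#' @export
sim_mk <- function(tree, Q, root_state = "stationary", seed = 1,
                   geo = FALSE, rho = 1) {
  Q <- as.matrix(Q)
  k <- nrow(Q)
  diag(Q) <- 0
  if (any(Q < 0)) stop("negative transition rates")
  set.seed(seed)
  if (identical(root_state, "stationary")) {
    pi <- mk_stationary(Q)
    root <- sample.int(k, 1, prob = pi)
  } else root <- as.integer(root_state) + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]  # preorder
  len <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  nstate <- integer(length(tree$tip.label) + tree$Nnode)
  nstate[length(tree$tip.label) + 1L] <- root
  for (i in seq_len(nrow(edge))) {
    s <- nstate[edge[i, 1]]
    tleft <- len[i]
    repeat {
      tot <- sum(Q[s, ])
      if (tot <= 0) break
      w <- rexp(1, tot)
      if (w > tleft) break
      tleft <- tleft - w
      s <- sample.int(k, 1, prob = Q[s, ])
    }
    nstate[edge[i, 2]] <- s
  }
  tipv <- nstate[seq_along(tree$tip.label)]
  if (geo) {
    if (k != 3) stop("geographic chain requires 3 states (A, B, AB)")
    st <- setNames(GEOSSE_STATES[tipv], tree$tip.label)
  } else {
    st <- setNames(tipv - 1L, tree$tip.label)
  }
  tip_states(st, rho = rho, k = if (geo) NULL else k)
}

## Stationary distribution of a CTMC rate matrix (off-diagonal part).
mk_stationary <- function(Q) {
  k <- nrow(Q)
  G <- Q
  diag(G) <- 0
  diag(G) <- -rowSums(G)
  A <- rbind(t(G), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' Jointly simulate a tree and tip states under an SSE process
#'
#' Gillespie simulation of speciation, extinction and state-transition
#' events with state-dependent rates. For `family = "bisse"` (or multistate
#' parameters) lineages speciate into two daughters of the parental state.
#' For `family = "geosse"`: endemics (A or B) speciate within region,
#' disperse to AB, or go extinct; widespread AB lineages speciate within
#' region (daughters AB + endemic), speciate between regions (daughters A
#' and B), or lose one region (AB -> endemic); the event table mirrors the
#' likelihood's node conventions so the simulator doubles as a convention
#' oracle. Per-state sampling fractions are applied to the surviving tips.
#'
#' @param family `"bisse"` (multistate) or `"geosse"`.
#' @param params A [musse_params()] or [geosse_params()].
#' @param stop Stopping rule, see [sim_bd_tree()].
#' @param rho Per-state sampling fractions (recycled to k).
#' @param seed Integer seed.
#' @param root_state Initial state of the two crown lineages:
#'   `"stationary"` (from the transition chain) or a state (0..k-1 index,
#'   or `"A"`/`"B"`/`"AB"`).
#' @return List with `tree` (validated ultrametric `phylo`), `states` (a
#'   [tip_states()]) and `attempts`.
#' @export
sim_sse_tree <- function(family = c("bisse", "geosse"), params,
                         stop = list(taxa = 100), rho = 1, seed = 1,
                         root_state = "stationary") {
  family <- match.arg(family)
  check_stop(stop)
  if (family == "geosse") {
    stopifnot(inherits(params, "geosse_params"))
    k <- 3L
    # classes 1 = A, 2 = B, 3 = AB
    tabs <- list(
      list(total = params$sA + params$xA + params$dA, events = list(
        list(rate = params$sA, type = "speciate", daughters = c(1L, 1L)),
        list(rate = params$xA, type = "die"),
        list(rate = params$dA, type = "move", to = 3L))),
      list(total = params$sB + params$xB + params$dB, events = list(
        list(rate = params$sB, type = "speciate", daughters = c(2L, 2L)),
        list(rate = params$xB, type = "die"),
        list(rate = params$dB, type = "move", to = 3L))),
      list(total = params$sA + params$sB + params$sAB + params$xA + params$xB,
           events = list(
        list(rate = params$sA, type = "speciate", daughters = c(3L, 1L)),
        list(rate = params$sB, type = "speciate", daughters = c(3L, 2L)),
        list(rate = params$sAB, type = "speciate", daughters = c(1L, 2L)),
        list(rate = params$xA, type = "move", to = 2L),   # lose region A
        list(rate = params$xB, type = "move", to = 1L)))) # lose region B
    trans <- matrix(0, 3, 3)
    trans[1, 3] <- params$dA; trans[2, 3] <- params$dB
    trans[3, 2] <- params$xA; trans[3, 1] <- params$xB
  } else {
    stopifnot(inherits(params, "musse_params"))
    k <- params$k
    qq <- params$q; diag(qq) <- 0
    tabs <- lapply(seq_len(k), function(i) {
      ev <- list(
        list(rate = params$lambda[i], type = "speciate", daughters = c(i, i)),
        list(rate = params$mu[i], type = "die"))
      for (j in seq_len(k)) if (j != i && qq[i, j] > 0)
        ev[[length(ev) + 1]] <- list(rate = qq[i, j], type = "move", to = j)
      list(total = params$lambda[i] + params$mu[i] + sum(qq[i, -i]),
           events = ev)
    })
    trans <- qq
  }
  rho <- rep_len(rho, k)
  set.seed(seed)
  root <- if (identical(root_state, "stationary")) {
    if (sum(trans) == 0) 1L else sample.int(k, 1, prob = mk_stationary(trans))
  } else if (is.character(root_state)) {
    match(root_state, GEOSSE_STATES)
  } else as.integer(root_state) + 1L
  rf <- function(cl) tabs[[cl]]
  res <- sim_forward(rf, c(root, root), stop, derive_seed(seed, 7),
                     sample_fn = function(cl) rho[cl])
  tr <- res$tree
  validate_ultrametric(tr)
  st <- if (family == "geosse") {
    tip_states(setNames(GEOSSE_STATES[res$tip_class], names(res$tip_class)),
               rho = rho)
  } else {
    tip_states(setNames(res$tip_class - 1L, names(res$tip_class)),
               rho = rho, k = k)
  }
  list(tree = tr, states = st, attempts = res$attempts)
}
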