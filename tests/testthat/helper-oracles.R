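# Independent oracles used across the suite. All are deliberately written
# against the ODE / pruning definitions with generic tools (deSolve, ape's
# matrix exponential), not via the package's own closed forms or compiled
# integrator.

# Birth-death log-likelihood by numeric integration of the E/D system with
# a generic stiff solver.
bd_ode_oracle <- function(times, lambda, mu, rho) {
  times <- sort(times, decreasing = TRUE)
  n <- length(times) + 1
  deriv <- function(t, y, p) {
    list(c(mu - (lambda + mu) * y[1] + lambda * y[1]^2,
           -(lambda + mu) * y[2] + 2 * lambda * y[1] * y[2]))
  }
  g <- function(tt) {
    if (tt == 0) return(c(1 - rho, 1))
    o <- deSolve::lsoda(c(E = 1 - rho, D = 1), c(0, tt), deriv, NULL,
                        rtol = 1e-12, atol = 1e-14)
    o[2, 2:3]
  }
  lg <- vapply(times, function(tt) log(g(tt)[2]), numeric(1))
  Ec <- g(times[1])[1]
  n * log(rho) + (n - 2) * log(lambda) + sum(lg) + lg[1] - 2 * log(1 - Ec)
}

# Closed-form extinction probability (logistic solution), used to check
# the package against an independently derived expression.
bd_E_closed <- function(t, lambda, mu, rho) {
  r <- lambda - mu
  E0 <- 1 - rho
  1 - r * (1 - E0) / (lambda * (1 - E0) + (r - lambda * (1 - E0)) * exp(-r * t))
}

# Mk (character-only) pruning likelihood with FitzJohn root weighting,
# via matrix exponentials of the generator.
mk_fitzjohn_oracle <- function(tree, states01, Q) {
  k <- nrow(Q)
  po <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  D <- matrix(0, nt + tree$Nnode, k)
  for (i in seq_len(nt)) D[i, states01[tree$tip.label[i]] + 1] <- 1
  G <- Q; diag(G) <- 0; diag(G) <- -rowSums(G)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    P <- ape::matexpo(G * po$edge.length[e])
    v <- as.numeric(P %*% D[ch, ])
    D[p, ] <- if (all(D[p, ] == 0)) v else D[p, ] * v
  }
  M <- D[nt + 1, ]
  log(sum(M^2) / sum(M))
}

# Monolithic MuSSE (k = 2) likelihood on the 3-tip tree
# ((A:0.5,B:0.5):0.5,C:1.0);, assembled segment by segment with lsoda.
musse3_oracle <- function(states, lambda, mu, q, rho) {
  deriv <- function(t, y, p) {
    E <- y[1:2]; D <- y[3:4]
    dE <- dD <- numeric(2)
    for (i in 1:2) {
      j <- 3 - i
      tot <- lambda[i] + mu[i] + q[i, j]
      dE[i] <- mu[i] - tot * E[i] + lambda[i] * E[i]^2 + q[i, j] * E[j]
      dD[i] <- -tot * D[i] + 2 * lambda[i] * E[i] * D[i] + q[i, j] * D[j]
    }
    list(c(dE, dD))
  }
  seg <- function(y0, len)
    deSolve::lsoda(y0, c(0, len), deriv, NULL, rtol = 1e-12, atol = 1e-14)[2, -1]
  tipd <- function(s) rho[s + 1] * as.numeric(0:1 == s)
  yA <- seg(c(1 - rho, tipd(states[["A"]])), 0.5)
  yB <- seg(c(1 - rho, tipd(states[["B"]])), 0.5)
  Dn <- lambda * yA[3:4] * yB[3:4]
  En <- (yA[1:2] + yB[1:2]) / 2
  yN <- seg(c(En, Dn), 0.5)
  yC <- seg(c(1 - rho, tipd(states[["C"]])), 1.0)
  Dr <- lambda * yN[3:4] * yC[3:4]
  Er <- (yN[1:2] + yC[1:2]) / 2
  w <- Dr / sum(Dr)
  log(sum(w * Dr) / sum(w * lambda * (1 - Er)^2))
}

# Monolithic GeoSSE likelihood on the same 3-tip tree (states named by
# tip: "A", "B" or "AB").
geosse3_oracle <- function(states, p, rho) {
  deriv <- function(t, y, pp) {
    EA <- y[1]; EB <- y[2]; EAB <- y[3]; DA <- y[4]; DB <- y[5]; DAB <- y[6]
    with(pp, list(c(
      xA - (sA + dA + xA) * EA + sA * EA^2 + dA * EAB,
      xB - (sB + dB + xB) * EB + sB * EB^2 + dB * EAB,
      -(sA + sB + sAB + xA + xB) * EAB + xA * EB + xB * EA +
        sA * EA * EAB + sB * EB * EAB + sAB * EA * EB,
      -(sA + dA + xA) * DA + 2 * sA * EA * DA + dA * DAB,
      -(sB + dB + xB) * DB + 2 * sB * EB * DB + dB * DAB,
      -(sA + sB + sAB + xA + xB) * DAB + xA * DB + xB * DA +
        sA * (EA * DAB + EAB * DA) + sB * (EB * DAB + EAB * DB) +
        sAB * (EA * DB + EB * DA))))
  }
  seg <- function(y0, len)
    deSolve::lsoda(y0, c(0, len), deriv, p, rtol = 1e-12, atol = 1e-14)[2, -1]
  combine <- function(Dl, Dr) c(
    p$sA * Dl[1] * Dr[1], p$sB * Dl[2] * Dr[2],
    0.5 * (p$sA * (Dl[3] * Dr[1] + Dl[1] * Dr[3]) +
           p$sB * (Dl[3] * Dr[2] + Dl[2] * Dr[3]) +
           p$sAB * (Dl[1] * Dr[2] + Dl[2] * Dr[1])))
  tipd <- function(s) rho[match(s, c("A", "B", "AB"))] *
    as.numeric(c("A", "B", "AB") == s)
  yA <- seg(c(1 - rho, tipd(states[["A"]])), 0.5)
  yB <- seg(c(1 - rho, tipd(states[["B"]])), 0.5)
  yN <- seg(c((yA[1:3] + yB[1:3]) / 2, combine(yA[4:6], yB[4:6])), 0.5)
  yC <- seg(c(1 - rho, tipd(states[["C"]])), 1.0)
  Dr <- combine(yN[4:6], yC[4:6])
  Er <- (yN[1:3] + yC[1:3]) / 2
  w <- Dr / sum(Dr)
  lam <- c(p$sA, p$sB, p$sA + p$sB + p$sAB)
  log(sum(w * Dr) / sum(w * lam * (1 - Er)^2))
}

# The shared 3-tip fixture.
tree3 <- function() read_newick(text = "((A:0.5,B:0.5):0.5,C:1.0);")

# Brute-force shortest-interval HPD: scan every window of the required
# size.
hpd_brute <- function(x, mass = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  if (m >= n) return(c(xs[1], xs[n]))
  best <- c(xs[1], xs[m]); bw <- xs[m] - xs[1]
  for (i in seq_len(n - m + 1)) {
    w <- xs[i + m - 1] - xs[i]
    if (w < bw - 1e-15) { best <- c(xs[i], xs[i + m - 1]); bw <- w }
  }
  best
}
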