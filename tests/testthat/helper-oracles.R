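# Independent oracles used to cross-check the package's solvers.
# These deliberately share no code with the implementation: dense base-R
# linear algebra, closed-form series/parallel hydraulics and brute-force
# grid searches only.

MMHG_PA_H <- 133.322
RES_SI_H <- MMHG_PA_H / 1e-6

# dense nodal solve of a resistor network, assembled edge by edge into a
# full base-R matrix (pressures in mmHg, flows in ml/s)
oracle_solve_dense <- function(nodes, edges) {
  n <- nrow(nodes)
  G <- matrix(0, n, n)
  for (e in seq_len(nrow(edges))) {
    i <- match(edges$from[e], nodes$name)
    j <- match(edges$to[e], nodes$name)
    g <- 1 / (edges$R[e] * RES_SI_H)
    G[i, i] <- G[i, i] + g; G[j, j] <- G[j, j] + g
    G[i, j] <- G[i, j] - g; G[j, i] <- G[j, i] - g
  }
  fixed <- nodes$fixed
  pf <- nodes$pressure * MMHG_PA_H
  free <- which(!fixed)
  p <- pf
  if (length(free)) {
    A <- G[free, free, drop = FALSE]
    b <- -G[free, which(fixed), drop = FALSE] %*% pf[fixed]
    p[free] <- base::solve(A, b)
  }
  Q <- numeric(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    i <- match(edges$from[e], nodes$name)
    j <- match(edges$to[e], nodes$name)
    Q[e] <- (p[i] - p[j]) / (edges$R[e] * RES_SI_H)
  }
  list(pressures = p / MMHG_PA_H, Q = Q / 1e-6)
}

# random connected resistor network with 2+ fixed-pressure nodes
random_network_spec <- function(seed) {
  set.seed(seed)
  n <- sample(4:20, 1)
  nodes <- data.frame(name = paste0("n", seq_len(n)),
                      fixed = FALSE, pressure = NA_real_,
                      stringsAsFactors = FALSE)
  nfix <- sample(2:min(4, n - 1), 1)
  fi <- sample(n, nfix)
  nodes$fixed[fi] <- TRUE
  nodes$pressure[fi] <- round(runif(nfix, 0, 30), 3)
  # random spanning tree plus extra edges, at most 50 total
  from <- to <- integer(0)
  for (k in 2:n) {
    from <- c(from, sample(k - 1, 1)); to <- c(to, k)
  }
  nextra <- sample(0:min(30, 50 - (n - 1)), 1)
  for (k in seq_len(nextra)) {
    ij <- sample(n, 2)
    from <- c(from, ij[1]); to <- c(to, ij[2])
  }
  edges <- data.frame(id = paste0("e", seq_along(from)),
                      from = paste0("n", from), to = paste0("n", to),
                      R = round(runif(length(from), 0.1, 30), 4),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

# closed-form stage hydraulics of the lumped AVM topology (series feeding
# lump into two parallel branches), independent of solve_flow
oracle_avm_flows <- function(P_in, R_art, lumps, R_nidus) {
  Ra <- lumps[["R_AO"]] + R_art
  Rv <- R_nidus + lumps[["R_ven"]]
  Rpar <- 1 / (1 / Ra + 1 / Rv)
  Q_in <- P_in / (lumps[["R_feed"]] + Rpar)
  PJ <- P_in - Q_in * lumps[["R_feed"]]
  list(Q_inlet = Q_in, Q_nidus = PJ / Rv, Q_art = PJ / Ra)
}

# brute-force grid-refinement search for the three lumped resistances
oracle_calibrate_lumps <- function(P_in, R_art, Rb, Rc, Qb, Qnb, Qc,
                                   box = rbind(c(1e-6, 8), c(1e-6, 40),
                                               c(1e-6, 40)),
                                   npts = 13, passes = 18) {
  score <- function(rf, rao, rv) {
    l <- c(R_feed = rf, R_AO = rao, R_ven = rv)
    b <- oracle_avm_flows(P_in, R_art, l, Rb)
    cc <- oracle_avm_flows(P_in, R_art, l, Rc)
    (b$Q_inlet - Qb)^2 + (b$Q_nidus - Qnb)^2 + (cc$Q_inlet - Qc)^2
  }
  best <- c(mean(box[1, ]), mean(box[2, ]), mean(box[3, ]))
  for (p in seq_len(passes)) {
    g1 <- seq(box[1, 1], box[1, 2], length.out = npts)
    g2 <- seq(box[2, 1], box[2, 2], length.out = npts)
    g3 <- seq(box[3, 1], box[3, 2], length.out = npts)
    grid <- expand.grid(rf = g1, rao = g2, rv = g3)
    s <- mapply(score, grid$rf, grid$rao, grid$rv)
    best <- unlist(grid[which.min(s), ])
    # recenter on the best grid point, keeping +-2 cells of slack
    w <- 2 * (box[, 2] - box[, 1]) / (npts - 1)
    box <- cbind(best - w, best + w)
    box[box < 1e-9] <- 1e-9
  }
  c(R_feed = unname(best[1]), R_AO = unname(best[2]),
    R_ven = unname(best[3]))
}

# Lagrange polynomial through three points, evaluated at x
oracle_lagrange3 <- function(x, xs, ys) {
  sum(vapply(1:3, function(i) {
    others <- setdiff(1:3, i)
    ys[i] * prod((x - xs[others]) / (xs[i] - xs[others]))
  }, 0))
}

# front-arrival kinematics: time for an advected front to traverse edges
oracle_arrival_time <- function(lengths, velocities) {
  sum(lengths / velocities)
}
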