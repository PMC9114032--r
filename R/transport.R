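#' Contrast bolus specification
#'
#' The contrast injection is idealised as a square concentration wave at
#' the network inlet: amplitude 1 kg/m^3 for `width` seconds, then zero.
#'
#' @param amplitude inlet concentration plateau in kg/m^3 (default 1).
#' @param width square-wave width in s (default 1.5).
#' @param total_time simulated horizon in s (default 5, long enough for
#'   the bolus to traverse the lesion).
#' @param time_step reporting/transport time step in s (default 0.01; the
#'   solver sub-divides it further whenever stability requires).
#' @return an object of class `bolus_spec`.
#' @export
bolus_spec <- function(amplitude = 1, width = 1.5, total_time = 5,
                       time_step = 0.01) {
  if (!(width > 0 && width < total_time)) {
    stop("bolus width must lie in (0, total_time)", call. = FALSE)
  }
  if (time_step <= 0 || amplitude <= 0) {
    stop("time_step and amplitude must be positive", call. = FALSE)
  }
  structure(list(amplitude = amplitude, width = width,
                 total_time = total_time, time_step = time_step),
            class = "bolus_spec")
}

#' Transport geometry of a network
#'
#' Pairs each hydraulic edge with a one-dimensional centerline: physical
#' length, cross-sectional area and a uniform cell subdivision. For vessel
#' segments the area is the lumen cross-section; for the nidus it is the
#' frontal area `W*H` of the bounding box, so the transport velocity is the
#' superficial (Darcy) velocity.
#'
#' @param edges data.frame with columns `id`, `from`, `to`, `L` (m),
#'   `A` (m^2).
#' @param ds target cell size in m (default 1 mm); each edge gets at least
#'   4 cells.
#' @return an object of class `transport_geometry`.
#' @export
transport_geometry <- function(edges, ds = 1e-3) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "from", "to", "L", "A") %in% names(edges)))
  if (any(edges$A <= 0)) stop("zero or negative cross-sectional area",
                              call. = FALSE)
  if (any(edges$L <= 0)) stop("edge lengths must be positive", call. = FALSE)
  edges$n <- pmax(4L, as.integer(round(edges$L / ds)))
  edges$ds <- edges$L / edges$n
  structure(list(edges = edges), class = "transport_geometry")
}

#' Transport geometry of an AVM case
#'
#' Builds the centerline geometry matching [build_stage_network()]:
#' feeding segment, arterial branch, nidus (superficial area `W*H`, path
#' length `L`) and the venous branches. Segment lengths missing from the
#' case default to 15 mm, a nominal value used only for transport timing.
#'
#' @param case an [avm_case()].
#' @param ds target cell size in m.
#' @return a [transport_geometry()].
#' @export
avm_transport_geometry <- function(case, ds = 1e-3) {
  seg <- case$segments
  len <- ifelse(is.finite(seg$length), seg$length, 15) * 1e-3
  area <- pi * (seg$diameter * 1e-3)^2 / 4
  feed <- which(seg$kind == "feeding")
  art <- which(seg$kind == "arterial_outlet")
  ven <- which(seg$kind == "venous")
  nid <- case$nidus
  edges <- data.frame(
    id = c("feeding", "arterial", "nidus", paste0("venous_", seg$id[ven])),
    from = c("inlet", "junction", "junction",
             rep("ven_confluence", length(ven))),
    to = c("junction", "art_outlet", "ven_confluence",
           paste0("ven_", seg$id[ven])),
    L = c(len[feed], len[art], nid$L * 1e-3, len[ven]),
    A = c(area[feed], area[art], nid$W * nid$H * 1e-6, area[ven]),
    stringsAsFactors = FALSE)
  transport_geometry(edges, ds = ds)
}

#' Peclet number
#'
#' Ratio of advective to diffusive transport, `Pe = D * v / diffusivity`,
#' the similarity number matched when scaling dye transport between the
#' patient-scale model and an enlarged phantom.
#'
#' @param diameter characteristic diameter in m.
#' @param velocity mean velocity in m/s.
#' @param diffusivity scalar diffusivity in m^2/s.
#' @return dimensionless Peclet number.
#' @examples
#' peclet_number(3.8e-3, 0.145, 2.2e-10) # about 2.5e6
#' @export
peclet_number <- function(diameter, velocity, diffusivity) {
  if (any(diameter <= 0) || any(velocity <= 0) || any(diffusivity <= 0)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  diameter * velocity / diffusivity
}

#' Simulate contrast-agent transport over a solved flow field
#'
#' Solves the one-dimensional advection-diffusion equation
#' `dc/dt + v dc/ds = D d2c/ds2` on every edge of the network, with the
#' edge velocity `v = Q/A` taken from the steady flow solution (flow and
#' transport are de-coupled: the steady haemodynamics are solved first and
#' then drive the time-dependent scalar). Junctions mix instantaneously
#' with flow weighting; walls are zero-flux; the inlet carries the square
#' bolus. The scheme is first-order upwind finite volume with explicit
#' time stepping, automatically sub-divided to respect the CFL and
#' diffusive stability limits; it is conservative and monotone, so the
#' discrete maximum principle holds.
#'
#' @param solution a `flow_solution` (edge ids must match the geometry).
#' @param geometry a [transport_geometry()].
#' @param bolus a [bolus_spec()].
#' @param diffusivity contrast diffusivity in m^2/s (default 2.2e-10).
#' @return an object of class `concentration_field`: `times` (s), `samples`
#'   (data.frame `edge, s, ds, A` at cell centers), `conc` (matrix, time by
#'   sample, kg/m^3), `amplitude`, and `mass` (injected/outflow/stored in
#'   kg and the relative balance error).
#' @export
simulate_bolus <- function(solution, geometry, bolus = bolus_spec(),
                           diffusivity = 2.2e-10) {
  stopifnot(inherits(solution, "flow_solution"),
            inherits(geometry, "transport_geometry"),
            inherits(bolus, "bolus_spec"))
  ed <- geometry$edges
  fl <- solution$flows
  m <- match(ed$id, fl$id)
  if (anyNA(m)) {
    stop("geometry edge(s) missing from the flow solution: ",
         paste(ed$id[is.na(m)], collapse = ", "), call. = FALSE)
  }
  Q <- fl$Q[m] * ML_M3                      # m^3/s, from->to positive
  # orient every edge along its flow direction (upwind handling of
  # reversed edges)
  rev <- Q < 0
  tmp <- ed$from[rev]; ed$from[rev] <- ed$to[rev]; ed$to[rev] <- tmp
  Q <- abs(Q)
  v <- Q / ed$A
  ne <- nrow(ed)
  # topological order of nodes along the flow direction
  nodes <- unique(c(ed$from, ed$to))
  indeg <- stats::setNames(tabulate(match(ed$to, nodes), length(nodes)), nodes)
  order_nodes <- character(0)
  frontier <- nodes[indeg == 0]
  indeg_w <- indeg
  while (length(frontier)) {
    nd <- frontier[1L]; frontier <- frontier[-1L]
    order_nodes <- c(order_nodes, nd)
    for (e in which(ed$from == nd)) {
      indeg_w[ed$to[e]] <- indeg_w[ed$to[e]] - 1L
      if (indeg_w[ed$to[e]] == 0L) frontier <- c(frontier, ed$to[e])
    }
  }
  if (length(order_nodes) != length(nodes)) {
    stop("transport network contains a directed cycle", call. = FALSE)
  }
  roots <- nodes[indeg == 0]
  # stability: dt <= 1 / (v/ds + 2 D/ds^2), with margin
  dt_lim <- 0.9 / max(v / ed$ds + 2 * diffusivity / ed$ds^2)
  nsub <- max(1L, as.integer(ceiling(bolus$time_step / dt_lim)))
  dts <- bolus$time_step / nsub
  nt <- as.integer(round(bolus$total_time / bolus$time_step))
  times <- seq(0, by = bolus$time_step, length.out = nt + 1L)
  conc_e <- lapply(seq_len(ne), function(e) numeric(ed$n[e]))
  nsamp <- sum(ed$n)
  samples <- data.frame(
    edge = rep(ed$id, ed$n),
    s = unlist(lapply(seq_len(ne),
                      function(e) (seq_len(ed$n[e]) - 0.5) * ed$ds[e])),
    ds = rep(ed$ds, ed$n), A = rep(ed$A, ed$n),
    stringsAsFactors = FALSE)
  conc <- matrix(0, nrow = nt + 1L, ncol = nsamp)
  injected <- 0; outflow <- 0
  sig <- function(t) if (t < bolus$width) bolus$amplitude else 0
  edges_from <- split(seq_len(ne), ed$from)
  leaves <- setdiff(nodes, ed$from)
  t <- 0
  for (step in seq_len(nt)) {
    for (sub in seq_len(nsub)) {
      cin <- sig(t)
      # node concentrations in topological order
      cnode <- stats::setNames(numeric(length(nodes)), nodes)
      for (nd in order_nodes) {
        if (nd %in% roots) {
          cnode[nd] <- cin
        } else {
          ein <- which(ed$to == nd)
          qin <- Q[ein]
          cnode[nd] <- if (sum(qin) > 0) {
            sum(qin * vapply(ein, function(e) conc_e[[e]][ed$n[e]], 0)) / sum(qin)
          } else 0
        }
      }
      for (e in seq_len(ne)) {
        ce <- conc_e[[e]]
        n <- ed$n[e]; dse <- ed$ds[e]
        up <- c(cnode[[ed$from[e]]], ce[-n])
        adv <- v[e] * (ce - up) / dse
        lo <- c(ce[1L], ce[-n]); hi <- c(ce[-1L], ce[n]) # zero-flux ends
        dif <- diffusivity * (hi - 2 * ce + lo) / dse^2
        conc_e[[e]] <- ce + dts * (dif - adv)
      }
      # mass bookkeeping on the same discrete fluxes
      for (nd in roots) {
        for (e in edges_from[[nd]]) injected <- injected + Q[e] * cin * dts
      }
      for (e in which(ed$to %in% leaves)) {
        outflow <- outflow + Q[e] * conc_e[[e]][ed$n[e]] * dts
      }
      t <- t + dts
    }
    conc[step + 1L, ] <- unlist(conc_e)
  }
  stored <- sum(unlist(conc_e) * samples$A * samples$ds)
  balance <- if (injected > 0) {
    abs(injected - outflow - stored) / injected
  } else 0
  structure(list(times = times, samples = samples, conc = conc,
                 amplitude = bolus$amplitude, diffusivity = diffusivity,
                 mass = list(injected = injected, outflow = outflow,
                             stored = stored, balance_error = balance)),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf(paste0("Contrast concentration field: %d samples x %d times ",
                     "(0..%g s)\n"),
              ncol(x$conc), nrow(x$conc), max(x$times)))
  cat(sprintf("  mass balance error %.3g%%\n", 100 * x$mass$balance_error))
  invisible(x)
}

#' Render a virtual angiogram frame series
#'
#' Thresholds the concentration field at a fraction of the bolus amplitude
#' and samples it at the angiographic frame rate, producing the boolean
#' dye-occupancy series that the swept-volume flow estimator consumes.
#'
#' @param field a `concentration_field` from [simulate_bolus()].
#' @param frame_rate frames per second (default 2, typical of DSA runs).
#' @param threshold occupancy threshold as a fraction of the bolus
#'   amplitude, in (0, 1); default 0.1.
#' @return a [frame_series()].
#' @export
render_angiogram_frames <- function(field, frame_rate = 2, threshold = 0.1) {
  stopifnot(inherits(field, "concentration_field"))
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly between 0 and 1", call. = FALSE)
  }
  interval <- 1 / frame_rate
  dt <- field$times[2L] - field$times[1L]
  stride <- interval / dt
  if (abs(stride - round(stride)) > 1e-9) {
    stop("frame interval must be a multiple of the transport time step",
         call. = FALSE)
  }
  stride <- as.integer(round(stride))
  rows <- seq(1L, nrow(field$conc), by = stride)
  occ <- field$conc[rows, , drop = FALSE] >= threshold * field$amplitude
  geometry <- centerline_geometry(data.frame(
    branch = field$samples$edge, s = field$samples$s,
    A = field$samples$A, ds = field$samples$ds,
    stringsAsFactors = FALSE))
  frame_series(occ, interval = interval, geometry = geometry,
               times = field$times[rows])
}
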