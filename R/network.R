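#' Poiseuille hydraulic resistance of a cylindrical vessel segment
#'
#' Fully developed laminar resistance `128*mu*L/(pi*d^4)`, returned in the
#' clinical unit mmHg.s/ml. Used as the reduced-order surrogate for the
#' distributed viscous losses of a vessel segment.
#'
#' @param diameter lumen diameter in m.
#' @param length segment length in m.
#' @param mu dynamic viscosity in Pa.s.
#' @return hydraulic resistance in mmHg.s/ml.
#' @examples
#' poiseuille_resistance(3.8e-3, 10e-3, 4e-3) # ~0.0586 mmHg.s/ml
#' @export
poiseuille_resistance <- function(diameter, length, mu) {
  if (any(diameter <= 0) || any(length <= 0) || any(mu <= 0)) {
    stop("diameter, length and mu must be positive", call. = FALSE)
  }
  r_si <- 128 * mu * length / (pi * diameter^4)
  r_si / RES_SI
}

#' Lumped Darcy resistance of the nidus
#'
#' The nidus is modelled as an isotropic porous medium (momentum sink
#' `-mu/K * U`). Lumping the Darcy pressure drop over an effective
#' length-to-area ratio `alpha` gives the hydraulic resistance
#' `R = mu * alpha / K` (SI), reported in mmHg.s/ml. `alpha` is a calibrated
#' shape factor, not the geometric ratio of the bounding box: the tortuous
#' three-dimensional flow path through the nidus makes the effective ratio
#' larger than `L/(W*H)`.
#'
#' @param K permeability in m^2.
#' @param alpha shape factor (effective length/area) in 1/m.
#' @param mu dynamic viscosity in Pa.s.
#' @return hydraulic resistance in mmHg.s/ml; strictly decreasing in `K`.
#' @seealso [nidus_shape_factor()] for the exact inverse.
#' @export
darcy_resistance <- function(K, alpha, mu) {
  if (any(K <= 0)) stop("permeability K must be positive", call. = FALSE)
  if (any(alpha <= 0) || any(mu <= 0)) {
    stop("alpha and mu must be positive", call. = FALSE)
  }
  (mu * alpha / K) / RES_SI
}

#' Build a hydraulic flow network
#'
#' General resistive-network container used by [solve_flow()]. Nodes with
#' `fixed = TRUE` carry a prescribed pressure (mmHg); all other nodal
#' pressures are solved from flow conservation. A resistance outlet
#' boundary condition (outlet pressure equal to outlet flow times a
#' prescribed downstream resistance) is expressed by adding a ground edge
#' from that node to a zero-pressure node.
#'
#' @param nodes data.frame with columns `name`, `fixed` (logical),
#'   `pressure` (mmHg; `NA` for free nodes).
#' @param edges data.frame with columns `id`, `from`, `to`, `R`
#'   (mmHg.s/ml, strictly positive).
#' @return an object of class `flow_network`.
#' @export
flow_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "fixed", "pressure") %in% names(nodes)),
            all(c("id", "from", "to", "R") %in% names(edges)))
  if (anyDuplicated(nodes$name)) stop("duplicate node names", call. = FALSE)
  unknown <- setdiff(c(edges$from, edges$to), nodes$name)
  if (length(unknown)) {
    stop("edges reference undefined node(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  if (any(edges$R < 0)) stop("negative edge resistance", call. = FALSE)
  if (any(edges$R == 0)) {
    stop("zero edge resistance not supported; merge the nodes instead",
         call. = FALSE)
  }
  iso <- setdiff(nodes$name, c(edges$from, edges$to))
  if (length(iso)) {
    stop("isolated node(s): ", paste(iso, collapse = ", "), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "flow_network")
}

#' Solve the steady pressure/flow state of a resistive network
#'
#' Assembles the nodal conservation equations (a weighted graph Laplacian
#' over the free nodes) in sparse form and solves them directly. Edge flows
#' follow from the pressure differences. The network is linear: convective
#' losses are neglected, consistent with the laminar, low-Reynolds regime
#' of a peripheral AVM (inlet Re of order 150).
#'
#' @param network a [flow_network()].
#' @return an object of class `flow_solution`: `pressures` (named, mmHg),
#'   `flows` (data.frame `id, from, to, R, Q` with Q in ml/s, positive in
#'   the `from -> to` direction), and `residual` (largest relative nodal
#'   flow imbalance).
#' @export
solve_flow <- function(network) {
  stopifnot(inherits(network, "flow_network"))
  nodes <- network$nodes
  edges <- network$edges
  # SI assembly
  g <- 1 / (edges$R * RES_SI)               # conductances, m^3/(s.Pa)
  p_fixed <- nodes$pressure * MMHG_PA
  free <- !nodes$fixed
  if (!any(free)) {
    p_all <- p_fixed
  } else {
    idx <- integer(nrow(nodes))
    idx[free] <- seq_len(sum(free))
    fi <- match(edges$from, nodes$name)
    ti <- match(edges$to, nodes$name)
    tri_i <- integer(0); tri_j <- integer(0); tri_x <- numeric(0)
    b <- numeric(sum(free))
    add <- function(a, bnode, ge) {
      # contribution of edge conductance ge between node rows a (free) and bnode
      tri_i <<- c(tri_i, idx[a]); tri_j <<- c(tri_j, idx[a]); tri_x <<- c(tri_x, ge)
      if (free[bnode]) {
        tri_i <<- c(tri_i, idx[a]); tri_j <<- c(tri_j, idx[bnode])
        tri_x <<- c(tri_x, -ge)
      } else {
        b[idx[a]] <<- b[idx[a]] + ge * p_fixed[bnode]
      }
    }
    for (e in seq_len(nrow(edges))) {
      if (free[fi[e]]) add(fi[e], ti[e], g[e])
      if (free[ti[e]]) add(ti[e], fi[e], g[e])
    }
    A <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x,
                              dims = c(sum(free), sum(free)))
    p_free <- tryCatch(
      as.numeric(Matrix::solve(A, b)),
      error = function(e) stop("singular network system (disconnected graph?): ",
                               conditionMessage(e), call. = FALSE))
    p_all <- p_fixed
    p_all[free] <- p_free
  }
  fi <- match(edges$from, nodes$name)
  ti <- match(edges$to, nodes$name)
  Q_si <- (p_all[fi] - p_all[ti]) * g        # m^3/s
  # nodal imbalance (free nodes only), relative to the largest edge flow
  imb <- numeric(nrow(nodes))
  for (e in seq_len(nrow(edges))) {
    imb[fi[e]] <- imb[fi[e]] - Q_si[e]
    imb[ti[e]] <- imb[ti[e]] + Q_si[e]
  }
  scale <- max(abs(Q_si), 1e-300)
  residual <- max(abs(imb[free]) / scale, 0)
  flows <- data.frame(id = edges$id, from = edges$from, to = edges$to,
                      R = edges$R, Q = Q_si / ML_M3,
                      stringsAsFactors = FALSE)
  structure(list(
    pressures = stats::setNames(p_all / MMHG_PA, nodes$name),
    flows = flows, residual = residual, network = network),
    class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("Steady network flow solution\n")
  cat(sprintf("  %d nodes, %d edges, conservation residual %.2e\n",
              length(x$pressures), nrow(x$flows), x$residual))
  print(x$flows[, c("id", "from", "to", "Q")], row.names = FALSE)
  invisible(x)
}

# ---- AVM-specific stage network -------------------------------------------

#' Build the lumped AVM network for one intervention stage
#'
#' Topology: inlet --R_feed--> junction; junction --R_AO--> arterial outlet
#' (closed by the resistance boundary condition R_art to zero pressure);
#' junction --R_nidus--> venous confluence --parallel venous lumps-->
#' venous outlets at the prescribed venous pressure. Venous outlets share
#' the calibrated venous lump `R_ven` in parallel, apportioned by the
#' fourth power of their printed diameters.
#'
#' @param case an [avm_case()].
#' @param resistances named list/vector with `R_feed`, `R_AO`, `R_ven`
#'   (mmHg.s/ml), e.g. `coef()` of a fitted [avm_model()].
#' @param R_nidus nidus hydraulic resistance for the stage (mmHg.s/ml).
#' @return a `flow_network` with an `avm_roles` attribute naming the
#'   inlet/nidus/arterial edges.
#' @export
build_stage_network <- function(case, resistances, R_nidus) {
  stopifnot(inherits(case, "avm_case"))
  r <- as.list(resistances)
  for (f in c("R_feed", "R_AO", "R_ven")) {
    if (is.null(r[[f]]) || !is.finite(r[[f]]) || r[[f]] < 0) {
      stop("resistances must supply non-negative ", f, call. = FALSE)
    }
  }
  if (!is.finite(R_nidus) || R_nidus <= 0) {
    stop("R_nidus must be positive", call. = FALSE)
  }
  ven <- case$segments[case$segments$kind == "venous", , drop = FALSE]
  w <- ven$diameter^4
  # parallel split of the venous lump: R_k = R_ven * sum(w) / w_k
  R_k <- r$R_ven * sum(w) / w
  bc <- case$boundary
  nodes <- data.frame(
    name = c("inlet", "junction", "art_outlet", "art_ground",
             "ven_confluence", paste0("ven_", ven$id)),
    fixed = c(TRUE, FALSE, FALSE, TRUE, FALSE, rep(TRUE, nrow(ven))),
    pressure = c(bc$P_in, NA, NA, 0, NA, rep(bc$P_ven, nrow(ven))),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    id = c("feeding", "arterial", "R_art_bc", "nidus",
           paste0("venous_", ven$id)),
    from = c("inlet", "junction", "art_outlet", "junction",
             rep("ven_confluence", nrow(ven))),
    to = c("junction", "art_outlet", "art_ground", "ven_confluence",
           paste0("ven_", ven$id)),
    R = c(r$R_feed, r$R_AO, bc$R_art, R_nidus, R_k),
    stringsAsFactors = FALSE)
  net <- flow_network(nodes, edges)
  attr(net, "avm_roles") <- list(inlet = "feeding", nidus = "nidus",
                                 arterial = "arterial",
                                 venous = paste0("venous_", ven$id))
  net
}

#' Summarise an AVM stage solution
#'
#' @param solution a `flow_solution` from [solve_flow()] on a network built
#'   by [build_stage_network()].
#' @return one-row data.frame: `Q_inlet`, `Q_nidus`, `Q_art` (ml/s),
#'   `nidus_fraction` (Q_nidus/Q_inlet), `art_to_ven_ratio`
#'   (Q_art/Q_nidus), `dP_nidus` and `dP_inlet_venous` (mmHg), `success`
#'   (nidus carries at most 1 percent of the inlet flow — the angiographic
#'   endpoint of embolisation).
#' @export
summarise_stage <- function(solution) {
  roles <- attr(solution$network, "avm_roles")
  if (is.null(roles)) stop("not an AVM stage solution", call. = FALSE)
  f <- solution$flows
  q <- function(id) f$Q[match(id, f$id)]
  Q_in <- q(roles$inlet); Q_nid <- q(roles$nidus); Q_art <- q(roles$arterial)
  p <- solution$pressures
  data.frame(
    Q_inlet = Q_in, Q_nidus = Q_nid, Q_art = Q_art,
    nidus_fraction = Q_nid / Q_in,
    art_to_ven_ratio = Q_art / Q_nid,
    dP_nidus = p[["junction"]] - p[["ven_confluence"]],
    dP_inlet_venous = p[["inlet"]] - min(p[grep("^ven_", names(p))]),
    success = (Q_nid / Q_in) <= 0.01)
}

#' Simulate every intervention stage of a case
#'
#' For each stage the nidus resistance is taken, in order of precedence,
#' from the stage's prescribed `R_nidus`, from its permeability `K` through
#' the calibrated shape factor, or — when only a DSA inlet-flow target is
#' recorded — by calibrating `K` to that target with
#' [calibrate_stage_permeability()]. A stage providing none of the three
#' raises an error naming the stage.
#'
#' @param case an [avm_case()].
#' @param calibration a `calibration_result` from
#'   [calibrate_reference_resistances()] (or a fitted [avm_model()]).
#' @return data.frame, one row per stage, with the [summarise_stage()]
#'   columns plus `stage`, `R_nidus` (mmHg.s/ml) and `K` (m^2).
#' @export
simulate_stages <- function(case, calibration) {
  if (inherits(calibration, "avm_model")) calibration <- calibration$calibration
  stopifnot(inherits(case, "avm_case"),
            inherits(calibration, "calibration_result"))
  mu <- case$fluid$viscosity
  alpha <- calibration$alpha
  out <- NULL
  for (i in seq_len(nrow(case$stages))) {
    st <- case$stages[i, ]
    if (is.finite(st$R_nidus) && st$R_nidus > 0) {
      R <- st$R_nidus
      K <- if (is.finite(st$K)) st$K else
        if (is.finite(alpha)) mu * alpha / (R * RES_SI) else NA_real_
    } else if (is.finite(st$K) && st$K > 0) {
      if (!is.finite(alpha)) {
        stop("stage '", st$name,
             "' gives K but no shape factor is calibrated", call. = FALSE)
      }
      K <- st$K
      R <- darcy_resistance(K, alpha, mu)
    } else if (is.finite(st$Q_target) && st$Q_target > 0) {
      fit <- calibrate_stage_permeability(case, calibration, st$Q_target)
      K <- fit$K; R <- fit$R_nidus
    } else {
      stop("stage '", st$name,
           "' supplies neither R_nidus, K nor a flow target", call. = FALSE)
    }
    net <- build_stage_network(case, calibration$resistances, R)
    row <- summarise_stage(solve_flow(net))
    out <- rbind(out, cbind(data.frame(stage = st$name, R_nidus = R, K = K,
                                       stringsAsFactors = FALSE), row))
  }
  rownames(out) <- NULL
  out
}

#' Inlet Reynolds number of a stage solution
#'
#' `Re = rho * v * D / mu` with the mean velocity `v = Q_inlet / (pi D^2/4)`
#' in the feeding artery.
#'
#' @param Q_inlet inlet flow rate in ml/s (or a `flow_solution` / one-row
#'   stage summary from which `Q_inlet` is taken).
#' @param diameter feeding-artery diameter in m.
#' @param fluid a [fluid_properties()].
#' @return dimensionless Reynolds number.
#' @export
reynolds_inlet <- function(Q_inlet, diameter, fluid) {
  if (is.data.frame(Q_inlet)) Q_inlet <- Q_inlet$Q_inlet[1L]
  if (inherits(Q_inlet, "flow_solution")) {
    Q_inlet <- summarise_stage(Q_inlet)$Q_inlet
  }
  if (diameter <= 0) stop("diameter must be positive", call. = FALSE)
  if (Q_inlet < 0) stop("Q_inlet must be non-negative", call. = FALSE)
  v <- (Q_inlet * ML_M3) / (pi * diameter^2 / 4)
  fluid$density * v * diameter / fluid$viscosity
}
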