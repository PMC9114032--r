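#' Shape factor linking nidus permeability to its lumped resistance
#'
#' Exact inverse of [darcy_resistance()]: `alpha = R_SI * K / mu` with `R`
#' converted to Pa.s/m^3. Evaluating it at the baseline (K, R) pair anchors
#' the permeability-to-resistance map used for stage calibration. Note the
#' calibrated value (about 220 1/m for the reference lesion) exceeds the
#' geometric bounding-box ratio `L/(W*H)` (about 148 1/m): the effective
#' flow path through the nidus tangle is longer and narrower than the box.
#'
#' @param K permeability in m^2.
#' @param R hydraulic resistance in mmHg.s/ml.
#' @param mu dynamic viscosity in Pa.s.
#' @return shape factor in 1/m.
#' @export
nidus_shape_factor <- function(K, R, mu) {
  if (any(K <= 0) || any(R <= 0) || any(mu <= 0)) {
    stop("K, R and mu must be positive", call. = FALSE)
  }
  (R * RES_SI) * K / mu
}

#' Calibrate the three lumped resistances of the AVM network
#'
#' With the inlet pressure `P_in` and the arterial outlet resistance
#' `R_art` fixed at their known values, the three unknown lumped
#' resistances (feeding path `R_feed`, arterial-outlet path `R_AO`, venous
#' path `R_ven`) are determined from three flow conditions: the baseline
#' inlet flow and nidus flow, and the completion-stage inlet flow. The
#' first two conditions are linear in the lumps once `R_feed` is fixed, so
#' the system reduces to a one-dimensional root find in `R_feed` (bracketed
#' bisection via [stats::uniroot()]), followed by verification of all three
#' targets through [solve_flow()].
#'
#' @param case an [avm_case()] whose baseline stage supplies `R_nidus`,
#'   `Q_target` (inlet flow, ml/s) and `Q_nidus_target` (ml/s), and whose
#'   final stage supplies `R_nidus` and `Q_target`.
#' @return an object of class `calibration_result` with elements
#'   `resistances` (named vector `R_feed`, `R_AO`, `R_ven` in mmHg.s/ml),
#'   `alpha` (shape factor from the baseline (K, R) pair, 1/m; `NA` if the
#'   baseline K is not given), `stages` (per-stage fitted K and R_nidus),
#'   `residual` (largest relative mismatch of the three targets after
#'   re-solving) and `iterations`.
#' @export
calibrate_reference_resistances <- function(case) {
  stopifnot(inherits(case, "avm_case"))
  st <- case$stages
  base <- st[1L, ]
  if (!is.finite(base$R_nidus) || !is.finite(base$Q_target)) {
    stop("baseline stage must supply R_nidus and Q_target", call. = FALSE)
  }
  if (is.null(st$Q_nidus_target) || !is.finite(base$Q_nidus_target)) {
    stop("baseline stage must supply Q_nidus_target", call. = FALSE)
  }
  comp_i <- max(which(is.finite(st$R_nidus) & is.finite(st$Q_target)))
  if (comp_i == 1L) {
    stop("a completion stage with R_nidus and Q_target is required",
         call. = FALSE)
  }
  comp <- st[comp_i, ]
  P_in <- case$boundary$P_in - case$boundary$P_ven
  R_art <- case$boundary$R_art
  Qb <- base$Q_target; Qnb <- base$Q_nidus_target; Qab <- Qb - Qnb
  if (Qnb >= Qb) {
    stop("calibration infeasible: baseline Q_nidus target (", Qnb,
         ") must be below the inlet target (", Qb, ")", call. = FALSE)
  }
  Rb <- base$R_nidus; Rc <- comp$R_nidus; Qc_t <- comp$Q_target
  lumps_of <- function(R_feed) {
    PJ <- P_in - Qb * R_feed
    c(R_feed = R_feed, R_AO = PJ / Qab - R_art, R_ven = PJ / Qnb - Rb)
  }
  q_completion <- function(r) {
    par <- 1 / (1 / (r[["R_AO"]] + R_art) + 1 / (Rc + r[["R_ven"]]))
    P_in / (r[["R_feed"]] + par)
  }
  f <- function(R_feed) q_completion(lumps_of(R_feed)) - Qc_t
  # feasible R_feed keeps both eliminated lumps non-negative
  upper <- min((P_in - Qab * R_art) / Qb, (P_in - Qnb * Rb) / Qb)
  if (!is.finite(upper) || upper <= 0) {
    stop("calibration infeasible: P_in too low for the baseline targets",
         call. = FALSE)
  }
  eps <- 1e-12
  flo <- f(eps); fhi <- f(upper * (1 - 1e-12))
  if (flo * fhi > 0) {
    stop("calibration infeasible: completion inlet-flow target ", Qc_t,
         " ml/s is outside the attainable range [",
         signif(min(flo, fhi) + Qc_t, 6), ", ",
         signif(max(flo, fhi) + Qc_t, 6), "] ml/s", call. = FALSE)
  }
  root <- stats::uniroot(f, c(eps, upper * (1 - 1e-12)), tol = 1e-14)
  r <- lumps_of(root$root)
  if (any(r < -1e-9)) {
    stop("calibration infeasible: fitted resistance negative (",
         paste(names(r)[r < 0], collapse = ", "), ")", call. = FALSE)
  }
  r <- pmax(r, 0)
  mu <- case$fluid$viscosity
  alpha <- if (is.finite(base$K) && base$K > 0) {
    nidus_shape_factor(base$K, base$R_nidus, mu)
  } else NA_real_
  # verify all three targets through the actual network solver
  sb <- summarise_stage(solve_flow(build_stage_network(case, r, Rb)))
  sc <- summarise_stage(solve_flow(build_stage_network(case, r, Rc)))
  residual <- max(abs(sb$Q_inlet - Qb) / Qb,
                  abs(sb$Q_nidus - Qnb) / Qnb,
                  abs(sc$Q_inlet - Qc_t) / Qc_t)
  stage_fit <- data.frame(
    stage = st$name,
    K = ifelse(is.finite(st$K), st$K,
               ifelse(is.finite(st$R_nidus) & is.finite(alpha),
                      mu * alpha / (st$R_nidus * RES_SI), NA_real_)),
    R_nidus = st$R_nidus, stringsAsFactors = FALSE)
  structure(list(resistances = r, alpha = alpha, stages = stage_fit,
                 residual = residual, iterations = root$iter,
                 targets = c(Q_inlet_baseline = Qb, Q_nidus_baseline = Qnb,
                             Q_inlet_completion = Qc_t)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("AVM network calibration\n")
  cat(sprintf("  R_feed = %.4g, R_AO = %.4g, R_ven = %.4g mmHg.s/ml\n",
              x$resistances[["R_feed"]], x$resistances[["R_AO"]],
              x$resistances[["R_ven"]]))
  if (is.finite(x$alpha)) {
    cat(sprintf("  nidus shape factor alpha = %.4g 1/m\n", x$alpha))
  }
  cat(sprintf("  target residual %.2e (%d iterations)\n",
              x$residual, x$iterations))
  invisible(x)
}

#' Calibrate the nidus permeability of a stage from its inlet-flow target
#'
#' The inlet flow of the calibrated network is a strictly increasing
#' function of the nidus permeability `K`, so the stage value is found by
#' bracketed root finding on `log10 K` until the solved inlet flow matches
#' the DSA-derived target to within 1e-6 ml/s. Targets outside the
#' attainable range (between the fully occluded and fully open limits)
#' raise an error that reports the bounds.
#'
#' @param case an [avm_case()].
#' @param calibration a `calibration_result` (or fitted [avm_model()]).
#' @param target_Q_inlet stage inlet flow target in ml/s.
#' @param log10K_bracket search bracket for `log10(K)`; the result is
#'   invariant to any bracket containing the root.
#' @return list with `K` (m^2), `R_nidus` (mmHg.s/ml), `Q_inlet` achieved
#'   (ml/s) and `iterations`.
#' @export
calibrate_stage_permeability <- function(case, calibration, target_Q_inlet,
                                         log10K_bracket = c(-16, -2)) {
  if (inherits(calibration, "avm_model")) calibration <- calibration$calibration
  stopifnot(inherits(case, "avm_case"),
            inherits(calibration, "calibration_result"))
  alpha <- calibration$alpha
  if (!is.finite(alpha)) {
    stop("calibration carries no shape factor; supply a baseline K",
         call. = FALSE)
  }
  mu <- case$fluid$viscosity
  q_of <- function(l10K) {
    R <- darcy_resistance(10^l10K, alpha, mu)
    summarise_stage(solve_flow(
      build_stage_network(case, calibration$resistances, R)))$Q_inlet
  }
  qlo <- q_of(log10K_bracket[1L]); qhi <- q_of(log10K_bracket[2L])
  if (target_Q_inlet < qlo || target_Q_inlet > qhi) {
    stop(sprintf(paste0("target %.6g ml/s outside attainable range ",
                        "[%.6g, %.6g] ml/s"),
                 target_Q_inlet, qlo, qhi), call. = FALSE)
  }
  root <- stats::uniroot(function(x) q_of(x) - target_Q_inlet,
                         log10K_bracket, tol = 1e-12)
  K <- 10^root$root
  R <- darcy_resistance(K, alpha, mu)
  Q <- q_of(root$root)
  if (abs(Q - target_Q_inlet) > 1e-6) {
    stop("stage permeability root finding did not converge to 1e-6 ml/s",
         call. = FALSE)
  }
  list(K = K, R_nidus = R, Q_inlet = Q, iterations = root$iter)
}

#' Interpolate the permeability of an undocumented stage
#'
#' When one intervention stage lacks angiographic data its permeability is
#' interpolated from three documented stages: the unique quadratic through
#' the three known points is fitted in (stage index, log10 K) space —
#' permeability spans more than four decades over an intervention, so
#' interpolating the logarithm keeps every knot influential — and evaluated
#' at the missing index.
#'
#' @param stages data.frame (or 2-column matrix) of exactly three known
#'   `(index, K)` pairs with distinct indices; `K` in m^2.
#' @param missing_index stage index to interpolate at.
#' @return interpolated permeability K in m^2 (positive by construction).
#' @export
interpolate_missing_stage <- function(stages, missing_index) {
  stages <- as.data.frame(stages)
  names(stages)[1:2] <- c("index", "K")
  if (nrow(stages) != 3L) {
    stop("exactly three known (index, K) pairs are required", call. = FALSE)
  }
  if (anyDuplicated(stages$index)) {
    stop("duplicate stage indices", call. = FALSE)
  }
  if (any(stages$K <= 0)) stop("K values must be positive", call. = FALSE)
  if (missing_index < min(stages$index) || missing_index > max(stages$index)) {
    warning("missing index ", missing_index,
            " lies outside the known bracket; extrapolating")
  }
  x <- stages$index; y <- log10(stages$K)
  V <- cbind(1, x, x^2)
  coefs <- solve(V, y)
  unname(10^(coefs[1L] + coefs[2L] * missing_index +
               coefs[3L] * missing_index^2))
}
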