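#' Fit the reduced-order AVM haemodynamic model to a case
#'
#' The central fitting function of the package. Given a case configuration
#' (printed boundary conditions, baseline and completion nidus resistances,
#' and DSA-derived flow targets) it calibrates the three unknown lumped
#' resistances of the network with
#' [calibrate_reference_resistances()], anchors the permeability-to-
#' resistance map at the baseline (K, R) pair, and pre-computes the
#' per-stage haemodynamics. The returned object supports the usual
#' modelling verbs: `print`, `summary`, `coef`, `predict`, `fitted`,
#' `residuals`, `plot` and `simulate`.
#'
#' @param case an [avm_case()], e.g. [make_reference_case()].
#' @return an object of class `avm_model` with elements `case`,
#'   `calibration` (a `calibration_result`) and `stages` (the
#'   [simulate_stages()] table).
#' @examples
#' fit <- avm_model(make_reference_case())
#' coef(fit)
#' predict(fit)
#' @export
avm_model <- function(case) {
  stopifnot(inherits(case, "avm_case"))
  calibration <- calibrate_reference_resistances(case)
  stages <- simulate_stages(case, calibration)
  structure(list(case = case, calibration = calibration, stages = stages),
            class = "avm_model")
}

#' @export
print.avm_model <- function(x, ...) {
  cat("Reduced-order AVM embolo-sclerotherapy model\n\n")
  print(x$calibration)
  cat("\nStage haemodynamics:\n")
  df <- x$stages
  df$nidus_fraction <- sprintf("%.1f%%", 100 * df$nidus_fraction)
  print(df[, c("stage", "R_nidus", "Q_inlet", "Q_nidus", "Q_art",
               "nidus_fraction", "success")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.avm_model <- function(object, ...) {
  c(object$calibration$resistances,
    alpha = unname(object$calibration$alpha))
}

#' @export
fitted.avm_model <- function(object, ...) {
  stats::setNames(object$stages$Q_inlet, object$stages$stage)
}

#' Residuals of the fitted AVM model against the DSA measurements
#'
#' Difference between the model's stage inlet flows and the DSA-derived
#' measurements recorded in the case (model minus measurement, ml/s).
#' Stages used directly as calibration targets have residuals near zero;
#' a large positive completion residual reflects post-intervention
#' vascular adaptation (e.g. lowered central pressure) that a fixed-
#' boundary-condition model cannot capture.
#'
#' @param object a fitted `avm_model`.
#' @param ... unused.
#' @return named numeric vector, one element per measured stage.
#' @export
residuals.avm_model <- function(object, ...) {
  tg <- object$case$dsa_targets
  if (is.null(tg)) return(stats::setNames(numeric(0), character(0)))
  m <- match(tg$stage, object$stages$stage)
  stats::setNames(object$stages$Q_inlet[m] - tg$Q_mean, tg$stage)
}

#' @export
summary.avm_model <- function(object, ...) {
  out <- list(coefficients = coef(object), stages = object$stages,
              residuals = residuals(object),
              calibration_residual = object$calibration$residual,
              Re_inlet = reynolds_inlet(
                object$stages$Q_inlet[1L],
                object$case$segments$diameter[
                  object$case$segments$kind == "feeding"][1L] * 1e-3,
                object$case$fluid))
  class(out) <- "summary.avm_model"
  out
}

#' @export
print.summary.avm_model <- function(x, ...) {
  cat("Calibrated lumped resistances (mmHg.s/ml) and shape factor (1/m):\n")
  print(signif(x$coefficients, 5))
  cat(sprintf("\nCalibration target residual: %.2e\n", x$calibration_residual))
  cat(sprintf("Baseline inlet Reynolds number: %.0f (laminar)\n", x$Re_inlet))
  cat("\nStage haemodynamics:\n")
  print(x$stages, row.names = FALSE, digits = 4)
  if (length(x$residuals)) {
    cat("\nModel - DSA inlet-flow residuals (ml/s):\n")
    print(signif(x$residuals, 4))
  }
  invisible(x)
}

#' Predict stage haemodynamics from a fitted AVM model
#'
#' Without arguments, returns the per-stage table for the case's own
#' stages. Alternatively predict for explicit nidus permeabilities or
#' resistances, e.g. to sweep candidate sclerotherapy endpoints.
#'
#' @param object a fitted `avm_model`.
#' @param K optional vector of nidus permeabilities (m^2).
#' @param R_nidus optional vector of nidus resistances (mmHg.s/ml);
#'   overrides `K`.
#' @param ... unused.
#' @return data.frame of stage summaries (one row per stage or per swept
#'   value).
#' @export
predict.avm_model <- function(object, K = NULL, R_nidus = NULL, ...) {
  if (is.null(K) && is.null(R_nidus)) return(object$stages)
  mu <- object$case$fluid$viscosity
  if (is.null(R_nidus)) {
    R_nidus <- darcy_resistance(K, object$calibration$alpha, mu)
  } else if (is.null(K)) {
    K <- if (is.finite(object$calibration$alpha)) {
      mu * object$calibration$alpha / (R_nidus * RES_SI)
    } else rep(NA_real_, length(R_nidus))
  }
  out <- NULL
  for (i in seq_along(R_nidus)) {
    net <- build_stage_network(object$case, object$calibration$resistances,
                               R_nidus[i])
    row <- summarise_stage(solve_flow(net))
    out <- rbind(out, cbind(data.frame(R_nidus = R_nidus[i], K = K[i]), row))
  }
  rownames(out) <- NULL
  out
}

#' Plot the staged haemodynamics of a fitted AVM model
#'
#' Base-graphics panel of the inlet, nidus and arterial-outlet flow rates
#' across intervention stages, with the DSA measurements overlaid where
#' available.
#'
#' @param x a fitted `avm_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.avm_model <- function(x, ...) {
  st <- x$stages
  idx <- seq_len(nrow(st))
  graphics::matplot(idx, cbind(st$Q_inlet, st$Q_nidus, st$Q_art),
                    type = "b", pch = 19, lty = 1, xaxt = "n",
                    xlab = "intervention stage", ylab = "flow rate (ml/s)",
                    col = c("black", "firebrick", "steelblue"), ...)
  graphics::axis(1, at = idx, labels = st$stage, las = 2, cex.axis = 0.8)
  tg <- x$case$dsa_targets
  if (!is.null(tg)) {
    m <- match(tg$stage, st$stage)
    graphics::points(m, tg$Q_mean, pch = 4, cex = 1.4)
    has_sd <- is.finite(tg$Q_sd)
    if (any(has_sd)) {
      graphics::arrows(m[has_sd], tg$Q_mean[has_sd] - tg$Q_sd[has_sd],
                       m[has_sd], tg$Q_mean[has_sd] + tg$Q_sd[has_sd],
                       angle = 90, code = 3, length = 0.04)
    }
  }
  graphics::legend("topright",
                   c("Q_inlet", "Q_nidus", "Q_art", "DSA"),
                   col = c("black", "firebrick", "steelblue", "black"),
                   pch = c(19, 19, 19, 4), lty = c(1, 1, 1, NA), bty = "n")
  invisible(x)
}

#' Simulate virtual angiograms from a fitted AVM model
#'
#' Runs the contrast bolus over the solved flow field of one stage and
#' renders DSA-like frame series (the virtual angiogram). With `nsim > 1`
#' and a positive `noise` fraction, each replicate gets independently
#' flipped occupancy bits, emulating segmentation noise.
#'
#' @param object a fitted `avm_model`.
#' @param nsim number of frame-series replicates (default 1).
#' @param seed optional RNG seed.
#' @param stage stage name (default `"baseline"`).
#' @param what `"frames"` (default) or `"concentration"` to return the
#'   underlying `concentration_field` instead.
#' @param noise fraction of occupancy bits to flip per replicate
#'   (default 0).
#' @param threshold occupancy threshold for frame rendering.
#' @param ds transport cell size in m.
#' @param ... unused.
#' @return a list of [frame_series()] of length `nsim`, or a single
#'   `concentration_field`.
#' @export
simulate.avm_model <- function(object, nsim = 1, seed = NULL,
                               stage = "baseline",
                               what = c("frames", "concentration"),
                               noise = 0, threshold = 0.1, ds = 1e-3, ...) {
  what <- match.arg(what)
  if (!is.null(seed)) set.seed(seed)
  st <- object$stages
  i <- match(stage, st$stage)
  if (is.na(i)) stop("unknown stage: ", stage, call. = FALSE)
  net <- build_stage_network(object$case, object$calibration$resistances,
                             st$R_nidus[i])
  sol <- solve_flow(net)
  geom <- avm_transport_geometry(object$case, ds = ds)
  field <- simulate_bolus(sol, geom, object$case$bolus,
                          diffusivity = object$case$dsa$diffusivity)
  if (what == "concentration") return(field)
  base <- render_angiogram_frames(field, object$case$dsa$frame_rate,
                                  threshold)
  lapply(seq_len(nsim), function(k) {
    if (noise > 0) flip_occupancy_bits(base, noise) else base
  })
}

# flip a seeded fraction of occupancy bits (noise model for synthetic DSA)
flip_occupancy_bits <- function(series, fraction) {
  occ <- series$occupancy
  nflip <- round(fraction * length(occ))
  if (nflip > 0) {
    idx <- sample.int(length(occ), nflip)
    occ[idx] <- !occ[idx]
  }
  frame_series(occ, interval = series$interval,
               geometry = series$geometry, times = series$times)
}
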