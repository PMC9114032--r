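# single straight tube carrying a prescribed flow, reused across tests
tube_setup <- function(Q_mls, L = 0.1, A = 1e-5, ds = 1e-3) {
  net <- flow_network(
    nodes = data.frame(name = c("in", "out"), fixed = c(TRUE, TRUE),
                       pressure = c(10, 0)),
    edges = data.frame(id = "tube", from = "in", to = "out",
                       R = 10 / Q_mls))
  geom <- transport_geometry(
    data.frame(id = "tube", from = "in", to = "out", L = L, A = A), ds = ds)
  list(sol = solve_flow(net), geom = geom)
}

front_arrival <- function(field, sample_idx, level = 0.5) {
  crossed <- which(field$conc[, sample_idx] >= level * field$amplitude)
  if (!length(crossed)) return(NA_real_)
  field$times[min(crossed)]
}

test_that("a pure-advection bolus front arrives at L/v", {
  # v = Q/A = 1e-6/1e-5 = 0.1 m/s over L = 0.1 m -> arrival at 1.0 s
  tu <- tube_setup(1)
  field <- simulate_bolus(tu$sol, tu$geom, bolus_spec(total_time = 3))
  n <- nrow(tu$geom$edges); last <- sum(tu$geom$edges$n)
  t_arr <- front_arrival(field, last)
  t_ref <- oracle_arrival_time(0.1, 0.1)
  # within one grid cell of travel time
  expect_lt(abs(t_arr - t_ref), 1e-3 / 0.1 + 0.011)
})

test_that("transport conserves mass and respects the maximum principle", {
  fit <- avm_model(make_reference_case())
  field <- simulate(fit, stage = "baseline", what = "concentration")
  expect_lt(field$mass$balance_error, 0.005)
  expect_gte(min(field$conc), -1e-12)
  expect_lte(max(field$conc), field$amplitude + 1e-12)
  # a plain tube too, at a different CFL
  tu <- tube_setup(0.4)
  f2 <- simulate_bolus(tu$sol, tu$geom, bolus_spec())
  expect_lt(f2$mass$balance_error, 0.005)
  expect_gte(min(f2$conc), -1e-12)
  expect_lte(max(f2$conc), f2$amplitude + 1e-12)
})

test_that("baseline dye perfuses all outlets; completion bypasses the nidus", {
  fit <- avm_model(make_reference_case())
  base <- simulate(fit, stage = "baseline", what = "concentration")
  frames <- render_angiogram_frames(base, 2, 0.1)
  branch <- frames$geometry$samples$branch
  reached <- tapply(apply(frames$occupancy, 2, any), branch, all)
  expect_true(all(reached[c("feeding", "arterial", "nidus",
                            "venous_VO1", "venous_VO2")]))
  # front-arrival kinematics oracle: dye must clear the slowest path
  # (feeding -> nidus -> widest vein) well before the 5 s horizon
  sol <- solve_flow(build_stage_network(fit$case, coef(fit)[1:3],
                                        fit$stages$R_nidus[1]))
  geom <- avm_transport_geometry(fit$case)
  ed <- geom$edges
  Q <- sol$flows$Q[match(ed$id, sol$flows$id)] * 1e-6
  v <- abs(Q) / ed$A
  slow <- oracle_arrival_time(ed$L[ed$id %in% c("feeding", "nidus",
                                                "venous_VO1")],
                              v[ed$id %in% c("feeding", "nidus",
                                             "venous_VO1")])
  expect_lt(slow, 5)
  # completion: flow bypasses the nidus almost completely
  comp <- simulate(fit, stage = "Post AE III", what = "concentration")
  nid <- comp$samples$edge == "nidus"
  mean_conc <- sum(comp$conc[nrow(comp$conc), nid] * comp$samples$ds[nid]) /
    sum(comp$samples$ds[nid])
  expect_lt(mean_conc, 0.01 * comp$amplitude)
  fr_c <- render_angiogram_frames(comp, 2, 0.1)
  expect_false(any(fr_c$occupancy[, frames$geometry$samples$branch == "nidus"]))
})

test_that("zero inlet flow leaves the field identically zero", {
  case <- make_reference_case()
  case$boundary$P_in <- 0
  net <- build_stage_network(case, c(R_feed = 1, R_AO = 16, R_ven = 16),
                             0.33)
  sol <- solve_flow(net)
  geom <- avm_transport_geometry(case)
  field <- simulate_bolus(sol, geom, bolus_spec(width = 0.5, total_time = 1))
  expect_true(all(field$conc == 0))
})

test_that("front arrival is stable under grid refinement", {
  t_of <- function(ds) {
    tu <- tube_setup(1, ds = ds)
    field <- simulate_bolus(tu$sol, tu$geom, bolus_spec(total_time = 3))
    front_arrival(field, sum(tu$geom$edges$n))
  }
  t1 <- t_of(1e-3); t2 <- t_of(5e-4)
  expect_lt(abs(t1 - t2) / t2, 0.02)
})

test_that("Peclet numbers reproduce the model/phantom similarity pair", {
  v_model <- 1.645e-6 / (pi * 3.8e-3^2 / 4)
  Pe_model <- peclet_number(3.8e-3, v_model, 2.2e-10)
  expect_equal(Pe_model, 2.5e6, tolerance = 0.01)
  # phantom at 2:1 scale with doubled flow and dye diffusivity 2e-10
  v_phantom <- 2 * 1.645e-6 / (pi * 7.6e-3^2 / 4)
  Pe_phantom <- peclet_number(7.6e-3, v_phantom, 2e-10)
  expect_equal(Pe_phantom, 2.76e6, tolerance = 0.01)
  # invariance: doubling D and halving v leaves Pe unchanged
  expect_equal(peclet_number(2 * 3.8e-3, v_model / 2, 2.2e-10), Pe_model,
               tolerance = 1e-12)
  expect_error(peclet_number(0, 1, 1), "positive")
})

test_that("angiogram rendering thresholds and timestamps are correct", {
  tu <- tube_setup(0.4)  # v = 0.04 m/s
  field <- simulate_bolus(tu$sol, tu$geom, bolus_spec())
  fr <- render_angiogram_frames(field, 2, 0.5)
  expect_equal(fr$times, seq(0, 5, by = 0.5))
  # kinematic oracle: the front advances v / frame_rate = 0.02 m per frame
  pos <- apply(fr$occupancy, 1, function(o) {
    if (!any(o)) 0 else max(fr$geometry$samples$s[o])
  })
  adv <- diff(pos[2:5])   # early frames, front well inside the tube
  expect_true(all(abs(adv - 0.02) <= 1e-3 + 1e-9))
  # uniform saturated field -> everything occupied
  sat <- field; sat$conc[] <- field$amplitude
  fr_sat <- render_angiogram_frames(sat, 2, 0.5)
  expect_true(all(fr_sat$occupancy))
  # occupancy shrinks monotonically with threshold
  n_low <- sum(render_angiogram_frames(field, 2, 0.1)$occupancy)
  n_high <- sum(render_angiogram_frames(field, 2, 0.999)$occupancy)
  expect_lt(n_high, n_low)
  expect_error(render_angiogram_frames(field, 2, 1.5), "threshold")
  expect_error(render_angiogram_frames(field, 3, 0.5), "multiple")
})
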