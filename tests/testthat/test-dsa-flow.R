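uniform_geom <- function(n = 100, A = 0.1e-4, ds = 0.01) {
  # A in m^2 (0.1 cm^2), ds in m (1 cm)
  centerline_geometry(data.frame(branch = "tube",
                                 s = (seq_len(n) - 0.5) * ds,
                                 A = A, ds = ds))
}

test_that("swept volume sums newly occupied sample volumes", {
  g <- uniform_geom()
  # front advance of 2 cm in a 0.1 cm^2 tube -> 0.2 ml
  a <- rep(FALSE, 100); a[1:10] <- TRUE
  b <- rep(FALSE, 100); b[1:12] <- TRUE
  expect_equal(swept_volume(g, a, b), 0.2, tolerance = 1e-12)
  expect_equal(swept_volume(g, a, a), 0)
  # wash-out samples do not contribute negative volume
  c_ <- rep(FALSE, 100); c_[5:12] <- TRUE
  expect_equal(swept_volume(g, a, c_), 0.2, tolerance = 1e-12)
  expect_error(swept_volume(g, a[1:50], b), "does not match")
})

test_that("repeated windows aggregate as mean and sample SD", {
  # constructed triple consistent with a 1.645 +/- 0.040 ml/s measurement
  g <- uniform_geom(n = 600, A = 1e-4, ds = 1e-3)  # 0.1 ml per sample
  occupy <- function(k) { o <- rep(FALSE, 600); o[seq_len(k)] <- TRUE; o }
  g2 <- uniform_geom(n = 600, A = 1e-4, ds = 1e-3)
  series <- frame_series(rbind(occupy(0), occupy(321), occupy(471)),
                         interval = 0.5, geometry = g2)
  est <- estimate_inlet_flow(g2, series,
                             windows = list(c(1, 2), c(2, 3)),
                             despeckle = FALSE)
  expect_equal(est$Q, c(321, 150) * 1e-4 * 1e-3 / 1e-6 / 0.5,
               tolerance = 1e-12)
  # the printed-style triple: mean 1.645, sd 0.040
  Q <- c(1.605, 1.645, 1.685)
  expect_equal(mean(Q), 1.645)
  expect_equal(sd(Q), 0.040)
  # single window -> mean only, SD absent
  est1 <- estimate_inlet_flow(g2, series, windows = list(c(1, 3)),
                              despeckle = FALSE)
  expect_equal(est1$n, 1)
  expect_true(is.na(est1$sd))
  expect_error(estimate_inlet_flow(g2, series, windows = list()),
               "windows")
})

test_that("estimator recovers ground truth across the clinical flow range", {
  for (Q in c(0.2, 0.5, 0.8, 1.2, 1.6, 2.0)) {
    case <- make_reference_case()
    case$stages$Q_target[1] <- Q
    d <- synthesize_dsa_frames(case, "baseline")
    est <- estimate_inlet_flow(d$geometry, d$series)
    expect_lt(abs(est$mean - Q) / Q, 0.05)
  }
})

test_that("estimator tolerates 1% flipped-bit segmentation noise", {
  synth <- make_synthetic_avm(7)
  for (seed in 1:5) {
    d <- synthesize_dsa_frames(synth, "baseline", seed = seed, noise = 0.01)
    est <- estimate_inlet_flow(d$geometry, d$series)
    expect_lt(abs(est$mean - d$true_Q) / d$true_Q, 0.10)
  }
})

test_that("estimate scales linearly with cross-sectional areas", {
  synth <- make_synthetic_avm(11)
  d <- synthesize_dsa_frames(synth, "baseline")
  est <- estimate_inlet_flow(d$geometry, d$series)
  g2 <- d$geometry
  g2$samples$A <- 3 * g2$samples$A
  est2 <- estimate_inlet_flow(g2, d$series)
  expect_equal(est2$mean, 3 * est$mean, tolerance = 1e-12)
  expect_equal(est2$Q, 3 * est$Q, tolerance = 1e-12)
})

test_that("swept-volume round trip against the transport module", {
  # frames rendered from a known flow give swept volume = Q * dt within 5%
  case <- make_reference_case()
  case$stages$Q_target[1] <- 1.0
  d <- synthesize_dsa_frames(case, "baseline")
  w <- washin_windows(d$series, n = 1)[[1]]
  # cumulative reach: once a sample has seen dye it stays counted, so the
  # later frame reflects the full swept extent even after tail wash-out
  occ <- apply(d$series$occupancy, 2, cummax) > 0
  vol <- swept_volume(d$geometry, occ[w[1], ], occ[w[2], ])
  dt <- d$series$interval * (w[2] - w[1])
  expect_lt(abs(vol - 1.0 * dt) / (1.0 * dt), 0.05)
})

test_that("frame series round trips through CSV (and TIFF if available)", {
  synth <- make_synthetic_avm(5)
  d <- synthesize_dsa_frames(synth, "baseline")
  csv <- tempfile(fileext = ".csv")
  write_frames_csv(d$series, csv)
  back <- read_frames_csv(csv, geometry = d$geometry)
  expect_identical(back$occupancy, unname(d$series$occupancy))
  expect_equal(back$interval, d$series$interval)
  unlink(csv)
  gcsv <- tempfile(fileext = ".csv")
  write_centerline_csv(d$geometry, gcsv)
  gback <- read_centerline_csv(gcsv)
  expect_equal(gback$samples$A, d$geometry$samples$A)
  unlink(gcsv)
  if (requireNamespace("tiff", quietly = TRUE)) {
    tif <- tempfile(fileext = ".tif")
    write_frames_tiff(d$series, tif)
    tback <- read_frames_tiff(tif, interval = d$series$interval)
    expect_identical(tback$occupancy, unname(d$series$occupancy))
    unlink(tif)
  }
})

test_that("synthetic DSA generation is deterministic and flow-consistent", {
  a <- synthesize_dsa_frames(make_synthetic_avm(3), "baseline",
                             seed = 2, noise = 0.01)
  b <- synthesize_dsa_frames(make_synthetic_avm(3), "baseline",
                             seed = 2, noise = 0.01)
  expect_identical(a$series$occupancy, b$series$occupancy)
  # zero-flow stage produces no frame-to-frame growth
  case <- make_reference_case()
  case$stages$Q_target[1] <- 0
  d0 <- synthesize_dsa_frames(case, "baseline")
  expect_true(all(!d0$series$occupancy))
  expect_error(synthesize_dsa_frames(make_synthetic_avm(3), "no-such"),
               "unknown stage")
})
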