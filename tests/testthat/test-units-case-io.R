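test_that("unit conversions are exact and invertible", {
  expect_equal(unit_convert(1, "mmHg", "Pa"), 133.322)
  # hand arithmetic: 0.330 * 133.322 / 1e-6
  expect_equal(unit_convert(0.330, "mmHg.s/ml", "Pa.s/m^3"),
               0.330 * 133.322 / 1e-6)
  expect_equal(unit_convert(1, "ml/s", "m^3/s"), 1e-6)
  expect_equal(unit_convert(10, "mm", "m"), 0.01)
  # middle-dot and spaced spellings are accepted
  expect_equal(unit_convert(1, "mmHg·s/ml", "Pa.s/m^3"),
               unit_convert(1, "mmHg s/ml", "Pa.s/m^3"))
  # round trips to machine precision over all supported pairs
  pairs <- list(c("mmHg", "Pa"), c("ml/s", "m^3/s"),
                c("mmHg.s/ml", "Pa.s/m^3"), c("mm", "m"), c("m^2", "m^2"))
  set.seed(42)
  for (p in pairs) {
    x <- runif(20, 1e-12, 1e3)
    expect_equal(unit_convert(unit_convert(x, p[1], p[2]), p[2], p[1]), x,
                 tolerance = 1e-14)
  }
  expect_error(unit_convert(1, "mmHg", "ml/s"), "cannot convert")
  expect_error(unit_convert(1, "furlong", "m"), "unsupported")
})

test_that("fluid properties validate positivity", {
  fl <- fluid_properties()
  expect_equal(fl$density, 1060)
  expect_equal(fl$viscosity, 4e-3)
  expect_error(fluid_properties(density = -1), "density")
  expect_error(fluid_properties(viscosity = 0), "viscosity")
})

test_that("reference case carries the printed parameters exactly", {
  case <- make_reference_case()
  expect_identical(case$boundary$P_in, 20.837)
  expect_identical(case$boundary$R_art, 24.138)
  expect_identical(case$fluid$density, 1060)
  expect_identical(case$fluid$viscosity, 4e-3)
  expect_identical(case$stages$K[1], 2e-8)
  expect_identical(case$stages$R_nidus[1], 0.330)
  expect_identical(case$stages$R_nidus[nrow(case$stages)], 3970)
  expect_identical(case$stages$K[nrow(case$stages)], 1.5e-12)
  expect_identical(case$nidus, list(L = 16, W = 12, H = 9))
  expect_identical(case$segments$diameter,
                   c(3.8, 2.0, 1.6, 2.3))
  tg <- case$dsa_targets
  expect_identical(tg$Q_mean, c(1.645, 1.011, 0.231))
  expect_identical(tg$Q_sd, c(0.040, NA, 0.021))
  expect_identical(case$bolus$width, 1.5)
  expect_identical(case$bolus$total_time, 5)
  expect_identical(case$bolus$time_step, 0.01)
  expect_identical(case$dsa$frame_rate, 2)
  expect_identical(case$dsa$diffusivity, 2.2e-10)
})

test_that("the shipped reference case file reproduces every printed value", {
  path <- system.file("extdata", "reference_case.json", package = "avmsim")
  case <- load_case(path)
  ref <- make_reference_case()
  expect_identical(case$boundary, ref$boundary)
  expect_identical(case$stages$K, ref$stages$K)
  expect_identical(case$stages$R_nidus, ref$stages$R_nidus)
  expect_identical(case$dsa_targets$Q_mean, ref$dsa_targets$Q_mean)
  expect_identical(case$fluid$density, 1060)
})

test_that("case save/load round trips through JSON and YAML", {
  case <- make_reference_case()
  for (ext in c("json", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    save_case(case, path)
    back <- load_case(path)
    expect_equal(back$boundary, case$boundary)
    expect_equal(back$stages, case$stages)
    expect_equal(back$segments, case$segments)
    expect_equal(back$fluid$viscosity, case$fluid$viscosity)
    expect_equal(back$dsa_targets, case$dsa_targets)
    expect_equal(unclass(back$bolus), unclass(case$bolus))
    unlink(path)
  }
})

test_that("case validation rejects malformed configurations", {
  case <- make_reference_case()
  # empty stages
  broken <- case; broken$stages <- case$stages[0, ]
  expect_error(validate_case(broken), "empty")
  # non-positive diameter
  broken <- case; broken$segments$diameter[1] <- -3.8
  expect_error(validate_case(broken), "positive")
  # duplicate stage names
  broken <- case; broken$stages$name[2] <- "baseline"
  expect_error(validate_case(broken), "unique")
  # stage order must be baseline-first
  broken <- case; broken$stages <- case$stages[c(2, 1, 3), ]
  expect_error(validate_case(broken), "baseline")
  # missing field in a case file is named in the error
  path <- tempfile(fileext = ".json")
  lst <- jsonlite::fromJSON(save_case(case, path))
  lst$boundary$P_in <- NULL
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_case(path), "P_in")
  unlink(path)
  expect_error(load_case(tempfile()), "not found")
})

test_that("stage results are written as CSV plus JSON summary", {
  fit <- avm_model(make_reference_case())
  dir <- tempfile()
  paths <- write_stage_results(fit$stages, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[["csv"]])
  expect_equal(back$Q_inlet, fit$stages$Q_inlet, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
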