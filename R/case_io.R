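#' Assemble an AVM case configuration
#'
#' A case bundles everything needed to calibrate and simulate one lesion:
#' the vessel segments around the nidus, the nidus bounding box, fluid
#' properties, boundary conditions, the ordered list of intervention stages
#' (baseline first), optional DSA-derived flow measurements, and the
#' contrast-bolus specification.
#'
#' @param segments data.frame with columns `id`, `kind` (one of `feeding`,
#'   `arterial_outlet`, `venous`, `internal`), `diameter` (mm), `length`
#'   (mm; used for transport geometry, may be `NA` when a lumped resistance
#'   is calibrated instead).
#' @param nidus list with elements `L`, `W`, `H` (bounding dimensions, mm)
#'   and optionally `alpha` (shape factor, 1/m) once calibrated.
#' @param fluid a [fluid_properties()] object.
#' @param boundary list with `P_in` (inlet pressure, mmHg), `R_art`
#'   (arterial outlet resistance, mmHg.s/ml) and `P_ven` (venous outlet
#'   pressure, mmHg; 0 by default).
#' @param stages data.frame with columns `name`, `K` (nidus permeability,
#'   m^2; `NA` if unknown), `R_nidus` (mmHg.s/ml; `NA` if unknown),
#'   `Q_target` (stage inlet flow target in ml/s used for calibration; `NA`
#'   if none) and optionally `Q_nidus_target` (ml/s, usually baseline only).
#' @param dsa_targets optional data.frame of DSA flow measurements:
#'   `stage`, `Q_mean` (ml/s), `Q_sd` (ml/s or `NA` when only one
#'   measurement was possible), `n`.
#' @param bolus a [bolus_spec()] describing the contrast injection.
#' @param dsa list with `frame_rate` (frames/s, default 2) and
#'   `diffusivity` (contrast diffusivity in m^2/s, default 2.2e-10).
#' @return an object of class `avm_case`.
#' @seealso [load_case()], [make_reference_case()]
#' @export
avm_case <- function(segments, nidus, fluid = fluid_properties(),
                     boundary, stages, dsa_targets = NULL,
                     bolus = bolus_spec(),
                     dsa = list(frame_rate = 2, diffusivity = 2.2e-10)) {
  case <- structure(
    list(segments = as.data.frame(segments, stringsAsFactors = FALSE),
         nidus = nidus, fluid = fluid, boundary = boundary,
         stages = as.data.frame(stages, stringsAsFactors = FALSE),
         dsa_targets = if (!is.null(dsa_targets))
           as.data.frame(dsa_targets, stringsAsFactors = FALSE),
         bolus = bolus, dsa = dsa),
    class = "avm_case")
  validate_case(case)
}

#' Validate an AVM case configuration
#'
#' Checks the structural invariants of a case: unique, baseline-first stage
#' names; positive diameters and nidus dimensions; positive fluid
#' properties; an inlet pressure above the venous pressure; and that every
#' stage referenced by a DSA target exists.
#'
#' @param case an `avm_case`.
#' @return the case, invisibly usable in a pipeline; errors describe the
#'   offending field.
#' @export
validate_case <- function(case) {
  seg <- case$segments
  need <- c("id", "kind", "diameter")
  miss <- setdiff(need, names(seg))
  if (length(miss)) stop("segments missing field(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(seg$id)) stop("duplicate segment ids", call. = FALSE)
  kinds <- c("feeding", "arterial_outlet", "venous", "internal")
  if (!all(seg$kind %in% kinds)) {
    stop("segment kind must be one of ", paste(kinds, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(seg$diameter) | seg$diameter <= 0)) {
    stop("segment diameters must be positive", call. = FALSE)
  }
  if (sum(seg$kind == "feeding") != 1L) {
    stop("exactly one feeding segment is required", call. = FALSE)
  }
  if (sum(seg$kind == "arterial_outlet") != 1L) {
    stop("exactly one arterial_outlet segment is required", call. = FALSE)
  }
  if (sum(seg$kind == "venous") < 1L) {
    stop("at least one venous segment is required", call. = FALSE)
  }
  nd <- case$nidus
  for (f in c("L", "W", "H")) {
    if (is.null(nd[[f]]) || !is.finite(nd[[f]]) || nd[[f]] <= 0) {
      stop("nidus dimension ", f, " must be positive", call. = FALSE)
    }
  }
  if (!inherits(case$fluid, "fluid_properties")) {
    case$fluid <- do.call(fluid_properties, case$fluid)
  }
  bc <- case$boundary
  for (f in c("P_in", "R_art")) {
    if (is.null(bc[[f]]) || !is.finite(bc[[f]])) {
      stop("boundary missing field: ", f, call. = FALSE)
    }
  }
  if (is.null(bc$P_ven)) case$boundary$P_ven <- 0
  if (bc$R_art < 0) stop("R_art must be >= 0", call. = FALSE)
  if (bc$P_in <= case$boundary$P_ven) {
    stop("P_in must exceed the venous outlet pressure", call. = FALSE)
  }
  st <- case$stages
  if (is.null(st) || nrow(st) == 0L) stop("stages list is empty", call. = FALSE)
  if (anyDuplicated(st$name)) stop("stage names must be unique", call. = FALSE)
  if (st$name[1L] != "baseline") {
    stop("stages must be ordered baseline-first", call. = FALSE)
  }
  for (col in c("K", "R_nidus", "Q_target")) {
    if (is.null(st[[col]])) case$stages[[col]] <- NA_real_
  }
  if (!is.null(case$dsa_targets)) {
    bad <- setdiff(case$dsa_targets$stage, st$name)
    if (length(bad)) {
      stop("dsa_targets reference unknown stage(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  case
}

.case_to_list <- function(case) {
  list(
    segments = case$segments,
    nidus = case$nidus,
    fluid = list(density = case$fluid$density,
                 viscosity = case$fluid$viscosity),
    boundary = case$boundary,
    stages = case$stages,
    dsa_targets = case$dsa_targets,
    bolus = unclass(case$bolus),
    dsa = case$dsa
  )
}

.case_from_list <- function(x) {
  for (f in c("segments", "nidus", "fluid", "boundary", "stages")) {
    if (is.null(x[[f]])) stop("case file missing field: ", f, call. = FALSE)
  }
  for (f in c("density", "viscosity")) {
    if (is.null(x$fluid[[f]])) {
      stop("case file missing field: fluid.", f, call. = FALSE)
    }
  }
  st <- as.data.frame(x$stages, stringsAsFactors = FALSE)
  if (nrow(st) == 0L) stop("stages list is empty", call. = FALSE)
  # JSON parsers return integer for whole numbers; keep all quantities double
  to_dbl <- function(v) if (is.numeric(v)) as.numeric(v) else v
  x$boundary <- lapply(x$boundary, to_dbl)
  x$fluid <- lapply(x$fluid, to_dbl)
  x$nidus <- lapply(x$nidus, to_dbl)
  st[] <- lapply(st, to_dbl)
  x$segments <- as.data.frame(x$segments, stringsAsFactors = FALSE)
  x$segments[] <- lapply(x$segments, to_dbl)
  if (!is.null(x$dsa)) {
    x$dsa[c("frame_rate", "diffusivity")] <-
      lapply(x$dsa[c("frame_rate", "diffusivity")], to_dbl)
  }
  if (!is.null(x$bolus)) x$bolus <- lapply(x$bolus, to_dbl)
  bolus <- if (is.null(x$bolus)) bolus_spec() else do.call(bolus_spec, x$bolus)
  dsa <- if (is.null(x$dsa)) list(frame_rate = 2, diffusivity = 2.2e-10) else x$dsa
  avm_case(segments = as.data.frame(x$segments, stringsAsFactors = FALSE),
           nidus = x$nidus,
           fluid = fluid_properties(x$fluid$density, x$fluid$viscosity),
           boundary = x$boundary,
           stages = st,
           dsa_targets = if (!is.null(x$dsa_targets) &&
                             length(x$dsa_targets))
             as.data.frame(x$dsa_targets, stringsAsFactors = FALSE),
           bolus = bolus, dsa = dsa)
}

#' Read a case configuration from JSON or YAML
#'
#' The on-disk schema is documented in
#' `system.file("extdata", "case.schema.json", package = "avmsim")`. YAML
#' files (`.yaml`/`.yml`) are accepted as an alias of the same schema. All
#' quantities are validated and kept in their clinical units (mm, mmHg,
#' ml/s, mmHg.s/ml); conversion to SI happens inside the solvers.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` case file.
#' @return a validated [avm_case()].
#' @export
load_case <- function(path) {
  if (!file.exists(path)) stop("case file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  .case_from_list(x)
}

#' Write a case configuration to JSON (or YAML)
#'
#' @param case an `avm_case`.
#' @param path destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_case <- function(case, path) {
  stopifnot(inherits(case, "avm_case"))
  x <- .case_to_list(case)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' @export
print.avm_case <- function(x, ...) {
  cat("AVM case configuration\n")
  cat(sprintf("  segments: %d (feeding d = %g mm)\n", nrow(x$segments),
              x$segments$diameter[x$segments$kind == "feeding"][1L]))
  cat(sprintf("  nidus: %g x %g x %g mm\n", x$nidus$L, x$nidus$W, x$nidus$H))
  cat(sprintf("  boundary: P_in = %g mmHg, R_art = %g mmHg.s/ml\n",
              x$boundary$P_in, x$boundary$R_art))
  cat(sprintf("  stages (%d): %s\n", nrow(x$stages),
              paste(x$stages$name, collapse = ", ")))
  invisible(x)
}

#' Write per-stage simulation results to CSV and a JSON summary
#'
#' @param results a data.frame as returned by [simulate_stages()].
#' @param dir output directory (created if needed).
#' @return paths of the two files written, invisibly.
#' @export
write_stage_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "stages.csv")
  js <- file.path(dir, "summary.json")
  utils::write.csv(results, csv, row.names = FALSE)
  jsonlite::write_json(results, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, json = js))
}
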