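#' Centerline geometry for swept-volume flow estimation
#'
#' Ordered centerline samples with local cross-sectional areas, the
#' geometric support on which angiographic dye occupancy is recorded. The
#' swept volume between two frames is the summed `A * ds` of the samples
#' newly reached by dye.
#'
#' @param samples data.frame with columns `branch`, `s` (arc length, m,
#'   strictly increasing within a branch), `A` (m^2) and optionally `ds`
#'   (sample cell width, m; inferred from the `s` spacing when absent).
#' @return an object of class `centerline_geometry`.
#' @export
centerline_geometry <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("branch", "s", "A") %in% names(samples)))
  if (any(samples$A <= 0)) stop("areas must be positive", call. = FALSE)
  for (b in unique(samples$branch)) {
    sb <- samples$s[samples$branch == b]
    if (any(diff(sb) <= 0)) {
      stop("arc length must be strictly increasing within branch ", b,
           call. = FALSE)
    }
  }
  if (is.null(samples$ds)) {
    samples$ds <- stats::ave(samples$s, samples$branch, FUN = function(s) {
      if (length(s) == 1L) return(s)
      d <- diff(s)
      c(d[1L], d)
    })
  }
  structure(list(samples = samples), class = "centerline_geometry")
}

#' Read / write centerline geometry as CSV
#'
#' @param path CSV file with columns `branch,s,A` (and optionally `ds`).
#' @return a [centerline_geometry()].
#' @export
read_centerline_csv <- function(path) {
  centerline_geometry(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_centerline_csv
#' @param geometry a `centerline_geometry` to write.
#' @export
write_centerline_csv <- function(geometry, path) {
  utils::write.csv(geometry$samples, path, row.names = FALSE)
  invisible(path)
}

#' Timestamped boolean dye-occupancy frames
#'
#' @param occupancy logical matrix, frames by centerline samples.
#' @param interval frame interval in s (default 0.5, i.e. 2 frames/s).
#' @param geometry the matching [centerline_geometry()].
#' @param times optional frame timestamps (default `0, interval, ...`).
#' @return an object of class `frame_series`.
#' @export
frame_series <- function(occupancy, interval = 0.5, geometry = NULL,
                         times = NULL) {
  occupancy <- as.matrix(occupancy)
  storage.mode(occupancy) <- "logical"
  if (interval <= 0) stop("frame interval must be positive", call. = FALSE)
  if (!is.null(geometry) &&
      ncol(occupancy) != nrow(geometry$samples)) {
    stop("occupancy has ", ncol(occupancy), " samples but geometry has ",
         nrow(geometry$samples), call. = FALSE)
  }
  if (is.null(times)) {
    times <- (seq_len(nrow(occupancy)) - 1L) * interval
  }
  structure(list(occupancy = occupancy, interval = interval,
                 geometry = geometry, times = times),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("DSA frame series: %d frames x %d samples, interval %g s\n",
              nrow(x$occupancy), ncol(x$occupancy), x$interval))
  invisible(x)
}

#' Volume swept by contrast between two frames
#'
#' Sums `A * ds` over the centerline samples occupied in the later frame
#' but not in the earlier one. Samples that lose dye (wash-out) do not
#' contribute, so the result is non-negative by construction.
#'
#' @param geometry a [centerline_geometry()].
#' @param frame_a,frame_b logical occupancy vectors (earlier, later).
#' @return swept volume in ml.
#' @export
swept_volume <- function(geometry, frame_a, frame_b) {
  stopifnot(inherits(geometry, "centerline_geometry"))
  sm <- geometry$samples
  if (length(frame_a) != nrow(sm) || length(frame_b) != nrow(sm)) {
    stop("frame length does not match the number of centerline samples",
         call. = FALSE)
  }
  new <- frame_b & !frame_a
  sum(sm$A[new] * sm$ds[new]) / ML_M3
}

#' Select wash-in measurement windows automatically
#'
#' Returns frame pairs over which total occupancy grows strictly (the
#' bolus front is still advancing through the imaged geometry); wash-out
#' frames are excluded. Pairs are taken as wide as possible and split into
#' `n` windows, mirroring the practice of repeating the measurement at
#' different positions/time windows of the DSA run.
#'
#' @param series a [frame_series()].
#' @param n number of windows wanted (default 3).
#' @return list of `c(a, b)` frame-index pairs (1-based).
#' @export
washin_windows <- function(series, n = 3L) {
  stopifnot(inherits(series, "frame_series"))
  # latch each sample once occupied: wash-in reach is monotone even while
  # the bolus tail washes out upstream
  occ <- apply(series$occupancy, 2L, cummax) > 0
  counts <- rowSums(occ)
  growing <- which(diff(counts) > 0)        # pair (i, i+1) grows
  if (!length(growing)) return(list())
  lo <- min(growing); hi <- max(growing) + 1L
  # once dye reaches the far end of a branch the swept volume is truncated
  # by the imaged field of view; stop the usable window there
  if (!is.null(series$geometry)) {
    sm <- series$geometry$samples
    last_idx <- cumsum(rle(as.character(sm$branch))$lengths)
    reached <- vapply(last_idx, function(k) {
      w <- which(occ[, k])
      if (length(w)) min(w) else NA_integer_
    }, 1L)
    if (any(is.finite(reached))) {
      hi <- min(hi, min(reached, na.rm = TRUE) - 1L)
    }
  }
  if (hi <= lo) return(list())
  cuts <- unique(round(seq(lo, hi, length.out = min(n, hi - lo) + 1L)))
  lapply(seq_len(length(cuts) - 1L),
         function(i) c(cuts[i], cuts[i + 1L]))
}

#' Estimate inlet flow from a DSA frame series by swept volume
#'
#' For each measurement window `(a, b)` the flow is the contrast-swept
#' volume divided by the elapsed time. Repeated windows are aggregated as
#' sample mean and (n-1)-denominator standard deviation; with a single
#' window the SD is reported as `NA`, mirroring runs where too few frames
#' are usable.
#'
#' @param geometry a [centerline_geometry()].
#' @param series a [frame_series()].
#' @param windows list of `c(a, b)` frame-index pairs (1-based); default
#'   [washin_windows()].
#' @param monotone_closure logical; when `TRUE` (default) each sample is
#'   latched on once it has been occupied, suppressing isolated
#'   noise-induced drop-outs during wash-in.
#' @param despeckle logical; when `TRUE` (default) a sample counts as
#'   occupied only if it is also occupied in an adjacent frame, removing
#'   single-frame segmentation speckle before the closure.
#' @return list with `mean` (ml/s), `sd` (ml/s or `NA`), `n`, and the
#'   per-window flows `Q`.
#' @export
estimate_inlet_flow <- function(geometry, series, windows = NULL,
                                monotone_closure = TRUE, despeckle = TRUE) {
  stopifnot(inherits(geometry, "centerline_geometry"),
            inherits(series, "frame_series"))
  occ <- series$occupancy
  nf <- nrow(occ)
  if (despeckle && nf > 1L) {
    prev <- occ[c(1L, seq_len(nf - 1L)), , drop = FALSE]
    prev[1L, ] <- occ[2L, ]
    nxt <- occ[c(2:nf, nf), , drop = FALSE]
    nxt[nf, ] <- occ[nf - 1L, ]
    occ <- occ & (prev | nxt)
    series <- frame_series(occ, interval = series$interval,
                           geometry = series$geometry,
                           times = series$times)
  }
  if (is.null(windows)) windows <- washin_windows(series)
  if (!length(windows)) stop("no measurement windows", call. = FALSE)
  if (monotone_closure) {
    occ <- apply(occ, 2L, cummax)
    storage.mode(occ) <- "logical"
  }
  Q <- vapply(windows, function(w) {
    a <- w[1L]; b <- w[2L]
    if (b <= a) stop("window must have b > a", call. = FALSE)
    vol <- swept_volume(geometry, occ[a, ], occ[b, ])
    vol / (series$interval * (b - a))
  }, 0)
  n <- length(Q)
  list(mean = mean(Q), sd = if (n > 1L) stats::sd(Q) else NA_real_,
       n = n, Q = Q)
}

#' Write / read a frame series as multi-frame TIFF
#'
#' Each frame is rasterised as a one-row strip (one pixel per centerline
#' sample). Requires the `tiff` package; the plain-text CSV form
#' ([write_frames_csv()]) carries the same information.
#'
#' @param series a [frame_series()].
#' @param path output `.tif` path.
#' @export
write_frames_tiff <- function(series, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export", call. = FALSE)
  }
  imgs <- lapply(seq_len(nrow(series$occupancy)), function(i) {
    matrix(as.numeric(series$occupancy[i, ]), nrow = 1L)
  })
  tiff::writeTIFF(imgs, path)
  invisible(path)
}

#' @rdname write_frames_tiff
#' @param interval frame interval in s for the series read back.
#' @param geometry optional [centerline_geometry()] to attach.
#' @export
read_frames_tiff <- function(path, interval = 0.5, geometry = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF import", call. = FALSE)
  }
  imgs <- tiff::readTIFF(path, all = TRUE)
  occ <- do.call(rbind, lapply(imgs, function(m) as.numeric(m) >= 0.5))
  frame_series(occ, interval = interval, geometry = geometry)
}

#' Write / read a frame series as occupancy CSV
#'
#' Long format with columns `frame`, `time`, `sample`, `occupied`.
#'
#' @param series a [frame_series()].
#' @param path output `.csv` path.
#' @export
write_frames_csv <- function(series, path) {
  nf <- nrow(series$occupancy); ns <- ncol(series$occupancy)
  df <- data.frame(frame = rep(seq_len(nf), each = ns),
                   time = rep(series$times, each = ns),
                   sample = rep(seq_len(ns), nf),
                   occupied = as.integer(t(series$occupancy)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frames_csv
#' @param geometry optional [centerline_geometry()] to attach.
#' @export
read_frames_csv <- function(path, geometry = NULL) {
  df <- utils::read.csv(path)
  nf <- max(df$frame); ns <- max(df$sample)
  occ <- matrix(FALSE, nf, ns)
  occ[cbind(df$frame, df$sample)] <- df$occupied > 0
  times <- df$time[match(seq_len(nf), df$frame)]
  interval <- if (nf > 1L) times[2L] - times[1L] else 0.5
  frame_series(occ, interval = interval, geometry = geometry, times = times)
}
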