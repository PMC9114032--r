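#' Two-dimensional channel grid for the Stokes-Brinkman solver
#'
#' Uniform staggered (MAC) grid on a rectangular channel of length `L`
#' (flow direction) and height `h`.
#'
#' @param nx,ny number of cells in x and y (each at least 4).
#' @param L channel length in m.
#' @param h channel height in m.
#' @return an object of class `grid2d`.
#' @export
grid2d <- function(nx, ny, L, h) {
  if (nx < 4 || ny < 4) stop("nx and ny must be at least 4", call. = FALSE)
  if (L <= 0 || h <= 0) stop("L and h must be positive", call. = FALSE)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 L = L, h = h, hx = L / nx, hy = h / ny),
            class = "grid2d")
}

#' Closed-form Darcy pressure drop of a porous channel
#'
#' One-dimensional Darcy balance: `dP = mu * L * U / K` for superficial
#' velocity `U` through a porous block of length `L` and permeability `K`.
#'
#' @param K permeability in m^2.
#' @param L block length in m.
#' @param U superficial velocity in m/s.
#' @param mu dynamic viscosity in Pa.s.
#' @return pressure drop in Pa.
#' @export
porous_channel_pressure_drop <- function(K, L, U, mu) {
  if (any(K <= 0) || any(L <= 0) || any(mu <= 0)) {
    stop("K, L and mu must be positive", call. = FALSE)
  }
  mu * L * U / K
}

#' Steady Stokes-Brinkman flow in a 2D porous channel
#'
#' Solves the Stokes equations with an isotropic Darcy momentum sink
#' `-(mu/K) u` on a staggered grid: uniform inflow velocity on the left
#' boundary, zero-pressure outflow on the right, no-slip top and bottom
#' walls. Convective terms are dropped — the verification regime is
#' creeping flow, where the Darcy closed form is exact — so the system is
#' linear and solved by a direct sparse factorisation. This solver is the
#' distributed counterpart of the lumped Darcy nidus element and is used
#' to verify that closure.
#'
#' @param grid a [grid2d()].
#' @param K permeability field: scalar or `nx` by `ny` matrix (m^2), all
#'   entries positive ("solid" regions are modelled by very small K).
#' @param U mean inflow velocity in m/s.
#' @param mu dynamic viscosity in Pa.s.
#' @return list with matrices `u` ((nx+1) x ny), `v` (nx x (ny+1)), `p`
#'   (nx x ny, Pa), the estimated end-to-end pressure drop `dp` (Pa, from
#'   a linear fit of the streamwise pressure profile), the volumetric flux
#'   per unit depth `Q` (m^2/s), and `div_residual` (largest cell
#'   divergence relative to the inflow flux).
#' @export
solve_stokes_brinkman <- function(grid, K, U, mu) {
  stopifnot(inherits(grid, "grid2d"))
  nx <- grid$nx; ny <- grid$ny; hx <- grid$hx; hy <- grid$hy
  if (length(K) == 1L) K <- matrix(K, nx, ny)
  K <- as.matrix(K)
  if (!all(dim(K) == c(nx, ny))) {
    stop("K must be scalar or an nx by ny matrix", call. = FALSE)
  }
  if (any(K <= 0)) stop("permeability must be positive everywhere",
                        call. = FALSE)
  # unknown numbering: u faces i=2..nx+1 (x-index), j=1..ny; v faces
  # i=1..nx, j=2..ny; p cells i=1..nx, j=1..ny
  nu <- nx * ny; nv <- nx * (ny - 1L); np <- nx * ny
  iu <- function(i, j) (j - 1L) * nx + (i - 1L)          # i in 2..nx+1
  iv <- function(i, j) nu + (j - 2L) * nx + i            # j in 2..ny
  ip <- function(i, j) nu + nv + (j - 1L) * nx + i
  ntot <- nu + nv + np
  cap <- 12L * ntot
  ti <- integer(cap); tj <- integer(cap); tx <- numeric(cap)
  cnt <- 0L
  b <- numeric(ntot)
  push <- function(r, c, v) {
    cnt <<- cnt + 1L
    ti[cnt] <<- r; tj[cnt] <<- c; tx[cnt] <<- v
  }
  harm <- function(a, b2) 2 / (1 / a + 1 / b2)
  # u lookup helper returning list(col=, val=) or fixed value contribution
  # boundary u (i = 1) is Dirichlet = U
  u_entry <- function(r, i, j, coef) {
    # neighbour u(i, j) of equation row r with coefficient coef
    if (j < 1L) { push(r, iu(i, 1L), -coef); return(invisible()) }  # ghost -u
    if (j > ny) { push(r, iu(i, ny), -coef); return(invisible()) }
    if (i == 1L) { b[r] <<- b[r] - coef * U; return(invisible()) }
    if (i > nx + 1L) stop("u index out of range")
    push(r, iu(i, j), coef)
  }
  ax <- mu / hx^2; ay <- mu / hy^2
  # --- u momentum -----------------------------------------------------
  for (j in seq_len(ny)) {
    for (i in 2:(nx + 1L)) {
      r <- iu(i, j)
      Kf <- if (i <= nx) harm(K[i - 1L, j], K[i, j]) else K[nx, j]
      diag_c <- -2 * ax - 2 * ay - mu / Kf
      if (i == nx + 1L) diag_c <- diag_c + ax  # zero-gradient east ghost
      push(r, iu(i, j), diag_c)
      u_entry(r, i - 1L, j, ax)
      if (i < nx + 1L) u_entry(r, i + 1L, j, ax)
      u_entry(r, i, j - 1L, ay)
      u_entry(r, i, j + 1L, ay)
      # pressure gradient -(p_i - p_{i-1})/hx; ghost p = 0 beyond outflow
      push(r, ip(i - 1L, j), 1 / hx)
      if (i <= nx) push(r, ip(i, j), -1 / hx)
    }
  }
  # --- v momentum -----------------------------------------------------
  if (ny > 1L) {
    for (j in 2:ny) {
      for (i in seq_len(nx)) {
        r <- iv(i, j)
        Kf <- harm(K[i, j - 1L], K[i, j])
        diag_c <- -2 * ax - 2 * ay - mu / Kf
        if (i == 1L) diag_c <- diag_c - ax   # reflected west ghost (v=0 inflow)
        if (i == nx) diag_c <- diag_c + ax   # zero-gradient east ghost
        push(r, iv(i, j), diag_c)
        if (i > 1L) push(r, iv(i - 1L, j), ax)
        if (i < nx) push(r, iv(i + 1L, j), ax)
        if (j > 2L) push(r, iv(i, j - 1L), ay)       # j=2 south neighbour is wall v=0
        if (j < ny) push(r, iv(i, j + 1L), ay)       # j=ny north neighbour is wall v=0
        push(r, ip(i, j - 1L), 1 / hy)
        push(r, ip(i, j), -1 / hy)
      }
    }
  }
  # --- continuity -----------------------------------------------------
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      r <- ip(i, j)
      # (u_{i+1} - u_i)/hx + (v_{j+1} - v_j)/hy = 0
      push(r, iu(i + 1L, j), 1 / hx)
      if (i == 1L) b[r] <- b[r] + U / hx else push(r, iu(i, j), -1 / hx)
      if (j < ny) push(r, iv(i, j + 1L), 1 / hy)
      if (j > 1L) push(r, iv(i, j), -1 / hy)
    }
  }
  A <- Matrix::sparseMatrix(i = ti[seq_len(cnt)], j = tj[seq_len(cnt)],
                            x = tx[seq_len(cnt)], dims = c(ntot, ntot))
  sol <- tryCatch(as.numeric(Matrix::solve(A, b)),
                  error = function(e) stop("singular Stokes-Brinkman system: ",
                                           conditionMessage(e), call. = FALSE))
  u <- matrix(0, nx + 1L, ny); u[1L, ] <- U
  for (j in seq_len(ny)) u[2:(nx + 1L), j] <- sol[iu(2:(nx + 1L), j)]
  v <- matrix(0, nx, ny + 1L)
  if (ny > 1L) for (j in 2:ny) v[, j] <- sol[iv(seq_len(nx), j)]
  p <- matrix(sol[(nu + nv + 1L):ntot], nx, ny)
  # divergence residual
  div <- (u[2:(nx + 1L), , drop = FALSE] - u[seq_len(nx), , drop = FALSE]) / hx +
    (v[, 2:(ny + 1L), drop = FALSE] - v[, seq_len(ny), drop = FALSE]) / hy
  div_residual <- max(abs(div)) * hx * hy / (U * grid$h)
  # streamwise pressure profile; linear fit past the entrance region
  pbar <- colMeans(t(p))                     # mean over y for each x column
  xc <- (seq_len(nx) - 0.5) * hx
  sel <- xc >= grid$L / 4
  fit <- stats::lm.fit(cbind(1, xc[sel]), pbar[sel])
  dp <- -fit$coefficients[2L] * grid$L
  Q <- sum(u[1L, ]) * hy
  list(u = u, v = v, p = p, dp = unname(dp), Q = Q,
       div_residual = div_residual, grid = grid)
}

#' Grid-convergence check of the Brinkman solver against closed forms
#'
#' Runs [solve_stokes_brinkman()] on a sequence of grids with a uniform
#' permeability and reports the relative error of the computed pressure
#' drop against the Darcy closed form `mu*L*U/K`, or — when the
#' permeability is high enough that viscous wall losses dominate — against
#' the plane Poiseuille drop `12*mu*L*U/h^2`.
#'
#' @param grid_sizes list of `c(nx, ny)` pairs (at least one).
#' @param K uniform permeability in m^2.
#' @param L,h channel length and height in m.
#' @param U mean inflow velocity in m/s.
#' @param mu dynamic viscosity in Pa.s.
#' @param reference `"auto"` (default), `"darcy"` or `"poiseuille"`.
#' @return data.frame with one row per grid: `nx`, `ny`, `dp_num`,
#'   `dp_ref`, `rel_error`, `reference`.
#' @export
verify_darcy_limit <- function(grid_sizes = list(c(32, 8), c(64, 16),
                                                 c(128, 32)),
                               K = 1e-10, L = 0.016, h = 2e-3, U = 0.01,
                               mu = 4e-3, reference = "auto") {
  if (!length(grid_sizes)) stop("at least one grid size required",
                                call. = FALSE)
  dp_darcy <- porous_channel_pressure_drop(K, L, U, mu)
  dp_pois <- 12 * mu * L * U / h^2
  if (reference == "auto") {
    reference <- if (dp_darcy >= dp_pois) "darcy" else "poiseuille"
  }
  dp_ref <- switch(reference, darcy = dp_darcy, poiseuille = dp_pois,
                   stop("unknown reference: ", reference, call. = FALSE))
  rows <- lapply(grid_sizes, function(gs) {
    g <- grid2d(gs[1L], gs[2L], L, h)
    s <- solve_stokes_brinkman(g, K, U, mu)
    data.frame(nx = gs[1L], ny = gs[2L], dp_num = s$dp, dp_ref = dp_ref,
               rel_error = abs(s$dp - dp_ref) / dp_ref,
               reference = reference, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export Brinkman fields as CSV grids or legacy VTK
#'
#' @param solution result of [solve_stokes_brinkman()].
#' @param path output file; `.vtk` writes a structured-points legacy VTK
#'   file with cell-centred `u`, `v` and `p`, anything else a CSV of
#'   `x, y, u, v, p` at cell centers.
#' @return `path`, invisibly.
#' @export
write_brinkman_fields <- function(solution, path) {
  g <- solution$grid
  nx <- g$nx; ny <- g$ny
  uc <- (solution$u[seq_len(nx), , drop = FALSE] +
           solution$u[2:(nx + 1L), , drop = FALSE]) / 2
  vc <- (solution$v[, seq_len(ny), drop = FALSE] +
           solution$v[, 2:(ny + 1L), drop = FALSE]) / 2
  if (tolower(tools::file_ext(path)) == "vtk") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "stokes-brinkman fields",
                 "ASCII", "DATASET STRUCTURED_POINTS",
                 sprintf("DIMENSIONS %d %d 1", nx, ny),
                 sprintf("ORIGIN %g %g 0", g$hx / 2, g$hy / 2),
                 sprintf("SPACING %g %g 1", g$hx, g$hy),
                 sprintf("POINT_DATA %d", nx * ny)), con)
    writeLines(c("SCALARS p double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(as.numeric(solution$p), digits = 10), con)
    writeLines("VECTORS velocity double", con)
    writeLines(paste(format(as.numeric(uc), digits = 10),
                     format(as.numeric(vc), digits = 10), "0"), con)
  } else {
    df <- expand.grid(i = seq_len(nx), j = seq_len(ny))
    df <- data.frame(x = (df$i - 0.5) * g$hx, y = (df$j - 0.5) * g$hy,
                     u = as.numeric(uc), v = as.numeric(vc),
                     p = as.numeric(solution$p))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
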