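#' Tissue grid
#'
#' Geometry and per-site composition of a 1D cable (\code{ny = 1}) or 2D
#' monodomain sheet: cell-type map, diffusion-scale field, obstacle mask
#' and optional fibroblast attachment.  One grid point is one cell
#' (\code{dx = 0.02} cm).  Obstacle sites carry no membrane dynamics and
#' all faces touching them are no-flux, which is the removed-node
#' equivalent of setting the local diffusion constant to zero.
#'
#' @param nx,ny site counts (ny = 1 for cables).
#' @param dx lattice spacing, cm (default 0.02).
#' @param d0 bulk diffusion constant D0, cm^2/ms (default 0.0012; note the
#'   units -- this is the value consistent with a conduction velocity of
#'   65 cm/s at dx = 0.02 cm).
#' @param cell_type character vector/matrix (length nx*ny) of type names
#'   indexing into \code{type_params}; default all \code{"normal"}.
#' @param type_params named list of \code{\link{myocyte_params}}, one per
#'   type name used.  Defaults provide \code{normal}, \code{type-I} and
#'   \code{type-II}.
#' @param dscale per-site diffusion scale relative to d0, in [0, 1].
#' @param obstacle logical per-site obstacle mask.
#' @param fibroblast \code{NULL}, or a list with elements \code{attach}
#'   (logical per site), \code{params} (\code{\link{fibroblast_params}})
#'   and \code{g_gap} (nS, scalar or per site).  \code{e_f} may also be
#'   given per site to override \code{params$e_f}.
#' @return an object of class \code{tissue_grid}.
#' @export
tissue_grid <- function(nx, ny = 1, dx = 0.02, d0 = 0.0012,
                        cell_type = NULL, type_params = NULL,
                        dscale = NULL, obstacle = NULL, fibroblast = NULL) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 1, ny >= 1, dx > 0, d0 > 0)
  ns <- nx * ny
  if (is.null(cell_type)) cell_type <- rep("normal", ns)
  cell_type <- as.character(cell_type)
  if (length(cell_type) != ns) stop("cell_type must have length nx*ny")
  if (is.null(type_params))
    type_params <- list(normal = myocyte_params(),
                        `type-I` = make_ead_parameters("type-I"),
                        `type-II` = make_ead_parameters("type-II"))
  if (!all(unique(cell_type) %in% names(type_params)))
    stop("cell_type contains names missing from type_params")
  if (is.null(dscale)) dscale <- rep(1, ns)
  dscale <- as.numeric(dscale)
  if (length(dscale) != ns) stop("dscale must have length nx*ny")
  if (any(dscale < 0 | dscale > 1)) stop("dscale values must be in [0, 1]")
  if (is.null(obstacle)) obstacle <- rep(FALSE, ns)
  obstacle <- as.logical(obstacle)
  if (length(obstacle) != ns) stop("obstacle must have length nx*ny")
  if (!is.null(fibroblast)) {
    stopifnot(is.list(fibroblast), length(fibroblast$attach) == ns,
              inherits(fibroblast$params, "fibroblast_params"))
    if (any(fibroblast$attach & obstacle))
      stop("obstacle sites cannot carry fibroblasts")
    if (is.null(fibroblast$g_gap)) fibroblast$g_gap <- 8
    if (length(fibroblast$g_gap) == 1)
      fibroblast$g_gap <- rep(fibroblast$g_gap, ns)
    if (is.null(fibroblast$e_f)) fibroblast$e_f <- fibroblast$params$e_f
    if (length(fibroblast$e_f) == 1)
      fibroblast$e_f <- rep(fibroblast$e_f, ns)
  }
  structure(list(nx = nx, ny = ny, dx = dx, d0 = d0,
                 cell_type = cell_type, type_params = type_params,
                 dscale = dscale, obstacle = obstacle,
                 fibroblast = fibroblast),
            class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat(sprintf("<tissue_grid> %d x %d sites (%.2f x %.2f cm), D0 = %g cm^2/ms\n",
              x$nx, x$ny, x$nx * x$dx, x$ny * x$dx, x$d0))
  cat("  types:", paste(sprintf("%s(%d)", names(table(x$cell_type)),
                                table(x$cell_type)), collapse = " "), "\n")
  if (any(x$obstacle)) cat("  obstacles:", sum(x$obstacle), "sites\n")
  if (!is.null(x$fibroblast))
    cat("  fibroblasts:", sum(x$fibroblast$attach), "sites\n")
  invisible(x)
}

# site index helper (column-major: x runs fastest)
site_index <- function(grid, ix, iy = 1) ix + grid$nx * (iy - 1L)

#' Conservative diffusion operator
#'
#' Applies the divergence-form diffusion operator to a potential field:
#' the flux across each lattice face is \code{D_face (V_n - V_i)/dx^2}
#' with \code{D_face} the arithmetic mean of the two sites' diffusion
#' values; faces on the domain boundary or touching an obstacle carry zero
#' flux (no-flux Neumann).  With uniform D this reduces exactly to the
#' five-point Laplacian stencil \code{D (V_E + V_W + V_N + V_S - 4V)/dx^2}.
#' This R implementation is the reference for the compiled solver.
#'
#' @param vm numeric field, length nx*ny (obstacle entries ignored).
#' @param grid a \code{\link{tissue_grid}}.
#' @return the diffusion term, mV/ms (NA on obstacle sites).
#' @export
diffusion_term <- function(vm, grid) {
  stopifnot(inherits(grid, "tissue_grid"))
  nx <- grid$nx; ny <- grid$ny
  if (length(vm) != nx * ny) stop("field shape does not match grid")
  v <- matrix(vm, nx, ny)
  D <- matrix(grid$d0 * grid$dscale, nx, ny)
  ob <- matrix(grid$obstacle, nx, ny)
  out <- matrix(0, nx, ny)
  flux_pair <- function(i1, j1, i2, j2) {
    # add flux between neighbour sets (vectorised over matched indices)
    open <- !ob[cbind(i1, j1)] & !ob[cbind(i2, j2)]
    w <- 0.5 * (D[cbind(i1, j1)] + D[cbind(i2, j2)]) / grid$dx^2
    f <- ifelse(open, w * (v[cbind(i2, j2)] - v[cbind(i1, j1)]), 0)
    out[cbind(i1, j1)] <<- out[cbind(i1, j1)] + f
    out[cbind(i2, j2)] <<- out[cbind(i2, j2)] - f
  }
  if (nx > 1) {
    g <- expand.grid(i = seq_len(nx - 1), j = seq_len(ny))
    flux_pair(g$i, g$j, g$i + 1L, g$j)
  }
  if (ny > 1) {
    g <- expand.grid(i = seq_len(nx), j = seq_len(ny - 1))
    flux_pair(g$i, g$j, g$i, g$j + 1L)
  }
  out[ob] <- NA_real_
  as.vector(out)
}

# map the grid's composition to the argument set of simulate_tissue_cpp
grid_cpp_args <- function(grid) {
  tn <- names(grid$type_params)
  type <- match(grid$cell_type, tn) - 1L
  mult <- do.call(rbind, lapply(grid$type_params, mult_vector))
  ns <- grid$nx * grid$ny
  fb <- grid$fibroblast
  if (is.null(fb)) {
    list(type = type, mult = mult,
         fib_attach = rep(FALSE, ns), fib_ef = numeric(ns),
         fib_ggap = numeric(ns), gf_lo = 4, gf_hi = 4, gf_vt = -20,
         cf = 6.3)
  } else {
    p <- fb$params
    list(type = type, mult = mult,
         fib_attach = fb$attach, fib_ef = fb$e_f, fib_ggap = fb$g_gap,
         gf_lo = p$g_f[1], gf_hi = p$g_f[length(p$g_f)],
         gf_vt = p$breakpoint, cf = p$c_f)
  }
}

# initial state matrix (35 x n_types)
grid_init_states <- function(grid, init = c("published", "rested")) {
  init <- match.arg(init)
  states <- lapply(grid$type_params, function(p) {
    if (init == "published") initial_state() else resting_state(p)
  })
  do.call(cbind, states)
}

#' Advance a tissue state by one explicit step
#'
#' Reference (R-level) single forward-Euler step of the monodomain system:
#' every non-obstacle site advances by its ionic right-hand side, gap
#' current (when a fibroblast is attached), stimulus current and diffusion
#' term; attached fibroblasts advance by their passive ODE.  Intended for
#' small grids and oracle tests; use \code{\link{run_simulation}} for real
#' runs.
#'
#' @param state list with \code{S} (35 x nsites matrix), \code{vf}
#'   (fibroblast potentials) and \code{t} (clock, ms); see
#'   \code{\link{tissue_initial_state}}.
#' @param grid a \code{\link{tissue_grid}}.
#' @param dt time step, ms.
#' @param i_stim per-site stimulus current density (uA/uF), or 0.
#' @return the advanced state (clock increased by \code{dt}).
#' @export
step_tissue <- function(state, grid, dt = 0.02, i_stim = 0) {
  stopifnot(inherits(grid, "tissue_grid"), dt > 0)
  ns <- grid$nx * grid$ny
  if (length(i_stim) == 1) i_stim <- rep(i_stim, ns)
  S <- state$S
  vf <- state$vf
  vm <- S[1, ]
  diff <- diffusion_term(vm, grid)
  fb <- grid$fibroblast
  Snew <- S
  vfnew <- vf
  for (i in seq_len(ns)) {
    if (grid$obstacle[i]) next
    p <- grid$type_params[[grid$cell_type[i]]]
    rhs <- cell_rhs_cpp(S[, i], mult_vector(p), i_stim[i])
    igap <- 0
    if (!is.null(fb) && fb$attach[i])
      igap <- gap_current(vm[i], vf[i], fb$g_gap[i])
    Snew[, i] <- S[, i] + dt * rhs$dstate
    Snew[1, i] <- vm[i] + dt * (-rhs$i_ion - i_stim[i] -
                                  igap / p$membrane_capacitance + diff[i])
    if (!is.null(fb) && fb$attach[i]) {
      If <- fibroblast_current(vf[i], fb_with_ef(fb, i))
      vfnew[i] <- vf[i] + dt * (igap - If) / fb$params$c_f
    }
  }
  if (any(!is.finite(Snew[1, !grid$obstacle])))
    stop("numerical instability in step_tissue")
  list(S = Snew, vf = vfnew, t = state$t + dt)
}

fb_with_ef <- function(fb, i) {
  p <- fb$params
  p$e_f <- fb$e_f[i]
  p
}

#' Initial tissue state
#'
#' @param grid a \code{\link{tissue_grid}}.
#' @param init \code{"published"} (the published resting condition) or
#'   \code{"rested"} (each type relaxed unpaced for 10 s).
#' @return list with the 35 x nsites state matrix \code{S}, fibroblast
#'   potentials \code{vf} (at E_f where attached) and clock \code{t = 0}.
#' @export
tissue_initial_state <- function(grid, init = c("published", "rested")) {
  init <- match.arg(init)
  ini <- grid_init_states(grid, init)
  tn <- names(grid$type_params)
  S <- ini[, match(grid$cell_type, tn), drop = FALSE]
  ns <- grid$nx * grid$ny
  vf <- numeric(ns)
  if (!is.null(grid$fibroblast))
    vf[grid$fibroblast$attach] <- grid$fibroblast$e_f[grid$fibroblast$attach]
  S[, grid$obstacle] <- NA_real_
  list(S = S, vf = vf, t = 0)
}

#' Run a monodomain tissue simulation
#'
#' Executes the explicit step loop (compiled), applying the pacing
#' protocol(s) and recording point traces, an activation-time map and
#' optional field snapshots.  Fully deterministic for a given grid and
#' protocol.
#'
#' @param grid a \code{\link{tissue_grid}}.
#' @param protocol a stimulus protocol (see \code{\link{asymmetric_pacing}}),
#'   a list of protocols (e.g. an S1-S2 schedule), or \code{NULL} for an
#'   unstimulated run.
#' @param duration_ms simulated time, ms.
#' @param sensors integer site indices to record (default: cable ends or
#'   four corner sensors); see \code{\link{place_sensors}}.
#' @param dt time step, ms (default 0.02).
#' @param sample_ms trace sampling interval, ms.
#' @param snapshot_ms field snapshot interval, ms (0 = none; the study's
#'   video cadence is 20 ms).
#' @param init initial condition: \code{"published"}, \code{"rested"}, or a
#'   state list from \code{\link{tissue_initial_state}} /a previous run's
#'   \code{final_state} (checkpoint resume).
#' @param gate_method \code{"rush_larsen"} (default) or \code{"euler"}.
#' @param record_vf record fibroblast potentials at sensors.
#' @param return_state return the full final state (for resuming).
#' @return an object of class \code{tissue_run}: list with \code{time},
#'   \code{traces} (samples x sensors), \code{activation_map} (ms, NA if
#'   never activated), \code{v_final}, \code{snapshots},
#'   \code{snapshot_times}, \code{sensors}, \code{grid}, \code{protocol}
#'   and optionally \code{vf_traces}, \code{final_state}.
#' @export
run_simulation <- function(grid, protocol, duration_ms,
                           sensors = NULL, dt = 0.02, sample_ms = 1,
                           snapshot_ms = 0,
                           init = c("published", "rested"),
                           gate_method = c("rush_larsen", "euler"),
                           record_vf = FALSE, return_state = FALSE) {
  stopifnot(inherits(grid, "tissue_grid"), duration_ms > 0, dt > 0)
  gate_method <- match.arg(gate_method)
  if (is.null(protocol)) protocol <- list()
  if (inherits(protocol, "stimulus_protocol")) protocol <- list(protocol)
  stopifnot(all(vapply(protocol, inherits, TRUE, "stimulus_protocol")))
  if (is.null(sensors)) {
    sensors <- if (grid$ny == 1)
      c(site_index(grid, max(1, round(grid$nx * 0.1))),
        site_index(grid, round(grid$nx * 0.9)))
    else place_sensors(grid, "four-corners")$index
  }
  a <- grid_cpp_args(grid)
  init_site <- NULL; init_vf <- NULL
  if (is.character(init)) {
    init <- match.arg(init)
    ini <- grid_init_states(grid, init)
  } else {
    st <- init
    ini <- grid_init_states(grid, "published") # placeholder, unused per site
    init_site <- st$S
    init_site[, grid$obstacle] <- 0
    init_vf <- st$vf
  }
  stim_sites <- lapply(protocol, function(p) protocol_sites(p, grid))
  stim_times <- lapply(protocol, function(p) pulse_times(p, duration_ms))
  stim_amp <- vapply(protocol, function(p) p$amplitude, 0)
  stim_dur <- vapply(protocol, function(p) p$pulse_duration, 0)
  r <- simulate_tissue_cpp(grid$nx, grid$ny, grid$dx, grid$d0, dt,
                           duration_ms, a$type, grid$obstacle, grid$dscale,
                           a$mult, ini, a$fib_attach, a$fib_ef, a$fib_ggap,
                           a$gf_lo, a$gf_hi, a$gf_vt, a$cf, 185,
                           stim_sites, stim_times, stim_amp, stim_dur,
                           as.integer(sensors), sample_ms, snapshot_ms,
                           gate_method == "rush_larsen", record_vf,
                           return_state, init_site, init_vf)
  out <- list(time = r$time, traces = r$traces,
              activation_map = r$activation_map, v_final = r$v_final,
              snapshots = r$snapshots, snapshot_times = r$snapshot_times,
              sensors = sensors, grid = grid, protocol = protocol,
              dt = dt, duration_ms = duration_ms)
  if (record_vf) out$vf_traces <- r$vf_traces
  if (return_state)
    out$final_state <- list(S = r$state_final, vf = r$vf_final,
                            t = duration_ms)
  class(out) <- "tissue_run"
  out
}

#' @export
print.tissue_run <- function(x, ...) {
  cat(sprintf("<tissue_run> %d x %d grid, %g ms, %d sensors\n",
              x$grid$nx, x$grid$ny, x$duration_ms, length(x$sensors)))
  invisible(x)
}
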