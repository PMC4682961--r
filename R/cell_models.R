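#' Myocyte parameter set
#'
#' Parameters of the modified O'Hara-Rudy endocardial myocyte used
#' throughout the package: the fast Na+ current is the Ten Tusscher-Panfilov
#' (2006) formulation and the membrane currents are the 14-current roster
#' \code{I_Na, I_to, I_CaL, I_CaNa, I_CaK, I_Kr, I_Ks, I_K1, I_NaCa, I_NaK,
#' I_Nab, I_Cab, I_pCa, I_Kb}.  Each current carries a positive
#' dimensionless conductance multiplier (1 = control).  The \code{I_CaL}
#' multiplier scales the L-type channel permeability, and therefore also the
#' channel's Na+ and K+ fluxes \code{I_CaNa}/\code{I_CaK}, whose own
#' multipliers act on top of it (in the source model the three
#' permeabilities are proportional).
#'
#' @param multipliers named numeric vector of conductance multipliers; names
#'   must be a subset of the current roster.  Unnamed currents keep 1.
#' @param membrane_capacitance myocyte capacitance C_m in pF (default 185).
#' @return an object of class \code{myocyte_params}.
#' @examples
#' p <- myocyte_params(c(I_CaL = 4, I_Kr = 0.21))
#' @export
myocyte_params <- function(multipliers = NULL, membrane_capacitance = 185) {
  m <- rep(1, length(CURRENT_NAMES))
  names(m) <- CURRENT_NAMES
  if (!is.null(multipliers)) {
    if (is.null(names(multipliers)) || !all(names(multipliers) %in% CURRENT_NAMES))
      stop("multiplier names must be a subset of: ",
           paste(CURRENT_NAMES, collapse = ", "))
    if (any(!is.finite(multipliers)) || any(multipliers <= 0))
      stop("all conductance multipliers must be finite and > 0")
    m[names(multipliers)] <- multipliers
  }
  if (!is.finite(membrane_capacitance) || membrane_capacitance <= 0)
    stop("membrane_capacitance must be > 0")
  structure(list(multipliers = m,
                 membrane_capacitance = membrane_capacitance,
                 base_model = "ORd2011-endo + TP06 INa"),
            class = "myocyte_params")
}

#' @export
print.myocyte_params <- function(x, ...) {
  cat("<myocyte_params>", x$base_model,
      sprintf("(Cm = %g pF)\n", x$membrane_capacitance))
  ch <- x$multipliers[x$multipliers != 1]
  if (length(ch))
    cat("  scaled:", paste(names(ch), "=", signif(ch, 4), collapse = ", "), "\n")
  else cat("  control (all multipliers 1)\n")
  invisible(x)
}

# multipliers in C++ order, with the CaL permeability scaling folded into
# the channel's Na+/K+ components
mult_vector <- function(params) {
  m <- params$multipliers
  m["I_CaNa"] <- m["I_CaNa"] * m["I_CaL"]
  m["I_CaK"] <- m["I_CaK"] * m["I_CaL"]
  unname(m[CURRENT_NAMES])
}

# default G_Kr multiplier for the type-II action potential, fixed by a
# downward scan from 0.21 (see the methods vignette for the scan criteria)
GKR_TYPE_II <- 0.12

#' EAD-capable myocyte parameters
#'
#' Reduced repolarization reserve is produced by raising the L-type Ca2+
#' conductance and lowering the rapid delayed-rectifier K+ conductance.
#' \code{"type-I"} (G_CaL x 4, G_Kr x 0.21) gives action potentials with
#' growing-amplitude EAD oscillations that eventually repolarize fully;
#' \code{"type-II"} (G_CaL x 4, G_Kr x 0.12, lower repolarization reserve)
#' gives decaying EAD oscillations that relax to a membrane potential well
#' above the normal resting value.
#'
#' @param ap_type \code{"type-I"} or \code{"type-II"}.
#' @param g_cal_mult multiplier for the L-type Ca2+ conductance (default 4).
#' @param g_kr_mult multiplier for G_Kr; defaults to 0.21 (type-I) or
#'   0.12 (type-II).
#' @return a \code{\link{myocyte_params}} object.
#' @export
make_ead_parameters <- function(ap_type = c("type-I", "type-II"),
                                g_cal_mult = 4, g_kr_mult = NULL) {
  ap_type <- match.arg(ap_type)
  if (is.null(g_kr_mult))
    g_kr_mult <- if (ap_type == "type-I") 0.21 else GKR_TYPE_II
  if (!is.finite(g_cal_mult) || g_cal_mult <= 0 ||
      !is.finite(g_kr_mult) || g_kr_mult <= 0)
    stop("conductance multipliers must be finite and > 0")
  myocyte_params(c(I_CaL = g_cal_mult, I_Kr = g_kr_mult))
}

#' Passive fibroblast parameters
#'
#' MacCannell-type passive fibroblast: membrane current
#' \code{I_f = G_f(V_f) * (V_f - E_f)} in pA with \code{G_f} in nS and
#' potentials in mV.  \code{G_f} is either constant (default 4 nS) or
#' piecewise (2 nS below -20 mV, 4 nS above; the breakpoint is fixed).
#'
#' @param e_f fibroblast resting membrane potential E_f, mV.
#' @param g_f membrane conductance, nS: a single value (constant model) or
#'   a length-2 vector \code{c(low, high)} for the piecewise model.
#' @param c_f membrane capacitance, pF (default 6.3).
#' @param model \code{"constant"} or \code{"piecewise"}; inferred from the
#'   length of \code{g_f} when missing.
#' @return an object of class \code{fibroblast_params}.
#' @export
fibroblast_params <- function(e_f, g_f = 4, c_f = 6.3,
                              model = c("constant", "piecewise")) {
  if (missing(model)) model <- if (length(g_f) == 2) "piecewise" else "constant"
  model <- match.arg(model)
  if (model == "piecewise" && length(g_f) == 1) g_f <- c(2, 4)
  if (model == "constant" && length(g_f) != 1)
    stop("constant model takes a single g_f")
  if (any(g_f <= 0) || c_f <= 0)
    stop("conductances and capacitance must be > 0")
  structure(list(e_f = e_f, g_f = g_f, c_f = c_f, model = model,
                 breakpoint = -20),
            class = "fibroblast_params")
}

#' Gap-junctional current between a myocyte and a fibroblast
#'
#' \code{I_gap = G_gap * (V_m - V_f)} (pA).  The same current is subtracted
#' from the myocyte and added to the fibroblast, so the charge transfer is
#' antisymmetric.
#'
#' @param vm,vf membrane potentials, mV.
#' @param g_gap gap-junctional conductance, nS (>= 0).
#' @return current in pA.
#' @export
gap_current <- function(vm, vf, g_gap) {
  if (any(g_gap < 0)) stop("g_gap must be >= 0")
  g_gap * (vm - vf)
}

#' Fibroblast membrane current
#'
#' @param vf fibroblast membrane potential, mV.
#' @param params a \code{\link{fibroblast_params}} object.
#' @return current I_f in pA.
#' @export
fibroblast_current <- function(vf, params) {
  stopifnot(inherits(params, "fibroblast_params"))
  gf <- if (params$model == "piecewise")
    ifelse(vf < params$breakpoint, params$g_f[1], params$g_f[2])
  else params$g_f
  gf * (vf - params$e_f)
}

#' Published initial (resting) state of the myocyte
#'
#' The published ORd resting condition with gates at their steady state for
#' V = -87 mV.  For a fully relaxed state see \code{\link{resting_state}}.
#'
#' @return named numeric vector of the 35 state variables.
#' @export
initial_state <- function() ord_initial_state_cpp()

#' Relaxed resting state
#'
#' Integrates the unpaced cell for \code{duration_ms} so that the slow
#' concentration variables settle; the returned state is a numerical fixed
#' point of the control model (|dV/dt| < 1e-6 mV/ms for control parameters).
#'
#' @param params myocyte parameters.
#' @param duration_ms relaxation time (default 10000 ms).
#' @param dt time step, ms.
#' @return named state vector.
#' @export
resting_state <- function(params = myocyte_params(), duration_ms = 10000,
                          dt = 0.02) {
  r <- simulate_cell_cpp(initial_state(), mult_vector(params), dt,
                         duration_ms, duration_ms, numeric(0), 0, 0,
                         FALSE, 0, 6.3, -35, 4, 4, -20, 0,
                         params$membrane_capacitance, TRUE, TRUE)
  r$state
}

#' Total ionic current and state derivatives
#'
#' Evaluates the right-hand side of the myocyte model at a given state:
#' the total membrane current density I_ion (sum of the 14 roster currents,
#' each scaled by its multiplier) and the time derivatives of all gating
#' variables and concentrations.  This is the exact (table-free) evaluation
#' used as the reference for the tabulated fast path.
#'
#' @param state named state vector (see \code{\link{initial_state}}).
#' @param params myocyte parameters.
#' @param i_stim stimulus current density (uA/uF) entering the K+
#'   bookkeeping, as in the source model.
#' @return list with \code{i_ion} (uA/uF), \code{dstate} and the named
#'   \code{currents} vector.
#' @export
ionic_rhs <- function(state, params = myocyte_params(), i_stim = 0) {
  validate_state(state)
  cell_rhs_cpp(as.numeric(state), mult_vector(params), i_stim)
}

validate_state <- function(state) {
  if (length(state) != 35 || any(!is.finite(state)))
    stop("state must be a finite numeric vector of length 35")
  invisible(state)
}

#' Myocyte-fibroblast composite unit
#'
#' A single myocyte optionally coupled to one passive fibroblast through a
#' gap-junctional conductance \code{g_gap} (nS).  With no fibroblast the
#' gap current is identically zero and the unit is the isolated myocyte.
#'
#' @param myocyte myocyte parameters.
#' @param fibroblast \code{NULL} or \code{\link{fibroblast_params}}.
#' @param g_gap gap conductance, nS; default 8 when a fibroblast is
#'   attached, 0 otherwise.
#' @param state initial myocyte state.
#' @param vf initial fibroblast potential (defaults to E_f).
#' @return an object of class \code{composite_unit}.
#' @export
composite_unit <- function(myocyte = myocyte_params(), fibroblast = NULL,
                           g_gap = if (is.null(fibroblast)) 0 else 8,
                           state = initial_state(),
                           vf = if (is.null(fibroblast)) NA_real_ else fibroblast$e_f) {
  stopifnot(inherits(myocyte, "myocyte_params"))
  if (!is.null(fibroblast)) stopifnot(inherits(fibroblast, "fibroblast_params"))
  if (g_gap < 0) stop("g_gap must be >= 0")
  if (is.null(fibroblast) && g_gap != 0)
    stop("g_gap must be 0 when no fibroblast is attached")
  validate_state(state)
  structure(list(myocyte = myocyte, fibroblast = fibroblast, g_gap = g_gap,
                 state = state, vf = vf),
            class = "composite_unit")
}

fib_args <- function(unit) {
  # flatten the optional fibroblast into the argument set of the C++ kernels
  f <- unit$fibroblast
  if (is.null(f))
    list(has_fib = FALSE, vf0 = 0, cf = 6.3, ef = -35, gf_lo = 4, gf_hi = 4,
         gf_vt = -20, ggap = 0)
  else
    list(has_fib = TRUE, vf0 = if (is.na(unit$vf)) f$e_f else unit$vf,
         cf = f$c_f, ef = f$e_f,
         gf_lo = f$g_f[1], gf_hi = f$g_f[length(f$g_f)],
         gf_vt = f$breakpoint, ggap = unit$g_gap)
}

#' Advance a composite unit by forward-Euler steps
#'
#' One (or \code{n}) explicit time step(s) of the coupled
#' myocyte-fibroblast ODEs: \code{dVm/dt = -(I_ion + I_gap/C_m + I_stim)},
#' \code{dVf/dt = (I_gap - I_f)/C_f}, with I_gap in pA converted through
#' C_m in pF.  Gating variables use the Rush-Larsen exponential update by
#' default (see the methods vignette); \code{gate_method = "euler"} selects
#' the plain forward-Euler update, which requires a much smaller \code{dt}.
#'
#' @param unit a \code{\link{composite_unit}}.
#' @param dt time step, ms (default 0.02).
#' @param i_stim stimulus current density, uA/uF (negative = depolarizing).
#' @param n number of steps.
#' @param gate_method \code{"rush_larsen"} (default) or \code{"euler"}.
#' @return the advanced \code{composite_unit}.
#' @export
step_composite <- function(unit, dt = 0.02, i_stim = 0, n = 1,
                           gate_method = c("rush_larsen", "euler")) {
  stopifnot(inherits(unit, "composite_unit"), dt > 0, n >= 1)
  gate_method <- match.arg(gate_method)
  fa <- fib_args(unit)
  stim_times <- if (i_stim != 0) 0 else numeric(0)
  r <- simulate_cell_cpp(as.numeric(unit$state), mult_vector(unit$myocyte),
                         dt, n * dt, dt, stim_times, n * dt, i_stim,
                         fa$has_fib, fa$vf0, fa$cf, fa$ef, fa$gf_lo,
                         fa$gf_hi, fa$gf_vt, fa$ggap,
                         unit$myocyte$membrane_capacitance,
                         gate_method == "rush_larsen", TRUE)
  unit$state <- r$state
  if (fa$has_fib) unit$vf <- r$vf_final
  unit
}

#' Simulate a paced single cell (or myocyte-fibroblast composite)
#'
#' Runs the composite unit under a periodic pacing protocol and returns the
#' sampled membrane potential trace.
#'
#' @param unit a \code{\link{composite_unit}}.
#' @param protocol a stimulus protocol, e.g. \code{\link{cell_pacing}}.
#'   Single-cell pacing defaults to -80 uA/uF for 0.5 ms (the cell-level
#'   stimulus of the source model); the tissue-level -150 uA/uF x 3 ms pulse
#'   is far too strong for an isolated cell.
#' @param duration_ms simulation length, ms.
#' @param dt time step, ms.
#' @param sample_ms sampling interval of the returned trace, ms.
#' @param gate_method gate update scheme, see \code{\link{step_composite}}.
#' @return a \code{cell_trace} data frame with columns \code{time_ms},
#'   \code{vm_mV} and, when a fibroblast is attached, \code{vf_mV}; the
#'   final unit is attached as attribute \code{"unit"}.
#' @export
simulate_cell <- function(unit, protocol = cell_pacing(),
                          duration_ms = 5000, dt = 0.02, sample_ms = 1,
                          gate_method = c("rush_larsen", "euler")) {
  stopifnot(inherits(unit, "composite_unit"), duration_ms > 0)
  gate_method <- match.arg(gate_method)
  stopifnot(inherits(protocol, "stimulus_protocol"))
  fa <- fib_args(unit)
  times <- pulse_times(protocol, duration_ms)
  r <- simulate_cell_cpp(as.numeric(unit$state), mult_vector(unit$myocyte),
                         dt, duration_ms, sample_ms, times,
                         protocol$pulse_duration, protocol$amplitude,
                         fa$has_fib, fa$vf0, fa$cf, fa$ef, fa$gf_lo,
                         fa$gf_hi, fa$gf_vt, fa$ggap,
                         unit$myocyte$membrane_capacitance,
                         gate_method == "rush_larsen", TRUE)
  out <- data.frame(time_ms = r$time, vm_mV = r$vm)
  if (fa$has_fib) out$vf_mV <- r$vf
  unit$state <- r$state
  if (fa$has_fib) unit$vf <- r$vf_final
  attr(out, "unit") <- unit
  attr(out, "protocol") <- protocol
  class(out) <- c("cell_trace", "data.frame")
  out
}

#' Write a trace to CSV
#'
#' @param trace a \code{cell_trace} (or any data frame).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
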