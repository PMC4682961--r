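#' Stimulus protocol
#'
#' A periodic rectangular-region current injection.  The region is a
#' rectangle in cm (\code{c(x0, y0, wx, wy)}, origin at the domain's
#' lower-left corner); sites whose centres fall inside receive the
#' amplitude (uA/uF, negative = depolarizing under the sign convention
#' \code{dVm/dt = -(I_ion + I_stim)}) for \code{pulse_duration} ms at
#' \code{first_ms + k * pcl}.
#'
#' @param region numeric rectangle \code{c(x0, y0, wx, wy)} in cm, or
#'   \code{NULL} for a single-cell protocol.
#' @param amplitude stimulus current density, uA/uF.
#' @param pulse_duration pulse length, ms.
#' @param pcl pacing cycle length, ms (Inf for a single pulse).
#' @param first_ms time of the first pulse, ms.
#' @param n_pulses optional cap on the number of pulses.
#' @return an object of class \code{stimulus_protocol}.
#' @export
stimulus_protocol <- function(region = NULL, amplitude = -150,
                              pulse_duration = 3, pcl = 1000,
                              first_ms = 50, n_pulses = Inf) {
  if (pulse_duration <= 0) stop("pulse_duration must be > 0")
  if (is.finite(pcl) && pulse_duration >= pcl)
    stop("pulse_duration must be smaller than the cycle length")
  structure(list(region = region, amplitude = amplitude,
                 pulse_duration = pulse_duration, pcl = pcl,
                 first_ms = first_ms, n_pulses = n_pulses),
            class = "stimulus_protocol")
}

#' Single-cell pacing protocol
#'
#' Periodic pacing for isolated cells / composites: the cell-level
#' stimulus of the source model (-80 uA/uF for 0.5 ms).
#'
#' @param pcl pacing cycle length, ms.
#' @param amplitude stimulus, uA/uF.
#' @param pulse_duration ms.
#' @param first_ms first pulse time, ms.
#' @return a \code{stimulus_protocol} with no region.
#' @export
cell_pacing <- function(pcl = 1000, amplitude = -80, pulse_duration = 0.5,
                        first_ms = 50) {
  stimulus_protocol(NULL, amplitude, pulse_duration, pcl, first_ms)
}

# pulse onset times within a run
pulse_times <- function(protocol, duration_ms) {
  if (protocol$first_ms > duration_ms) return(numeric(0))
  tt <- if (is.finite(protocol$pcl))
    seq(protocol$first_ms, duration_ms, by = protocol$pcl)
  else protocol$first_ms
  head(tt, protocol$n_pulses)
}

# 1-based site indices covered by the protocol's region
protocol_sites <- function(protocol, grid) {
  r <- protocol$region
  if (is.null(r)) stop("protocol has no spatial region")
  xs <- (seq_len(grid$nx) - 0.5) * grid$dx
  ys <- (seq_len(grid$ny) - 0.5) * grid$dx
  inx <- xs > r[1] & xs < r[1] + r[3]
  iny <- ys > r[2] & ys < r[2] + r[4]
  sites <- which(as.vector(outer(inx, iny, `&`)))
  if (!length(sites)) stop("stimulus region does not intersect the domain")
  as.integer(sites)
}

#' Asymmetric pacing protocol
#'
#' The study's tissue pacing: a -150 uA/uF, 3 ms pulse over a 0.14 x 3 cm^2
#' region abutting the lower-right boundary (at dx = 0.02 cm this is a
#' 150 x 7 site rectangle: 3 cm along the bottom edge, ending at the right
#' edge, 0.14 cm tall).  The placement is configurable because the study
#' describes it as both "lower" and "lower-right"; lower-right is the
#' default.
#'
#' @param grid a \code{\link{tissue_grid}} (used to right-align the region).
#' @param pcl pacing cycle length, ms (study values 1000 and 1400).
#' @param amplitude uA/uF.
#' @param pulse_duration ms.
#' @param first_ms first pulse time, ms.
#' @param width,height stimulated region extent, cm (3 x 0.14 default).
#' @param placement \code{"lower-right"} or \code{"lower-left"}.
#' @return a \code{stimulus_protocol}.
#' @export
asymmetric_pacing <- function(grid, pcl = 1000, amplitude = -150,
                              pulse_duration = 3, first_ms = 50,
                              width = 3, height = 0.14,
                              placement = c("lower-right", "lower-left")) {
  placement <- match.arg(placement)
  lx <- grid$nx * grid$dx
  width <- min(width, lx)
  x0 <- if (placement == "lower-right") lx - width else 0
  stimulus_protocol(c(x0, 0, width, height), amplitude, pulse_duration,
                    pcl, first_ms)
}

#' Cable end-pacing protocol
#'
#' Stimulates the left-side end of a 1D cable (first \code{n_sites} cells).
#'
#' @param grid a cable \code{\link{tissue_grid}} (ny = 1).
#' @param pcl,amplitude,pulse_duration,first_ms as in
#'   \code{\link{stimulus_protocol}}.
#' @param n_sites number of stimulated end cells (default 7, i.e. 0.14 cm).
#' @return a \code{stimulus_protocol}.
#' @export
cable_pacing <- function(grid, pcl = 1000, amplitude = -150,
                         pulse_duration = 3, first_ms = 50, n_sites = 7) {
  stimulus_protocol(c(0, 0, n_sites * grid$dx, grid$dx), amplitude,
                    pulse_duration, pcl, first_ms)
}

#' S1-S2 cross-field spiral initiation schedule
#'
#' S1 is a planar stimulus along the full left edge; S2 covers the lower
#' half-domain and is delivered when the S1 repolarization tail is expected
#' to cross mid-domain, producing a single free spiral in control tissue.
#' The S2 timing rule is \code{s1_time + (Lx/2)/CV + refractory}, with the
#' defaults calibrated to the control tissue (CV 65 cm/s, effective
#' refractory period ~320 ms); \code{s2_time} overrides the rule.
#'
#' @param grid a 2D \code{\link{tissue_grid}}.
#' @param s1_time S1 onset, ms.
#' @param s2_time explicit S2 onset, ms (NULL = use the rule).
#' @param amplitude,pulse_duration stimulus strength and length.
#' @param cv_cm_s assumed conduction velocity for the timing rule.
#' @param refractory_ms assumed refractory period for the timing rule.
#' @param s1_width S1 strip width, cm.
#' @return list of two \code{stimulus_protocol}s (S1, S2) with attribute
#'   \code{"s2_time"}.
#' @export
s1s2_cross_field <- function(grid, s1_time = 20, s2_time = NULL,
                             amplitude = -150, pulse_duration = 3,
                             cv_cm_s = 65, refractory_ms = 320,
                             s1_width = 0.1) {
  if (grid$ny < 2) stop("S1-S2 cross-field needs a 2D grid")
  lx <- grid$nx * grid$dx
  ly <- grid$ny * grid$dx
  if (is.null(s2_time))
    s2_time <- s1_time + (lx / 2) / (cv_cm_s / 1000) + refractory_ms
  if (s2_time <= s1_time) stop("S2 must come after S1")
  s1 <- stimulus_protocol(c(0, 0, s1_width, ly), amplitude, pulse_duration,
                          pcl = Inf, first_ms = s1_time)
  s2 <- stimulus_protocol(c(0, 0, lx, ly / 2), amplitude, pulse_duration,
                          pcl = Inf, first_ms = s2_time)
  out <- list(s1 = s1, s2 = s2)
  attr(out, "s2_time") <- s2_time
  out
}

#' Sensor placement
#'
#' \code{"four-corners"}: one sensor per quadrant, inset \code{margin} cm
#' from each corner (the study records spectra from four points near the
#' corners).  \code{"clump-ring"}: \code{n} sensors equally spaced on a
#' circle of radius \code{R + margin} around the clump centre (for PVC
#' counting just outside the clump).  \code{"cable-every-site"}: every
#' site of a cable.  Sensors falling on obstacle sites are relocated to
#' the nearest non-obstacle site with a warning.
#'
#' @param grid a \code{\link{tissue_grid}}.
#' @param scheme placement scheme.
#' @param margin inset / ring clearance, cm (default 0.5 for corners,
#'   0.2 for the ring).
#' @param R clump radius, cm (ring scheme).
#' @param center clump centre, cm (default domain centre).
#' @param n number of ring sensors.
#' @return data frame with columns \code{index}, \code{x_cm}, \code{y_cm}.
#' @export
place_sensors <- function(grid, scheme = c("four-corners", "clump-ring",
                                           "cable-every-site"),
                          margin = NULL, R = NULL, center = NULL, n = 32) {
  scheme <- match.arg(scheme)
  lx <- grid$nx * grid$dx
  ly <- grid$ny * grid$dx
  pts <- switch(scheme,
    "four-corners" = {
      m <- if (is.null(margin)) 0.5 else margin
      cbind(x = c(m, lx - m, m, lx - m), y = c(m, m, ly - m, ly - m))
    },
    "clump-ring" = {
      if (is.null(R)) stop("clump-ring needs the clump radius R")
      m <- if (is.null(margin)) 0.2 else margin
      if (is.null(center)) center <- c(lx, ly) / 2
      th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
      cbind(x = center[1] + (R + m) * cos(th),
            y = center[2] + (R + m) * sin(th))
    },
    "cable-every-site" = {
      cbind(x = (seq_len(grid$nx) - 0.5) * grid$dx, y = rep(ly / 2, grid$nx))
    })
  ix <- pmin(pmax(ceiling(pts[, 1] / grid$dx), 1), grid$nx)
  iy <- pmin(pmax(ceiling(pts[, 2] / grid$dx), 1), grid$ny)
  idx <- site_index(grid, ix, iy)
  if (any(grid$obstacle[idx])) {
    warning("sensor(s) on obstacle sites relocated to nearest open site")
    open <- which(!grid$obstacle)
    ox <- (open - 1) %% grid$nx + 1
    oy <- (open - 1) %/% grid$nx + 1
    for (k in which(grid$obstacle[idx])) {
      d2 <- (ox - ix[k])^2 + (oy - iy[k])^2
      j <- open[which.min(d2)]
      idx[k] <- j
      ix[k] <- (j - 1) %% grid$nx + 1
      iy[k] <- (j - 1) %/% grid$nx + 1
    }
  }
  data.frame(index = as.integer(idx),
             x_cm = (ix - 0.5) * grid$dx, y_cm = (iy - 0.5) * grid$dx)
}
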