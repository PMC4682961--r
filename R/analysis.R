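#' Linearly interpolated threshold-crossing (activation) time
#'
#' @param time,vm uniformly sampled trace.
#' @param threshold crossing level, mV (default -40, the upstroke
#'   criterion used throughout).
#' @param all return all upward crossings (default: the first).
#' @return crossing time(s) in ms (length 0 if none).
#' @export
activation_time <- function(time, vm, threshold = -40, all = FALSE) {
  up <- which(vm[-1] > threshold & vm[-length(vm)] <= threshold)
  if (!length(up)) return(numeric(0))
  if (!all) up <- up[1]
  time[up] + (time[up + 1] - time[up]) *
    (threshold - vm[up]) / (vm[up + 1] - vm[up])
}

#' Detect action potentials in a voltage trace
#'
#' An AP starts at an upward crossing of \code{v_up} (positive slope) and
#' ends at the downward crossing of its 90\% repolarization level or at
#' the next upstroke, whichever comes first.
#'
#' @param trace a \code{cell_trace} data frame, or any data frame/list with
#'   \code{time_ms}/\code{time} and \code{vm_mV}/\code{vm}.
#' @param v_up upstroke threshold, mV.
#' @param repol_frac repolarization fraction defining AP end (default 0.9).
#' @param ead_prominence minimum EAD amplitude, mV (passed to
#'   \code{\link{detect_eads}}).
#' @return data frame of class \code{ap_features}, one row per AP:
#'   \code{upstroke_ms}, \code{peak_mV}, \code{peak_ms}, \code{end_ms},
#'   \code{apd_ms}, \code{repolarized}, \code{final_mV}, \code{rest_mV},
#'   \code{n_eads}; the per-AP EAD tables are in attribute \code{"eads"}.
#' @export
detect_aps <- function(trace, v_up = -40, repol_frac = 0.9,
                       ead_prominence = 1) {
  tv <- trace_vectors(trace)
  t <- tv$time; v <- tv$vm
  if (any(!is.finite(v))) stop("trace contains non-finite samples")
  up <- which(v[-1] > v_up & v[-length(v)] <= v_up)
  if (!length(up)) {
    out <- empty_ap_frame()
    attr(out, "eads") <- list()
    class(out) <- c("ap_features", "data.frame")
    return(out)
  }
  n <- length(up)
  rows <- vector("list", n)
  eads <- vector("list", n)
  for (k in seq_len(n)) {
    i0 <- up[k]
    i1 <- if (k < n) up[k + 1] else length(v)
    seg <- i0:i1
    # resting level: potential just before the upstroke
    ipre <- max(1, i0 - round(5 / max(diff(t)[1], 1e-9)))
    rest <- min(v[ipre:i0])
    pk <- which.max(v[seg])
    vpeak <- v[seg][pk]
    v90 <- vpeak - repol_frac * (vpeak - rest)
    after <- seg[-(1:pk)]
    dn <- after[which(v[after] < v90)[1]]
    iend <- if (!is.na(dn)) dn else i1
    repol <- !is.na(dn)
    ead <- detect_eads(t[seg[pk]:iend], v[seg[pk]:iend],
                       prominence = ead_prominence)
    rows[[k]] <- data.frame(
      upstroke_ms = activation_time(t[i0:(i0 + 1)], v[i0:(i0 + 1)], v_up),
      peak_mV = vpeak, peak_ms = t[seg[pk]], end_ms = t[iend],
      apd_ms = t[iend] - t[i0], repolarized = repol,
      # the potential the AP relaxes to: end of the full span, i.e. just
      # before the next upstroke (or trace end), not the 90% crossing
      final_mV = v[i1], rest_mV = rest, n_eads = nrow(ead))
    eads[[k]] <- ead
  }
  out <- do.call(rbind, rows)
  attr(out, "eads") <- eads
  class(out) <- c("ap_features", "data.frame")
  out
}

empty_ap_frame <- function() {
  data.frame(upstroke_ms = numeric(0), peak_mV = numeric(0),
             peak_ms = numeric(0), end_ms = numeric(0), apd_ms = numeric(0),
             repolarized = logical(0), final_mV = numeric(0),
             rest_mV = numeric(0), n_eads = integer(0))
}

trace_vectors <- function(trace) {
  if (is.list(trace)) {
    t <- trace$time_ms %||% trace$time
    v <- trace$vm_mV %||% trace$vm
  } else stop("trace must be a data frame or list")
  if (is.null(t) || is.null(v)) stop("trace needs time and vm columns")
  list(time = t, vm = v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect EAD oscillations in a repolarization segment
#'
#' EADs are local minima followed by local maxima of Vm occurring after the
#' AP peak and before repolarization completes; each event's amplitude is
#' the peak minus the preceding minimum.  Events below \code{prominence}
#' are discarded.
#'
#' @param time,vm the trace segment from the AP peak to the AP end.
#' @param prominence minimum amplitude, mV (default 1).
#' @return data frame with \code{time_ms}, \code{peak_mV},
#'   \code{amplitude_mV}.
#' @export
detect_eads <- function(time, vm, prominence = 1) {
  n <- length(vm)
  empty <- data.frame(time_ms = numeric(0), peak_mV = numeric(0),
                      amplitude_mV = numeric(0))
  if (n < 3) return(empty)
  d <- diff(vm)
  maxima <- which(head(d, -1) > 0 & tail(d, -1) <= 0) + 1
  minima <- which(head(d, -1) < 0 & tail(d, -1) >= 0) + 1
  if (!length(maxima)) return(empty)
  rows <- lapply(maxima, function(i) {
    pm <- minima[minima < i]
    if (!length(pm)) return(NULL)
    amp <- vm[i] - vm[max(pm)]
    data.frame(time_ms = time[i], peak_mV = vm[i], amplitude_mV = amp)
  })
  out <- do.call(rbind, rows) %||% empty
  out[out$amplitude_mV >= prominence, , drop = FALSE]
}

#' Classify an action potential
#'
#' \itemize{
#'   \item \code{normal}: no EADs, repolarization complete;
#'   \item \code{type-I}: EADs with a non-decreasing amplitude trend and
#'     complete repolarization (growing oscillations that eventually
#'     repolarize);
#'   \item \code{type-II}: EADs with a decreasing amplitude trend and a
#'     final potential elevated above rest by at least
#'     \code{elevation_margin} (decaying oscillations relaxing to a
#'     depolarized level);
#'   \item \code{other}: anything else.
#' }
#'
#' @param ap one row of \code{\link{detect_aps}} output (or the whole
#'   frame, classifying each AP).
#' @param eads the AP's EAD table (taken from the frame's attribute when
#'   \code{ap} is a full \code{ap_features} object).
#' @param elevation_margin mV above rest that counts as elevated
#'   (default 10).
#' @return character classification(s).
#' @export
classify_ap <- function(ap, eads = NULL, elevation_margin = 10) {
  if (inherits(ap, "ap_features") && nrow(ap) > 1) {
    el <- attr(ap, "eads")
    return(vapply(seq_len(nrow(ap)), function(k)
      classify_ap(ap[k, ], el[[k]], elevation_margin), ""))
  }
  if (inherits(ap, "ap_features") && is.null(eads))
    eads <- attr(ap, "eads")[[1]]
  stopifnot(nrow(ap) == 1)
  amps <- eads$amplitude_mV
  elevated <- (ap$final_mV - ap$rest_mV) >= elevation_margin
  if (!length(amps)) {
    if (ap$repolarized && !elevated) return("normal")
    return("other")
  }
  trend_up <- length(amps) == 1 || tail(amps, 1) >= amps[1]
  if (trend_up && ap$repolarized) return("type-I")
  if (!trend_up && elevated) return("type-II")
  if (trend_up && !ap$repolarized && elevated) return("type-I")
  "other"
}

#' Conduction velocity from two activation times
#'
#' \code{CV = distance / (t2 - t1)}, with activation times taken at the
#' -40 mV upward crossing (linearly interpolated).  Both sites must have
#' been activated by the same planar wave.
#'
#' @param times length-2 activation times, ms (e.g. from a run's
#'   \code{activation_map}).
#' @param distance_cm separation of the two sites, cm (> 0).
#' @return conduction velocity, cm/s.
#' @export
conduction_velocity <- function(times, distance_cm) {
  if (length(times) != 2 || any(!is.finite(times)))
    stop("need two finite activation times (site not activated?)")
  if (!is.finite(distance_cm) || distance_cm <= 0)
    stop("sites must be distinct (distance > 0)")
  dt <- abs(times[2] - times[1])
  if (dt == 0) stop("equal activation times: cannot form a velocity")
  distance_cm / dt * 1000
}

#' Count premature ventricular complexes at a sensor array
#'
#' An upstroke at a sensor is attributed to pacing when it falls within a
#' conduction-delay window after a pacing pulse (the wave needs at most
#' \code{delay_ms} to reach any sensor); remaining upstrokes are ectopic.
#' Ectopic upstrokes across sensors within \code{merge_ms} of each other
#' are merged into one wavefront episode; \code{n} is the episode count
#' inside the analysis window.  The absolute count depends on this
#' attribution rule (the study does not state one); zero/nonzero outcomes
#' and trends are the comparable quantities.
#'
#' @param run a \code{tissue_run}, or a traces matrix (samples x sensors).
#' @param time sample times (taken from \code{run} when omitted).
#' @param pacing_times pacing pulse onset times, ms (taken from the run's
#'   first protocol when omitted).
#' @param delay_ms pacing attribution window after each pulse; default
#'   \code{diag(domain)/cv_min} with \code{cv_min} = 40 cm/s.
#' @param cv_min minimum credible conduction speed, cm/s (used only when
#'   \code{delay_ms} is NULL).
#' @param merge_ms episode merge window, ms (default 50).
#' @param window analysis window \code{c(t0, t1)}, ms (default: whole run).
#' @param threshold upstroke threshold, mV.
#' @return object of class \code{pvc_report}: list with \code{n}, the
#'   per-event table \code{events} (time, sensor), \code{pacing_times} and
#'   the parameters used.
#' @export
count_pvcs <- function(run, time = NULL, pacing_times = NULL,
                       delay_ms = NULL, cv_min = 40, merge_ms = 50,
                       window = NULL, threshold = -40) {
  if (inherits(run, "tissue_run")) {
    traces <- run$traces
    time <- run$time
    if (is.null(pacing_times))
      pacing_times <- pulse_times(run$protocol[[1]], run$duration_ms)
    if (is.null(delay_ms)) {
      g <- run$grid
      delay_ms <- sqrt((g$nx * g$dx)^2 + (g$ny * g$dx)^2) / cv_min * 1000
    }
  } else {
    traces <- as.matrix(run)
    if (is.null(time) || is.null(pacing_times))
      stop("time and pacing_times are required with a bare trace matrix")
    if (is.null(delay_ms)) stop("delay_ms is required with a bare matrix")
  }
  if (is.null(window)) window <- range(time)
  ev <- do.call(rbind, lapply(seq_len(ncol(traces)), function(s) {
    tt <- activation_time(time, traces[, s], threshold, all = TRUE)
    if (!length(tt)) return(NULL)
    data.frame(time_ms = tt, sensor = s)
  }))
  if (is.null(ev)) ev <- data.frame(time_ms = numeric(0), sensor = integer(0))
  ev <- ev[ev$time_ms >= window[1] & ev$time_ms <= window[2], , drop = FALSE]
  paced <- vapply(ev$time_ms, function(tt)
    any(tt >= pacing_times & tt <= pacing_times + delay_ms), TRUE)
  ect <- ev[!paced, , drop = FALSE]
  ect <- ect[order(ect$time_ms), , drop = FALSE]
  # merge into wavefront episodes
  if (nrow(ect)) {
    episode <- cumsum(c(1, diff(ect$time_ms) > merge_ms))
    ect$episode <- episode
    events <- do.call(rbind, lapply(split(ect, episode), function(d)
      d[which.min(d$time_ms), c("time_ms", "sensor")]))
  } else {
    events <- data.frame(time_ms = numeric(0), sensor = integer(0))
  }
  structure(list(n = nrow(events), events = events,
                 pacing_times = pacing_times, delay_ms = delay_ms,
                 merge_ms = merge_ms, window = window),
            class = "pvc_report")
}

#' @export
print.pvc_report <- function(x, ...) {
  cat(sprintf("<pvc_report> N = %d PVC episode(s) in [%g, %g] ms\n",
              x$n, x$window[1], x$window[2]))
  if (x$n) print(x$events, row.names = FALSE)
  invisible(x)
}

#' Averaged power spectrum of sensor traces
#'
#' Removes each trace's mean, computes the one-sided periodogram on the
#' analysis window and averages the power across traces (the study's
#' four corner sensors).  The power normalisation satisfies Parseval:
#' \code{sum(power) == mean((x - mean(x))^2)} per trace.
#'
#' @param traces matrix (samples x sensors) or a \code{tissue_run}.
#' @param time sample times, ms (taken from the run when omitted).
#' @param window analysis window \code{c(t0, t1)} in ms; default the last
#'   10 s (excludes the initiation transient), clipped to the trace.
#' @param taper apply a Hann taper (default FALSE).
#' @param peak_rel relative power threshold for peak detection
#'   (default 1e-3 of the maximum).
#' @return object of class \code{spectrum_result}: list with
#'   \code{freq_hz}, \code{power}, \code{peaks} (data frame: freq_hz,
#'   power; parabolic-interpolated frequencies) and \code{df_hz}.
#' @export
averaged_power_spectrum <- function(traces, time = NULL, window = NULL,
                                    taper = FALSE, peak_rel = 1e-3) {
  if (inherits(traces, "tissue_run")) {
    time <- traces$time
    traces <- traces$traces
  }
  traces <- as.matrix(traces)
  if (is.null(time)) stop("time vector required")
  if (is.null(window)) window <- c(max(time[1], max(time) - 10000), max(time))
  sel <- time >= window[1] & time <= window[2]
  x <- traces[sel, , drop = FALSE]
  n <- nrow(x)
  if (n < 8) stop("analysis window too short")
  dt_s <- diff(time[sel][1:2]) / 1000
  if (n * dt_s < 2) # less than ~2 s of signal
    warning("window may be too short for the frequencies of interest")
  w <- if (taper) 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1))) else rep(1, n)
  wnorm <- mean(w^2)
  spec <- 0
  for (s in seq_len(ncol(x))) {
    xs <- (x[, s] - mean(x[, s])) * w
    X <- fft(xs)
    spec <- spec + Mod(X)^2 / n^2 / wnorm
  }
  spec <- spec / ncol(x)
  half <- seq_len(floor(n / 2) + 1)
  pow <- spec[half]
  dbl <- 2:(length(half) - if (n %% 2 == 0) 1 else 0)
  pow[dbl] <- 2 * pow[dbl]
  freq <- (half - 1) / (n * dt_s)
  pk <- find_peaks(freq, pow, peak_rel)
  structure(list(freq_hz = freq, power = pow, peaks = pk,
                 df_hz = 1 / (n * dt_s), window = window),
            class = "spectrum_result")
}

# local maxima above rel*max(power), frequency refined by parabolic
# interpolation of log-power
find_peaks <- function(freq, pow, rel) {
  if (length(pow) < 3) return(data.frame(freq_hz = numeric(0), power = numeric(0)))
  thr <- rel * max(pow[-1])
  i <- which(pow[-c(1, 2)] <= pow[-c(1, length(pow))] &
             pow[-c(length(pow) - 1, length(pow))] < pow[-c(1, length(pow))]) + 1
  i <- i[pow[i] >= thr]
  if (!length(i)) return(data.frame(freq_hz = numeric(0), power = numeric(0)))
  df <- freq[2] - freq[1]
  fh <- vapply(i, function(k) {
    if (k <= 1 || k >= length(pow)) return(freq[k])
    y <- log(pmax(pow[(k - 1):(k + 1)], 1e-300))
    den <- y[1] - 2 * y[2] + y[3]
    if (den >= 0) return(freq[k])
    freq[k] + 0.5 * (y[1] - y[3]) / den * df
  }, 0)
  data.frame(freq_hz = fh, power = pow[i])[order(pow[i], decreasing = TRUE), ]
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result> df = %.3g Hz, %d peak(s)\n",
              x$df_hz, nrow(x$peaks)))
  print(head(x$peaks, 8), row.names = FALSE)
  invisible(x)
}

#' Index spectral peaks as n1*w1 (+ n2*w2)
#'
#' Classifies a peak set as \code{periodic} (all peaks integer multiples
#' of one base within tolerance), \code{quasiperiodic} (all peaks integer
#' combinations \code{n1*w1 + n2*w2} with |n| <= \code{max_order}, where
#' the bases' ratio is not a low-order rational), or \code{other}.  Bases
#' are refined by least squares over the assigned integer indices and the
#' residual of every indexed peak is reported.
#'
#' @param spectrum a \code{spectrum_result}, or a numeric vector of peak
#'   frequencies (Hz).
#' @param max_order maximum |n| for the two-base indexing (default 4).
#' @param tol relative tolerance (default 0.02 of the base frequency).
#' @param max_peaks use at most this many strongest peaks (default 8).
#' @return list of class \code{peak_indexing}: \code{classification},
#'   \code{omega1}, \code{omega2} (NA if periodic), and \code{table}
#'   (freq, n1, n2, fitted, residual).
#' @export
index_peaks <- function(spectrum, max_order = 4, tol = 0.02,
                        max_peaks = 8) {
  f <- if (inherits(spectrum, "spectrum_result"))
    head(spectrum$peaks$freq_hz, max_peaks) else as.numeric(spectrum)
  f <- sort(unique(f[f > 0]))
  if (!length(f))
    return(structure(list(classification = "other", omega1 = NA_real_,
                          omega2 = NA_real_, table = NULL),
                     class = "peak_indexing"))
  if (length(f) == 1)
    return(structure(list(classification = "periodic", omega1 = f,
                          omega2 = NA_real_,
                          table = data.frame(freq_hz = f, n1 = 1, n2 = 0,
                                             fitted = f, residual = 0)),
                     class = "peak_indexing"))
  # ---- one-base (periodic) attempt ----
  per <- try_one_base(f, max_order, tol)
  if (!is.null(per))
    return(structure(c(list(classification = "periodic"), per),
                     class = "peak_indexing"))
  # ---- two-base (quasiperiodic) attempt ----
  qp <- try_two_base(f, max_order, tol)
  if (!is.null(qp))
    return(structure(c(list(classification = "quasiperiodic"), qp),
                     class = "peak_indexing"))
  structure(list(classification = "other", omega1 = NA_real_,
                 omega2 = NA_real_, table = NULL),
            class = "peak_indexing")
}

try_one_base <- function(f, max_order, tol) {
  # the harmonic index n is bounded by max_order, like the two-base |n|
  # bound: this is what makes a {w2-w1, w1, w2, w1+w2} set with a
  # near-rational base ratio index as quasiperiodic rather than as high
  # harmonics of the (possibly absent) difference tone
  cand <- unique(as.vector(outer(f, seq_len(max_order), `/`)))
  cand <- cand[cand >= max(f) / max_order - 1e-12]
  best <- NULL
  for (w in cand) {
    n <- round(f / w)
    if (any(n < 1) || any(n > max_order)) next
    res <- abs(f - n * w)
    if (all(res <= tol * w)) {
      w1 <- sum(n * f) / sum(n^2) # least squares
      n <- round(f / w1)
      res <- f - n * w1
      score <- sum(res^2)
      if (is.null(best) || score < best$score)
        best <- list(w1 = w1, n = n, res = res, score = score)
    }
  }
  if (is.null(best)) return(NULL)
  list(omega1 = best$w1, omega2 = NA_real_,
       table = data.frame(freq_hz = f, n1 = best$n, n2 = 0,
                          fitted = best$n * best$w1, residual = best$res))
}

try_two_base <- function(f, max_order, tol) {
  pairs <- which(upper.tri(matrix(0, length(f), length(f))), arr.ind = TRUE)
  combos <- expand.grid(n1 = -max_order:max_order, n2 = -max_order:max_order)
  combos <- combos[!(combos$n1 == 0 & combos$n2 == 0), ]
  best <- NULL
  for (r in seq_len(nrow(pairs))) {
    w1 <- f[pairs[r, 1]]; w2 <- f[pairs[r, 2]]
    # degenerate pairs: w2 an integer multiple of w1 makes the two-base
    # representation non-unique (a genuinely periodic set must have been
    # caught by the one-base route first)
    if (abs(w2 / w1 - round(w2 / w1)) <= tol) next
    fit <- index_against(f, w1, w2, combos, tol * min(w1, w2))
    if (is.null(fit)) next
    # refine by least squares and re-index
    A <- cbind(fit$n1, fit$n2)
    sol <- tryCatch(solve(crossprod(A), crossprod(A, f)), error = function(e) NULL)
    if (is.null(sol)) next
    w1r <- sol[1]; w2r <- sol[2]
    if (w1r <= 0 || w2r <= 0) next
    fit2 <- index_against(f, w1r, w2r, combos, tol * min(w1r, w2r))
    if (is.null(fit2)) next
    # canonical base choice: the pair needing the lowest total indexing
    # order (so planted bases beat e.g. (w2, w1+w2) reparametrisations),
    # residual as tie-break
    score <- sum(abs(fit2$n1) + abs(fit2$n2)) + sum(fit2$residual^2)
    if (is.null(best) || score < best$score)
      best <- list(w1 = w1r, w2 = w2r, fit = fit2, score = score)
  }
  if (is.null(best)) return(NULL)
  list(omega1 = min(best$w1, best$w2), omega2 = max(best$w1, best$w2),
       table = data.frame(freq_hz = f,
                          n1 = if (best$w1 <= best$w2) best$fit$n1 else best$fit$n2,
                          n2 = if (best$w1 <= best$w2) best$fit$n2 else best$fit$n1,
                          fitted = best$fit$fitted,
                          residual = best$fit$residual))
}

index_against <- function(f, w1, w2, combos, atol) {
  vals <- combos$n1 * w1 + combos$n2 * w2
  ord <- abs(combos$n1) + abs(combos$n2)
  n1 <- integer(length(f)); n2 <- integer(length(f))
  fitted <- numeric(length(f))
  for (k in seq_along(f)) {
    # near-rational base ratios alias (e.g. 4w1 - w2 = 2w2 when
    # w1/w2 = 3/4): among admissible combinations take the lowest order
    ok <- which(abs(vals - f[k]) <= atol)
    if (!length(ok)) return(NULL)
    j <- ok[order(ord[ok], abs(vals[ok] - f[k]))[1]]
    n1[k] <- combos$n1[j]; n2[k] <- combos$n2[j]; fitted[k] <- vals[j]
  }
  # both bases must actually be used
  if (all(n2 == 0) || all(n1 == 0)) return(NULL)
  data.frame(n1 = n1, n2 = n2, fitted = fitted, residual = f - fitted)
}

#' @export
print.peak_indexing <- function(x, ...) {
  cat("<peak_indexing>", x$classification)
  if (!is.na(x$omega1)) cat(sprintf("  w1 = %.4g Hz", x$omega1))
  if (!is.na(x$omega2)) cat(sprintf(", w2 = %.4g Hz", x$omega2))
  cat("\n")
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write analysis artefacts as plain text
#'
#' CSV/JSON serialisations of the analysis results: spectra as
#' (freq_hz, power), PVC reports as one row per event plus a JSON
#' summary, and stimulus schedules as (pulse_ms, protocol) for audit.
#'
#' @param x a \code{spectrum_result}, \code{pvc_report}, or a list of
#'   \code{stimulus_protocol}s.
#' @param path output file (CSV; for \code{pvc_report} a sibling
#'   \code{.json} summary is written as well).
#' @param duration_ms schedule horizon (protocol lists only).
#' @return \code{path}, invisibly.
#' @export
write_analysis_csv <- function(x, path, duration_ms = NULL) {
  if (inherits(x, "spectrum_result")) {
    utils::write.csv(data.frame(freq_hz = x$freq_hz, power = x$power),
                     path, row.names = FALSE)
  } else if (inherits(x, "pvc_report")) {
    utils::write.csv(x$events, path, row.names = FALSE)
    jsonlite::write_json(list(n = x$n, window = x$window,
                              delay_ms = x$delay_ms,
                              merge_ms = x$merge_ms),
                         sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                         digits = NA)
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "stimulus_protocol"))) {
    if (is.null(duration_ms)) stop("duration_ms needed for schedules")
    if (is.null(names(x))) names(x) <- paste0("protocol", seq_along(x))
    rows <- do.call(rbind, lapply(names(x), function(nm)
      data.frame(pulse_ms = pulse_times(x[[nm]], duration_ms),
                 protocol = nm)))
    utils::write.csv(rows, path, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
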