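#' Named experiment registry
#'
#' Each experiment id mirrors one figure of the study.  \code{scale =
#' "full"} uses the study's geometry (448 x 448 sites for pacing studies,
#' 960 x 960 for spirals, 15 s runs) -- these are long-running
#' configurations intended for batch execution.  \code{scale = "reduced"}
#' uses the desk-scale proxies documented in the methods vignette: 1D
#' cables for single-cell/cable studies and a 360 x 8 site strip
#' (7.2 x 0.16 cm) with band-shaped clumps, dt = 0.04 ms and 5 s of
#' pacing for 2D threshold studies.
#'
#' @return character vector of known experiment ids.
#' @export
experiment_ids <- function() {
  c("fig2", "fig3", "fig4", "fig5a", "fig5b", "fig5c", "fig6", "fig7",
    "fig8", "fig9", "fig10", "fig11", "fig12", "fig13", "fig14",
    "fig15", "fig16", "s1fig", "s2fig", "s3fig")
}

# reduced-scale strip geometry shared by the 2D threshold experiments
strip_defaults <- function() {
  list(nx = 360L, ny = 8L, dx = 0.02, d0 = 0.0012, dt = 0.04,
       duration_ms = 5000, pcl = 1000, r_small = 1.8, r_large = 2.6,
       cv_min = 25)
}

# build, run and report one strip scenario; the clump is the intersection
# of the R-disc with the strip (a band of length 2R)
run_strip_scenario <- function(R, d_ratio = 1, p_f = 0, attach_mode = "none",
                               p_a = NULL, e_f = -35, g_gap = 8,
                               g_f_model = "constant", ead_type = "type-I",
                               seed = 1, cfg = strip_defaults(),
                               snapshot_ms = 0) {
  grid <- build_scenario(nx = cfg$nx, ny = cfg$ny, dx = cfg$dx, d0 = cfg$d0,
                         R = R, ead_type = ead_type, d_ratio = d_ratio,
                         p_f = p_f, attach_mode = attach_mode, p_a = p_a,
                         e_f = e_f, g_gap = g_gap, g_f_model = g_f_model,
                         seed = seed,
                         center = c(cfg$nx, cfg$ny) / 2 * cfg$dx,
                         allow_clip = TRUE)
  protocol <- cable_pacing(grid, pcl = cfg$pcl)
  sensors <- strip_sensors(grid)
  run <- run_simulation(grid, protocol, cfg$duration_ms, sensors = sensors,
                        dt = cfg$dt, snapshot_ms = snapshot_ms)
  report <- count_pvcs(run, cv_min = cfg$cv_min)
  list(grid = grid, run = run, report = report)
}

strip_sensors <- function(grid) {
  xi <- c(20L, grid$nx - 20L)
  yi <- unique(c(2L, max(1L, grid$ny - 1L)))
  as.integer(outer(xi, (yi - 1L) * grid$nx, `+`))
}

#' Run a named experiment
#'
#' Composes the scenario generators, protocols, solver and analysis for
#' one of the study's figures and returns a result bundle with a
#' reproducibility manifest.  Long-running ids at \code{scale = "full"}
#' (the spiral studies fig15/fig16 and the full 448 x 448 pacing runs) are
#' intended for batch execution; every id has a \code{"reduced"} proxy
#' that runs on a desk.
#'
#' @param id experiment id, see \code{\link{experiment_ids}}.
#' @param scale \code{"reduced"} (default) or \code{"full"}.
#' @param seed integer seed for all randomised scenario elements.
#' @param pcl pacing cycle length, ms.
#' @param out optional output directory; when given, traces / reports /
#'   manifest are written as CSV + JSON.
#' @param overrides named list of overrides for the scale defaults
#'   (e.g. \code{list(duration_ms = 3000)}); recorded in the manifest.
#' @return a list of class \code{experiment_result} with elements
#'   \code{id}, \code{scale}, \code{results} (experiment-specific) and
#'   \code{manifest}.
#' @export
run_experiment <- function(id, scale = c("reduced", "full"), seed = 1,
                           pcl = 1000, out = NULL, overrides = list()) {
  scale <- match.arg(scale)
  id <- match.arg(id, experiment_ids())
  cfg <- modifyList(strip_defaults(), overrides)
  cfg$pcl <- pcl
  if (scale == "full") {
    cfg <- modifyList(cfg, list(nx = 448L, ny = 448L, dt = 0.02,
                                duration_ms = 15000, r_small = 2.2,
                                r_large = 2.4))
    cfg <- modifyList(cfg, overrides)
  }
  res <- switch(id,
    fig2 = exp_fig2(cfg),
    fig9 = exp_fig9(cfg),
    fig13 = exp_fig13(cfg, seed),
    fig12 = exp_fig12(cfg, seed),
    fig14 = exp_fig14(cfg, seed),
    fig3 = exp_clump_pair(cfg, seed, vary = "ap_type"),
    fig4 = , fig5a = exp_clump_pair(cfg, seed, vary = "radius"),
    fig5b = , fig6 = exp_clump_pair(cfg, seed, vary = "coupling"),
    fig5c = , fig7 = exp_clump_pair(cfg, seed, vary = "fibrosis"),
    fig8 = exp_clump_pair(cfg, seed, vary = "e_f"),
    fig10 = exp_clump_pair(cfg, seed, vary = "g_gap"),
    fig11 = exp_clump_pair(cfg, seed, vary = "random_attach"),
    s1fig = exp_clump_pair(cfg, seed, vary = "e_f", g_f_model = "piecewise"),
    s2fig = exp_clump_pair(cfg, seed, vary = "g_gap", g_f_model = "piecewise"),
    s3fig = exp_clump_pair(cfg, seed, vary = "random_attach",
                           g_f_model = "piecewise"),
    fig15 = , fig16 = exp_spiral(cfg, seed, scale))
  bundle <- structure(list(id = id, scale = scale, results = res,
                           manifest = list(id = id, scale = scale,
                                           seed = seed, pcl = pcl,
                                           config = cfg,
                                           overrides = overrides,
                                           package_version =
                                             as.character(utils::packageVersion("eadclump")))),
                      class = "experiment_result")
  if (!is.null(out)) write_bundle(bundle, out)
  bundle
}

exp_fig2 <- function(cfg) {
  res <- lapply(c("type-I", "type-II"), function(tp) {
    unit <- composite_unit(make_ead_parameters(tp))
    tr <- simulate_cell(unit, cell_pacing(pcl = cfg$pcl),
                        duration_ms = 10 * cfg$pcl)
    aps <- detect_aps(tr)
    list(ap_type = tp, trace = tr, aps = aps, classes = classify_ap(aps))
  })
  names(res) <- c("type-I", "type-II")
  res
}

exp_fig9 <- function(cfg) {
  mk <- function(e_f, g_gap) {
    fb <- if (is.null(e_f)) NULL else fibroblast_params(e_f)
    unit <- composite_unit(make_ead_parameters("type-I"), fb,
                           g_gap = if (is.null(fb)) 0 else g_gap)
    tr <- simulate_cell(unit, cell_pacing(pcl = cfg$pcl),
                        duration_ms = 10 * cfg$pcl)
    list(e_f = e_f, trace = tr, aps = detect_aps(tr))
  }
  list(isolated = mk(NULL, 0), ef_m35 = mk(-35, 8), ef_m30 = mk(-30, 8))
}

exp_fig12 <- function(cfg, seed) {
  res <- lapply(c("A", "B", "C", "D"), function(p) {
    pat <- cable_pattern(p, seed = seed)
    grid <- tissue_grid(280, 1, cell_type = pat$cell_type,
                        fibroblast = pat$fibroblast)
    run <- run_simulation(grid, cable_pacing(grid, pcl = cfg$pcl),
                          duration_ms = min(cfg$duration_ms * 2, 10000),
                          sensors = c(20L, 260L), dt = 0.02)
    list(pattern = p, run = run,
         report = count_pvcs(run, cv_min = cfg$cv_min))
  })
  names(res) <- c("A", "B", "C", "D")
  res
}

exp_fig13 <- function(cfg, seed) {
  res <- lapply(c("A", "B", "C"), function(p) {
    pat <- cable_pattern(p, seed = seed)
    grid <- tissue_grid(280, 1, cell_type = pat$cell_type,
                        fibroblast = pat$fibroblast)
    run <- run_simulation(grid, cable_pacing(grid, pcl = cfg$pcl),
                          duration_ms = 3000, sensors = 140L, dt = 0.02)
    list(pattern = p, time = run$time, vm = run$traces[, 1])
  })
  names(res) <- c("A", "B", "C")
  res
}

exp_fig14 <- function(cfg, seed, e_f_values = c(-45, -35, -25),
                      p_a_values = c(20, 50, 80)) {
  grid_cells <- expand.grid(e_f = e_f_values, p_a = p_a_values)
  rows <- lapply(seq_len(nrow(grid_cells)), function(k) {
    ef <- grid_cells$e_f[k]; pa <- grid_cells$p_a[k]
    seg <- rep(FALSE, 280); seg[61:220] <- TRUE
    fb <- fibroblast_attachment(seg, "random", p_a = pa,
                                params = fibroblast_params(ef),
                                g_gap = 8, seed = seed + k)
    ct <- rep("normal", 280); ct[61:220] <- "type-I"
    grid <- tissue_grid(280, 1, cell_type = ct, fibroblast = fb)
    run <- run_simulation(grid, cable_pacing(grid, pcl = cfg$pcl),
                          duration_ms = cfg$duration_ms,
                          sensors = c(20L, 260L), dt = 0.02)
    data.frame(e_f = ef, p_a = pa,
               n = count_pvcs(run, cv_min = cfg$cv_min)$n)
  })
  do.call(rbind, rows)
}

# paired/series clump scenarios on the reduced strip (or full domain)
exp_clump_pair <- function(cfg, seed, vary, g_f_model = "constant") {
  base <- list(R = cfg$r_small, d_ratio = 1, p_f = 0, attach_mode = "none",
               p_a = NULL, e_f = -35, g_gap = 8, g_f_model = g_f_model,
               ead_type = "type-I", seed = seed, cfg = cfg)
  series <- switch(vary,
    ap_type = list(`type-I` = list(R = cfg$r_large, ead_type = "type-I"),
                   `type-II` = list(R = cfg$r_large, ead_type = "type-II")),
    radius = list(small = list(R = cfg$r_small),
                  large = list(R = cfg$r_large)),
    coupling = list(d1.0 = list(d_ratio = 1), d0.7 = list(d_ratio = 0.7),
                    d0.2 = list(d_ratio = 0.2)),
    fibrosis = list(pf0 = list(p_f = 0), pf15 = list(p_f = 15),
                    pf55 = list(p_f = 55)),
    e_f = list(ef_m35 = list(attach_mode = "uniform", e_f = -35),
               ef_m30 = list(attach_mode = "uniform", e_f = -30)),
    g_gap = list(g8 = list(R = cfg$r_large, attach_mode = "uniform",
                           g_gap = 8),
                 g1 = list(R = cfg$r_large, attach_mode = "uniform",
                           g_gap = 1)),
    random_attach = list(random40 = list(attach_mode = "random", p_a = 40)))
  res <- lapply(series, function(ov) {
    args <- modifyList(base, ov)
    do.call(run_strip_scenario, args)
  })
  res
}

exp_spiral <- function(cfg, seed, scale) {
  # spiral studies: the full-size 19.2 x 19.2 cm configurations are
  # emitted as runnable configs; only the schedule is constructed here
  # unless scale == "full" (long-running batch execution).
  n <- if (scale == "full") 960L else cfg$nx
  mk <- function(R) {
    grid <- if (R > 0)
      build_scenario(nx = n, ny = n, R = R, seed = seed)
    else tissue_grid(n, n)
    sched <- s1s2_cross_field(grid)
    list(grid_spec = attr(grid, "scenario") %||%
           list(nx = n, ny = n, R = 0), schedule = sched)
  }
  cfgs <- list(free = mk(0), anchored_r2 = mk(if (scale == "full") 2 else 0.5),
               anchored_r3 = mk(if (scale == "full") 3 else 0.7))
  if (scale == "full") {
    cfgs <- lapply(cfgs, function(cc) {
      grid <- if (cc$grid_spec$R > 0) do.call(build_scenario, cc$grid_spec)
      else tissue_grid(n, n)
      run <- run_simulation(grid, cc$schedule, 15000,
                            sensors = place_sensors(grid, "four-corners")$index,
                            dt = 0.02)
      if (all(run$v_final < -70, na.rm = TRUE))
        warning(sprintf(paste("S2 produced no sustained reentry: tissue at",
                              "rest at t = 15000 ms (Vm range %.1f to %.1f",
                              "mV); retune s2_time"),
                        min(run$v_final, na.rm = TRUE),
                        max(run$v_final, na.rm = TRUE)))
      spec <- averaged_power_spectrum(run)
      c(cc, list(run = run, spectrum = spec, indexing = index_peaks(spec)))
    })
  }
  cfgs
}

#' Parameter sweep
#'
#' Runs the strip clump scenario over a grid of one variable and returns a
#' tidy table (one row per value and replicate).  Individual failures are
#' recorded and do not stop the sweep.
#'
#' @param variable one of \code{"R"}, \code{"d_ratio"}, \code{"p_f"},
#'   \code{"p_a"}, \code{"e_f"}, \code{"g_gap"}.
#' @param values numeric values to sweep.
#' @param replicates seeds per value (default 1).
#' @param seed base seed; replicate r of value v uses
#'   \code{seed + 1000*r + match(v)}.
#' @param pcl pacing cycle length, ms.
#' @param overrides reduced-geometry overrides, as in
#'   \code{\link{run_experiment}}.
#' @return data frame: \code{variable}, \code{value}, \code{replicate},
#'   \code{seed}, \code{pcl}, \code{n} (PVC count; NA on failure),
#'   \code{runtime_s}, \code{error}.
#' @export
sweep_experiment <- function(variable, values, replicates = 1, seed = 1,
                             pcl = 1000, overrides = list()) {
  stopifnot(variable %in% c("R", "d_ratio", "p_f", "p_a", "e_f", "g_gap"))
  cfg <- modifyList(strip_defaults(), overrides)
  cfg$pcl <- pcl
  rows <- list()
  for (r in seq_len(replicates)) for (k in seq_along(values)) {
    v <- values[k]
    sd <- seed + 1000 * r + k
    args <- list(R = cfg$r_small, seed = sd, cfg = cfg)
    args[[switch(variable, R = "R", d_ratio = "d_ratio", p_f = "p_f",
                 p_a = "p_a", e_f = "e_f", g_gap = "g_gap")]] <- v
    if (variable == "p_a") args$attach_mode <- "random"
    if (variable %in% c("e_f", "g_gap")) args$attach_mode <- "uniform"
    t0 <- Sys.time()
    res <- tryCatch(do.call(run_strip_scenario, args),
                    error = function(e) e)
    el <- as.numeric(Sys.time() - t0, units = "secs")
    rows[[length(rows) + 1]] <- data.frame(
      variable = variable, value = v, replicate = r, seed = sd, pcl = pcl,
      n = if (inherits(res, "error")) NA_integer_ else res$report$n,
      runtime_s = el,
      error = if (inherits(res, "error")) conditionMessage(res) else "")
  }
  out <- do.call(rbind, rows)
  out[order(out$value, out$replicate), ]
}

write_bundle <- function(bundle, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(bundle$manifest,
                       file.path(out, paste0(bundle$id, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # per-result reports where available
  rs <- bundle$results
  if (is.data.frame(rs)) {
    utils::write.csv(rs, file.path(out, paste0(bundle$id, "_table.csv")),
                     row.names = FALSE)
  } else if (is.list(rs)) {
    for (nm in names(rs)) {
      el <- rs[[nm]]
      if (is.list(el) && !is.null(el$report))
        jsonlite::write_json(
          list(n = el$report$n, events = el$report$events),
          file.path(out, sprintf("%s_%s_pvc.json", bundle$id, nm)),
          auto_unbox = TRUE, digits = NA)
      if (is.list(el) && !is.null(el$trace))
        write_trace_csv(el$trace,
                        file.path(out, sprintf("%s_%s_trace.csv",
                                               bundle$id, nm)))
    }
  }
  invisible(out)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s (%s scale)\n", x$id, x$scale))
  invisible(x)
}

#' Command-line interface
#'
#' Entry point used by \code{inst/cli/eadclump.R}:
#' \preformatted{
#'   eadclump run <experiment-id> [--scale reduced|full] [--seed N]
#'                [--pcl MS] [--out DIR]
#'   eadclump sweep <variable> --values v1,v2,... [--replicates N]
#'                [--seed N] [--pcl MS] [--out DIR]
#'   eadclump generate [--seed N] [--out DIR]   # scenario bundle
#' }
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
eadclump_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: eadclump <run|sweep|generate> ...")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- parse_cli_opts(args[-1])
  status <- 0L
  if (cmd == "run") {
    id <- opt$positional[1]
    b <- run_experiment(id, scale = opt$scale %||% "reduced",
                        seed = as.integer(opt$seed %||% "1"),
                        pcl = as.numeric(opt$pcl %||% "1000"),
                        out = opt$out)
    message(sprintf("experiment %s done", id))
  } else if (cmd == "sweep") {
    v <- opt$positional[1]
    vals <- as.numeric(strsplit(opt$values, ",")[[1]])
    tab <- sweep_experiment(v, vals,
                            replicates = as.integer(opt$replicates %||% "1"),
                            seed = as.integer(opt$seed %||% "1"),
                            pcl = as.numeric(opt$pcl %||% "1000"))
    if (!is.null(opt$out)) {
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(tab, file.path(opt$out, "sweep.csv"),
                       row.names = FALSE)
    } else print(tab)
  } else if (cmd == "generate") {
    g <- build_scenario(nx = as.integer(opt$nx %||% "448"),
                        ny = as.integer(opt$ny %||% "448"),
                        R = as.numeric(opt$R %||% "2.4"),
                        seed = as.integer(opt$seed %||% "1"))
    sc <- attr(g, "scenario")
    if (!is.null(opt$out)) {
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(sc, file.path(opt$out, "scenario.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      utils::write.csv(data.frame(site = seq_along(g$cell_type),
                                  cell_type = g$cell_type,
                                  dscale = g$dscale,
                                  obstacle = g$obstacle),
                       file.path(opt$out, "maps.csv"), row.names = FALSE)
    } else utils::str(sc)
  } else {
    message("unknown command: ", cmd)
    status <- 1L
  }
  invisible(status)
}

parse_cli_opts <- function(args) {
  opt <- list(positional = character(0))
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      opt[[substring(a, 3)]] <- args[i + 1]
      i <- i + 2
    } else {
      opt$positional <- c(opt$positional, a)
      i <- i + 1
    }
  }
  opt
}
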