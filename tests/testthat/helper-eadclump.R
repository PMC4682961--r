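# shared fixtures: heavy simulations are computed once per test session
# and reused across test files (testthat runs all files in one process)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# control cable run at the nominal numerical parameters (the CV fixture)
control_cable_run <- function(dscale = 1, dt = 0.02, nx = 448L,
                              duration_ms = 500, dx = 0.02) {
  key <- sprintf("cable_%g_%g_%d_%g_%g", dscale, dt, nx, duration_ms, dx)
  cached(key, {
    grid <- tissue_grid(nx, 1, dx = dx, dscale = rep(dscale, nx))
    run_simulation(grid, cable_pacing(grid, pcl = Inf),
                   duration_ms = duration_ms, dt = dt,
                   sensors = c(100L, 300L))
  })
}

cable_cv <- function(run, i1 = 100L, i2 = 300L) {
  conduction_velocity(run$activation_map[c(i1, i2)],
                      (i2 - i1) * run$grid$dx)
}

# long single-cell traces for the two EAD phenotypes and control
typeI_trace <- function() cached("typeI_trace",
  simulate_cell(composite_unit(make_ead_parameters("type-I")),
                cell_pacing(), duration_ms = 10000))

typeII_trace <- function() cached("typeII_trace",
  simulate_cell(composite_unit(make_ead_parameters("type-II")),
                cell_pacing(), duration_ms = 10000))

control_trace <- function() cached("control_trace",
  simulate_cell(composite_unit(), cell_pacing(), duration_ms = 5000))

# 15-s composite runs for the fibroblast E_f comparison
composite_run <- function(e_f, g_gap) {
  key <- sprintf("comp_%s_%g", if (is.null(e_f)) "iso" else e_f, g_gap)
  cached(key, {
    fb <- if (is.null(e_f)) NULL else fibroblast_params(e_f)
    simulate_cell(composite_unit(make_ead_parameters("type-I"), fb,
                                 g_gap = if (is.null(fb)) 0 else g_gap),
                  cell_pacing(), duration_ms = 15000)
  })
}

# cable-pattern runs (Fig 12 configuration)
pattern_run <- function(p, duration_ms = 10000, seed = 7) {
  cached(paste0("pattern_", p), {
    pat <- cable_pattern(p, seed = seed)
    grid <- tissue_grid(280, 1, cell_type = pat$cell_type,
                        fibroblast = pat$fibroblast)
    run_simulation(grid, cable_pacing(grid, pcl = 1000),
                   duration_ms = duration_ms, sensors = c(20L, 260L),
                   dt = 0.02)
  })
}

pattern_pvcs <- function(p) count_pvcs(pattern_run(p), cv_min = 25)$n

# reduced-scale strip scenarios (criterion-5 geometry)
strip_run <- function(R, d_ratio = 1, p_f = 0, seed = 1) {
  key <- sprintf("strip_%g_%g_%g_%d", R, d_ratio, p_f, seed)
  cached(key, eadclump:::run_strip_scenario(R = R, d_ratio = d_ratio,
                                            p_f = p_f, seed = seed))
}

# small random heterogeneous grid for operator tests
random_small_grid <- function(seed, nx = 8, ny = 8, p_obst = 0.15) {
  with_seed <- eadclump:::with_seed
  with_seed(seed, {
    ob <- runif(nx * ny) < p_obst
    ds <- runif(nx * ny, 0.2, 1)
    tissue_grid(nx, ny, cell_type = rep("normal", nx * ny),
                dscale = ds, obstacle = ob)
  })
}

# dense matrix of the diffusion operator (oracle for conservation tests)
diffusion_matrix <- function(grid) {
  n <- grid$nx * grid$ny
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n)
    e[j] <- 1
    col <- diffusion_term(e, grid)
    col[is.na(col)] <- 0
    M[, j] <- col
  }
  M
}
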