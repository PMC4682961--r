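#' Circular EAD clump map
#'
#' Marks all sites whose centre lies within distance R (cm, Euclidean) of
#' the clump centre as EAD cells.  The default centre is the domain centre,
#' matching the study's "circular clumps embedded in the middle of the
#' simulation domain".
#'
#' @param grid_shape \code{c(nx, ny)}.
#' @param dx lattice spacing, cm.
#' @param R clump radius, cm (>= 0; 0 gives an all-normal map).
#' @param center clump centre in cm, default the domain centre.
#' @param ead_type name for the clump sites (default \code{"type-I"}).
#' @param allow_clip permit a disc that extends beyond the domain (used by
#'   the reduced-scale strip proxies, where the clump is the intersection
#'   of the disc with a thin strip); by default an oversized clump is a
#'   configuration error.
#' @return character vector (length nx*ny, column-major) of cell types.
#' @export
circular_clump <- function(grid_shape, dx = 0.02, R = 2.4, center = NULL,
                           ead_type = "type-I", allow_clip = FALSE) {
  nx <- grid_shape[1]; ny <- grid_shape[2]
  if (R < 0) stop("R must be >= 0")
  if (is.null(center)) center <- c(nx, ny) / 2 * dx
  if (!allow_clip && R > 0 &&
      (center[1] - R < 0 || center[1] + R > nx * dx ||
       center[2] - R < 0 || center[2] + R > ny * dx))
    stop("clump of radius ", R, " cm does not fit inside the domain")
  inside <- clump_mask(grid_shape, dx, R, center)
  ifelse(inside, ead_type, "normal")
}

# logical disc membership by site-centre distance
clump_mask <- function(grid_shape, dx, R, center = NULL) {
  nx <- grid_shape[1]; ny <- grid_shape[2]
  if (is.null(center)) center <- c(nx, ny) / 2 * dx
  xs <- (seq_len(nx) - 0.5) * dx
  ys <- (seq_len(ny) - 0.5) * dx
  as.vector(outer(xs, ys, function(a, b)
    (a - center[1])^2 + (b - center[2])^2) <= R^2)
}

# round-half-up percentage -> count
pct_count <- function(p, n) floor(p / 100 * n + 0.5)

#' Diffuse fibrosis obstacle mask
#'
#' Places exactly \code{round(P_f/100 * region size)} inexcitable point
#' obstacles uniformly at random (without replacement) inside the region --
#' the diffuse-fibrosis representation of interspersed collagen deposits.
#'
#' @param region_map logical vector: sites eligible for obstacles (e.g. the
#'   clump mask).
#' @param p_f fibrosis percentage, 0 <= P_f < 100.
#' @param seed RNG seed (required: generators are pure functions of
#'   (spec, seed)).
#' @return logical obstacle mask of the same length.
#' @export
fibrosis_mask <- function(region_map, p_f, seed) {
  if (p_f < 0 || p_f >= 100) stop("P_f must be in [0, 100)")
  region_map <- as.logical(region_map)
  mask <- rep(FALSE, length(region_map))
  n <- pct_count(p_f, sum(region_map))
  if (n > 0) {
    picks <- with_seed(seed, sample(which(region_map), n))
    mask[picks] <- TRUE
  }
  mask
}

#' Fibroblast attachment map
#'
#' \code{mode = "uniform"} attaches a fibroblast to every region site
#' (the myocyte-fibroblast bilayer clump); \code{mode = "random"} attaches
#' exactly \code{round(P_a/100 * region size)} fibroblasts at seeded random
#' sites; \code{mode = "none"} attaches nothing.
#'
#' @param region_map logical vector of region membership.
#' @param mode \code{"none"}, \code{"uniform"} or \code{"random"}.
#' @param p_a attachment percentage (random mode only).
#' @param params a \code{\link{fibroblast_params}} object.
#' @param g_gap gap conductance, nS.
#' @param seed RNG seed (random mode).
#' @return a fibroblast specification list for \code{\link{tissue_grid}}
#'   (elements \code{attach}, \code{params}, \code{g_gap}), or \code{NULL}
#'   for \code{mode = "none"}.
#' @export
fibroblast_attachment <- function(region_map, mode = c("none", "uniform", "random"),
                                  p_a = NULL, params = fibroblast_params(-35),
                                  g_gap = 8, seed = NULL) {
  mode <- match.arg(mode)
  region_map <- as.logical(region_map)
  if (mode == "none") return(NULL)
  attach <- rep(FALSE, length(region_map))
  if (mode == "uniform") {
    if (!is.null(p_a))
      warning("p_a is ignored for mode = 'uniform' (every region site attached)")
    attach[region_map] <- TRUE
  } else {
    if (is.null(p_a) || p_a < 0 || p_a >= 100)
      stop("random mode needs P_a in [0, 100)")
    if (is.null(seed)) stop("random mode needs a seed")
    n <- pct_count(p_a, sum(region_map))
    if (n > 0)
      attach[with_seed(seed, sample(which(region_map), n))] <- TRUE
  }
  list(attach = attach, params = params, g_gap = g_gap)
}

#' One-dimensional cable patterns
#'
#' The four myocyte-fibroblast distribution patterns on a 280-cell cable:
#' an EAD segment of 160 type-I cells at 0-based positions [60, 220)
#' sandwiched between normal myocytes, with (A) no fibroblasts, (B)
#' fibroblasts on every EAD-segment site, (C) 40 fibroblasts on the middle
#' block [120, 160), (D) fibroblasts attached at random EAD-segment sites.
#' Index ranges are half-open so the stated counts (160 EAD cells, 40
#' fibroblasts) hold exactly.
#'
#' @param pattern_id \code{"A"}, \code{"B"}, \code{"C"} or \code{"D"}.
#' @param p_a random-attachment percentage for pattern D (default 40).
#' @param seed seed for pattern D.
#' @param params fibroblast parameters (default E_f = -35 mV).
#' @param g_gap gap conductance, nS.
#' @return list with \code{cell_type} (length 280) and \code{fibroblast}
#'   (attachment spec or NULL).
#' @export
cable_pattern <- function(pattern_id = c("A", "B", "C", "D"), p_a = 40,
                          seed = NULL, params = fibroblast_params(-35),
                          g_gap = 8) {
  pattern_id <- match.arg(pattern_id)
  n <- 280L
  ct <- rep("normal", n)
  seg <- 61:220      # 0-based [60, 220): 160 cells
  ct[seg] <- "type-I"
  segmask <- seq_len(n) %in% seg
  fb <- switch(pattern_id,
    A = NULL,
    B = fibroblast_attachment(segmask, "uniform", params = params,
                              g_gap = g_gap),
    C = {
      mid <- rep(FALSE, n)
      mid[121:160] <- TRUE # 0-based [120, 160): 40 cells
      fibroblast_attachment(mid, "uniform", params = params, g_gap = g_gap)
    },
    D = {
      if (is.null(seed)) stop("pattern D needs a seed")
      fibroblast_attachment(segmask, "random", p_a = p_a, params = params,
                            g_gap = g_gap, seed = seed)
    })
  list(cell_type = ct, fibroblast = fb)
}

#' Reduced-coupling clump diffusion field
#'
#' Diffusion scale \code{d_ratio} inside the clump disc and 1 outside;
#' the diffusion constant outside the clump always keeps its normal value.
#'
#' @param grid_shape \code{c(nx, ny)}.
#' @param dx spacing, cm.
#' @param R clump radius, cm.
#' @param d_ratio clump diffusion ratio D/D0, in (0, 1].
#' @param center optional clump centre, cm.
#' @return numeric per-site diffusion-scale field.
#' @export
reduced_coupling_clump <- function(grid_shape, dx = 0.02, R = 2,
                                   d_ratio = 1, center = NULL) {
  if (d_ratio <= 0 || d_ratio > 1) stop("d_ratio must be in (0, 1]")
  inside <- clump_mask(grid_shape, dx, R, center)
  ifelse(inside, d_ratio, 1)
}

#' Scenario specification and construction
#'
#' Builds a complete \code{\link{tissue_grid}} from a declarative scenario:
#' a circular EAD clump of radius R at the domain centre, optional
#' reduced coupling inside the clump, optional diffuse fibrosis at
#' percentage P_f inside the clump, and optional fibroblast attachment
#' (uniform or random at percentage P_a).  All randomness is governed by
#' \code{seed}; the same spec and seed reproduce the same grid exactly.
#'
#' @param nx,ny,dx,d0 domain geometry (see \code{\link{tissue_grid}}).
#' @param R clump radius, cm.
#' @param ead_type \code{"type-I"} or \code{"type-II"}.
#' @param d_ratio clump D/D0 in (0, 1].
#' @param p_f fibrosis percentage inside the clump.
#' @param attach_mode \code{"none"}, \code{"uniform"} or \code{"random"}.
#' @param p_a attachment percentage (random mode).
#' @param e_f fibroblast resting potential, mV.
#' @param g_gap myocyte-fibroblast gap conductance, nS.
#' @param g_f_model \code{"constant"} or \code{"piecewise"}.
#' @param seed RNG seed; recorded in the result.
#' @param center optional clump centre, cm.
#' @param allow_clip permit the clump disc to be clipped by the domain
#'   (reduced-scale strip proxies).
#' @return a \code{tissue_grid} with attribute \code{"scenario"} recording
#'   the scenario fields (including the seed).
#' @export
build_scenario <- function(nx = 448, ny = 448, dx = 0.02, d0 = 0.0012,
                           R = 2.4, ead_type = "type-I", d_ratio = 1,
                           p_f = 0, attach_mode = "none", p_a = NULL,
                           e_f = -35, g_gap = 8,
                           g_f_model = c("constant", "piecewise"),
                           seed = 1, center = NULL, allow_clip = FALSE) {
  g_f_model <- match.arg(g_f_model)
  shape <- c(nx, ny)
  ct <- circular_clump(shape, dx, R, center, ead_type, allow_clip)
  inclump <- ct != "normal"
  ds <- reduced_coupling_clump(shape, dx, R, d_ratio, center)
  ob <- if (p_f > 0) fibrosis_mask(inclump, p_f, seed) else rep(FALSE, nx * ny)
  fparams <- fibroblast_params(e_f, model = g_f_model)
  fb <- fibroblast_attachment(inclump & !ob, attach_mode, p_a = p_a,
                              params = fparams, g_gap = g_gap,
                              seed = if (is.null(seed)) NULL else seed + 1)
  grid <- tissue_grid(nx, ny, dx, d0, cell_type = ct, dscale = ds,
                      obstacle = ob, fibroblast = fb)
  attr(grid, "scenario") <- list(nx = nx, ny = ny, dx = dx, d0 = d0, R = R,
                                 ead_type = ead_type, d_ratio = d_ratio,
                                 p_f = p_f, attach_mode = attach_mode,
                                 p_a = p_a, e_f = e_f, g_gap = g_gap,
                                 g_f_model = g_f_model, seed = seed)
  grid
}
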