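#' Thermal properties of the phantom and its surroundings
#'
#' Defaults are water-like gel values with a natural-convection surface
#' coefficient; all are illustrative and configurable.
#'
#' @param k Thermal conductivity, W m^-1 K^-1.
#' @param rho Density, kg m^-3.
#' @param c_p Specific heat, J kg^-1 K^-1.
#' @param h_conv Surface convection coefficient, W m^-2 K^-1.
#' @param t_amb Ambient temperature, degrees C.
#' @return An object of class `thermal_props`.
#' @export
thermal_props <- function(k = 0.6, rho = 1000, c_p = 4186, h_conv = 10,
                          t_amb = 25) {
  if (any(c(k, rho, c_p, h_conv) <= 0)) stop("thermal properties must be positive")
  structure(list(k = k, rho = rho, c_p = c_p, h_conv = h_conv, t_amb = t_amb),
            class = "thermal_props")
}

#' Virtual thermocouple probe positions
#'
#' Probes are placed at radial distances from the beam axis, by default 3, 6,
#' 9 and 12 mm at mid-height (mirroring a four-thermocouple phantom rig with
#' 3-mm spacing, the nearest 3 mm from the beam).
#'
#' @param radial Radial distances, mm.
#' @param depth Depths, mm (recycled); `NULL` means mid-height, resolved when
#'   the solver is called.
#' @return An object of class `probe_set`.
#' @export
probe_set <- function(radial = c(3, 6, 9, 12), depth = NULL) {
  if (any(radial < 0)) stop("radial distances must be >= 0")
  structure(list(radial = radial, depth = depth), class = "probe_set")
}

#' Transient temperature field driven by an absorbed-power map
#'
#' Solves axisymmetric transient heat conduction on the tally grid with the
#' Monte Carlo absorbed-power density as the volumetric source
#' (Q = power x a_total) and Robin (convective) boundaries on all faces,
#' using an implicit (backward Euler) finite-volume scheme -- unconditionally
#' stable, so 20-minute horizons run on coarse grids with large steps. The
#' sparse system is factorised once and reused across time steps. Probe
#' temperatures are bilinearly interpolated between cell centres.
#'
#' @param absorption An `absorption_map` from [run_transport()] (a_total in
#'   mm^-3 per incident W).
#' @param power Incident optical power, W.
#' @param geom The [geometry()] the map was tallied on.
#' @param props A [thermal_props()].
#' @param duration Irradiation time, s.
#' @param probes A [probe_set()]; all probes must lie inside the domain.
#' @param dt Time step, s (default `duration/600`).
#' @return An object of class `temperature_trace`: `t` (s), `dT` (matrix,
#'   time x probe, degrees C above ambient), `final_field` (n_r x n_z), and
#'   the inputs. `dT[1, ] == 0`.
#' @export
solve_heat <- function(absorption, power, geom, props = thermal_props(),
                       duration = 1200, probes = probe_set(), dt = NULL) {
  stopifnot(inherits(props, "thermal_props"), inherits(probes, "probe_set"),
            inherits(geom, "geometry"))
  a_total <- if (inherits(absorption, "absorption_map")) absorption$a_total
             else absorption
  if (!is.matrix(a_total) || nrow(a_total) != geom$n_r || ncol(a_total) != geom$n_z)
    stop("absorption grid does not match geometry")
  if (power < 0) stop("power must be >= 0")
  if (is.null(dt)) dt <- duration / 600
  if (dt <= 0 || dt > duration) stop("invalid time step")

  depth <- if (is.null(probes$depth)) rep(geom$height / 2, length(probes$radial))
           else rep(probes$depth, length.out = length(probes$radial))
  if (any(probes$radial > geom$radius) || any(depth < 0) || any(depth > geom$height))
    stop("probe outside domain")

  n_r <- geom$n_r; n_z <- geom$n_z; nv <- n_r * n_z
  dr <- geom$dr * 1e-3; dz <- geom$dz * 1e-3        # m
  r_edges <- seq(0, geom$radius, length.out = n_r + 1) * 1e-3
  vol <- pi * diff(r_edges^2) * dz                   # m^3, per radial ring
  idx <- function(i, j) i + n_r * (j - 1)

  k <- props$k; h <- props$h_conv
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(nv)
  add_pair <- function(a, b, G) {
    ii <<- c(ii, a, b); jj <<- c(jj, b, a); xx <<- c(xx, -G, -G)
    diag_acc[c(a, b)] <<- diag_acc[c(a, b)] + G
  }
  # radial conduction between rings i and i+1 (face at r_edges[i+1])
  for (i in seq_len(n_r - 1)) {
    A <- 2 * pi * r_edges[i + 1] * dz
    G <- k * A / dr
    for (j in seq_len(n_z)) add_pair(idx(i, j), idx(i + 1, j), G)
  }
  # axial conduction between layers j and j+1
  A_ann <- pi * diff(r_edges^2)
  for (j in seq_len(n_z - 1)) {
    G <- k * A_ann / dz
    for (i in seq_len(n_r)) add_pair(idx(i, j), idx(i, j + 1), G[i])
  }
  # Robin boundaries: half-cell conduction in series with surface convection
  robin <- function(A, d_half) 1 / (d_half / (k * A) + 1 / (h * A))
  for (j in seq_len(n_z)) {  # outer radial face
    A <- 2 * pi * r_edges[n_r + 1] * dz
    diag_acc[idx(n_r, j)] <- diag_acc[idx(n_r, j)] + robin(A, dr / 2)
  }
  for (i in seq_len(n_r)) {  # top and bottom faces
    G <- robin(A_ann[i], dz / 2)
    diag_acc[idx(i, 1)] <- diag_acc[idx(i, 1)] + G
    diag_acc[idx(i, n_z)] <- diag_acc[idx(i, n_z)] + G
  }
  ii <- c(ii, seq_len(nv)); jj <- c(jj, seq_len(nv)); xx <- c(xx, diag_acc)
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, nv))

  C_vec <- props$rho * props$c_p * rep(vol, n_z)     # heat capacity, J/K
  # source: a_total [mm^-3 per W] * voxel volume [mm^3] * power [W] = W
  Q <- as.numeric(a_total) * rep(pi * diff((r_edges * 1e3)^2) * geom$dz, n_z) * power

  A_sys <- Matrix::Diagonal(x = C_vec / dt) + L
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A_sys), LDL = FALSE)

  nt <- ceiling(duration / dt)
  times <- seq(0, by = dt, length.out = nt + 1)
  # probe interpolation weights on (r,z) cell centres
  rc <- .r_centers(geom); zc <- .z_centers(geom)
  interp_w <- lapply(seq_along(probes$radial), function(p)
    .bilinear_weights(probes$radial[p], depth[p], rc, zc, n_r, n_z))

  Tv <- numeric(nv)
  dT <- matrix(0, nt + 1, length(probes$radial))
  for (m in seq_len(nt)) {
    rhs <- C_vec / dt * Tv + Q
    Tv <- as.numeric(Matrix::solve(ch, rhs))
    for (p in seq_along(interp_w))
      dT[m + 1, p] <- sum(Tv[interp_w[[p]]$idx] * interp_w[[p]]$w)
  }
  colnames(dT) <- sprintf("r%gmm", probes$radial)
  structure(list(t = times, dT = dT,
                 final_field = matrix(Tv, n_r, n_z),
                 probes = probes, probe_depth = depth, geom = geom,
                 props = props, power = power, dt = dt),
            class = "temperature_trace")
}

.bilinear_weights <- function(r, z, rc, zc, n_r, n_z) {
  clamp <- function(v, lo, hi) min(max(v, lo), hi)
  fi <- clamp((r - rc[1]) / (rc[2] - rc[1]) + 1, 1, n_r)
  fj <- clamp((z - zc[1]) / (zc[2] - zc[1]) + 1, 1, n_z)
  i0 <- floor(fi); j0 <- floor(fj)
  i1 <- min(i0 + 1, n_r); j1 <- min(j0 + 1, n_z)
  ti <- fi - i0; tj <- fj - j0
  idx <- function(i, j) i + n_r * (j - 1)
  list(idx = c(idx(i0, j0), idx(i1, j0), idx(i0, j1), idx(i1, j1)),
       w = c((1 - ti) * (1 - tj), ti * (1 - tj), (1 - ti) * tj, ti * tj))
}

#' @export
print.temperature_trace <- function(x, ...) {
  nt <- length(x$t)
  cat(sprintf("<temperature_trace> %d steps to %g s, %d probes\n",
              nt - 1, max(x$t), ncol(x$dT)))
  cat("  final dT (degC):",
      paste(sprintf("%s=%.3f", colnames(x$dT), x$dT[nt, ]), collapse = ", "), "\n")
  invisible(x)
}

#' Extract probe temperature rise at a given time
#'
#' @param trace A [solve_heat()] result.
#' @param time Time, s (linearly interpolated between steps).
#' @param probe Probe index or column name (default all probes).
#' @return Named numeric vector of dT (degrees C).
#' @export
probe_dT <- function(trace, time, probe = NULL) {
  stopifnot(inherits(trace, "temperature_trace"))
  if (time < 0 || time > max(trace$t)) stop("time outside simulated horizon")
  out <- apply(trace$dT, 2, function(col) stats::approx(trace$t, col, xout = time)$y)
  if (!is.null(probe)) out <- out[probe]
  out
}

#' Lumped (well-stirred) heat-balance model
#'
#' Single-node energy balance: absorbed power against surface convection,
#' `C dT/dt = p_abs - h A dT`, giving a steady rise `dT_ss = p_abs / (h A)`,
#' a time constant `tau = m c_p / (h A)` and an exponential approach
#' `dT(t) = dT_ss (1 - exp(-t/tau))`. The spatial solver converges to this
#' trace in the high-conductivity limit.
#'
#' @param p_abs Absorbed power, W (>= 0).
#' @param surface_area Convective surface area, m^2.
#' @param mass Phantom mass, kg.
#' @param props A [thermal_props()] (uses `h_conv` and `c_p`).
#' @param times Optional times (s) at which to evaluate the trace.
#' @return A list with `dT_ss` (degC), `tau` (s), and `trace` (data.frame
#'   t, dT; NULL when `times` is NULL).
#' @export
lumped_heat_balance <- function(p_abs, surface_area, mass,
                                props = thermal_props(), times = NULL) {
  if (p_abs < 0 || surface_area <= 0 || mass <= 0)
    stop("inputs must be positive (p_abs >= 0)")
  hA <- props$h_conv * surface_area
  dT_ss <- p_abs / hA
  tau <- mass * props$c_p / hA
  trace <- NULL
  if (!is.null(times))
    trace <- data.frame(t = times, dT = dT_ss * (1 - exp(-times / tau)))
  list(dT_ss = dT_ss, tau = tau, trace = trace)
}
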