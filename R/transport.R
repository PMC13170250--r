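#' Cylindrical phantom geometry and tally grid
#'
#' The phantom is a cylinder illuminated on its top face; z is depth from the
#' illuminated face (increasing downward), voxels are half-open in both r and
#' z. Tallies are axisymmetric on an (n_r x n_z) cylindrical-shell grid.
#'
#' @param radius Cylinder radius, mm.
#' @param height Cylinder height, mm.
#' @param n_r,n_z Number of radial / depth voxels (each >= 2).
#' @return An object of class `geometry`.
#' @export
geometry <- function(radius = 15, height = 20, n_r = 60, n_z = 40) {
  if (radius <= 0 || height <= 0) stop("radius and height must be positive")
  if (n_r < 2 || n_z < 2) stop("grid dimensions must be >= 2")
  structure(list(radius = radius, height = height,
                 n_r = as.integer(n_r), n_z = as.integer(n_z),
                 dr = radius / n_r, dz = height / n_z),
            class = "geometry")
}

# Voxel volumes (mm^3) as an n_r x n_z matrix.
.voxel_volumes <- function(geom) {
  r_edges <- seq(0, geom$radius, length.out = geom$n_r + 1)
  v_r <- pi * diff(r_edges^2) * geom$dz
  matrix(v_r, nrow = geom$n_r, ncol = geom$n_z)
}

# Voxel centre coordinates.
.r_centers <- function(geom) (seq_len(geom$n_r) - 0.5) * geom$dr
.z_centers <- function(geom) (seq_len(geom$n_z) - 0.5) * geom$dz

#' Incident beam specification
#'
#' Normally incident, centred on the cylinder axis at z = 0.
#'
#' @param power Optical power, W (>= 0).
#' @param radius Beam radius, mm. For `"gaussian"` this is the 1/e^2
#'   intensity radius.
#' @param profile `"flat"` (top hat) or `"gaussian"`.
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(power = 0.5, radius = 5, profile = c("flat", "gaussian")) {
  profile <- match.arg(profile)
  if (power < 0) stop("power must be >= 0")
  if (radius <= 0) stop("beam radius must be positive")
  structure(list(power = power, radius = radius, profile = profile),
            class = "beam_spec")
}

#' Monte Carlo transport settings
#'
#' @param n_photons Number of photon packets (>= 1000).
#' @param seed Integer RNG seed; identical (configuration, seed) pairs give
#'   bit-identical tallies. `NULL` leaves the RNG state untouched.
#' @param w_min Russian-roulette threshold weight (0 < w_min < 1).
#' @param p_survive Roulette survival probability (0 < p < 1).
#' @param n_outside Ambient refractive index.
#' @param n_batches Number of statistically independent batches used for
#'   per-voxel standard errors.
#' @return An object of class `transport_settings`.
#' @export
transport_settings <- function(n_photons = 1e5, seed = NULL, w_min = 1e-4,
                               p_survive = 0.1, n_outside = 1.0,
                               n_batches = 25) {
  if (n_photons < 1e3) stop("n_photons must be >= 1000")
  if (w_min <= 0 || w_min >= 1) stop("w_min must lie in (0, 1)")
  if (p_survive <= 0 || p_survive >= 1) stop("p_survive must lie in (0, 1)")
  if (n_outside < 1) stop("n_outside must be >= 1")
  structure(list(n_photons = as.integer(n_photons), seed = seed,
                 w_min = w_min, p_survive = p_survive,
                 n_outside = n_outside, n_batches = as.integer(n_batches)),
            class = "transport_settings")
}

#' Sample the Henyey-Greenstein phase function
#'
#' Returns the cosine of the single-scattering deflection angle for anisotropy
#' `g`, using the closed-form inverse CDF. `g = 0` is handled as isotropic
#' (cos theta uniform on \[-1, 1\]). The first moment of the returned cosines
#' equals `g`.
#'
#' @param g Anisotropy, |g| < 1.
#' @param u Uniform(0,1) deviates (vectorised).
#' @return Deflection cosines in \[-1, 1\].
#' @export
sample_phase_function <- function(g, u) {
  if (abs(g) >= 1) stop("|g| must be < 1")
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  .hg_sample_cpp(g, as.numeric(u))
}

#' Unpolarized Fresnel reflectance at a planar index step
#'
#' Average of the s- and p-polarized reflectances; returns 1 beyond the
#' critical angle (total internal reflection) and 0 for matched media.
#'
#' @param n1 Index on the incident side (>= 1).
#' @param n2 Index on the far side (>= 1).
#' @param cos_incident Cosine of the incidence angle, in (0, 1\].
#' @return Reflectance in \[0, 1\].
#' @examples
#' fresnel_reflectance(1.0, 1.34, 1.0)  # ~0.0211
#' @export
fresnel_reflectance <- function(n1, n2, cos_incident) {
  if (any(n1 < 1) || any(n2 < 1)) stop("refractive indices must be >= 1")
  if (any(cos_incident <= 0) || any(cos_incident > 1))
    stop("cos_incident must lie in (0, 1]")
  .fresnel_cpp(as.numeric(n1), as.numeric(n2), as.numeric(cos_incident))
}

#' Voxelized optical-property field
#'
#' Per-voxel optical coefficients on the tally grid of a [geometry()], for
#' heterogeneous media. Scalars are recycled to the full grid.
#'
#' @param geom A [geometry()].
#' @param mu_a,mu_s Absorption / scattering coefficient, mm^-1 (scalar or
#'   n_r x n_z matrix).
#' @param g Anisotropy (scalar or matrix).
#' @param n Refractive index of the medium (scalar; a single index is used at
#'   the boundaries).
#' @return An object of class `voxel_optics`.
#' @export
voxel_optics <- function(geom, mu_a, mu_s, g = 0, n = 1.34) {
  stopifnot(inherits(geom, "geometry"))
  expand <- function(x, what) {
    if (length(x) == 1L) x <- matrix(x, geom$n_r, geom$n_z)
    if (!is.matrix(x) || nrow(x) != geom$n_r || ncol(x) != geom$n_z)
      stop(what, " must be a scalar or an n_r x n_z matrix")
    x
  }
  mu_a <- expand(mu_a, "mu_a"); mu_s <- expand(mu_s, "mu_s")
  g <- expand(g, "g")
  if (any(mu_a < 0) || any(mu_s < 0)) stop("coefficients must be non-negative")
  if (any(g < -1) || any(g > 1)) stop("g must lie in [-1, 1]")
  if (n < 1) stop("refractive index must be >= 1")
  structure(list(geom = geom, mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "voxel_optics")
}

#' Run Monte Carlo photon transport
#'
#' Transports photon packets through the phantom and tallies the fluence rate
#' per unit incident power (track-length estimator, mm^-2) and the deposited
#' power density per incident watt (mm^-3) on the cylindrical (r, z) grid.
#' Variance control uses implicit capture (w <- w * mu_s/mu_t at each
#' collision) with Russian roulette below `w_min`. Boundaries on all faces
#' receive the same unpolarized Fresnel treatment; specular reflection of the
#' collimated beam at entry is removed before injection and tallied as
#' reflected.
#'
#' @param medium A [compose_medium()] result (homogeneous) or a
#'   [voxel_optics()] field.
#' @param geom A [geometry()]. Ignored (taken from the field) when `medium`
#'   is a `voxel_optics`.
#' @param beam A [beam_spec()].
#' @param settings A [transport_settings()].
#' @return A list with components `fluence` (class `fluence_map`: `phi`,
#'   `stderr`, `budget`, `mean_pathlength`, `mean_scatter_events`) and
#'   `absorption` (class `absorption_map`: `a_total`, `stderr`,
#'   `a_by_species`, `absorbed_fraction`). Budget fractions (reflected,
#'   transmitted, side-escaped, absorbed) sum to 1 within Monte Carlo
#'   roulette noise.
#' @examples
#' \donttest{
#' med <- compose_medium(background_optics())
#' run <- run_transport(med, geometry(n_r = 20, n_z = 20),
#'                      beam_spec(), transport_settings(1e4, seed = 1))
#' run$fluence$budget
#' }
#' @export
run_transport <- function(medium, geom = geometry(), beam = beam_spec(),
                          settings = transport_settings()) {
  stopifnot(inherits(beam, "beam_spec"), inherits(settings, "transport_settings"))
  if (inherits(medium, "voxel_optics")) {
    geom <- medium$geom
    mu_a <- medium$mu_a; mu_s <- medium$mu_s; g <- medium$g; n_med <- medium$n
    by_species <- NULL
    mu_a_bkg <- NULL
  } else if (inherits(medium, "composite_optics")) {
    stopifnot(inherits(geom, "geometry"))
    mu_a <- matrix(medium$mu_a_total, geom$n_r, geom$n_z)
    mu_s <- matrix(medium$mu_s_total, geom$n_r, geom$n_z)
    g <- matrix(medium$g_eff, geom$n_r, geom$n_z)
    n_med <- medium$n
    by_species <- medium$mu_a_by_species
    mu_a_bkg <- medium$mu_a_bkg
  } else {
    stop("medium must be a composite_optics or voxel_optics object")
  }
  if (beam$radius <= 0) stop("zero-size beam rejected")

  if (!is.null(settings$seed)) set.seed(settings$seed)
  ds_max <- 0.5 * min(geom$dr, geom$dz)
  raw <- .mc_transport_cpp(mu_a, mu_s, g, n_med, settings$n_outside,
                           geom$radius, geom$height,
                           settings$n_photons, beam$radius,
                           if (beam$profile == "flat") 0L else 1L,
                           settings$w_min, settings$p_survive,
                           ds_max, settings$n_batches)

  budget <- raw$budget[c("reflected", "transmitted", "side_escaped", "absorbed")]
  fluence <- structure(list(
    phi = raw$phi, stderr = raw$phi_se, geom = geom, beam = beam,
    budget = budget, roulette_residual = raw$budget[["roulette_residual"]],
    mean_pathlength = raw$mean_pathlength,
    mean_scatter_events = raw$mean_scatter_events,
    n_photons = raw$n_photons, seed = settings$seed),
    class = "fluence_map")

  a_by_species <- NULL
  if (!is.null(by_species) && length(by_species)) {
    mu_tot <- mu_a[1, 1]
    a_by_species <- lapply(by_species, function(mi)
      if (mu_tot > 0) raw$a_total * (mi / mu_tot) else raw$a_total * 0)
  }
  absorption <- structure(list(
    a_total = raw$a_total, stderr = raw$a_se, geom = geom, beam = beam,
    a_by_species = a_by_species,
    absorbed_fraction = budget[["absorbed"]],
    n_photons = raw$n_photons, seed = settings$seed),
    class = "absorption_map")

  list(fluence = fluence, absorption = absorption)
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("<fluence_map> %d x %d voxels, %d packets\n",
              nrow(x$phi), ncol(x$phi), x$n_photons))
  cat(sprintf("  budget: R %.4f | T %.4f | side %.4f | A %.4f (sum %.6f)\n",
              x$budget[["reflected"]], x$budget[["transmitted"]],
              x$budget[["side_escaped"]], x$budget[["absorbed"]],
              sum(x$budget)))
  cat(sprintf("  mean pathlength %.3f mm, mean scatter events %.2f\n",
              x$mean_pathlength, x$mean_scatter_events))
  invisible(x)
}

#' @export
print.absorption_map <- function(x, ...) {
  cat(sprintf("<absorption_map> %d x %d voxels, absorbed fraction %.4f\n",
              nrow(x$a_total), ncol(x$a_total), x$absorbed_fraction))
  invisible(x)
}
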