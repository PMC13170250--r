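# Shared builders for small, fast test fixtures.

small_geom <- function(radius = 10, height = 10, n_r = 20, n_z = 20) {
  geometry(radius, height, n_r, n_z)
}

# Homogeneous medium as a voxel field on a geometry.
uniform_medium <- function(geom, mu_a, mu_s, g = 0, n = 1.34) {
  voxel_optics(geom, mu_a, mu_s, g, n)
}

quick_settings <- function(n = 2e4, seed = 1, ...) {
  transport_settings(n_photons = n, seed = seed, ...)
}

# Default illustrative species used across tests.
test_absorber <- function() {
  particle_species("absorber", sigma_abs = 50000, sigma_sca = 0, g_p = 0,
                   diameter = 60, mass_density = 19.3)
}

test_scatterer <- function(g_p = 0) {
  particle_species("scatterer", sigma_abs = 0, sigma_sca = 30000, g_p = g_p,
                   diameter = 100, mass_density = 3.51)
}

# The standard phantom comparison media (mm^-1), mirroring the preset gels:
# blank background, scatterer adds mu_s 0.1 isotropic, absorber adds mu_a 0.05.
phantom_media <- function(geom) {
  list(
    blank = voxel_optics(geom, 0.01, 0.1, 0.9, 1.34),
    scatterer = voxel_optics(geom, 0.01, 0.2, 0.1 * 0.9 / 0.2, 1.34),
    absorber = voxel_optics(geom, 0.06, 0.1, 0.9, 1.34),
    combined = voxel_optics(geom, 0.06, 0.2, 0.1 * 0.9 / 0.2, 1.34))
}
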