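#' Particle species: single-particle optical and physical properties
#'
#' Defines a nanoparticle species by its optical cross-sections at the working
#' wavelength (default context: 808 nm) and its physical properties. The two
#' archetypes in scattering-absorption coupled photothermal systems are a
#' plasmonic absorber (large `sigma_abs`, negligible `sigma_sca`, e.g. gold
#' nanostars) and a dielectric scatterer (negligible `sigma_abs`, effective
#' `sigma_sca`, e.g. nanodiamond).
#'
#' @param name Species label.
#' @param sigma_abs Absorption cross-section, nm^2 (>= 0).
#' @param sigma_sca Scattering cross-section, nm^2 (>= 0).
#' @param g_p Single-particle scattering anisotropy in \[-1, 1\]. Small
#'   (Rayleigh-regime) scatterers default to 0 (isotropic).
#' @param diameter Particle diameter, nm (> 0); used for volume-fraction
#'   conversions assuming spherical particles.
#' @param mass_density Bulk material density, g cm^-3 (> 0); used for mass
#'   concentration conversions.
#' @return An object of class `particle_species`.
#' @examples
#' nd <- particle_species("ND", sigma_abs = 0, sigma_sca = 49.1,
#'                        diameter = 10, mass_density = 3.51)
#' @export
particle_species <- function(name, sigma_abs, sigma_sca, g_p = 0,
                             diameter, mass_density) {
  stopifnot(is.character(name), length(name) == 1L)
  if (sigma_abs < 0 || sigma_sca < 0)
    stop("cross-sections must be non-negative")
  if (g_p < -1 || g_p > 1) stop("g_p must lie in [-1, 1]")
  if (diameter <= 0) stop("diameter must be positive")
  if (mass_density <= 0) stop("mass_density must be positive")
  structure(list(name = name, sigma_abs = sigma_abs, sigma_sca = sigma_sca,
                 g_p = g_p, diameter = diameter, mass_density = mass_density),
            class = "particle_species")
}

#' @export
print.particle_species <- function(x, ...) {
  cat(sprintf("<particle_species> %s: sigma_abs %.4g nm^2, sigma_sca %.4g nm^2, g %.3g, d %.4g nm, %.3g g/cm^3\n",
              x$name, x$sigma_abs, x$sigma_sca, x$g_p, x$diameter, x$mass_density))
  invisible(x)
}

# Avogadro constant, mol^-1
.N_AVOGADRO <- 6.02214076e23

# Sphere volume of a particle, in mm^3 (diameter in nm; 1 nm^3 = 1e-18 mm^3).
.particle_volume_mm3 <- function(species) {
  (pi / 6) * species$diameter^3 * 1e-18
}

# Single-particle mass in grams (volume in cm^3 = nm^3 * 1e-21).
.particle_mass_g <- function(species) {
  (pi / 6) * species$diameter^3 * 1e-21 * species$mass_density
}

#' Particle loading in one concentration representation
#'
#' A loading states the amount of one species in exactly one of four
#' representations: number density (mm^-3), molar concentration (pM), volume
#' fraction (v%), or mass concentration (ug/ml). On construction the amount is
#' canonicalised to a number density via [convert_loading()].
#'
#' @param species A [particle_species()].
#' @param number_density Particles per mm^3.
#' @param picomolar Molar concentration, pM.
#' @param volume_percent Volume fraction in percent (v%).
#' @param ug_per_ml Mass concentration, ug/ml.
#' @return An object of class `loading` with field `canonical_density` (mm^-3).
#' @export
loading <- function(species, number_density = NULL, picomolar = NULL,
                    volume_percent = NULL, ug_per_ml = NULL) {
  stopifnot(inherits(species, "particle_species"))
  given <- list(number_density = number_density, picomolar = picomolar,
                volume_percent = volume_percent, ug_per_ml = ug_per_ml)
  set <- !vapply(given, is.null, logical(1))
  if (sum(set) != 1L)
    stop("exactly one representation of the loading must be given")
  unit <- names(given)[set]
  amount <- given[[unit]]
  if (!is.numeric(amount) || length(amount) != 1L || amount < 0)
    stop("loading amount must be a single non-negative number")
  l <- structure(list(species = species, unit = unit, amount = amount,
                      canonical_density = NA_real_),
                 class = "loading")
  l$canonical_density <- convert_loading(l, species)
  l
}

#' @export
print.loading <- function(x, ...) {
  cat(sprintf("<loading> %s: %.4g %s (= %.4g mm^-3)\n",
              x$species$name, x$amount, x$unit, x$canonical_density))
  invisible(x)
}

#' Convert a loading to canonical number density (mm^-3)
#'
#' Conversions: pM via the Avogadro constant; v% via the spherical particle
#' volume; ug/ml via the single-particle mass.
#'
#' @param l A [loading()] (or a bare list with `unit` and `amount`).
#' @param species The [particle_species()] the loading refers to.
#' @return Number density in mm^-3.
#' @examples
#' nd <- particle_species("ND", 0, 49.1, 0, diameter = 10, mass_density = 3.51)
#' convert_loading(loading(nd, volume_percent = 3.2e-4), nd)
#' @export
convert_loading <- function(l, species) {
  stopifnot(inherits(species, "particle_species"))
  amount <- l$amount
  if (amount < 0) stop("loading amount must be non-negative")
  if (amount == 0) return(0)
  switch(l$unit,
    number_density = amount,
    # 1 pM = 1e-12 mol/L; 1 L = 1e6 mm^3
    picomolar = amount * 1e-12 * .N_AVOGADRO / 1e6,
    volume_percent = {
      if (species$diameter <= 0) stop("volume-fraction conversion needs a positive diameter")
      (amount / 100) / .particle_volume_mm3(species)
    },
    ug_per_ml = {
      # 1 ug/ml = 1e-6 g per cm^3 = 1e-9 g per mm^3
      amount * 1e-9 / .particle_mass_g(species)
    },
    stop("unknown loading unit: ", l$unit))
}

#' Express a loading in another representation
#'
#' Inverse of [convert_loading()]: converts the canonical number density back
#' to any of the four representations. Round trips agree to well within 0.5%.
#'
#' @param l A [loading()].
#' @param unit One of `"number_density"`, `"picomolar"`, `"volume_percent"`,
#'   `"ug_per_ml"`.
#' @return The loading amount in the requested unit.
#' @export
loading_as <- function(l, unit = c("number_density", "picomolar",
                                   "volume_percent", "ug_per_ml")) {
  unit <- match.arg(unit)
  rho <- l$canonical_density
  sp <- l$species
  switch(unit,
    number_density = rho,
    picomolar = rho * 1e6 / .N_AVOGADRO / 1e-12,
    volume_percent = rho * .particle_volume_mm3(sp) * 100,
    ug_per_ml = rho * .particle_mass_g(sp) / 1e-9)
}

#' Background optical properties of the host medium
#'
#' Bulk absorption and scattering of the unloaded matrix (e.g. an agarose
#' phantom), its scattering anisotropy and refractive index. Defaults are
#' illustrative agarose-like values at 808 nm.
#'
#' @param mu_a Background absorption coefficient, mm^-1.
#' @param mu_s Background scattering coefficient, mm^-1.
#' @param g Background anisotropy in \[-1, 1\].
#' @param n Refractive index (>= 1).
#' @return An object of class `background_optics`.
#' @export
background_optics <- function(mu_a = 0.01, mu_s = 0.1, g = 0.9, n = 1.34) {
  if (mu_a < 0 || mu_s < 0) stop("optical coefficients must be non-negative")
  if (g < -1 || g > 1) stop("g must lie in [-1, 1]")
  if (n < 1) stop("refractive index must be >= 1")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "background_optics")
}

#' Near-field coupling multiplier on the absorber cross-section
#'
#' A scalar surrogate for the near-field gain in absorbed power when a
#' scatterer sits within tens of nanometres of a plasmonic absorber: when the
#' designated scatterer species is co-loaded, the designated absorber's
#' `sigma_abs` is multiplied by `kappa`. With no scatterer loading the
#' multiplier is inactive (effective kappa 1).
#'
#' @param kappa Multiplicative gain, >= 1. Default 1 (off).
#' @param absorber Name of the absorber species the gain applies to.
#' @param scatterer Name of the scatterer species whose presence activates it.
#' @return An object of class `coupling_model`.
#' @export
coupling_model <- function(kappa = 1, absorber = NULL, scatterer = NULL) {
  if (kappa < 1) stop("kappa must be >= 1")
  structure(list(kappa = kappa, absorber = absorber, scatterer = scatterer),
            class = "coupling_model")
}

#' Compose effective bulk optics of a particle-loaded medium
#'
#' Assumes independent-scattering additivity of cross-sections (valid for the
#' dilute loadings used here, <= 1e-2 volume fraction):
#' `mu_a = mu_a_bkg + sum(rho_i * sigma_abs_i * kappa_i)` and
#' `mu_s = mu_s_bkg + sum(rho_i * sigma_sca_i)` with cross-sections converted
#' nm^2 -> mm^2 (factor 1e-12). The effective anisotropy is the
#' scattering-weighted mean of the component anisotropies; it is 0 when the
#' total scattering vanishes.
#'
#' @param background A [background_optics()].
#' @param loadings List of [loading()] objects (may be empty).
#' @param coupling Optional [coupling_model()].
#' @return An object of class `composite_optics` with fields `mu_a_total`,
#'   `mu_s_total`, `g_eff`, `n` and `mu_a_by_species`.
#' @examples
#' bg <- background_optics()
#' nd <- particle_species("ND", 0, 49.1, 0, 10, 3.51)
#' compose_medium(bg, list(loading(nd, volume_percent = 3.2e-3)))
#' @export
compose_medium <- function(background, loadings = list(), coupling = NULL) {
  stopifnot(inherits(background, "background_optics"))
  if (inherits(loadings, "loading")) loadings <- list(loadings)
  for (l in loadings) {
    stopifnot(inherits(l, "loading"))
    if (l$species$g_p < -1 || l$species$g_p > 1)
      stop("species anisotropy outside [-1, 1]")
  }
  scatterer_present <- function(name) {
    any(vapply(loadings, function(l)
      identical(l$species$name, name) && l$canonical_density > 0 &&
        l$species$sigma_sca > 0, logical(1)))
  }
  mu_a <- background$mu_a
  mu_s <- background$mu_s
  g_num <- background$mu_s * background$g
  by_species <- list()
  for (l in loadings) {
    sp <- l$species
    rho <- l$canonical_density
    kappa_i <- 1
    if (!is.null(coupling) && identical(coupling$absorber, sp$name) &&
        !is.null(coupling$scatterer) && scatterer_present(coupling$scatterer)) {
      kappa_i <- coupling$kappa
    }
    mu_a_i <- rho * sp$sigma_abs * 1e-12 * kappa_i  # nm^2 -> mm^2
    mu_s_i <- rho * sp$sigma_sca * 1e-12
    mu_a <- mu_a + mu_a_i
    mu_s <- mu_s + mu_s_i
    g_num <- g_num + mu_s_i * sp$g_p
    by_species[[sp$name]] <- mu_a_i
  }
  g_eff <- if (mu_s > 0) g_num / mu_s else 0
  structure(list(mu_a_total = mu_a, mu_s_total = mu_s, g_eff = g_eff,
                 n = background$n, mu_a_bkg = background$mu_a,
                 mu_a_by_species = by_species),
            class = "composite_optics")
}

#' @export
print.composite_optics <- function(x, ...) {
  cat(sprintf("<composite_optics> mu_a %.4g mm^-1, mu_s %.4g mm^-1, g %.4g, n %.3g\n",
              x$mu_a_total, x$mu_s_total, x$g_eff, x$n))
  if (length(x$mu_a_by_species))
    for (nm in names(x$mu_a_by_species))
      cat(sprintf("  mu_a[%s] = %.4g mm^-1\n", nm, x$mu_a_by_species[[nm]]))
  invisible(x)
}
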