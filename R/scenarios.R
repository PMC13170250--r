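#' Simulation scenario: medium, geometry, beam, transport and thermal setup
#'
#' Bundles everything one phantom case needs: the background optics, particle
#' loadings, optional near-field coupling, geometry, beam, transport settings
#' and the thermal configuration.
#'
#' @param label Scenario label (unique within a run set).
#' @param background A [background_optics()].
#' @param loadings List of [loading()] objects.
#' @param coupling Optional [coupling_model()].
#' @param geometry A [geometry()].
#' @param beam A [beam_spec()].
#' @param transport A [transport_settings()].
#' @param thermal A [thermal_props()].
#' @param probes A [probe_set()].
#' @param duration Irradiation time for the thermal solve, s.
#' @return An object of class `scenario`.
#' @export
scenario <- function(label, background = background_optics(),
                     loadings = list(), coupling = NULL,
                     geometry = photonheat::geometry(),
                     beam = beam_spec(),
                     transport = transport_settings(),
                     thermal = thermal_props(), probes = probe_set(),
                     duration = 1200) {
  stopifnot(is.character(label), length(label) == 1L,
            inherits(background, "background_optics"),
            inherits(geometry, "geometry"), inherits(beam, "beam_spec"),
            inherits(transport, "transport_settings"),
            inherits(thermal, "thermal_props"), inherits(probes, "probe_set"))
  if (inherits(loadings, "loading")) loadings <- list(loadings)
  for (l in loadings) stopifnot(inherits(l, "loading"))
  if (!is.null(coupling)) stopifnot(inherits(coupling, "coupling_model"))
  if (duration <= 0) stop("duration must be positive")
  structure(list(label = label, background = background, loadings = loadings,
                 coupling = coupling, geometry = geometry, beam = beam,
                 transport = transport, thermal = thermal, probes = probes,
                 duration = duration),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> '%s': %d loading(s), cylinder %g x %g mm, beam %g mm, %d packets\n",
              x$label, length(x$loadings), x$geometry$radius,
              x$geometry$height, x$beam$radius, x$transport$n_photons))
  invisible(x)
}

# Default illustrative species. Cross-sections are effective values chosen so
# the reference loadings (absorber 3.6 pM, scatterer 3.2e-3 v%) contribute
# mu_a ~ 0.05 mm^-1 and mu_s ~ 0.1 mm^-1: in that regime the scatterer
# loading modulates the local fluence while leaving the global absorbed
# fraction nearly unchanged, the behaviour expected of a dilute non-absorbing
# scatterer in a gel. True single-particle values depend on particle batch
# and wavelength.
.default_absorber <- function() {
  particle_species("AuNS", sigma_abs = 23064, sigma_sca = 0, g_p = 0,
                   diameter = 60, mass_density = 19.3)
}

.default_scatterer <- function() {
  particle_species("ND", sigma_abs = 0, sigma_sca = 1.64, g_p = 0,
                   diameter = 10, mass_density = 3.51)
}

#' Preset scenarios for the 2 x 2 phantom design
#'
#' Presets mirror the four compared gel cases -- blank, scatterer-only,
#' absorber-only and combined -- with the reference particle concentrations
#' (absorber 3.6 pM; scatterer volume fraction selectable among 3.2e-4,
#' 3.2e-3 and 9.6e-3 v%). Background optics, cross-sections, beam radius and
#' thermal properties are illustrative defaults.
#'
#' @param name One of `"blank_gel"`, `"scatterer_gel"`, `"absorber_gel"`,
#'   `"combined"`.
#' @param nd_volume_percent Scatterer volume fraction, v% (default 3.2e-3).
#' @param auns_picomolar Absorber concentration, pM (default 3.6).
#' @param kappa Near-field coupling multiplier (default 1, off).
#' @param n_photons,seed Transport settings overrides.
#' @return A [scenario()].
#' @export
scenario_preset <- function(name = c("blank_gel", "scatterer_gel",
                                     "absorber_gel", "combined"),
                            nd_volume_percent = 3.2e-3, auns_picomolar = 3.6,
                            kappa = 1, n_photons = 1e5, seed = NULL) {
  name <- match.arg(name)
  absorber <- .default_absorber()
  scatterer <- .default_scatterer()
  loadings <- switch(name,
    blank_gel = list(),
    scatterer_gel = list(loading(scatterer, volume_percent = nd_volume_percent)),
    absorber_gel = list(loading(absorber, picomolar = auns_picomolar)),
    combined = list(loading(absorber, picomolar = auns_picomolar),
                    loading(scatterer, volume_percent = nd_volume_percent)))
  scenario(label = name,
           background = background_optics(),
           loadings = loadings,
           coupling = coupling_model(kappa, absorber = "AuNS", scatterer = "ND"),
           geometry = geometry(),
           beam = beam_spec(power = 0.5, radius = 5),
           transport = transport_settings(n_photons = n_photons, seed = seed))
}

#' Run the transport stage of a scenario
#'
#' @param sc A [scenario()].
#' @param seed Optional seed override.
#' @return The [run_transport()] result with the scenario attached.
#' @export
run_scenario <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "scenario"))
  settings <- sc$transport
  if (!is.null(seed)) settings$seed <- seed
  med <- compose_medium(sc$background, sc$loadings, sc$coupling)
  out <- run_transport(med, sc$geometry, sc$beam, settings)
  out$scenario <- sc
  out
}

#' Run a case/reference comparison and derive enhancement maps
#'
#' Runs Monte Carlo transport for a case and a reference scenario sharing the
#' same grid, and derives the photon-density enhancement map, the absorption
#' enhancement map, laterally averaged depth profiles and summary statistics.
#' By default the two runs use independent seeds (`seed` and `seed + 1`) so
#' the ratio is not biased by correlated tallies; `paired_seed = TRUE` reuses
#' the same seed for both (identity checks).
#'
#' When `out_dir` is given, maps and profiles are written as long-format CSV,
#' summaries and a run manifest as JSON.
#'
#' @param case,ref [scenario()] objects with identical geometry.
#' @param seed Base seed for the pair (default: the case scenario's seed).
#' @param floor_sigma Noise-floor multiplier for masking (default 10).
#' @param paired_seed Reuse the same seed for both runs (default FALSE).
#' @param out_dir Optional output directory.
#' @return A list with `case`, `ref` (transport results), `enhancement`,
#'   `absorption_enhancement`, `profiles` (case/ref depth profiles and their
#'   ratio), `summary`, and `manifest`.
#' @export
run_compare <- function(case, ref, seed = NULL, floor_sigma = 10,
                        paired_seed = FALSE, out_dir = NULL) {
  stopifnot(inherits(case, "scenario"), inherits(ref, "scenario"))
  if (!isTRUE(all.equal(unclass(case$geometry), unclass(ref$geometry))))
    stop("case and reference scenarios must share geometry and grid")
  if (is.null(seed)) seed <- case$transport$seed
  if (is.null(seed)) stop("a seed is required for a reproducible comparison")
  seed_case <- seed
  seed_ref <- if (paired_seed) seed else seed + 1L

  rc <- run_scenario(case, seed = seed_case)
  rr <- run_scenario(ref, seed = seed_ref)
  emap <- enhancement_map(rc$fluence, rr$fluence, floor_sigma = floor_sigma)
  amap <- absorption_enhancement_map(rc$absorption, rr$absorption,
                                     floor_sigma = floor_sigma)
  prof <- list(case = depth_profile(rc$fluence),
               ref = depth_profile(rr$fluence),
               enhancement = enhancement_profile(rc$fluence, rr$fluence,
                                                 floor_sigma = floor_sigma))
  summary <- list(
    case = case$label, ref = ref$label,
    seeds = c(case = seed_case, ref = seed_ref),
    n_photons = rc$fluence$n_photons,
    budget_case = as.list(rc$fluence$budget),
    budget_ref = as.list(rr$fluence$budget),
    max_entry_region = emap$summary$max_entry,
    median_volume = emap$summary$median_volume,
    frac_above_one = emap$summary$frac_above_one,
    median_upper_half = median_upper_region(emap),
    absorption_median_upper_half = median_upper_region(amap))

  manifest <- list(
    scenarios = c(case$label, ref$label),
    seeds = c(seed_case, seed_ref),
    n_photons = rc$fluence$n_photons,
    package_version = as.character(utils::packageVersion("photonheat")),
    outputs = character(0))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      write_map_csv(rc$fluence, file.path(out_dir, "fluence_case.csv")),
      write_map_csv(rr$fluence, file.path(out_dir, "fluence_ref.csv")),
      write_map_csv(emap, file.path(out_dir, "enhancement.csv")),
      write_map_csv(amap, file.path(out_dir, "absorption_enhancement.csv")),
      write_profile_csv(prof$enhancement,
                        file.path(out_dir, "enhancement_profile.csv")),
      write_summary_json(summary, file.path(out_dir, "summary.json")))
    manifest$outputs <- basename(paths)
    write_summary_json(manifest, file.path(out_dir, "manifest.json"))
  }
  list(case = rc, ref = rr, enhancement = emap, absorption_enhancement = amap,
       profiles = prof, summary = summary, manifest = manifest)
}

#' Generate a synthetic dose-response table
#'
#' Draws viability data from a four-parameter logistic curve with optional
#' additive Gaussian noise (clamped to \[0, 1\]). With `noise_sd = 0` the
#' exact logistic values are returned; at `dose == ld50` the noiseless
#' viability is exactly midway between the asymptotes.
#'
#' @param ld50 Dose at the asymptote midpoint, mW cm^-2 (> 0).
#' @param slope Hill slope (> 0).
#' @param upper,lower Upper / lower viability asymptotes (0 <= lower <= upper <= 1).
#' @param doses Dose grid, mW cm^-2.
#' @param replicates Replicates per dose.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Optional RNG seed; fixed seeds reproduce the table exactly.
#' @return A data.frame with columns `dose`, `viability`, `replicate`.
#' @export
gen_dose_response <- function(ld50, slope, upper = 1, lower = 0,
                              doses = c(0, 20.4, 61.2, 102.0, 142.9, 183.7),
                              replicates = 3, noise_sd = 0.05, seed = NULL) {
  if (ld50 <= 0 || slope <= 0) stop("ld50 and slope must be positive")
  if (lower < 0 || upper > 1 || lower > upper)
    stop("asymptotes must satisfy 0 <= lower <= upper <= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(doses < 0)) stop("doses must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  d <- rep(doses, each = replicates)
  v <- lower + (upper - lower) / (1 + (d / ld50)^slope)
  if (noise_sd > 0) v <- pmin(1, pmax(0, v + stats::rnorm(length(v), 0, noise_sd)))
  data.frame(dose = d, viability = v,
             replicate = rep(seq_len(replicates), times = length(doses)))
}

#' Load and validate a scenario configuration file
#'
#' Reads YAML (or JSON) with the documented unit conventions (mm, mm^-1,
#' nm^2, pM, v%, ug/ml, W, degC, s) and returns a validated [scenario()].
#' Unknown keys are rejected in strict mode and warned about otherwise. An
#' optional `dose_response` block (lists `dose`, `viability`) is range-checked
#' and attached as attribute `"dose_response"`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @param strict Reject unknown keys (default TRUE).
#' @return A [scenario()].
#' @export
load_scenario <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else .fix_yaml_keys(yaml::read_yaml(path))

  known <- c("label", "background", "species", "loadings", "coupling",
             "geometry", "beam", "transport", "thermal", "dose_response")
  .check_keys(cfg, known, "top level", strict)
  if (is.null(cfg$label)) stop("config is missing required field 'label'")

  take <- function(block, defaults, where) {
    if (is.null(block)) return(defaults)
    .check_keys(block, names(defaults), where, strict)
    utils::modifyList(defaults, block[!vapply(block, is.null, logical(1))])
  }

  bg <- take(cfg$background, list(mu_a = 0.01, mu_s = 0.1, g = 0.9, n = 1.34),
             "background")
  background <- background_optics(bg$mu_a, bg$mu_s, bg$g, bg$n)

  species <- list()
  for (s in cfg$species) {
    .check_keys(s, c("name", "sigma_abs", "sigma_sca", "g_p", "diameter",
                     "mass_density"), "species", strict)
    if (is.null(s$name)) stop("species entry is missing 'name'")
    species[[s$name]] <- particle_species(
      s$name, sigma_abs = s$sigma_abs %||% 0, sigma_sca = s$sigma_sca %||% 0,
      g_p = s$g_p %||% 0, diameter = s$diameter, mass_density = s$mass_density)
  }

  loadings <- lapply(cfg$loadings, function(l) {
    .check_keys(l, c("species", "number_density", "picomolar",
                     "volume_percent", "ug_per_ml"), "loading", strict)
    sp <- species[[l$species]]
    if (is.null(sp)) {
      sp <- switch(l$species %||% "", AuNS = .default_absorber(),
                   ND = .default_scatterer(), NULL)
      if (is.null(sp)) stop("loading refers to undeclared species: ", l$species)
    }
    do.call(loading, c(list(species = sp), l[setdiff(names(l), "species")]))
  })

  coupling <- NULL
  if (!is.null(cfg$coupling)) {
    .check_keys(cfg$coupling, c("kappa", "absorber", "scatterer"), "coupling",
                strict)
    coupling <- coupling_model(cfg$coupling$kappa %||% 1,
                               cfg$coupling$absorber, cfg$coupling$scatterer)
  }

  ge <- take(cfg$geometry, list(radius = 15, height = 20, n_r = 60, n_z = 40),
             "geometry")
  bm <- take(cfg$beam, list(power = 0.5, radius = 5, profile = "flat"), "beam")
  tr <- take(cfg$transport, list(n_photons = 1e5, seed = NULL, w_min = 1e-4,
                                 p_survive = 0.1, n_outside = 1.0,
                                 n_batches = 25), "transport")
  th <- take(cfg$thermal, list(k = 0.6, rho = 1000, c_p = 4186, h_conv = 10,
                               t_amb = 25, duration = 1200,
                               probes = c(3, 6, 9, 12), probe_depth = NULL),
             "thermal")

  if (!is.null(cfg$dose_response)) {
    dr <- cfg$dose_response
    .check_keys(dr, c("dose", "viability", "replicate"), "dose_response", strict)
    if (any(dr$dose < 0)) stop("dose_response: doses must be >= 0")
    if (any(dr$viability < 0 | dr$viability > 1))
      stop("dose_response: viability must lie in [0, 1]")
  }

  sc <- scenario(
    label = cfg$label, background = background, loadings = loadings,
    coupling = coupling,
    geometry = geometry(ge$radius, ge$height, ge$n_r, ge$n_z),
    beam = beam_spec(bm$power, bm$radius, bm$profile),
    transport = transport_settings(tr$n_photons, tr$seed, tr$w_min,
                                   tr$p_survive, tr$n_outside, tr$n_batches),
    thermal = thermal_props(th$k, th$rho, th$c_p, th$h_conv, th$t_amb),
    probes = probe_set(unlist(th$probes), th$probe_depth),
    duration = th$duration)
  if (!is.null(cfg$dose_response))
    attr(sc, "dose_response") <- as.data.frame(cfg$dose_response)
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML 1.1 implicit typing turns the bare key `n` into the boolean FALSE;
# restore it (the schema's only boolean-like key is the refractive index).
.fix_yaml_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) names(x) <- ifelse(nm == "FALSE", "n", nm)
  lapply(x, .fix_yaml_keys)
}

.check_keys <- function(block, known, where, strict) {
  unknown <- setdiff(names(block), known)
  if (length(unknown)) {
    msg <- sprintf("unknown key(s) in %s: %s", where,
                   paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  invisible(TRUE)
}

#' Write a map as long-format CSV
#'
#' Columns: `r` and `z` (voxel-centre coordinates, mm), `value`, `stderr`
#' (and `valid` for enhancement maps). Values are written in full precision,
#' so fixed-seed runs reproduce files byte for byte.
#'
#' @param map A `fluence_map`, `absorption_map` or `enhancement_map`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_map_csv <- function(map, path) {
  geom <- map$geom
  d <- expand.grid(r = .r_centers(geom), z = .z_centers(geom))
  if (inherits(map, "fluence_map")) {
    d$value <- as.numeric(map$phi); d$stderr <- as.numeric(map$stderr)
  } else if (inherits(map, "absorption_map")) {
    d$value <- as.numeric(map$a_total); d$stderr <- as.numeric(map$stderr)
  } else if (inherits(map, "enhancement_map")) {
    d$value <- as.numeric(map$e); d$stderr <- as.numeric(map$stderr)
    d$valid <- as.logical(map$valid_mask)
  } else stop("unsupported map type")
  utils::write.csv(format(d, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a depth profile or temperature trace as CSV
#'
#' Depth profiles are written as-is; temperature traces in long format
#' (t, probe, dT).
#'
#' @param x A depth-profile data.frame or a `temperature_trace`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(x, path) {
  if (inherits(x, "temperature_trace")) {
    x <- data.frame(t = rep(x$t, times = ncol(x$dT)),
                    probe = rep(colnames(x$dT), each = length(x$t)),
                    dT = as.numeric(x$dT))
  }
  utils::write.csv(format(x, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
write_trace_csv <- write_profile_csv

#' Write a summary or manifest as JSON
#'
#' @param x A named list.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
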