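#' Synergy coefficient of a two-component photothermal system
#'
#' S = dT_combined / (dT_a + dT_b): the temperature rise of the co-loaded
#' system divided by the sum of the single-component rises under identical
#' irradiation. S > 1 declares supra-additive (synergistic) heating. S is
#' invariant under a common rescaling of all three inputs.
#'
#' @param dT_combined Temperature rise of the combined system, degC.
#' @param dT_a,dT_b Single-component temperature rises, degC.
#' @return An object of class `synergy_result` with fields `s`,
#'   `synergistic` (strict `s > 1`), and the inputs.
#' @examples
#' synergy_coefficient(9.04, 5.38, 2.6)  # supra-additive
#' @export
synergy_coefficient <- function(dT_combined, dT_a, dT_b) {
  if (!all(is.finite(c(dT_combined, dT_a, dT_b))))
    stop("temperature rises must be finite")
  if (dT_a + dT_b <= 0)
    stop("synergy coefficient undefined: dT_a + dT_b must be positive")
  s <- dT_combined / (dT_a + dT_b)
  structure(list(s = s, synergistic = s > 1,
                 dT_combined = dT_combined, dT_a = dT_a, dT_b = dT_b),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("<synergy_result> S = %.4f (%s): %.3g / (%.3g + %.3g)\n",
              x$s, if (x$synergistic) "synergistic" else "not synergistic",
              x$dT_combined, x$dT_a, x$dT_b))
  invisible(x)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit `v = lower + (upper - lower) / (1 + (dose/ld50)^slope)`
#' via Levenberg-Marquardt. `ld50` is the dose at which viability is midway
#' between the asymptotes. The lower asymptote is bounded at 0; the upper
#' asymptote is free (controls that never reach 50% kill within the tested
#' range are extrapolated by the fit).
#'
#' @param data A data.frame with columns `dose` (>= 0) and `viability`
#'   (in \[0, 1\]); an optional `replicate` column is ignored by the fit.
#' @param start Optional named list of starting values
#'   (`ld50`, `slope`, `upper`, `lower`).
#' @return An object of class `logistic_fit` with fields `ld50`, `slope`,
#'   `upper`, `lower`, `covariance` (scaled Gauss-Newton estimate, `NULL` when
#'   the Hessian is singular, e.g. for step-like data), `increasing` (warning
#'   flag for viability rising with dose) and the underlying `nls.lm` fit.
#' @export
fit_dose_response <- function(data, start = NULL) {
  stopifnot(is.data.frame(data), all(c("dose", "viability") %in% names(data)))
  if (any(data$dose < 0)) stop("doses must be >= 0")
  if (any(data$viability < 0 | data$viability > 1))
    stop("viability must lie in [0, 1]")
  if (length(unique(data$dose)) < 4)
    stop("need at least 4 distinct doses for a 4PL fit")

  increasing <- stats::cor(data$dose, data$viability) > 0
  if (isTRUE(increasing))
    warning("viability increases with dose; fit returned with warning flag")

  if (is.null(start)) {
    up0 <- max(data$viability)
    lo0 <- max(0, min(data$viability))
    mid <- (up0 + lo0) / 2
    pos <- data$dose[data$dose > 0]
    ld0 <- data$dose[which.min(abs(data$viability - mid))]
    if (ld0 <= 0) ld0 <- stats::median(pos)
    start <- list(ld50 = ld0, slope = 3, upper = up0, lower = lo0)
  }
  fourpl <- function(p, dose)
    p[["lower"]] + (p[["upper"]] - p[["lower"]]) /
      (1 + (dose / p[["ld50"]])^p[["slope"]])
  resid_fn <- function(p) data$viability - fourpl(p, data$dose)
  fit <- minpack.lm::nls.lm(
    par = start[c("ld50", "slope", "upper", "lower")], fn = resid_fn,
    lower = c(ld50 = 1e-9, slope = 1e-3, upper = 0, lower = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4)
    stop("dose-response fit did not converge: ", fit$message)
  cf <- stats::coef(fit)
  # scaled covariance from the Gauss-Newton Hessian, when invertible
  vc <- tryCatch({
    rdf <- length(fit$fvec) - length(cf)
    chol2inv(chol(fit$hessian)) * stats::deviance(fit) / rdf
  }, error = function(e) NULL)
  if (cf[["lower"]] > cf[["upper"]])
    warning("fitted lower asymptote exceeds upper asymptote")
  structure(list(ld50 = cf[["ld50"]], slope = cf[["slope"]],
                 upper = cf[["upper"]], lower = cf[["lower"]],
                 covariance = vc, increasing = isTRUE(increasing), fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> LD50 = %.4g, slope = %.3g, asymptotes [%.3g, %.3g]%s\n",
              x$ld50, x$slope, x$lower, x$upper,
              if (x$increasing) " [warning: viability increases with dose]" else ""))
  invisible(x)
}

#' LD50 fold reduction between two dose-response fits
#'
#' Ratio `LD50_ref / LD50_new`; values above 1 mean the new formulation needs
#' proportionally less power for 50% kill. Antisymmetric under argument swap
#' (the ratio inverts).
#'
#' @param fit_ref,fit_new [fit_dose_response()] results or bare LD50 values
#'   (mW cm^-2), both positive.
#' @return Dimensionless fold reduction.
#' @examples
#' ld50_fold_reduction(143, 34)  # ~4.2
#' @export
ld50_fold_reduction <- function(fit_ref, fit_new) {
  ld <- function(x) if (inherits(x, "logistic_fit")) x$ld50 else as.numeric(x)
  a <- ld(fit_ref); b <- ld(fit_new)
  if (a <= 0) stop("reference LD50 must be positive")
  if (b <= 0) stop("fold reduction undefined for non-positive LD50")
  a / b
}

#' Incident power density over a circular beam
#'
#' `power / (pi (d/2)^2)`, computed with the exact beam area and rounded only
#' at presentation. `rounded_area = TRUE` reproduces tables computed with the
#' beam area itself pre-rounded to one decimal (e.g. 4.9 cm^2 for a 2.5-cm
#' beam, which turns 101.9 into 102.0).
#'
#' @param power_mw Laser power, mW.
#' @param beam_diameter_cm Beam diameter, cm (> 0).
#' @param rounded_area Use the area rounded to one decimal (presentation
#'   mode); default FALSE (exact area).
#' @return Power density, mW cm^-2 (unrounded).
#' @examples
#' round(power_density(100, 2.5), 1)                       # 20.4
#' round(power_density(500, 2.5), 1)                       # 101.9
#' round(power_density(500, 2.5, rounded_area = TRUE), 1)  # 102.0
#' @export
power_density <- function(power_mw, beam_diameter_cm, rounded_area = FALSE) {
  if (beam_diameter_cm <= 0) stop("beam diameter must be positive")
  if (any(power_mw < 0)) stop("power must be >= 0")
  area <- pi * (beam_diameter_cm / 2)^2
  if (rounded_area) area <- round(area, 1)
  power_mw / area
}

#' One-at-a-time sensitivity scan of the transport outputs
#'
#' Perturbs each optical parameter of a scenario by relative amounts,
#' re-composes the medium, reruns Monte Carlo transport with a fixed seed per
#' parameter (common random numbers) and records, per perturbation, the change
#' in absorbed fraction and the normalized L1 distance between fluence maps
#' (`sum |phi - phi0| V / sum phi0 V`). Per parameter, two normalized indices
#' are derived: `index_absorbed`, the log-log regression slope of absorbed
#' fraction on the parameter (d log A / d log p), and `index_spatial`, the
#' mean spatial L1 change per unit relative perturbation.
#'
#' Recognised parameters: `mu_a_bkg`, `mu_s_bkg`, `g_bkg`, `n`,
#' `mu_a_absorber` (scales the sigma_abs of the species contributing the most
#' absorption), `mu_s_scatterer` (scales the sigma_sca of the species
#' contributing the most scattering). Perturbations that leave the physical
#' range (|g| >= 1, n < 1) are skipped with a warning.
#'
#' @param sc A [scenario()] whose loadings include the species to perturb.
#' @param parameters Character vector of parameter names.
#' @param rel Relative perturbations (default +/-10%, +/-20%); a zero entry
#'   contributes zero deltas. An empty grid returns an empty report.
#' @param settings Optional [transport_settings()] override.
#' @return An object of class `sensitivity_report`: data.frame `cells` with
#'   one row per (parameter, perturbation) and data.frame `index` with one
#'   row per parameter.
#' @export
sensitivity_scan <- function(sc,
                             parameters = c("mu_a_bkg", "mu_s_bkg", "g_bkg",
                                            "n", "mu_a_absorber",
                                            "mu_s_scatterer"),
                             rel = c(-0.2, -0.1, 0.1, 0.2),
                             settings = NULL) {
  stopifnot(inherits(sc, "scenario"))
  if (is.null(settings)) settings <- sc$transport
  empty <- data.frame(parameter = character(), rel = numeric(),
                      value = numeric(), absorbed_fraction = numeric(),
                      absorbed_fraction_delta = numeric(),
                      spatial_delta = numeric())
  if (length(rel) == 0 || length(parameters) == 0)
    return(structure(list(cells = empty,
                          index = data.frame(parameter = character(),
                                             index_absorbed = numeric(),
                                             index_spatial = numeric())),
                     class = "sensitivity_report"))

  base_value <- function(p) switch(p,
    mu_a_bkg = sc$background$mu_a, mu_s_bkg = sc$background$mu_s,
    g_bkg = sc$background$g, n = sc$background$n,
    mu_a_absorber = .species_sigma(sc, "sigma_abs")$value,
    mu_s_scatterer = .species_sigma(sc, "sigma_sca")$value,
    stop("unknown sensitivity parameter: ", p))

  perturbed_scenario <- function(p, fac) {
    s2 <- sc
    if (p %in% c("mu_a_bkg", "mu_s_bkg", "g_bkg", "n")) {
      f <- switch(p, mu_a_bkg = "mu_a", mu_s_bkg = "mu_s", g_bkg = "g", n = "n")
      s2$background[[f]] <- sc$background[[f]] * fac
    } else {
      field <- if (p == "mu_a_absorber") "sigma_abs" else "sigma_sca"
      target <- .species_sigma(sc, field)$name
      s2$loadings <- lapply(sc$loadings, function(l) {
        if (identical(l$species$name, target)) {
          l$species[[field]] <- l$species[[field]] * fac
        }
        l
      })
    }
    s2
  }

  run_once <- function(s2) {
    med <- compose_medium(s2$background, s2$loadings, s2$coupling)
    run_transport(med, s2$geometry, s2$beam, settings)
  }

  vols <- .voxel_volumes(sc$geometry)
  cells <- empty
  index <- data.frame(parameter = character(), index_absorbed = numeric(),
                      index_spatial = numeric())
  for (p in parameters) {
    v0 <- base_value(p)
    base_run <- run_once(sc)  # same seed per cell: common random numbers
    a0 <- base_run$fluence$budget[["absorbed"]]
    phi0 <- base_run$fluence$phi
    norm0 <- sum(phi0 * vols)
    rows <- list()
    for (d in rel) {
      if (d == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          parameter = p, rel = 0, value = v0, absorbed_fraction = a0,
          absorbed_fraction_delta = 0, spatial_delta = 0)
        next
      }
      fac <- 1 + d
      vnew <- v0 * fac
      if ((p == "g_bkg" && abs(vnew) >= 1) || (p == "n" && vnew < 1)) {
        warning(sprintf("perturbation %+g%% of %s leaves the physical range; skipped",
                        100 * d, p))
        next
      }
      r <- run_once(perturbed_scenario(p, fac))
      a <- r$fluence$budget[["absorbed"]]
      rows[[length(rows) + 1]] <- data.frame(
        parameter = p, rel = d, value = vnew, absorbed_fraction = a,
        absorbed_fraction_delta = a - a0,
        spatial_delta = sum(abs(r$fluence$phi - phi0) * vols) / norm0)
    }
    if (length(rows)) {
      df <- do.call(rbind, rows)
      cells <- rbind(cells, df)
      nz <- df[df$rel != 0 & df$value > 0 & df$absorbed_fraction > 0, ]
      ia <- if (nrow(nz) >= 2 && a0 > 0 && v0 > 0) {
        stats::coef(stats::lm(log(c(a0, nz$absorbed_fraction)) ~
                                log(c(v0, nz$value))))[[2]]
      } else NA_real_
      is_ <- if (nrow(nz) >= 1) mean(nz$spatial_delta / abs(nz$rel)) else NA_real_
      index <- rbind(index, data.frame(parameter = p, index_absorbed = ia,
                                       index_spatial = is_))
    }
  }
  structure(list(cells = cells, index = index), class = "sensitivity_report")
}

# Find the loaded species contributing most through the given cross-section.
.species_sigma <- function(sc, field) {
  contrib <- vapply(sc$loadings, function(l)
    l$canonical_density * l$species[[field]], numeric(1))
  if (!length(contrib) || all(contrib == 0))
    stop("scenario has no species with nonzero ", field)
  l <- sc$loadings[[which.max(contrib)]]
  list(name = l$species$name, value = l$species[[field]])
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %d cells, %d parameters\n",
              nrow(x$cells), nrow(x$index)))
  if (nrow(x$index)) print(x$index, row.names = FALSE)
  invisible(x)
}
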