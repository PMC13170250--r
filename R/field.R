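#' Photon-density enhancement map E = Phi_case / Phi_reference
#'
#' Computes the voxelwise ratio of two fluence maps tallied on identical
#' grids. The ratio is reported only where the reference field exceeds a
#' noise floor (`floor_sigma` times its Monte Carlo standard error); this
#' avoids division-by-noise artefacts in deep, poorly sampled voxels. The
#' pooled relative standard error of the ratio is propagated from both maps.
#'
#' Summary statistics over the valid mask: the maximum laterally averaged
#' enhancement in the entry region (first `entry_depth` mm), the
#' volume-weighted median, and the volume fraction of valid voxels with
#' E > 1.
#'
#' @param case,ref `fluence_map` objects from [run_transport()] on identical
#'   grids.
#' @param floor_sigma Noise-floor multiplier on the reference standard error
#'   (default 10).
#' @param entry_depth Depth (mm) of the entry region used for the summary
#'   maximum (default 2).
#' @return An object of class `enhancement_map` with fields `e`, `stderr`,
#'   `valid_mask` and `summary`.
#' @export
enhancement_map <- function(case, ref, floor_sigma = 10, entry_depth = 2) {
  .enhancement(case$phi, case$stderr, ref$phi, ref$stderr,
               case$geom, ref$geom, case$beam, floor_sigma, entry_depth)
}

#' Absorption enhancement map on mu_a * Phi fields
#'
#' As [enhancement_map()], but on the deposited-power-density fields
#' (`a_total`, i.e. mu_a * Phi) of two [run_transport()] absorption maps. A
#' reference with no absorbed power anywhere yields an all-invalid mask and
#' an empty summary.
#'
#' @param case,ref `absorption_map` objects on identical grids.
#' @inheritParams enhancement_map
#' @return An object of class `enhancement_map`.
#' @export
absorption_enhancement_map <- function(case, ref, floor_sigma = 10,
                                       entry_depth = 2) {
  .enhancement(case$a_total, case$stderr, ref$a_total, ref$stderr,
               case$geom, ref$geom, case$beam, floor_sigma, entry_depth)
}

.enhancement <- function(fc, sc, fr, sr, geom_c, geom_r, beam,
                         floor_sigma, entry_depth) {
  if (!identical(dim(fc), dim(fr)) ||
      !isTRUE(all.equal(unclass(geom_c), unclass(geom_r))))
    stop("case and reference must be tallied on identical grids")
  valid <- fr > floor_sigma * sr & fr > 0
  e <- matrix(NA_real_, nrow(fc), ncol(fc))
  se <- matrix(NA_real_, nrow(fc), ncol(fc))
  e[valid] <- fc[valid] / fr[valid]
  # pooled relative error of the ratio
  rel2 <- (sc[valid] / pmax(fc[valid], .Machine$double.xmin))^2 +
          (sr[valid] / fr[valid])^2
  se[valid] <- e[valid] * sqrt(rel2)

  vols <- .voxel_volumes(geom_c)
  z <- .z_centers(geom_c)
  summary <- list(max_entry = NA_real_, median_volume = NA_real_,
                  frac_above_one = NA_real_, n_valid = sum(valid))
  if (any(valid)) {
    # laterally averaged profile ratio within the beam footprint
    prof <- .profile_ratio(fc, sc, fr, sr, geom_c, beam, floor_sigma)
    in_entry <- prof$z <= entry_depth & is.finite(prof$e)
    if (any(in_entry)) summary$max_entry <- max(prof$e[in_entry])
    summary$median_volume <- .weighted_median(e[valid], vols[valid])
    summary$frac_above_one <- sum(vols[valid][e[valid] > 1]) / sum(vols[valid])
  }
  structure(list(e = e, stderr = se, valid_mask = valid, geom = geom_c,
                 beam = beam, floor_sigma = floor_sigma,
                 entry_depth = entry_depth, summary = summary),
            class = "enhancement_map")
}

# Volume-weighted median.
.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

# Laterally averaged (within beam footprint, volume weighted) profile ratio
# with pooled standard errors.
.profile_ratio <- function(fc, sc, fr, sr, geom, beam, floor_sigma) {
  pc <- .lateral_average(fc, sc, geom, beam$radius)
  pr <- .lateral_average(fr, sr, geom, beam$radius)
  ok <- pr$value > floor_sigma * pr$stderr & pr$value > 0
  e <- ifelse(ok, pc$value / pr$value, NA_real_)
  se <- ifelse(ok, abs(e) * sqrt((pc$stderr / pmax(pc$value, .Machine$double.xmin))^2 +
                                 (pr$stderr / pr$value)^2), NA_real_)
  data.frame(z = pc$z, e = e, stderr = se)
}

# Volume-weighted lateral average restricted to radii within r_max.
.lateral_average <- function(f, s, geom, r_max) {
  rc <- .r_centers(geom)
  sel <- rc <= r_max
  if (!any(sel)) sel[1] <- TRUE  # beam narrower than one voxel: use the axis bin
  vols <- .voxel_volumes(geom)[sel, 1]
  w <- vols / sum(vols)
  val <- as.numeric(w %*% f[sel, , drop = FALSE])
  err <- sqrt(as.numeric((w^2) %*% (s[sel, , drop = FALSE]^2)))
  list(z = .z_centers(geom), value = val, stderr = err)
}

#' @export
print.enhancement_map <- function(x, ...) {
  cat(sprintf("<enhancement_map> %d valid voxels (floor %g sigma)\n",
              x$summary$n_valid, x$floor_sigma))
  cat(sprintf("  max (entry, first %g mm): %.3f | volume median: %.3f | frac E>1: %.3f\n",
              x$entry_depth, x$summary$max_entry, x$summary$median_volume,
              x$summary$frac_above_one))
  invisible(x)
}

#' Laterally averaged depth profile of a fluence or absorption map
#'
#' Averages the field over the radii inside the beam footprint at each depth
#' bin (volume weighted); standard errors are pooled from the per-voxel Monte
#' Carlo errors.
#'
#' @param map A `fluence_map` or `absorption_map`.
#' @param r_max Radius (mm) within which to average; defaults to the beam
#'   radius used for the run.
#' @return A `data.frame` with columns `z` (mm, strictly increasing), `value`
#'   and `stderr`.
#' @export
depth_profile <- function(map, r_max = NULL) {
  f <- if (inherits(map, "fluence_map")) map$phi
       else if (inherits(map, "absorption_map")) map$a_total
       else stop("map must be a fluence_map or absorption_map")
  if (is.null(r_max)) r_max <- map$beam$radius
  p <- .lateral_average(f, map$stderr, map$geom, r_max)
  data.frame(z = p$z, value = p$value, stderr = p$stderr)
}

#' Laterally averaged enhancement profile of two fluence maps
#'
#' Ratio of the [depth_profile()] of case and reference, with pooled errors
#' and the same noise-floor masking as [enhancement_map()].
#'
#' @inheritParams enhancement_map
#' @return A `data.frame` with columns `z`, `e`, `stderr`.
#' @export
enhancement_profile <- function(case, ref, floor_sigma = 10) {
  if (!identical(dim(case$phi), dim(ref$phi)))
    stop("case and reference must be tallied on identical grids")
  .profile_ratio(case$phi, case$stderr, ref$phi, ref$stderr,
                 case$geom, case$beam, floor_sigma)
}

#' Median enhancement over the upper half-depth
#'
#' Volume-weighted median of the enhancement over valid voxels whose depth is
#' at most `frac` of the cylinder height (default the upper half). This is the
#' "broad region" statistic for combined-vs-absorber comparisons.
#'
#' @param emap An [enhancement_map()].
#' @param frac Depth fraction defining the upper region (default 0.5).
#' @return The weighted median (NA if no valid voxels in the region).
#' @export
median_upper_region <- function(emap, frac = 0.5) {
  stopifnot(inherits(emap, "enhancement_map"))
  z <- .z_centers(emap$geom)
  upper <- matrix(rep(z <= frac * emap$geom$height, each = emap$geom$n_r),
                  emap$geom$n_r, emap$geom$n_z)
  sel <- emap$valid_mask & upper
  if (!any(sel)) return(NA_real_)
  .weighted_median(emap$e[sel], .voxel_volumes(emap$geom)[sel])
}
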