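#' Describe a single micropillar bed
#'
#' A bed is a rectangular microfluidic chamber of dimensions
#' length x width x depth populated with a regular array of micropillars.
#' Pillars are either circular (diameter `pillar_size_um`) or diamond
#' (a square of side `pillar_size_um` rotated 45 degrees, the usual
#' reading of "10 um x 10 um" diamond posts). All dimensions are stored
#' internally in SI metres; the constructor takes the units in which
#' device drawings are normally annotated.
#'
#' @param length_mm Bed length along the flow axis (mm).
#' @param width_mm Bed width (mm).
#' @param depth_um Bed depth, i.e. pillar height (micrometres).
#' @param pillar_shape `"circular"` or `"diamond"`.
#' @param pillar_size_um Pillar diameter (circular) or side (diamond), um.
#' @param pillar_spacing_um Inter-pillar gap, um. This is the width of the
#'   microchannels between pillars and sets the lateral diffusion distance
#'   a particle must cover to reach a capture surface.
#' @param n_pillars Number of pillars in the bed.
#'
#' @return An object of class `bed_geometry` with all lengths in metres.
#' @examples
#' bed_geometry(122, 1.7, 90, "circular", 100, 15, 15202)
#' @export
bed_geometry <- function(length_mm, width_mm, depth_um,
                         pillar_shape = c("circular", "diamond"),
                         pillar_size_um, pillar_spacing_um, n_pillars) {
  pillar_shape <- match.arg(pillar_shape)
  dims <- c(
    length_mm = length_mm, width_mm = width_mm, depth_um = depth_um,
    pillar_size_um = pillar_size_um, pillar_spacing_um = pillar_spacing_um
  )
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    bad <- names(dims)[!is.finite(dims) | dims <= 0][1]
    stop("bed dimension `", bad, "` must be strictly positive", call. = FALSE)
  }
  if (!is.finite(n_pillars) || n_pillars < 0 || n_pillars != round(n_pillars)) {
    stop("`n_pillars` must be a non-negative integer", call. = FALSE)
  }
  bed <- structure(
    list(
      length = length_mm * 1e-3,
      width = width_mm * 1e-3,
      depth = depth_um * 1e-6,
      pillar_shape = pillar_shape,
      pillar_size = pillar_size_um * 1e-6,
      pillar_spacing = pillar_spacing_um * 1e-6,
      n_pillars = as.integer(n_pillars)
    ),
    class = "bed_geometry"
  )
  if (pillar_footprint_area(bed) >= bed$length * bed$width) {
    stop("total pillar footprint exceeds the bed floor area", call. = FALSE)
  }
  bed
}

# Perimeter of one pillar (m). A diamond of side s has perimeter 4 s
# regardless of orientation.
pillar_perimeter <- function(bed) {
  switch(bed$pillar_shape,
    circular = pi * bed$pillar_size,
    diamond = 4 * bed$pillar_size
  )
}

# Footprint of all pillars in the bed (m^2).
pillar_footprint_area <- function(bed) {
  one <- switch(bed$pillar_shape,
    circular = pi * (bed$pillar_size / 2)^2,
    diamond = bed$pillar_size^2
  )
  one * bed$n_pillars
}

#' Assemble beds into a device
#'
#' Multi-bed devices come in two plumbing arrangements: `"serial"` (the
#' full volumetric flow passes through each bed in turn) and
#' `"parallel"` (a manifold splits the flow evenly over identical beds,
#' as in a z-configuration feed). Parallel devices must consist of
#' identical beds so the flow split is uniform.
#'
#' @param beds A `bed_geometry` or list of them.
#' @param arrangement `"serial"` or `"parallel"`.
#' @param name Optional device label.
#'
#' @return An object of class `device_geometry`.
#' @examples
#' bed <- bed_geometry(23, 3.6, 50, "diamond", 10, 10, 210816)
#' device_geometry(rep(list(bed), 7), "parallel", "7-bed")
#' @export
device_geometry <- function(beds, arrangement = c("serial", "parallel"),
                            name = "device") {
  arrangement <- match.arg(arrangement)
  if (inherits(beds, "bed_geometry")) beds <- list(beds)
  if (!length(beds) || !all(vapply(beds, inherits, logical(1), "bed_geometry"))) {
    stop("`beds` must be one or more bed_geometry objects", call. = FALSE)
  }
  if (arrangement == "parallel" && length(beds) > 1L) {
    first <- beds[[1]]
    same <- vapply(beds[-1], function(b) identical(unclass(b), unclass(first)),
                   logical(1))
    if (!all(same)) {
      stop("parallel arrangement requires all beds identical", call. = FALSE)
    }
  }
  structure(
    list(beds = beds, arrangement = arrangement, name = name),
    class = "device_geometry"
  )
}

as_device <- function(x) {
  if (inherits(x, "device_geometry")) return(x)
  if (inherits(x, "bed_geometry")) return(device_geometry(x, "serial", "bed"))
  stop("expected a bed_geometry or device_geometry", call. = FALSE)
}

#' @export
print.bed_geometry <- function(x, ...) {
  cat(sprintf(
    "<bed_geometry> %.4g x %.4g mm x %.4g um; %s pillars: %d x %.4g um, gap %.4g um\n",
    x$length * 1e3, x$width * 1e3, x$depth * 1e6,
    x$pillar_shape, x$n_pillars, x$pillar_size * 1e6, x$pillar_spacing * 1e6
  ))
  invisible(x)
}

#' @export
print.device_geometry <- function(x, ...) {
  cat(sprintf("<device_geometry> '%s': %d bed(s), %s\n",
              x$name, length(x$beds), x$arrangement))
  for (b in x$beds) print(b)
  invisible(x)
}

#' Internal capture surface area of a device
#'
#' Sums, over beds, the lateral area of all pillars
#' (perimeter x depth x count) plus the floor and ceiling area
#' (2 x bed footprint minus 2 x pillar footprint). Side walls and
#' inlet/outlet manifolds are excluded: for dense pillar arrays they are
#' a negligible fraction of the functionalizable area and their
#' dimensions are rarely specified on device drawings.
#'
#' @param device A `device_geometry` (or single `bed_geometry`).
#' @return Surface area in cm^2.
#' @examples
#' bed <- bed_geometry(23, 3.6, 50, "diamond", 10, 10, 210816)
#' internal_surface_area(device_geometry(rep(list(bed), 7), "parallel"))
#' @export
internal_surface_area <- function(device) {
  device <- as_device(device)
  per_bed <- vapply(device$beds, function(bed) {
    floor_area <- bed$length * bed$width - pillar_footprint_area(bed)
    if (floor_area < 0) {
      stop("invalid geometry: pillar footprint exceeds bed floor area",
           call. = FALSE)
    }
    pillar_perimeter(bed) * bed$depth * bed$n_pillars + 2 * floor_area
  }, numeric(1))
  sum(per_bed) * 1e4 # m^2 -> cm^2
}

#' Internal (dead) volume of a device
#'
#' Bed volume minus the volume displaced by the pillars, in microlitres.
#'
#' @inheritParams internal_surface_area
#' @return Volume in uL.
#' @export
internal_volume <- function(device) {
  device <- as_device(device)
  per_bed <- vapply(device$beds, function(bed) {
    (bed$length * bed$width - pillar_footprint_area(bed)) * bed$depth
  }, numeric(1))
  sum(per_bed) * 1e9 # m^3 -> uL
}

#' Monolayer EV load capacity of a capture surface
#'
#' Maximum number of vesicles that fit on an area as a close-packed
#' monolayer of spheres of the given diameter. The default packing is
#' hexagonal close packing of circles, pi/(2*sqrt(3)) ~ 0.9069, the
#' densest planar arrangement.
#'
#' @param area_cm2 Capture surface area (cm^2).
#' @param ev_diameter_nm Vesicle diameter (nm); 150 nm is a typical
#'   exosome/microvesicle mode.
#' @param packing Packing fraction in (0, 1].
#' @return Particle count (numeric, typically 1e10-1e11).
#' @examples
#' ev_load_capacity(6.8) # ~3.5e10 particles
#' @export
ev_load_capacity <- function(area_cm2, ev_diameter_nm = 150,
                             packing = pi / (2 * sqrt(3))) {
  if (!is.finite(area_cm2) || area_cm2 <= 0) {
    stop("`area_cm2` must be positive", call. = FALSE)
  }
  if (!is.finite(ev_diameter_nm) || ev_diameter_nm <= 0) {
    stop("`ev_diameter_nm` must be positive", call. = FALSE)
  }
  if (!is.finite(packing) || packing <= 0 || packing > 1) {
    stop("`packing` must be in (0, 1]", call. = FALSE)
  }
  area <- area_cm2 * 1e-4
  d <- ev_diameter_nm * 1e-9
  packing * area / (pi * (d / 2)^2)
}

#' Antibody amount and surface coverage
#'
#' Converts a mass of immobilized antibody into molar amount and areal
#' density. IgG-class monoclonals are ~150 kDa.
#'
#' @param mass_ug Antibody mass immobilized (ug).
#' @param molar_mass_kda Antibody molar mass (kDa).
#' @param area_cm2 Functionalized surface area (cm^2).
#' @return A tibble with columns `amount_pmol` and `density_pmol_cm2`.
#' @examples
#' antibody_coverage(23.1, 150, 38.5) # ~154 pmol, ~4 pmol/cm^2
#' @export
antibody_coverage <- function(mass_ug, molar_mass_kda = 150, area_cm2) {
  stopifnot(is.finite(mass_ug), mass_ug >= 0,
            is.finite(molar_mass_kda), molar_mass_kda > 0,
            is.finite(area_cm2), area_cm2 > 0)
  # ug -> 1e-9 kg; kDa -> kg/mol; mol -> 1e12 pmol
  amount_pmol <- mass_ug / molar_mass_kda * 1e3
  tibble::tibble(
    amount_pmol = amount_pmol,
    density_pmol_cm2 = amount_pmol / area_cm2
  )
}

#' Open flow cross-section of a device
#'
#' Cross-sectional area available to flow at a pillar row: bed width x
#' depth scaled by the open-width fraction spacing/(spacing + pillar
#' size), i.e. the constriction between pillars where the
#' capture-relevant interstitial velocity is set. Parallel devices sum
#' over beds; a serial device presents its single-bed cross-section.
#'
#' @inheritParams internal_surface_area
#' @return Area in m^2.
#' @export
open_cross_section <- function(device) {
  device <- as_device(device)
  per_bed <- vapply(device$beds, bed_open_cross_section, numeric(1))
  if (device$arrangement == "parallel") sum(per_bed) else per_bed[[1]]
}

bed_open_cross_section <- function(bed) {
  open_frac <- if (bed$n_pillars > 0) {
    bed$pillar_spacing / (bed$pillar_spacing + bed$pillar_size)
  } else {
    1
  }
  bed$width * bed$depth * open_frac
}

#' Table of derived device metrics
#'
#' One-row tibble summarising the deterministic design metrics of a
#' device: surface area, internal volume, open cross-section, EV
#' monolayer capacity and (optionally) antibody coverage.
#'
#' @inheritParams internal_surface_area
#' @param antibody_mass_ug Optional immobilized antibody mass (ug).
#' @param ev_diameter_nm Vesicle diameter used for the capacity (nm).
#' @return A tibble with one row per device.
#' @export
geometry_report <- function(device, antibody_mass_ug = NA_real_,
                            ev_diameter_nm = 150) {
  device <- as_device(device)
  area <- internal_surface_area(device)
  out <- tibble::tibble(
    name = device$name,
    n_beds = length(device$beds),
    arrangement = device$arrangement,
    n_pillars = sum(vapply(device$beds, `[[`, integer(1), "n_pillars")),
    surface_area_cm2 = area,
    internal_volume_ul = internal_volume(device),
    open_cross_section_m2 = open_cross_section(device),
    ev_capacity = ev_load_capacity(area, ev_diameter_nm)
  )
  if (!is.na(antibody_mass_ug)) {
    cov <- antibody_coverage(antibody_mass_ug, area_cm2 = area)
    out$antibody_pmol <- cov$amount_pmol
    out$antibody_pmol_cm2 <- cov$density_pmol_cm2
  }
  out
}
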