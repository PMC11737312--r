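## PCSA-torque-lever chain. Units throughout: g, mm, mm^2, mm^3, rad, N,
## N.mm. All elementary steps are vectorized over muscles.

#' Photograph scale factor
#'
#' Lens compression makes digitally measured distances differ from physical
#' ones; the ratio between a physically and a digitally measured reference
#' distance (two known landmarks) gives a linear correction factor for the
#' photographed specimen.
#'
#' @param physical_ref physically measured reference distance, mm.
#' @param digital_ref the same distance measured on the image, mm.
#' @return Dimensionless linear scale factor, physical / digital.
#' @seealso [correct_area()] which applies the factor to surface areas.
#' @export
scale_factor <- function(physical_ref, digital_ref) {
  if (any(!is.finite(physical_ref)) || any(physical_ref <= 0))
    stop("invalid measurement: 'physical_ref' must be finite and > 0")
  if (any(!is.finite(digital_ref)) || any(digital_ref <= 0))
    stop("invalid measurement: 'digital_ref' must be finite and > 0")
  physical_ref / digital_ref
}

#' Correct a digitally measured area for lens compression
#'
#' Areas scale as the square of a linear magnification, so the linear scale
#' factor is applied twice by default; `power = 1` is available for
#' sensitivity analyses.
#'
#' @param area digital surface area, mm^2.
#' @param sf linear scale factor from [scale_factor()].
#' @param power 2 (default, dimensionally consistent) or 1.
#' @return Corrected area, mm^2.
#' @export
correct_area <- function(area, sf, power = 2) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop("invalid measurement: 'area' must be finite and > 0")
  area * sf^power
}

#' Muscle volume from wet mass
#'
#' @param wet_mass muscle wet mass, g.
#' @param density muscle density, g/mm^3 (default 1.06e-3).
#' @return Volume, mm^3.
#' @export
muscle_volume <- function(wet_mass, density = 1.06e-3) {
  if (any(!is.finite(wet_mass)) || any(wet_mass < 0))
    stop("invalid measurement: 'wet_mass' must be finite and >= 0")
  if (any(density <= 0)) stop("'density' must be > 0")
  wet_mass / density
}

#' Muscle thickness from volume and area
#'
#' Thickness is the depth of the muscle sheet if its fascicles projected
#' straight out of the bone: T = V / A.
#'
#' @param volume muscle volume, mm^3.
#' @param area corrected surface area, mm^2.
#' @return Thickness, mm.
#' @export
muscle_thickness <- function(volume, area) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop("invalid measurement: 'area' must be finite and > 0")
  volume / area
}

#' Fascicle length from thickness
#'
#' Fascicles leave the bony elements at an angle (45 degrees by default)
#' rather than projecting straight out, so the in-situ thickness is divided
#' by the sine of that angle: l = T / sin(angle).
#'
#' @param thickness muscle thickness, mm.
#' @param fascicle_angle fascicle angle to the bone, radians, in (0, pi/2].
#' @return Fascicle length, mm.
#' @export
fascicle_length <- function(thickness, fascicle_angle = pi / 4) {
  if (any(fascicle_angle <= 0) || any(fascicle_angle > pi / 2))
    stop("'fascicle_angle' must lie in (0, pi/2]")
  thickness / sin(fascicle_angle)
}

#' Physiological cross-sectional area
#'
#' PCSA = m cos(theta) / (rho l), with m the wet mass (g), theta the
#' pennation angle (rad), rho the muscle density (g/mm^3) and l the
#' fascicle length (mm). When l is itself derived from the same mass via
#' the thickness chain, mass and density cancel algebraically and
#' PCSA = corrected area x sin(fascicle angle) x cos(pennation).
#'
#' @param wet_mass muscle wet mass, g.
#' @param pennation_angle pennation angle of the fibres, radians, in
#'   \[0, pi/2).
#' @param density muscle density, g/mm^3.
#' @param fl fascicle length, mm.
#' @return PCSA, mm^2.
#' @export
pcsa <- function(wet_mass, pennation_angle, density, fl) {
  if (any(!is.finite(fl)) || any(fl <= 0))
    stop("invalid measurement: fascicle length must be finite and > 0")
  if (any(pennation_angle < 0) || any(pennation_angle >= pi / 2))
    stop("'pennation_angle' must lie in [0, pi/2)")
  wet_mass * cos(pennation_angle) / (density * fl)
}

#' Muscle force from PCSA
#'
#' @param pcsa physiological cross-sectional area, mm^2.
#' @param tetanic_stress maximal muscle stress, N/mm^2 (default 0.3).
#' @return Force, N.
#' @export
muscle_force <- function(pcsa, tetanic_stress = 0.3) {
  tetanic_stress * pcsa
}

#' Mean moment arm
#'
#' Jaw muscles are not uniform rectangles: moment arms are measured at the
#' start, midpoint and end of the line of action and averaged.
#'
#' @param arms numeric vector of three arm lengths (mm), or a matrix with
#'   three columns (one row per muscle).
#' @return Mean arm length, mm (one value per muscle).
#' @export
mean_moment_arm <- function(arms) {
  if (is.matrix(arms)) {
    if (ncol(arms) != 3L) stop("'arms' must have three columns")
    bad <- !is.finite(arms) | arms < 0
  } else {
    if (length(arms) != 3L) stop("'arms' must contain three measurements")
    bad <- !is.finite(arms) | arms < 0
  }
  if (any(bad)) stop("invalid measurement: moment arms must be finite and >= 0")
  if (is.matrix(arms)) rowMeans(arms) else mean(arms)
}

#' Torque of one muscle about the jaw fulcrum
#'
#' tau = r F sin(loa), where r is the mean moment arm (mm), F the muscle
#' force (N) and loa the angle of the line of action to the defined
#' horizontal (rad).
#'
#' @param arm mean moment arm, mm.
#' @param force muscle force, N.
#' @param loa_angle line-of-action angle, radians, in \[0, pi\].
#' @return Torque, N.mm.
#' @export
muscle_torque <- function(arm, force, loa_angle) {
  if (any(loa_angle < 0) || any(loa_angle > pi))
    stop("'loa_angle' must lie in [0, pi]")
  arm * force * sin(loa_angle)
}

#' Per-muscle derived quantities
#'
#' Runs the full chain (volume, thickness, fascicle length, PCSA, force,
#' mean arm, torque) for a table of muscle observations from one specimen.
#'
#' @param muscles data frame with columns `muscle`, `role` ("adductor" or
#'   "abductor"), `wet_mass` (g), `surface_area` (mm^2, digital), `pennation`
#'   and `loa` (radians), `arm1`, `arm2`, `arm3` (mm), and optionally
#'   `area_is_proxy` (logical; TRUE when a bone area stands in for the
#'   muscle area, as the palatine bone does for the pterygoideus dorsalis).
#' @param sf linear scale factor for the specimen's photographs.
#' @param constants a [model_constants()] object.
#' @return The input with columns `corrected_area`, `volume`, `thickness`,
#'   `fascicle_length`, `pcsa`, `force`, `mean_arm`, `torque` appended.
#' @export
muscle_derived <- function(muscles, sf = 1, constants = model_constants()) {
  stopifnot(is.data.frame(muscles))
  need <- c("muscle", "role", "wet_mass", "surface_area",
            "pennation", "loa", "arm1", "arm2", "arm3")
  miss <- setdiff(need, names(muscles))
  if (length(miss))
    stop("missing muscle columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(muscles$muscle))
    stop("muscle names must be unique within a specimen")
  if (!all(muscles$role %in% c("adductor", "abductor")))
    stop("'role' must be \"adductor\" or \"abductor\"")
  if (is.null(muscles$area_is_proxy)) muscles$area_is_proxy <- FALSE

  m <- muscles
  m$corrected_area <- correct_area(m$surface_area, sf,
                                   constants$area_scale_power)
  m$volume <- muscle_volume(m$wet_mass, constants$muscle_density)
  m$thickness <- muscle_thickness(m$volume, m$corrected_area)
  m$fascicle_length <- fascicle_length(m$thickness, constants$fascicle_angle)
  ## zero-mass muscles short-circuit: zero volume => zero force
  m$pcsa <- ifelse(m$wet_mass > 0,
                   pcsa(pmax(m$wet_mass, .Machine$double.xmin), m$pennation,
                        constants$muscle_density,
                        pmax(m$fascicle_length, .Machine$double.xmin)),
                   0)
  m$force <- muscle_force(m$pcsa, constants$tetanic_stress)
  m$mean_arm <- mean_moment_arm(as.matrix(m[, c("arm1", "arm2", "arm3")]))
  m$torque <- muscle_torque(m$mean_arm, m$force, m$loa)
  m
}

#' Bite force of one specimen
#'
#' The jaw is modelled as a static third-class lever. Adductor torques are
#' summed, divided by the out-lever moment arm (fulcrum to bite point) and
#' multiplied by the bilateral factor to give whole-jaw bite force.
#' Abductors (the depressor mandibulae) are carried through the chain for
#' reporting but contribute nothing to the sum.
#'
#' @param muscles muscle observation table, see [muscle_derived()].
#' @param geometry list or one-row data frame with `out_lever` (mm) and
#'   either `sf` or the pair `physical_ref` / `digital_ref` (mm).
#' @param constants a [model_constants()] object.
#' @return Object of class `"bite_force"`: a list with `bite_force` (N),
#'   `per_muscle` (the [muscle_derived()] table), `out_lever`, `sf`,
#'   `n_adductors` and `constants`.
#' @examples
#' m <- data.frame(muscle = "EM", role = "adductor", wet_mass = 1.06,
#'                 surface_area = 100, pennation = 0, loa = pi / 2,
#'                 arm1 = 10, arm2 = 10, arm3 = 10)
#' bite_force(m, list(out_lever = 50, sf = 1))
#' @export
bite_force <- function(muscles, geometry, constants = model_constants()) {
  geometry <- as.list(geometry)
  if (is.null(geometry$out_lever) || !is.finite(geometry$out_lever) ||
      geometry$out_lever <= 0)
    stop("'out_lever' must be finite and > 0")
  sf <- if (!is.null(geometry$sf)) {
    geometry$sf
  } else {
    scale_factor(geometry$physical_ref, geometry$digital_ref)
  }
  per <- muscle_derived(muscles, sf = sf, constants = constants)
  add <- per$role == "adductor"
  if (!any(add)) {
    warning("specimen has no adductor muscles; bite force is 0 N")
    bf <- 0
  } else {
    bf <- constants$bilateral_factor * sum(per$torque[add]) /
      geometry$out_lever
  }
  per$contributes <- add
  structure(
    list(bite_force = bf, per_muscle = per,
         out_lever = geometry$out_lever, sf = sf,
         n_adductors = sum(add), constants = constants),
    class = "bite_force"
  )
}

#' @export
print.bite_force <- function(x, digits = 3, ...) {
  cat(sprintf("Bite force: %.*f N (%d adductors, out-lever %.3g mm, scale factor %.4g)\n",
              digits, x$bite_force, x$n_adductors, x$out_lever, x$sf))
  tab <- x$per_muscle[, c("muscle", "role", "pcsa", "force", "mean_arm",
                          "torque")]
  tab[-(1:2)] <- lapply(tab[-(1:2)], round, digits)
  print(tab, row.names = FALSE)
  if (any(as.logical(x$per_muscle$area_is_proxy), na.rm = TRUE))
    cat("note: some areas use a bone-surface proxy\n")
  invisible(x)
}

#' Bite force for a table of specimens
#'
#' Applies [bite_force()] specimen by specimen. When both sides of a head
#' were dissected (rows `side = "left"` and `"right"` for the same
#' specimen and muscle), per-muscle measurements are averaged across sides
#' before modelling, and the bilateral factor then restores whole-jaw
#' force.
#'
#' @param muscles long table, one row per specimen x muscle (x side):
#'   columns `specimen_id`, `species`, optional `side`, plus the columns of
#'   [muscle_derived()].
#' @param geometry one row per specimen: `specimen_id`, `out_lever`,
#'   `physical_ref`, `digital_ref`.
#' @param constants a [model_constants()] object.
#' @return Data frame, one row per specimen: `specimen_id`, `species`,
#'   `bite_force_N`. The per-muscle breakdown (long format) is attached as
#'   attribute `"per_muscle"`.
#' @export
compute_bite_forces <- function(muscles, geometry,
                                constants = model_constants()) {
  stopifnot(is.data.frame(muscles), is.data.frame(geometry))
  if (anyDuplicated(geometry$specimen_id))
    stop("duplicate specimen_id in geometry table")
  ids <- unique(muscles$specimen_id)
  miss <- setdiff(ids, geometry$specimen_id)
  if (length(miss))
    stop("specimens missing from geometry table: ",
         paste(miss, collapse = ", "))
  res <- vector("list", length(ids))
  breakdown <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    mi <- muscles[muscles$specimen_id == ids[i], , drop = FALSE]
    species <- mi$species[1]
    if (!is.null(mi$side) && length(unique(mi$side)) > 1L) {
      num <- c("wet_mass", "surface_area", "pennation", "loa",
               "arm1", "arm2", "arm3")
      agg <- aggregate(mi[num], by = mi[c("muscle", "role")], FUN = mean)
      if (is.null(mi$area_is_proxy)) mi$area_is_proxy <- FALSE
      prox <- aggregate(mi["area_is_proxy"], by = mi["muscle"], FUN = any)
      mi <- merge(agg, prox, by = "muscle")
    }
    gi <- as.list(geometry[geometry$specimen_id == ids[i], , drop = FALSE])
    fit <- bite_force(mi, gi, constants)
    res[[i]] <- data.frame(specimen_id = ids[i], species = species,
                           bite_force_N = fit$bite_force)
    pm <- fit$per_muscle
    pm$specimen_id <- ids[i]
    pm$species <- species
    breakdown[[i]] <- pm
  }
  out <- do.call(rbind, res)
  attr(out, "per_muscle") <- do.call(rbind, breakdown)
  out
}

#' @importFrom stats aggregate
NULL
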