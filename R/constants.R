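#' Physical constants of the bite-force model
#'
#' Bundles the constants used throughout the PCSA-torque-lever chain.
#' Defaults follow the standard values for vertebrate skeletal muscle:
#' density 1.06 x 10^-3 g/mm^3 (i.e. 1.06 g/cm^3; some sources misprint
#' this as 1060 g/mm^3 -- the SI-consistent value in g/mm^3 is used here),
#' maximal tetanic stress 0.3 N/mm^2, a 45-degree projection of fascicles
#' away from the bone, and a factor of two to account for the musculature
#' on both sides of the jaw.
#'
#' @param muscle_density muscle tissue density, g/mm^3.
#' @param tetanic_stress maximal isometric muscle stress, N/mm^2.
#' @param fascicle_angle angle at which fascicles leave the bony origin,
#'   radians, in (0, pi/2]. Muscle thickness is divided by its sine to give
#'   fascicle length.
#' @param bilateral_factor 2 when per-side muscle data should be doubled to
#'   whole-jaw force, 1 for a single-side force.
#' @param area_scale_power power to which the linear photograph scale factor
#'   is raised when correcting surface areas; 2 (the dimensionally
#'   consistent choice for an area) by default, 1 available for
#'   sensitivity checks.
#' @return An object of class `"model_constants"`: a named list of the five
#'   validated constants.
#' @examples
#' model_constants()
#' model_constants(bilateral_factor = 1) # per-side force
#' @export
model_constants <- function(muscle_density = 1.06e-3,
                            tetanic_stress = 0.3,
                            fascicle_angle = pi / 4,
                            bilateral_factor = 2,
                            area_scale_power = 2) {
  stopifnot(
    is.numeric(muscle_density), length(muscle_density) == 1L,
    is.numeric(tetanic_stress), length(tetanic_stress) == 1L,
    is.numeric(fascicle_angle), length(fascicle_angle) == 1L
  )
  if (muscle_density <= 0) stop("'muscle_density' must be strictly positive")
  if (tetanic_stress <= 0) stop("'tetanic_stress' must be strictly positive")
  if (fascicle_angle <= 0 || fascicle_angle > pi / 2)
    stop("'fascicle_angle' must lie in (0, pi/2] radians")
  if (!bilateral_factor %in% c(1, 2))
    stop("'bilateral_factor' must be 1 or 2")
  if (!area_scale_power %in% c(1, 2))
    stop("'area_scale_power' must be 1 or 2")
  structure(
    list(
      muscle_density = muscle_density,
      tetanic_stress = tetanic_stress,
      fascicle_angle = fascicle_angle,
      bilateral_factor = bilateral_factor,
      area_scale_power = area_scale_power
    ),
    class = "model_constants"
  )
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Bite-force model constants\n")
  cat(sprintf("  muscle density:   %g g/mm^3\n", x$muscle_density))
  cat(sprintf("  tetanic stress:   %g N/mm^2\n", x$tetanic_stress))
  cat(sprintf("  fascicle angle:   %.1f deg\n", x$fascicle_angle * 180 / pi))
  cat(sprintf("  bilateral factor: %d\n", x$bilateral_factor))
  cat(sprintf("  area scale power: %d\n", x$area_scale_power))
  invisible(x)
}
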