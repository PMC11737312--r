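## CSV and Newick I/O with validation. CSV dialect: comma separator, '.'
## decimal, mandatory header. Angles live in radians inside the package;
## files may carry degrees (the default) or radians, declared per call.

.check_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("'", path, "' is missing columns: ", paste(miss, collapse = ", "))
}

.check_numeric <- function(df, cols, path) {
  bad <- character()
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      rows <- which(!is.na(v) & v != "" & is.na(vn) & v != "NA")
      if (length(rows))
        bad <- c(bad, paste0(cl, " (rows ",
                             paste(rows, collapse = ","), ")"))
      df[[cl]] <- vn
    }
  }
  if (length(bad))
    stop("'", path, "' has non-numeric cells in: ",
         paste(bad, collapse = "; "))
  df
}

#' Read a species trait table
#'
#' @param path CSV with columns `species`, `body_mass_g` and any of
#'   `skull_mass_g`, `skull_length_mm`, `jaw_muscle_mass_g`,
#'   `bite_force_N`, `scar_length_mm`, `bite_force_source`.
#' @return Validated data frame; species normalised to
#'   underscore-separated labels.
#' @export
read_traits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("'", path, "' contains no data rows")
  .check_columns(df, c("species", "body_mass_g"), path)
  num <- intersect(c("body_mass_g", "skull_mass_g", "skull_length_mm",
                     "jaw_muscle_mass_g", "bite_force_N", "scar_length_mm"),
                   names(df))
  df <- .check_numeric(df, num, path)
  df$species <- gsub(" ", "_", trimws(df$species))
  if (anyDuplicated(df$species) && is.null(df$bite_force_source))
    stop("'", path, "' has duplicate species")
  df
}

#' Read a per-specimen muscle table
#'
#' One row per specimen x muscle (x side). Expected columns:
#' `specimen_id`, `species`, optional `side`, `muscle`, `role`,
#' `wet_mass_g`, `surface_area_mm2`, angle columns (`pennation_deg` +
#' `loa_deg`, or `pennation_rad` + `loa_rad`), `arm1_mm`, `arm2_mm`,
#' `arm3_mm`, optional `area_is_proxy`.
#'
#' @param path CSV path.
#' @param angle_unit `"degree"` (default) or `"radian"`; must match the
#'   angle column suffix present in the file.
#' @return Data frame in the internal schema of [compute_bite_forces()]
#'   (angles in radians).
#' @export
read_muscles <- function(path, angle_unit = c("degree", "radian")) {
  angle_unit <- match.arg(angle_unit)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("'", path, "' contains no data rows")
  suffix <- if (angle_unit == "degree") "deg" else "rad"
  pen <- paste0("pennation_", suffix); loa <- paste0("loa_", suffix)
  .check_columns(df, c("specimen_id", "species", "muscle", "role",
                       "wet_mass_g", "surface_area_mm2", pen, loa,
                       "arm1_mm", "arm2_mm", "arm3_mm"), path)
  df <- .check_numeric(df, c("wet_mass_g", "surface_area_mm2", pen, loa,
                             "arm1_mm", "arm2_mm", "arm3_mm"), path)
  key <- paste(df$specimen_id, df$muscle,
               if (is.null(df$side)) "" else df$side)
  if (anyDuplicated(key))
    stop("'", path, "' has duplicate specimen/muscle rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  conv <- if (angle_unit == "degree") pi / 180 else 1
  out <- data.frame(specimen_id = df$specimen_id,
                    species = gsub(" ", "_", trimws(df$species)),
                    muscle = df$muscle, role = df$role,
                    wet_mass = df$wet_mass_g,
                    surface_area = df$surface_area_mm2,
                    pennation = df[[pen]] * conv,
                    loa = df[[loa]] * conv,
                    arm1 = df$arm1_mm, arm2 = df$arm2_mm, arm3 = df$arm3_mm)
  if (!is.null(df$side)) out$side <- df$side
  out$area_is_proxy <- if (is.null(df$area_is_proxy)) FALSE else
    as.logical(df$area_is_proxy)
  out
}

#' Read a specimen jaw-geometry table
#'
#' @param path CSV with `specimen_id`, `out_lever_mm`, `physical_ref_mm`,
#'   `digital_ref_mm`.
#' @return Data frame in the internal schema (`out_lever`, `physical_ref`,
#'   `digital_ref`).
#' @export
read_geometry <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("'", path, "' contains no data rows")
  .check_columns(df, c("specimen_id", "out_lever_mm", "physical_ref_mm",
                       "digital_ref_mm"), path)
  df <- .check_numeric(df, c("out_lever_mm", "physical_ref_mm",
                             "digital_ref_mm"), path)
  if (anyDuplicated(df$specimen_id))
    stop("'", path, "' has duplicate specimen_id")
  data.frame(specimen_id = df$specimen_id, out_lever = df$out_lever_mm,
             physical_ref = df$physical_ref_mm,
             digital_ref = df$digital_ref_mm)
}

#' Read a Newick tree
#'
#' Thin validating wrapper over [ape::read.tree()]: the tree must parse,
#' be rooted and carry branch lengths.
#'
#' @param path Newick file path (or a `text =`-style string via `text`).
#' @param text optional literal Newick string instead of a file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w))
  )
  if (is.null(tr)) stop("Newick parse error: no tree found")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths; a time-calibrated tree is required")
  ## a basal polytomy (e.g. a star tree) is treated as rooted at the
  ## polytomy, which is what the Brownian covariance assumes
  tr
}

#' Write a bite-force result table
#'
#' Writes one row per specimen plus, when present, the per-muscle
#' breakdown in wide columns (`<muscle>_pcsa_mm2`, `<muscle>_force_N`,
#' `<muscle>_torque_Nmm`).
#'
#' @param result output of [compute_bite_forces()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_biteforce_csv <- function(result, path) {
  out <- result
  pm <- attr(result, "per_muscle")
  if (!is.null(pm)) {
    for (q in c("pcsa", "force", "torque")) {
      w <- reshape(pm[, c("specimen_id", "muscle", q)],
                   idvar = "specimen_id", timevar = "muscle",
                   direction = "wide")
      names(w) <- sub(paste0("^", q, "\\."),
                      "", names(w))
      names(w)[-1] <- paste0(names(w)[-1], "_", q)
      out <- merge(out, w, by = "specimen_id", sort = FALSE)
    }
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `tree.nwk`, `traits.csv`, `muscles.csv`, `geometry.csv` and
#' `ground_truth.json` (the latter only when the jsonlite package is
#' available).
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  write.csv(dataset$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  m <- dataset$specimens$muscles
  mus <- data.frame(specimen_id = m$specimen_id, species = m$species,
                    side = m$side, muscle = m$muscle, role = m$role,
                    wet_mass_g = m$wet_mass,
                    surface_area_mm2 = m$surface_area,
                    pennation_deg = m$pennation * 180 / pi,
                    loa_deg = m$loa * 180 / pi,
                    arm1_mm = m$arm1, arm2_mm = m$arm2, arm3_mm = m$arm3,
                    area_is_proxy = m$area_is_proxy)
  write.csv(mus, file.path(dir, "muscles.csv"), row.names = FALSE)
  g <- dataset$specimens$geometry
  geo <- data.frame(specimen_id = g$specimen_id, out_lever_mm = g$out_lever,
                    physical_ref_mm = g$physical_ref,
                    digital_ref_mm = g$digital_ref)
  write.csv(geo, file.path(dir, "geometry.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(list(seed = dataset$seed,
                              ground_truth = dataset$specimens$ground_truth),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Packaged parrot species means
#'
#' Species-mean morphometrics and calculated bite forces for 19 parrot
#' species in three families (body mass, skull mass, skull length,
#' one-side total jaw muscle mass, calculated bite force, and the
#' published bite-force:body-mass ratio).
#'
#' @return Data frame with 19 rows.
#' @export
parrot_traits <- function() {
  read_traits(system.file("extdata", "parrot_species_traits.csv",
                          package = "parrotbite", mustWork = TRUE))
}

#' Packaged measured and scar-predicted parrot bite forces
#'
#' In-vivo transducer bite forces for nine parrot species, together with
#' bite forces predicted from the adductor scar on skulls of the same
#' species (two species lack skull images, hence NA), and the published
#' ratio columns.
#'
#' @return Data frame with 9 rows.
#' @export
parrot_measured <- function() {
  read_traits(system.file("extdata", "parrot_measured_biteforce.csv",
                          package = "parrotbite", mustWork = TRUE))
}

#' @importFrom stats reshape
NULL
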