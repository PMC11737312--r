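## Synthetic parrots: Yule trees, Brownian body mass, allometric traits
## and dissection tables constructed to be exactly consistent with the
## forward biomechanical model. Defaults are calibrated once to the
## observed ranges of real parrot species means (body mass ~29-1254 g,
## bite force ~12-444 N) and to the log-log trait fits on those means.

#' Configuration for the synthetic-data generator
#'
#' @param n_species number of tips / species.
#' @param birth_rate Yule speciation rate (the tree is rescaled to unit
#'   depth, so this only shapes relative node heights).
#' @param root_log_body_mass log10 body mass (g) at the root (2.6, about
#'   400 g, the middle of the parrot range).
#' @param brownian_sigma2 Brownian rate of log10 body mass per unit tree
#'   depth (0.25 spans roughly 30-1250 g over a unit-depth tree).
#' @param rules named list of per-trait allometric rules
#'   `c(a, b, sd)` (log10 intercept, exponent on body mass, residual sd)
#'   for `skull_mass_g`, `skull_length_mm`, `jaw_muscle_mass_g`,
#'   `bite_force_N`, `scar_length_mm`. Defaults follow the log-log fits on
#'   real parrot species means, rounded.
#' @param muscle_profile data frame with columns `muscle`, `role`,
#'   `fraction` (of one-side jaw muscle mass; must sum to 1),
#'   `pennation_deg`, `loa_deg`, `arm_frac` (moment arm as a fraction of
#'   skull length), `area_is_proxy`. Default: the six parrot jaw muscles
#'   with the ethmomandibularis and adductor mandibulae externus dominant.
#' @param out_lever_frac out-lever as a fraction of skull length.
#' @param physical_ref_mm physical reference distance for the lens
#'   correction.
#' @param photo_scale_factor true linear lens-compression factor applied
#'   when generating digital measurements.
#' @param measurement_noise sd of multiplicative log-normal noise on
#'   masses and areas (0 = exact).
#' @param method_offset systematic offset (log10 units) of "measured" over
#'   calculated bite force, for ANCOVA experiments.
#' @param measured_noise_sd sd (log10 units) of measured bite forces about
#'   the offset line.
#' @return Classed list (`"sim_config"`) of validated settings.
#' @export
sim_config <- function(n_species = 19,
                       birth_rate = 1,
                       root_log_body_mass = 2.6,
                       brownian_sigma2 = 0.25,
                       rules = list(
                         skull_mass_g = c(a = -2.11, b = 1.14, sd = 0.11),
                         skull_length_mm = c(a = 0.89, b = 0.36, sd = 0.03),
                         jaw_muscle_mass_g = c(a = -2.57, b = 1.13, sd = 0.16),
                         bite_force_N = c(a = -0.40, b = 0.93, sd = 0.14),
                         scar_length_mm = c(a = -0.17, b = 0.42, sd = 0.02)),
                       muscle_profile = default_muscle_profile(),
                       out_lever_frac = 0.55,
                       physical_ref_mm = 30,
                       photo_scale_factor = 1.07,
                       measurement_noise = 0,
                       method_offset = 0,
                       measured_noise_sd = 0.05) {
  stopifnot(n_species >= 2, birth_rate > 0, brownian_sigma2 >= 0,
            out_lever_frac > 0, physical_ref_mm > 0,
            photo_scale_factor > 0, measurement_noise >= 0,
            measured_noise_sd >= 0)
  for (r in rules)
    if (length(r) != 3L || r[["sd"]] < 0)
      stop("each rule must be c(a, b, sd) with sd >= 0")
  p <- muscle_profile
  if (abs(sum(p$fraction) - 1) > 1e-8)
    stop("muscle_profile fractions must sum to 1")
  if (sum(p$fraction[p$role == "adductor"]) <= 0)
    stop("infeasible profile: adductor mass fraction is zero")
  structure(list(n_species = n_species, birth_rate = birth_rate,
                 root_log_body_mass = root_log_body_mass,
                 brownian_sigma2 = brownian_sigma2, rules = rules,
                 muscle_profile = p, out_lever_frac = out_lever_frac,
                 physical_ref_mm = physical_ref_mm,
                 photo_scale_factor = photo_scale_factor,
                 measurement_noise = measurement_noise,
                 method_offset = method_offset,
                 measured_noise_sd = measured_noise_sd),
            class = "sim_config")
}

#' Default six-muscle jaw profile
#'
#' Mass fractions, angles and moment-arm fractions for the six parrot jaw
#' muscles: depressor mandibulae (DM, the abductor), pterygoideus
#' ventralis (PTVL), adductor mandibulae externus (AME), pseudomasseter
#' (PSM), pterygoideus dorsalis (PTD, whose area is measured via the
#' palatine bone) and ethmomandibularis (EM, the parrot-specific adductor).
#' EM and AME carry the largest mass fractions. Pennation defaults to 0
#' (fibres parallel to the line of action).
#'
#' @return Data frame usable as `muscle_profile` in [sim_config()].
#' @export
default_muscle_profile <- function() {
  data.frame(
    muscle = c("DM", "PTVL", "AME", "PSM", "PTD", "EM"),
    role = c("abductor", rep("adductor", 5)),
    fraction = c(0.12, 0.16, 0.26, 0.10, 0.08, 0.28),
    pennation_deg = 0,
    loa_deg = c(60, 80, 75, 85, 70, 90),
    arm_frac = c(0.10, 0.16, 0.22, 0.20, 0.14, 0.25),
    area_is_proxy = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree rescaled so every tip sits at depth 1.
#'
#' @param n_species number of tips.
#' @param birth_rate speciation rate.
#' @param seed optional integer seed.
#' @return A `phylo` tree, tips labelled `sp_01`, `sp_02`, ...
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  stopifnot(n_species >= 2)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp_%02d", seq_len(n_species))
  tr
}

#' Simulate species traits on a tree
#'
#' Log10 body mass evolves by Brownian motion (root value and rate from
#' the config); the remaining traits follow the config's allometric rules
#' with independent normal residuals on the log10 scale, so all traits are
#' positive after back-transform. The calculated bite force is itself a
#' trait here: the specimen generator then builds dissection tables that
#' reproduce it exactly through the biomechanical model.
#'
#' @param tree `phylo` tree (tips define the species).
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return Species trait data frame (`species`, `body_mass_g`,
#'   `skull_mass_g`, `skull_length_mm`, `jaw_muscle_mass_g`,
#'   `bite_force_N`, `scar_length_mm`, `bite_force_source =
#'   "calculated"`).
#' @export
simulate_traits <- function(tree, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pc <- brownian_covariance(tree)
  n <- length(pc$tip_order)
  log_bm <- config$root_log_body_mass +
    if (config$brownian_sigma2 > 0)
      drop(t(chol(config$brownian_sigma2 * pc$C)) %*% rnorm(n))
    else rep(0, n)
  out <- data.frame(species = pc$tip_order, body_mass_g = 10^log_bm)
  for (tr in names(config$rules)) {
    r <- config$rules[[tr]]
    lt <- r[["a"]] + r[["b"]] * log_bm +
      if (r[["sd"]] > 0) rnorm(n, sd = r[["sd"]]) else 0
    out[[tr]] <- 10^lt
  }
  out$bite_force_source <- "calculated"
  out
}

#' Generate dissection tables consistent with species bite forces
#'
#' Works backwards through the biomechanical model: one-side jaw muscle
#' mass is split over the profile's muscles, moment arms and the
#' out-lever are fractions of skull length, and (corrected) muscle areas
#' are chosen so that [bite_force()] reproduces each species' trait-table
#' bite force exactly. Digital areas are the corrected areas divided by
#' the squared photo scale factor, so the lens correction also
#' round-trips. Optional multiplicative measurement noise then perturbs
#' masses and areas (after which exact agreement no longer holds -- that
#' is the point of the noise).
#'
#' @param traits output of [simulate_traits()] (or a compatible table).
#' @param config a [sim_config()].
#' @param seed optional integer seed (used only when `measurement_noise >
#'   0`).
#' @return List with `muscles` (long specimen x muscle table in the
#'   [compute_bite_forces()] schema, angles in radians), `geometry` (one
#'   row per specimen) and `ground_truth` (species, true bite force, out
#'   lever, scale factor).
#' @export
generate_specimens <- function(traits, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- config$muscle_profile
  const <- model_constants()
  sf <- config$photo_scale_factor
  add <- p$role == "adductor"
  if (!any(add) && any(traits$bite_force_N > 0))
    stop("infeasible profile: no adductor fraction but nonzero target force")
  muscles <- vector("list", nrow(traits))
  geometry <- vector("list", nrow(traits))
  for (i in seq_len(nrow(traits))) {
    sl <- traits$skull_length_mm[i]
    out_lever <- config$out_lever_frac * sl
    target <- traits$bite_force_N[i]
    r <- p$arm_frac * sl
    loa <- p$loa_deg * pi / 180
    theta <- p$pennation_deg * pi / 180
    ## torque per unit corrected area for each muscle
    per_area <- const$tetanic_stress * sin(const$fascicle_angle) *
      cos(theta) * r * sin(loa)
    need <- target * out_lever / const$bilateral_factor
    w <- p$fraction / sum(p$fraction[add])
    a_tot <- need / sum((w * per_area)[add])
    corrected <- w * a_tot
    digital <- corrected / sf^const$area_scale_power
    mass <- p$fraction * traits$jaw_muscle_mass_g[i]
    if (config$measurement_noise > 0) {
      mass <- mass * exp(rnorm(nrow(p), sd = config$measurement_noise))
      digital <- digital * exp(rnorm(nrow(p), sd = config$measurement_noise))
    }
    muscles[[i]] <- data.frame(
      specimen_id = traits$species[i], species = traits$species[i],
      side = "mean", muscle = p$muscle, role = p$role,
      wet_mass = mass, surface_area = digital,
      pennation = theta, loa = loa,
      arm1 = 0.9 * r, arm2 = r, arm3 = 1.1 * r,
      area_is_proxy = p$area_is_proxy
    )
    geometry[[i]] <- data.frame(
      specimen_id = traits$species[i], out_lever = out_lever,
      physical_ref = config$physical_ref_mm,
      digital_ref = config$physical_ref_mm / sf
    )
  }
  list(muscles = do.call(rbind, muscles),
       geometry = do.call(rbind, geometry),
       ground_truth = data.frame(species = traits$species,
                                 bite_force_N = traits$bite_force_N,
                                 out_lever = vapply(geometry, `[[`,
                                                    numeric(1), "out_lever"),
                                 scale_factor = sf))
}

#' Simulate in-vivo "measured" bite forces
#'
#' Adds a method offset and log-normal noise to the calculated bite
#' forces: `log10 BF_measured = log10 BF_calculated + delta + N(0, sd)`.
#' With `delta = 0` this emulates the null scenario in which the
#' dissection-based calculation is unbiased with respect to transducer
#' measurements.
#'
#' @param traits species trait table with `bite_force_N`.
#' @param method_offset delta, log10 units.
#' @param noise_sd residual sd, log10 units.
#' @param seed optional integer seed.
#' @return Copy of `traits` with perturbed `bite_force_N` and
#'   `bite_force_source = "measured"`.
#' @export
simulate_measured_bite_forces <- function(traits, method_offset = 0,
                                          noise_sd = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- traits
  out$bite_force_N <- 10^(log10(traits$bite_force_N) + method_offset +
                            rnorm(nrow(traits), sd = noise_sd))
  out$bite_force_source <- "measured"
  out
}

#' One-call synthetic dataset
#'
#' Tree, traits, specimen tables, measured bite forces and ground truth,
#' all from one seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed fixing the whole stream.
#' @return List of class `"synthetic_dataset"`: `tree`, `traits`,
#'   `specimens` (muscles + geometry + ground_truth), `measured`,
#'   `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  tree <- simulate_tree(config$n_species, config$birth_rate)
  traits <- simulate_traits(tree, config)
  specimens <- generate_specimens(traits, config)
  measured <- simulate_measured_bite_forces(traits, config$method_offset,
                                            config$measured_noise_sd)
  structure(list(tree = tree, traits = traits, specimens = specimens,
                 measured = measured, config = config, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic parrot dataset: %d species (seed %d)\n",
              nrow(x$traits), x$seed))
  cat(sprintf("  body mass %.3g-%.3g g, calculated bite force %.3g-%.3g N\n",
              min(x$traits$body_mass_g), max(x$traits$body_mass_g),
              min(x$traits$bite_force_N), max(x$traits$bite_force_N)))
  invisible(x)
}
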