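test_that("Yule trees are ultrametric with unit depth and reproducible", {
  tr2 <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(tr2), 2L)
  expect_equal(max(ape::node.depth.edgelength(tr2)), 1)

  tr <- simulate_tree(50, seed = 77)
  expect_equal(ape::Ntip(tr), 50L)
  expect_equal(tr$Nnode, 49L)
  depths <- ape::node.depth.edgelength(tr)[seq_len(50)]
  expect_true(all(abs(depths - 1) < 1e-9))

  expect_identical(ape::write.tree(simulate_tree(12, seed = 5)),
                   ape::write.tree(simulate_tree(12, seed = 5)))
})

test_that("noise-free traits sit exactly on the allometric line", {
  cfg <- sim_config(n_species = 10, brownian_sigma2 = 0,
                    rules = list(skull_mass_g = c(a = -2.11, b = 1.14, sd = 0),
                                 skull_length_mm = c(a = 0.89, b = 0.36, sd = 0),
                                 jaw_muscle_mass_g = c(a = -2.57, b = 1.13, sd = 0),
                                 bite_force_N = c(a = -0.4, b = 0.93, sd = 0),
                                 scar_length_mm = c(a = -0.17, b = 0.42, sd = 0)))
  tr <- simulate_tree(10, seed = 3)
  traits <- simulate_traits(tr, cfg, seed = 3)
  # sigma2 = 0: every species is the root mass
  expect_true(all(abs(traits$body_mass_g - 10^2.6) < 1e-9))
  expect_true(all(abs(log10(traits$skull_mass_g) -
                        (-2.11 + 1.14 * log10(traits$body_mass_g))) < 1e-12))

  # with variation but no residual noise the rule is recovered exactly
  cfg2 <- sim_config(n_species = 60, rules = cfg$rules)
  tr2 <- simulate_tree(60, seed = 4)
  t2 <- simulate_traits(tr2, cfg2, seed = 4)
  f <- lm(log10(skull_mass_g) ~ log10(body_mass_g), t2)
  expect_equal(unname(coef(f)), c(-2.11, 1.14), tolerance = 1e-6)
})

test_that("synthetic specimens reproduce ground-truth bite forces exactly", {
  cfg <- sim_config(n_species = 12)
  ds <- simulate_dataset(cfg, seed = 11)
  res <- compute_bite_forces(ds$specimens$muscles, ds$specimens$geometry)
  rel <- abs(res$bite_force_N - ds$specimens$ground_truth$bite_force_N) /
    ds$specimens$ground_truth$bite_force_N
  expect_lt(max(rel), 1e-9)

  # doubling every muscle mass with areas fixed leaves bite force
  # unchanged: mass cancels in the PCSA chain
  mus2 <- transform(ds$specimens$muscles, wet_mass = 2 * wet_mass)
  res2 <- compute_bite_forces(mus2, ds$specimens$geometry)
  expect_equal(res2$bite_force_N, res$bite_force_N, tolerance = 1e-12)

  # measurement noise breaks exactness on areas (that is its purpose)
  cfgn <- sim_config(n_species = 12, measurement_noise = 0.05)
  dsn <- simulate_dataset(cfgn, seed = 11)
  resn <- compute_bite_forces(dsn$specimens$muscles, dsn$specimens$geometry)
  expect_gt(max(abs(resn$bite_force_N -
                      dsn$specimens$ground_truth$bite_force_N)), 1e-6)
})

test_that("the full dataset stream is deterministic under its seed", {
  d1 <- simulate_dataset(sim_config(n_species = 8), seed = 99)
  d2 <- simulate_dataset(sim_config(n_species = 8), seed = 99)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$traits, d2$traits)
  expect_identical(d1$specimens$muscles, d2$specimens$muscles)
  expect_identical(d1$measured, d2$measured)

  # byte-identical CSV output
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_dataset(d1, dir1); write_dataset(d2, dir2)
  for (f in c("tree.nwk", "traits.csv", "muscles.csv", "geometry.csv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})

test_that("infeasible profiles are rejected", {
  p <- default_muscle_profile()
  p$fraction <- c(1, 0, 0, 0, 0, 0)   # all mass in the abductor
  expect_error(sim_config(muscle_profile = p), "infeasible")
  p2 <- default_muscle_profile()
  p2$fraction[1] <- 0.5
  expect_error(sim_config(muscle_profile = p2), "sum to 1")
})

test_that("round trip: simulated traits recover the bite-force exponent", {
  # forward pipeline (specimens -> bite force -> allometry) recovers the
  # generating exponent within its standard error
  cfg <- sim_config(n_species = 50)
  ds <- simulate_dataset(cfg, seed = 21)
  bf <- compute_bite_forces(ds$specimens$muscles, ds$specimens$geometry)
  traits <- ds$traits
  traits$bite_force_N <- bf$bite_force_N[match(traits$species,
                                               bf$species)]
  rep <- allometry_report(traits, cov = ds$tree)
  row <- rep[rep$predictor == "body_mass", ]
  expect_lt(abs(row$slope - 0.93), 3 * row$slope_se)
})
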