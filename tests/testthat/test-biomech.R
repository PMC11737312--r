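test_that("scale factor and area correction behave as a linear/areal pair", {
  expect_equal(scale_factor(30, 30), 1)
  expect_equal(correct_area(100, scale_factor(30, 30)), 100)
  expect_equal(scale_factor(30, 25), 1.2)
  expect_equal(correct_area(100, 1.2), 144)
  expect_equal(correct_area(100, 1.2, power = 1), 120)
  expect_error(scale_factor(30, 0), "invalid measurement")
  expect_error(scale_factor(-1, 25), "invalid measurement")
})

test_that("volume, thickness and fascicle length follow the stated chain", {
  expect_equal(muscle_volume(0), 0)
  expect_equal(muscle_volume(1.06, 1.06e-3), 1000)
  expect_equal(muscle_volume(2.7), 2547.1698, tolerance = 1e-6)
  expect_error(muscle_volume(-1), "invalid measurement")

  expect_equal(muscle_thickness(1000, 100), 10)
  expect_equal(muscle_thickness(400, 400), 1)
  expect_equal(muscle_thickness(2547.17, 400), 6.3679, tolerance = 1e-4)
  expect_error(muscle_thickness(10, 0), "invalid measurement")

  expect_equal(fascicle_length(0), 0)
  expect_equal(fascicle_length(sin(pi / 4)), 1)
  expect_equal(fascicle_length(10), 14.1421, tolerance = 1e-4)
  expect_error(fascicle_length(1, 0), "fascicle_angle")
})

test_that("PCSA formula, force and the mass-cancellation identity hold", {
  # cos(pi/2) = 0 within fp error; use a pennation just below the bound
  expect_equal(pcsa(1, pi / 2 - 1e-12, 1.06e-3, 10), 0, tolerance = 1e-10)
  expect_error(pcsa(1, pi / 2, 1.06e-3, 10), "pennation")
  expect_equal(pcsa(1.06, 0, 1.06e-3, 14.142136), 70.7107, tolerance = 1e-4)
  expect_error(pcsa(1, 0, 1.06e-3, 0), "invalid measurement")

  expect_equal(muscle_force(0), 0)
  expect_equal(muscle_force(100), 30)
  expect_equal(muscle_force(70.711), 21.2133)

  # identity: PCSA derived through the thickness chain equals
  # A * sin(fascicle angle) * cos(pennation); mass and density cancel
  set.seed(11)
  for (i in 1:1000) {
    m <- runif(1, 1e-3, 20); A <- runif(1, 5, 2000)
    th <- runif(1, 0, 0.95 * pi / 2)
    fl <- fascicle_length(muscle_thickness(muscle_volume(m), A))
    got <- pcsa(m, th, 1.06e-3, fl)
    want <- A * sin(pi / 4) * cos(th)
    expect_lt(abs(got - want) / want, 1e-12)
  }
})

test_that("moment arms and torque match hand values", {
  expect_equal(mean_moment_arm(c(1, 2, 3)), 2)
  expect_equal(mean_moment_arm(c(7, 7, 7)), 7)
  expect_equal(mean_moment_arm(c(10, 12, 14)), 12)
  expect_equal(mean_moment_arm(rbind(c(1, 2, 3), c(10, 12, 14))), c(2, 12))
  expect_error(mean_moment_arm(c(1, 2)), "three")
  expect_error(mean_moment_arm(c(-1, 2, 3)), "invalid measurement")

  expect_equal(muscle_torque(10, 21.213, 0), 0)
  expect_equal(muscle_torque(10, 21.213, pi / 2), 212.13)
  expect_equal(muscle_torque(10, 21.213, pi / 6),
               muscle_torque(10, 21.213, pi / 2) / 2)
  expect_error(muscle_torque(10, 1, -0.1), "loa_angle")
})

test_that("specimen bite force sums adductor torques over the out-lever", {
  sp <- one_muscle_specimen()   # torque 212.132 N.mm, out-lever 50 mm
  b <- bite_force(sp$muscles, sp$geometry)
  expect_s3_class(b, "bite_force")
  expect_equal(b$bite_force, 2 * 212.13203 / 50, tolerance = 1e-6)

  # abductors are reported but excluded
  m2 <- rbind(sp$muscles,
              transform(sp$muscles, muscle = "DM", role = "abductor"))
  b2 <- bite_force(m2, sp$geometry)
  expect_equal(b2$bite_force, b$bite_force)
  expect_equal(nrow(b2$per_muscle), 2L)
  expect_false(b2$per_muscle$contributes[b2$per_muscle$role == "abductor"])

  # duplicating every adductor doubles the force (linearity)
  m3 <- rbind(sp$muscles, transform(sp$muscles, muscle = "EM2"))
  expect_equal(bite_force(m3, sp$geometry)$bite_force, 2 * b$bite_force)

  # no adductors -> 0 N with a warning
  mab <- transform(sp$muscles, role = "abductor")
  expect_warning(b0 <- bite_force(mab, sp$geometry), "no adductor")
  expect_equal(b0$bite_force, 0)

  expect_error(bite_force(sp$muscles, list(out_lever = 0, sf = 1)),
               "out_lever")
  expect_error(bite_force(rbind(sp$muscles, sp$muscles), sp$geometry),
               "unique")
})

test_that("bite force scales correctly under geometric rescaling", {
  mus <- random_muscles(6, seed = 21)
  geo <- list(out_lever = 40, sf = 1.1)
  b <- bite_force(mus, geo)$bite_force

  # scaling only the out-lever by k divides the force by k
  b_k <- bite_force(mus, list(out_lever = 80, sf = 1.1))$bite_force
  expect_equal(b_k, b / 2)

  # scaling all moment arms and the out-lever by k, areas fixed,
  # leaves the force unchanged (arms cancel against the lever)
  mus_k <- transform(mus, arm1 = 3 * arm1, arm2 = 3 * arm2, arm3 = 3 * arm3)
  b_s <- bite_force(mus_k, list(out_lever = 3 * 40, sf = 1.1))$bite_force
  expect_equal(b_s, b)
})

test_that("bite force is monotone in pennation and adductor area", {
  sp <- one_muscle_specimen()
  pens <- seq(0, 0.95 * pi / 2, length.out = 12)
  bfs <- vapply(pens, function(th) {
    bite_force(transform(sp$muscles, pennation = th), sp$geometry)$bite_force
  }, numeric(1))
  expect_true(all(diff(bfs) <= 0))

  areas <- seq(50, 500, length.out = 10)
  bfa <- vapply(areas, function(a) {
    bite_force(transform(sp$muscles, surface_area = a),
               sp$geometry)$bite_force
  }, numeric(1))
  expect_true(all(diff(bfa) > 0))
})

test_that("pipeline agrees with a naive brute-force recomputation", {
  for (seed in c(3, 17, 99)) {
    mus <- random_muscles(6, seed = seed)
    out_lever <- runif(1, 20, 80)
    sf <- runif(1, 0.9, 1.3)
    got <- bite_force(mus, list(out_lever = out_lever, sf = sf))$bite_force
    want <- brute_force_bite_force(mus, out_lever, sf)
    expect_lt(abs(got - want) / want, 1e-9)
  }
})

test_that("side-averaged specimens match pre-averaged muscle masses", {
  base <- random_muscles(3, seed = 5)
  left <- transform(base, specimen_id = "s1", species = "sp", side = "left")
  right <- transform(base, specimen_id = "s1", species = "sp", side = "right",
                     surface_area = surface_area * 1.5)
  two_sided <- rbind(left, right)
  mean_side <- transform(base, specimen_id = "s1", species = "sp",
                         side = "mean", surface_area = surface_area * 1.25)
  geo <- data.frame(specimen_id = "s1", out_lever = 40,
                    physical_ref = 30, digital_ref = 28)
  r2 <- compute_bite_forces(two_sided, geo)
  r1 <- compute_bite_forces(mean_side, geo)
  expect_equal(r2$bite_force_N, r1$bite_force_N)
})
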