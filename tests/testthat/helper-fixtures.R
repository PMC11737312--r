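# Shared fixtures, all built in code.

# hand-built 5-tip tree with known shared branch lengths
hand_tree5 <- function() {
  read_newick(text = "(((A:1,B:1):1,(C:1.5,D:1.5):0.5):1,E:3);")
}

# one-adductor specimen whose chain is easy to follow by hand
one_muscle_specimen <- function(wet_mass = 1.06, area = 100, pennation = 0,
                                loa = pi / 2, arm = 10) {
  list(
    muscles = data.frame(muscle = "EM", role = "adductor",
                         wet_mass = wet_mass, surface_area = area,
                         pennation = pennation, loa = loa,
                         arm1 = arm, arm2 = arm, arm3 = arm),
    geometry = list(out_lever = 50, sf = 1)
  )
}

# random but valid muscle table, n muscles
random_muscles <- function(n, seed) {
  set.seed(seed)
  data.frame(
    muscle = paste0("m", seq_len(n)),
    role = sample(c("adductor", "abductor"), n, replace = TRUE,
                  prob = c(0.8, 0.2)),
    wet_mass = runif(n, 0.05, 12),
    surface_area = runif(n, 20, 900),
    pennation = runif(n, 0, 0.9 * pi / 2),
    loa = runif(n, 0.1, pi - 0.1),
    arm1 = runif(n, 1, 30), arm2 = runif(n, 1, 30), arm3 = runif(n, 1, 30)
  )
}

# naive re-derivation of bite force from raw fields, no package internals
brute_force_bite_force <- function(muscles, out_lever, sf,
                                   density = 1.06e-3, stress = 0.3,
                                   fasc = pi / 4, bilat = 2) {
  tot <- 0
  for (i in seq_len(nrow(muscles))) {
    if (muscles$role[i] != "adductor") next
    A <- muscles$surface_area[i] * sf^2
    V <- muscles$wet_mass[i] / density
    l <- (V / A) / sin(fasc)
    P <- muscles$wet_mass[i] * cos(muscles$pennation[i]) / (density * l)
    Fm <- stress * P
    r <- mean(c(muscles$arm1[i], muscles$arm2[i], muscles$arm3[i]))
    tot <- tot + r * Fm * sin(muscles$loa[i])
  }
  bilat * tot / out_lever
}
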