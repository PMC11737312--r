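test_that("Brownian covariance equals shared branch lengths", {
  # two-tip cherry
  C2 <- brownian_covariance(read_newick(text = "(A:1,B:1);"))$C
  expect_equal(unname(C2), rbind(c(1, 0), c(0, 1)))

  # hand tree: C[A,B] = 1, C[A,C] = 0, diagonal = depth 2
  C3 <- brownian_covariance(read_newick(text = "((A:1,B:1):1,C:2);"))$C
  expect_equal(unname(diag(C3)), c(2, 2, 2))
  expect_equal(C3["A", "B"], 1)
  expect_equal(C3["A", "C"], 0)

  # star tree: diagonal matrix
  Cs <- brownian_covariance(read_newick(text = "(A:1,B:1,C:1,D:1);"))$C
  expect_equal(unname(Cs), diag(4))

  # richer hand tree, every entry checked
  C5 <- brownian_covariance(hand_tree5())$C
  expect_equal(unname(diag(C5)), rep(3, 5))
  expect_equal(C5["A", "B"], 2)
  expect_equal(C5["C", "D"], 1.5)
  expect_equal(C5["A", "C"], 1)
  expect_equal(C5["A", "E"], 0)

  expect_error(brownian_covariance(ape::rtree(4, br = NULL)),
               "branch lengths")
})

test_that("PGLS with lambda 0 is OLS and lambda 1 matches brute-force GLS", {
  pc <- brownian_covariance(hand_tree5())
  set.seed(42)
  d <- data.frame(species = pc$tip_order, x = rnorm(5))
  d$y <- 1 + 2 * d$x + rnorm(5, sd = 0.3)

  f0 <- pgls(y ~ x, d, cov = pc, lambda = 0)
  ols <- lm(y ~ x, d)
  expect_lt(max(abs(coef(f0) - coef(ols))), 1e-10)
  expect_lt(max(abs(f0$se - summary(ols)$coefficients[, 2])), 1e-10)
  expect_equal(f0$r.squared, summary(ols)$r.squared, tolerance = 1e-10)

  # brute-force GLS with explicit matrix inversion
  f1 <- pgls(y ~ x, d, cov = pc, lambda = 1)
  X <- cbind(1, d$x)
  Vi <- solve(pc$C)
  beta <- solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% d$y
  expect_equal(unname(coef(f1)), drop(beta), tolerance = 1e-12)
  e <- d$y - X %*% beta
  s2 <- drop(t(e) %*% Vi %*% e) / 3
  expect_equal(unname(f1$se),
               sqrt(diag(s2 * solve(t(X) %*% Vi %*% X))), tolerance = 1e-10)
})

test_that("PGLS equals OLS on a star tree for any lambda", {
  star <- read_newick(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  set.seed(8)
  d <- data.frame(species = LETTERS[1:6], x = rnorm(6))
  d$y <- 0.5 + 1.4 * d$x + rnorm(6)
  for (lam in c(0, 0.5, 1)) {
    f <- pgls(y ~ x, d, cov = star, lambda = lam)
    expect_lt(max(abs(coef(f) - coef(lm(y ~ x, d)))), 1e-10)
  }
})

test_that("PGLS agrees with nlme::gls under corPagel at fixed lambda", {
  skip_if_not_installed("nlme")
  pc <- brownian_covariance(hand_tree5())
  set.seed(3)
  d <- data.frame(species = pc$tip_order, x = rnorm(5))
  d$y <- 2 + 0.8 * d$x + rnorm(5, sd = 0.2)
  for (lam in c(0.25, 0.7)) {
    ours <- pgls(y ~ x, d, cov = pc, lambda = lam)
    ref <- nlme::gls(y ~ x, d,
                     correlation = ape::corPagel(lam, pc$tree, fixed = TRUE,
                                                 form = ~species))
    expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 1e-8)
    expect_equal(unname(ours$se),
                 unname(sqrt(diag(ref$varBeta))), tolerance = 1e-8)
  }
})

test_that("ML lambda profiling is invariant to tip reordering", {
  set.seed(19)
  tr <- simulate_tree(20, seed = 19)
  pc <- brownian_covariance(tr)
  d <- data.frame(species = pc$tip_order, x = rnorm(20))
  bm <- drop(t(chol(0.5 * pc$C)) %*% rnorm(20))
  d$y <- 1 + 0.9 * d$x + bm
  f <- pgls(y ~ x, d, cov = pc)
  d2 <- d[sample(nrow(d)), ]
  f2 <- pgls(y ~ x, d2, cov = pc)
  expect_equal(f$lambda, f2$lambda, tolerance = 1e-6)
  expect_equal(coef(f), coef(f2), tolerance = 1e-8)

  # the profiled likelihood is finite and continuous across [0, 1]
  lls <- vapply(seq(0, 1, by = 0.05), function(l)
    pgls(y ~ x, d, cov = pc, lambda = l)$logLik, numeric(1))
  expect_true(all(is.finite(lls)))
  expect_lt(max(abs(diff(lls))), 10)
})

test_that("PGLS slope is unbiased under Brownian residuals (recovery)", {
  # y = a + b x + Brownian noise on Yule trees; slope should be recovered
  set.seed(2024)
  nrep <- 60
  slopes <- numeric(nrep)
  lambdas <- numeric(nrep)
  for (r in seq_len(nrep)) {
    tr <- simulate_tree(30)
    pc <- brownian_covariance(tr)
    x <- rnorm(30)
    y <- 1 + 0.75 * x + drop(t(chol(0.3 * pc$C)) %*% rnorm(30))
    f <- pgls(y ~ x, data.frame(species = pc$tip_order, x = x, y = y),
              cov = pc)
    slopes[r] <- coef(f)[2]
    lambdas[r] <- f$lambda
  }
  expect_lt(abs(mean(slopes) - 0.75), 0.03)
  expect_gt(mean(lambdas), 0.7)   # lambda-hat concentrates near 1
})

test_that("species alignment normalises labels and warns on drops", {
  pc <- brownian_covariance(read_newick(text = "((A_a:1,B_b:1):1,C_c:2);"))
  d <- data.frame(species = c("C c", "a_A", "B_B", "X_x"),
                  y = c(3, 1, 2, 9), x = c(1, 2, 3, 4))
  expect_warning(al <- align_to_tips(d, pc$tip_order), "X_x")
  expect_equal(al$y, c(1, 2, 3))
  expect_error(pgls(y ~ x, d[4, , drop = FALSE], cov = pc), "at least 3|common")
})
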