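test_that("bounds are the per-probe training min/max and flag degenerate probes", {
  m <- matrix(c(2, 5, 8,
                4, 4, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("pA", "pB"), c("s1", "s2", "s3")))
  b <- fit_bounds(m)
  expect_equal(unname(b$min), c(2, 4))
  expect_equal(unname(b$max), c(8, 4))
  expect_equal(unname(b$degenerate), c(FALSE, TRUE))

  # bounds come from the supplied (training) samples only: a larger value in
  # a sample not passed in does not move them
  b13 <- fit_bounds(m[, c("s1", "s2"), drop = FALSE])
  expect_equal(unname(b13$max[1]), 5)

  expect_error(fit_bounds(m[, 1, drop = FALSE]), "2 training samples")
  m[1, ] <- NA
  expect_error(fit_bounds(m), "pA")
})

test_that("standardization maps the training range onto [0,1], clips, and fixes degenerate probes at 0.5", {
  m <- matrix(c(2, 5, 8), nrow = 1, dimnames = list("pA", NULL))
  b <- fit_bounds(m)
  z <- standardize(m, b)
  expect_equal(unname(z[1, ]), c(0, 0.5, 1))
  # out-of-range deployment values are clipped
  expect_equal(unname(standardize(c(pA = 9), b)), 1)
  expect_equal(unname(standardize(c(pA = -3), b)), 0)

  # degenerate probe -> 0.5 for any value; NA preserved
  m2 <- rbind(m, pB = c(4, 4, 4))
  b2 <- fit_bounds(m2)
  z2 <- standardize(rbind(pA = c(2, NA), pB = c(7, NA)), b2)
  expect_equal(unname(z2[, 1]), c(0, 0.5))
  expect_true(all(is.na(z2[, 2])))
})

test_that("standardize round-trips min to 0 and max to 1 for every probe", {
  set.seed(11)
  x <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("p%02d", 1:20), NULL))
  b <- fit_bounds(x)
  z <- standardize(x, b)
  expect_true(all(z >= 0 & z <= 1))
  expect_equal(unname(apply(z, 1, min)), rep(0, 20))
  expect_equal(unname(apply(z, 1, max)), rep(1, 20))
})

test_that("binomial membership matches its closed form and stays in (0,1]", {
  xs <- seq(0, 1, by = 0.05)
  expect_equal(membership_binomial(xs, 0.5), rep(0.5, length(xs)))
  expect_equal(membership_binomial(1, 0.8), 0.8)
  expect_equal(membership_binomial(0.5, 0.8), sqrt(0.8 * 0.2))
  # direct power-form oracle on a grid, away from the clamp region
  for (rho in c(0.1, 0.37, 0.92)) {
    expect_equal(membership_binomial(xs, rho),
                 rho^xs * (1 - rho)^(1 - xs), tolerance = 1e-12)
  }
  # extreme prototypes are clamped rather than degenerate
  expect_true(all(membership_binomial(xs, 0) > 0))
  expect_true(all(membership_binomial(xs, 1) > 0))
  expect_true(all(membership_binomial(c(0, 1), c(0, 1)) <= 1))
})

test_that("binomial membership is monotone in x, increasing iff rho > 0.5", {
  xs <- seq(0, 1, by = 0.01)
  expect_true(all(diff(membership_binomial(xs, 0.8)) > 0))
  expect_true(all(diff(membership_binomial(xs, 0.2)) < 0))
})

test_that("gaussian membership peaks at the center, hits exp(-1/2) one spread out, and is symmetric", {
  expect_equal(membership_gaussian(0.4, 0.4, 0.1), 1)
  expect_equal(membership_gaussian(0.5, 0.4, 0.1), exp(-0.5))
  d <- seq(0, 0.3, by = 0.05)
  expect_equal(membership_gaussian(0.5 + d, 0.5, 0.07),
               membership_gaussian(0.5 - d, 0.5, 0.07))
  expect_error(membership_gaussian(0.5, 0.5, 0), "spread")
})

test_that("membership parameters are class means (and floored SDs) of standardized data", {
  xs <- matrix(c(0, 1, 0.8, 0.9,
                 0.1, 0.2, 0.8, 0.9), nrow = 2, byrow = TRUE,
               dimnames = list(c("pA", "pB"), NULL))
  cls <- c("1", "1", "3", "3")
  pb <- fit_membership_params(xs, cls, "binomial")
  expect_equal(pb$params$fMG1$rho, c(pA = 0.5, pB = 0.15))
  expect_equal(pb$params$fMG3$rho, c(pA = 0.85, pB = 0.85))

  pg <- fit_membership_params(xs, cls, "gaussian")
  expect_equal(pg$params$fMG1$mu, c(pA = 0.5, pB = 0.15))
  expect_equal(unname(pg$params$fMG1$sigma["pB"]), sd(c(0.1, 0.2)))
  # zero-variance class values hit the spread floor
  xs2 <- rbind(pC = c(0.7, 0.7, 0.7, 0.7))
  pg2 <- fit_membership_params(xs2, cls, "gaussian")
  expect_equal(unname(pg2$params$fMG1$mu), 0.7)
  expect_equal(unname(pg2$params$fMG1$sigma), 0.01)

  expect_error(fit_membership_params(xs[, 1:3], c("1", "1", "3"), "binomial"),
               "at least 2")
})

test_that("fuzzification is probe-wise: permuting probe order permutes memberships identically", {
  set.seed(3)
  x <- matrix(runif(60, 2, 10), 6, 10,
              dimnames = list(sprintf("p%d", 1:6), NULL))
  cls <- rep(c("1", "3"), each = 5)
  b <- fit_bounds(x)
  prm <- fit_membership_params(standardize(x, b), cls, "binomial")
  m <- fuzzygrade:::membership_matrix(standardize(x, b), prm, "fMG3")
  perm <- c(4, 2, 6, 1, 3, 5)
  xp <- x[perm, ]
  bp <- fit_bounds(xp)
  prmp <- fit_membership_params(standardize(xp, bp), cls, "binomial")
  mp <- fuzzygrade:::membership_matrix(standardize(xp, bp), prmp, "fMG3")
  expect_equal(mp, m[perm, ])
})
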