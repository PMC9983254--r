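sphere_residuals <- function(sphere, pts) {
  sqrt(rowSums(sweep(pts, 2L, sphere$center)^2)) - sphere$radius
}

test_that("fit_sphere_linear recovers exact spheres and rejects degeneracy", {
  # symmetric unit-sphere sextet
  sextet <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  fit <- fit_sphere_linear(sextet)
  expect_equal(fit$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$radius, 1, tolerance = 1e-12)

  # 20 noise-free points, centre (10,-5,3), R = 50, hemispheric-plus spread
  set.seed(61)
  pts <- on_sphere(20L, c(10, -5, 3), 50)
  fit20 <- fit_sphere_linear(pts)
  expect_lt(max(abs(fit20$center - c(10, -5, 3))), 1e-9)
  expect_lt(abs(fit20$radius - 50), 1e-9)
  expect_lt(max(abs(sphere_residuals(fit20, pts))), 1e-9)

  # planar circle: rank-deficient design (verified: 4th singular value ~ 0)
  ang <- seq(0, 2 * pi, length.out = 13L)[-13L]
  circle <- cbind(7 + 3 * cos(ang), -2 + 3 * sin(ang), 5)
  expect_lt(svd(cbind(1, circle))$d[4L] / svd(cbind(1, circle))$d[1L], 1e-12)
  expect_error(fit_sphere_linear(circle), "degenerate")
  expect_error(fit_sphere_linear(circle[1:3, ]), "at least 4")
})

test_that("enumerate_4pt_combinations is complete, ordered and capped", {
  expect_identical(nrow(enumerate_4pt_combinations(5)), 5L)   # C(5,4)
  expect_identical(enumerate_4pt_combinations(4), matrix(1:4, 1L))
  c6 <- enumerate_4pt_combinations(6)
  expect_identical(nrow(c6), 15L)                             # C(6,4)
  expect_identical(c6, t(combn(6, 4)))                        # lexicographic
  expect_error(enumerate_4pt_combinations(3), "n >= 4")

  # seeded subsample above the cap: right size, valid, deterministic
  sub1 <- enumerate_4pt_combinations(60, max_combinations = 500L, seed = 9L)
  sub2 <- enumerate_4pt_combinations(60, max_combinations = 500L, seed = 9L)
  expect_identical(sub1, sub2)
  expect_identical(nrow(sub1), 500L)
  expect_identical(nrow(unique(sub1)), 500L)
  expect_true(all(sub1[, 1] < sub1[, 2] & sub1[, 2] < sub1[, 3] &
                    sub1[, 3] < sub1[, 4]))
})

test_that("fit_sphere_4pt solves exact quadruples and flags degenerate ones", {
  quad <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  fit <- fit_sphere_4pt(quad)
  expect_true(fit$valid)
  expect_equal(fit$sphere$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$sphere$radius, 1, tolerance = 1e-12)
  # back-substitution identity p -> sphere
  expect_equal(fit$sphere$center, -fit$p[2:4] / 2, tolerance = 1e-12)
  expect_equal(fit$sphere$radius^2, sum(fit$sphere$center^2) - fit$p[1L],
               tolerance = 1e-12)

  coplanar <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_false(fit_sphere_4pt(coplanar)$valid)

  set.seed(71)
  for (rep in 1:25) {
    pts <- on_sphere(4L, c(2, 3, 4), 7)
    f <- fit_sphere_4pt(pts)
    expect_true(f$valid)
    # oracle: all four residuals vanish
    expect_lt(max(abs(sphere_residuals(f$sphere, pts))), 1e-8)
    expect_lt(max(abs(f$sphere$center - c(2, 3, 4))), 1e-6)
  }
})

test_that("fit_sphere_linear on exactly 4 points equals fit_sphere_4pt", {
  set.seed(81)
  for (rep in 1:10) {
    pts <- on_sphere(4L, rnorm(3L, sd = 10), runif(1L, 20, 80))
    f4 <- fit_sphere_4pt(pts)
    if (!f4$valid) next
    fl <- fit_sphere_linear(pts)
    expect_equal(fl$center, f4$sphere$center, tolerance = 1e-8)
    expect_equal(fl$radius, f4$sphere$radius, tolerance = 1e-8)
  }
})

test_that("batch quadruple solver agrees with the single-quadruple route", {
  set.seed(91)
  pts <- on_sphere(9L, c(-4, 2, 11), 35) + matrix(rnorm(27L, sd = 0.3), 9L)
  report <- fit_sphere_robust(pts, iterations = 1L, k_sd = 100)
  combos <- report$combinations
  for (k in sample(nrow(combos), 20L)) {
    f <- fit_sphere_4pt(pts[combos[k, ], ])
    if (f$valid) {
      expect_equal(unname(report$params[k, 1:3]), f$sphere$center,
                   tolerance = 1e-8)
      expect_equal(unname(report$params[k, 4L]), f$sphere$radius,
                   tolerance = 1e-8)
    } else {
      expect_true(all(is.na(report$params[k, ])))
    }
  }
})

test_that("robust fit: zero-variance ensemble on exact data", {
  set.seed(101)
  pts <- on_sphere(10L, c(10, -5, 3), 50)
  report <- fit_sphere_robust(pts)
  expect_equal(report$param_sd, c(x_m = 0, y_m = 0, z_m = 0, R = 0),
               tolerance = 1e-6)
  expect_lt(max(abs(report$final$center - c(10, -5, 3))), 1e-6)
  expect_lt(abs(report$final$radius - 50), 1e-6)
  expect_true(report$spherical)
  expect_true(assess_sphericity(report, tol = 1e-3))
})

test_that("robust fit beats the naive linear fit under gross outliers", {
  set.seed(111)
  truth <- c(10, -5, 3)
  pts <- on_sphere(12L, truth, 50)
  out <- add_outliers(point_set(pts, "ARAMIS"), count = 2L, magnitude = 20,
                      seed = 5L)
  robust <- fit_sphere_robust(out)
  naive <- fit_sphere_linear(out)
  err_robust <- sqrt(sum((robust$final$center - truth)^2))
  err_naive <- sqrt(sum((naive$center - truth)^2))
  expect_lt(err_robust, 0.5)
  expect_gt(err_naive, err_robust)
})

test_that("robust-fit invariants: survivors shrink, means match masks, scale", {
  set.seed(121)
  pts <- on_sphere(14L, c(0, 0, 100), 40) + matrix(rnorm(42L, sd = 0.5), 14L)
  report <- fit_sphere_robust(pts, k_sd = 1, iterations = 4L)
  counts <- vapply(report$survivor_mask_per_iteration, sum, integer(1L))
  expect_true(all(diff(counts) <= 0))
  last <- report$survivor_mask_per_iteration[[length(counts)]]
  expect_identical(report$n_survivors, sum(last))
  expect_equal(report$final$center,
               unname(colMeans(report$params[last, 1:3, drop = FALSE])),
               tolerance = 1e-12)
  expect_equal(report$final$radius,
               mean(report$params[last, 4L]), tolerance = 1e-12)

  # scale equivariance: scaling points by s scales centre and radius by s
  r2 <- fit_sphere_robust(pts * 2.5, k_sd = 1, iterations = 4L)
  expect_equal(r2$final$center, 2.5 * report$final$center, tolerance = 1e-6)
  expect_equal(r2$final$radius, 2.5 * report$final$radius, tolerance = 1e-6)
})

test_that("sphericity assessment separates spheres from ellipsoids", {
  fake <- structure(list(param_sd = c(0.2, 0.2, 0.2, 0.3)),
                    class = "robust_fit_report")
  expect_false(assess_sphericity(fake, tol = 0.25))
  expect_true(assess_sphericity(fake, tol = 0.35))

  # ellipsoidal trajectory (50/50/70 axes): not a sphere at 1 mm tolerance
  set.seed(131)
  u <- on_sphere(40L, c(0, 0, 0), 1)
  ell <- sweep(u, 2L, c(50, 50, 70), "*")
  rep_ell <- fit_sphere_robust(ell, max_combinations = 20000L, seed = 3L)
  expect_false(assess_sphericity(rep_ell, tol = 1))
})

test_that("robust fit refuses unusable input", {
  expect_error(fit_sphere_robust(on_sphere(4L, c(0, 0, 0), 10)), "n >= 5")
  flat <- cbind(matrix(runif(24L), 12L), 0)
  expect_error(fit_sphere_robust(flat), "no solvable quadruples")
  expect_error(fit_sphere_robust(on_sphere(8L, c(0, 0, 0), 10), k_sd = 0),
               "k_sd")
})
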