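test_that("zero_shift subtracts the first sample and records the anchor", {
  ps <- point_set(rbind(c(1, 2, 3), c(4, 6, 8)), "ROBOT")
  z <- zero_shift(ps)
  expect_identical(z$points, rbind(c(0, 0, 0), c(3, 4, 5)))
  expect_identical(z$anchor, c(1, 2, 3))
  expect_true(z$zeroed)

  single <- zero_shift(point_set(c(5, 5, 5), "ARAMIS"))
  expect_identical(single$points, matrix(0, 1L, 3L))
  expect_identical(single$anchor, c(5, 5, 5))

  expect_error(zero_shift(z), "already zeroed")
})

test_that("point_set validates its invariants", {
  expect_error(point_set(c(1, NA, 3), "ROBOT"), "finite")
  expect_error(point_set(rbind(c(0, 0, 0), c(1, 1, 1)), "ROBOT",
                         pose_index = c(2L, 2L)), "unique")
  expect_error(point_set(c(1, 2, 3), "ROBOT", anchor = c(0, 0, 0)),
               "zeroed")
})

test_that("estimate_transform recovers known maps", {
  # identity: target = source
  src <- zero_shift(point_set(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                    c(0, 0, 1), c(2, 3, 1)), "ARAMIS"))
  tgt <- point_set(src$points, "ROBOT", zeroed = TRUE, anchor = c(0, 0, 0))
  t_id <- estimate_transform(tgt, src)
  expect_equal(t_id$linear_map, diag(3), tolerance = 1e-12)
  expect_equal(t_id$residual_rms, 0, tolerance = 1e-12)

  # 90 degree rotation about z: solved by hand, map = [[0,-1,0],[1,0,0],[0,0,1]]
  rz90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  tgt90 <- point_set(src$points %*% t(rz90), "ROBOT",
                     zeroed = TRUE, anchor = c(0, 0, 0))
  t90 <- estimate_transform(tgt90, src)
  expect_equal(t90$linear_map, rz90, tolerance = 1e-12)

  # 10 random non-coplanar points under a random rotation, no noise
  set.seed(11)
  rot <- rand_rotation()
  pts <- matrix(runif(30L, -100, 100), 10L)
  pts[1L, ] <- 0
  src10 <- point_set(pts, "ARAMIS", zeroed = TRUE, anchor = c(1, 2, 3))
  tgt10 <- point_set(pts %*% t(rot), "ROBOT", zeroed = TRUE, anchor = c(9, 8, 7))
  fit <- estimate_transform(tgt10, src10)
  expect_lt(max(abs(fit$linear_map - rot)), 1e-9)
  # noise-free rigid data: estimate is orthogonal
  expect_lt(max(abs(crossprod(fit$linear_map) - diag(3))), 1e-9)
})

test_that("estimate_transform rejects degenerate and undersized geometry", {
  planar <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0), c(4, 0, 0))
  src <- point_set(planar, "ARAMIS", zeroed = TRUE, anchor = c(0, 0, 0))
  tgt <- point_set(planar, "ROBOT", zeroed = TRUE, anchor = c(0, 0, 0))
  expect_error(estimate_transform(tgt, src), "degenerate")

  three <- point_set(diag(3), "ARAMIS")
  expect_error(
    estimate_transform(zero_shift(three), zero_shift(three)),
    "at least 4")
  expect_error(estimate_transform(zero_shift(point_set(diag(3), "ROBOT")),
                                  three),
               "must be zeroed")
})

test_that("estimator matches independent least-squares oracles", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(4:10, 1L)
    pts <- matrix(runif(3L * n, -50, 50), n)
    pts[1L, ] <- 0
    map_true <- matrix(rnorm(9L), 3L)
    noise <- matrix(rnorm(3L * n, sd = 0.05), n)
    tgt_pts <- pts %*% t(map_true) + noise
    tgt_pts[1L, ] <- 0
    src <- point_set(pts, "A", zeroed = TRUE, anchor = c(0, 0, 0))
    tgt <- point_set(tgt_pts, "B", zeroed = TRUE, anchor = c(0, 0, 0))
    fit <- tryCatch(estimate_transform(tgt, src), error = function(e) NULL)
    if (is.null(fit)) next  # oracle equivalence only defined when solvable
    expect_lt(max(abs(fit$linear_map - lstsq_map_oracle(tgt_pts, pts))), 1e-10)
    expect_lt(max(abs(fit$linear_map - lstsq_map_qr(tgt_pts, pts))), 1e-7)
  }
})

test_that("equivariance: rotating all targets pre-multiplies the map", {
  set.seed(31)
  pts <- matrix(runif(24L, -50, 50), 8L); pts[1L, ] <- 0
  rot <- rand_rotation()
  q <- rand_rotation()
  src <- point_set(pts, "A", zeroed = TRUE, anchor = c(0, 0, 0))
  tgt1 <- point_set(pts %*% t(rot), "B", zeroed = TRUE, anchor = c(0, 0, 0))
  tgt2 <- point_set(pts %*% t(rot) %*% t(q), "B", zeroed = TRUE,
                    anchor = c(0, 0, 0))
  m1 <- estimate_transform(tgt1, src)$linear_map
  m2 <- estimate_transform(tgt2, src)$linear_map
  expect_lt(max(abs(m2 - q %*% m1)), 1e-9)
})

test_that("invert_transform reverses direction and round-trips", {
  rz90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  tr <- frame_transform(rz90, source_anchor = c(1, 2, 3),
                        target_anchor = c(-4, 5, 6),
                        source_frame = "ARAMIS", target_frame = "ROBOT")
  inv <- invert_transform(tr)
  expect_identical(inv$direction, "ROBOT->ARAMIS")
  expect_equal(inv$linear_map, t(rz90), tolerance = 1e-12)  # rotation inverse
  expect_identical(inv$source_anchor, c(-4, 5, 6))

  set.seed(41)
  for (rep in 1:20) {
    m <- matrix(rnorm(9L), 3L) + 3 * diag(3)  # well-conditioned
    tr <- frame_transform(m, rnorm(3L), rnorm(3L), "A", "B")
    expect_lt(max(abs(tr$linear_map %*% invert_transform(tr)$linear_map -
                        diag(3))), 1e-9)
    pts <- point_set(matrix(rnorm(30L, sd = 100), 10L), "A")
    back <- apply_transform(invert_transform(tr), apply_transform(tr, pts))
    expect_lt(max(abs(back$points - pts$points)), 1e-9)
  }
  expect_error(invert_transform(frame_transform(
    matrix(0, 3L, 3L) + outer(1:3, 1:3), c(0, 0, 0), c(0, 0, 0), "A", "B")),
    "singular")
})

test_that("apply_transform anchors, maps and checks frames", {
  tr <- frame_transform(diag(3), c(0, 0, 0), c(0, 0, 0), "ARAMIS", "ROBOT")
  pts <- point_set(rbind(c(1, 2, 3), c(4, 5, 6)), "ARAMIS")
  moved <- apply_transform(tr, pts)
  expect_equal(moved$points, pts$points)
  expect_identical(moved$frame, "ROBOT")
  expect_error(apply_transform(tr, moved), "frame mismatch")

  # anchored affine action: target_anchor + map (p - source_anchor)
  rz90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  tr2 <- frame_transform(rz90, c(1, 1, 1), c(10, 0, 0), "ARAMIS", "ROBOT")
  out <- apply_transform(tr2, point_set(c(2, 1, 1), "ARAMIS"))
  expect_equal(as.numeric(out$points), c(10, 1, 0))
})

test_that("orthogonalized estimate is a proper rotation under noise", {
  set.seed(51)
  rot <- rand_rotation()
  pts <- matrix(runif(36L, -100, 100), 12L); pts[1L, ] <- 0
  noisy <- pts %*% t(rot) + matrix(rnorm(36L, sd = 0.5), 12L)
  noisy[1L, ] <- 0
  src <- point_set(pts, "A", zeroed = TRUE, anchor = c(0, 0, 0))
  tgt <- point_set(noisy, "B", zeroed = TRUE, anchor = c(0, 0, 0))
  plain <- estimate_transform(tgt, src)
  ortho <- estimate_transform(tgt, src, orthogonalize = TRUE)
  expect_gt(max(abs(crossprod(plain$linear_map) - diag(3))), 1e-6)
  expect_lt(max(abs(crossprod(ortho$linear_map) - diag(3))), 1e-12)
  expect_equal(det(ortho$linear_map), 1, tolerance = 1e-12)
})
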