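#' Define a synthetic rig scenario
#'
#' Fixes every ground-truth quantity of a simulated test rig: the hidden rigid
#' motion linking the optical and robot world frames, the joint rotation
#' centre, the tool (femur-plus-holder) length, marker noise, the stage-II
#' calibration pose schedule, the physiological arcs of the manual motion, the
#' mounting-grid offsets and optional gross outliers. Everything downstream is
#' reproducible from the seed (R's default Mersenne-Twister RNG; every
#' stochastic operation reseeds locally and restores the RNG state).
#'
#' Default constants mirror the physical rig's scale: the joint centre sits
#' about a metre from the robot origin and the tool length is 367 mm. Arc
#' extents default to a conservative hip range of motion (flexion-extension
#' 90 degrees, abduction-adduction 45 degrees, circumduction cone 30 degrees),
#' together giving 230 trajectory samples.
#'
#' @param seed integer seed; the single source of randomness.
#' @param noise_sd Gaussian marker noise SD in mm (default 0.1, the optical
#'   system's order of magnitude on this rig).
#' @param n_calibration_poses total stage-II poses (default 11: 5 on the YZ
#'   plane, the rest on XZ); must be at least 8.
#' @param true_jrc joint rotation centre in robot world coordinates (mm).
#' @param true_lot marker-to-centre distance = tool length (mm).
#' @param rom_arcs list of arcs, each `list(plane, range_deg, n)` with `plane`
#'   one of `"flexion"`, `"abduction"`, `"circumduction"`.
#' @param mounting_offsets `k x 3` matrix of grid mounting offsets (mm).
#' @param grid_pitch hole-grid pitch in mm (default 50).
#' @param outlier_count,outlier_magnitude gross outliers to inject into the
#'   manual trajectory (defaults 0 and 20 mm).
#' @param ellipsoid_scale per-axis scale of the joint surface (default
#'   `c(1,1,1)` = sphere); unequal values emulate a non-ball joint.
#' @return an object of class `synthetic_scenario` including the drawn
#'   `rotation` (3 x 3 proper rotation) and `translation` of the true
#'   optical-to-robot motion.
#' @export
synthetic_scenario <- function(seed = 1L, noise_sd = 0.1,
                               n_calibration_poses = 11L,
                               true_jrc = c(1010, -125, 60),
                               true_lot = 367,
                               rom_arcs = list(
                                 list(plane = "flexion", range_deg = 90, n = 90L),
                                 list(plane = "abduction", range_deg = 45, n = 60L),
                                 list(plane = "circumduction", range_deg = 30, n = 80L)),
                               mounting_offsets = rbind(
                                 c(0, 0, 0), c(50, 0, 0), c(0, 50, 0),
                                 c(50, 50, 0), c(100, 0, 0), c(100, 50, 0)),
                               grid_pitch = 50,
                               outlier_count = 0L, outlier_magnitude = 20,
                               ellipsoid_scale = c(1, 1, 1)) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_calibration_poses < 8L) stop("need at least 8 calibration poses")
  if (length(rom_arcs) < 1L) stop("rom_arcs must be non-empty")
  seed <- as.integer(seed)
  rt <- with_seed(seed, {
    m <- matrix(rnorm(9L), 3L)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 3L] <- -q[, 3L]   # proper rotation
    list(rotation = q, translation = runif(3L, -1000, 1000))
  })
  structure(
    list(seed = seed, noise_sd = noise_sd,
         n_calibration_poses = as.integer(n_calibration_poses),
         true_jrc = as.numeric(true_jrc), true_lot = as.numeric(true_lot),
         rotation = rt$rotation, translation = rt$translation,
         rom_arcs = rom_arcs,
         mounting_offsets = as.matrix(mounting_offsets),
         grid_pitch = grid_pitch,
         outlier_count = as.integer(outlier_count),
         outlier_magnitude = outlier_magnitude,
         ellipsoid_scale = as.numeric(ellipsoid_scale)),
    class = "synthetic_scenario")
}

# run expr under a local seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# true map optical -> robot: r = rotation %*% a + translation
to_robot <- function(s, a) sweep(a %*% t(s$rotation), 2L, s$translation, "+")
to_optical <- function(s, r) sweep(r, 2L, s$translation) %*% s$rotation

#' Simulate the stage-II calibration pose pair
#'
#' Lays out the commanded robot poses on the two calibration planes -- the
#' first five at constant x (the YZ plane), the remainder at constant y, both
#' planes through the first pose -- and produces the corresponding optical
#' observations by pushing them through the scenario's hidden rigid motion and
#' adding Gaussian marker noise.
#'
#' @param s a [synthetic_scenario()].
#' @return list with `robot` ([point_set()], ROBOT frame, commanded) and
#'   `optical` (`point_set`, ARAMIS frame, observed).
#' @export
simulate_calibration_poses <- function(s) {
  stopifnot(inherits(s, "synthetic_scenario"))
  n <- s$n_calibration_poses
  # YZ plane: constant x = 800; generous spread in y and z
  yz <- cbind(800, c(-200, 200, 0, -150, 180),
              c(-100, -50, 250, 150, 40))
  # XZ plane: constant y = first pose's y; spread in x and z
  n_xz <- n - 5L
  xz <- cbind(seq(650, 950, length.out = n_xz),
              yz[1L, 2L],
              150 * sin(seq(0.5, 2.8, length.out = n_xz)) - 30)
  commanded <- rbind(yz, xz)
  optical <- to_optical(s, commanded)
  if (s$noise_sd > 0)
    optical <- optical + with_seed(s$seed + 101L,
                                   matrix(rnorm(3L * n, sd = s$noise_sd), n))
  list(robot = point_set(commanded, "ROBOT"),
       optical = point_set(optical, "ARAMIS"))
}

rotmat <- function(axis, theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  switch(axis,
         x = rbind(c(1, 0, 0), c(0, c_, -s_), c(0, s_, c_)),
         y = rbind(c(c_, 0, s_), c(0, 1, 0), c(-s_, 0, c_)),
         z = rbind(c(c_, -s_, 0), c(s_, c_, 0), c(0, 0, 1)))
}

arc_directions <- function(arc) {
  half <- arc$range_deg * pi / 360  # half-range in radians
  n <- arc$n
  v0 <- c(0, 0, -1)  # femur hangs along -z in the joint's anatomical frame
  switch(arc$plane,
    flexion = t(vapply(seq(-half, half, length.out = n),
                       function(th) as.numeric(rotmat("x", th) %*% v0),
                       numeric(3L))),
    abduction = t(vapply(seq(-half, half, length.out = n),
                         function(th) as.numeric(rotmat("y", th) %*% v0),
                         numeric(3L))),
    circumduction = {
      tilt <- rotmat("x", half)  # cone half-angle = half range
      t(vapply(seq(0, 2 * pi, length.out = n),
               function(ph) as.numeric(rotmat("z", ph) %*% tilt %*% v0),
               numeric(3L)))
    },
    stop(sprintf("unknown arc plane '%s'", arc$plane)))
}

#' Simulate the manually recorded joint motion
#'
#' Sweeps the tracked femur-end marker along the scenario's physiological arcs
#' at distance `true_lot` from the joint rotation centre (per-axis scaled when
#' `ellipsoid_scale` departs from a sphere), expresses the samples in the
#' optical frame, and adds Gaussian marker noise and any configured gross
#' outliers.
#'
#' @param s a [synthetic_scenario()].
#' @return list with `observed` ([point_set()], ARAMIS frame),
#'   `truth_optical` and `truth_robot` (noiseless `n x 3` matrices), and
#'   `outlier_indices` (integer vector, possibly empty).
#' @export
simulate_manual_rom <- function(s) {
  stopifnot(inherits(s, "synthetic_scenario"))
  dirs <- do.call(rbind, lapply(s$rom_arcs, arc_directions))
  offsets <- s$true_lot * sweep(dirs, 2L, s$ellipsoid_scale, "*")
  truth_robot <- sweep(offsets, 2L, s$true_jrc, "+")
  truth_optical <- to_optical(s, truth_robot)
  n <- nrow(truth_optical)
  observed <- truth_optical
  if (s$noise_sd > 0)
    observed <- observed + with_seed(s$seed + 202L,
                                     matrix(rnorm(3L * n, sd = s$noise_sd), n))
  ps <- point_set(observed, "ARAMIS")
  out_idx <- integer(0L)
  if (s$outlier_count > 0L) {
    ps <- add_outliers(ps, s$outlier_count, s$outlier_magnitude,
                       seed = s$seed + 303L)
    out_idx <- attr(ps, "outlier_indices")
  }
  list(observed = ps, truth_optical = truth_optical,
       truth_robot = truth_robot, outlier_indices = out_idx)
}

#' Displace randomly chosen samples by a fixed magnitude
#'
#' Emulates gross measurement disturbances: `count` samples, chosen uniformly
#' without replacement, are displaced along random directions by exactly
#' `magnitude` mm. The affected indices are recorded in the
#' `"outlier_indices"` attribute of the result.
#'
#' @param points a [point_set()].
#' @param count number of samples to displace (`< n`).
#' @param magnitude displacement length in mm.
#' @param seed RNG seed.
#' @return the modified `point_set` with attribute `outlier_indices`.
#' @export
add_outliers <- function(points, count, magnitude, seed = 1L) {
  stopifnot(inherits(points, "point_set"))
  n <- nrow(points$points)
  count <- as.integer(count)
  if (count >= n) stop("outlier count must be smaller than the sample count")
  if (count == 0L) {
    attr(points, "outlier_indices") <- integer(0L)
    return(points)
  }
  pert <- with_seed(seed, {
    idx <- sample.int(n, count)
    dirs <- matrix(rnorm(3L * count), count)
    list(idx = idx, dirs = dirs / sqrt(rowSums(dirs^2)))
  })
  pts <- points$points
  pts[pert$idx, ] <- pts[pert$idx, ] + magnitude * pert$dirs
  out <- point_set(pts, frame = points$frame, pose_index = points$pose_index,
                   orientation = points$orientation)
  attr(out, "outlier_indices") <- sort(pert$idx)
  out
}

#' Generate a complete ground-truthed synthetic dataset
#'
#' Bundles [simulate_calibration_poses()] and [simulate_manual_rom()] into a
#' ready-to-run [calibration_inputs()] plus the ground truth needed to score
#' recovery: the hidden rigid motion, the joint rotation centre in both frames,
#' the tool length, and the noiseless trajectories.
#'
#' @param s a [synthetic_scenario()].
#' @return list with `inputs` (a `calibration_inputs`) and `truth` (list:
#'   `rotation`, `translation`, `jrc_robot`, `jrc_optical`, `lot`,
#'   `trajectory_robot`, `trajectory_optical`, `outlier_indices`).
#' @export
simulate_dataset <- function(s) {
  stopifnot(inherits(s, "synthetic_scenario"))
  poses <- simulate_calibration_poses(s)
  rom <- simulate_manual_rom(s)
  list(
    inputs = calibration_inputs(poses$robot, poses$optical, rom$observed),
    truth = list(rotation = s$rotation, translation = s$translation,
                 jrc_robot = s$true_jrc,
                 jrc_optical = as.numeric(to_optical(s, matrix(s$true_jrc, 1L))),
                 lot = s$true_lot,
                 trajectory_robot = rom$truth_robot,
                 trajectory_optical = rom$truth_optical,
                 outlier_indices = rom$outlier_indices))
}
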