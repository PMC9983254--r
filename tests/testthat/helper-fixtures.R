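# Shared fixtures and independent oracles. Everything is generated in code;
# seeds are fixed so the suite is deterministic.

# random proper rotation (QR of a Gaussian matrix, det forced to +1)
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  if (det(q) < 0) q[, 3L] <- -q[, 3L]
  q
}

# brute-force normal-equation oracle for the 3x3 map: accumulate the outer
# products point by point and solve, no matrix-product shortcuts
lstsq_map_oracle <- function(target_pts, source_pts) {
  AAt <- matrix(0, 3L, 3L)
  RAt <- matrix(0, 3L, 3L)
  for (i in seq_len(nrow(source_pts))) {
    AAt <- AAt + outer(source_pts[i, ], source_pts[i, ])
    RAt <- RAt + outer(target_pts[i, ], source_pts[i, ])
  }
  t(solve(AAt, t(RAt)))
}

# same system solved by QR instead (independent algorithm, looser agreement)
lstsq_map_qr <- function(target_pts, source_pts) {
  t(qr.solve(source_pts, target_pts))
}

# brute-force summary statistics, written independently of summary_stats()
brute_summary <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  s <- sort(v)
  med <- if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
  list(mean = m,
       sd = sqrt(sum((v - m)^2) / n),
       median_deviation = med - m,
       max_dev_pos = s[n] - m,
       min_dev_neg = m - s[1L])
}

# points exactly on a sphere, spread over more than a hemisphere
on_sphere <- function(n, center, radius) {
  theta <- acos(runif(n, -0.3, 1))          # polar spread past the equator
  phi <- runif(n, 0, 2 * pi)
  dirs <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  sweep(radius * dirs, 2L, center, "+")
}

# small synthetic scenario (30 trajectory points) for fast pipeline tests
small_scenario <- function(seed, noise_sd = 0, ...) {
  synthetic_scenario(
    seed = seed, noise_sd = noise_sd,
    rom_arcs = list(list(plane = "flexion", range_deg = 90, n = 10L),
                    list(plane = "abduction", range_deg = 45, n = 10L),
                    list(plane = "circumduction", range_deg = 30, n = 10L)),
    ...)
}

# |computed - printed| small enough that the computed value prints as `printed`
# (digits = decimal places of the printed cell)
matches_printed <- function(computed, printed, digits) {
  all(abs(computed - printed) <= 0.5 * 10^(-digits) + 1e-12)
}

validation_csv <- function(name) {
  read.csv(system.file("extdata", "validation", name, package = "jointcal"))
}
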