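test_that("coarse graining: uniform fields, point masses, periodic wrap", {
  L <- 10
  n <- 128
  dx <- L / n
  r <- 0.5
  # uniform field is unchanged
  expect_equal(coarse_grain(matrix(3.7, n, n), r, L), matrix(3.7, n, n),
               tolerance = 1e-12)
  # single-pixel mass spreads over the disk, mean preserved (direct
  # summation oracle)
  f <- matrix(0, n, n)
  f[40, 60] <- 5
  cg <- coarse_grain(f, r, L)
  expect_equal(mean(cg), mean(f), tolerance = 1e-12)
  xs <- (seq_len(n) - 1) * dx
  d1 <- abs(xs - xs[40]); d1 <- pmin(d1, L - d1)
  d2 <- abs(xs - xs[60]); d2 <- pmin(d2, L - d2)
  disk <- outer(d1^2, d2^2, `+`) < r^2
  expect_equal(cg[disk], rep(5 / sum(disk), sum(disk)), tolerance = 1e-10)
  expect_equal(max(abs(cg[!disk])), 0, tolerance = 1e-10)
  # wrap-around: mass at the domain corner reaches all four corners
  f2 <- matrix(0, n, n)
  f2[1, 1] <- 1
  cg2 <- coarse_grain(f2, r, L)
  expect_gt(cg2[n, n], 0)
  expect_gt(cg2[1, n], 0)
  expect_gt(cg2[n, 1], 0)
  expect_error(coarse_grain(f, L / n * 0.5, L), "grid spacings")
})

test_that("gap fraction covers the three scripted regimes", {
  p <- tiny_params()
  n <- p$grid_n
  full <- monolayer_state(array(1, c(n, n, 2)), c(0, 0), 0, p)
  expect_equal(gap_fraction(full), 0)
  empty <- monolayer_state(array(-1, c(n, n, 2)), c(0, 0), 0, p)
  expect_equal(gap_fraction(empty), 1)
  half <- array(-1, c(n, n, 2))
  half[seq_len(n / 2), , 1] <- 1
  expect_equal(gap_fraction(monolayer_state(half, c(0, 0), 0, p)), 0.5)
})

test_that("shape index: disk, square and regular pentagon", {
  p <- sim_params("desk", N = 2, L = 8, grid_n = 256, T = 1)
  disk <- polygon_phase_field(params = p, center = c(4, 4), radius = 2)
  expect_equal(shape_index(disk, p$L), 2 * sqrt(pi), tolerance = 0.005)
  sq <- polygon_phase_field(rbind(c(2.5, 2.5), c(5.5, 2.5),
                                  c(5.5, 5.5), c(2.5, 5.5)), p)
  expect_equal(shape_index(sq, p$L), 4, tolerance = 0.005)
  ang <- pi / 2 + 2 * pi * (0:4) / 5
  pent <- polygon_phase_field(cbind(4 + 2 * cos(ang), 4 + 2 * sin(ang)), p)
  expect_equal(shape_index(pent, p$L), 3.813, tolerance = 0.005 * 3.813)
})

## synthetic run scaffold: uniform coarse-energy fields with scripted values,
## one scripted event, constant observables
synthetic_run <- function(values, times, events, obs_value = NULL) {
  p <- sim_params("desk", N = 5, L = 8, grid_n = 128, T = max(times),
                  tau_save = diff(times)[1])
  n <- p$grid_n
  obs <- do.call(rbind, lapply(times, function(tk) {
    data.frame(t = tk, cell = 1:5, x = 4, y = 4, area = 1, perimeter = 4,
               shape_index = if (is.null(obs_value)) 3.6 else obs_value(tk),
               S0 = 0, S1 = 0, lambda_plus = 0, theta = 0,
               vx = 0, vy = 0,
               speed = if (is.null(obs_value)) 0.2 else obs_value(tk))
  }))
  structure(list(params = p, times = times,
                 graphs = structure(list(), class = "contact_sequence"),
                 obs = obs,
                 energy = data.frame(t = times, total = values,
                                     ch = values, int = 0),
                 f_ravg = lapply(values, function(v) matrix(v, n, n)),
                 gap_fraction = rep(0, length(times)),
                 final = NULL),
            class = "monolayer_run")
}

test_that("event-aligned profile reproduces a scripted triangle exactly", {
  times <- seq(0, 20, by = 1)
  # triangular pulse: rises to 10 at t = 10, falls back; baseline 1
  values <- 1 + pmax(0, 8 - abs(times - 10)) * (10 - 1) / 8
  ev <- data.frame(a = 1, b = 2, c = 3, d = 4,
                   t_start = 8, t_end = 12, duration = 4,
                   epi_x = 4, epi_y = 4)
  run <- synthetic_run(values, times, ev)
  pr <- event_energy_profile(run, ev, window = 6)
  # pre side: t_rel -6..0 maps to t = 2..8
  expect_equal(pr$pre$mean, values[match(8 + pr$pre$t_rel, times)],
               tolerance = 1e-12)
  expect_equal(pr$post$mean, values[match(12 + pr$post$t_rel, times)],
               tolerance = 1e-12)
  # the discontinuity at 0 carries the scripted start/end values
  expect_equal(pr$start_value, values[times == 8])
  expect_equal(pr$end_value, values[times == 12])
  # during-event 21-point resampling interpolates the scripted ramp
  expect_equal(pr$during$mean[1], values[times == 8])
  expect_equal(pr$during$mean[21], values[times == 12])
  expect_equal(pr$during$mean[11], values[times == 10])  # the peak
  expect_equal(pr$baseline, mean(values))
})

test_that("averaging identical events leaves the mean and zeroes the std", {
  times <- seq(0, 20, by = 1)
  values <- 1 + pmax(0, 6 - abs(times - 10))
  ev1 <- data.frame(a = 1, b = 2, c = 3, d = 4, t_start = 9, t_end = 11,
                    duration = 2, epi_x = 4, epi_y = 4)
  run <- synthetic_run(values, times, ev1)
  pr1 <- event_energy_profile(run, ev1, window = 5)
  ev3 <- do.call(rbind, replicate(3, ev1, simplify = FALSE))
  pr3 <- event_energy_profile(run, ev3, window = 5)
  expect_equal(pr3$pre$mean, pr1$pre$mean)
  expect_equal(pr3$post$mean, pr1$post$mean)
  expect_true(all(pr3$pre$sd == 0))
  expect_true(all(pr3$post$sd == 0))
  expect_equal(pr3$pre$n[pr3$pre$t_rel >= -5], rep(3L, 6))
})

test_that("constant scripted observables give flat profiles", {
  times <- seq(0, 10, by = 1)
  values <- rep(2, length(times))
  ev <- data.frame(a = 1, b = 2, c = 3, d = 4, t_start = 4, t_end = 6,
                   duration = 2, epi_x = 4, epi_y = 4)
  run <- synthetic_run(values, times, ev)
  sv <- event_shape_velocity_profiles(run, ev, window = 3)
  expect_true(all(abs(sv$shape$pre$mean - 3.6) < 1e-12))
  expect_true(all(sv$shape$pre$sd == 0))
  expect_true(all(abs(sv$velocity$post$mean - 0.2) < 1e-12))
})

test_that("duration statistics: trivial summaries and degenerate fits", {
  expect_equal(duration_stats(c(2, 4))$mean, 3.0)
  one <- duration_stats(rep(1.5, 8))
  expect_equal(one$mean, 1.5)
  expect_true(one$degenerate)
  expect_null(one$fit)
})

test_that("Gamma MLE recovers synthetic duration parameters within 10%", {
  set.seed(7)
  d <- rgamma(2000, shape = 3, scale = 1.2)
  fit <- duration_stats(d)$fit
  expect_false(is.null(fit))
  expect_lt(abs(fit$shape - 3) / 3, 0.1)
  expect_lt(abs(fit$scale - 1.2) / 1.2, 0.15)
})

test_that("duration-energy relation: perfect monotone and degenerate cases", {
  ev <- data.frame(duration = c(4, 2, 1, 0.5), max_energy = c(1, 2, 4, 8))
  r <- duration_vs_max_energy(ev)
  expect_equal(r$spearman, -1)
  evc <- data.frame(duration = rep(2, 5), max_energy = 1:5)
  rc <- duration_vs_max_energy(evc)
  expect_true(is.na(rc$spearman))
  expect_match(attr(rc$spearman, "reason"), "constant")
  ev2 <- data.frame(duration = c(1, 2), max_energy = c(2, 1))
  expect_true(is.na(duration_vs_max_energy(ev2)$spearman))
})

test_that("tissue flow field: uniform translation, smoothing, mean", {
  L <- 10
  set.seed(3)
  cen <- matrix(runif(20, 0, L), 10, 2)
  u <- c(0.3, -0.2)
  vel <- matrix(u, 10, 2, byrow = TRUE)
  g <- structure(list(t = 0, relations = cbind(1:9, 2:10)),
                 class = "contact_graph")
  ff <- tissue_flow_field(cen, vel, g, L, grid_n = 32)
  expect_equal(max(abs(ff$v1 - u[1])), 0, tolerance = 1e-9)
  expect_equal(max(abs(ff$v2 - u[2])), 0, tolerance = 1e-9)

  # an outlier among uniform velocities is pulled toward the mean
  vel2 <- vel
  vel2[5, ] <- c(5, 5)
  ff2 <- tissue_flow_field(cen, vel2, g, L, grid_n = 32)
  expect_lt(max(ff2$v1), 5 * 0.8)

  # interpolated field mean is close to the sample mean for well-spread
  # centroids (quadrature check on a divergence-free sample)
  lat <- as.matrix(expand.grid(x = (0:3 + 0.5) * L / 4,
                               y = (0:3 + 0.5) * L / 4))
  lat <- (lat + matrix(runif(32, -0.3, 0.3), 16, 2)) %% L
  vel3 <- cbind(sin(2 * pi * lat[, 2] / L), cos(2 * pi * lat[, 1] / L))
  ff3 <- tissue_flow_field(lat, vel3, NULL, L, grid_n = 64)
  expect_equal(mean(ff3$v1), mean(vel3[, 1]), tolerance = 0.1)
  expect_equal(mean(ff3$v2), mean(vel3[, 2]), tolerance = 0.1)

  # collinear centroids: nearest-neighbour fallback, flagged
  cenc <- cbind(seq(1, 9, length.out = 5), rep(3, 5))
  velc <- matrix(u, 5, 2, byrow = TRUE)
  ffc <- tissue_flow_field(cenc, velc, NULL, L, grid_n = 16)
  expect_equal(attr(ffc, "interp"), "nearest")
  expect_equal(max(abs(ffc$v1 - u[1])), 0, tolerance = 1e-12)
})

test_that("chain grouping links co-located ordered events", {
  ev <- data.frame(t_start = c(0, 1, 10), epi_x = c(2, 2.3, 2.1),
                   epi_y = c(5, 5.2, 5.1))
  ch <- chain_candidates(ev, r_chain = 1, dt_chain = 3, L = 10)
  sizes <- sort(vapply(ch, length, integer(1)))
  expect_equal(sizes, c(1L, 2L))
  # far-separated events stay singletons
  ev2 <- data.frame(t_start = c(0, 1), epi_x = c(1, 8), epi_y = c(1, 8))
  expect_equal(vapply(chain_candidates(ev2, 1, 3, 10), length, integer(1)),
               c(1L, 1L))
  # invariance under event relabeling (row permutation)
  ev3 <- ev[c(2, 3, 1), ]
  ch3 <- chain_candidates(ev3, r_chain = 1, dt_chain = 3, L = 10)
  expect_equal(sort(vapply(ch3, length, integer(1))), sizes)
})
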