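test_that("shape tensor vanishes for a disk and finds an ellipse axis", {
  p <- tiny_params()
  st <- disk_state(p, radius = 1.2)
  s <- shape_tensor(st, i = 1)
  expect_lt(abs(s$S0), 1e-6 * s$area)
  expect_lt(abs(s$S1), 1e-6 * s$area)

  # ellipse with major axis along x2 at 90 degrees
  n <- p$grid_n
  dx <- p$L / n
  xs <- (seq_len(n) - 1) * dx
  px <- matrix(xs, n, n)
  py <- t(px)
  d <- 1 - sqrt(((px - 2) / 0.7)^2 + ((py - 2) / 1.4)^2)
  phi <- tanh(d / (sqrt(2) * p$epsilon))
  s2 <- shape_tensor(phi, L = p$L)
  expect_false(s2$isotropic)
  # angle is nematic: compare modulo pi
  ang <- s2$angle %% pi
  expect_lt(abs(ang - pi / 2), pi / 180)
  # eigen relation S eta = lambda eta
  S <- matrix(c(s2$S0, s2$S1, s2$S1, -s2$S0), 2, 2)
  expect_equal(S %*% s2$eta_plus, s2$lambda_plus * matrix(s2$eta_plus),
               tolerance = 1e-8)
})

test_that("rotating a cell rotates its elongation axis", {
  p <- tiny_params()
  n <- p$grid_n
  dx <- p$L / n
  xs <- (seq_len(n) - 1) * dx
  px <- matrix(xs, n, n) - 2
  py <- t(matrix(xs, n, n)) - 2
  mk <- function(psi) {
    u <- cos(psi) * px + sin(psi) * py
    v <- -sin(psi) * px + cos(psi) * py
    tanh((1 - sqrt((u / 1.4)^2 + (v / 0.7)^2)) / (sqrt(2) * p$epsilon))
  }
  a0 <- shape_tensor(mk(0), L = p$L)$angle %% pi
  for (psi in c(0.3, 1.1, 2.0)) {
    ai <- shape_tensor(mk(psi), L = p$L)$angle %% pi
    dd <- abs((ai - a0 - psi) %% pi)
    expect_lt(min(dd, pi - dd), 0.02)
  }
})

test_that("beta selection picks the nematic representative nearest theta", {
  expect_equal(select_beta(0.1, c(cos(0.2), sin(0.2))), 0.2)
  # antipodal representative when theta is near pi
  expect_equal(select_beta(pi - 0.1, c(1, 0)), pi)
  # isotropic cell: no torque
  expect_equal(select_beta(0.7, NULL), 0.7)
  expect_equal(select_beta(0.7, c(0, 0)), 0.7)
  # property: |beta - theta| <= pi/2 over random angles
  set.seed(1)
  for (k in 1:200) {
    th <- runif(1, -pi, pi)
    ps <- runif(1, -pi, pi)
    b <- select_beta(th, c(cos(ps), sin(ps)))
    expect_lte(abs(wrap_angle(b - th)), pi / 2 + 1e-12)
    # beta is parallel to the axis
    expect_lt(min(abs(wrap_angle(b - ps)), abs(wrap_angle(b - ps - pi))),
              1e-12)
  }
})

test_that("orientation update: fixed point, exponential alignment, diffusion", {
  p <- tiny_params(D_r = 0, alpha = 0.5, tau = 0.01)
  expect_equal(update_orientation(0.4, 0.4, p, dW = 0), 0.4)

  # offset from beta decays as exp(-alpha t) (linear ODE closed form)
  delta0 <- 0.3
  th <- delta0
  nst <- 200
  for (k in seq_len(nst)) th <- update_orientation(th, 0, p, dW = 0)
  expect_equal(th, delta0 * exp(-p$alpha * nst * p$tau), tolerance = 0.01)

  # alpha = 0: pure rotational diffusion, Var = 2 D_r t
  p2 <- tiny_params(D_r = 0.4, alpha = 0, tau = 0.01)
  set.seed(2)
  nreal <- 1e4
  nst <- 50
  th <- matrix(0, nreal)
  for (k in seq_len(nst)) {
    th <- th + sqrt(2 * p2$D_r) * rnorm(nreal, 0, sqrt(p2$tau))
  }
  expect_equal(var(as.numeric(th)), 2 * p2$D_r * nst * p2$tau,
               tolerance = 0.05)
})

test_that("advection velocity: active interior/exterior and passive shear", {
  p <- tiny_params(v0 = 0.5)
  st <- disk_state(p, radius = 1.2)
  st$theta[1] <- 0.7
  v <- advection_velocity(st, p, i = 1)
  speed <- sqrt(v$v1^2 + v$v2^2)
  inner <- st$phi[, , 1] > 0.999
  expect_equal(max(speed[inner]), p$v0, tolerance = 1e-3)
  outer_region <- st$phi[, , 1] < -0.999
  expect_equal(max(speed[outer_region]), 0, tolerance = 1e-3)

  ps <- tiny_params(mode = "passive_shear")
  sts <- disk_state(ps, radius = 1.2)
  vs <- advection_velocity(sts, ps, i = 1)
  n <- ps$grid_n
  i_mid <- which.min(abs((seq_len(n) - 1) * ps$L / n - ps$L / 2))
  expect_equal(max(abs(vs$v2[i_mid, ])), 0, tolerance = ps$L / n)
  expect_equal(vs$v2[1, 1], ps$L / 4)  # x1 = 0
  expect_true(all(vs$v1 == 0))
})

test_that("stepping conserves mass and dissipates energy without activity", {
  p <- tiny_params(v0 = 0, D_r = 0, T = 1, tau_save = 0.5)
  n <- p$grid_n
  dx <- p$L / n
  xs <- (seq_len(n) - 1) * dx
  px <- matrix(xs, n, n) - 2
  py <- t(matrix(xs, n, n)) - 2
  phi <- array(-1, c(n, n, 2))
  phi[, , 1] <- tanh((1 - sqrt((px / 1.3)^2 + (py / 0.75)^2)) /
                       (sqrt(2) * p$epsilon))
  st <- monolayer_state(phi, c(0, 0), 0, p)
  mass0 <- sum(st$phi[, , 1]) * dx^2

  fvals <- numeric(0)
  lam <- numeric(0)
  state <- st
  dW <- matrix(0, 2, 1)
  for (k in 1:1000) {
    state <- step_monolayer(state, p, dW = dW)
    if (k %% 100 == 0) {
      fvals <- c(fvals, free_energy(state, p)$value)
      lam <- c(lam, shape_tensor(state, i = 1)$lambda_plus)
    }
  }
  mass1 <- sum(state$phi[, , 1]) * dx^2
  expect_lt(abs(mass1 - mass0) / abs(mass0), 1e-6)
  expect_true(all(diff(fvals) <= 1e-8))
  # slightly elliptical passive cell relaxes toward a disk
  expect_true(all(diff(lam) < 0))
})

test_that("active advection is also mass-neutral", {
  p <- tiny_params(v0 = 0.5, D_r = 0.1, T = 1)
  st <- disk_state(p, radius = 1, center2 = c(1, 1), radius2 = 0.8)
  st$theta <- c(0.3, 2.1)
  dx <- p$L / p$grid_n
  m0 <- apply(st$phi, 3, sum) * dx^2
  run <- run_simulation(p, state = st, T = 1, seed = 3,
                        keep_energy_fields = FALSE)
  m1 <- apply(run$final$phi, 3, sum) * dx^2
  expect_lt(max(abs(m1 - m0) / abs(m0)), 1e-6)
})

test_that("dynamics is equivariant under lattice translations", {
  p <- tiny_params(v0 = 0.4, D_r = 0.2, T = 0.5)
  st <- disk_state(p, center = c(1.5, 2.5), radius = 1)
  st$theta <- c(1.0, 0)
  sh <- 16L  # lattice shift in grid points
  st_sh <- st
  idx <- c((sh + 1):p$grid_n, 1:sh)
  st_sh$phi <- st$phi[idx, , , drop = FALSE]
  r1 <- run_simulation(p, state = st, T = 0.5, seed = 9,
                       keep_energy_fields = FALSE)
  r2 <- run_simulation(p, state = st_sh, T = 0.5, seed = 9,
                       keep_energy_fields = FALSE)
  expect_equal(r2$final$phi, r1$final$phi[idx, , , drop = FALSE],
               tolerance = 1e-12)
  expect_equal(r2$final$theta, r1$final$theta)
})

test_that("halving the time step changes the final energy by < 1%", {
  p1 <- tiny_params(v0 = 0, D_r = 0, tau = 0.005, T = 1, tau_save = 1)
  p2 <- tiny_params(v0 = 0, D_r = 0, tau = 0.0025, T = 1, tau_save = 1)
  n <- p1$grid_n
  dx <- p1$L / n
  xs <- (seq_len(n) - 1) * dx
  px <- matrix(xs, n, n) - 2
  py <- t(matrix(xs, n, n)) - 2
  mk <- function(p) {
    phi <- array(-1, c(n, n, 2))
    phi[, , 1] <- tanh((1 - sqrt((px / 1.3)^2 + (py / 0.75)^2)) /
                         (sqrt(2) * p$epsilon))
    monolayer_state(phi, c(0, 0), 0, p)
  }
  f1 <- run_simulation(p1, state = mk(p1), T = 1, seed = 1,
                       keep_energy_fields = FALSE)$energy$total
  f2 <- run_simulation(p2, state = mk(p2), T = 1, seed = 1,
                       keep_energy_fields = FALSE)$energy$total
  expect_lt(abs(tail(f1, 1) - tail(f2, 1)) / tail(f2, 1), 0.01)
})
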