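## Time integration and per-cell kinematics.

#' Shape deformation tensor of one cell
#'
#' The symmetric traceless tensor with components
#' `S0 = (1/8) int [(d phi/dy)^2 - (d phi/dx)^2] dx` and
#' `S1 = -(1/4) int [(d phi/dx)(d phi/dy)] dx`, eigenvalues `+/- lambda` with
#' `lambda = sqrt(S0^2 + S1^2)`, and principal axis at angle
#' `psi = atan2(S1, S0) / 2` (the cell's elongation axis, defined mod pi).
#'
#' @param phi_i one phase field (matrix) or a [monolayer_state()].
#' @param L domain side (taken from the state if one is given).
#' @param i cell index when a state is given.
#' @return list with `S0`, `S1`, `lambda_plus`, `eta_plus` (unit principal
#'   eigenvector), `angle` (its angle, in (-pi/2, pi/2]), `isotropic` flag.
#' @export
shape_tensor <- function(phi_i, L = NULL, i = NULL) {
  if (inherits(phi_i, "monolayer_state")) {
    L <- phi_i$params$L
    phi_i <- phi_i$phi[, , i]
  }
  st <- cpp_shape_tensor(phi_i, L)
  lam <- sqrt(st$S0^2 + st$S1^2)
  iso <- lam < 1e-12 * max(st$area, .Machine$double.eps)
  ang <- if (iso) NA_real_ else 0.5 * atan2(st$S1, st$S0)
  eta <- if (iso) c(NA_real_, NA_real_) else c(cos(ang), sin(ang))
  list(S0 = st$S0, S1 = st$S1, lambda_plus = lam, eta_plus = eta,
       angle = ang, area = st$area, isotropic = iso)
}

#' Select the alignment target angle beta
#'
#' The elongation axis is nematic (defined mod pi); the self-propulsion
#' angle relaxes towards the representative of the axis nearest to the
#' current orientation `theta` (so that `|beta - theta| <= pi/2`). The
#' alternative `rule = "literal"` applies the signed-argument form
#' `beta = +/- arg(eta_plus)` depending on the sign of `e . eta_plus`.
#'
#' @param theta_i current self-propulsion angle.
#' @param eta_plus principal eigenvector (any nonzero length), or `NULL` /
#'   zero vector for an isotropic cell.
#' @param rule `"nearest"` (default) or `"literal"`.
#' @return the target angle `beta`.
#' @export
select_beta <- function(theta_i, eta_plus, rule = c("nearest", "literal")) {
  rule <- match.arg(rule)
  if (is.null(eta_plus) || any(is.na(eta_plus)) ||
      sum(eta_plus^2) < .Machine$double.eps) {
    return(theta_i)  # isotropic: no alignment torque
  }
  psi <- atan2(eta_plus[2], eta_plus[1])
  if (rule == "literal") {
    edot <- cos(theta_i) * eta_plus[1] + sin(theta_i) * eta_plus[2]
    return(wrap_angle(if (edot >= 0) psi else -psi))
  }
  d <- wrap_angle(psi - theta_i)
  if (abs(d) > pi / 2) psi <- psi + pi
  wrap_angle(psi)
}

#' Euler-Maruyama update of a self-propulsion angle
#'
#' `theta' = theta + alpha wrap(beta - theta) tau + sqrt(2 D_r) dW` with
#' `dW ~ N(0, tau)`; the angle difference is wrapped to (-pi, pi] before the
#' drift is applied and the result is wrapped again.
#'
#' @param theta_i current angle.
#' @param beta_i alignment target.
#' @param params a [sim_params()].
#' @param dW Gaussian increment with variance `tau` (drawn if missing).
#' @return the updated angle.
#' @export
update_orientation <- function(theta_i, beta_i, params,
                               dW = rnorm(length(theta_i), 0,
                                          sqrt(params$tau))) {
  wrap_angle(theta_i + params$alpha * wrap_angle(beta_i - theta_i) *
               params$tau + sqrt(2 * params$D_r) * dW)
}

#' Advection velocity field of one cell
#'
#' Active mode: `v_i = v0 B(phi_i) e_i` with `e_i = (cos theta_i,
#' sin theta_i)`. Passive shear mode: the externally imposed profile of
#' magnitude `0.5 |x1 - L/2|` directed along the x2 axis, identical for all
#' cells (`v0` ignored).
#'
#' @param state a [monolayer_state()].
#' @param params a [sim_params()].
#' @param i cell index.
#' @return list of component fields `v1`, `v2`.
#' @export
advection_velocity <- function(state, params = state$params, i) {
  n <- params$grid_n
  if (params$mode == "passive_shear") {
    x1 <- matrix((seq_len(n) - 1) * params$L / n, n, n)
    v2 <- 0.5 * abs(x1 - params$L / 2)
    return(list(v1 = matrix(0, n, n), v2 = v2))
  }
  B <- indicator_B(state$phi[, , i])
  list(v1 = params$v0 * B * cos(state$theta[i]),
       v2 = params$v0 * B * sin(state$theta[i]))
}

## internal driver around the C++ kernel
.run_chunk <- function(state, params, nsteps, dW) {
  res <- cpp_run_chunk(state$phi, state$theta, dW, as.integer(nsteps),
                       params$tau, params$L, params$epsilon, params$v0,
                       params$a, params$Ca, params$In, params$D_r,
                       params$alpha, params$sigma_stab,
                       if (params$mode == "active") 0L else 1L,
                       if (params$beta_rule == "literal") 1L else 0L)
  if (!res$ok) {
    stop("solver blow-up (NaN) at t ~ ",
         signif(state$t + res$steps_done * params$tau, 6),
         "; reduce tau or increase sigma_stab")
  }
  monolayer_state(res$phi, res$theta, state$t + nsteps * params$tau, params)
}

#' Advance the monolayer by one time step
#'
#' One semi-implicit step of the conserved dynamics (the linear stiff
#' Cahn-Hilliard operator is implicit in Fourier space, the cubic well,
#' interaction and advection terms explicit with a stabilising split
#' constant), followed by the Euler-Maruyama orientation update.
#'
#' @param state a [monolayer_state()].
#' @param params a [sim_params()].
#' @param dW optional `N x 1` matrix of Gaussian increments (variance `tau`);
#'   drawn from the current RNG stream if missing.
#' @return the advanced state.
#' @export
step_monolayer <- function(state, params = state$params, dW = NULL) {
  N <- dim(state$phi)[3]
  if (is.null(dW)) dW <- matrix(rnorm(N, 0, sqrt(params$tau)), N, 1)
  .run_chunk(state, params, 1L, dW)
}

#' Run a monolayer simulation
#'
#' Integrates the model from `state` (or a fresh Voronoi monolayer) for time
#' `T`, recording at every save interval `tau_save`: the contact graph, the
#' per-cell observables (centroid, area, perimeter, shape index, shape
#' tensor, orientation, centre-of-mass velocity), the total energies, the
#' gap fraction and the coarse-grained total energy field.
#'
#' All noise comes from the R RNG seeded once with `seed`; orientation
#' increments are drawn as one matrix per save chunk with one row per cell,
#' so the stream is independent of cell iteration order and a run resumed
#' from a saved state (with its RNG state) reproduces the original
#' trajectory step for step.
#'
#' @param params a [sim_params()].
#' @param state optional initial [monolayer_state()]; default
#'   [init_voronoi_monolayer()].
#' @param T total simulated time; default `params$T`.
#' @param seed RNG seed; `NULL` continues the current stream (for resumes).
#' @param keep_energy_fields store the coarse-grained energy field at every
#'   save time (needed for event-aligned energy profiles).
#' @param progress print progress every 10 saves.
#' @return an object of class `monolayer_run`: list with `params`, `times`,
#'   `graphs` (contact_sequence), `obs` (per-cell per-save data frame),
#'   `energy` (data frame of totals), `f_ravg` (list of coarse energy
#'   fields), `gap_fraction` vector and the `final` state.
#' @export
run_simulation <- function(params, state = NULL, T = params$T,
                           seed = params$seed, keep_energy_fields = TRUE,
                           progress = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- init_voronoi_monolayer(params, seed = NULL)
  N <- dim(state$phi)[3]
  nsub <- round(params$tau_save / params$tau)
  stopifnot(abs(nsub * params$tau - params$tau_save) < 1e-9)
  nsave <- round(T / params$tau_save)

  times <- numeric(nsave + 1)
  graphs <- vector("list", nsave + 1)
  obs <- vector("list", nsave + 1)
  fields <- if (keep_energy_fields) vector("list", nsave + 1) else NULL
  energy <- matrix(0, nsave + 1, 3,
                   dimnames = list(NULL, c("total", "ch", "int")))
  gapf <- numeric(nsave + 1)

  record <- function(k, state) {
    fe <- free_energy(state, params)
    times[k] <<- state$t
    graphs[[k]] <<- contact_graph(state, params)
    obs[[k]] <<- cell_observables(state, params)
    energy[k, ] <<- c(fe$value, fe$ch, fe$int)
    gapf[k] <<- gap_fraction(state, params)
    if (keep_energy_fields) {
      fields[[k]] <<- coarse_grain(fe$density, params$r_avg_frac * params$L,
                                   params$L)
    }
  }

  record(1, state)
  for (k in seq_len(nsave)) {
    dW <- matrix(rnorm(N * nsub, 0, sqrt(params$tau)), N, nsub)
    state <- .run_chunk(state, params, nsub, dW)
    record(k + 1, state)
    if (progress && k %% 10 == 0) {
      message(sprintf("t = %.2f / %.2f  F = %.4g", state$t, T,
                      energy[k + 1, "total"]))
    }
  }

  obs <- do.call(rbind, obs)
  # centre-of-mass velocity by minimal-image finite difference over tau_save
  obs <- obs[order(obs$cell, obs$t), ]
  obs$vx <- NA_real_
  obs$vy <- NA_real_
  for (i in seq_len(N)) {
    sel <- which(obs$cell == i)
    dxs <- torus_diff(obs$x[sel][-1], obs$x[sel][-length(sel)], params$L)
    dys <- torus_diff(obs$y[sel][-1], obs$y[sel][-length(sel)], params$L)
    obs$vx[sel] <- c(NA, dxs / params$tau_save)
    obs$vy[sel] <- c(NA, dys / params$tau_save)
  }
  obs$speed <- sqrt(obs$vx^2 + obs$vy^2)
  rownames(obs) <- NULL

  structure(list(params = params, times = times,
                 graphs = structure(graphs, class = "contact_sequence"),
                 obs = obs,
                 energy = as.data.frame(cbind(t = times, energy)),
                 f_ravg = fields, gap_fraction = gapf, final = state),
            class = "monolayer_run")
}

#' @export
print.monolayer_run <- function(x, ...) {
  cat("<monolayer_run>", length(x$times), "saves, t in [",
      min(x$times), ",", max(x$times), "], N =", x$params$N,
      ", mode =", x$params$mode, "\n")
  cat("  mean total energy:", signif(mean(x$energy$total), 5),
      " mean gap fraction:", signif(mean(x$gap_fraction), 4), "\n")
  invisible(x)
}

#' @param x a `monolayer_run`.
#' @param time save time to draw (nearest match); default the final state.
#' @param ... passed to [graphics::contour()].
#' @rdname run_simulation
#' @export
plot.monolayer_run <- function(x, time = NULL, ...) {
  st <- x$final
  if (!is.null(time)) {
    stopifnot(abs(time - st$t) < 1e-9)  # only the final state is retained
  }
  n <- x$params$grid_n
  xs <- (seq_len(n) - 1) * x$params$L / n
  graphics::plot(NA, xlim = c(0, x$params$L), ylim = c(0, x$params$L),
                 xlab = "x1", ylab = "x2", asp = 1,
                 main = sprintf("cell boundaries, t = %.1f", st$t))
  for (i in seq_len(dim(st$phi)[3])) {
    graphics::contour(xs, xs, st$phi[, , i], levels = 0, add = TRUE,
                      drawlabels = FALSE, col = grDevices::hcl.colors(
                        dim(st$phi)[3], "Dark 3")[i], ...)
  }
  invisible(x)
}

#' Per-cell observables of a state
#'
#' @param state a [monolayer_state()].
#' @param params a [sim_params()].
#' @return data frame with one row per cell: time, centroid, diffuse area,
#'   contour perimeter, shape index, shape tensor components, orientation.
#' @export
cell_observables <- function(state, params = state$params) {
  N <- dim(state$phi)[3]
  dx <- params$L / params$grid_n
  out <- lapply(seq_len(N), function(i) {
    p <- state$phi[, , i]
    B <- indicator_B(p)
    cen <- torus_centroid(B, params$L)
    st <- shape_tensor(p, params$L)
    geom <- tryCatch(cell_contour_geometry(p, params$L),
                     error = function(e) list(perimeter = NA_real_,
                                              area = NA_real_))
    area <- sum(B) * dx^2
    data.frame(t = state$t, cell = i, x = cen[1], y = cen[2],
               area = area, perimeter = geom$perimeter,
               shape_index = geom$perimeter / sqrt(geom$area),
               S0 = st$S0, S1 = st$S1, lambda_plus = st$lambda_plus,
               theta = state$theta[i])
  })
  do.call(rbind, out)
}
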