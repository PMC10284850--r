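## Coarse-grained energy, event-aligned statistics, shape and flow analysis.

#' Coarse-grain a field by disk averaging
#'
#' Periodic convolution with the normalized indicator of a disk of radius
#' `r_avg` (the T1 "core" radius, default `0.02 L` at full scale): the value
#' at a point is the average of the field over the disk centred there. The
#' kernel is normalized so the spatial mean is preserved exactly.
#'
#' @param f field matrix on the periodic grid.
#' @param r_avg disk radius (same units as `L`); must cover at least 2 grid
#'   spacings.
#' @param L domain side.
#' @return the coarse-grained field.
#' @export
coarse_grain <- function(f, r_avg, L) {
  n <- nrow(f)
  dx <- L / n
  if (r_avg < 2 * dx) stop("r_avg (", r_avg, ") must be >= 2 grid spacings")
  xs <- (seq_len(n) - 1) * dx
  d1 <- pmin(xs, L - xs)
  disk <- outer(d1^2, d1^2, `+`) < r_avg^2
  kern <- disk / sum(disk)
  Re(fft(fft(f) * fft(kern), inverse = TRUE)) / n^2
}

#' Gap fraction of a state
#'
#' Fraction of the domain where the summed cell indicators fall below the
#' gap threshold (default 0.2): the extracellular space at junctions and
#' rosettes. Confluency is `100 (1 - gap fraction)`.
#'
#' @param state a [monolayer_state()].
#' @param params a [sim_params()].
#' @return scalar in `[0, 1]`.
#' @export
gap_fraction <- function(state, params = state$params) {
  sumB <- matrix(0, params$grid_n, params$grid_n)
  for (i in seq_len(dim(state$phi)[3])) {
    sumB <- sumB + indicator_B(state$phi[, , i])
  }
  mean(sumB < params$gap_threshold)
}

#' Contour geometry of one cell
#'
#' Perimeter and area of the `phi = 0` level set extracted by marching
#' squares ([grDevices::contourLines]); the field is recentred by a periodic
#' circular shift first so the contour does not wrap.
#'
#' @param phi one phase field.
#' @param L domain side.
#' @return list with `perimeter`, `area` and the contour `x`, `y`.
#' @export
cell_contour_geometry <- function(phi, L) {
  n <- nrow(phi)
  dx <- L / n
  cen <- torus_centroid(indicator_B(phi), L)
  sh <- round((c(L / 2, L / 2) - cen) / dx)
  idx1 <- ((seq_len(n) - 1 - sh[1]) %% n) + 1
  idx2 <- ((seq_len(n) - 1 - sh[2]) %% n) + 1
  pc <- phi[idx1, idx2]
  xs <- (seq_len(n) - 1) * dx
  cl <- grDevices::contourLines(xs, xs, pc, levels = 0)
  if (length(cl) == 0) stop("no phi = 0 contour found for cell")
  # keep the contour enclosing the largest area
  areas <- vapply(cl, function(cc) {
    x <- cc$x; y <- cc$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2)
  }, numeric(1))
  cc <- cl[[which.max(areas)]]
  x <- cc$x
  y <- cc$y
  if (abs(x[1] - x[length(x)]) + abs(y[1] - y[length(y)]) > 1e-9) {
    # contourLines leaves closed loops implicitly closed
    x <- c(x, x[1]); y <- c(y, y[1])
  }
  per <- sum(sqrt(diff(x)^2 + diff(y)^2))
  list(perimeter = per, area = max(areas), x = x, y = y)
}

#' Shape index of a cell
#'
#' `perimeter / sqrt(area)` of the `phi = 0` contour: `2 sqrt(pi) ~ 3.545`
#' for a disk, 3.813 for a regular pentagon, 4 for a square. Used as a
#' fluidity/jamming diagnostic of the monolayer.
#'
#' @inheritParams cell_contour_geometry
#' @return scalar shape index.
#' @export
shape_index <- function(phi, L) {
  g <- cell_contour_geometry(phi, L)
  g$perimeter / sqrt(g$area)
}

## ---- event-aligned profile machinery ------------------------------------

## sampler(event_row, save_index) -> scalar; returns a t1_profile
.align_profiles <- function(run, events, sampler, window, baseline,
                            during_points = 21) {
  tau_save <- run$params$tau_save
  nb <- round(window / tau_save)
  pre_grid <- -(nb:0) * tau_save
  post_grid <- (0:nb) * tau_save
  frac_grid <- seq(0, 1, length.out = during_points)
  pre_acc <- matrix(NA_real_, nrow(events), length(pre_grid))
  post_acc <- matrix(NA_real_, nrow(events), length(post_grid))
  dur_acc <- matrix(NA_real_, nrow(events), during_points)
  for (e in seq_len(nrow(events))) {
    ev <- events[e, ]
    for (b in seq_along(pre_grid)) {
      k <- which.min(abs(run$times - (ev$t_start + pre_grid[b])))
      if (abs(run$times[k] - (ev$t_start + pre_grid[b])) < tau_save / 2 &&
          run$times[k] <= ev$t_start + 1e-9) {
        pre_acc[e, b] <- sampler(ev, k)
      }
    }
    for (b in seq_along(post_grid)) {
      k <- which.min(abs(run$times - (ev$t_end + post_grid[b])))
      if (abs(run$times[k] - (ev$t_end + post_grid[b])) < tau_save / 2 &&
          run$times[k] >= ev$t_end - 1e-9) {
        post_acc[e, b] <- sampler(ev, k)
      }
    }
    inside <- which(run$times >= ev$t_start - 1e-9 &
                      run$times <= ev$t_end + 1e-9)
    if (length(inside) >= 2) {
      vals <- vapply(inside, function(k) sampler(ev, k), numeric(1))
      fr <- (run$times[inside] - ev$t_start) / (ev$t_end - ev$t_start)
      dur_acc[e, ] <- stats::approx(fr, vals, xout = frac_grid)$y
    } else if (length(inside) == 1) {
      dur_acc[e, ] <- sampler(ev, inside)
    }
  }
  agg <- function(acc, grid, name) {
    data.frame(t_rel = grid,
               mean = apply(acc, 2, mean, na.rm = TRUE),
               sd = apply(acc, 2, function(v) {
                 if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0
               }),
               n = apply(acc, 2, function(v) sum(!is.na(v))))
  }
  pre <- agg(pre_acc, pre_grid)
  post <- agg(post_acc, post_grid)
  during <- agg(dur_acc, frac_grid)
  names(during)[1] <- "frac"
  start_value <- pre$mean[nrow(pre)]
  end_value <- post$mean[1]
  peak <- max(c(pre$mean, post$mean), na.rm = TRUE)
  thr <- 0.75 * peak
  cross_time <- function(t, m, side) {
    ok <- which(!is.na(m))
    t <- t[ok]; m <- m[ok]
    if (length(m) < 2) return(NA_real_)
    if (side == "pre") {
      below <- which(m < thr & t < 0)
      if (length(below) == 0) return(NA_real_)
      i <- max(below)
      if (i == length(m)) return(NA_real_)
      t[i] + (thr - m[i]) / (m[i + 1] - m[i]) * (t[i + 1] - t[i])
    } else {
      below <- which(m < thr & t > 0)
      if (length(below) == 0) return(NA_real_)
      i <- min(below)
      if (i == 1) return(NA_real_)
      t[i - 1] + (thr - m[i - 1]) / (m[i] - m[i - 1]) * (t[i] - t[i - 1])
    }
  }
  structure(list(pre = pre, post = post, during = during,
                 start_value = start_value, end_value = end_value,
                 baseline = baseline,
                 cross75 = c(pre = cross_time(pre$t_rel, pre$mean, "pre"),
                             post = cross_time(post$t_rel, post$mean, "post")),
                 n_events = nrow(events), window = window),
            class = "t1_profile")
}

#' @export
print.t1_profile <- function(x, ...) {
  cat("<t1_profile>", x$n_events, "events, window", x$window, "\n")
  cat("  start/end values at t_rel = 0:", signif(x$start_value, 5), "/",
      signif(x$end_value, 5), "  baseline:", signif(x$baseline, 5), "\n")
  cat("  75%-of-peak crossings (pre/post):", signif(x$cross75[1], 4), "/",
      signif(x$cross75[2], 4), "\n")
  invisible(x)
}

#' @export
plot.t1_profile <- function(x, ylab = "value", main = "event-aligned profile",
                            ...) {
  tr <- c(x$pre$t_rel, x$post$t_rel)
  m <- c(x$pre$mean, x$post$mean)
  s <- c(x$pre$sd, x$post$sd)
  graphics::plot(tr, m, type = "n", xlab = "t_rel", ylab = ylab, main = main,
                 ylim = range(c(m - s, m + s, x$baseline), na.rm = TRUE), ...)
  seg <- function(p) {
    ok <- !is.na(p$mean)
    graphics::polygon(c(p$t_rel[ok], rev(p$t_rel[ok])),
                      c((p$mean + p$sd)[ok], rev((p$mean - p$sd)[ok])),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(p$t_rel[ok], p$mean[ok], lwd = 2, col = "steelblue4")
  }
  seg(x$pre)
  seg(x$post)
  graphics::abline(h = x$baseline, lty = 2, col = "gray40")
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Event-aligned energy profile
#'
#' Samples the coarse-grained total energy at each event's epicenter (a
#' fixed point) on the save grid, aligns samples before the event at
#' `t_rel = t - t_start < 0` and after it at `t_rel = t - t_end > 0`
#' (in-event samples are excluded, producing the discontinuity at
#' `t_rel = 0` whose two values are the averaged energies at start and end),
#' resamples the in-event values onto a normalized 0-100% duration grid,
#' and averages over events with per-bin standard deviations. The domain
#' mean energy over the run is attached as the baseline, and the times at
#' which the mean profile crosses 75% of its peak quantify the asymmetry.
#'
#' @param run a `monolayer_run` with stored energy fields.
#' @param events a [detect_t1()] result with epicenters attached (see
#'   [analyze_run()]), or without (epicenters are then computed).
#' @param window half-width of the alignment window in time units.
#' @return a `t1_profile` object.
#' @export
event_energy_profile <- function(run, events, window = 20) {
  if (nrow(events) == 0) stop("no events to align")
  if (is.null(events$epi_x)) events <- .attach_epicenters(events, run)
  if (is.null(run$f_ravg)) stop("run was made with keep_energy_fields = FALSE")
  baseline <- mean(vapply(run$f_ravg, mean, numeric(1)))
  sampler <- function(ev, k) {
    interp_periodic(run$f_ravg[[k]], c(ev$epi_x, ev$epi_y), run$params$L)
  }
  .align_profiles(run, events, sampler, window, baseline)
}

#' Event-aligned shape-index and velocity profiles
#'
#' The same alignment machinery as [event_energy_profile()] applied to the
#' mean shape index of an event's four cells and to their mean
#' centre-of-mass speed.
#'
#' @inheritParams event_energy_profile
#' @return list with `t1_profile`s `shape` and `velocity`.
#' @export
event_shape_velocity_profiles <- function(run, events, window = 20) {
  if (nrow(events) == 0) stop("no events to align")
  obs <- run$obs
  shape_sampler <- function(ev, k) {
    o <- obs[obs$t == run$times[k] &
               obs$cell %in% c(ev$a, ev$b, ev$c, ev$d), ]
    mean(o$shape_index, na.rm = TRUE)
  }
  vel_sampler <- function(ev, k) {
    o <- obs[obs$t == run$times[k] &
               obs$cell %in% c(ev$a, ev$b, ev$c, ev$d), ]
    mean(o$speed, na.rm = TRUE)
  }
  list(shape = .align_profiles(run, events, shape_sampler, window,
                               mean(obs$shape_index, na.rm = TRUE)),
       velocity = .align_profiles(run, events, vel_sampler, window,
                                  mean(obs$speed, na.rm = TRUE)))
}

#' Asymmetry of an event-aligned profile
#'
#' Time for the mean profile to rise from `level` to the event (pre side)
#' and to decay back to `level` after it (post side). The characteristic
#' T1 signature is a post decay slower than the pre rise.
#'
#' @param profile a `t1_profile`.
#' @param level reference level; default the profile baseline.
#' @return named vector `c(pre = ..., post = ...)` (`Inf` if never reached
#'   inside the window).
#' @export
profile_asymmetry <- function(profile, level = profile$baseline) {
  pre <- profile$pre
  post <- profile$post
  below_pre <- which(pre$mean <= level & !is.na(pre$mean))
  pre_t <- if (length(below_pre) == 0) Inf else -pre$t_rel[max(below_pre)]
  below_post <- which(post$mean <= level & !is.na(post$mean))
  post_t <- if (length(below_post) == 0) Inf else post$t_rel[min(below_post)]
  c(pre = pre_t, post = post_t)
}

#' Duration statistics with a Gamma fit
#'
#' Mean and count of event durations, plus a maximum-likelihood Gamma fit
#' (shape/scale) capturing the exponential tail of the duration
#' distribution.
#'
#' @param events a [detect_t1()] result, or a numeric vector of durations.
#' @return list with `mean`, `n`, `degenerate` flag and (when `n >= 5` and
#'   the durations vary) `fit = list(shape, scale, loglik)`.
#' @export
duration_stats <- function(events) {
  d <- if (is.numeric(events)) events else events$duration
  out <- list(mean = mean(d), n = length(d), degenerate = FALSE, fit = NULL)
  if (length(d) == 0) {
    out$mean <- NA_real_
    return(out)
  }
  if (stats::var(d) == 0 || length(d) < 5) {
    out$degenerate <- stats::var(d) == 0
    return(out)
  }
  fit <- tryCatch(suppressWarnings(MASS::fitdistr(d, "gamma")),
                  error = function(e) NULL)
  if (!is.null(fit)) {
    out$fit <- list(shape = unname(fit$estimate["shape"]),
                    scale = 1 / unname(fit$estimate["rate"]),
                    loglik = fit$loglik)
  } else {
    out$degenerate <- TRUE
  }
  out
}

#' Duration versus maximum event energy
#'
#' Per-event (max energy, duration) pairs and their Spearman rank
#' correlation; high-energy T1 transitions relaxing faster shows up as a
#' negative correlation.
#'
#' @param events a [detect_t1()] result carrying `max_energy` (see
#'   [analyze_run()]).
#' @return list with the `table` (data frame) and `spearman` (NA with a
#'   `reason` attribute when undefined).
#' @export
duration_vs_max_energy <- function(events) {
  stopifnot(!is.null(events$max_energy))
  tab <- data.frame(max_energy = events$max_energy,
                    duration = events$duration)
  rho <- NA_real_
  reason <- NULL
  if (nrow(tab) < 3) {
    reason <- "fewer than 3 events"
  } else if (stats::var(tab$duration) == 0 || stats::var(tab$max_energy) == 0) {
    reason <- "constant durations or energies"
  } else {
    rho <- stats::cor(tab$max_energy, tab$duration, method = "spearman")
  }
  if (!is.null(reason)) attr(rho, "reason") <- reason
  list(table = tab, spearman = rho)
}

#' Interpolated tissue flow field
#'
#' Each cell's centre-of-mass velocity is first averaged with its
#' contact-graph neighbours, then interpolated to the grid by normalized
#' Gaussian-kernel weighting under the periodic metric (bandwidth of the
#' order of a cell radius), giving a continuous monolayer velocity field.
#' If all centroids are collinear the field falls back to nearest-cell
#' values (flagged in the `interp` attribute).
#'
#' @param centroids 2-column matrix of cell centroids.
#' @param velocities 2-column matrix of cell velocities.
#' @param graph a `contact_graph` for the neighbour averaging (or `NULL`
#'   to skip averaging).
#' @param L domain side.
#' @param grid_n output grid resolution.
#' @param bandwidth kernel bandwidth; default half the mean nearest-centroid
#'   spacing.
#' @return list of component fields `v1`, `v2` with attribute `interp`.
#' @export
tissue_flow_field <- function(centroids, velocities, graph, L, grid_n,
                              bandwidth = NULL) {
  centroids <- matrix(centroids, ncol = 2)
  velocities <- matrix(velocities, ncol = 2)
  N <- nrow(centroids)
  stopifnot(N >= 3, nrow(velocities) == N)
  # neighbour averaging over the contact graph (cell itself included)
  vavg <- velocities
  if (!is.null(graph) && nrow(graph$relations) > 0) {
    for (i in seq_len(N)) {
      nb <- c(graph$relations[graph$relations[, 1] == i, 2],
              graph$relations[graph$relations[, 2] == i, 1])
      vavg[i, ] <- colMeans(velocities[c(i, nb), , drop = FALSE])
    }
  }
  if (is.null(bandwidth)) {
    nnd <- vapply(seq_len(N), function(i) {
      min(torus_dist(centroids[-i, , drop = FALSE],
                     matrix(centroids[i, ], N - 1, 2, byrow = TRUE), L))
    }, numeric(1))
    bandwidth <- mean(nnd) / 2
  }
  xs <- (seq_len(grid_n) - 1) * L / grid_n
  v1 <- matrix(0, grid_n, grid_n)
  v2 <- matrix(0, grid_n, grid_n)
  wsum <- matrix(0, grid_n, grid_n)
  # collinearity check (degenerate geometry)
  dc <- sweep(centroids, 2, centroids[1, ])
  collinear <- qr(dc)$rank < 2
  if (collinear) {
    lab <- matrix(0L, grid_n, grid_n)
    best <- matrix(Inf, grid_n, grid_n)
    for (i in seq_len(N)) {
      d1 <- abs(xs - centroids[i, 1]); d1 <- pmin(d1, L - d1)
      d2 <- abs(xs - centroids[i, 2]); d2 <- pmin(d2, L - d2)
      dist2 <- outer(d1^2, d2^2, `+`)
      upd <- dist2 < best
      best[upd] <- dist2[upd]
      lab[upd] <- i
    }
    v1[] <- vavg[lab, 1]
    v2[] <- vavg[lab, 2]
    out <- list(v1 = v1, v2 = v2)
    attr(out, "interp") <- "nearest"
    return(out)
  }
  for (i in seq_len(N)) {
    d1 <- abs(xs - centroids[i, 1]); d1 <- pmin(d1, L - d1)
    d2 <- abs(xs - centroids[i, 2]); d2 <- pmin(d2, L - d2)
    w <- exp(-outer(d1^2, d2^2, `+`) / (2 * bandwidth^2))
    v1 <- v1 + w * vavg[i, 1]
    v2 <- v2 + w * vavg[i, 2]
    wsum <- wsum + w
  }
  out <- list(v1 = v1 / wsum, v2 = v2 / wsum)
  attr(out, "interp") <- "kernel"
  out
}

#' Centre-of-mass trajectory of a cell group
#'
#' Area-weighted mean centroid of the named cells at every save time,
#' unwrapped across periodic boundaries into a continuous path.
#'
#' @param run a `monolayer_run`.
#' @param cells integer vector of cell indices.
#' @return data frame with `t`, `x`, `y` (unwrapped coordinates).
#' @export
group_com_trajectory <- function(run, cells) {
  L <- run$params$L
  path <- t(vapply(run$times, function(tk) {
    o <- run$obs[run$obs$t == tk & run$obs$cell %in% cells, ]
    ang_x <- 2 * pi * o$x / L
    ang_y <- 2 * pi * o$y / L
    c(Arg(sum(o$area * exp(1i * ang_x))) / (2 * pi) * L,
      Arg(sum(o$area * exp(1i * ang_y))) / (2 * pi) * L) %% L
  }, numeric(2)))
  # unwrap
  for (j in 1:2) {
    d <- torus_diff(path[-1, j], path[-nrow(path), j], L)
    path[, j] <- path[1, j] + c(0, cumsum(d))
  }
  data.frame(t = run$times, x = path[, 1], y = path[, 2])
}

#' Chains of nearby T1 events
#'
#' Single-linkage grouping of events whose epicenters lie within `r_chain`
#' (periodic metric) and whose start times are ordered within `dt_chain`
#' (`0 < t_start(j) - t_start(i) < dt_chain`), quantifying the chaining of
#' T1 transitions that propagates deformation to tissue scale.
#'
#' @param events a [detect_t1()] result with epicenters attached.
#' @param r_chain spatial linkage radius.
#' @param dt_chain temporal linkage window.
#' @param L domain side.
#' @return list of chains, each an integer vector of event row indices
#'   ordered by `t_start`.
#' @export
chain_candidates <- function(events, r_chain, dt_chain, L) {
  n <- nrow(events)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dt <- events$t_start[j] - events$t_start[i]
      if (dt <= 0 || dt >= dt_chain) next
      d <- torus_dist(c(events$epi_x[i], events$epi_y[i]),
                      c(events$epi_x[j], events$epi_y[j]), L)
      if (d < r_chain) parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  chains <- split(seq_len(n), roots)
  chains <- lapply(chains, function(ix) ix[order(events$t_start[ix])])
  names(chains) <- NULL
  chains[order(vapply(chains, function(ix) min(events$t_start[ix]),
                      numeric(1)))]
}

.attach_epicenters <- function(events, run) {
  if (nrow(events) == 0) {
    events$epi_x <- numeric(0)
    events$epi_y <- numeric(0)
    return(events)
  }
  ep <- t(vapply(seq_len(nrow(events)), function(e) {
    t1_epicenter(events[e, ], run)
  }, numeric(2)))
  events$epi_x <- ep[, 1]
  events$epi_y <- ep[, 2]
  events
}
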