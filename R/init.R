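## Initial conditions and deterministic fixtures.

## squared minimal-image distance field from every grid point to one seed
.dist2_field <- function(seed, n, L) {
  dx <- L / n
  xs <- (seq_len(n) - 1) * dx
  d1 <- abs(xs - seed[1]); d1 <- pmin(d1, L - d1)
  d2 <- abs(xs - seed[2]); d2 <- pmin(d2, L - d2)
  outer(d1^2, d2^2, `+`)
}

## Lloyd-relaxed periodic Voronoi assignment; returns relaxed seeds
.lloyd_relax <- function(seeds, n, L, iters = 30) {
  N <- nrow(seeds)
  dx <- L / n
  xs <- (seq_len(n) - 1) * dx
  ang <- 2 * pi * xs / L
  e1 <- matrix(exp(1i * ang), n, n)
  e2 <- t(e1)
  for (it in seq_len(iters)) {
    best <- matrix(Inf, n, n)
    lab <- matrix(0L, n, n)
    for (i in seq_len(N)) {
      d2 <- .dist2_field(seeds[i, ], n, L)
      upd <- d2 < best
      best[upd] <- d2[upd]
      lab[upd] <- i
    }
    for (i in seq_len(N)) {
      m <- lab == i
      seeds[i, ] <- c(Arg(mean(e1[m])) / (2 * pi) * L,
                      Arg(mean(e2[m])) / (2 * pi) * L) %% L
    }
  }
  seeds
}

#' Initialize a confluent Voronoi monolayer
#'
#' Seeds `N` cells from a jittered lattice, relaxes the seeds by periodic
#' Lloyd iteration towards a centroidal (near-hexagonal) Voronoi tessellation,
#' and sets each phase field to the equilibrium interface profile
#' `phi_i = tanh(d_i / (sqrt(2) epsilon))`, with `d_i` the signed distance to
#' the cell's Voronoi boundary offset inward by a per-cell margin. The margin
#' is chosen so every cell mass `integral B(phi_i) dx` is `coverage * L^2 / N`
#' within 1%; the leftover area forms the extracellular gaps at junctions.
#'
#' @param params a [sim_params()] object.
#' @param coverage coverage factor: target cell area is `c * L^2 / N`.
#'   Values below 1 leave a geometric gap fraction `1 - c`; the default
#'   1.2 pre-compresses the monolayer to offset the mass the conserved
#'   dynamics relaxes into the uniform diffuse background (a finite-cell
#'   -size effect, strongest at the reduced desk geometry), keeping the
#'   relaxed monolayer confluent.
#' @param seed RNG seed for the jitter; default `params$seed`.
#' @param lloyd_iters Lloyd relaxation sweeps.
#' @return a [monolayer_state()] at `t = 0` with `theta ~ U[0, 2 pi)`.
#' @export
init_voronoi_monolayer <- function(params, coverage = 1.2,
                                   seed = params$seed, lloyd_iters = 30) {
  # coverage slightly above 1 pre-compresses the monolayer to offset the
  # mass that conserved dynamics moves into the uniform diffuse background
  stopifnot(inherits(params, "sim_params"), coverage > 0, coverage <= 1.5)
  N <- params$N
  n <- params$grid_n
  L <- params$L
  eps <- params$epsilon
  dx <- L / n
  diam <- 2 * sqrt(coverage * L^2 / (pi * N))
  if (diam < 8 * dx) {
    stop("N too large for grid resolution: cell diameter ", signif(diam, 3),
         " < 8 grid spacings")
  }
  if (!is.null(seed)) set.seed(seed)

  k <- ceiling(sqrt(N))
  lat <- expand.grid(i = seq_len(k) - 1, j = seq_len(k) - 1)
  lat$x <- (lat$i + 0.5 + 0.5 * (lat$j %% 2)) * L / k
  lat$y <- (lat$j + 0.5) * L / k
  pick <- sort(sample.int(k^2, N))
  seeds <- cbind(lat$x[pick], lat$y[pick]) %% L
  seeds <- (seeds + matrix(stats::runif(2 * N, -0.15, 0.15) * L / k, N, 2)) %% L
  seeds <- .lloyd_relax(seeds, n, L, iters = lloyd_iters)

  # two smallest seed-distance fields -> signed distance to Voronoi boundary
  d <- array(0, dim = c(n, n, N))
  for (i in seq_len(N)) d[, , i] <- sqrt(.dist2_field(seeds[i, ], n, L))
  best <- apply(d, c(1, 2), function(v) sort.int(v, partial = 2)[1:2])
  d1 <- best[1, , ]
  d2 <- best[2, , ]
  lab <- apply(d, c(1, 2), which.min)

  target <- coverage * L^2 / N
  phi <- array(-1, dim = c(n, n, N))
  for (i in seq_len(N)) {
    minothers <- ifelse(lab == i, d2, d1)
    sd_i <- (minothers - d[, , i]) / 2
    # per-cell margin: first-order from the cell's boundary length, then
    # Newton-refined on the actual diffuse mass
    area_i <- sum(lab == i) * dx^2
    perim_i <- max(sum(abs(sd_i) < dx) * dx^2 / (2 * dx), dx)
    m <- (area_i - target) / perim_i
    for (it in 1:3) {
      f <- tanh((sd_i - m) / (sqrt(2) * eps))
      mass <- sum((f + 1) / 2) * dx^2
      m <- m + (mass - target) / perim_i
    }
    phi[, , i] <- tanh((sd_i - m) / (sqrt(2) * eps))
  }

  theta <- stats::runif(N, 0, 2 * pi)
  monolayer_state(phi, theta, t = 0, params = params)
}

#' Phase field of a polygon or disk
#'
#' Rasterizes a convex or non-convex simple polygon (or a disk) as the
#' equilibrium interface profile `tanh(d / (sqrt(2) epsilon))` of its signed
#' distance function. Used to build fixtures and analytic test shapes.
#'
#' @param vertices 2-column matrix of polygon vertices (in order), or `NULL`
#'   when `radius`/`center` describe a disk.
#' @param params a [sim_params()] object (supplies `L`, `grid_n`, `epsilon`).
#' @param center,radius disk specification when `vertices` is `NULL`.
#' @return an `grid_n x grid_n` matrix.
#' @export
polygon_phase_field <- function(vertices = NULL, params, center = NULL,
                                radius = NULL) {
  n <- params$grid_n
  L <- params$L
  dx <- L / n
  xs <- (seq_len(n) - 1) * dx
  px <- matrix(xs, n, n)
  py <- t(px)
  if (is.null(vertices)) {
    stopifnot(!is.null(center), !is.null(radius))
    d <- radius - sqrt((px - center[1])^2 + (py - center[2])^2)
    return(tanh(d / (sqrt(2) * params$epsilon)))
  }
  v <- rbind(vertices, vertices[1, ])
  m <- nrow(vertices)
  dmin <- matrix(Inf, n, n)
  inside <- matrix(0L, n, n)
  for (k in seq_len(m)) {
    a <- v[k, ]; b <- v[k + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- pmin(pmax(((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2, 0), 1)
    dseg <- sqrt((px - (a[1] + tt * ab[1]))^2 + (py - (a[2] + tt * ab[2]))^2)
    dmin <- pmin(dmin, dseg)
    # even-odd ray casting, rays along +x2
    crosses <- ((a[2] > py) != (b[2] > py)) &
      (px < (b[1] - a[1]) * (py - a[2]) / (b[2] - a[2]) + a[1])
    inside <- inside + crosses
  }
  sgn <- ifelse(inside %% 2 == 1, 1, -1)
  tanh(sgn * dmin / (sqrt(2) * params$epsilon))
}

#' Four-cell T1 fixture
#'
#' Deterministic diamond arrangement of four disk cells A, B, C, D with the
#' B-D diagonal in contact and the A-C diagonal separated, pre-strained so
#' that forward simulation drives exactly one neighbour exchange: B and D
#' lose contact, A and C gain it. In active mode the self-propulsion
#' orientations point B and D apart and A and C together (no noise, no
#' alignment); in passive shear mode the diamond is rotated 45 degrees and
#' centred in the linear region of the shear profile.
#'
#' Cells are indexed A = 1, B = 2, C = 3, D = 4.
#'
#' @param params a [sim_params()] with `N = 4`; `NULL` for the packaged
#'   default fixture geometry.
#' @return a [monolayer_state()] at `t = 0`.
#' @export
init_t1_fixture <- function(params = NULL) {
  if (is.null(params)) {
    params <- sim_params("desk", N = 4, L = 12, grid_n = 256, T = 10,
                         D_r = 0, alpha = 0, v0 = 1.2, In = 0.7)
  }
  stopifnot(inherits(params, "sim_params"), params$N == 4)
  L <- params$L
  n <- params$grid_n
  R <- 0.1625 * L
  if (params$mode == "passive_shear") {
    # centred in the linear branch of the shear profile; the diamond is
    # pre-rotated past the -45 degree strain eigenframe so the flow's
    # vorticity carries the A-C axis through the compression direction
    # while the exchange completes
    ctr <- c(L / 4, L / 2)
    rot <- -pi / 4 + 0.4
  } else {
    ctr <- c(L / 2, L / 2)
    rot <- 0
  }
  # local diamond: B-D along x1 just touching, A and C flanking in firm
  # contact with both; the domain is large enough that no pair interacts
  # across the periodic wrap
  loc <- rbind(A = c(0, 1.10 * R),
               B = c(-0.95 * R, 0),
               C = c(0, -1.10 * R),
               D = c(0.95 * R, 0))
  Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  centers <- sweep(loc %*% t(Rm), 2, ctr, `+`)
  phi <- array(-1, dim = c(n, n, 4))
  for (i in 1:4) {
    phi[, , i] <- polygon_phase_field(params = params, center = centers[i, ],
                                      radius = R)
  }
  # aimed orientations: A down, B left, C up, D right (then rotated)
  theta <- wrap_angle(c(-pi / 2, pi, pi / 2, 0) + rot)
  monolayer_state(phi, theta, t = 0, params = params)
}

#' Scripted contact-graph sequence
#'
#' Builds a time-stamped sequence of contact graphs directly from a list of
#' relation sets, for driving the T1 detector without simulation.
#'
#' @param spec list of entries `list(t = <time>, relations = <list of pairs
#'   or 2-column matrix>)`.
#' @return an object of class `contact_sequence` (list of `contact_graph`s).
#' @export
scripted_contact_sequence <- function(spec) {
  graphs <- lapply(spec, function(g) {
    rel <- g$relations
    if (is.list(rel)) rel <- do.call(rbind, rel)
    if (is.null(rel)) rel <- matrix(integer(0), 0, 2)
    rel <- matrix(as.integer(rel), ncol = 2)
    if (any(rel[, 1] == rel[, 2])) {
      stop("self-relation (", rel[which(rel[, 1] == rel[, 2])[1], 1],
           ",", rel[which(rel[, 1] == rel[, 2])[1], 2], ") is not allowed")
    }
    rel <- cbind(pmin(rel[, 1], rel[, 2]), pmax(rel[, 1], rel[, 2]))
    rel <- unique(rel)
    structure(list(t = g$t, relations = rel), class = "contact_graph")
  })
  if (length(graphs) > 1) {
    tt <- vapply(graphs, `[[`, numeric(1), "t")
    stopifnot(all(diff(tt) > 0))
  }
  structure(graphs, class = "contact_sequence")
}
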