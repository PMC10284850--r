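# Shared fixtures. Everything is generated in code; the heavier simulation
# fixtures are memoized so several test files can share one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## small parameter set for cheap solver tests
tiny_params <- function(...) {
  sim_params("desk", N = 2, L = 4, grid_n = 64, T = 1, tau_save = 0.1, ...)
}

## state with a single straight-interface strip cell (plus an empty slot),
## interfaces at x1 = a and x1 = b
strip_state <- function(params, a = params$L * 0.25, b = params$L * 0.75) {
  n <- params$grid_n
  dx <- params$L / n
  xs <- (seq_len(n) - 1) * dx
  d <- pmin(xs - a, b - xs)
  phi <- array(-1, c(n, n, params$N))
  phi[, , 1] <- matrix(tanh(d / (sqrt(2) * params$epsilon)), n, n)
  monolayer_state(phi, rep(0, params$N), 0, params)
}

## state with one disk cell (slot 1), optionally a second disk
disk_state <- function(params, center = c(params$L / 2, params$L / 2),
                       radius = params$L / 4, center2 = NULL,
                       radius2 = radius) {
  n <- params$grid_n
  phi <- array(-1, c(n, n, params$N))
  phi[, , 1] <- polygon_phase_field(params = params, center = center,
                                    radius = radius)
  if (!is.null(center2)) {
    phi[, , 2] <- polygon_phase_field(params = params, center = center2,
                                      radius = radius2)
  }
  monolayer_state(phi, rep(0, params$N), 0, params)
}

## smooth random periodic field (low-pass filtered noise), for Gateaux tests
random_smooth_field <- function(n, L, seed, kmax = 6) {
  set.seed(seed)
  F <- matrix(0+0i, n, n)
  kk <- fft_freqs <- c(0:(n %/% 2), -(n - n %/% 2 - 1):-1)[seq_len(n)]
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(kk[i]) <= kmax && abs(kk[j]) <= kmax) {
        F[i, j] <- complex(real = rnorm(1), imaginary = rnorm(1))
      }
    }
  }
  f <- Re(fft(F, inverse = TRUE)) / n
  f / max(abs(f))
}

## the four-cell active fixture driven through its neighbour exchange
fixture_t1_run <- function() {
  memo("fixture_t1_run", {
    st <- init_t1_fixture()
    run_simulation(st$params, state = st, T = 6, seed = 7,
                   keep_energy_fields = TRUE)
  })
}

## scripted three-graph 5 -> 4 -> 5 exchange (cells A=1 B=2 C=3 D=4)
scripted_exchange <- function(t = c(0, 1, 2)) {
  perim <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  scripted_contact_sequence(list(
    list(t = t[1], relations = c(perim, list(c(2, 4)))),
    list(t = t[2], relations = perim),
    list(t = t[3], relations = c(perim, list(c(1, 3))))
  ))
}
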