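## Free-energy functionals, densities and variational derivatives.
##
## F = F_CH + F_INT with
##   F_CH  = (1/Ca) sum_i int (eps/2)|grad phi_i|^2 + (1/(4 eps))(phi_i^2-1)^2
##   F_INT = (1/In) sum_i int B(phi_i) sum_{j != i} w(phi_j)
## Gradients and Laplacians are Fourier-spectral on the periodic grid, so the
## discrete chemical potential is the exact adjoint of the discrete energy
## (the Gateaux consistency tests rely on this).

#' Cell indicator function B
#'
#' `B(phi) = (phi + 1) / 2`: 1 in the cell interior, 0 outside, 1/2 on the
#' interface midline.
#'
#' @param phi scalar, vector or field.
#' @return same shape as `phi`.
#' @export
indicator_B <- function(phi) (phi + 1) / 2

#' Interaction potential w
#'
#' `w(phi) = 1 - (a+1)((phi-1)/2)^2 + a((phi-1)/2)^4`. For `a = 1` the
#' potential is a non-negative squared well (pure repulsion); for `a > 1` it
#' dips below zero (adhesive well, minimum `-1/24` at `a = 1.5`).
#'
#' @param phi scalar, vector or field.
#' @param a interaction shape parameter, `a >= 1`.
#' @return same shape as `phi`.
#' @export
interaction_w <- function(phi, a) {
  u <- (phi - 1) / 2
  1 - (a + 1) * u^2 + a * u^4
}

#' @rdname interaction_w
#' @export
interaction_w_prime <- function(phi, a) {
  # d w / d phi = -(a+1)(phi-1)/2 + a (phi-1)^3 / 4
  u <- (phi - 1) / 2
  -(a + 1) * u + 2 * a * u^3
}

#' Cahn-Hilliard energy
#'
#' Interfacial part of the free energy, summed over cells. A relaxed straight
#' interface of length `l` contributes `(2 sqrt(2) / 3) l / Ca`.
#'
#' @param state a [monolayer_state()].
#' @param params a [sim_params()]; defaults to the state's own.
#' @return list with scalar `value` and the pointwise `density` field.
#' @export
ch_energy <- function(state, params = state$params) {
  n <- params$grid_n
  dx <- params$L / n
  dens <- matrix(0, n, n)
  for (i in seq_len(dim(state$phi)[3])) {
    p <- state$phi[, , i]
    g <- spectral_gradient(p, params$L)
    dens <- dens + (params$epsilon / 2) * (g$gx^2 + g$gy^2) +
      (1 / (4 * params$epsilon)) * (p^2 - 1)^2
  }
  dens <- dens / params$Ca
  list(value = sum(dens) * dx^2, density = dens)
}

#' Interaction energy
#'
#' Overlap penalty/adhesion between distinct cells,
#' `(1/In) sum_i B(phi_i) sum_{j != i} w(phi_j)`, using the identity
#' `sum_i B_i (W - w_i)` with `W = sum_j w_j` so the cost is linear in `N`.
#'
#' @inheritParams ch_energy
#' @return list with scalar `value` and the pointwise `density` field.
#' @export
interaction_energy <- function(state, params = state$params) {
  n <- params$grid_n
  dx <- params$L / n
  N <- dim(state$phi)[3]
  if (N < 2) {
    return(list(value = 0, density = matrix(0, n, n)))
  }
  sumW <- matrix(0, n, n)
  for (i in seq_len(N)) sumW <- sumW + interaction_w(state$phi[, , i], params$a)
  dens <- matrix(0, n, n)
  for (i in seq_len(N)) {
    p <- state$phi[, , i]
    dens <- dens + indicator_B(p) * (sumW - interaction_w(p, params$a))
  }
  dens <- dens / params$In
  list(value = sum(dens) * dx^2, density = dens)
}

#' Total free energy
#'
#' @inheritParams ch_energy
#' @param include_interaction include the interaction term in the returned
#'   density and value (default) or restrict to the Cahn-Hilliard part.
#' @return list with `value`, `density`, and the two components `ch`, `int`.
#' @export
free_energy <- function(state, params = state$params,
                        include_interaction = TRUE) {
  ch <- ch_energy(state, params)
  int <- interaction_energy(state, params)
  if (include_interaction) {
    list(value = ch$value + int$value, density = ch$density + int$density,
         ch = ch$value, int = int$value)
  } else {
    list(value = ch$value, density = ch$density, ch = ch$value,
         int = int$value)
  }
}

#' Chemical potential (variational derivative of the free energy)
#'
#' `dF/dphi_i = (1/Ca)(-eps Lap phi_i + (phi_i^3 - phi_i)/eps) +
#'  (1/In)((1/2) sum_{j != i} w(phi_j) + w'(phi_i) sum_{j != i} B(phi_j))`.
#'
#' @inheritParams ch_energy
#' @param i cell index.
#' @return an `grid_n x grid_n` field.
#' @export
chemical_potential <- function(state, params = state$params, i) {
  N <- dim(state$phi)[3]
  p <- state$phi[, , i]
  mu <- (-params$epsilon * spectral_laplacian(p, params$L) +
           (p^3 - p) / params$epsilon) / params$Ca
  if (N > 1) {
    sumW <- matrix(0, params$grid_n, params$grid_n)
    sumB <- matrix(0, params$grid_n, params$grid_n)
    for (j in seq_len(N)[-i]) {
      sumW <- sumW + interaction_w(state$phi[, , j], params$a)
      sumB <- sumB + indicator_B(state$phi[, , j])
    }
    mu <- mu + (0.5 * sumW + interaction_w_prime(p, params$a) * sumB) / params$In
  }
  mu
}
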