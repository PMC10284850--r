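## Monolayer state container and snapshot persistence.

#' Construct a monolayer state
#'
#' A `monolayer_state` bundles the `N` phase fields (an
#' `grid_n x grid_n x N` array over the periodic domain, +1 inside a cell,
#' -1 outside), the self-propulsion orientations `theta` (radians, wrapped
#' to (-pi, pi]) and the current time `t`.
#'
#' @param phi numeric array `grid_n x grid_n x N`.
#' @param theta numeric vector of length `N`.
#' @param t current simulation time.
#' @param params the [sim_params()] the state belongs to.
#' @return an object of class `monolayer_state`.
#' @export
monolayer_state <- function(phi, theta, t, params) {
  stopifnot(length(dim(phi)) == 3, dim(phi)[1] == dim(phi)[2],
            dim(phi)[3] == length(theta))
  if (dim(phi)[1] != params$grid_n) {
    stop("state grid (", dim(phi)[1], ") does not match params grid_n (",
         params$grid_n, ")")
  }
  structure(list(phi = phi, theta = wrap_angle(theta), t = t,
                 params = params),
            class = "monolayer_state")
}

#' @export
print.monolayer_state <- function(x, ...) {
  cat("<monolayer_state> N =", dim(x$phi)[3], " grid =", dim(x$phi)[1],
      "^2  t =", x$t, "\n")
  invisible(x)
}

#' Cell masses of a state
#'
#' Per-cell mass `integral of B(phi_i) dx`, the diffuse cell area.
#'
#' @param state a `monolayer_state`.
#' @return numeric vector of length `N`.
#' @export
cell_masses <- function(state) {
  dx <- state$params$L / state$params$grid_n
  apply(state$phi, 3, function(p) sum((p + 1) / 2)) * dx^2
}

#' Save / load a monolayer state
#'
#' The snapshot round trip is bit-faithful: all phase fields, orientations,
#' the time stamp, the parameters and the RNG state (if any) are restored
#' exactly. Loading against a mismatched grid is an error.
#'
#' @param state a `monolayer_state`.
#' @param path file path (RDS container).
#' @return `save_state`: `path` invisibly; `load_state`: the state.
#' @export
save_state <- function(state, path) {
  stopifnot(inherits(state, "monolayer_state"))
  rng <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  saveRDS(list(format = "t1phase-state-1", state = state, rng = rng), path)
  invisible(path)
}

#' @param expect_grid_n if not `NULL`, error unless the stored grid matches.
#' @param restore_rng restore the saved RNG state (for exact run resumption).
#' @rdname save_state
#' @export
load_state <- function(path, expect_grid_n = NULL, restore_rng = FALSE) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt or unreadable state container: ", path)
  })
  if (!identical(obj$format, "t1phase-state-1")) {
    stop("not a t1phase state container: ", path)
  }
  st <- obj$state
  if (!is.null(expect_grid_n) && dim(st$phi)[1] != expect_grid_n) {
    stop("stored grid_n (", dim(st$phi)[1], ") does not match expected (",
         expect_grid_n, ")")
  }
  if (restore_rng && !is.null(obj$rng)) {
    assign(".Random.seed", obj$rng, envir = globalenv())
  }
  st
}
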