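## Contact graphs, T1 detection, epicenter localisation.

#' Contact graph of a monolayer state
#'
#' Two cells are in contact when their diffuse interfaces overlap
#' materially: `max over the grid of min(B(phi_i), B(phi_j)) >=
#' contact_threshold`. The threshold (default 0.15) sits below the gap
#' threshold 0.2 so that a forming junctional gap breaks the contact.
#'
#' @param state a [monolayer_state()].
#' @param params a [sim_params()].
#' @return a `contact_graph`: list with save time `t` and `relations`, a
#'   2-column matrix of unordered cell-index pairs.
#' @export
contact_graph <- function(state, params = state$params) {
  N <- dim(state$phi)[3]
  L <- params$L
  dx <- L / params$grid_n
  B <- array(0, dim = dim(state$phi))
  for (i in seq_len(N)) B[, , i] <- indicator_B(state$phi[, , i])
  cen <- t(vapply(seq_len(N), function(i) torus_centroid(B[, , i], L),
                  numeric(2)))
  # generous reach: only centroid pairs closer than the sum of equivalent
  # disk radii plus a few interface widths can possibly touch
  rad <- vapply(seq_len(N), function(i) sqrt(max(sum(B[, , i]), 0) * dx^2 / pi),
                numeric(1))
  rel <- matrix(integer(0), 0, 2)
  if (N >= 2) {
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        if (torus_dist(cen[i, ], cen[j, ], L) >
              1.5 * (rad[i] + rad[j]) + 8 * params$epsilon) next
        if (max(pmin(B[, , i], B[, , j])) >= params$contact_threshold) {
          rel <- rbind(rel, c(i, j))
        }
      }
    }
  }
  structure(list(t = state$t, relations = rel), class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("<contact_graph> t =", x$t, ":", nrow(x$relations), "relations\n")
  invisible(x)
}

.relation_keys <- function(g) {
  if (nrow(g$relations) == 0) character(0)
  else pair_key(g$relations[, 1], g$relations[, 2])
}

.neighbours_of <- function(keys, cell) {
  prs <- lapply(keys, key_to_pair)
  unlist(lapply(prs, function(p) if (cell %in% p) setdiff(p, cell) else NULL))
}

#' Detect T1 transitions in a contact-graph sequence
#'
#' Finite-state tracking of the 5-4-5 neighbour-relation signature: when a
#' contact pair (B, D) disappears, the common neighbours A, C of B and D at
#' the last time the pair was present form the candidate quadruple (all four
#' perimeter relations (A,B), (B,C), (C,D), (D,A) must be present). The
#' event completes at the first time a pair of common neighbours (A, C)
#' bonds with the perimeter intact; if (B, D) reappears first, the candidate
#' is a reversal and is discarded. When more than two common neighbours
#' exist (rosette-like), the completing pair is whichever pair first bonds.
#'
#' Timing conventions (the sampling leaves sub-save timing undefined):
#' `"boundary"` (default) sets `t_start` to the last save at which the lost
#' pair was present and `t_end` to the first save at which the gained pair
#' is present, so the duration is the time for the relation count to go
#' from 5 to 4 and back to 5; `"midpoint"` places both ends halfway between
#' the bracketing saves, halving the quantisation bias (durations are then
#' shorter by exactly one save interval).
#'
#' @param graphs a `contact_sequence` (from a run or
#'   [scripted_contact_sequence()]).
#' @param convention `"boundary"` or `"midpoint"`.
#' @return data frame of class `t1_events`, one row per event: cells
#'   `a, b, c, d` (cyclic order; the lost diagonal is (b, d), the gained
#'   (a, c)), `t_start`, `t_end`, `duration`. Unresolved candidates at the
#'   end of the sequence are counted in `attr(, "dropped")`.
#' @export
detect_t1 <- function(graphs, convention = c("boundary", "midpoint")) {
  convention <- match.arg(convention)
  S <- length(graphs)
  empty <- data.frame(a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), t_start = numeric(0),
                      t_end = numeric(0), duration = numeric(0))
  class(empty) <- c("t1_events", "data.frame")
  attr(empty, "dropped") <- 0L
  if (S < 2) return(empty)
  keys <- lapply(graphs, .relation_keys)
  tt <- vapply(graphs, `[[`, numeric(1), "t")

  events <- list()
  cand <- list()  # open candidates keyed by lost pair
  dropped <- 0L
  for (s in 2:S) {
    now <- keys[[s]]
    prev <- keys[[s - 1]]

    # close or discard open candidates
    for (ck in names(cand)) {
      cd <- cand[[ck]]
      if (ck %in% now) {  # lost pair back: reversal
        cand[[ck]] <- NULL
        next
      }
      gained <- NULL
      for (pk in cd$completing) {
        if (pk %in% now && !(pk %in% prev)) {
          # perimeter must be intact at the closing save
          AC <- key_to_pair(pk)
          BD <- key_to_pair(ck)
          perim <- pair_key(c(AC[1], BD[1], AC[2], BD[2]),
                            c(BD[1], AC[2], BD[2], AC[1]))
          if (all(perim %in% now)) {
            gained <- pk
            break
          }
        }
      }
      if (!is.null(gained)) {
        AC <- key_to_pair(gained)
        BD <- key_to_pair(ck)
        if (convention == "boundary") {
          t0 <- cd$t_last_present
          t1 <- tt[s]
        } else {
          t0 <- (cd$t_last_present + cd$t_first_absent) / 2
          t1 <- (tt[s - 1] + tt[s]) / 2
        }
        events[[length(events) + 1]] <-
          data.frame(a = AC[1], b = BD[1], c = AC[2], d = BD[2],
                     t_start = t0, t_end = t1, duration = t1 - t0)
        cand[[ck]] <- NULL
      }
    }

    # open new candidates for pairs lost at this save
    for (ck in setdiff(prev, now)) {
      BD <- key_to_pair(ck)
      nb1 <- .neighbours_of(prev, BD[1])
      nb2 <- .neighbours_of(prev, BD[2])
      common <- setdiff(intersect(nb1, nb2), BD)
      if (length(common) < 2) next
      # completing pairs: common-neighbour pairs not already bonded
      cmb <- utils::combn(sort(common), 2)
      comp <- pair_key(cmb[1, ], cmb[2, ])
      comp <- comp[!(comp %in% prev)]
      if (length(comp) == 0) next
      cand[[ck]] <- list(t_last_present = tt[s - 1], t_first_absent = tt[s],
                         completing = comp)
    }
  }
  dropped <- length(cand)
  if (length(events) == 0) {
    attr(empty, "dropped") <- dropped
    return(empty)
  }
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$t_start), ]
  rownames(ev) <- NULL
  class(ev) <- c("t1_events", "data.frame")
  attr(ev, "dropped") <- dropped
  ev
}

#' @export
print.t1_events <- function(x, ...) {
  cat("<t1_events>", nrow(x), "events")
  if (nrow(x) > 0) {
    cat(", mean duration", signif(mean(x$duration), 4))
  }
  dropped <- attr(x, "dropped")
  if (!is.null(dropped)) cat(" (", dropped, "unresolved dropped )")
  cat("\n")
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Geometric median on the periodic domain (Weiszfeld iteration)
#'
#' Minimises the total distance to a set of points under the torus metric.
#' Points are mapped to their minimal-image representatives around the
#' current iterate each sweep; an iterate landing on a data point is
#' perturbed by half a tolerance step.
#'
#' @param pts 2-column matrix of points.
#' @param L domain period.
#' @param tol convergence tolerance (default `1e-8 * L`).
#' @param max_iter iteration cap.
#' @return the median point in `[0, L)^2`.
#' @export
weiszfeld_median <- function(pts, L, tol = 1e-8 * L, max_iter = 1000L) {
  pts <- matrix(pts, ncol = 2)
  # The torus makes the objective multimodal when the points are spread
  # over the domain, so iterate from several starts (the circular mean and
  # every data point) and keep the best local optimum. For T1 epicenters
  # the four centres are clustered and all starts coincide.
  obj <- function(y) {
    sum(sqrt(torus_diff(pts[, 1], y[1], L)^2 +
               torus_diff(pts[, 2], y[2], L)^2))
  }
  lattice <- as.matrix(expand.grid((0:3 + 0.5) * L / 4, (0:3 + 0.5) * L / 4))
  starts <- rbind(c(Arg(sum(exp(1i * 2 * pi * pts[, 1] / L))) / (2 * pi) * L,
                    Arg(sum(exp(1i * 2 * pi * pts[, 2] / L))) / (2 * pi) * L)
                  %% L,
                  pts + tol,
                  lattice)
  cand <- t(apply(starts, 1, .weiszfeld_from, pts = pts, L = L, tol = tol,
                  max_iter = max_iter))
  best <- which.min(apply(cand, 1, obj))
  cand[best, ]
}

.weiszfeld_from <- function(y, pts, L, tol, max_iter) {
  for (it in seq_len(max_iter)) {
    # minimal-image representatives around the current iterate
    rep_pts <- cbind(y[1] + torus_diff(pts[, 1], y[1], L),
                     y[2] + torus_diff(pts[, 2], y[2], L))
    d <- sqrt((rep_pts[, 1] - y[1])^2 + (rep_pts[, 2] - y[2])^2)
    if (any(d < tol / 2)) {
      # on a data point: if it is the median, done; else nudge off it
      k <- which.min(d)
      others <- rep_pts[-k, , drop = FALSE]
      do <- sqrt((others[, 1] - y[1])^2 + (others[, 2] - y[2])^2)
      dirsum <- colSums((others - matrix(y, nrow(others), 2,
                                         byrow = TRUE)) / do)
      if (sqrt(sum(dirsum^2)) <= 1) break
      y <- y + tol * dirsum / sqrt(sum(dirsum^2))
      next
    }
    w <- 1 / d
    ynew <- c(sum(rep_pts[, 1] * w), sum(rep_pts[, 2] * w)) / sum(w)
    if (sqrt(sum((ynew - y)^2)) < tol) {
      y <- ynew
      break
    }
    y <- ynew
  }
  y %% L
}

#' Epicenter of a T1 event
#'
#' The geometric median (under the periodic metric) of the B-weighted
#' centroids of the four participating cells, evaluated at the save time
#' nearest the temporal midpoint of the event.
#'
#' @param event one row of a [detect_t1()] result (or a list with the same
#'   fields).
#' @param run a `monolayer_run` (supplies the per-save centroids).
#' @return numeric epicenter `c(x, y)` with attribute `t_mid`, the save
#'   time used.
#' @export
t1_epicenter <- function(event, run) {
  tmid <- (event$t_start + event$t_end) / 2
  k <- which.min(abs(run$times - tmid))
  ob <- run$obs[run$obs$t == run$times[k], ]
  cells <- c(event$a, event$b, event$c, event$d)
  pts <- as.matrix(ob[match(cells, ob$cell), c("x", "y")])
  e <- weiszfeld_median(pts, run$params$L)
  attr(e, "t_mid") <- run$times[k]
  e
}
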