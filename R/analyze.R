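## Full analysis of a finished run: events, epicenters, statistics, outputs.

#' Analyse a monolayer run for T1 transitions
#'
#' Runs the complete event toolchain on a `monolayer_run`: detects T1
#' events from the contact-graph sequence, localises their epicenters,
#' records the peak coarse-grained energy at the epicenter during each
#' event, builds the event-aligned energy / shape-index / velocity
#' profiles, fits the duration distribution, computes the duration-energy
#' rank correlation and groups chained events.
#'
#' @param run a `monolayer_run` (with stored energy fields).
#' @param window profile alignment half-window in time units.
#' @param r_chain,dt_chain chaining thresholds; defaults: two cell radii
#'   and twice the mean duration.
#' @param out_dir if not `NULL`, write `events.csv`, `profiles.csv`,
#'   `cells.csv`, `durations.csv`, `chains.csv` and `summary.json` there.
#' @param convention duration convention passed to [detect_t1()].
#' @return an object of class `t1_analysis`.
#' @export
analyze_run <- function(run, window = 20, r_chain = NULL, dt_chain = NULL,
                        out_dir = NULL, convention = "boundary") {
  stopifnot(inherits(run, "monolayer_run"))
  p <- run$params
  events <- detect_t1(run$graphs, convention = convention)
  events <- .attach_epicenters(events, run)

  # peak coarse-grained energy at the epicenter over the event
  if (nrow(events) > 0 && !is.null(run$f_ravg)) {
    events$max_energy <- vapply(seq_len(nrow(events)), function(e) {
      ks <- which(run$times >= events$t_start[e] - 1e-9 &
                    run$times <= events$t_end[e] + 1e-9)
      max(vapply(ks, function(k) {
        interp_periodic(run$f_ravg[[k]],
                        c(events$epi_x[e], events$epi_y[e]), p$L)
      }, numeric(1)))
    }, numeric(1))
  }

  profiles <- NULL
  sv <- NULL
  dve <- NULL
  if (nrow(events) > 0) {
    if (!is.null(run$f_ravg)) {
      profiles <- event_energy_profile(run, events, window = window)
    }
    sv <- event_shape_velocity_profiles(run, events, window = window)
    if (!is.null(events$max_energy) && nrow(events) >= 1) {
      dve <- duration_vs_max_energy(events)
    }
  }
  dstats <- duration_stats(events)

  cell_rad <- sqrt(p$L^2 / (pi * p$N))
  if (is.null(r_chain)) r_chain <- 2 * cell_rad
  if (is.null(dt_chain)) {
    dt_chain <- if (nrow(events) > 0) 2 * max(mean(events$duration),
                                              p$tau_save) else 2 * p$tau_save
  }
  chains <- chain_candidates(events, r_chain, dt_chain, p$L)

  out <- structure(list(events = events, duration_stats = dstats,
                        energy_profile = profiles,
                        shape_profile = sv$shape,
                        velocity_profile = sv$velocity,
                        duration_energy = dve, chains = chains,
                        r_chain = r_chain, dt_chain = dt_chain,
                        params = p,
                        mean_gap_fraction = mean(run$gap_fraction)),
                   class = "t1_analysis")
  if (!is.null(out_dir)) write_analysis(out, run, out_dir)
  out
}

#' @export
print.t1_analysis <- function(x, ...) {
  cat("<t1_analysis>", nrow(x$events), "T1 events\n")
  if (nrow(x$events) > 0) {
    cat("  mean duration:", signif(x$duration_stats$mean, 5),
        " ( n =", x$duration_stats$n, ")\n")
    if (!is.null(x$duration_stats$fit)) {
      cat("  Gamma fit: shape", signif(x$duration_stats$fit$shape, 4),
          " scale", signif(x$duration_stats$fit$scale, 4), "\n")
    }
    if (!is.null(x$duration_energy)) {
      cat("  Spearman(duration, max energy):",
          signif(x$duration_energy$spearman, 4), "\n")
    }
    if (!is.null(x$energy_profile)) {
      asym <- profile_asymmetry(x$energy_profile)
      cat("  energy profile: start/end", signif(x$energy_profile$start_value, 5),
          "/", signif(x$energy_profile$end_value, 5),
          " baseline", signif(x$energy_profile$baseline, 5), "\n")
      cat("  baseline rise/decay times:", signif(asym[1], 4), "/",
          signif(asym[2], 4), "\n")
    }
    nch <- sum(vapply(x$chains, length, integer(1)) > 1)
    cat("  chains with >1 event:", nch, "\n")
  }
  cat("  mean gap fraction:", signif(x$mean_gap_fraction, 4), "\n")
  invisible(x)
}

#' Write analysis outputs to a directory
#'
#' @param analysis a [analyze_run()] result.
#' @param run the analysed run (for `cells.csv`).
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(analysis, run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ev <- analysis$events
  evout <- data.frame(cell_a = ev$a, cell_b = ev$b, cell_c = ev$c,
                      cell_d = ev$d,
                      lost_pair = paste0("(", ev$b, ",", ev$d, ")"),
                      gained_pair = paste0("(", ev$a, ",", ev$c, ")"),
                      t_start = ev$t_start, t_end = ev$t_end,
                      duration = ev$duration,
                      epicenter_x = ev$epi_x, epicenter_y = ev$epi_y,
                      max_energy = if (is.null(ev$max_energy)) NA else
                        ev$max_energy)
  write.csv(evout, file.path(out_dir, "events.csv"), row.names = FALSE)
  write.csv(run$obs, file.path(out_dir, "cells.csv"), row.names = FALSE)
  prof <- list()
  for (nm in c("energy_profile", "shape_profile", "velocity_profile")) {
    pr <- analysis[[nm]]
    if (is.null(pr)) next
    lab <- sub("_profile", "", nm)
    prof[[nm]] <- rbind(
      data.frame(quantity = lab, side = "pre", pr$pre),
      data.frame(quantity = lab, side = "post", pr$post))
  }
  if (length(prof) > 0) {
    write.csv(do.call(rbind, prof), file.path(out_dir, "profiles.csv"),
              row.names = FALSE)
  }
  write.csv(data.frame(duration = ev$duration),
            file.path(out_dir, "durations.csv"), row.names = FALSE)
  if (length(analysis$chains) > 0) {
    ch <- do.call(rbind, lapply(seq_along(analysis$chains), function(k) {
      data.frame(chain = k, event = analysis$chains[[k]],
                 order = seq_along(analysis$chains[[k]]))
    }))
    write.csv(ch, file.path(out_dir, "chains.csv"), row.names = FALSE)
  }
  summ <- list(
    n_events = nrow(ev),
    mean_duration = analysis$duration_stats$mean,
    gamma_fit = analysis$duration_stats$fit,
    spearman_duration_energy =
      if (is.null(analysis$duration_energy)) NULL else
        as.numeric(analysis$duration_energy$spearman),
    mean_gap_fraction = analysis$mean_gap_fraction,
    params = unclass(analysis$params))
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
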