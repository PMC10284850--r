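## Model parameters and configuration files.

.model_defaults <- list(
  tau = 0.005, tau_save = 0.5, T = 150, L = 100, epsilon = 0.15,
  v0 = 0.5, a = 1.5, Ca = 0.2, In = 0.1, D_r = 0.1, alpha = 0.1
)

## Geometry completions for the two run profiles. The model reference gives
## no cell number or mesh resolution; these are this package's documented
## choices (see the methods vignette).
##   full: the full reference geometry (L = 100). The interface-resolution
##     invariant dx <= epsilon/2 then forces 2048 grid points per side;
##     running it is a multi-hour commitment.
##   desk:  reduced geometry with the same interface width, cell area ~25
##     (cell radius ~2.8). Two derived quantities are rescaled to preserve
##     the reference regime at the smaller cell radius: the coarse-graining
##     radius keeps the same fraction of the cell radius (r_avg ~ 0.355 R)
##     and the activity keeps the same driving-to-line-tension ratio
##     (v0 ~ R_ref / R_desk times the reference value), which restores the
##     reference per-cell T1 rate.
.profile_defaults <- list(
  full = list(N = 100, grid_n = 2048, r_avg_frac = 0.02),
  desk  = list(N = 13, grid_n = 256, L = 18, T = 60, r_avg_frac = 0.055,
               v0 = 1.0)
)

#' Model and solver parameters
#'
#' Construct the validated parameter set of the multi-phase field model:
#' the time step `tau`, save interval `tau_save`, total time `T`, domain
#' side `L`, interface width `epsilon`, activity `v0`, interaction shape
#' parameter `a` (`a = 1` pure repulsion, `a > 1` repulsion plus adhesion),
#' capillary number `Ca` (deformability), interaction number `In`,
#' rotational diffusivity `D_r` and elongation-alignment rate `alpha`,
#' together with the solver/analysis settings (`N` cells, `grid_n` points
#' per side, coarse-graining radius fraction `r_avg_frac`, thresholds,
#' mode and seed).
#'
#' @param profile `"full"` for the full reference geometry or `"desk"` for
#'   the reduced geometry used by the examples and tests.
#' @param ... named overrides of any parameter field.
#' @return an object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params("desk", N = 4, L = 8, grid_n = 128, T = 5)
#' p$Ca
#' @export
sim_params <- function(profile = c("full", "desk"), ...) {
  profile <- match.arg(profile)
  p <- c(.model_defaults, list(
    N = 100, grid_n = 2048, seed = 1L,
    r_avg_frac = 0.02, gap_threshold = 0.2, contact_threshold = 0.15,
    mode = "active", sigma_stab = NA_real_, beta_rule = "nearest"
  ))
  p <- modifyList(p, .profile_defaults[[profile]])
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  }
  p <- modifyList(p, over)
  p$profile <- profile
  if (is.na(p$sigma_stab)) {
    # stabilising split constant of the semi-implicit scheme; bounds the
    # explicit linearised well term |f''|/(eps*Ca) <= 2/(eps*Ca)
    p$sigma_stab <- 2 / (p$epsilon * p$Ca)
  }
  class(p) <- "sim_params"
  validate_params(p)
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> profile:", x$profile, " mode:", x$mode, "\n")
  num <- vapply(x, is.numeric, logical(1))
  v <- unlist(x[num])
  cat(paste(names(v), signif(v, 6), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

validate_params <- function(p) {
  chk <- function(ok, msg) if (!ok) stop("invalid parameter: ", msg,
                                         call. = FALSE)
  chk(p$tau > 0, "tau must be > 0")
  chk(p$tau_save >= p$tau, "tau_save must be >= tau")
  chk(p$T >= p$tau_save, "T must be >= tau_save")
  chk(p$L > 0, "L must be > 0")
  chk(p$epsilon > 0, "epsilon must be > 0")
  chk(p$Ca > 0, "Ca must be > 0")
  chk(p$In > 0, "In must be > 0")
  chk(p$a >= 1, "a must be >= 1")
  chk(p$D_r >= 0, "D_r must be >= 0")
  chk(p$alpha >= 0, "alpha must be >= 0")
  chk(p$v0 >= 0, "v0 must be >= 0")
  chk(p$N >= 2, "N must be >= 2")
  chk(p$grid_n >= 8 && bitwAnd(p$grid_n, p$grid_n - 1L) == 0,
      "grid_n must be a power of two")
  chk(p$L / p$grid_n <= p$epsilon / 2,
      "grid spacing L/grid_n must be <= epsilon/2 (interface resolution)")
  chk(p$gap_threshold > 0 && p$gap_threshold < 1, "gap_threshold in (0,1)")
  chk(p$contact_threshold > 0 && p$contact_threshold < 1,
      "contact_threshold in (0,1)")
  chk(p$mode %in% c("active", "passive_shear"),
      "mode must be 'active' or 'passive_shear'")
  chk(p$beta_rule %in% c("nearest", "literal"),
      "beta_rule must be 'nearest' or 'literal'")
  chk(p$r_avg_frac * p$L >= 2 * p$L / p$grid_n,
      "r_avg must cover at least 2 grid spacings")
  invisible(p)
}

.config_fields <- c("tau", "tau_save", "T", "L", "epsilon", "v0", "a", "Ca",
                    "In", "D_r", "alpha", "N", "grid_n", "seed", "r_avg_frac",
                    "gap_threshold", "contact_threshold", "mode",
                    "sigma_stab", "beta_rule", "profile")

#' Read model parameters from a flat key-value configuration file
#'
#' The file holds one `key = value` pair per line (TOML-style flat table);
#' keys are the transliterated model symbols (`tau`, `tau_save`, `T`, `L`,
#' `epsilon`, `v0`, `a`, `Ca`, `In`, `D_r`, `alpha`) plus solver fields.
#' Omitted keys take the default values of the chosen profile; unknown keys
#' are an error.
#'
#' @param path path to the configuration file.
#' @param profile profile supplying defaults for omitted keys.
#' @return a validated [sim_params()] object.
#' @export
load_config <- function(path, profile = "full") {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: '", ln, "'")
    key <- m[2]
    val <- gsub("^\"|\"$", "", trimws(m[3]))
    if (!key %in% .config_fields) stop("unknown config key: ", key)
    if (key %in% c("mode", "beta_rule", "profile")) {
      over[[key]] <- val
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("non-numeric value for key ", key, ": ", val)
      over[[key]] <- if (key %in% c("N", "grid_n", "seed")) as.integer(num) else num
    }
  }
  if (!is.null(over$profile)) {
    profile <- over$profile
    over$profile <- NULL
  }
  do.call(sim_params, c(list(profile = profile), over))
}

#' Write model parameters to a flat key-value configuration file
#'
#' Inverse of [load_config()]: `load_config(write_config(p, f))` returns a
#' parameter set identical to `p`.
#'
#' @param params a [sim_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  fmt <- function(key) {
    v <- params[[key]]
    if (is.character(v)) sprintf("%s = \"%s\"", key, v)
    else sprintf("%s = %.17g", key, v)
  }
  writeLines(c(sprintf("profile = \"%s\"", params$profile),
               vapply(setdiff(.config_fields, "profile"), fmt, character(1))),
             path)
  invisible(path)
}
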