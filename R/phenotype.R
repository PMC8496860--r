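#' Scan settings for single-parameter phenotype switching
#'
#' @param n_points number of log-spaced multipliers (default 48).
#' @param decades half-width of the scan in orders of magnitude (default
#'   3, i.e. multipliers from 1e-3 to 1e+3, endpoints inclusive).
#' @return list of class `gal_scan_config`.
#' @export
scan_config <- function(n_points = 48, decades = 3) {
  structure(list(n_points = as.integer(n_points), decades = decades),
            class = "gal_scan_config")
}

scan_multipliers <- function(cfg = scan_config()) {
  10^seq(-cfg$decades, cfg$decades, length.out = cfg$n_points)
}

## profile cache shared across strains in a sweep: the simulated profile
## of a perturbed parameter set does not depend on the strain table
profile_cache <- function() new.env(parent = emptyenv())

cached_profile <- function(cache, params, grid, cfg) {
  key <- paste(format(as.numeric(params), digits = 15), collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  prof <- try(suppressMessages(simulate_grid(params, grid, cfg)),
              silent = TRUE)
  if (!is.null(cache)) cache[[key]] <- prof
  prof
}

#' Scan one parameter against a strain table
#'
#' Evaluates the fitting objective at 48 multipliers evenly log-spaced
#' across six orders of magnitude centred on the default value (1e-3 to
#' 1e+3, endpoints inclusive), plus the x1 default as an extra candidate
#' so the best objective can never exceed the starting one. Ties are
#' broken toward the multiplier closest to 1.
#'
#' @param base_params starting `gal_params`.
#' @param table strain table to fit.
#' @param name parameter to scan.
#' @param cfg a [scan_config()].
#' @param grid,cfg_solver grid and solver settings for the objective.
#' @param cache optional [profile_cache()] shared across scans.
#' @return tibble of class `gal_scan` with columns `multiplier`,
#'   `objective`, `valid`; attributes `parameter`, `best_multiplier`,
#'   `best_objective`, `obj_start`.
#' @export
scan_parameter <- function(base_params, table, name, cfg = scan_config(),
                           grid = sugar_grid(), cfg_solver = solver_config(),
                           cache = NULL) {
  if (!name %in% .gal_param_names) {
    abort(paste0("Unknown parameter: ", name))
  }
  mult <- sort(unique(c(scan_multipliers(cfg), 1)))
  objs <- rep(NA_real_, length(mult))
  for (i in seq_along(mult)) {
    p <- make_variant(base_params, stats::setNames(mult[i], name))
    prof <- cached_profile(cache, p, grid, cfg_solver)
    if (inherits(prof, "try-error")) next
    objs[i] <- tryCatch(objective_from_profile(prof, table),
                        error = function(e) NA_real_)
  }
  if (all(is.na(objs))) abort("Objective failed at every multiplier.")
  valid <- !is.na(objs)
  best_obj <- min(objs[valid])
  cand <- which(valid & objs <= best_obj)
  best_i <- cand[which.min(abs(log10(mult[cand])))]
  out <- tibble::tibble(multiplier = mult, objective = objs, valid = valid)
  class(out) <- c("gal_scan", class(out))
  attr(out, "parameter") <- name
  attr(out, "best_multiplier") <- mult[best_i]
  attr(out, "best_objective") <- objs[best_i]
  attr(out, "obj_start") <- objs[mult == 1]
  out
}

#' Fitting improvement
#'
#' `(obj_start - obj_best) / obj_start`, the fraction of the starting
#' objective removed by the best single-parameter modification; 0 when
#' nothing improves (including the degenerate already-perfect case
#' `obj_start = 0`).
#'
#' @param obj_start objective at the default parameters (>= 0).
#' @param obj_best best objective over the scan (<= `obj_start`).
#' @return improvement in \[0, 1).
#' @export
#' @examples
#' improvement(10, 1)  # 0.9
improvement <- function(obj_start, obj_best) {
  if (obj_start < 0 || obj_best < 0) abort("Objectives must be non-negative.")
  if (obj_best > obj_start + 1e-12) {
    abort("obj_best must not exceed obj_start (the x1 candidate guarantees this).")
  }
  ## a starting objective at numerical zero is an already-perfect fit
  if (obj_start < 1e-12) return(0)
  (obj_start - min(obj_best, obj_start)) / obj_start
}

#' Strain-by-parameter fitting-improvement matrix
#'
#' For every (strain, parameter) pair, scans the parameter across six
#' orders of magnitude and records the fitting improvement and the best
#' multiplier. Simulated profiles are cached across strains, since a
#' perturbed parameter set's profile does not depend on the strain being
#' fitted.
#'
#' @param base_params starting `gal_params`.
#' @param panel list of strain tables.
#' @param param_names parameters to scan (default: all 45).
#' @param cfg a [scan_config()].
#' @inheritParams scan_parameter
#' @return tibble of class `improvement_matrix` with columns `strain`,
#'   `parameter`, `delta_obj`, `best_multiplier`, `obj_start`,
#'   `obj_best`.
#' @export
improvement_matrix <- function(base_params, panel,
                               param_names = galswitch::param_names(),
                               cfg = scan_config(), grid = sugar_grid(),
                               cfg_solver = solver_config()) {
  if (length(panel) == 0) abort("Panel must contain at least one strain.")
  cache <- profile_cache()
  rows <- list()
  for (tab in panel) {
    sid <- tab$strain_id[1] %||% "strain"
    for (nm in param_names) {
      sc <- tryCatch(
        scan_parameter(base_params, tab, nm, cfg, grid, cfg_solver, cache),
        error = function(e) NULL)
      rows[[length(rows) + 1]] <- if (is.null(sc)) {
        tibble::tibble(strain = sid, parameter = nm, delta_obj = NA_real_,
                       best_multiplier = NA_real_, obj_start = NA_real_,
                       obj_best = NA_real_)
      } else {
        tibble::tibble(
          strain = sid, parameter = nm,
          delta_obj = improvement(attr(sc, "obj_start"),
                                  attr(sc, "best_objective")),
          best_multiplier = attr(sc, "best_multiplier"),
          obj_start = attr(sc, "obj_start"),
          obj_best = attr(sc, "best_objective"))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("improvement_matrix", class(out))
  out
}
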