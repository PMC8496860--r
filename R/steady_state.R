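#' Solver and classification settings
#'
#' Collects the numerical settings shared by all steady-state machinery.
#' Convergence is declared when the maximum relative change of every state
#' component across one window of duration `t_window` falls below
#' `rel_tol`; integration gives up (and the condition is masked) at
#' `t_max`.
#'
#' @param rel_tol relative steady-state tolerance per window.
#' @param t_window window duration in model time units.
#' @param t_max maximum integration time.
#' @param on_init_gal galactose concentration (% w/v) used to
#'   pre-equilibrate the ON initial condition.
#' @param fold_threshold fold ratio of high over low state required to call
#'   a condition bimodal.
#' @param epsilon floor applied to the low state before the fold-ratio
#'   test, so a true-zero OFF state with an induced ON state is bimodal.
#' @param ode_rtol,ode_atol tolerances handed to the stiff integrator.
#' @param mode `"dual"` equilibrates every condition from the shared
#'   ON/OFF initial states; `"titrate"` sweeps the galactose ladder in
#'   both directions, seeding each condition with the previous steady
#'   state.
#' @return a list of class `gal_solver_config`.
#' @export
solver_config <- function(rel_tol = 1e-6, t_window = 100, t_max = 1e5,
                          on_init_gal = 2, fold_threshold = 5,
                          epsilon = 1e-9, ode_rtol = 1e-8, ode_atol = 1e-10,
                          mode = c("dual", "titrate")) {
  structure(list(rel_tol = rel_tol, t_window = t_window, t_max = t_max,
                 on_init_gal = on_init_gal, fold_threshold = fold_threshold,
                 epsilon = epsilon, ode_rtol = ode_rtol, ode_atol = ode_atol,
                 mode = match.arg(mode)),
            class = "gal_solver_config")
}

as_solver_config <- function(cfg) {
  if (is.null(cfg)) return(solver_config())
  if (inherits(cfg, "gal_solver_config")) return(cfg)
  do.call(solver_config, cfg)
}

#' Integrate the model to steady state
#'
#' Integrates the GAL network ODEs from `init` under fixed external sugars
#' until every state component changes by less than `rel_tol` (relative)
#' across a window of `t_window` time units, or `t_max` is reached.
#' Non-convergence is flagged, not fatal. Tiny negative undershoot from
#' the integrator is clamped to zero; a large negative component aborts
#' with a stiffness diagnostic.
#'
#' @param params a `gal_params` object.
#' @param condition a [sugar_condition()].
#' @param init named non-negative state vector (see [zero_state()]).
#' @param cfg a [solver_config()].
#' @return the final state vector with attributes `converged` (logical)
#'   and `time` (integration time used).
#' @export
equilibrate <- function(params, condition, init = zero_state(),
                        cfg = solver_config()) {
  cfg <- as_solver_config(cfg)
  if (any(init < 0)) abort("Initial state must be non-negative.")
  p <- compiled_parms(params, condition)
  y <- as.numeric(init)
  names(y) <- .gal_state_names
  t_now <- 0
  chunk <- 10L  # windows per integrator call; grows geometrically
  converged <- FALSE
  while (t_now < cfg$t_max && !converged) {
    n_win <- min(chunk, ceiling((cfg$t_max - t_now) / cfg$t_window))
    times <- t_now + cfg$t_window * (0:n_win)
    ## capture.output keeps the Fortran solver's diagnostics (printed
    ## directly to the console on pathological parameter sets) out of
    ## logs; failures are handled through istate below
    utils::capture.output(sol <- suppressWarnings(
      deSolve::ode(y = y, times = times, func = "gal_derivs",
                   parms = p, dllname = "galswitch",
                   initfunc = "gal_initmod", method = "lsoda",
                   rtol = cfg$ode_rtol, atol = cfg$ode_atol,
                   maxsteps = 100000)))
    istate <- attr(sol, "istate")[1]
    if (!is.null(istate) && istate < 0) {
      ## integrator gave up (excess work / repeated step failures): the
      ## caller treats this like any non-converged condition
      last <- sol[nrow(sol), -1]
      last[!is.finite(last) | last < 0] <- 0
      names(last) <- .gal_state_names
      attr(last, "converged") <- FALSE
      attr(last, "time") <- sol[nrow(sol), 1]
      return(last)
    }
    mat <- unname(sol[, -1, drop = FALSE])
    if (min(mat) < -1e-6) {
      abort("Integration produced a large negative component; the system appears numerically stiff beyond tolerance.")
    }
    mat[mat < 0] <- 0
    for (i in 2:nrow(mat)) {
      ref <- pmax(abs(mat[i, ]), cfg$ode_atol * 10)
      if (max(abs(mat[i, ] - mat[i - 1, ]) / ref) < cfg$rel_tol) {
        converged <- TRUE
        y <- mat[i, ]
        t_now <- times[i]
        break
      }
    }
    if (!converged) {
      y <- mat[nrow(mat), ]
      t_now <- times[length(times)]
    }
    chunk <- min(chunk * 2L, 160L)
  }
  names(y) <- .gal_state_names
  attr(y, "converged") <- converged
  attr(y, "time") <- t_now
  y
}

#' ON and OFF initial conditions
#'
#' The OFF state is the steady state in the absence of both sugars; the
#' ON state is the steady state after pre-equilibration in saturating
#' galactose (`on_init_gal`, default 2% w/v) without glucose. Both start
#' from the zero state.
#'
#' @inheritParams equilibrate
#' @return list with elements `on` and `off` (state vectors).
#' @export
on_off_inits <- function(params, cfg = solver_config()) {
  cfg <- as_solver_config(cfg)
  off <- equilibrate(params, sugar_condition(0, 0), zero_state(), cfg)
  on <- if (cfg$on_init_gal == 0) off else {
    equilibrate(params, sugar_condition(0, cfg$on_init_gal), zero_state(), cfg)
  }
  list(on = on, off = off)
}

#' Default sugar grid
#'
#' The experimental design: a twofold glucose dilution ladder from 1% to
#' 0.015625% plus zero (8 levels) crossed with a twofold galactose ladder
#' from 4% to 0.00390625% plus zero (12 levels), 96 conditions in total.
#' Levels are stored exactly (unrounded), strictly decreasing with the
#' zero level last.
#'
#' @param glucose_levels,galactose_levels optional custom ladders
#'   (% w/v).
#' @return list of class `sugar_grid` with fields `glucose` and
#'   `galactose`.
#' @export
#' @examples
#' g <- sugar_grid()
#' nrow(grid_conditions(g))  # 96
sugar_grid <- function(glucose_levels = c(1 / 2^(0:6), 0),
                       galactose_levels = c(4 / 2^(0:10), 0)) {
  if (any(glucose_levels < 0) || any(galactose_levels < 0)) {
    abort("Grid levels must be non-negative.")
  }
  structure(list(glucose = as.numeric(glucose_levels),
                 galactose = as.numeric(galactose_levels)),
            class = "sugar_grid")
}

#' @rdname sugar_grid
#' @param grid a `sugar_grid`.
#' @return `grid_conditions()`: tibble with one row per (glucose,
#'   galactose) condition.
#' @export
grid_conditions <- function(grid) {
  tidyr::expand_grid(glucose = grid$glucose, galactose = grid$galactose)
}

#' Default growth mask
#'
#' The four lowest-galactose cells of the zero-glucose row support very
#' poor to no growth and are excluded by default from normalization,
#' classification summaries, and objective functions.
#'
#' @param grid a `sugar_grid`.
#' @return logical vector aligned with `grid_conditions(grid)`; `TRUE`
#'   marks a masked cell.
#' @export
default_growth_mask <- function(grid) {
  cond <- grid_conditions(grid)
  low_gal <- sort(grid$galactose)[seq_len(min(4L, length(grid$galactose)))]
  cond$glucose == 0 & cond$galactose %in% low_gal
}

#' Classify the modality of one condition
#'
#' A condition is bimodal when the high steady state is at least
#' `fold_threshold`-fold (default 5) above the low steady state (low state
#' floored at `epsilon`); otherwise it is unimodal ON when the high state
#' reaches the profile half-maximum, else unimodal OFF.
#'
#' @param g1_high,g1_low high/low steady-state Gal1p levels
#'   (`g1_high >= g1_low >= 0`); vectorized.
#' @param profile_half_max half of the profile's maximum high level.
#' @param fold_threshold bimodality fold threshold (boundary inclusive).
#' @param epsilon floor for the low state.
#' @return character vector in
#'   `c("unimodal_OFF", "unimodal_ON", "bimodal")`.
#' @export
#' @examples
#' classify_modality(5, 1, profile_half_max = 2)  # "bimodal"
classify_modality <- function(g1_high, g1_low, profile_half_max,
                              fold_threshold = 5, epsilon = 1e-9) {
  if (any(g1_low < 0) || any(g1_high < g1_low)) {
    abort("Require g1_high >= g1_low >= 0.")
  }
  if (profile_half_max <= 0) abort("profile_half_max must be > 0.")
  ifelse(g1_high >= fold_threshold * pmax(g1_low, epsilon), "bimodal",
         ifelse(g1_high >= profile_half_max, "unimodal_ON", "unimodal_OFF"))
}

equilibrate_g1 <- function(params, glucose, galactose, init, cfg) {
  s <- equilibrate(params, sugar_condition(glucose, galactose), init, cfg)
  s
}

#' Simulate an induction profile over a sugar grid
#'
#' For every condition the system is equilibrated from the shared ON and
#' OFF initial states (or, in titration mode, by continuation along the
#' galactose ladder in both sweep directions). High/low Gal1p levels are
#' normalized to the profile maximum over unmasked cells and each
#' condition is classified as unimodal OFF, unimodal ON, or bimodal.
#'
#' @param params a `gal_params` object.
#' @param grid a [sugar_grid()].
#' @param cfg a [solver_config()].
#' @param mask logical vector of masked cells aligned with
#'   `grid_conditions(grid)`, or `NULL` for the default growth mask.
#' @return a tibble of class `induction_profile` with columns `glucose`,
#'   `galactose`, `g1_high`, `g1_low`, `converged_high`, `converged_low`,
#'   `normalized_high`, `normalized_low`, `modality`, `masked`.
#' @export
simulate_grid <- function(params, grid = sugar_grid(), cfg = solver_config(),
                          mask = NULL) {
  cfg <- as_solver_config(cfg)
  mask <- mask %||% default_growth_mask(grid)
  cond <- grid_conditions(grid)
  stopifnot(length(mask) == nrow(cond))
  inits <- on_off_inits(params, cfg)

  hi <- lo <- numeric(nrow(cond))
  ch <- cl <- logical(nrow(cond))
  if (cfg$mode == "dual") {
    for (i in seq_len(nrow(cond))) {
      sh <- equilibrate_g1(params, cond$glucose[i], cond$galactose[i],
                           inits$on, cfg)
      sl <- equilibrate_g1(params, cond$glucose[i], cond$galactose[i],
                           inits$off, cfg)
      hi[i] <- max(sh[["G1"]], sl[["G1"]])
      lo[i] <- min(sh[["G1"]], sl[["G1"]])
      ch[i] <- attr(sh, "converged")
      cl[i] <- attr(sl, "converged")
    }
  } else {
    ## titration: continuation along the galactose ladder per glucose row
    for (g in unique(cond$glucose)) {
      idx <- which(cond$glucose == g)
      idx_up <- idx[order(cond$galactose[idx])]       # low -> high, OFF seed
      idx_dn <- rev(idx_up)                           # high -> low, ON seed
      seed <- inits$off
      for (i in idx_up) {
        seed <- equilibrate_g1(params, g, cond$galactose[i], seed, cfg)
        lo[i] <- seed[["G1"]]
        cl[i] <- attr(seed, "converged")
      }
      seed <- inits$on
      for (i in idx_dn) {
        seed <- equilibrate_g1(params, g, cond$galactose[i], seed, cfg)
        hi[i] <- seed[["G1"]]
        ch[i] <- attr(seed, "converged")
      }
      swap <- hi[idx] < lo[idx]
      if (any(swap)) {
        j <- idx[swap]
        tmp <- hi[j]; hi[j] <- lo[j]; lo[j] <- tmp
      }
    }
  }

  masked <- mask | !ch | !cl
  if (any(!ch | !cl)) {
    inform(sprintf("simulate_grid: %d condition(s) did not converge and were masked.",
                   sum(!ch | !cl)))
  }
  peak <- if (all(masked)) 0 else max(hi[!masked])
  if (peak <= 0) {
    warn("All-zero induction profile; normalized levels set to 0.")
    nh <- nl <- rep(0, length(hi))
    modality <- rep("unimodal_OFF", length(hi))
  } else {
    nh <- hi / peak
    nl <- lo / peak
    modality <- classify_modality(hi, lo, peak / 2, cfg$fold_threshold,
                                  cfg$epsilon)
  }
  out <- tibble::tibble(
    glucose = cond$glucose, galactose = cond$galactose,
    g1_high = hi, g1_low = lo,
    converged_high = ch, converged_low = cl,
    normalized_high = nh, normalized_low = nl,
    modality = modality, masked = masked
  )
  class(out) <- c("induction_profile", class(out))
  attr(out, "grid") <- grid
  attr(out, "params") <- params
  out
}

#' Extract the decision front of an induction profile
#'
#' For each glucose level, locates the pair of adjacent nonzero galactose
#' ladder points whose normalized high levels bracket 0.5 and interpolates
#' the crossing log-linearly in galactose. Rows that never span 0.5 are
#' absent from the result.
#'
#' @param profile an `induction_profile` from [simulate_grid()].
#' @return tibble of class `decision_front` with columns `glucose`,
#'   `galactose_crossing`.
#' @export
decision_front <- function(profile) {
  rows <- list()
  for (g in unique(profile$glucose)) {
    sub <- profile[profile$glucose == g & profile$galactose > 0 &
                     !profile$masked, ]
    sub <- sub[order(sub$galactose), ]
    if (nrow(sub) < 2) next
    v <- sub$normalized_high
    cross <- which(v[-length(v)] < 0.5 & v[-1] >= 0.5)
    if (length(cross) == 0) next
    i <- cross[1]
    lg <- log(sub$galactose[i]) +
      (0.5 - v[i]) / (v[i + 1] - v[i]) *
        (log(sub$galactose[i + 1]) - log(sub$galactose[i]))
    rows[[length(rows) + 1]] <- tibble::tibble(glucose = g,
                                               galactose_crossing = exp(lg))
  }
  out <- if (length(rows) == 0) {
    tibble::tibble(glucose = numeric(), galactose_crossing = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  class(out) <- c("decision_front", class(out))
  out
}

#' Induction ratio of a decision front
#'
#' The representative external glucose/galactose concentration ratio along
#' the decision front: the median over front rows (excluding the
#' zero-glucose row) of `glucose / galactose_crossing`, reported both raw
#' and snapped to the nearest power of two.
#'
#' @param front a `decision_front` with at least two crossings.
#' @return list with elements `ratio` (snapped to a power of 2) and `raw`.
#' @export
induction_ratio <- function(front) {
  f <- front[front$glucose > 0, ]
  if (nrow(f) < 2) {
    abort("Induction ratio undefined: fewer than two decision-front crossings.")
  }
  raw <- stats::median(f$glucose / f$galactose_crossing)
  list(ratio = 2^round(log2(raw)), raw = raw)
}
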