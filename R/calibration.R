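#' Match strain-table conditions to grid conditions
#'
#' @noRd
match_conditions <- function(table, grid) {
  cond <- grid_conditions(grid)
  idx <- integer(nrow(table))
  for (i in seq_len(nrow(table))) {
    dg <- abs(cond$glucose - table$glucose[i]) /
      pmax(abs(cond$glucose), 1e-12)
    da <- abs(cond$galactose - table$galactose[i]) /
      pmax(abs(cond$galactose), 1e-12)
    dg[cond$glucose == 0 & table$glucose[i] == 0] <- 0
    da[cond$galactose == 0 & table$galactose[i] == 0] <- 0
    j <- which(dg < 1e-6 & da < 1e-6)
    if (length(j) != 1) {
      near <- which.min(pmax(dg, da))
      abort(sprintf(paste0("Condition (%g%% glucose, %g%% galactose) does not ",
                           "match the grid; nearest grid condition is ",
                           "(%g, %g)."),
                    table$glucose[i], table$galactose[i],
                    cond$glucose[near], cond$galactose[near]))
    }
    idx[i] <- j
  }
  idx
}

objective_from_profile <- function(profile, table) {
  idx <- match(paste(signif(table$glucose, 9), signif(table$galactose, 9)),
               paste(signif(profile$glucose, 9), signif(profile$galactose, 9)))
  if (any(is.na(idx))) abort("Strain table conditions not aligned with the simulated grid.")
  use <- table$valid & !profile$masked[idx]
  if (!any(use)) abort("No valid conditions to score.")
  sum((table$on_peak[use] - profile$normalized_high[idx[use]])^2) +
    sum((table$off_peak[use] - profile$normalized_low[idx[use]])^2)
}

#' Mean squared deviation objective against a strain table
#'
#' Simulates the induction profile of `params` on `grid` and scores it
#' against the measured (or synthetic) ON/OFF peak positions: the sum of
#' squared residuals of the normalized high steady states against the ON
#' peaks plus the squared residuals of the normalized low steady states
#' against the OFF peaks, over conditions that are valid in the table and
#' unmasked in the simulation.
#'
#' @param params a `gal_params` object.
#' @param table a strain table (see [generate_strain_table()] /
#'   [read_strain_table()]).
#' @param grid a [sugar_grid()] whose conditions cover the table.
#' @param cfg a [solver_config()].
#' @param profile optionally, a precomputed `induction_profile` for
#'   `params` on `grid` (skips the simulation).
#' @return non-negative scalar objective.
#' @export
objective <- function(params, table, grid = sugar_grid(),
                      cfg = solver_config(), profile = NULL) {
  if (is.null(profile)) {
    profile <- suppressMessages(simulate_grid(params, grid, cfg))
  }
  objective_from_profile(profile, table)
}

#' Simultaneous multi-strain objective
#'
#' Scores one shared parameter vector against several strains at once.
#' Each strain spec applies its own knockouts (and optional absolute
#' parameter overrides) to the shared vector before simulation, mirroring
#' joint fits in which all strains share kinetics except the synthesis
#' rates of deleted genes.
#'
#' @param shared_params a `gal_params` object.
#' @param strain_specs list of lists with elements `table` (strain table),
#'   `knockouts` (character, optional) and `overrides` (named numeric of
#'   absolute replacement values, optional).
#' @inheritParams objective
#' @return list with `total` and named numeric `per_strain`.
#' @export
multi_strain_objective <- function(shared_params, strain_specs,
                                   grid = sugar_grid(),
                                   cfg = solver_config()) {
  if (length(strain_specs) == 0) abort("At least one strain is required.")
  per <- vapply(strain_specs, function(sp) {
    p <- shared_params
    ov <- sp$overrides
    if (length(ov) > 0) {
      x <- stats::setNames(as.numeric(p), names(p))
      x[names(ov)] <- as.numeric(ov)
      p <- gal_params(x, knockouts = knockouts(p))
    }
    for (g in sp$knockouts %||% character()) p <- apply_knockout(p, g)
    objective(p, sp$table, grid, cfg)
  }, numeric(1))
  ids <- vapply(seq_along(strain_specs), function(i) {
    strain_specs[[i]]$table$strain_id[1] %||% paste0("strain", i)
  }, character(1))
  names(per) <- ids
  list(total = sum(per), per_strain = per)
}

#' Log-normal priors centered on a parameter set
#'
#' @param center a `gal_params` object (or named numeric) giving prior
#'   centers.
#' @param sd_decades prior standard deviation in log10 decades.
#' @param names parameters to include (default: the free parameters).
#' @return named list of `c(center, sd)` pairs in log10 space.
#' @export
default_priors <- function(center = reference_parameters(), sd_decades = 1,
                           names = free_param_names()) {
  out <- lapply(names, function(nm) {
    c(center = log10(as.numeric(center[[nm]])), sd = sd_decades)
  })
  stats::setNames(out, names)
}

#' Log posterior of a parameter set given strain tables
#'
#' The Gaussian likelihood applied to the stacked residual vector gives
#' `-Obj / sigma^2`; log-normal priors are evaluated in log10 parameter
#' space. A non-positive value for a parameter carrying a log-normal
#' prior yields `-Inf` (rejected state).
#'
#' @param params a `gal_params` object.
#' @param strain_specs as in [multi_strain_objective()]; may be an empty
#'   list for a prior-only score.
#' @param priors named list of `c(center, sd)` in log10 space (see
#'   [default_priors()]), or `NULL` for flat priors.
#' @param sigma residual standard deviation on the normalized induction
#'   scale; must be > 0.
#' @inheritParams objective
#' @return scalar log posterior (up to an additive constant), with
#'   attribute `objective` holding the summed objective.
#' @export
log_posterior <- function(params, strain_specs, priors = NULL, sigma = 0.1,
                          grid = sugar_grid(), cfg = solver_config()) {
  if (sigma <= 0) abort("sigma must be > 0.")
  lp_prior <- 0
  if (!is.null(priors)) {
    for (nm in names(priors)) {
      v <- as.numeric(params[[nm]])
      if (v <= 0) {
        out <- -Inf
        attr(out, "objective") <- Inf
        return(out)
      }
      pr <- priors[[nm]]
      lp_prior <- lp_prior + stats::dnorm(log10(v), pr[["center"]],
                                          pr[["sd"]], log = TRUE)
    }
  }
  obj <- if (length(strain_specs) == 0) 0 else {
    multi_strain_objective(params, strain_specs, grid, cfg)$total
  }
  out <- -obj / sigma^2 + lp_prior
  attr(out, "objective") <- obj
  out
}

#' Metropolis-Hastings sampling configuration
#'
#' @param free names of the free parameters sampled by the chain.
#' @param step proposal standard deviation per parameter, in log10
#'   decades.
#' @param n_steps chain length (post-initialization proposals).
#' @param burn_in number of initial steps discarded by summaries.
#' @param sigma likelihood standard deviation (normalized induction
#'   scale).
#' @param priors prior list as in [log_posterior()]; `"default"` builds
#'   log-normal priors centered on the packaged reference values with a
#'   1-decade sd; `NULL` means flat.
#' @param seed integer seed; mandatory for reproducibility.
#' @return list of class `gal_fit_config`.
#' @export
fit_config <- function(free = "kf83", step = 0.1, n_steps = 500,
                       burn_in = floor(n_steps / 5), sigma = 0.1,
                       priors = "default", seed = 1) {
  bad <- setdiff(free, .gal_param_names)
  if (length(bad) > 0) {
    abort(paste0("Unknown free parameter(s): ", paste(bad, collapse = ", ")))
  }
  if (any(free %in% .gal_hill)) {
    warn("Hill coefficients are normally structural; sampling them is an explicit override.")
  }
  structure(list(free = free, step = step, n_steps = as.integer(n_steps),
                 burn_in = as.integer(burn_in), sigma = sigma,
                 priors = priors, seed = as.integer(seed)),
            class = "gal_fit_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Metropolis-Hastings sampler in log10 parameter space
#'
#' Random-walk Metropolis with independent Gaussian proposals of standard
#' deviation `cfg$step` per free parameter, applied in log10 space (which
#' also enforces positivity). A proposal is accepted with probability
#' `min(1, exp(delta log posterior))`. The best-so-far state is tracked by
#' objective when the log-posterior function attaches an `objective`
#' attribute (ties keep the earlier state), otherwise by log posterior.
#' The chain is fully determined by `cfg$seed`.
#'
#' @param log_posterior_fn function taking a named numeric vector of free
#'   parameter values (natural scale) and returning the log posterior,
#'   optionally with an `objective` attribute.
#' @param init_params named numeric vector of initial free values
#'   (natural scale) with finite log posterior.
#' @param cfg a [fit_config()].
#' @return object of class `gal_chain`: list with `draws` (tibble: step,
#'   log_posterior, objective, accepted, one column per free parameter in
#'   log10), `best` (list: params, objective, log_posterior, step),
#'   `acceptance_rate`, `config`.
#' @export
mh_sample <- function(log_posterior_fn, init_params, cfg) {
  if (cfg$n_steps < 1) abort("Chain length must be at least 1.")
  free <- cfg$free
  theta <- log10(as.numeric(init_params[free]))
  names(theta) <- free
  lp <- log_posterior_fn(10^theta)
  if (!is.finite(lp)) abort("Initial parameters have non-finite log posterior.")
  obj <- attr(lp, "objective") %||% -as.numeric(lp)

  n <- cfg$n_steps
  draws <- matrix(NA_real_, n + 1, length(free),
                  dimnames = list(NULL, free))
  lps <- objs <- numeric(n + 1)
  acc <- logical(n + 1)
  draws[1, ] <- theta
  lps[1] <- lp; objs[1] <- obj; acc[1] <- TRUE
  best <- list(theta = theta, objective = obj, log_posterior = as.numeric(lp),
               step = 0L)

  with_seed(cfg$seed, {
    for (s in seq_len(n)) {
      prop <- theta + stats::rnorm(length(free), 0, cfg$step)
      names(prop) <- free
      lp_new <- log_posterior_fn(10^prop)
      accept <- is.finite(lp_new) &&
        log(stats::runif(1)) < (as.numeric(lp_new) - as.numeric(lp))
      if (accept) {
        theta <- prop; lp <- lp_new
        obj <- attr(lp_new, "objective") %||% -as.numeric(lp_new)
        if (obj < best$objective) {
          best <- list(theta = theta, objective = obj,
                       log_posterior = as.numeric(lp), step = s)
        }
      }
      draws[s + 1, ] <- theta
      lps[s + 1] <- as.numeric(lp); objs[s + 1] <- obj; acc[s + 1] <- accept
    }
  })

  rate <- mean(acc[-1])
  if (rate < 0.05 || rate > 0.8) {
    warn(sprintf("MH acceptance rate %.2f outside (0.05, 0.8); consider adjusting the proposal step.", rate))
  }
  out <- list(
    draws = tibble::as_tibble(cbind(
      tibble::tibble(step = 0:n, log_posterior = lps, objective = objs,
                     accepted = acc),
      tibble::as_tibble(draws)
    )),
    best = list(params = stats::setNames(10^best$theta, free),
                objective = best$objective,
                log_posterior = best$log_posterior, step = best$step),
    acceptance_rate = rate,
    config = cfg
  )
  class(out) <- "gal_chain"
  out
}

#' @export
print.gal_chain <- function(x, ...) {
  cat(sprintf("<gal_chain> %d steps over {%s}; acceptance %.2f; best objective %.4g at step %d\n",
              nrow(x$draws) - 1, paste(x$config$free, collapse = ", "),
              x$acceptance_rate, x$best$objective, x$best$step))
  invisible(x)
}

#' Fit shared parameters to a strain panel by MCMC
#'
#' Runs [mh_sample()] over the configured free parameters on the
#' multi-strain posterior and returns the best-so-far parameter set (by
#' objective) together with per-strain objectives at the optimum. With an
#' empty free list the initial parameters are returned after a single
#' objective evaluation.
#'
#' @param panel list of strain specs as in [multi_strain_objective()].
#' @param init_params a `gal_params` starting point.
#' @param cfg a [fit_config()].
#' @inheritParams objective
#' @return object of class `gal_fit`: list with `best_params`
#'   (`gal_params`), `objective`, `per_strain`, `chain`, `config`.
#' @export
fit_strains <- function(panel, init_params, cfg = fit_config(),
                        grid = sugar_grid(), cfg_solver = solver_config()) {
  priors <- cfg$priors
  if (identical(priors, "default")) {
    priors <- default_priors(init_params, names = cfg$free)
  }
  base <- stats::setNames(as.numeric(init_params), names(init_params))
  score <- function(free_vals) {
    x <- base
    x[names(free_vals)] <- free_vals
    tryCatch({
      p <- gal_params(x, knockouts = knockouts(init_params))
      log_posterior(p, panel, priors = priors, sigma = cfg$sigma,
                    grid = grid, cfg = cfg_solver)
    }, error = function(e) {
      out <- -Inf
      attr(out, "objective") <- Inf
      out
    })
  }
  if (length(cfg$free) == 0) {
    per <- multi_strain_objective(init_params, panel, grid, cfg_solver)
    out <- list(best_params = init_params, objective = per$total,
                per_strain = per$per_strain, chain = NULL, config = cfg)
    class(out) <- "gal_fit"
    return(out)
  }
  chain <- mh_sample(score, stats::setNames(as.numeric(init_params[cfg$free]),
                                            cfg$free), cfg)
  x <- base
  x[cfg$free] <- chain$best$params
  best <- gal_params(x, knockouts = knockouts(init_params))
  per <- multi_strain_objective(best, panel, grid, cfg_solver)
  out <- list(best_params = best, objective = per$total,
              per_strain = per$per_strain, chain = chain, config = cfg)
  class(out) <- "gal_fit"
  out
}

#' @export
print.gal_fit <- function(x, ...) {
  cat(sprintf("<gal_fit> total objective %.4g over %d strain(s)\n",
              x$objective, length(x$per_strain)))
  for (nm in names(x$per_strain)) {
    cat(sprintf("  %-12s Obj = %.4g\n", nm, x$per_strain[[nm]]))
  }
  if (!is.null(x$chain)) print(x$chain)
  invisible(x)
}
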