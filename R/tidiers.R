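#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Metropolis-Hastings chain
#'
#' One row per free parameter with posterior summaries over the
#' post-burn-in draws (natural scale).
#'
#' @param x a `gal_chain`.
#' @param ... unused.
#' @return tibble with columns `parameter`, `estimate` (posterior
#'   median), `mean`, `sd` (both in log10 space), `conf.low`,
#'   `conf.high` (central 95%, natural scale), `best` (best-so-far
#'   value).
#' @export
tidy.gal_chain <- function(x, ...) {
  keep <- x$draws$step > x$config$burn_in
  dplyr::bind_rows(lapply(x$config$free, function(nm) {
    th <- x$draws[[nm]][keep]
    tibble::tibble(parameter = nm,
                   estimate = stats::median(10^th),
                   mean = mean(th), sd = stats::sd(th),
                   conf.low = stats::quantile(10^th, 0.025, names = FALSE),
                   conf.high = stats::quantile(10^th, 0.975, names = FALSE),
                   best = x$best$params[[nm]])
  }))
}

#' @rdname tidy.gal_chain
#' @return `glance()`: one-row tibble with chain length, acceptance rate,
#'   best objective and best log posterior.
#' @export
glance.gal_chain <- function(x, ...) {
  tibble::tibble(n_steps = nrow(x$draws) - 1L,
                 acceptance_rate = x$acceptance_rate,
                 best_objective = x$best$objective,
                 best_log_posterior = x$best$log_posterior)
}

#' Tidy a multi-strain fit
#'
#' @param x a `gal_fit`.
#' @param ... unused.
#' @return one row per fitted free parameter (plus chain summaries when a
#'   chain was run).
#' @export
tidy.gal_fit <- function(x, ...) {
  if (is.null(x$chain)) {
    return(tibble::tibble(parameter = character(), estimate = numeric()))
  }
  tidy(x$chain)
}

#' @rdname tidy.gal_fit
#' @export
glance.gal_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective,
                 n_strains = length(x$per_strain),
                 acceptance_rate = x$chain$acceptance_rate %||% NA_real_)
}
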