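#' Specification of a synthetic strain
#'
#' A synthetic strain is a base genotype plus multiplicative parameter
#' modifications, gene knockouts, Gaussian measurement noise on the
#' normalized induction scale, and a mandatory seed, so that any
#' generated table is regenerable bit-exactly from its spec.
#'
#' @param strain_id strain identifier.
#' @param modifications named numeric vector of strictly positive
#'   multipliers (may be empty).
#' @param knockouts character vector of deleted genes.
#' @param noise_sd Gaussian noise standard deviation on the normalized
#'   scale (default 0.05).
#' @param seed integer seed (mandatory).
#' @return list of class `gal_strain_spec`.
#' @export
strain_spec <- function(strain_id, modifications = NULL,
                        knockouts = character(), noise_sd = 0.05, seed) {
  if (missing(seed)) abort("A seed is mandatory for a strain spec.")
  if (length(modifications) > 0) {
    m <- unlist(modifications)
    if (any(m <= 0)) abort("Multipliers must be > 0.")
    unknown <- setdiff(names(m), .gal_param_names)
    if (length(unknown) > 0) {
      abort(paste0("Unknown parameter(s): ", paste(unknown, collapse = ", ")))
    }
    modifications <- m
  }
  structure(list(strain_id = as.character(strain_id),
                 modifications = modifications,
                 knockouts = validate_knockouts(knockouts),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "gal_strain_spec")
}

#' Generate a synthetic strain induction table
#'
#' Simulates the spec's variant genotype over the grid, adds Gaussian
#' measurement noise (truncated at zero) to the normalized ON/OFF peak
#' positions, re-normalizes so the maximum valid ON peak is 1, and
#' applies the growth mask. Non-convergent conditions are emitted with
#' `valid = FALSE`. Deterministic under the spec's seed.
#'
#' @param spec a [strain_spec()].
#' @param base base `gal_params` (default: the packaged reference set).
#' @param grid a [sugar_grid()].
#' @param cfg a [solver_config()].
#' @return a strain table: tibble with columns `strain_id`, `glucose`,
#'   `galactose`, `on_peak`, `off_peak`, `valid`; the generating spec is
#'   attached as attribute `spec`.
#' @export
generate_strain_table <- function(spec, base = reference_parameters(),
                                  grid = sugar_grid(),
                                  cfg = solver_config()) {
  params <- make_variant(base, spec$modifications, spec$knockouts)
  prof <- suppressMessages(simulate_grid(params, grid, cfg))
  if (max(prof$g1_high[!prof$masked], 0) <= 0) {
    abort("Degenerate all-zero induction profile; check the spec's parameters.")
  }
  on_peak <- prof$normalized_high
  off_peak <- prof$normalized_low
  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      on_peak <- pmax(on_peak + stats::rnorm(length(on_peak), 0, spec$noise_sd), 0)
      off_peak <- pmax(off_peak + stats::rnorm(length(off_peak), 0, spec$noise_sd), 0)
    })
  }
  off_peak <- pmin(off_peak, on_peak)  # peak ordering survives noise
  valid <- !prof$masked
  peak <- max(on_peak[valid], 0)
  if (peak > 0) {
    on_peak <- on_peak / peak
    off_peak <- off_peak / peak
  }
  out <- tibble::tibble(strain_id = spec$strain_id,
                        glucose = prof$glucose, galactose = prof$galactose,
                        on_peak = on_peak, off_peak = off_peak,
                        valid = valid)
  attr(out, "spec") <- spec
  out
}

#' Default synthetic strain panel
#'
#' The packaged panel emulates the strains a mechanistic survey isolates:
#' the base strain, the `mig1` and `gal80` deletions, and three variants
#' tuned in the three mechanisms that shift the decision front — HXT
#' relative affinity (`rHXT` / 10), Gal3p-Gal80p binding (`kf83` x 10),
#' and galactose-Gal3p binding (`kf3` x 10).
#'
#' @param noise_sd noise level shared by all members.
#' @param seed base seed; member seeds are derived deterministically.
#' @return named list of [strain_spec()]s.
#' @export
default_panel_specs <- function(noise_sd = 0.05, seed = 101) {
  specs <- list(
    base      = strain_spec("base", NULL, character(), noise_sd, seed + 1),
    mig1d     = strain_spec("mig1d", NULL, "MIG1", noise_sd, seed + 2),
    gal80d    = strain_spec("gal80d", NULL, "GAL80", noise_sd, seed + 3),
    rHXT_low  = strain_spec("rHXT_low", c(rHXT = 0.1), character(),
                            noise_sd, seed + 4),
    kf83_high = strain_spec("kf83_high", c(kf83 = 10), character(),
                            noise_sd, seed + 5),
    kf3_high  = strain_spec("kf3_high", c(kf3 = 10), character(),
                            noise_sd, seed + 6)
  )
  specs
}

#' Generate a panel of synthetic strain tables
#'
#' @param specs list of [strain_spec()]s (default:
#'   [default_panel_specs()]).
#' @inheritParams generate_strain_table
#' @return named list of strain tables.
#' @export
generate_panel <- function(specs = default_panel_specs(),
                           base = reference_parameters(),
                           grid = sugar_grid(), cfg = solver_config()) {
  if (length(specs) == 0) abort("Panel spec list must be non-empty.")
  out <- lapply(specs, generate_strain_table, base = base, grid = grid,
                cfg = cfg)
  names(out) <- vapply(out, function(t) t$strain_id[1], character(1))
  out
}
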