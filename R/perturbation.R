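#' Bimodal-range boundaries along a galactose titration
#'
#' At a fixed glucose concentration, sweeps the galactose ladder in both
#' directions by continuation (the previous steady state seeds the next
#' ladder point): low-to-high seeded from the OFF state gives the low
#' branch, high-to-low seeded from the ON state gives the high branch.
#' Each ladder point is classified as unimodal OFF, bimodal, or unimodal
#' ON and the emergence (`gal_on`: lowest bimodal galactose) and
#' full-induction (`gal_full`: lowest unimodal-ON galactose) boundaries
#' are reported.
#'
#' @param params a `gal_params` object.
#' @param glucose fixed glucose concentration (% w/v).
#' @param gal_ladder strictly increasing, strictly positive galactose
#'   concentrations (default: the nonzero twofold ladder of the default
#'   grid).
#' @param cfg a [solver_config()].
#' @param inits optional precomputed [on_off_inits()] result.
#' @param half_max absolute Gal1p level separating unimodal ON from
#'   unimodal OFF for non-bimodal points. Defaults to half the ladder's
#'   own high-branch peak; when comparing a perturbed system against a
#'   reference, pass half the reference peak so that a uniformly
#'   repressed system classifies as unimodal OFF rather than as induced
#'   relative to its own collapsed scale.
#' @return list of class `bimodal_boundaries` with fields `gal_on`,
#'   `gal_full` (each `NA` when absent), `always_off`, `always_bimodal`,
#'   `modality` (per ladder point), `level_at_max` (high-branch Gal1p
#'   level at the top of the ladder), `peak_level`, `ladder`.
#' @export
bimodal_boundaries <- function(params, glucose, gal_ladder = NULL,
                               cfg = solver_config(), inits = NULL,
                               half_max = NULL) {
  cfg <- as_solver_config(cfg)
  gal_ladder <- gal_ladder %||% sort(sugar_grid()$galactose[sugar_grid()$galactose > 0])
  if (any(diff(gal_ladder) <= 0) || any(gal_ladder <= 0)) {
    abort("gal_ladder must be strictly increasing and positive.")
  }
  inits <- inits %||% on_off_inits(params, cfg)
  n <- length(gal_ladder)
  hi <- lo <- numeric(n)
  ok <- rep(TRUE, n)
  seed <- inits$off
  for (i in seq_len(n)) {
    seed <- equilibrate(params, sugar_condition(glucose, gal_ladder[i]),
                        seed, cfg)
    lo[i] <- seed[["G1"]]
    ok[i] <- ok[i] && attr(seed, "converged")
  }
  seed <- inits$on
  for (i in rev(seq_len(n))) {
    seed <- equilibrate(params, sugar_condition(glucose, gal_ladder[i]),
                        seed, cfg)
    hi[i] <- seed[["G1"]]
    ok[i] <- ok[i] && attr(seed, "converged")
  }
  swap <- hi < lo
  if (any(swap)) {
    tmp <- hi[swap]; hi[swap] <- lo[swap]; lo[swap] <- tmp
  }
  peak <- max(hi[ok], 0)
  thr <- half_max %||% (peak / 2)
  modality <- rep(NA_character_, n)
  if (thr > 0) {
    modality[ok] <- classify_modality(hi[ok], lo[ok], thr,
                                      cfg$fold_threshold, cfg$epsilon)
  } else {
    modality[ok] <- "unimodal_OFF"
  }
  i_on <- which(modality == "bimodal")[1]
  i_full <- which(modality == "unimodal_ON")[1]
  out <- list(
    gal_on = if (is.na(i_on)) NA_real_ else gal_ladder[i_on],
    gal_full = if (is.na(i_full)) NA_real_ else gal_ladder[i_full],
    always_off = all(modality == "unimodal_OFF", na.rm = TRUE),
    always_bimodal = is.na(i_full) && !is.na(i_on),
    modality = modality,
    level_at_max = hi[n],
    peak_level = peak,
    ladder = gal_ladder
  )
  class(out) <- "bimodal_boundaries"
  out
}

sentinel_cap <- function(ladder) 2 * max(ladder)

#' Log2 shift of the bimodality-emergence boundary
#'
#' `delta_on = log2(gal_on' / gal_on)`: positive when the perturbation
#' makes bimodality emerge at higher galactose (more repressed), negative
#' when at lower galactose (more inducible). A perturbation that
#' eliminates bimodality entirely (unimodal OFF everywhere) is reported at
#' the positive sentinel cap, one twofold step beyond the ladder maximum,
#' with the `degenerate` attribute set; a perturbation that is induced
#' over the whole ladder maps to the symmetric negative cap.
#'
#' @param ref,pert `bimodal_boundaries` for the reference and perturbed
#'   parameter sets (same ladder); `ref$gal_on` must be present.
#' @return log2 shift with attribute `degenerate` (logical).
#' @export
#' @examples
#' b <- function(on, full) structure(list(gal_on = on, gal_full = full,
#'   always_off = FALSE, always_bimodal = FALSE,
#'   ladder = 4 / 2^(10:0)), class = "bimodal_boundaries")
#' delta_on(b(0.0625, 0.25), b(0.25, 1))  # +2
delta_on <- function(ref, pert) {
  if (is.na(ref$gal_on)) {
    abort("delta_on undefined: reference has no bimodality-emergence boundary.")
  }
  if (pert$always_off) {
    out <- log2(sentinel_cap(ref$ladder) / ref$gal_on)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (is.na(pert$gal_on)) {
    ## bimodality never emerges because the system is already induced at
    ## the ladder minimum: symmetric negative cap
    out <- log2((min(ref$ladder) / 2) / ref$gal_on)
    attr(out, "degenerate") <- FALSE
    return(out)
  }
  out <- log2(pert$gal_on / ref$gal_on)
  attr(out, "degenerate") <- FALSE
  out
}

#' Log2 shift of the full-induction boundary
#'
#' `delta_full = log2(gal_full' / gal_full)`. Degeneration of the
#' perturbed system to unimodal OFF maps to the positive sentinel cap with
#' the `degenerate` attribute set. A system that remains bimodal at the
#' ladder maximum has no full-induction boundary; by convention it is
#' placed one twofold step beyond the ladder maximum.
#'
#' @inheritParams delta_on
#' @return log2 shift with attribute `degenerate` (logical).
#' @export
delta_full <- function(ref, pert) {
  cap <- sentinel_cap(ref$ladder)
  ref_full <- if (is.na(ref$gal_full)) cap else ref$gal_full
  if (pert$always_off) {
    out <- log2(cap / ref_full)
    if (out <= 0) out <- 1  # degeneration is always reported positive
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  pert_full <- if (is.na(pert$gal_full)) cap else pert$gal_full
  out <- log2(pert_full / ref_full)
  attr(out, "degenerate") <- FALSE
  out
}

#' Relative change of the full-induction level
#'
#' `delta_level = (level' - level) / level`, where levels are the
#' un-normalized high-branch Gal1p steady states at the highest ladder
#' galactose for the fixed glucose concentration. Positive values indicate
#' elevated induction.
#'
#' @param ref_level,pert_level reference and perturbed levels;
#'   `ref_level` must be > 0.
#' @return dimensionless change, bounded below by -1 for non-negative
#'   levels.
#' @export
delta_level <- function(ref_level, pert_level) {
  if (is.na(ref_level) || ref_level <= 0) {
    abort("delta_level undefined for a zero reference level.")
  }
  (pert_level - ref_level) / ref_level
}

#' Build the parameter-perturbation matrix
#'
#' Applies every multiplicative perturbation (free parameter x factor) to
#' the reference set and records the three bimodal-range metrics
#' (`delta_on`, `delta_full`, `delta_level`) at each fixed glucose level.
#' With the default 36 free parameters and 6 factors the matrix has 216
#' rows and 3 x 8 = 24 metric columns.
#'
#' @param params reference `gal_params`.
#' @param free_names parameters to perturb (default: the 36 free,
#'   non-Hill parameters).
#' @param factors multiplicative perturbation factors (default
#'   `c(0.01, 0.1, 0.5, 2, 10, 100)`).
#' @param glucose_levels fixed glucose concentrations (default: the 8
#'   levels of the default grid, including zero).
#' @param gal_ladder galactose titration ladder (default: the nonzero
#'   twofold ladder).
#' @param cfg a [solver_config()].
#' @return tibble of class `perturbation_matrix`: columns `parameter`,
#'   `factor`, `degenerate` (any glucose level degenerated to unimodal
#'   OFF), then `delta_on_g*`, `delta_full_g*`, `delta_level_g*` per
#'   glucose level. Metrics whose reference boundary is undefined are
#'   `NA`.
#' @export
build_perturbation_matrix <- function(params,
                                      free_names = free_param_names(),
                                      factors = c(0.01, 0.1, 0.5, 2, 10, 100),
                                      glucose_levels = sugar_grid()$glucose,
                                      gal_ladder = NULL,
                                      cfg = solver_config()) {
  cfg <- as_solver_config(cfg)
  gal_ladder <- gal_ladder %||%
    sort(sugar_grid()$galactose[sugar_grid()$galactose > 0])
  glucose_levels <- sort(glucose_levels, decreasing = TRUE)
  ref <- lapply(glucose_levels, function(g) {
    bimodal_boundaries(params, g, gal_ladder, cfg)
  })
  gtag <- paste0("g", signif(glucose_levels, 3))

  one_row <- function(nm, f) {
    pert_params <- try(make_variant(params, stats::setNames(f, nm)),
                       silent = TRUE)
    vals <- stats::setNames(
      rep(NA_real_, 3 * length(glucose_levels)),
      c(paste0("delta_on_", gtag), paste0("delta_full_", gtag),
        paste0("delta_level_", gtag)))
    degen <- FALSE
    if (!inherits(pert_params, "try-error")) {
      pinits <- try(on_off_inits(pert_params, cfg), silent = TRUE)
      for (k in seq_along(glucose_levels)) {
        pb <- try(bimodal_boundaries(pert_params, glucose_levels[k],
                                     gal_ladder, cfg,
                                     inits = if (!inherits(pinits, "try-error")) pinits,
                                     half_max = ref[[k]]$peak_level / 2),
                  silent = TRUE)
        if (inherits(pb, "try-error")) next
        if (!is.na(ref[[k]]$gal_on)) {
          d1 <- delta_on(ref[[k]], pb)
          vals[paste0("delta_on_", gtag[k])] <- as.numeric(d1)
          degen <- degen || isTRUE(attr(d1, "degenerate"))
        }
        d2 <- delta_full(ref[[k]], pb)
        vals[paste0("delta_full_", gtag[k])] <- as.numeric(d2)
        degen <- degen || isTRUE(attr(d2, "degenerate"))
        if (!is.na(ref[[k]]$level_at_max) && ref[[k]]$level_at_max > 0) {
          vals[paste0("delta_level_", gtag[k])] <-
            delta_level(ref[[k]]$level_at_max, pb$level_at_max)
        }
      }
    }
    c(list(parameter = nm, factor = f, degenerate = degen), as.list(vals))
  }

  rows <- list()
  for (nm in free_names) {
    for (f in factors) rows[[length(rows) + 1]] <- one_row(nm, f)
  }
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  class(out) <- c("perturbation_matrix", class(out))
  attr(out, "glucose_levels") <- glucose_levels
  attr(out, "gal_ladder") <- gal_ladder
  out
}

#' Classify perturbation-matrix rows
#'
#' Rule-based grouping of perturbations following the fold-change
#' language of the survey: `more_inducible` when bimodality emerges at
#' >= 8-fold lower galactose (delta_on <= -3) at `min_rows` or more
#' glucose levels; `more_repressed` when delta_on >= +3 at `min_rows`
#' levels or the system degenerated to unimodal OFF anywhere;
#' `bimodality_insensitive` when all |delta_on| and |delta_full| <= 1 and
#' |delta_level| <= `level_tol`; `other` otherwise (including rows that
#' qualify in both directions).
#'
#' @param matrix a `perturbation_matrix`.
#' @param min_rows minimum number of glucose levels at which the shift
#'   must occur (default 2).
#' @param level_tol tolerance on |delta_level| for the insensitive class.
#' @return the matrix with a `label` column appended.
#' @export
classify_perturbations <- function(matrix, min_rows = 2, level_tol = 0.1) {
  don <- as.matrix(matrix[, grep("^delta_on_", names(matrix))])
  dfu <- as.matrix(matrix[, grep("^delta_full_", names(matrix))])
  dlv <- as.matrix(matrix[, grep("^delta_level_", names(matrix))])
  lab <- character(nrow(matrix))
  for (i in seq_len(nrow(matrix))) {
    ind <- sum(don[i, ] <= -3, na.rm = TRUE) >= min_rows
    rep_ <- sum(don[i, ] >= 3, na.rm = TRUE) >= min_rows || matrix$degenerate[i]
    ins <- all(abs(don[i, ]) <= 1, na.rm = TRUE) &&
      all(abs(dfu[i, ]) <= 1, na.rm = TRUE) &&
      all(abs(dlv[i, ]) <= level_tol, na.rm = TRUE) &&
      !matrix$degenerate[i]
    lab[i] <- if (ind && rep_) "other"
      else if (ind) "more_inducible"
      else if (rep_) "more_repressed"
      else if (ins) "bimodality_insensitive"
      else "other"
  }
  matrix$label <- lab
  matrix
}

#' Two-dimensional embedding of the perturbation matrix
#'
#' Projects the rows of the perturbation matrix to two dimensions by
#' classical multidimensional scaling of pairwise Minkowski row
#' distances. Missing metric cells are imputed as zero for the embedding
#' only (classification uses the raw values). The embedding is
#' deterministic; the `seed` argument is accepted for interface stability
#' with stochastic embeddings.
#'
#' @param matrix a `perturbation_matrix`.
#' @param minkowski_order order of the Minkowski distance (default 2,
#'   Euclidean).
#' @param seed unused by the deterministic embedding; kept so that
#'   configured seeds round-trip.
#' @return tibble with columns `parameter`, `factor`, `x`, `y`.
#' @export
embed_perturbations <- function(matrix, minkowski_order = 2, seed = 1) {
  cols <- grep("^delta_", names(matrix))
  m <- as.matrix(matrix[, cols])
  m[is.na(m)] <- 0
  if (all(apply(m, 2, function(col) diff(range(col)) == 0))) {
    abort("Cannot embed a constant perturbation matrix.")
  }
  dm <- stats::dist(m, method = "minkowski", p = minkowski_order)
  xy <- stats::cmdscale(dm, k = 2)
  tibble::tibble(parameter = matrix$parameter, factor = matrix$factor,
                 x = xy[, 1], y = xy[, 2])
}
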