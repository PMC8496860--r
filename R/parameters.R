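#' @keywords internal
"_PACKAGE"

#' @useDynLib galswitch, .registration = TRUE
#' @importFrom rlang .data abort warn inform
#' @importFrom tibble tibble as_tibble
NULL

## canonical parameter ordering; the compiled ODE core indexes by position
.gal_synthesis <- c("a1", "ag1", "a2", "ag2", "a3", "ag3", "a80", "ag80",
                    "a4", "ag4", "a0HXT", "aHXT", "aR")
.gal_act_thresholds <- c("KG1", "KG2", "KG3", "KG80", "KHXT")
.gal_rep_thresholds <- c("KR1", "KR3", "KR4", "KRs")
.gal_binding <- c("kf3", "kr3", "kf83", "kr83", "kf84", "kr84")
.gal_transport <- c("kG2", "rG2", "KGgluc", "rcat", "rHXT", "KHXTgluc")
.gal_turnover <- c("d", "dsugar")
.gal_hill <- c("n1", "n2", "n3", "n80", "nHXT", "nR1", "nR3", "nR4", "nRs")

.gal_param_names <- c(.gal_synthesis, .gal_act_thresholds, .gal_rep_thresholds,
                      .gal_binding, .gal_transport, .gal_turnover, .gal_hill)

## genes whose deletion is modelled by zeroing synthesis rates
.gal_knockout_map <- list(
  MIG1  = "aR",
  GAL80 = c("a80", "ag80"),
  GAL3  = c("a3", "ag3"),
  GAL2  = c("a2", "ag2"),
  GAL1  = c("a1", "ag1")
)

.gal_state_names <- c("G1", "G2", "G3", "G3s", "G80", "G4", "C83", "C84",
                      "HXT", "Rtot", "gluc_in", "gal_in")

#' Names of the model parameters
#'
#' `param_names()` returns the 45 kinetic parameter names in canonical
#' order; `free_param_names()` returns the 36 non-Hill parameters that are
#' allowed to vary in calibration and in the perturbation survey. Hill
#' coefficients are structural and never part of the free list.
#'
#' @param free logical; return only the free (non-Hill) parameters?
#' @return character vector of parameter names.
#' @export
#' @examples
#' length(param_names())       # 45
#' length(free_param_names())  # 36
param_names <- function(free = FALSE) {
  if (free) setdiff(.gal_param_names, .gal_hill) else .gal_param_names
}

#' @rdname param_names
#' @export
free_param_names <- function() param_names(free = TRUE)

#' Construct a validated model parameter set
#'
#' Builds a `gal_params` object from a named numeric vector holding all 45
#' kinetic constants of the GAL network model. Values must be positive,
#' except that the synthesis rates of genes listed in `knockouts` are
#' structurally zero.
#'
#' @param values named numeric vector with exactly the 45 parameter names
#'   (any order; stored canonically).
#' @param knockouts character vector of deleted genes, subset of
#'   `r paste(names(.gal_knockout_map), collapse = ", ")`.
#' @return a `gal_params` object: a named numeric vector of length 45 with
#'   a `knockouts` attribute.
#' @export
gal_params <- function(values, knockouts = character()) {
  if (is.list(values)) values <- unlist(values)
  if (!is.numeric(values) || is.null(names(values))) {
    abort("`values` must be a named numeric vector of model parameters.")
  }
  unknown <- setdiff(names(values), .gal_param_names)
  if (length(unknown) > 0) {
    abort(paste0("Unknown parameter name(s): ",
                 paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(.gal_param_names, names(values))
  if (length(missing) > 0) {
    abort(paste0("Missing parameter(s): ", paste(missing, collapse = ", ")))
  }
  knockouts <- validate_knockouts(knockouts)
  x <- as.numeric(values[.gal_param_names])
  names(x) <- .gal_param_names
  if (any(!is.finite(x))) abort("All parameters must be finite.")
  allowed_zero <- unlist(.gal_knockout_map[knockouts], use.names = FALSE)
  bad <- names(x)[x <= 0 & !(names(x) %in% allowed_zero)]
  if (length(bad) > 0) {
    abort(paste0("Non-positive value for parameter(s) without a matching ",
                 "knockout: ", paste(bad, collapse = ", ")))
  }
  if (any(x < 0)) abort("Parameters must be non-negative.")
  structure(x, knockouts = knockouts, class = "gal_params")
}

validate_knockouts <- function(knockouts) {
  knockouts <- unique(as.character(knockouts))
  unknown <- setdiff(knockouts, names(.gal_knockout_map))
  if (length(unknown) > 0) {
    abort(paste0("Unknown gene(s): ", paste(unknown, collapse = ", "),
                 ". Supported knockouts: ",
                 paste(names(.gal_knockout_map), collapse = ", ")))
  }
  knockouts
}

#' @export
print.gal_params <- function(x, ...) {
  ko <- attr(x, "knockouts")
  cat("<gal_params> 45 kinetic parameters",
      if (length(ko) > 0) paste0(" [knockouts: ", paste(ko, collapse = ", "), "]"),
      "\n", sep = "")
  print(unclass(structure(as.numeric(x), names = names(x))), ...)
  invisible(x)
}

#' Knockout genes of the parameter set
#' @param params a `gal_params` object.
#' @return character vector of knocked-out gene names.
#' @export
knockouts <- function(params) attr(params, "knockouts") %||% character()

#' Reference kinetic parameter set
#'
#' The packaged default parameter set of the GAL network model. The values
#' are literature-scale placeholders chosen so that the simulated default
#' sugar grid exhibits the three canonical induction regimes (unimodal OFF,
#' bimodal, unimodal ON), a straight log-log decision front, monotone
#' glucose repression, and the expected knockout phenotypes; they are not
#' fitted to any experimental strain table. Time is in model time units
#' (dilution rate `d` sets the protein turnover scale) and external sugars
#' are % w/v.
#'
#' @return a `gal_params` object.
#' @export
#' @examples
#' p <- reference_parameters()
#' p[["kf83"]]
reference_parameters <- function() {
  gal_params(c(
    ## synthesis rates (abundance / time); the regulatory core (Gal3p,
    ## Gal80p, Gal4p) runs at low copy numbers with tight binding, so the
    ## bistable boundary is set by binding equilibria rather than by
    ## complex-turnover flux
    a1 = 0.001, ag1 = 0.5,
    a2 = 0.005, ag2 = 0.8,
    a3 = 0.013, ag3 = 0.12,
    a80 = 0.05, ag80 = 0.02,
    a4 = 0.004, ag4 = 0.016,
    a0HXT = 0.05, aHXT = 0.3,
    aR = 0.1,
    ## Gal4p activation thresholds (free-Gal4p scale)
    KG1 = 0.05, KG2 = 0.05, KG3 = 0.02, KG80 = 0.1, KHXT = 0.2,
    ## repression thresholds (active repressor / intracellular glucose)
    KR1 = 2.5, KR3 = 2.5, KR4 = 2.5, KRs = 0.02,
    ## binding / unbinding
    kf3 = 1, kr3 = 2, kf83 = 20, kr83 = 0.02, kf84 = 20, kr84 = 0.02,
    ## transport
    kG2 = 0.25, rG2 = 2, KGgluc = 0.05, rcat = 0.3, rHXT = 20,
    KHXTgluc = 0.02,
    ## turnover
    d = 0.05, dsugar = 0.25,
    ## Hill coefficients (structural, never free)
    n1 = 2, n2 = 2, n3 = 2, n80 = 2, nHXT = 2,
    nR1 = 2, nR3 = 2, nR4 = 2, nRs = 2
  ))
}

#' Apply a gene knockout to a parameter set
#'
#' Deletion strains are modelled by setting the synthesis rates of the
#' deleted gene to zero: `MIG1` zeroes `aR`; `GAL80` zeroes `a80`, `ag80`;
#' `GAL3` zeroes `a3`, `ag3`; `GAL2` zeroes `a2`, `ag2`; `GAL1` zeroes
#' `a1`, `ag1`. Applying the same knockout twice is a no-op.
#'
#' @param params a `gal_params` object.
#' @param gene gene to delete, one of `"MIG1"`, `"GAL80"`, `"GAL3"`,
#'   `"GAL2"`, `"GAL1"`.
#' @return a modified copy of `params` with the knockout flag recorded.
#' @export
#' @examples
#' p <- apply_knockout(reference_parameters(), "GAL80")
#' p[["a80"]]  # 0
apply_knockout <- function(params, gene) {
  stopifnot(inherits(params, "gal_params"))
  gene <- validate_knockouts(gene)
  if (length(gene) != 1) abort("Apply one knockout at a time.")
  x <- as.numeric(params)
  names(x) <- names(params)
  x[.gal_knockout_map[[gene]]] <- 0
  gal_params(x, knockouts = union(knockouts(params), gene))
}

#' Derive a variant parameter set by multiplicative modification
#'
#' Emulates a strain that differs from a base genotype by fold-changes of
#' named kinetic parameters (and, optionally, gene deletions applied after
#' the fold-changes).
#'
#' @param base a `gal_params` object.
#' @param modifications named numeric vector or list of strictly positive
#'   multipliers, keyed by parameter name. Use `knockouts` for structural
#'   zeros, never a zero multiplier.
#' @param knockouts character vector of genes to delete.
#' @return a new `gal_params` object; `base` is untouched.
#' @export
#' @examples
#' v <- make_variant(reference_parameters(), c(kf83 = 10))
make_variant <- function(base, modifications = NULL, knockouts = character()) {
  stopifnot(inherits(base, "gal_params"))
  x <- as.numeric(base)
  names(x) <- names(base)
  if (length(modifications) > 0) {
    m <- unlist(modifications)
    unknown <- setdiff(names(m), .gal_param_names)
    if (length(unknown) > 0) {
      abort(paste0("Unknown parameter name(s) in modifications: ",
                   paste(unknown, collapse = ", ")))
    }
    if (any(m <= 0)) {
      abort("Multipliers must be > 0; use `knockouts` for structural zeros.")
    }
    x[names(m)] <- x[names(m)] * m
  }
  out <- gal_params(x, knockouts = knockouts(base))
  for (g in validate_knockouts(knockouts)) out <- apply_knockout(out, g)
  out
}

#' Sugar condition constructor
#'
#' @param glucose,galactose external sugar concentrations in % w/v, both
#'   non-negative. Twofold-ladder values should be passed unrounded
#'   (0.03125, not 0.031).
#' @return named numeric vector `c(glucose, galactose)`.
#' @export
sugar_condition <- function(glucose, galactose) {
  if (glucose < 0 || galactose < 0) {
    abort("Sugar concentrations must be non-negative.")
  }
  c(glucose = as.numeric(glucose), galactose = as.numeric(galactose))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
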